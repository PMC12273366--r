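#' Convolutional-channel feature vector of an image
#'
#' Runs the backbone over an image and concatenates, for every counted conv
#' layer (taken after its nonlinearity), the spatial mean of each output
#' channel, in architecture order. The resulting dimension is
#' `sum(conv_channel_list)`: 24 for the default `tiny_cnn`, 7,616 for
#' `resnet34_shape`.
#'
#' @param model An `rfed_model`.
#' @param image `H x W` matrix, or an array/list of images for the batch
#'   version.
#' @return Numeric vector of length `d_feat` ([image_feature_vector()]), or
#'   an `N x d_feat` matrix ([image_feature_matrix()]).
#' @export
image_feature_vector <- function(model, image) {
  drop(image_feature_matrix(model, image))
}

#' @rdname image_feature_vector
#' @export
image_feature_matrix <- function(model, image) {
  x <- as_image_batch(image)
  if (dim(x)[1] != model$spec$input_size && model$spec$name == "tiny_cnn") {
    # tiny_cnn is size-agnostic (global pooling); resnet strides require
    # a minimum size, checked implicitly by the conv kernels.
  }
  model_forward(model, x, want_taps = TRUE)$taps
}

#' Patient-level pooled feature vector
#'
#' The arithmetic mean of the per-image feature vectors over all of one
#' patient's images.
#'
#' @param model An `rfed_model`.
#' @param images List of image matrices (or an array).
#' @return Numeric vector of length `d_feat`.
#' @export
patient_feature_vector <- function(model, images) {
  x <- as_image_batch(images)
  if (dim(x)[4] < 1) stop("patient has no images")
  colMeans(image_feature_matrix(model, x))
}

#' Patient-by-feature matrix for one split
#'
#' @param model An `rfed_model` used as feature extractor.
#' @param split_data Split list (`X`, `y`, `patient`) as produced by
#'   [load_center_data()].
#' @return List of class `rfed_features`: `X` (patients x d_feat), `y`,
#'   `patient_ids`, `feature_names` (layer/channel provenance).
#' @export
feature_matrix <- function(model, split_data) {
  feats <- image_feature_matrix(model, split_data$X)
  pids <- unique(split_data$patient)
  X <- t(vapply(pids, function(p)
    colMeans(feats[split_data$patient == p, , drop = FALSE]),
    numeric(ncol(feats))))
  y <- vapply(pids, function(p) split_data$y[split_data$patient == p][1], 1L)
  ch <- model$spec$conv_channel_list
  fn <- unlist(lapply(seq_along(ch), function(i)
    sprintf("conv%02d_c%03d", i, seq_len(ch[i]))))
  if (any(!is.finite(X))) stop("non-finite feature values")
  structure(list(X = X, y = as.integer(y), patient_ids = pids,
                 feature_names = fn), class = "rfed_features")
}

#' Mutual information between a binned feature and binary labels
#'
#' Plug-in estimate (natural log) after equal-frequency discretization of
#' `x` into at most `bins` bins. A constant feature has zero information.
#'
#' @param x Numeric feature column.
#' @param y Binary labels (0/1).
#' @param bins Number of equal-frequency bins (default 10).
#' @return Non-negative scalar (nats).
#' @export
mutual_information_binned <- function(x, y, bins = 10) {
  n <- length(x)
  if (n != length(y)) stop("x and y lengths differ")
  if (n < bins) stop("need at least as many samples as bins")
  xb <- discretize_ef(x, bins)
  yb <- discretize_ef(y, bins)
  tab <- table(xb, yb) / n
  px <- rowSums(tab); py <- colSums(tab)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py))
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
  max(mi, 0)
}

# Equal-frequency discretization; columns with few distinct values (e.g.
# binary labels) are used as categories directly.
discretize_ef <- function(v, bins) {
  u <- unique(v)
  if (length(u) <= bins) return(match(v, sort(u)))
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(v)))
  cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Greedy minimum-redundancy maximum-relevance feature selection
#'
#' The first feature maximizes mutual information with the label; each
#' subsequent feature maximizes relevance minus (`"MID"`, default) or
#' divided by (`"MIQ"`) the mean mutual information with the already
#' selected features. Ties break to the lowest feature index.
#'
#' @param X Patients-by-features numeric matrix (or an `rfed_features`).
#' @param y Binary labels (ignored when `X` is an `rfed_features`).
#' @param m Number of features to select.
#' @param bins Discretization bins (default 10).
#' @param criterion `"MID"` or `"MIQ"`.
#' @return List of class `rfed_mrmr`: `selected` (ordered indices),
#'   `scores` (criterion value at each step), `bins`, `criterion`.
#' @export
mrmr_select <- function(X, y = NULL, m, bins = 10,
                        criterion = c("MID", "MIQ")) {
  criterion <- match.arg(criterion)
  if (inherits(X, "rfed_features")) { y <- X$y; X <- X$X }
  X <- as.matrix(X)
  d <- ncol(X)
  if (m > d) stop("cannot select more features than available")
  rel <- vapply(seq_len(d), function(j)
    mutual_information_binned(X[, j], y, bins), 1)
  red <- matrix(NA_real_, d, d)   # pairwise MI, filled lazily
  pair_mi <- function(a, b) {
    if (is.na(red[a, b])) {
      v <- mutual_information_binned(X[, a], X[, b], bins)
      red[a, b] <<- v; red[b, a] <<- v
    }
    red[a, b]
  }
  selected <- integer(0)
  scores <- numeric(0)
  for (step in seq_len(m)) {
    cand <- setdiff(seq_len(d), selected)
    crit <- vapply(cand, function(j) {
      if (length(selected) == 0) return(rel[j])
      rd <- mean(vapply(selected, function(s) pair_mi(j, s), 1))
      if (criterion == "MID") rel[j] - rd else rel[j] / max(rd, .Machine$double.eps)
    }, 1)
    best <- cand[which.max(crit)]   # which.max takes the first (lowest index) tie
    selected <- c(selected, best)
    scores <- c(scores, max(crit))
  }
  structure(list(selected = selected, scores = scores, bins = bins,
                 criterion = criterion), class = "rfed_mrmr")
}

#' Bayesian extreme learning machine
#'
#' A single-hidden-layer network whose input weights are fixed random draws
#' `U(-1, 1)` and whose output weights are inferred by Bayesian linear
#' regression on 0/1 targets: the posterior mean is
#' `b_n * solve(a*I + b_n * t(Phi) %*% Phi) %*% t(Phi) %*% y` with
#' `Phi = sigmoid(X %*% t(W_in) + b_in)` plus an intercept column. The
#' prior precision `a` and noise precision `b_n` are updated by
#' evidence maximization (MacKay fixed-point updates) unless
#' `max_evidence_iters = 0`, in which case the fit is exactly ridge
#' regression with penalty `a / b_n`.
#'
#' @param X Training feature matrix (n x m).
#' @param y Binary labels (0/1), both classes present.
#' @param H Hidden units (default 100).
#' @param seed Seed for the random input layer.
#' @param max_evidence_iters Evidence-maximization iterations (default 100).
#' @param tol Relative convergence tolerance on (a, b_n) (default 1e-6).
#' @param a_init,b_init Initial prior/noise precisions.
#' @return List of class `rfed_belm` with `W_in`, `b_in`, `posterior_mean`,
#'   `posterior_cov`, `a`, `b_n`, `seed`.
#' @export
belm_fit <- function(X, y, H = 100, seed = 1, max_evidence_iters = 100,
                     tol = 1e-6, a_init = 1, b_init = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least two training samples")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  m <- ncol(X)
  wi <- with_seed(seed, {
    list(W = matrix(stats::runif(H * m, -1, 1), H, m),
         b = stats::runif(H, -1, 1))
  })
  Phi <- cbind(1, sigmoid(sweep(X %*% t(wi$W), 2, wi$b, `+`)))
  D <- ncol(Phi)
  PtP <- crossprod(Phi)
  Pty <- crossprod(Phi, y)
  eg <- eigen(PtP, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  a <- a_init; b_n <- b_init
  solve_mean <- function(a, b_n) {
    Ainv_diag <- 1 / (a + b_n * lam)
    mw <- eg$vectors %*% (Ainv_diag * crossprod(eg$vectors, Pty)) * b_n
    drop(mw)
  }
  iters <- max(0, max_evidence_iters)
  if (iters > 0) {
    for (it in seq_len(iters)) {
      mw <- solve_mean(a, b_n)
      gam <- sum(b_n * lam / (a + b_n * lam))
      rss <- sum((y - Phi %*% mw)^2)
      a_new <- gam / max(sum(mw^2), .Machine$double.eps)
      b_new <- max(n - gam, .Machine$double.eps) / max(rss, .Machine$double.eps)
      if (abs(a_new - a) < tol * abs(a) && abs(b_new - b_n) < tol * abs(b_n)) {
        a <- a_new; b_n <- b_new
        break
      }
      a <- a_new; b_n <- b_new
    }
  }
  mw <- solve_mean(a, b_n)
  cov <- eg$vectors %*% (t(eg$vectors) / (a + b_n * lam))
  structure(list(W_in = wi$W, b_in = wi$b, posterior_mean = mw,
                 posterior_cov = cov, a = a, b_n = b_n, seed = seed,
                 m = m, H = H), class = "rfed_belm")
}

#' @rdname belm_fit
#' @param model A fitted `rfed_belm`.
#' @param variance Also return the posterior predictive variance.
#' @return [belm_predict()]: scores clipped to `[0, 1]` (with attribute
#'   `variance` when requested).
#' @export
belm_predict <- function(model, X, variance = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != model$m) stop("feature count differs from the fit")
  Phi <- cbind(1, sigmoid(sweep(X %*% t(model$W_in), 2, model$b_in, `+`)))
  raw <- drop(Phi %*% model$posterior_mean)
  out <- pmin(pmax(raw, 0), 1)
  if (variance)
    attr(out, "variance") <- rowSums((Phi %*% model$posterior_cov) * Phi) +
      1 / model$b_n
  out
}

#' Downstream classification pipeline
#'
#' Z-scores the training features per column, selects `m` features by
#' [mrmr_select()], fits a [belm_fit()] classifier and scores the test set
#' with the training-set statistics applied throughout.
#'
#' @param fm_train,fm_test `rfed_features` objects (or lists with `X`, `y`).
#' @param m Number of selected features (default 20).
#' @param bins mRMR discretization bins.
#' @param H BELM hidden units.
#' @param seed Seed for the BELM input layer.
#' @return List with `selection` (`rfed_mrmr`), `model` (`rfed_belm`),
#'   `train_scores`, `test_scores`.
#' @export
downstream_classify <- function(fm_train, fm_test, m = 20, bins = 10,
                                H = 100, seed = 1) {
  mu <- colMeans(fm_train$X)
  sg <- apply(fm_train$X, 2, stats::sd)
  sg[sg == 0] <- 1
  ztr <- sweep(sweep(fm_train$X, 2, mu), 2, sg, `/`)
  zte <- sweep(sweep(fm_test$X, 2, mu), 2, sg, `/`)
  sel <- mrmr_select(ztr, fm_train$y, m = min(m, ncol(ztr)), bins = bins)
  fit <- belm_fit(ztr[, sel$selected, drop = FALSE], fm_train$y, H = H,
                  seed = seed)
  list(selection = sel, model = fit,
       train_scores = belm_predict(fit, ztr[, sel$selected, drop = FALSE]),
       test_scores = belm_predict(fit, zte[, sel$selected, drop = FALSE]))
}
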