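#' Linear classifier head
#'
#' @param W `C x d` weight matrix, one row per class.
#' @param b Length-`C` bias vector.
#' @return List of class `rfed_head` with `W`, `b`, `C`, `d`.
#' @export
classifier_head <- function(W, b) {
  W <- as.matrix(W)
  if (length(b) != nrow(W)) stop("bias length must equal the number of classes")
  if (!all(is.finite(W)) || !all(is.finite(b))) stop("head has non-finite entries")
  structure(list(W = W, b = as.numeric(b), C = nrow(W), d = ncol(W)),
            class = "rfed_head")
}

#' Per-class margin calibration parameters
#'
#' Per-class scale `omega` and offset `beta` used by [marc_loss()] to
#' rebalance decision margins under class imbalance. At
#' `omega = 1, beta = 0` the calibrated loss is exactly the ordinary
#' cross-entropy.
#'
#' @param omega Length-`C` positive scales.
#' @param beta Length-`C` offsets.
#' @param trainable Whether the trainer updates these jointly with the model.
#' @return List of class `rfed_calib`.
#' @export
margin_calibration <- function(omega, beta, trainable = TRUE) {
  if (length(omega) != length(beta)) stop("omega and beta must have equal length")
  if (!all(is.finite(omega)) || !all(is.finite(beta)))
    stop("calibration has non-finite entries")
  if (any(omega <= 0)) stop("omega must be strictly positive")
  structure(list(omega = as.numeric(omega), beta = as.numeric(beta),
                 trainable = isTRUE(trainable)), class = "rfed_calib")
}

#' A batch of encoded features with labels
#'
#' @param z `B x d` feature matrix (or a length-`d` vector for one sample).
#'   The training loop also stores raw image batches (`H x W x 1 x B`
#'   arrays) here, which the encoder turns into features.
#' @param y Integer labels in `0 .. C-1`.
#' @return List of class `rfed_batch`.
#' @export
labeled_batch <- function(z, y) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  else if (length(dim(z)) == 2) z <- as.matrix(z)
  y <- as.integer(y)
  nb <- if (length(dim(z)) == 4) dim(z)[4] else nrow(z)
  if (nb != length(y)) stop("feature rows and labels differ in length")
  if (nb < 1) stop("batch must contain at least one sample")
  if (any(y < 0)) stop("labels must be non-negative integers (0-based)")
  structure(list(z = z, y = y), class = "rfed_batch")
}

#' Class scores and classification margins
#'
#' `class_logits()` computes the linear scores `eta_c = W_c . z + b_c`;
#' `classification_margin()` divides each score by the L2 norm of its class
#' weight row, `d_c = eta_c / ||W_c||`, the geometric margin of the sample
#' to the class-`c` decision boundary.
#'
#' @param head A [classifier_head()].
#' @param z Length-`d` feature vector or `B x d` matrix.
#' @return `B x C` matrix of scores (a vector when `z` is a vector).
#' @export
class_logits <- function(head, z) {
  stopifnot(inherits(head, "rfed_head"))
  vec <- is.null(dim(z))
  z <- if (vec) matrix(z, nrow = 1) else as.matrix(z)
  if (ncol(z) != head$d) stop("feature dimension does not match head")
  eta <- z %*% t(head$W)
  eta <- sweep(eta, 2, head$b, `+`)
  if (vec) drop(eta) else eta
}

#' @rdname class_logits
#' @export
classification_margin <- function(head, z) {
  eta <- class_logits(head, z)
  nrm <- sqrt(rowSums(head$W^2))
  if (any(nrm == 0)) stop("zero-norm class weight row has undefined margin")
  if (is.null(dim(eta))) eta / nrm else sweep(eta, 2, nrm, `/`)
}

#' Cross-entropy loss
#'
#' `-log softmax(eta)[y]`, averaged over the batch when `eta` is a matrix.
#'
#' @param eta Length-`C` score vector or `B x C` matrix.
#' @param y Label(s) in `0 .. C-1`.
#' @return Scalar loss.
#' @examples
#' cross_entropy_loss(c(0, 0), 0)  # log(2)
#' @export
cross_entropy_loss <- function(eta, y) {
  eta <- if (is.null(dim(eta))) matrix(eta, nrow = 1) else as.matrix(eta)
  y <- as.integer(y)
  if (length(y) != nrow(eta)) stop("label count does not match score rows")
  if (any(y < 0 | y >= ncol(eta))) stop("label out of range 0 .. C-1")
  ll <- vapply(seq_len(nrow(eta)), function(i)
    eta[i, y[i] + 1L] - logsumexp(eta[i, ]), 1)
  -mean(ll)
}

# Shared core for the margin-calibrated loss and its gradients.
marc_core <- function(head, calib, batch) {
  stopifnot(inherits(head, "rfed_head"), inherits(calib, "rfed_calib"),
            inherits(batch, "rfed_batch"))
  if (length(calib$omega) != head$C) stop("calibration length must equal C")
  if (any(batch$y >= head$C)) stop("label out of range 0 .. C-1")
  z <- batch$z
  B <- nrow(z)
  eta <- class_logits(head, z)
  if (is.null(dim(eta))) eta <- matrix(eta, nrow = B)
  wn <- sqrt(rowSums(head$W^2))
  u <- sweep(sweep(eta, 2, calib$omega, `*`), 2, calib$beta * wn, `+`)
  mx <- apply(u, 1, max)
  lse <- mx + log(rowSums(exp(u - mx)))
  yi <- batch$y + 1L
  loss <- -mean(u[cbind(seq_len(B), yi)] - lse)
  list(z = z, B = B, eta = eta, wn = wn, u = u, lse = lse, yi = yi, loss = loss)
}

#' Margin-calibrated cross-entropy (MARC) loss
#'
#' Cross-entropy on calibrated logits `u_c = omega_c * eta_c +
#' beta_c * ||W_c||`: the per-class scale and offset reshape class margins so
#' that minority-class boundaries are not crowded out by the majority class.
#' `marc_loss_grad()` additionally returns analytic gradients with respect
#' to the head weights/bias, the features and the calibration parameters,
#' as used by the SGD trainer.
#'
#' @param head A [classifier_head()].
#' @param calib A [margin_calibration()].
#' @param batch A [labeled_batch()].
#' @return `marc_loss()`: scalar mean loss. `marc_loss_grad()`: list with
#'   `loss`, `dW`, `db`, `dz`, `domega`, `dbeta`.
#' @export
marc_loss <- function(head, calib, batch) {
  marc_core(head, calib, batch)$loss
}

#' @rdname marc_loss
#' @export
marc_loss_grad <- function(head, calib, batch) {
  cc <- marc_core(head, calib, batch)
  p <- exp(cc$u - cc$lse)                       # B x C softmax of calibrated logits
  G <- p
  G[cbind(seq_len(cc$B), cc$yi)] <- G[cbind(seq_len(cc$B), cc$yi)] - 1
  G <- G / cc$B
  Gw <- sweep(G, 2, calib$omega, `*`)           # dL/d eta
  csum <- colSums(G)
  # d||W_c||/dW_c = W_c / ||W_c||; length-C vector * matrix scales rows
  dW <- t(Gw) %*% cc$z + (calib$beta * csum / cc$wn) * head$W
  db <- colSums(Gw)
  dz <- Gw %*% head$W
  domega <- colSums(G * cc$eta)
  dbeta <- csum * cc$wn
  list(loss = cc$loss, dW = dW, db = db, dz = dz, domega = domega,
       dbeta = dbeta)
}

#' Bank of classifier-layer representations for the contrastive term
#'
#' The global model's flattened fully-connected-layer parameters `f_global`
#' and each client's local counterparts `f_locals` (broadcast by the server
#' each round), together with the contrastive temperature and the weight
#' `alpha` of the contrastive term in the total loss.
#'
#' @param f_global Numeric vector.
#' @param f_locals List of `K` numeric vectors, same length as `f_global`.
#' @param tau Temperature > 0 (default 1).
#' @param alpha Weight of the contrastive term (default 0.6).
#' @return List of class `rfed_bank`.
#' @export
representation_bank <- function(f_global, f_locals, tau = 1, alpha = 0.6) {
  if (tau <= 0) stop("tau must be positive")
  if (alpha < 0) stop("alpha must be non-negative")
  if (length(f_locals) < 1) stop("need at least one local representation")
  len <- length(f_global)
  for (f in f_locals) if (length(f) != len) stop("representation lengths differ")
  structure(list(f_global = as.numeric(f_global),
                 f_locals = lapply(f_locals, as.numeric),
                 tau = tau, alpha = alpha, K = length(f_locals)),
            class = "rfed_bank")
}

cosine_sim <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-norm vector in cosine similarity")
  sum(u * v) / (nu * nv)
}

#' Contrastive alignment loss between local and global classifier layers
#'
#' InfoNCE-style term that pulls client `k`'s fully-connected-layer
#' parameters toward the global model's while pushing away the other
#' clients': `-log( s_hat(f_G, f_k) / sum_i s_hat(f_G, f_i) )` with
#' `s_hat = exp(cos(u, v) / tau)`. The exponentiated similarity keeps the
#' ratio positive (raw cosine can be negative). Equals 0 when `K = 1` and
#' `log K` when all local representations are identical.
#'
#' @param bank A [representation_bank()].
#' @param k Client index, `1 <= k <= K`.
#' @return `cpc_loss()`: scalar. `cpc_loss_grad()`: list with `loss` and
#'   `df` (gradient with respect to `f_locals[[k]]`).
#' @export
cpc_loss <- function(bank, k) {
  cpc_core(bank, k)$loss
}

cpc_core <- function(bank, k) {
  stopifnot(inherits(bank, "rfed_bank"))
  if (k < 1 || k > bank$K) stop("client index out of range")
  s <- vapply(bank$f_locals, function(f) cosine_sim(bank$f_global, f) / bank$tau, 1)
  lse <- logsumexp(s)
  list(s = s, lse = lse, loss = -(s[k] - lse))
}

#' @rdname cpc_loss
#' @export
cpc_loss_grad <- function(bank, k) {
  cc <- cpc_core(bank, k)
  p <- exp(cc$s - cc$lse)
  g <- bank$f_global
  f <- bank$f_locals[[k]]
  ng <- sqrt(sum(g^2)); nf <- sqrt(sum(f^2))
  cosv <- sum(g * f) / (ng * nf)
  dcos <- g / (ng * nf) - cosv * f / nf^2
  df <- (p[k] - 1) * dcos / bank$tau
  list(loss = cc$loss, df = df)
}

#' Total personalized loss
#'
#' `marc + alpha * cpc`: the margin-calibrated supervised loss plus the
#' weighted contrastive alignment term (regularization weight
#' `alpha`, default 0.6).
#'
#' @param marc Scalar supervised loss.
#' @param cpc Scalar contrastive loss.
#' @param alpha Non-negative weight.
#' @return Scalar total loss.
#' @export
total_personalized_loss <- function(marc, cpc, alpha = 0.6) {
  if (alpha < 0) stop("alpha must be non-negative")
  marc + alpha * cpc
}
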