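# Independent oracles used by the tests: textbook definitions written
# without any of the package's own helpers.

# Discrete Fourier transform by the definition (O(n^2) sum).
naive_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)), complex(1))
}

naive_idft <- function(X) {
  n <- length(X)
  vapply(0:(n - 1), function(t)
    sum(X * exp(2i * pi * (0:(n - 1)) * t / n)) / n, complex(1))
}

# Pairwise-counting AUC, O(n^2): ties count one half.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Plug-in mutual information after equal-frequency binning, written
# independently of the package (same estimator definition).
oracle_mi <- function(x, y, bins = 10) {
  disc <- function(v) {
    u <- sort(unique(v))
    if (length(u) <= bins) return(match(v, u))
    br <- unique(quantile(v, probs = seq(0, 1, length.out = bins + 1),
                          names = FALSE))
    if (length(br) < 2) return(rep(1L, length(v)))
    cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  tab <- table(disc(x), disc(y)) / length(x)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    p <- tab[i, j]
    if (p > 0) mi <- mi + p * log(p / (sum(tab[i, ]) * sum(tab[, j])))
  }
  max(mi, 0)
}

# Brute-force greedy minimum-redundancy maximum-relevance selection.
oracle_mrmr <- function(X, y, m, bins = 10, criterion = "MID") {
  d <- ncol(X)
  rel <- sapply(seq_len(d), function(j) oracle_mi(X[, j], y, bins))
  sel <- integer(0)
  for (step in seq_len(m)) {
    cand <- setdiff(seq_len(d), sel)
    crit <- sapply(cand, function(j) {
      if (length(sel) == 0) return(rel[j])
      rd <- mean(sapply(sel, function(s) oracle_mi(X[, j], X[, s], bins)))
      if (criterion == "MID") rel[j] - rd
      else rel[j] / max(rd, .Machine$double.eps)
    })
    sel <- c(sel, cand[which.max(crit)])
  }
  sel
}

# Small random parameter set for spectral tests (fixed architecture so
# sets from different seeds can be aggregated together).
random_param_set <- function(seed) {
  set.seed(seed)
  parameter_set(list(
    w = rnorm(10),
    m = matrix(rnorm(12), 3, 4),
    b = rnorm(5)))
}

# A tiny in-memory split (images + labels + patient ids) for training tests.
toy_split <- function(n_img = 24, size = 16, seed = 1) {
  cfg <- center_config("T", 20, image_size = size, noise_sigma = 0.03,
                       blur_sigma = 0)
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n_img)
  imgs <- lapply(y, function(l) render_patient_images(l, cfg, n_slices = 1)[[1]])
  X <- array(0, c(size, size, 1, n_img))
  for (i in seq_len(n_img)) X[, , 1, i] <- imgs[[i]]
  list(X = X, y = y, patient = sprintf("p%02d", seq_len(n_img)))
}
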