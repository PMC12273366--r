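test_that("linear scores and margins follow the head geometry", {
  h <- classifier_head(rbind(c(3, 4), c(1, 1)), c(1, 0))
  expect_equal(class_logits(h, c(1, 1)), c(8, 2))
  expect_equal(classification_margin(h, c(1, 1))[1], 8 / 5)
  expect_equal(class_logits(h, c(0, 0)), h$b)
  W <- diag(2)
  expect_equal(class_logits(classifier_head(W, c(0, 0)), c(1, 0)), W[, 1])
  expect_error(class_logits(h, c(1, 2, 3)), "dimension")
})

test_that("cross-entropy matches direct evaluation", {
  expect_equal(cross_entropy_loss(c(0, 0), 0), log(2))
  expect_equal(cross_entropy_loss(c(2, 0), 0), -log(exp(2) / (exp(2) + 1)))
  expect_lt(cross_entropy_loss(c(60, 0), 0), 1e-10)   # dominant true logit
  # batch version averages
  eta <- rbind(c(2, 0), c(0, 0))
  expect_equal(cross_entropy_loss(eta, c(0, 1)),
               mean(c(cross_entropy_loss(c(2, 0), 0), log(2))))
  expect_error(cross_entropy_loss(c(1, 2), 2), "range")
})

test_that("margin-calibrated loss reduces to cross-entropy at (1, 0)", {
  set.seed(5)
  for (i in 1:20) {
    C <- sample(2:4, 1); d <- sample(2:6, 1); B <- sample(1:8, 1)
    h <- classifier_head(matrix(rnorm(C * d), C), rnorm(C))
    b <- labeled_batch(matrix(rnorm(B * d), B), sample(0:(C - 1), B, TRUE))
    expect_equal(marc_loss(h, margin_calibration(rep(1, C), rep(0, C)), b),
                 cross_entropy_loss(class_logits(h, b$z), b$y),
                 tolerance = 1e-7)
  }
})

test_that("margin-calibrated loss matches direct evaluation of its formula", {
  # C = 2, eta = [1, 0], ||W|| = [1, 1], omega = [2, 1], beta = [0.5, 0]
  h <- classifier_head(diag(2), c(0, 0))   # rows have unit norm
  b <- labeled_batch(c(1, 0), 0)           # z = e1 so eta = (1, 0)
  val <- marc_loss(h, margin_calibration(c(2, 1), c(0.5, 0)), b)
  expect_equal(val, -log(exp(2.5) / (exp(2.5) + 1)), tolerance = 1e-9)
})

test_that("calibrated loss is invariant to constant logit shifts", {
  set.seed(6)
  h <- classifier_head(matrix(rnorm(6), 2), rnorm(2))   # 2 classes, d = 3
  wn <- sqrt(rowSums(h$W^2))
  b <- labeled_batch(matrix(rnorm(15), 5), sample(0:1, 5, TRUE))
  # equal row norms scaled to 1: beta adds the same constant to all classes
  h1 <- classifier_head(h$W / wn, h$b)
  l_beta <- marc_loss(h1, margin_calibration(c(1, 1), c(0.7, 0.7)), b)
  l_zero <- marc_loss(h1, margin_calibration(c(1, 1), c(0, 0)), b)
  expect_equal(l_beta, l_zero, tolerance = 1e-10)
  expect_error(margin_calibration(c(0, 1), c(0, 0)), "positive")
})

test_that("analytic MARC gradients match finite differences", {
  set.seed(8)
  C <- 3; d <- 4; B <- 6
  h <- classifier_head(matrix(rnorm(C * d), C), rnorm(C))
  calib <- margin_calibration(runif(C, 0.5, 2), rnorm(C, 0, 0.3))
  b <- labeled_batch(matrix(rnorm(B * d), B), sample(0:(C - 1), B, TRUE))
  g <- marc_loss_grad(h, calib, b)
  eps <- 1e-6
  fd <- function(f) (f(eps) - f(-eps)) / (2 * eps)
  for (i in seq_len(C * d)) {
    num <- fd(function(e) {
      h2 <- h; h2$W[i] <- h2$W[i] + e
      marc_loss(h2, calib, b)
    })
    expect_equal(g$dW[i], num, tolerance = 1e-4)
  }
  for (i in seq_len(C)) {
    expect_equal(g$db[i], fd(function(e) {
      h2 <- h; h2$b[i] <- h2$b[i] + e; marc_loss(h2, calib, b)
    }), tolerance = 1e-4)
    expect_equal(g$domega[i], fd(function(e) {
      c2 <- calib; c2$omega[i] <- c2$omega[i] + e; marc_loss(h, c2, b)
    }), tolerance = 1e-4)
    expect_equal(g$dbeta[i], fd(function(e) {
      c2 <- calib; c2$beta[i] <- c2$beta[i] + e; marc_loss(h, c2, b)
    }), tolerance = 1e-4)
  }
  for (i in seq_len(B * d)) {
    expect_equal(g$dz[i], fd(function(e) {
      b2 <- b; b2$z[i] <- b2$z[i] + e; marc_loss(h, calib, b2)
    }), tolerance = 1e-4)
  }
})

test_that("contrastive alignment loss has its closed-form special cases", {
  f <- rnorm(6)
  expect_equal(cpc_loss(representation_bank(f, list(f)), 1), 0)
  bank <- representation_bank(f, list(f, f, f))
  for (k in 1:3) expect_equal(cpc_loss(bank, k), log(3))
  # K = 2, cosine similarities (1, -1), tau = 1
  b2 <- representation_bank(c(1, 0), list(c(2, 0), c(-3, 0)), tau = 1)
  expect_equal(cpc_loss(b2, 1), -log(exp(1) / (exp(1) + exp(-1))),
               tolerance = 1e-9)
  expect_error(cpc_loss(bank, 4), "out of range")
  expect_error(representation_bank(f, list(f, c(0, 0, 0, 0, 0, 0))), NA)
  expect_error(cpc_loss(representation_bank(f, list(rep(0, 6))), 1), "zero-norm")
})

test_that("contrastive loss is bounded and decreases with alignment", {
  set.seed(10)
  for (i in 1:10) {
    K <- sample(2:5, 1); len <- sample(4:10, 1); tau <- runif(1, 0.5, 2)
    bank <- representation_bank(rnorm(len),
                                lapply(seq_len(K), function(j) rnorm(len)),
                                tau = tau)
    l <- cpc_loss(bank, 1)
    expect_gte(l, 0)
    expect_lte(l, log(K) + 2 / tau)
  }
  # raising cos(f_G, f_k) with the others fixed lowers the loss
  g <- c(1, 0, 0)
  mk <- function(ang) {
    representation_bank(g, list(c(cos(ang), sin(ang), 0), c(0, 1, 1)), tau = 1)
  }
  expect_lt(cpc_loss(mk(0.2), 1), cpc_loss(mk(1.2), 1))
})

test_that("contrastive gradient matches finite differences", {
  set.seed(12)
  bank <- representation_bank(rnorm(5), list(rnorm(5), rnorm(5), rnorm(5)))
  g <- cpc_loss_grad(bank, 2)
  eps <- 1e-6
  for (i in 1:5) {
    bp <- bank; bp$f_locals[[2]][i] <- bp$f_locals[[2]][i] + eps
    bm <- bank; bm$f_locals[[2]][i] <- bm$f_locals[[2]][i] - eps
    expect_equal(g$df[i], (cpc_loss(bp, 2) - cpc_loss(bm, 2)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("total loss combines the two terms linearly", {
  expect_equal(total_personalized_loss(0.5, 0.5, 0.6), 0.8)
  expect_equal(total_personalized_loss(1.3, 9, 0), 1.3)
  expect_equal(total_personalized_loss(0.7, 0, 0.6), 0.7)
  expect_error(total_personalized_loss(1, 1, -0.1), "non-negative")
})
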