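test_that("backbone channel bookkeeping matches the architectures", {
  tiny <- backbone_spec("tiny_cnn", conv_channels = c(8, 16))
  expect_equal(sum(tiny$conv_channel_list), 24)
  rn <- backbone_spec("resnet34_shape")
  expect_length(rn$conv_channel_list, 33)      # 1 + 2 * (3 + 4 + 6 + 3)
  expect_equal(sum(rn$conv_channel_list), 7616)
  expect_error(backbone_spec("vgg"), "arg")
})

test_that("initialization is deterministic given the seed", {
  sp <- backbone_spec("tiny_cnn", input_size = 16)
  m1 <- build_backbone(sp, seed = 42)
  m2 <- build_backbone(sp, seed = 42)
  expect_identical(m1$params, m2$params)
  m3 <- build_backbone(sp, seed = 43)
  expect_false(identical(m1$params, m3$params))
})

test_that("elementwise averaging behaves as the federated baseline", {
  p <- random_param_set(1)
  expect_equal(fedavg_aggregate(list(p, p)), p)
  z0 <- parameter_set(lapply(p, function(v) v * 0))
  z2 <- parameter_set(lapply(p, function(v) v * 0 + 2))
  avg <- fedavg_aggregate(list(z0, z2))
  expect_true(all(abs(unlist(avg) - 1) < 1e-12))
  expect_error(fedavg_aggregate(list()), "no clients")
})

test_that("spectral and time-domain averaging agree only under equal phases", {
  set.seed(2)
  x <- rnorm(12)
  p1 <- parameter_set(list(v = x)); p2 <- parameter_set(list(v = 3 * x))
  cfg <- aggregation_config(1, 0, r_max = 1, retain_local_high_band = FALSE)
  # equal phases (positive scaling): spectral aggregation = elementwise mean
  spectral <- epfa_aggregate(list(p1, p2), cfg)[[1]]
  timedom <- fedavg_aggregate(list(p1, p2))
  expect_equal(spectral$v, timedom$v, tolerance = 1e-8)
  # opposite phases: the two disagree (complex mean would vanish)
  p3 <- parameter_set(list(v = -x))
  spectral2 <- epfa_aggregate(list(p1, p3), cfg)[[1]]
  timedom2 <- fedavg_aggregate(list(p1, p3))
  expect_lt(max(abs(timedom2$v)), 1e-12)
  expect_gt(max(abs(spectral2$v)), 0.1)
})

test_that("a zero-iteration local round is a no-op on the deputy", {
  sp <- backbone_spec("tiny_cnn", input_size = 16)
  d0 <- build_backbone(sp, seed = 1)
  tr <- client_triplet(d0, d0, client_index = 1L)
  data <- toy_split(size = 16, seed = 4)
  cfg <- training_config(rounds = 1, local_iters_per_round = 0, seed = 1)
  out <- local_round(tr, data, cfg)
  expect_identical(out$theta, d0$params)
})

test_that("local rounds are reproducible and losses stay finite", {
  sp <- backbone_spec("tiny_cnn", input_size = 16)
  d0 <- build_backbone(sp, seed = 1)
  tr <- client_triplet(d0, d0, client_index = 1L)
  data <- toy_split(n_img = 40, size = 16, seed = 5)
  cfg <- training_config(rounds = 1, local_iters_per_round = 20,
                         batch_size = 8, seed = 1)
  set.seed(7); out1 <- local_round(tr, data, cfg)
  set.seed(7); out2 <- local_round(tr, data, cfg)
  expect_identical(out1$theta, out2$theta)
  expect_true(all(is.finite(out1$block_loss)))
})

test_that("training loss trends downward on separable data", {
  sp <- backbone_spec("tiny_cnn", input_size = 16)
  d0 <- build_backbone(sp, seed = 3)
  tr <- client_triplet(d0, d0, client_index = 1L)
  data <- toy_split(n_img = 60, size = 16, seed = 8)
  cfg <- training_config(rounds = 1, local_iters_per_round = 100,
                         batch_size = 16, seed = 1)
  set.seed(9)
  out <- local_round(tr, data, cfg, attl_config(lambda_A = 0, plain_ce = TRUE),
                     method = "fedavg")
  nb <- length(out$block_loss)
  expect_lt(mean(out$block_loss[(nb - 4):nb]),
            mean(out$block_loss[1:5]))
})

test_that("class probabilities and patient scores pool correctly", {
  sp <- backbone_spec("tiny_cnn", input_size = 16)
  m <- build_backbone(sp, seed = 2)
  m$params$fc_W[] <- 0; m$params$fc_b[] <- 0       # logits (0, 0)
  img <- matrix(runif(256), 16)
  expect_equal(predict_with_personalized(m, img), 0.5)
  m2 <- build_backbone(sp, seed = 2)
  p1 <- predict_with_personalized(m2, img)
  expect_equal(patient_score(m2, list(img, img)), p1)   # duplicate image
  expect_equal(patient_score(m2, list(img)), p1)
})

test_that("identical centers under time-domain averaging stay in lockstep", {
  # two copies of the same center, fedavg: round-end models identical
  data1 <- toy_split(n_img = 30, size = 16, seed = 10)
  pats <- unique(data1$patient)
  val_ids <- pats[1:6]
  mk <- function(d, ids, keep) {
    sel <- if (keep) d$patient %in% ids else !(d$patient %in% ids)
    list(X = d$X[, , , sel, drop = FALSE], y = d$y[sel],
         patient = d$patient[sel])
  }
  center <- list(train = mk(data1, val_ids, FALSE),
                 validation = mk(data1, val_ids, TRUE),
                 test = mk(data1, val_ids, TRUE))
  data <- list(A = center, B = center)
  st <- run_federated_training(data, training_config(rounds = 2, seed = 1,
                                                     local_iters_per_round = 10,
                                                     batch_size = 8),
                               method = "fedavg",
                               backbone = backbone_spec("tiny_cnn",
                                                        input_size = 16))
  expect_identical(st$clients[[1]]$deputy$params,
                   st$clients[[2]]$deputy$params)
  expect_identical(st$clients[[1]]$personalized$params,
                   st$clients[[2]]$personalized$params)
  expect_equal(nrow(st$history), 4)
})
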