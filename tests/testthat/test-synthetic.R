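small_configs <- function(size = 16) {
  list(center_config("A", 20, image_size = size, noise_sigma = 0.03),
       center_config("B", 24, image_size = size, intensity_offset = 0.1,
                     contrast_scale = 0.8, noise_sigma = 0.08,
                     blur_sigma = 0.7))
}

test_that("rendered images are bounded, sized and label-dependent", {
  cfg <- center_config("A", 20, image_size = 24)
  set.seed(1)
  imgs <- render_patient_images(1, cfg, n_slices = 3)
  expect_length(imgs, 3)
  for (im in imgs) {
    expect_equal(dim(im), c(24, 24))
    expect_true(all(im >= 0 & im <= 1))
  }
  expect_error(render_patient_images(2, cfg), "label")
})

test_that("an intensity offset shifts the image mean accordingly", {
  base <- center_config("A", 20, image_size = 32, noise_sigma = 0,
                        blur_sigma = 0)
  off <- center_config("A", 20, image_size = 32, noise_sigma = 0,
                       blur_sigma = 0, intensity_offset = 0.15)
  set.seed(5); i0 <- render_patient_images(0, base, 1)[[1]]
  set.seed(5); i1 <- render_patient_images(0, off, 1)[[1]]
  expect_equal(mean(i1) - mean(i0), 0.15, tolerance = 0.02)  # before clipping
})

test_that("progressive lesions carry more boundary-gradient energy", {
  cfg <- center_config("A", 20, image_size = 32, noise_sigma = 0,
                       blur_sigma = 0)
  grad_energy <- function(im) {
    gx <- im[-1, ] - im[-nrow(im), ]
    gy <- im[, -1] - im[, -ncol(im)]
    mean(abs(gx)) + mean(abs(gy))
  }
  set.seed(7)
  ge0 <- replicate(100, grad_energy(render_patient_images(0, cfg, 1)[[1]]))
  ge1 <- replicate(100, grad_energy(render_patient_images(1, cfg, 1)[[1]]))
  expect_gt(mean(ge1), mean(ge0))
})

test_that("generated cohorts match their prevalence exactly and reproduce", {
  d1 <- file.path(tempdir(), "synth_a"); d2 <- file.path(tempdir(), "synth_b")
  m1 <- generate_multicenter_dataset(small_configs(), seed = 3, out_dir = d1)
  m2 <- generate_multicenter_dataset(small_configs(), seed = 3, out_dir = d2)
  pm <- unique(m1[, c("patient_id", "center", "label")])
  expect_equal(sum(pm$label[pm$center == "A"]), round(0.2 * 20))
  expect_equal(sum(pm$label[pm$center == "B"]), round(0.2 * 24))
  # byte-identical manifests and images across identical seeds
  expect_equal(m1[, 1:5], m2[, 1:5])
  f1 <- file.path(d1, m1$image_path[1]); f2 <- file.path(d2, m2$image_path[1])
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # splits are disjoint by patient and stratified
  ps <- table(m1$patient_id, m1$split)
  expect_true(all(rowSums(ps > 0) == 1))
  for (ct in c("A", "B")) for (sp in c("train", "validation", "test")) {
    sub <- unique(m1[m1$center == ct & m1$split == sp, c("patient_id", "label")])
    expect_true(all(0:1 %in% sub$label))
  }
})

test_that("an oracle classifier passes end to end through the manifest", {
  d <- file.path(tempdir(), "synth_o")
  m <- generate_multicenter_dataset(small_configs(), seed = 5, out_dir = d)
  loaded <- load_manifest(file.path(d, "manifest.csv"))
  expect_equal(nrow(loaded), nrow(m))
  data <- load_center_data(loaded)
  te <- data$A$test
  pat_lab <- tapply(te$y, te$patient, function(v) v[1])
  expect_equal(roc_auc(as.numeric(pat_lab), as.integer(pat_lab)), 1)
  expect_true(all(te$X >= 0 & te$X <= 1))
})

test_that("manifest validation names the offending row", {
  d <- file.path(tempdir(), "synth_v")
  m <- generate_multicenter_dataset(small_configs(), seed = 7, out_dir = d)
  path <- file.path(d, "manifest.csv")
  bad <- utils::read.csv(path)
  bad$label[3] <- 2
  bp <- tempfile(fileext = ".csv"); utils::write.csv(bad, bp, row.names = FALSE)
  expect_error(load_manifest(bp), "row 3")
  bad2 <- utils::read.csv(path); bad2$split[5] <- "holdout"
  bp2 <- tempfile(fileext = ".csv"); utils::write.csv(bad2, bp2, row.names = FALSE)
  expect_error(load_manifest(bp2), "split")
  bad3 <- utils::read.csv(path)[, -3]
  bp3 <- tempfile(fileext = ".csv"); utils::write.csv(bad3, bp3, row.names = FALSE)
  expect_error(load_manifest(bp3), "missing column")
  empty <- utils::read.csv(path)[0, ]
  bp4 <- tempfile(fileext = ".csv"); utils::write.csv(empty, bp4, row.names = FALSE)
  expect_error(load_manifest(bp4), "empty")
  expect_error(load_manifest(tempfile()), "not found")
})

test_that("centers are measurably heterogeneous for a pixel-space model", {
  # a linear score learned on one center's raw pixels transfers worse to a
  # differently configured center than to held-out data from its own
  gaps <- sapply(1:3, function(s) {
    cfgs <- list(center_config("A", 40, image_size = 16, noise_sigma = 0.03),
                 center_config("B", 40, image_size = 16,
                               intensity_offset = 0.15, contrast_scale = 0.7,
                               noise_sigma = 0.1, blur_sigma = 1.0))
    d <- tempfile("het")
    m <- generate_multicenter_dataset(cfgs, seed = 100 + s, out_dir = d)
    data <- load_center_data(m)
    flat <- function(sp) t(apply(sp$X, 4, identity))
    Xtr <- flat(data$A$train); ytr <- data$A$train$y
    # ridge-regularized linear score on raw pixels
    lam <- 10
    beta <- solve(crossprod(Xtr) + lam * diag(ncol(Xtr)),
                  crossprod(Xtr, ytr - mean(ytr)))
    score <- function(sp) drop(flat(sp) %*% beta)
    own <- roc_auc(score(data$A$test), data$A$test$y)
    other <- roc_auc(score(data$B$test), data$B$test$y)
    own - other
  })
  expect_gt(mean(gaps), 0)
})
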