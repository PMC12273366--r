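#' Configuration of one synthetic imaging center
#'
#' Each center draws lesion images with its own acquisition character:
#' a brightness offset, a contrast scale, Gaussian blur and additive
#' Gaussian noise, emulating the heterogeneity of scanners and protocols
#' across hospitals. The positive (progression) class is the minority class
#' at a prevalence of about 0.2.
#'
#' @param center_id Character label of the center.
#' @param n_patients Number of patients (>= 5).
#' @param prevalence Positive-class fraction in (0, 1), default 0.2.
#' @param intensity_offset Additive brightness shift.
#' @param contrast_scale Multiplicative contrast around mid-gray.
#' @param noise_sigma Additive Gaussian pixel noise SD.
#' @param blur_sigma Gaussian blur SD in pixels (0 disables).
#' @param slices_per_patient Integer range (min, max) of images per patient.
#' @param image_size Square image side in pixels (default 128; the
#'   scaled-down benchmark uses 32).
#' @return List of class `rfed_center_config`.
#' @export
center_config <- function(center_id, n_patients, prevalence = 0.2,
                          intensity_offset = 0, contrast_scale = 1,
                          noise_sigma = 0.05, blur_sigma = 0,
                          slices_per_patient = c(1L, 4L), image_size = 128L) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  if (n_patients < 5) stop("need at least 5 patients per center")
  stopifnot(all(is.finite(c(intensity_offset, contrast_scale, noise_sigma,
                            blur_sigma))))
  structure(list(center_id = as.character(center_id),
                 n_patients = as.integer(n_patients), prevalence = prevalence,
                 intensity_offset = intensity_offset,
                 contrast_scale = contrast_scale, noise_sigma = noise_sigma,
                 blur_sigma = blur_sigma,
                 slices_per_patient = as.integer(slices_per_patient),
                 image_size = as.integer(image_size)),
            class = "rfed_center_config")
}

#' Default 4-center benchmark configuration
#'
#' Four centers with patient counts 96/224/72/56, prevalence 0.2 and
#' distinct offset/contrast/noise/blur characteristics, mirroring a
#' multicenter cohort's shape without any clinical data.
#'
#' @param image_size Image side in pixels (default 32 for the scaled-down
#'   benchmark).
#' @return List of four [center_config()] objects.
#' @export
default_benchmark_configs <- function(image_size = 32L) {
  list(center_config("A", 96, intensity_offset = 0.00, contrast_scale = 1.00,
                     noise_sigma = 0.03, blur_sigma = 0, image_size = image_size),
       center_config("B", 224, intensity_offset = 0.12, contrast_scale = 0.75,
                     noise_sigma = 0.08, blur_sigma = 0.8, image_size = image_size),
       center_config("C", 72, intensity_offset = -0.10, contrast_scale = 1.25,
                     noise_sigma = 0.05, blur_sigma = 0.5, image_size = image_size),
       center_config("D", 56, intensity_offset = 0.06, contrast_scale = 0.90,
                     noise_sigma = 0.12, blur_sigma = 1.2, image_size = image_size))
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, ceiling(2.5 * sigma))
  k1 <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  ker <- outer(k1, k1); ker <- ker / sum(ker)
  kw <- 2L * rad + 1L
  x <- array(img, c(nrow(img), ncol(img), 1, 1))
  w <- array(ker, c(kw, kw, 1, 1))
  num <- rfed_conv2d_fw(x, w, 0, 1L, rad)
  den <- rfed_conv2d_fw(array(1, dim(x)), w, 0, 1L, rad)
  matrix(num / den, nrow(img))   # normalized convolution: no border darkening
}

#' Render the synthetic images of one patient
#'
#' Negative-class lesions are smooth, soft-edged ellipses with low internal
#' texture; positive-class lesions are irregular spiculated shapes (strong
#' high-order radial harmonics), sharper-edged and with higher internal
#' texture variance. Center effects are then applied in order: contrast
#' scaling, intensity offset, Gaussian blur, additive Gaussian noise;
#' finally pixel values are clipped to `[0, 1]`. Uses the current RNG
#' state; seed the session for reproducibility.
#'
#' @param label 0 (non-progression) or 1 (progression).
#' @param cfg A [center_config()].
#' @param n_slices Number of images; by default drawn from
#'   `cfg$slices_per_patient`.
#' @return List of `image_size x image_size` matrices with values in
#'   `[0, 1]`.
#' @export
render_patient_images <- function(label, cfg, n_slices = NULL) {
  stopifnot(inherits(cfg, "rfed_center_config"), label %in% c(0, 1))
  if (is.null(n_slices))
    n_slices <- sample(cfg$slices_per_patient[1]:cfg$slices_per_patient[2], 1)
  S <- cfg$image_size
  ax <- seq(-1, 1, length.out = S)
  gx <- matrix(ax, S, S); gy <- t(gx)
  lapply(seq_len(n_slices), function(i) {
    cx <- runif(1, -0.2, 0.2); cy <- runif(1, -0.2, 0.2)
    r0 <- runif(1, 0.30, 0.45)
    asp <- runif(1, 0.7, 1)
    th <- atan2((gy - cy), (gx - cx) * asp)
    rr <- sqrt(((gx - cx) * asp)^2 + (gy - cy)^2)
    if (label == 0) {
      phi <- runif(1, 0, 2 * pi)
      rad <- r0 * (1 + 0.06 * sin(2 * th + phi))
      edge <- 0.09
      tex_sd <- 0.04
    } else {
      h <- 5:9
      amp <- runif(length(h), 0.04, 0.11)
      phi <- runif(length(h), 0, 2 * pi)
      rad <- r0 * (1 + Reduce(`+`, Map(function(a, hh, p)
        a * sin(hh * th + p), amp, h, phi)))
      edge <- 0.05
      tex_sd <- 0.05
    }
    inside <- sigmoid((rad - rr) / edge)
    img <- 0.15 + 0.55 * inside
    img <- img + inside * matrix(rnorm(S * S, sd = tex_sd), S, S)
    img <- (img - 0.5) * cfg$contrast_scale + 0.5 + cfg$intensity_offset
    img <- gaussian_blur(img, cfg$blur_sigma)
    img <- img + matrix(rnorm(S * S, sd = cfg$noise_sigma), S, S)
    pmin(pmax(img, 0), 1)
  })
}

# Stratified patient-level split: per class, proportional allocation with
# largest-remainder rounding; guarantees every split gets at least one
# patient of each class when the class has >= number-of-splits members.
stratified_split <- function(labels, fractions) {
  splits <- names(fractions)
  assign <- character(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))        # random order within class
    n <- length(idx)
    base <- floor(fractions * n)
    rem <- fractions * n - base
    left <- n - sum(base)
    if (left > 0)
      base[order(rem, decreasing = TRUE)[seq_len(left)]] <-
        base[order(rem, decreasing = TRUE)[seq_len(left)]] + 1
    if (n >= length(splits) && any(base == 0)) {
      donor <- which.max(base)
      for (s in which(base == 0)) {
        base[s] <- 1; base[donor] <- base[donor] - 1
      }
    }
    off <- 0
    for (s in seq_along(splits)) {
      if (base[s] > 0) assign[idx[(off + 1):(off + base[s])]] <- splits[s]
      off <- off + base[s]
    }
  }
  assign
}

#' Generate a seeded multicenter synthetic dataset
#'
#' Draws every center's patients (positive count = `round(prevalence *
#' n_patients)` exactly), renders their images, performs a stratified
#' patient-level train/validation/test split, writes 8-bit grayscale PNGs
#' plus a CSV manifest, and returns the manifest. Fully reproducible from
#' `seed`.
#'
#' @param configs List of [center_config()] objects.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if missing).
#' @param split_fractions Named fractions summing to 1 (default
#'   train 0.6, validation 0.15, test 0.25).
#' @return Data frame manifest (`patient_id`, `center`, `label`, `split`,
#'   `image_path`), with attributes `root` and `seed`; also written to
#'   `out_dir/manifest.csv`.
#' @export
generate_multicenter_dataset <- function(configs, seed, out_dir,
                                         split_fractions = c(train = 0.6,
                                                             validation = 0.15,
                                                             test = 0.25)) {
  if (length(configs) < 1) stop("need at least one center config")
  if (abs(sum(split_fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1")
  if (is.null(names(split_fractions)))
    stop("split fractions must be named")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  set.seed(derive_seed(seed, 97))
  for (cfg in configs) {
    stopifnot(inherits(cfg, "rfed_center_config"))
    n <- cfg$n_patients
    n_pos <- round(cfg$prevalence * n)
    labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    split <- stratified_split(labels, split_fractions)
    cdir <- file.path(out_dir, cfg$center_id)
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_len(n)) {
      pid <- sprintf("%s%04d", cfg$center_id, i)
      imgs <- render_patient_images(labels[i], cfg)
      for (j in seq_along(imgs)) {
        rel <- file.path(cfg$center_id, sprintf("%s_s%02d.png", pid, j))
        png::writePNG(imgs[[j]], file.path(out_dir, rel))
        rows[[length(rows) + 1L]] <-
          data.frame(patient_id = pid, center = cfg$center_id,
                     label = labels[i], split = split[i], image_path = rel,
                     stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "root") <- out_dir
  attr(manifest, "seed") <- seed
  manifest
}

#' Load and validate a dataset manifest
#'
#' @param path Path to a manifest CSV with columns `patient_id`, `center`,
#'   `label`, `split`, `image_path`.
#' @param check_files Verify that every referenced image exists (relative
#'   to the manifest's directory).
#' @return The validated manifest data frame with attribute `root`.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "center", "label", "split", "image_path")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0)
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(m) == 0) stop("manifest is empty")
  bad <- which(!m$label %in% c(0L, 1L))
  if (length(bad) > 0)
    stop(sprintf("row %d: invalid label '%s' (must be 0 or 1)", bad[1],
                 m$label[bad[1]]))
  bad <- which(!m$split %in% c("train", "validation", "test"))
  if (length(bad) > 0)
    stop(sprintf("row %d: unknown split tag '%s'", bad[1], m$split[bad[1]]))
  pl <- tapply(m$label, m$patient_id, function(v) length(unique(v)))
  if (any(pl > 1))
    stop("patient ", names(pl)[which(pl > 1)[1]], " has inconsistent labels")
  ps <- tapply(m$split, m$patient_id, function(v) length(unique(v)))
  if (any(ps > 1))
    stop("patient ", names(ps)[which(ps > 1)[1]], " appears in several splits")
  root <- dirname(path)
  if (check_files) {
    ex <- file.exists(file.path(root, m$image_path))
    if (!all(ex))
      stop(sprintf("row %d: image file not found: %s", which(!ex)[1],
                   m$image_path[which(!ex)[1]]))
  }
  attr(m, "root") <- root
  m
}

read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a
}

#' Load per-center image data from a manifest
#'
#' Reads every referenced PNG and groups images by center and split into
#' the in-memory structure consumed by [run_federated_training()].
#'
#' @param manifest Manifest data frame (from [load_manifest()] or
#'   [generate_multicenter_dataset()]).
#' @param root Image root directory (defaults to the manifest's `root`
#'   attribute).
#' @return Named list (one element per center) of split lists; each split
#'   has `X` (`H x W x 1 x N` array), `y` (per-image labels) and `patient`
#'   (per-image patient ids).
#' @export
load_center_data <- function(manifest, root = attr(manifest, "root")) {
  if (is.null(root)) stop("no image root directory given")
  out <- list()
  for (ct in unique(manifest$center)) {
    msub <- manifest[manifest$center == ct, ]
    out[[as.character(ct)]] <- lapply(
      stats::setNames(c("train", "validation", "test"),
                      c("train", "validation", "test")),
      function(sp) {
        ms <- msub[msub$split == sp, ]
        if (nrow(ms) == 0) return(list(X = NULL, y = integer(0),
                                       patient = character(0)))
        imgs <- lapply(file.path(root, ms$image_path), read_gray_png)
        list(X = as_image_batch(imgs), y = as.integer(ms$label),
             patient = as.character(ms$patient_id))
      })
  }
  out
}
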