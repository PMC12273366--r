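#' Backbone architecture specification
#'
#' Two convolutional backbones are supported. `tiny_cnn` is a small trainable
#' network (conv-relu-pool-conv-relu-global-mean-fc) used for the scaled-down
#' federated benchmark; its gradient path is fully implemented. The
#' `resnet34_shape` backbone reproduces the ResNet-34 topology — a 7x7 stem
#' convolution plus two 3x3 convolutions in each basic block over stages of
#' 3/4/6/3 blocks with 64/128/256/512 channels (projection-shortcut 1x1
#' convolutions are not counted) — and supports initialization, forward
#' inference and channel-mean feature extraction. Summing the counted conv
#' output channels gives the downstream feature dimension: 7,616 for
#' `resnet34_shape`.
#'
#' @param name `"tiny_cnn"` or `"resnet34_shape"`.
#' @param input_size Input image side length in pixels (images are square
#'   grayscale).
#' @param num_classes Number of classes `C` (default 2).
#' @param conv_channels For `tiny_cnn`, the two conv channel counts
#'   (default `c(8, 16)`).
#' @return List of class `rfed_backbone_spec` including `conv_channel_list`,
#'   the ordered output-channel count of every counted conv layer, and
#'   `d_feat = sum(conv_channel_list)`.
#' @examples
#' sum(backbone_spec("resnet34_shape")$conv_channel_list)  # 7616
#' @export
backbone_spec <- function(name = c("tiny_cnn", "resnet34_shape"),
                          input_size = 32, num_classes = 2,
                          conv_channels = c(8, 16)) {
  name <- match.arg(name)
  if (input_size < 8) stop("input_size must be at least 8")
  if (name == "tiny_cnn") {
    if (length(conv_channels) != 2 || any(conv_channels < 1))
      stop("tiny_cnn needs two positive conv channel counts")
    ch <- as.integer(conv_channels)
  } else {
    stage_ch <- c(64L, 128L, 256L, 512L)
    stage_blocks <- c(3L, 4L, 6L, 3L)
    ch <- c(64L, unlist(mapply(function(c_, b) rep(c_, 2L * b),
                               stage_ch, stage_blocks, SIMPLIFY = FALSE)))
  }
  structure(list(name = name, input_size = as.integer(input_size),
                 num_classes = as.integer(num_classes),
                 conv_channel_list = ch, d_feat = sum(ch)),
            class = "rfed_backbone_spec")
}

he_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

#' Build a backbone model
#'
#' Deterministically initializes all parameters from `seed` (He-normal conv
#' weights, zero biases, small-normal classifier head) together with
#' per-class margin-calibration parameters (scale 1, offset 0).
#'
#' @param spec A [backbone_spec()].
#' @param seed Integer seed; the same seed yields bit-identical parameters.
#' @return List of class `rfed_model` with `spec`, `params` (a
#'   [parameter_set()]) and `calib` (`rho` is the pre-softplus scale so the
#'   trained scale stays positive; `beta` the offset).
#' @export
build_backbone <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "rfed_backbone_spec"))
  params <- with_seed(seed, {
    if (spec$name == "tiny_cnn") {
      ch <- spec$conv_channel_list
      list(conv1_W = he_init(3, 3, 1, ch[1]), conv1_b = numeric(ch[1]),
           conv2_W = he_init(3, 3, ch[1], ch[2]), conv2_b = numeric(ch[2]),
           # near-zero head: the initial ranking direction is learned from
           # data instead of being a random draw
           fc_W = matrix(stats::rnorm(spec$num_classes * ch[2], sd = 0.01),
                         spec$num_classes, ch[2]),
           fc_b = numeric(spec$num_classes))
    } else {
      p <- list(conv1_W = he_init(7, 7, 1, 64), conv1_b = numeric(64))
      stage_ch <- c(64L, 128L, 256L, 512L)
      stage_blocks <- c(3L, 4L, 6L, 3L)
      cin <- 64L
      for (s in 1:4) {
        cout <- stage_ch[s]
        for (b in seq_len(stage_blocks[s])) {
          pre <- sprintf("s%db%d_", s, b)
          p[[paste0(pre, "convA_W")]] <- he_init(3, 3, cin, cout)
          p[[paste0(pre, "convA_b")]] <- numeric(cout)
          p[[paste0(pre, "convB_W")]] <- he_init(3, 3, cout, cout)
          p[[paste0(pre, "convB_b")]] <- numeric(cout)
          if (b == 1 && cin != cout) {
            p[[paste0(pre, "proj_W")]] <- he_init(1, 1, cin, cout)
            p[[paste0(pre, "proj_b")]] <- numeric(cout)
          }
          cin <- cout
        }
      }
      p$fc_W <- matrix(stats::rnorm(spec$num_classes * 512,
                                    sd = sqrt(1 / 512)),
                       spec$num_classes, 512)
      p$fc_b <- numeric(spec$num_classes)
      p
    }
  })
  structure(list(spec = spec, params = parameter_set(params),
                 calib = list(rho = rep(inv_softplus(1), spec$num_classes),
                              beta = numeric(spec$num_classes))),
            class = "rfed_model")
}

# Coerce images to an (H, W, 1, N) batch array.
as_image_batch <- function(x) {
  if (is.list(x)) {
    stopifnot(length(x) >= 1)
    H <- nrow(x[[1]]); W <- ncol(x[[1]])
    arr <- array(0, c(H, W, 1, length(x)))
    for (i in seq_along(x)) arr[, , 1, i] <- x[[i]]
    return(arr)
  }
  d <- dim(x)
  if (is.null(d)) stop("images must be matrices or arrays")
  if (length(d) == 2) array(x, c(d[1], d[2], 1, 1))
  else if (length(d) == 3) array(x, c(d[1], d[2], 1, d[3]))
  else x
}

# Spatial mean of every channel: (H, W, C, N) -> N x C matrix.
channel_means <- function(a) {
  d <- dim(a)
  t(matrix(colMeans(matrix(a, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}

# Fixed preprocessing/scaling constants of the tiny_cnn architecture:
# inputs in [0, 1] are centered at mid-gray, and the globally pooled
# features are scaled so their magnitude suits SGD at the default
# learning rate.
TINY_INPUT_SHIFT <- 0.5
TINY_Z_GAIN <- 8

# Forward pass for tiny_cnn. Returns logits, pooled features z and (if
# wanted) the backward cache and the per-conv channel-mean feature taps.
forward_tiny <- function(model, x, want_cache = FALSE, want_taps = FALSE) {
  p <- model$params
  x <- x - TINY_INPUT_SHIFT
  r1 <- rfed_conv2d_fw(x, p$conv1_W, p$conv1_b, 1L, 1L, 1L)  # fused ReLU
  p1 <- rfed_pool_fw(r1, 4L, 4L, 0L, 0L)$out
  r2 <- rfed_conv2d_fw(p1, p$conv2_W, p$conv2_b, 1L, 1L, 1L)
  z <- channel_means(r2) * TINY_Z_GAIN           # N x C2
  eta <- sweep(z %*% t(p$fc_W), 2, p$fc_b, `+`)  # N x num_classes
  out <- list(z = z, eta = eta)
  if (want_cache)
    out$cache <- list(x = x, r1 = r1, p1 = p1, r2 = r2)
  if (want_taps) out$taps <- cbind(channel_means(r1), channel_means(r2))
  out
}

# Backward pass for tiny_cnn. dz: N x C2 gradient w.r.t. pooled features
# (head gradients dfcW/dfcb are passed through unchanged).
backward_tiny <- function(model, cache, dz, dfcW, dfcb) {
  d2 <- dim(cache$r2)
  # global channel mean (scaled by the fixed gain): each spatial cell
  # receives gain * dz / (H*W)
  dpost2 <- rfed_global_mean_bw(dz * TINY_Z_GAIN, d2[1], d2[2])
  dpost2 <- rfed_relu_mask(dpost2, cache$r2)
  bw2 <- rfed_conv2d_bw(cache$p1, model$params$conv2_W, dpost2, 1L, 1L)
  dp1 <- rfed_pool_bw(bw2$dx, dim(cache$r1), integer(0), 4L, 4L, 0L, 0L)
  dp1 <- rfed_relu_mask(dp1, cache$r1)
  bw1 <- rfed_conv2d_bw(cache$x, model$params$conv1_W, dp1, 1L, 1L)
  list(conv1_W = bw1$dw, conv1_b = bw1$db,
       conv2_W = bw2$dw, conv2_b = bw2$db,
       fc_W = dfcW, fc_b = dfcb)
}

# Forward pass for the ResNet-34-topology backbone (inference/feature
# extraction only; the training gradient path is implemented for tiny_cnn).
forward_resnet <- function(model, x, want_taps = FALSE) {
  p <- model$params
  relu <- function(a) { r <- pmax(a, 0); dim(r) <- dim(a); r }
  taps <- list()
  tap <- function(a) if (want_taps) taps[[length(taps) + 1L]] <<- channel_means(a)
  a <- relu(rfed_conv2d_fw(x, p$conv1_W, p$conv1_b, 2L, 3L))
  tap(a)
  a <- rfed_pool_fw(a, 3L, 2L, 1L, 1L)$out
  stage_blocks <- c(3L, 4L, 6L, 3L)
  for (s in 1:4) {
    for (b in seq_len(stage_blocks[s])) {
      pre <- sprintf("s%db%d_", s, b)
      stride <- if (s > 1 && b == 1) 2L else 1L
      ha <- relu(rfed_conv2d_fw(a, p[[paste0(pre, "convA_W")]],
                                p[[paste0(pre, "convA_b")]], stride, 1L))
      tap(ha)
      hb <- rfed_conv2d_fw(ha, p[[paste0(pre, "convB_W")]],
                           p[[paste0(pre, "convB_b")]], 1L, 1L)
      shortcut <- if (!is.null(p[[paste0(pre, "proj_W")]]))
        rfed_conv2d_fw(a, p[[paste0(pre, "proj_W")]],
                       p[[paste0(pre, "proj_b")]], stride, 0L)
      else a
      a <- relu(hb + shortcut)
      tap(a)
    }
  }
  z <- channel_means(a)
  eta <- sweep(z %*% t(p$fc_W), 2, p$fc_b, `+`)
  out <- list(z = z, eta = eta)
  if (want_taps) out$taps <- do.call(cbind, taps)
  out
}

# Unified forward dispatch.
model_forward <- function(model, x, want_cache = FALSE, want_taps = FALSE) {
  stopifnot(inherits(model, "rfed_model"))
  x <- as_image_batch(x)
  if (model$spec$name == "tiny_cnn")
    forward_tiny(model, x, want_cache, want_taps)
  else forward_resnet(model, x, want_taps)
}

#' Class probabilities and patient-level scores
#'
#' `predict_with_personalized()` runs a trained model over images and
#' returns the softmax probability of the positive class (label 1) for each
#' image; `patient_score()` averages those probabilities over one patient's
#' images.
#'
#' @param model An `rfed_model` (typically a client's personalized model).
#' @param images A matrix (one image), `H x W x N` array, or list of
#'   matrices.
#' @return Numeric vector of per-image positive-class probabilities.
#' @export
predict_with_personalized <- function(model, images) {
  x <- as_image_batch(images)
  if (dim(x)[4] == 0) stop("empty image list")
  eta <- model_forward(model, x)$eta
  em <- exp(eta - apply(eta, 1, max))
  (em / rowSums(em))[, 2]
}

#' @rdname predict_with_personalized
#' @export
patient_score <- function(model, images) {
  mean(predict_with_personalized(model, images))
}
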