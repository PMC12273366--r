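#' Configuration of the staged transfer schedule
#'
#' @param lambda_A Non-negative weight of the distribution-alignment term
#'   (default 0.1; the feature-space anchor must stay subdominant to the
#'   supervised gradient or staged transfer deadlocks at desk scale).
#' @param surrogate `"mean_feature"` (default; squared distance between
#'   batch-mean features, differentiable) or `"proxy_a"` (classical proxy
#'   A-distance from a held-out linear discriminator, reported for
#'   monitoring only).
#' @param plain_ce Use plain cross-entropy as the supervised loss instead of
#'   the personalized (margin-calibrated + contrastive) loss.
#' @param eval_every Check stage transitions every this many communication
#'   rounds (default 5: AUC comparisons between deputy and personalized
#'   models are meaningful only after a substantial block of local
#'   training; validation AUCs themselves are logged every round).
#' @return List of class `rfed_attl_config`.
#' @export
attl_config <- function(lambda_A = 0.1, surrogate = c("mean_feature", "proxy_a"),
                        plain_ce = FALSE, eval_every = 5L) {
  surrogate <- match.arg(surrogate)
  if (lambda_A < 0) stop("lambda_A must be non-negative")
  structure(list(lambda_A = lambda_A, surrogate = surrogate,
                 plain_ce = isTRUE(plain_ce),
                 eval_every = as.integer(eval_every)),
            class = "rfed_attl_config")
}

#' Distribution-discrepancy term between two feature batches
#'
#' With the `mean_feature` surrogate (default) this is the squared Euclidean
#' distance between the two batch-mean feature vectors: zero iff the means
#' coincide, and differentiable in the updated model's features. With
#' `proxy_a` it is the classical proxy A-distance `2 * (1 - 2 * eps)`, where
#' `eps` is the held-out error of a logistic discriminator trained to tell
#' the two feature sets apart (non-differentiable; used for monitoring).
#'
#' @param feats_ref `B x d` features from the frozen reference model.
#' @param feats_upd `B x d` features from the model being updated.
#' @param cfg An [attl_config()].
#' @return Scalar discrepancy.
#' @export
a_distance_term <- function(feats_ref, feats_upd, cfg = attl_config()) {
  feats_ref <- as.matrix(feats_ref); feats_upd <- as.matrix(feats_upd)
  if (ncol(feats_ref) != ncol(feats_upd))
    stop("feature dimensions differ between the two batches")
  if (cfg$surrogate == "mean_feature")
    return(sum((colMeans(feats_upd) - colMeans(feats_ref))^2))
  n1 <- nrow(feats_ref); n2 <- nrow(feats_upd)
  if (n1 < 2 || n2 < 2) stop("proxy_a needs at least 2 samples per batch")
  X <- rbind(feats_ref, feats_upd)
  ylab <- c(rep(0, n1), rep(1, n2))
  idx <- sample.int(nrow(X))                     # shuffle before the split
  X <- X[idx, , drop = FALSE]; ylab <- ylab[idx]
  ntr <- floor(nrow(X) / 2)
  fit <- suppressWarnings(stats::glm.fit(cbind(1, X[seq_len(ntr), , drop = FALSE]),
                                         ylab[seq_len(ntr)],
                                         family = stats::binomial()))
  te <- (ntr + 1):nrow(X)
  pr <- sigmoid(cbind(1, X[te, , drop = FALSE]) %*% fit$coefficients)
  eps <- mean((pr >= 0.5) != ylab[te])
  2 * (1 - 2 * eps)
}

#' Stage-transition rule of the three-stage transfer schedule
#'
#' Training advances from stage I (personalized model frozen, deputy learns)
#' to stage II (mutual learning) once the deputy's validation AUC exceeds
#' the personalized model's, and from stage II to stage III (deputy frozen,
#' personalized model learns) once the personalized model's AUC exceeds the
#' deputy's. Stage III is absorbing and exact ties keep the current stage,
#' so the stage walk is monotone I -> II -> III.
#'
#' @param auc_P,auc_D Latest validation AUCs of the personalized and deputy
#'   models, in `[0, 1]`.
#' @param stage Current stage, one of `"I"`, `"II"`, `"III"`.
#' @return The next stage.
#' @export
stage_transition <- function(auc_P, auc_D, stage = c("I", "II", "III")) {
  stage <- match.arg(stage)
  stopifnot(auc_P >= 0, auc_P <= 1, auc_D >= 0, auc_D <= 1)
  if (stage == "I" && auc_D > auc_P) return("II")
  if (stage == "II" && auc_P > auc_D) return("III")
  stage
}

#' Client model triplet
#'
#' Bundles one client's deputy model `D` (receives aggregated knowledge),
#' personalized model `P` (never leaves the client, serves as its final
#' predictor), current transfer stage and contrastive bank.
#'
#' @param deputy,personalized `rfed_model` objects sharing one architecture.
#' @param stage Transfer stage (`"I"`, `"II"`, `"III"`).
#' @param client_index 1-based index of this client in the federation.
#' @param bank Optional [representation_bank()] broadcast by the server.
#' @return List of class `rfed_triplet`.
#' @export
client_triplet <- function(deputy, personalized, stage = "I",
                           client_index = 1L, bank = NULL) {
  stopifnot(inherits(deputy, "rfed_model"), inherits(personalized, "rfed_model"))
  structure(list(deputy = deputy, personalized = personalized,
                 stage = match.arg(stage, c("I", "II", "III")),
                 client_index = as.integer(client_index), bank = bank,
                 val_auc_D = NA_real_, val_auc_P = NA_real_),
            class = "rfed_triplet")
}

# Flattened fully-connected-layer parameters of a model (weights then bias).
fc_representation <- function(params) {
  c(as.numeric(params$fc_W), as.numeric(params$fc_b))
}

#' One supervised SGD step on a single model
#'
#' Minimizes the supervised objective (margin-calibrated cross-entropy plus
#' `alpha` times the contrastive alignment term when a bank is present; or
#' plain cross-entropy with `plain_ce`) plus `lambda_A` times the
#' `mean_feature` distribution-alignment term against the frozen reference
#' model. The step is purely deterministic given the batch. Only the
#' `tiny_cnn` backbone has a gradient path.
#'
#' @param model The `rfed_model` to update.
#' @param batch A [labeled_batch()] whose `z` slot holds raw images (an
#'   `(H, W, 1, B)` array) rather than encoded features.
#' @param lr Learning rate (plain SGD).
#' @param ref_model Optional frozen reference model for the alignment term.
#' @param bank Optional [representation_bank()]; `k` is this client's index.
#' @param k Client index into the bank.
#' @param attl_cfg An [attl_config()].
#' @param marc_trainable Update the margin-calibration parameters jointly.
#' @param clip_norm Clip the global L2 norm of the gradient (model and
#'   calibration parameters together) to this value before the update
#'   (default 5; `Inf` disables).
#' @return List with the updated `model` and scalar diagnostics `loss`,
#'   `marc`, `cpc`, `adist`.
#' @export
supervised_step <- function(model, batch, lr = 0.01, ref_model = NULL,
                            bank = NULL, k = 1L, attl_cfg = attl_config(),
                            marc_trainable = TRUE, clip_norm = 5) {
  stopifnot(inherits(model, "rfed_model"))
  if (model$spec$name != "tiny_cnn")
    stop("gradient training is implemented for the tiny_cnn backbone")
  x <- as_image_batch(batch$z)
  B <- dim(x)[4]
  fw <- forward_tiny(model, x, want_cache = TRUE)
  head <- classifier_head(model$params$fc_W, model$params$fc_b)
  if (isTRUE(attl_cfg$plain_ce)) {
    calib <- margin_calibration(rep(1, head$C), rep(0, head$C))
    update_calib <- FALSE
  } else {
    # softplus keeps the scale positive; the floor guards underflow when
    # rho drifts far negative
    calib <- margin_calibration(softplus(model$calib$rho) + 1e-6,
                                model$calib$beta)
    update_calib <- isTRUE(marc_trainable)
  }
  fb <- labeled_batch(fw$z, batch$y)
  mg <- marc_loss_grad(head, calib, fb)
  dz <- mg$dz; dfcW <- mg$dW; dfcb <- mg$db
  loss_marc <- mg$loss
  loss_cpc <- 0
  if (!is.null(bank) && bank$K > 1 && !attl_cfg$plain_ce) {
    bank$f_locals[[k]] <- fc_representation(model$params)
    cg <- cpc_loss_grad(bank, k)
    loss_cpc <- cg$loss
    nW <- length(model$params$fc_W)
    dfcW <- dfcW + bank$alpha * matrix(cg$df[seq_len(nW)],
                                       nrow(model$params$fc_W))
    dfcb <- dfcb + bank$alpha * cg$df[(nW + 1):length(cg$df)]
  }
  loss_adist <- 0
  if (!is.null(ref_model) && attl_cfg$lambda_A > 0) {
    z_ref <- model_forward(ref_model, x)$z
    mu_d <- colMeans(fw$z) - colMeans(z_ref)
    loss_adist <- sum(mu_d^2)
    dz <- dz + attl_cfg$lambda_A *
      matrix(2 * mu_d / B, B, length(mu_d), byrow = TRUE)
  }
  alpha <- if (is.null(bank)) 0 else bank$alpha
  loss <- loss_marc + alpha * loss_cpc + attl_cfg$lambda_A * loss_adist
  if (!is.finite(loss))
    stop(sprintf("non-finite training loss (marc=%g cpc=%g adist=%g)",
                 loss_marc, loss_cpc, loss_adist))
  grads <- backward_tiny(model, fw$cache, dz, dfcW, dfcb)
  drho <- if (update_calib) mg$domega * sigmoid(model$calib$rho) else NULL
  if (is.finite(clip_norm)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 1)) +
                 (if (update_calib) sum(drho^2) + sum(mg$dbeta^2) else 0))
    if (gn > clip_norm) {
      sc <- clip_norm / gn
      grads <- lapply(grads, `*`, sc)
      if (update_calib) drho <- drho * sc
      if (update_calib) mg$dbeta <- mg$dbeta * sc
    }
  }
  for (nm in names(grads))
    model$params[[nm]] <- model$params[[nm]] - lr * grads[[nm]]
  if (update_calib) {
    # omega = softplus(rho): chain rule through the positivity constraint
    model$calib$rho <- model$calib$rho - lr * drho
    model$calib$beta <- model$calib$beta - lr * mg$dbeta
  }
  list(model = model, loss = loss, marc = loss_marc, cpc = loss_cpc,
       adist = loss_adist)
}

#' One staged transfer update on a client triplet
#'
#' Applies the stage-dependent optimization step: stage I freezes the
#' personalized model and updates the deputy against it; stage II performs
#' mutual learning (deputy step, then personalized step against the freshly
#' updated deputy); stage III freezes the deputy and updates the
#' personalized model against it. The frozen model is returned untouched.
#'
#' @param triplet A [client_triplet()].
#' @param batch A [labeled_batch()] of raw images.
#' @param lr Learning rate.
#' @param attl_cfg An [attl_config()].
#' @return List with the updated `triplet` and a `record` of per-model
#'   losses for this step.
#' @export
attl_update <- function(triplet, batch, lr = 0.01, attl_cfg = attl_config()) {
  stopifnot(inherits(triplet, "rfed_triplet"))
  k <- triplet$client_index
  rec <- list(stage = triplet$stage, loss_D = NA_real_, loss_P = NA_real_)
  if (triplet$stage %in% c("I", "II")) {
    st <- supervised_step(triplet$deputy, batch, lr,
                          ref_model = triplet$personalized,
                          bank = triplet$bank, k = k, attl_cfg = attl_cfg)
    triplet$deputy <- st$model
    rec$loss_D <- st$loss
  }
  if (triplet$stage %in% c("II", "III")) {
    st <- supervised_step(triplet$personalized, batch, lr,
                          ref_model = triplet$deputy,
                          bank = triplet$bank, k = k, attl_cfg = attl_cfg)
    triplet$personalized <- st$model
    rec$loss_P <- st$loss
  }
  list(triplet = triplet, record = rec)
}
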