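#' Federated training configuration
#'
#' Defaults follow the study conditions: batch size 32, plain SGD at
#' learning rate 0.01, communication every 50 local batch iterations
#' organized as blocks of 5 staged-transfer steps.
#'
#' @param rounds Total communication rounds `T`.
#' @param batch_size Mini-batch size (default 32).
#' @param lr SGD learning rate (default 0.01).
#' @param local_iters_per_round Local batch iterations between
#'   communications (default 50).
#' @param attl_steps_per_block Steps per staged-transfer block (default 5).
#' @param pretrain_iters Supervised-only iterations that initialize each
#'   center's personalized model before federation starts (default 100).
#'   The staged transfer begins by moving knowledge from the personalized
#'   model to the deputy, which presumes the personalized model is the
#'   center's trained local model rather than a random draw.
#' @param seed Integer seed controlling every source of randomness.
#' @return List of class `rfed_train_config`.
#' @export
training_config <- function(rounds, batch_size = 32, lr = 0.01,
                            local_iters_per_round = 50,
                            attl_steps_per_block = 5, pretrain_iters = 100,
                            seed = 1L) {
  stopifnot(rounds >= 1, batch_size >= 1, lr > 0,
            local_iters_per_round >= 0, attl_steps_per_block >= 1,
            pretrain_iters >= 0)
  structure(list(rounds = as.integer(rounds),
                 batch_size = as.integer(batch_size), lr = lr,
                 local_iters_per_round = as.integer(local_iters_per_round),
                 attl_steps_per_block = as.integer(attl_steps_per_block),
                 pretrain_iters = as.integer(pretrain_iters),
                 seed = as.integer(seed)),
            class = "rfed_train_config")
}

# Sample a batch of image indices (with replacement only if the split is
# smaller than the batch).
sample_batch_idx <- function(n, batch_size) {
  sample.int(n, min(n, batch_size), replace = n < batch_size)
}

make_batch <- function(split_data, idx) {
  labeled_batch(split_data$X[, , , idx, drop = FALSE], split_data$y[idx])
}

#' One local training round on a client
#'
#' Runs `local_iters_per_round` mini-batch iterations, grouped into blocks
#' of `attl_steps_per_block` staged-transfer updates, and returns the
#' deputy's parameters for communication. The personalized model never
#' leaves the client. With `local_iters_per_round = 0` the returned
#' parameters equal the deputy's pre-round parameters.
#'
#' @param triplet A [client_triplet()].
#' @param data Client split list with `X` (`H x W x 1 x N` image array) and
#'   `y` (labels) for the training split.
#' @param cfg A [training_config()].
#' @param attl_cfg An [attl_config()].
#' @param method `"rfed"` (staged transfer, personalized loss) or
#'   `"fedavg"` (single deputy model, plain cross-entropy).
#' @return List with the updated `triplet`, `theta` (deputy parameters) and
#'   `block_loss` (mean deputy/personalized loss per block).
#' @export
local_round <- function(triplet, data, cfg, attl_cfg = attl_config(),
                        method = c("rfed", "fedavg")) {
  method <- match.arg(method)
  n <- length(data$y)
  if (n == 0) stop("client has no training data")
  iters <- cfg$local_iters_per_round
  block_loss <- numeric(0)
  if (iters > 0) {
    n_blocks <- ceiling(iters / cfg$attl_steps_per_block)
    it <- 0
    for (blk in seq_len(n_blocks)) {
      losses <- c()
      while (it < min(iters, blk * cfg$attl_steps_per_block)) {
        it <- it + 1
        batch <- make_batch(data, sample_batch_idx(n, cfg$batch_size))
        if (method == "rfed") {
          up <- attl_update(triplet, batch, cfg$lr, attl_cfg)
          triplet <- up$triplet
          # the deputy is locally updated every round for communication;
          # in stage III the staged-transfer step no longer trains it, so
          # it takes a plain supervised step here (no alignment term)
          if (triplet$stage == "III") {
            st <- supervised_step(triplet$deputy, batch, cfg$lr,
                                  bank = triplet$bank,
                                  k = triplet$client_index,
                                  attl_cfg = attl_config(
                                    lambda_A = 0,
                                    plain_ce = attl_cfg$plain_ce))
            triplet$deputy <- st$model
          }
          losses <- c(losses, mean(c(up$record$loss_D, up$record$loss_P),
                                   na.rm = TRUE))
        } else {
          st <- supervised_step(triplet$deputy, batch, cfg$lr,
                                attl_cfg = attl_config(lambda_A = 0,
                                                       plain_ce = TRUE))
          triplet$deputy <- st$model
          losses <- c(losses, st$loss)
        }
      }
      block_loss <- c(block_loss, mean(losses))
    }
  }
  list(triplet = triplet, theta = triplet$deputy$params,
       block_loss = block_loss)
}

# Patient-level scores of one model on one split.
split_patient_scores <- function(model, split_data) {
  probs <- predict_with_personalized(model, split_data$X)
  agg <- tapply(probs, split_data$patient, mean)
  lab <- tapply(split_data$y, split_data$patient, function(v) v[1])
  data.frame(patient_id = names(agg), score = as.numeric(agg),
             label = as.integer(lab[names(agg)]), stringsAsFactors = FALSE)
}

model_with_params <- function(model, params) {
  model$params <- params
  model
}

#' Run multicenter federated training
#'
#' Orchestrates the full loop: per round, every client trains locally
#' ([local_round()]); the server aggregates deputies (Fourier-domain partial
#' aggregation for `"rfed"`, elementwise averaging for `"fedavg"`); the
#' global model is the elementwise mean of the deputies; the contrastive
#' bank (global + per-client classifier-layer parameters) is refreshed and
#' broadcast; and per-client validation AUCs of deputy and personalized
#' models drive the stage transitions. Deterministic given `cfg$seed`.
#'
#' @param data Per-center data as returned by [load_center_data()]: a named
#'   list, one element per center, each with `train`, `validation`, `test`
#'   splits (`X`, `y`, `patient`).
#' @param cfg A [training_config()].
#' @param method `"rfed"` or `"fedavg"`.
#' @param backbone A [backbone_spec()] (default `tiny_cnn` sized to the
#'   data).
#' @param agg Aggregation settings: list with `r_max`,
#'   `retain_local_high_band`, `reshape_mode` (see [aggregation_config()]).
#' @param loss_cfg List with `alpha` (contrastive weight, default 0.6) and
#'   `tau` (temperature, default 1).
#' @param attl_cfg An [attl_config()].
#' @param verbose Print round summaries.
#' @return List of class `rfed_state`: `clients` (triplets), `global_params`,
#'   `history` (round-by-round per-client data frame), plus the configs.
#' @export
run_federated_training <- function(data, cfg, method = c("rfed", "fedavg"),
                                   backbone = NULL,
                                   agg = list(r_max = 0.3,
                                              retain_local_high_band = TRUE,
                                              reshape_mode = "whole_model"),
                                   loss_cfg = list(alpha = 0.6, tau = 1),
                                   attl_cfg = attl_config(),
                                   verbose = FALSE) {
  method <- match.arg(method)
  K <- length(data)
  if (K < 1) stop("need at least one center")
  centers <- names(data)
  if (is.null(backbone))
    backbone <- backbone_spec("tiny_cnn", input_size = dim(data[[1]]$train$X)[1])
  set.seed(derive_seed(cfg$seed, 1))
  g0 <- build_backbone(backbone, seed = derive_seed(cfg$seed, 2))
  clients <- lapply(seq_len(K), function(k) {
    m <- g0
    # head bias starts at the center's log class prior so that the
    # imbalance prior is absorbed by the bias, not by the weights (whose
    # prior-fitting direction would anti-rank high-activation samples)
    prev <- mean(data[[k]]$train$y == 1)
    prev <- min(max(prev, 1 / length(data[[k]]$train$y)), 1 - 1e-6)
    m$params$fc_b <- c(0, log(prev / (1 - prev)))
    client_triplet(m, m, client_index = k)
  })
  # local supervised pretraining of each personalized model: the staged
  # transfer starts by distilling P into D, so P enters as the center's
  # trained local model
  pre <- cfg$pretrain_iters %||% 0L
  if (method == "rfed" && pre > 0) {
    for (k in seq_len(K)) {
      set.seed(derive_seed(cfg$seed, 7001, k))
      n <- length(data[[k]]$train$y)
      for (i in seq_len(pre)) {
        batch <- make_batch(data[[k]]$train,
                            sample_batch_idx(n, cfg$batch_size))
        clients[[k]]$personalized <-
          supervised_step(clients[[k]]$personalized, batch, cfg$lr,
                          attl_cfg = attl_config(lambda_A = 0))$model
      }
    }
  }
  global_params <- g0$params
  history <- list()
  for (t in 0:(cfg$rounds - 1)) {
    thetas <- vector("list", K)
    for (k in seq_len(K)) {
      set.seed(derive_seed(cfg$seed, t, k))
      lr_out <- local_round(clients[[k]], data[[k]]$train, cfg, attl_cfg,
                            method)
      clients[[k]] <- lr_out$triplet
      thetas[[k]] <- lr_out$theta
    }
    if (method == "rfed") {
      acfg <- aggregation_config(cfg$rounds, t, r_max = agg$r_max,
                                 retain_local_high_band =
                                   isTRUE(agg$retain_local_high_band),
                                 reshape_mode = agg$reshape_mode %||%
                                   "whole_model")
      deputies <- epfa_aggregate(thetas, acfg)
    } else {
      deputies <- rep(list(fedavg_aggregate(thetas)), K)
    }
    global_params <- fedavg_aggregate(deputies)
    bank <- representation_bank(fc_representation(global_params),
                                lapply(thetas, fc_representation),
                                tau = loss_cfg$tau %||% 1,
                                alpha = loss_cfg$alpha %||% 0.6)
    for (k in seq_len(K)) {
      clients[[k]]$deputy$params <- deputies[[k]]
      clients[[k]]$bank <- bank
      if (method == "fedavg")
        clients[[k]]$personalized$params <- deputies[[k]]
    }
    # validation AUCs and stage transitions
    for (k in seq_len(K)) {
      val <- data[[k]]$validation
      sc_D <- split_patient_scores(clients[[k]]$deputy, val)
      sc_P <- split_patient_scores(clients[[k]]$personalized, val)
      auc_D <- roc_auc(sc_D$score, sc_D$label)
      auc_P <- roc_auc(sc_P$score, sc_P$label)
      clients[[k]]$val_auc_D <- auc_D
      clients[[k]]$val_auc_P <- auc_P
      if (method == "rfed" && (t + 1L) %% attl_cfg$eval_every == 0L)
        clients[[k]]$stage <- stage_transition(auc_P, auc_D,
                                               clients[[k]]$stage)
      history[[length(history) + 1L]] <-
        data.frame(round = t, center = centers[k] %||% k,
                   stage = clients[[k]]$stage, auc_D = auc_D, auc_P = auc_P)
    }
    if (verbose) {
      h <- do.call(rbind, utils::tail(history, K))
      message(sprintf("round %d: mean val AUC D=%.3f P=%.3f", t,
                      mean(h$auc_D), mean(h$auc_P)))
    }
  }
  structure(list(clients = clients, global_params = global_params,
                 history = do.call(rbind, history), cfg = cfg,
                 method = method, backbone = backbone, centers = centers),
            class = "rfed_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Final predictor of one center
#'
#' Under the personalized-federated-learning principle each center deploys
#' whichever of its two models serves it better: with
#' `predictor = "auto"` (the default) the deputy is chosen when its latest
#' validation AUC strictly exceeds the personalized model's, otherwise the
#' personalized model; `"personalized"` and `"deputy"` force the choice.
#'
#' @param state An `rfed_state` from [run_federated_training()].
#' @param k Client index.
#' @param predictor `"auto"`, `"personalized"` or `"deputy"`.
#' @return The selected `rfed_model`.
#' @export
client_predictor <- function(state, k,
                             predictor = c("auto", "personalized", "deputy")) {
  predictor <- match.arg(predictor)
  cl <- state$clients[[k]]
  if (predictor == "deputy") return(cl$deputy)
  if (predictor == "personalized") return(cl$personalized)
  if (!is.na(cl$val_auc_D) && !is.na(cl$val_auc_P) &&
      cl$val_auc_D > cl$val_auc_P) cl$deputy else cl$personalized
}

#' Patient-level test scores of a trained federation
#'
#' Scores every center's split with that center's final predictor (see
#' [client_predictor()]).
#'
#' @param state An `rfed_state` from [run_federated_training()].
#' @param data The per-center data list used for training.
#' @param split Which split to score (default `"test"`).
#' @param predictor Predictor choice per center (default `"auto"`).
#' @return Data frame with `patient_id`, `center`, `label`, `score`.
#' @export
federated_scores <- function(state, data, split = "test",
                             predictor = c("auto", "personalized", "deputy")) {
  predictor <- match.arg(predictor)
  out <- list()
  for (k in seq_along(state$clients)) {
    model <- client_predictor(state, k, predictor)
    sc <- split_patient_scores(model, data[[k]][[split]])
    sc$center <- state$centers[k] %||% k
    out[[k]] <- sc
  }
  do.call(rbind, out)[, c("patient_id", "center", "label", "score")]
}
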