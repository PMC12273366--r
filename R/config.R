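#' Default run configuration
#'
#' The nested configuration consumed by the command-line interface and
#' [config_from_yaml()]. Sections: `federation` (rounds, batch size,
#' learning rate, iteration schedule, seed), `aggregation` (`r_max`,
#' `retain_local_high_band`, `reshape_mode`), `loss` (`alpha`, `tau`,
#' `marc_trainable`) and `attl` (`lambda_A`, `surrogate`, `plain_ce`,
#' `eval_every`).
#'
#' @return Nested named list of defaults.
#' @export
default_run_config <- function() {
  list(
    federation = list(rounds = 20L, batch_size = 32L, lr = 0.01,
                      local_iters_per_round = 50L, attl_steps_per_block = 5L,
                      pretrain_iters = 100L, seed = 1L),
    aggregation = list(r_max = 0.3, retain_local_high_band = TRUE,
                       reshape_mode = "whole_model"),
    loss = list(alpha = 0.6, tau = 1.0, marc_trainable = TRUE),
    attl = list(lambda_A = 0.1, surrogate = "mean_feature",
                plain_ce = FALSE, eval_every = 5L)
  )
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; unknown keys are rejected.
#'
#' @param path Path to a YAML file (may be missing sections).
#' @return Nested named list.
#' @export
config_from_yaml <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (sec in names(user)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
    for (key in names(user[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop(sprintf("unknown config key: %s.%s", sec, key))
      cfg[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  cfg
}

#' Save / load a parameter set as a text checkpoint
#'
#' Writes one JSON file holding every tensor's values plus a shape
#' manifest; plain text, loadable on any platform.
#'
#' @param params A [parameter_set()].
#' @param path Output file path (JSON).
#' @return [load_parameter_set()] returns the restored parameter set.
#' @export
save_parameter_set <- function(params, path) {
  params <- parameter_set(params)
  fl <- flatten_params(params)
  obj <- list(shapes = fl$shapes, values = fl$vector)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname save_parameter_set
#' @export
load_parameter_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  shapes <- lapply(obj$shapes, as.integer)
  unflatten_params(as.numeric(obj$values), shapes)
}
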