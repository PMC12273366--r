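#' Aggregation configuration for Fourier-domain parameter sharing
#'
#' Settings for one server aggregation round: `t` is the 0-based index of the
#' current communication round out of `T_total`, `r_max` the maximum fraction
#' of low-frequency bins ever shared, and `retain_local_high_band` selects
#' whether each client keeps its own high-frequency spectrum (the default,
#' partially personalized variant) or all clients receive the identical
#' low-pass model (the literal pseudocode variant used for ablation).
#'
#' @param T_total Total number of communication rounds (>= 1).
#' @param t Current round index, `0 <= t < T_total`.
#' @param r_max Maximum low-frequency fraction in (0, 1]. Default 0.3.
#' @param retain_local_high_band Keep client-local high-frequency bins
#'   (default `TRUE`).
#' @param reshape_mode `"whole_model"` (one DFT over the concatenated
#'   parameter vector, the default) or `"per_tensor"` (one DFT per tensor).
#' @return A list of class `rfed_agg_config`.
#' @export
aggregation_config <- function(T_total, t, r_max = 0.3,
                               retain_local_high_band = TRUE,
                               reshape_mode = c("whole_model", "per_tensor")) {
  reshape_mode <- match.arg(reshape_mode)
  if (T_total < 1) stop("T_total must be >= 1")
  if (t < 0 || t >= T_total) stop("round index t must satisfy 0 <= t < T_total")
  if (r_max <= 0 || r_max > 1) stop("r_max must lie in (0, 1]")
  structure(list(T_total = as.integer(T_total), t = as.integer(t),
                 r_max = r_max,
                 retain_local_high_band = isTRUE(retain_local_high_band),
                 reshape_mode = reshape_mode),
            class = "rfed_agg_config")
}

#' Amplitude/phase spectrum of a real parameter vector
#'
#' Computes the discrete Fourier transform of a real vector and stores the
#' non-redundant half-spectrum (bins 0..floor(n/2)) as amplitude (modulus)
#' and phase (argument in (-pi, pi]). [inverse_spectrum()] reconstructs the
#' full spectrum by Hermitian symmetry and returns the real part of the
#' inverse transform, so spectra whose amplitude/phase have been averaged
#' across clients still invert to a real parameter vector.
#'
#' @param x Real numeric vector, length >= 1, no NAs.
#' @return An `rfed_spectrum`: list with `amplitude`, `phase` (length
#'   `floor(n/2) + 1`) and `n`, the original signal length.
#' @examples
#' sp <- spectrum_decomp(c(1, 0, 0, 0))
#' sp$amplitude  # all ones
#' max(abs(inverse_spectrum(sp) - c(1, 0, 0, 0)))
#' @export
spectrum_decomp <- function(x) {
  if (length(x) < 1) stop("vector must have length >= 1")
  if (!all(is.finite(x))) stop("vector contains non-finite values")
  f <- stats::fft(x)
  m <- floor(length(x) / 2) + 1
  f <- f[seq_len(m)]
  structure(list(amplitude = Mod(f), phase = Arg(f), n = length(x)),
            class = "rfed_spectrum")
}

#' @rdname spectrum_decomp
#' @param sd_ An `rfed_spectrum`.
#' @export
inverse_spectrum <- function(sd_) {
  stopifnot(inherits(sd_, "rfed_spectrum"))
  n <- sd_$n
  m <- length(sd_$amplitude)
  half <- complex(modulus = sd_$amplitude, argument = sd_$phase)
  full <- complex(n)
  full[seq_len(m)] <- half
  if (n > m) {
    idx <- (m + 1):n                      # bins m..n-1 (0-based)
    full[idx] <- Conj(half[n - idx + 2])  # Hermitian mirror of bins n-k
  }
  Re(stats::fft(full, inverse = TRUE)) / n
}

#' Average client spectra bin-wise
#'
#' Aggregates client parameter spectra by taking the arithmetic mean of the
#' amplitudes and of the phases (as stored in (-pi, pi]) at every bin. Note
#' that separate amplitude/phase averaging is not the complex mean: clients
#' with equal amplitudes and opposite phases average to full amplitude here,
#' whereas the complex mean would shrink toward zero.
#'
#' @param decomps Non-empty list of `rfed_spectrum` objects of equal length.
#' @return The averaged `rfed_spectrum`.
#' @export
aggregate_spectra <- function(decomps) {
  if (length(decomps) == 0) stop("no spectra to aggregate")
  for (d in decomps) stopifnot(inherits(d, "rfed_spectrum"))
  n <- decomps[[1]]$n
  m <- length(decomps[[1]]$amplitude)
  for (d in decomps)
    if (d$n != n || length(d$amplitude) != m)
      stop("spectra have mismatched lengths")
  A <- rowMeans(vapply(decomps, `[[`, numeric(m), "amplitude"))
  P <- rowMeans(vapply(decomps, `[[`, numeric(m), "phase"))
  structure(list(amplitude = A, phase = P, n = n), class = "rfed_spectrum")
}

#' Low-frequency sharing schedule
#'
#' The fraction of the spectrum shared at round `t` follows the hyperbolic
#' schedule `r(t) = r_max / (T - t)` (capped at 1): almost nothing is shared at
#' the start and the band widens monotonically until a fraction `r_max` of
#' bins is shared in the final round.
#'
#' @param t Current round, `0 <= t < T_total`.
#' @param T_total Total rounds.
#' @param r_max Maximum fraction in (0, 1].
#' @return Fraction `r` in (0, 1].
#' @examples
#' low_freq_ratio(0, 10, 0.3)   # 0.03
#' low_freq_ratio(9, 10, 0.3)   # 0.3
#' @export
low_freq_ratio <- function(t, T_total, r_max = 0.3) {
  if (t < 0 || t >= T_total) stop("round index t must satisfy 0 <= t < T_total")
  if (r_max <= 0 || r_max > 1) stop("r_max must lie in (0, 1]")
  min(1, r_max / (T_total - t))
}

#' Low-frequency mask over spectrum bins
#'
#' Selects the `max(1, round(r * n_bins))` lowest-frequency bins of a
#' half-spectrum (bin 1 is DC and is always kept). Rounding is half-up so
#' that e.g. `n_bins = 10, r = 0.25` keeps 3 bins.
#'
#' @param n_bins Number of distinct (half-spectrum) bins.
#' @param r Fraction in (0, 1].
#' @return Logical vector of length `n_bins`.
#' @export
low_freq_mask <- function(n_bins, r) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (r <= 0 || r > 1) stop("r must lie in (0, 1]")
  k <- max(1L, min(n_bins, as.integer(floor(r * n_bins + 0.5))))
  c(rep(TRUE, k), rep(FALSE, n_bins - k))
}

# Shared worker: aggregate a list of equal-length real vectors in the
# frequency domain; returns one deputy vector per client.
epfa_aggregate_vectors <- function(vecs, r, retain_local_high_band) {
  decomps <- lapply(vecs, spectrum_decomp)
  avg <- aggregate_spectra(decomps)
  F_avg <- complex(modulus = avg$amplitude, argument = avg$phase)
  mask <- low_freq_mask(length(F_avg), r)
  F_low <- F_avg * mask
  lapply(decomps, function(d) {
    F_dep <- if (retain_local_high_band) {
      F_k <- complex(modulus = d$amplitude, argument = d$phase)
      F_low + F_k * !mask
    } else F_low
    inverse_spectrum(structure(list(amplitude = Mod(F_dep),
                                    phase = Arg(F_dep), n = d$n),
                               class = "rfed_spectrum"))
  })
}

#' Fourier-domain partial aggregation of client models
#'
#' One server aggregation step: every client's flattened parameters are
#' Fourier-transformed; amplitude and phase spectra are averaged bin-wise;
#' the averaged spectrum is masked to its lowest-frequency band (whose width
#' follows [low_freq_ratio()]); and each client's new deputy model is the
#' inverse transform of the shared low band combined with (by default) that
#' client's own high-frequency bins. With
#' `retain_local_high_band = FALSE` the high band is zeroed instead and all
#' clients receive the identical low-pass deputy.
#'
#' @param client_params List of parameter sets, one per client, sharing one
#'   architecture (same tensor names, shapes and ordering).
#' @param cfg An [aggregation_config()].
#' @return List of deputy parameter sets, one per client, with the input
#'   shapes.
#' @export
epfa_aggregate <- function(client_params, cfg) {
  stopifnot(inherits(cfg, "rfed_agg_config"))
  if (length(client_params) == 0) stop("no clients to aggregate")
  client_params <- lapply(client_params, parameter_set)
  check_same_architecture(client_params)
  r <- low_freq_ratio(cfg$t, cfg$T_total, cfg$r_max)
  flat <- lapply(client_params, flatten_params)
  shapes <- flat[[1]]$shapes
  if (cfg$reshape_mode == "whole_model") {
    vecs <- lapply(flat, `[[`, "vector")
    deps <- epfa_aggregate_vectors(vecs, r, cfg$retain_local_high_band)
    lapply(deps, unflatten_params, shapes = shapes)
  } else {
    nm <- names(client_params[[1]])
    out <- lapply(client_params, function(p) p)  # template copies
    for (tn in nm) {
      vecs <- lapply(client_params, function(p) as.numeric(p[[tn]]))
      deps <- epfa_aggregate_vectors(vecs, r, cfg$retain_local_high_band)
      for (k in seq_along(out)) {
        v <- deps[[k]]
        dim(v) <- dim(client_params[[k]][[tn]])
        out[[k]][[tn]] <- v
      }
    }
    lapply(out, parameter_set)
  }
}

#' Elementwise-mean (time-domain) aggregation
#'
#' The classical federated-averaging aggregator: the elementwise arithmetic
#' mean of all client parameter sets. Used both as the comparison baseline
#' and to form the global model from the deputies.
#'
#' @param client_params Non-empty list of parameter sets sharing one
#'   architecture.
#' @return A parameter set.
#' @export
fedavg_aggregate <- function(client_params) {
  if (length(client_params) == 0) stop("no clients to aggregate")
  client_params <- lapply(client_params, parameter_set)
  check_same_architecture(client_params)
  out <- client_params[[1]]
  if (length(client_params) > 1) {
    for (tn in names(out)) {
      acc <- out[[tn]]
      for (k in 2:length(client_params)) acc <- acc + client_params[[k]][[tn]]
      out[[tn]] <- acc / length(client_params)
    }
  }
  out
}
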