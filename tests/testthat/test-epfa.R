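test_that("flattening conserves sizes and inverts exactly", {
  p <- parameter_set(list(a = matrix(1:4 / 2, 2), b = c(1, 2, 3, 4, 5, 6)))
  fl <- flatten_params(p)
  expect_length(fl$vector, 10)
  expect_equal(fl$vector[1:4], c(0.5, 1, 1.5, 2))
  back <- unflatten_params(fl$vector, fl$shapes)
  expect_equal(unclass(back), unclass(p), ignore_attr = FALSE)

  fl2 <- flatten_params(list(a = c(1, 2), b = 3))
  expect_equal(fl2$vector, c(1, 2, 3))
  expect_equal(unname(vapply(fl2$shapes, prod, 1)), c(2, 1))
})

test_that("invalid parameter sets are rejected with the tensor named", {
  expect_error(parameter_set(list()), "non-empty")
  expect_error(parameter_set(list(a = c(1, NaN))), "'a'")
  expect_error(parameter_set(list(a = 1, a = 2)), "unique")
})

test_that("spectrum matches the DFT definition and inverts", {
  sp <- spectrum_decomp(c(1, 0, 0, 0))
  expect_equal(sp$amplitude, rep(1, 3))
  expect_equal(sp$phase, rep(0, 3))

  x <- rep(2.5, 9)
  spc <- spectrum_decomp(x)
  expect_equal(spc$amplitude[1], 9 * 2.5)
  expect_equal(spc$amplitude[-1], rep(0, 4))

  set.seed(4)
  for (n in c(1, 2, 5, 8, 33)) {
    v <- rnorm(n)
    expect_lt(max(abs(inverse_spectrum(spectrum_decomp(v)) - v)), 1e-6)
  }
  # against the O(n^2) textbook transform
  v <- rnorm(16)
  expect_lt(max(Mod(naive_dft(v)[1:9]) - spectrum_decomp(v)$amplitude), 1e-9)
  expect_error(spectrum_decomp(c(1, NaN)), "finite")
})

test_that("spectra aggregate by separate amplitude/phase means", {
  s1 <- spectrum_decomp(c(1, 3, -2, 0.5))
  expect_equal(aggregate_spectra(list(s1, s1, s1)), s1)
  expect_equal(aggregate_spectra(list(s1)), s1)

  a <- structure(list(amplitude = c(1, 1), phase = c(0, 0), n = 3),
                 class = "rfed_spectrum")
  b <- structure(list(amplitude = c(3, 3), phase = c(0, 0), n = 3),
                 class = "rfed_spectrum")
  expect_equal(aggregate_spectra(list(a, b))$amplitude, c(2, 2))
  expect_error(aggregate_spectra(list()), "no spectra")
  expect_error(aggregate_spectra(list(s1, a)), "mismatch")
})

test_that("low-frequency schedule follows r_max/(T-t) and is monotone", {
  expect_equal(low_freq_ratio(0, 10, 0.3), 0.03)
  expect_equal(low_freq_ratio(9, 10, 0.3), 0.3)
  expect_equal(low_freq_ratio(4, 5, 0.9), 0.9)
  rs <- sapply(0:9, low_freq_ratio, T_total = 10, r_max = 0.3)
  expect_true(all(diff(rs) >= 0))
  expect_error(low_freq_ratio(10, 10, 0.3), "round index")
})

test_that("low-frequency mask keeps max(1, round(r*n)) lowest bins", {
  expect_equal(sum(low_freq_mask(10, 0.3)), 3)
  expect_true(all(low_freq_mask(7, 1)))
  m <- low_freq_mask(100, 0.001)
  expect_equal(sum(m), 1)
  expect_true(m[1])            # DC always kept
  expect_true(all(which(low_freq_mask(10, 0.42)) <= 4))  # lowest bins only
  expect_error(low_freq_mask(10, 0), "r must")
})

test_that("aggregation of identical clients at r = 1 is the identity", {
  p <- random_param_set(11)
  for (retain in c(TRUE, FALSE)) {
    out <- epfa_aggregate(list(p, p, p),
                          aggregation_config(1, 0, r_max = 1,
                                             retain_local_high_band = retain))
    expect_length(out, 3)
    for (d in out)
      expect_lt(max(abs(unlist(d) - unlist(p))), 1e-6)
  }
})

test_that("literal (non-retaining) mode returns one common deputy", {
  p1 <- random_param_set(1); p2 <- random_param_set(2)
  out <- epfa_aggregate(list(p1, p2),
                        aggregation_config(4, 1, r_max = 0.5,
                                           retain_local_high_band = FALSE))
  expect_equal(out[[1]], out[[2]])
})

test_that("two-client aggregation matches a from-scratch DFT oracle", {
  # length-8 vectors, r = 0.25, both high-band modes
  set.seed(9)
  v1 <- rnorm(8); v2 <- rnorm(8)
  shapes <- list(v = 8L)
  r <- 0.25
  n_bins <- 5                       # distinct bins of a length-8 real DFT
  keep <- seq_len(max(1, floor(r * n_bins + 0.5)))
  F1 <- naive_dft(v1); F2 <- naive_dft(v2)
  half <- function(F_) F_[1:n_bins]
  A_avg <- (Mod(half(F1)) + Mod(half(F2))) / 2
  P_avg <- (Arg(half(F1)) + Arg(half(F2))) / 2
  F_avg <- complex(modulus = A_avg, argument = P_avg)
  mask <- seq_len(n_bins) %in% keep
  mirror <- function(h) c(h, Conj(rev(h[2:4])))   # Hermitian full spectrum
  for (retain in c(TRUE, FALSE)) {
    deps <- epfa_aggregate(
      list(parameter_set(list(v = v1)), parameter_set(list(v = v2))),
      aggregation_config(T_total = 4, t = 3, r_max = r,
                         retain_local_high_band = retain))
    for (k in 1:2) {
      own <- half(if (k == 1) F1 else F2)
      F_dep <- F_avg * mask + if (retain) own * !mask else 0
      expected <- Re(naive_idft(mirror(F_dep)))
      expect_lt(max(abs(deps[[k]]$v - expected)), 1e-9)
    }
  }
})

test_that("amplitude/phase averaging is not the complex mean", {
  # equal amplitudes, opposite phases phi and -phi at one frequency
  n <- 16; tt <- 0:(n - 1); phi <- 1.1
  x1 <- cos(2 * pi * tt / n + phi)
  x2 <- cos(2 * pi * tt / n - phi)
  s1 <- spectrum_decomp(x1); s2 <- spectrum_decomp(x2)
  agg <- aggregate_spectra(list(s1, s2))
  expect_equal(agg$amplitude[2], s1$amplitude[2], tolerance = 1e-9)
  complex_mean <- (complex(modulus = s1$amplitude[2], argument = s1$phase[2]) +
                   complex(modulus = s2$amplitude[2], argument = s2$phase[2])) / 2
  expect_lt(Mod(complex_mean), agg$amplitude[2])
})

test_that("per-tensor reshape mode aggregates every tensor separately", {
  p <- random_param_set(21)
  out_id <- epfa_aggregate(list(p, p),
                           aggregation_config(1, 0, r_max = 1,
                                              reshape_mode = "per_tensor"))
  expect_lt(max(abs(unlist(out_id[[1]]) - unlist(p))), 1e-6)
  # with distinct clients each tensor is masked against its own bin count:
  # sharing only the DC bin leaves every tensor's non-DC content untouched
  p2 <- random_param_set(22)
  out <- epfa_aggregate(list(p, p2),
                        aggregation_config(100, 0, r_max = 0.01,
                                           reshape_mode = "per_tensor"))
  expect_equal(lapply(out[[1]], dim), lapply(p, dim))
  for (tn in names(p)) {
    v <- as.numeric(p[[tn]])
    got <- as.numeric(out[[1]][[tn]])
    # replacing only the DC bin shifts every entry by the same constant
    expect_lt(max(abs((got - v) - mean(got - v))), 1e-9)
  }
})

test_that("architecture mismatches and empty client lists are rejected", {
  p <- random_param_set(3)
  q <- parameter_set(list(other = 1:3 / 2))
  cfg <- aggregation_config(2, 0)
  expect_error(epfa_aggregate(list(), cfg), "no clients")
  expect_error(epfa_aggregate(list(p, q), cfg), "differ")
})
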