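test_that("evaluate_field matches pointwise summation and handles trivial coefficients", {
  g <- build_grid(5, c(-1, 3), padding_fraction = 0.2)
  m <- build_mode_set(2, g)

  z <- structure(list(a = array(0i, 5), harmonics = 2L), class = "ff_coeffs")
  expect_equal(evaluate_field(z, g), rep(0, 5))

  a0 <- array(0i, 5); a0[3] <- 0.5 + 0i
  c0 <- structure(list(a = a0, harmonics = 2L), class = "ff_coeffs")
  expect_equal(evaluate_field(c0, g), rep(1, 5))   # 2 * Re{0.5}

  set.seed(71)
  for (rep in 1:5) {
    cf <- random_symmetric_coeffs(m)
    expect_equal(evaluate_field(cf, g), oracle_evaluate(cf, g),
                 tolerance = 1e-12)
  }

  # 2D case against the pointwise oracle
  g2 <- build_grid(c(4, 6), c(-2, 2))
  m2 <- build_mode_set(c(1, 2), g2)
  cf2 <- random_symmetric_coeffs(m2)
  expect_equal(evaluate_field(cf2, g2), oracle_evaluate(cf2, g2),
               tolerance = 1e-12)

  # off-grid evaluation agrees with the oracle on shifted coordinates
  shift <- list(g2$axis_coords[[1]] + 0.37, g2$axis_coords[[2]] - 0.81)
  gshift <- g2; gshift$axis_coords <- shift
  expect_equal(evaluate_field(cf2, g2, coords = shift),
               oracle_evaluate(cf2, gshift), tolerance = 1e-12)

  bad <- structure(list(a = array(c(1 + 1i, 0i, 2 + 0i), 3),
                        harmonics = 1L), class = "ff_coeffs")
  expect_error(evaluate_field(bad, build_grid(5, c(0, 1))), "symmetry")
})

test_that("fitting a field synthesized from known coefficients recovers them exactly", {
  set.seed(81)
  g <- build_grid(24, c(-5, 5), padding_fraction = 0.1)
  m <- build_mode_set(3, g)
  truth <- random_symmetric_coeffs(m)
  f <- evaluate_field(truth, g)
  fit <- fit_masked_field(f, g, m)   # full mask
  expect_equal(as.vector(fit$coefficients$a), as.vector(truth$a),
               tolerance = 1e-8)
  expect_true(fit$diagnostics$residual_objective <=
                fit$diagnostics$objective_at_zero)
  expect_lt(fit$diagnostics$residual_objective, 1e-14)

  # 2D recovery with a masked hole: representable fields are still exact
  g2 <- build_grid(c(12, 12), c(0, 1), padding_fraction = 0)
  m2 <- build_mode_set(c(2, 2), g2)
  truth2 <- random_symmetric_coeffs(m2)
  f2 <- evaluate_field(truth2, g2)
  mask2 <- array(TRUE, c(12, 12)); mask2[5:7, 5:7] <- FALSE
  fit2 <- fit_masked_field(masked_field(f2, mask2), g2, m2,
                           config = regularizer_config(residual_criterion = 1e-10))
  expect_equal(as.vector(fit2$coefficients$a), as.vector(truth2$a),
               tolerance = 1e-6)
})

test_that("full-mask half-open fit equals the frequency-truncated DFT", {
  set.seed(91)
  # 1D and 2D: reconstruction must equal the inverse DFT of the truncated DFT
  for (cs in list(list(shape = 16L, N = 3L),
                  list(shape = c(12L, 10L), N = c(2L, 3L)))) {
    g <- build_grid(cs$shape, c(0, 1), padding_fraction = 0,
                    convention = "half-open")
    f <- array(rnorm(prod(cs$shape)), c(cs$shape, 1)[seq_along(cs$shape)])
    fit <- fit_masked_field(f, g, cs$N, solver = "direct")
    # oracle: truncate the DFT to |n_i| <= N_i and invert
    Fh <- fft(f)
    d <- length(cs$shape)
    keep <- lapply(seq_len(d), function(i) {
      L <- cs$shape[i]; N <- cs$N[i]
      idx0 <- c(0:(L - 1))
      freq <- ifelse(idx0 > L / 2, idx0 - L, idx0)   # DFT bin -> signed mode
      abs(freq) <= N
    })
    keepmask <- keep[[1]]
    if (d == 2) keepmask <- outer(keep[[1]], keep[[2]], `&`)
    Fh[!keepmask] <- 0
    recon_dft <- Re(fft(Fh, inverse = TRUE)) / prod(cs$shape)
    expect_equal(as.vector(fit$fitted), as.vector(recon_dft),
                 tolerance = 1e-9)
  }
})

test_that("refitting a reconstruction returns the same coefficients", {
  set.seed(101)
  g <- build_grid(30, c(-5, 5))
  mask <- rep(TRUE, 30); mask[10:14] <- FALSE
  f <- sin(g$axis_coords[[1]]) + 0.3 * cos(2.1 * g$axis_coords[[1]])
  fit1 <- fit_masked_field(masked_field(f, array(mask, 30L)), g, 4,
                           solver = "direct")
  fit2 <- fit_masked_field(masked_field(fit1$fitted, array(mask, 30L)), g, 4,
                           solver = "direct")
  expect_equal(as.vector(fit2$coefficients$a),
               as.vector(fit1$coefficients$a), tolerance = 1e-8)
})

test_that("richer mode sets never fit worse (nested model classes)", {
  set.seed(111)
  g <- build_grid(40, c(-5, 5))
  mask <- runif(40) > 0.2; mask[1] <- TRUE
  f <- exp(-abs(g$axis_coords[[1]])) + 0.1 * sin(3 * g$axis_coords[[1]])
  obj <- vapply(c(1, 2, 4, 6, 8), function(N) {
    fit_masked_field(masked_field(f, array(mask, 40L)), g, N,
                     solver = "direct")$diagnostics$residual_objective
  }, numeric(1))
  expect_true(all(diff(obj) <= 1e-10))
})

test_that("time series with a constant mask factorizes exactly once", {
  set.seed(121)
  g <- build_grid(c(14, 12), c(-1, 1))
  mask <- array(runif(168) > 0.25, c(14, 12)); mask[1, 1] <- TRUE
  steps <- lapply(1:20, function(t)
    array(sin(t / 3) * rnorm(168), c(14, 12)))
  ff_reset_counters()
  cache <- factorization_cache()
  # 3 vector components x 20 time steps through one shared cache
  fits <- list()
  for (comp in 1:3)
    fits[[comp]] <- fit_time_series(steps, g, c(2, 2), mask = mask,
                                    cache = cache)
  expect_equal(ff_counters()$svd_calls, 1L)
  expect_equal(ff_counters()$solve_calls, 60L)
  expect_length(fits[[1]], 20L)

  # a cache hit serves an AA bitwise equal to a fresh assembly
  key <- ls(cache)[1]
  cached_AA <- get(key, envir = cache)$AA
  modes <- build_mode_set(c(2, 2), g)
  tab <- precompute_exponentials(g, modes)
  S <- compute_structure_factors(mask, tab, g)
  sp <- compute_rhs_spectrum(masked_field(steps[[1]], mask), tab)
  fresh <- fourierfit:::assemble_reduced_system(S, sp, modes)
  expect_identical(cached_AA, fresh$AA)

  # a length-1 series equals a plain fit
  single <- fit_time_series(steps[1], g, c(2, 2), mask = mask)
  plain <- fit_masked_field(masked_field(steps[[1]], mask), g, c(2, 2))
  expect_identical(single[[1]]$coefficients$a, plain$coefficients$a)

  # identical data give bitwise-identical results
  twice <- fit_time_series(steps[c(1, 1)], g, c(2, 2), mask = mask)
  expect_identical(twice[[1]]$coefficients$a, twice[[2]]$coefficients$a)

  # varying masks are rejected with guidance
  mask2 <- mask; mask2[2, 2] <- !mask2[2, 2]
  expect_error(
    fit_time_series(list(masked_field(steps[[1]], mask),
                         masked_field(steps[[2]], mask2)), g, c(2, 2)),
    "mask varies")
})

test_that("fit validates inputs and warns when underdetermined", {
  g <- build_grid(10, c(0, 1))
  expect_error(fit_masked_field(masked_field(rep(1, 10),
                                             rep(FALSE, 10)), g, 1),
               "empty mask|nothing to fit")
  v <- rep(1, 10); v[3] <- NA
  expect_error(masked_field(v, rep(TRUE, 10)), "non-finite")
  mask <- rep(FALSE, 10); mask[1:2] <- TRUE
  expect_warning(fit_masked_field(masked_field(rep(1, 10), mask), g, 2),
                 "underdetermined")
})

test_that("polarity combination removes common-mode structure", {
  set.seed(131)
  d <- array(rnorm(24), c(4, 6))
  eps <- array(rnorm(24), c(4, 6))
  expect_equal(combine_polarities(d, d), array(0, c(4, 6)))
  expect_equal(combine_polarities(d, -d), d)
  expect_equal(combine_polarities(d + eps, -d + eps), d)
  expect_error(combine_polarities(d, t(d)), "shapes differ")
})
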