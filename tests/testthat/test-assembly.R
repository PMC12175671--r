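make_setup <- function(shape, bounds, N, padding = 0.1,
                       convention = "inclusive") {
  grid <- build_grid(shape, bounds, padding_fraction = padding,
                     convention = convention)
  modes <- build_mode_set(N, grid)
  table <- precompute_exponentials(grid, modes)
  list(grid = grid, modes = modes, table = table)
}

test_that("structure factors: orthogonality, symmetry, counts", {
  # full mask, half-open, no padding: geometric-series orthogonality
  s <- make_setup(c(8, 8), c(0, 1), N = 1, padding = 0,
                  convention = "half-open")
  mask <- array(TRUE, c(8, 8))
  S <- compute_structure_factors(mask, s$table, s$grid)
  expect_equal(S$n_unmasked, 64)
  ext <- as.matrix(expand.grid(-2:2, -2:2))
  for (i in seq_len(nrow(ext))) {
    v <- S$S[ext[i, 1] + 3, ext[i, 2] + 3]
    if (all(ext[i, ] == 0)) expect_equal(Re(v), 64, tolerance = 1e-12)
    else expect_lt(abs(v), 1e-9)
  }

  # Hermitian symmetry S_{-i} = Conj(S_i) for a random mask, any convention
  set.seed(42)
  s2 <- make_setup(c(5, 4, 3), c(-2, 2), N = 1)
  mask2 <- array(runif(60) > 0.4, c(5, 4, 3))
  mask2[1, 1, 1] <- TRUE
  S2 <- compute_structure_factors(mask2, s2$table, s2$grid)$S
  rev_all <- S2[rev(seq_len(5)), rev(seq_len(5)), rev(seq_len(5))]
  expect_equal(S2, Conj(rev_all), tolerance = 1e-12)
  # |S_i| <= S_0 = number of unmasked points
  expect_true(all(abs(S2) <= sum(mask2) + 1e-9))

  expect_error(compute_structure_factors(array(FALSE, c(5, 4, 3)),
                                         s2$table, s2$grid), "empty mask")
})

test_that("contraction scalar-product counts match the separable-cost formula", {
  s <- make_setup(c(6, 5, 4), c(0, 1), N = c(2, 1, 1))
  mask <- array(TRUE, c(6, 5, 4))
  field <- masked_field(array(rnorm(120), c(6, 5, 4)), mask)
  L <- c(6, 5, 4); K4 <- 4 * c(2, 1, 1) + 1; K2 <- 2 * c(2, 1, 1) + 1
  ff_reset_counters()
  compute_structure_factors(mask, s$table, s$grid)
  expect_equal(ff_counters()$scalar_products_mask,
               L[1] * L[2] * K4[3] + L[1] * K4[2] * K4[3] +
                 K4[1] * K4[2] * K4[3])
  compute_rhs_spectrum(field, s$table)
  expect_equal(ff_counters()$scalar_products_data,
               L[1] * L[2] * K2[3] + L[1] * K2[2] * K2[3] +
                 K2[1] * K2[2] * K2[3])
})

test_that("structure factors and spectra equal brute-force summation", {
  set.seed(7)
  cases <- list(
    list(shape = 6L, bounds = c(-1, 2), N = 2L, conv = "inclusive"),
    list(shape = c(4L, 4L), bounds = c(0, 1), N = c(2L, 1L),
         conv = "half-open"),
    list(shape = c(4L, 4L, 4L), bounds = c(-5, 5), N = c(1L, 1L, 1L),
         conv = "inclusive"))
  for (cs in cases) {
    s <- make_setup(cs$shape, cs$bounds, cs$N, convention = cs$conv)
    mask <- array(runif(prod(cs$shape)) > 0.3, c(cs$shape, 1)[seq_along(cs$shape)])
    mask[1] <- TRUE
    vals <- array(rnorm(prod(cs$shape)), dim(mask))
    S <- compute_structure_factors(mask, s$table, s$grid)$S
    S_oracle <- oracle_structure_factors(mask, s$grid, s$modes)
    expect_equal(as.vector(S), as.vector(S_oracle), tolerance = 1e-12)

    sp <- compute_rhs_spectrum(masked_field(vals, mask), s$table)
    sp_oracle <- oracle_spectrum(vals, mask, s$grid, s$modes)
    expect_equal(as.vector(sp), as.vector(sp_oracle), tolerance = 1e-12)
  }
})

test_that("spectrum special cases: zero field, constant field", {
  s <- make_setup(c(5, 5), c(0, 1), N = 1)
  set.seed(1)
  mask <- array(runif(25) > 0.3, c(5, 5)); mask[1, 1] <- TRUE
  z <- compute_rhs_spectrum(masked_field(array(0, c(5, 5)), mask), s$table)
  expect_true(all(z == 0))
  # f == 1: spectrum equals structure factors restricted to the full lattice
  one <- compute_rhs_spectrum(masked_field(array(1, c(5, 5)), mask), s$table)
  S <- compute_structure_factors(mask, s$table, s$grid)$S
  expect_equal(one, S[2:4, 2:4], tolerance = 1e-12)
})

test_that("assembled systems match the per-point normal-equation oracle", {
  set.seed(11)
  for (cs in list(list(shape = c(5L, 4L), N = c(1L, 2L)),
                  list(shape = c(4L, 4L, 4L), N = c(1L, 1L, 1L)))) {
    s <- make_setup(cs$shape, c(-1, 1), cs$N)
    mask <- array(runif(prod(cs$shape)) > 0.35, cs$shape)
    mask[1] <- TRUE
    vals <- array(rnorm(prod(cs$shape)), cs$shape)
    S <- compute_structure_factors(mask, s$table, s$grid)
    sp <- compute_rhs_spectrum(masked_field(vals, mask), s$table)
    sys <- assemble_full_system(S, sp, s$modes)
    oracle <- oracle_full_system(vals, mask, s$grid, s$modes)
    expect_equal(sys$A, oracle$A, tolerance = 1e-12)
    expect_equal(sys$B, oracle$B, tolerance = 1e-12)
    # reduction = leading M x M block
    red <- reduce_system(sys, s$modes)
    M <- s$modes$M
    expect_identical(red$AA, sys$A[1:M, 1:M])
    expect_identical(red$BB, sys$B[1:M])
    # direct reduced assembly agrees bitwise with slicing the full system
    direct <- fourierfit:::assemble_reduced_system(S, sp, s$modes)
    expect_identical(direct$AA, red$AA)
    expect_identical(direct$BB, red$BB)
  }
})

test_that("full-mask half-open rows couple only modes m and -m", {
  s <- make_setup(12, c(0, 1), N = 2, padding = 0, convention = "half-open")
  mask <- rep(TRUE, 12)
  S <- compute_structure_factors(array(mask, 12L), s$table, s$grid)
  sp <- compute_rhs_spectrum(masked_field(array(rnorm(12), 12L),
                                          array(mask, 12L)), s$table)
  A <- assemble_full_system(S, sp, s$modes)$A
  M <- s$modes$M
  lat <- drop(s$modes$lattice)
  for (mi in seq_len(M)) {
    brow <- A[2 * mi - 1, c(TRUE, FALSE)]   # b-entries of the b-row of mode m
    allowed <- which(lat == lat[mi] | lat == -lat[mi])
    expect_lt(max(abs(brow[-allowed]), 0), 1e-9)
  }
})

test_that("masked-out values never influence any assembled quantity", {
  set.seed(3)
  s <- make_setup(c(6, 5), c(-2, 2), N = c(2, 1))
  mask <- array(runif(30) > 0.4, c(6, 5)); mask[2, 2] <- TRUE
  vals <- array(rnorm(30), c(6, 5))
  vals2 <- vals
  vals2[!mask] <- 1e6 * rnorm(sum(!mask))   # scramble hidden values
  f1 <- masked_field(vals, mask); f2 <- masked_field(vals2, mask)
  sp1 <- compute_rhs_spectrum(f1, s$table)
  sp2 <- compute_rhs_spectrum(f2, s$table)
  expect_identical(sp1, sp2)
  S1 <- compute_structure_factors(mask, s$table, s$grid)
  sys1 <- fourierfit:::assemble_reduced_system(S1, sp1, s$modes)
  sys2 <- fourierfit:::assemble_reduced_system(S1, sp2, s$modes)
  expect_identical(sys1$AA, sys2$AA)
  expect_identical(sys1$BB, sys2$BB)
})

test_that("system realness: no imaginary residue leaks into A or B", {
  set.seed(9)
  s <- make_setup(c(7, 6), c(-3, 1), N = c(2, 2))
  mask <- array(runif(42) > 0.25, c(7, 6)); mask[1, 1] <- TRUE
  S <- compute_structure_factors(mask, s$table, s$grid)$S
  # Hermitian symmetry S_{-i} = Conj(S_i) is what makes every A entry and
  # every B entry real; assert it with no imaginary residue
  herm <- S - Conj(S[rev(seq_len(nrow(S))), rev(seq_len(ncol(S)))])
  expect_lt(max(abs(herm)) / max(abs(S)), 1e-10)
})
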