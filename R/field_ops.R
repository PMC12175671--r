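# Expansion counterpart of the assembly contractions: coefficients ->
# field values, one axis at a time (mode axis replaced by spatial axis).
.ff_expand_eval <- function(a3, Kshape3, tabs3) {
  Kx <- Kshape3[1]; Ky <- Kshape3[2]; Kz <- Kshape3[3]
  Lx <- ncol(tabs3[[1]]); Ly <- ncol(tabs3[[2]]); Lz <- ncol(tabs3[[3]])
  m <- matrix(a3, Kx * Ky, Kz) %*% tabs3[[3]]
  a <- aperm(array(m, c(Kx, Ky, Lz)), c(1L, 3L, 2L))
  m <- matrix(a, Kx * Lz, Ky) %*% tabs3[[2]]
  a <- aperm(array(m, c(Kx, Lz, Ly)), c(2L, 3L, 1L))
  m <- matrix(a, Lz * Ly, Kx) %*% tabs3[[1]]
  aperm(array(m, c(Lz, Ly, Lx)), c(3L, 2L, 1L))
}

#' Reconstruct a real field from Fourier coefficients
#'
#' Evaluates `fhat(r) = 2 * Re(sum_n a_n * exp(1i * k_n . r))` by per-axis
#' contractions mirroring the assembly factorization. The coefficients must
#' satisfy the conjugate symmetry `a_{-n} = Conj(a_n)`, which makes the
#' result real up to floating-point noise; the residual imaginary part is
#' checked against `1e-9` of the field scale before being dropped.
#'
#' Evaluation is not restricted to the original grid: `coords` may supply
#' arbitrary per-axis coordinate vectors (a tensor-product evaluation),
#' enabling inter-/extrapolation. Beyond the padded period the basis wraps
#' periodically, so extrapolation is meaningful only within it.
#'
#' @param coeffs An `ff_coeffs` (from a fit or built directly).
#' @param grid The `ff_grid` supplying periods/wavenumbers (and, when
#'   `coords` is `NULL`, the evaluation coordinates).
#' @param coords Optional list of per-axis coordinate vectors.
#' @return Real array of the evaluated field (vector in 1D).
#' @export
evaluate_field <- function(coeffs, grid, coords = NULL) {
  stopifnot(inherits(coeffs, "ff_coeffs"), inherits(grid, "ff_grid"))
  d <- grid$ndim
  if (length(coeffs$harmonics) != d)
    stop("coefficients and grid dimensionality differ", call. = FALSE)
  a <- as.vector(coeffs$a)
  scale <- max(1, max(abs(a)))
  if (max(abs(a - Conj(rev(a)))) > 1e-9 * scale)
    stop("coefficient conjugate symmetry violated", call. = FALSE)
  coords <- coords %||% grid$axis_coords
  stopifnot(is.list(coords), length(coords) == d)
  N <- coeffs$harmonics
  tabs <- lapply(seq_len(d), function(i) {
    ext <- .ff_axis_exp(coords[[i]], grid$k0[i], N[i], alias_ok = FALSE)
    ext[seq.int(N[i] + 1L, 3L * N[i] + 1L), , drop = FALSE]
  })
  Ls <- vapply(coords, length, 1L)
  Kshape3 <- c(2L * N + 1L, rep(1L, 3L - d))
  tabs3 <- c(tabs, rep(list(matrix(1 + 0i, 1L, 1L)), 3L - d))
  out <- .ff_expand_eval(array(coeffs$a, Kshape3), Kshape3, tabs3)
  re <- 2 * Re(out)
  fs <- max(1, max(abs(re)))
  if (2 * max(abs(Im(out))) > 1e-9 * fs)
    stop("reconstruction has non-negligible imaginary part", call. = FALSE)
  if (d == 1L) as.vector(re) else array(re, Ls)
}

#' Create a factorization cache for repeated fits under one mask
#'
#' Stores, per (mask, grid, mode set, convention) key, the structure
#' factors, the reduced matrix `AA` and its SVD, so that time series and
#' vector components sharing a constant mask pay for assembly and
#' factorization exactly once.
#'
#' @return An empty cache of class `ff_cache`.
#' @export
factorization_cache <- function() {
  structure(new.env(parent = emptyenv()), class = "ff_cache")
}

.ff_cache_key <- function(mask_checksum, grid, modes) {
  paste(mask_checksum,
        .ff_checksum(list(grid$shape, grid$bounds, grid$padding_fraction,
                          grid$convention, modes$harmonics)),
        sep = "-")
}

#' Fit a truncated Fourier basis to a masked field
#'
#' End-to-end pipeline: precompute exponential tables, compute mask
#' structure factors and the data spectrum, assemble the reduced real
#' normal-equation system, solve it (SVD-regularized by default), expand
#' the reduced solution and return complex coefficients plus diagnostics.
#' The least-squares objective `sum_mask (f - fhat)^2` at the solution
#' never exceeds its value at the zero coefficient vector.
#'
#' @param field An `ff_field` ([masked_field()]), or a plain array (taken
#'   as fully observed).
#' @param grid The `ff_grid`.
#' @param modes An `ff_modes`, or an integer vector of harmonics.
#' @param config An [regularizer_config()].
#' @param solver `"svd"` (adaptive truncated-SVD regularization, default)
#'   or `"direct"` (minimal-norm pseudo-inverse solve).
#' @param cache Optional [factorization_cache()] shared across fits.
#' @param keep_fitted Keep the reconstruction on the grid (needed for the
#'   objective diagnostics; default `TRUE`).
#' @return Class `ff_fit`: `coefficients` (`ff_coeffs`), `diagnostics`
#'   (`ff_diag`, including `residual_objective` and `objective_at_zero`),
#'   `fitted` (reconstruction or `NULL`), `provenance`.
#' @export
fit_masked_field <- function(field, grid, modes,
                             config = regularizer_config(),
                             solver = c("svd", "direct"),
                             cache = NULL, keep_fitted = TRUE) {
  solver <- match.arg(solver)
  stopifnot(inherits(grid, "ff_grid"))
  if (!inherits(field, "ff_field")) {
    v <- field
    field <- masked_field(v, array(TRUE, dim(v) %||% length(v)))
  }
  if (!inherits(modes, "ff_modes")) modes <- build_mode_set(modes, grid)
  dm <- dim(field$mask) %||% length(field$mask)
  if (!identical(as.integer(dm), grid$shape))
    stop("field shape does not match the grid", call. = FALSE)
  if (!any(field$mask)) stop("empty mask: nothing to fit", call. = FALSE)
  if (any(!is.finite(field$values[field$mask])))
    stop("non-finite values under the mask", call. = FALSE)
  if (sum(field$mask) < modes$M)
    warning("fewer unmasked points (", sum(field$mask), ") than unknowns (",
            modes$M, "): system is underdetermined", call. = FALSE)

  mask_checksum <- .ff_checksum(field$mask)
  key <- .ff_cache_key(mask_checksum, grid, modes)
  hit <- !is.null(cache) && exists(key, envir = cache, inherits = FALSE)
  entry <- if (hit) get(key, envir = cache, inherits = FALSE)
  table <- if (hit) entry$table else precompute_exponentials(grid, modes)
  if (hit) {
    S <- entry$S
    AA <- entry$AA
    fact <- entry$factorization
  } else {
    S <- compute_structure_factors(field$mask, table, grid)
    AA <- assemble_block_cpp(as.complex(S$S), modes$evec, modes$eoffset,
                             modes$M)
    fact <- NULL
  }
  spectrum <- compute_rhs_spectrum(field, table)
  BB <- .ff_interleave_rhs(spectrum)[seq_len(modes$M)]

  if (is.null(fact)) {
    # very large systems: let dsyevd consume AA in place (halves the peak
    # footprint) and reassemble it afterwards - assembly costs seconds,
    # the factorization minutes
    big <- modes$M > 4096L
    fact <- svd_factorize(AA, .ff_row_signs(modes$M), destroy = big)
    if (big)
      AA <- assemble_block_cpp(as.complex(S$S), modes$evec, modes$eoffset,
                               modes$M)
  }
  if (solver == "svd") {
    sol <- solve_regularized(AA, BB, config, factorization = fact)
    xx <- sol$xx
    diagnostics <- sol$diagnostics
  } else {
    xx <- solve_direct(AA, BB, factorization = fact)
    rs <- drop(AA %*% xx) - BB
    diagnostics <- structure(list(
      retained_rank = sum(fact$d > max(dim(AA)) * .Machine$double.eps *
                            max(fact$d, 0)),
      iterations = 1L, converged = TRUE, residual_trajectory = numeric(0),
      absolute_system_residual = max(abs(rs)),
      relative_system_residual =
        if (all(BB == 0)) 0 else max(abs(rs)) / max(abs(BB)),
      sv_threshold_used = NA_real_, sv_max = max(fact$d, 0),
      factorization_method = fact$method), class = "ff_diag")
  }

  if (!is.null(cache) && !hit)
    assign(key, list(table = table, S = S, AA = AA, factorization = fact),
           envir = cache)

  x <- expand_solution(xx, modes)
  coeffs <- coefficients_from_solution(x, modes)

  fitted <- NULL
  if (keep_fitted) {
    fitted <- evaluate_field(coeffs, grid)
    dev <- (field$values - fitted)[field$mask]
    diagnostics$residual_objective <- sum(dev^2)
    diagnostics$objective_at_zero <- sum(field$values[field$mask]^2)
  }

  structure(list(
    coefficients = coeffs, diagnostics = diagnostics, fitted = fitted,
    provenance = list(
      harmonics = modes$harmonics, padding = grid$padding_fraction,
      convention = grid$convention, solver = solver, config = unclass(config),
      mask_checksum = mask_checksum, n_unmasked = S$n_unmasked,
      package_version = as.character(utils::packageVersion("fourierfit")))
  ), class = "ff_fit")
}

#' @export
print.ff_fit <- function(x, ...) {
  d <- x$diagnostics
  cat("<ff_fit> N = (", paste(x$provenance$harmonics, collapse = ", "),
      "), rank ", d$retained_rank, ", ", d$iterations, " iteration(s), ",
      if (isTRUE(d$converged)) "converged" else "NOT converged",
      ", rel. residual ", signif(d$relative_system_residual, 3), "\n",
      sep = "")
  invisible(x)
}

#' Fit a time series of fields sharing one mask
#'
#' The mask determines the structure factors, the reduced matrix and its
#' SVD; for a constant mask these are computed once and every time step
#' (and every vector component) costs only a spectrum, a back-substitution
#' and a reconstruction.
#'
#' @param fields List of `ff_field` objects, or list of plain value arrays
#'   combined with `mask`.
#' @param grid,modes,config,solver,cache,keep_fitted As in
#'   [fit_masked_field()]; a fresh cache is created when none is given.
#' @param mask Shared logical mask (required when `fields` are plain
#'   arrays).
#' @return List of `ff_fit`, one per time step.
#' @export
fit_time_series <- function(fields, grid, modes, mask = NULL,
                            config = regularizer_config(),
                            solver = c("svd", "direct"),
                            cache = NULL, keep_fitted = TRUE) {
  solver <- match.arg(solver)
  stopifnot(is.list(fields), length(fields) >= 1L)
  fields <- lapply(fields, function(f) {
    if (inherits(f, "ff_field")) f else {
      if (is.null(mask)) stop("plain arrays need a shared mask", call. = FALSE)
      masked_field(f, mask)
    }
  })
  cks <- vapply(fields, function(f) .ff_checksum(f$mask), character(1))
  if (length(unique(cks)) != 1L)
    stop("mask varies across time steps; the cached factorization is only ",
         "valid for a constant mask - fit the steps separately or refit ",
         "with a per-step cache", call. = FALSE)
  cache <- cache %||% factorization_cache()
  lapply(fields, fit_masked_field, grid = grid, modes = modes,
         config = config, solver = solver, cache = cache,
         keep_fitted = keep_fitted)
}

#' Combine two opposite-polarity acquisitions
#'
#' Background/common-mode structure is removed by halving the difference of
#' the two polarities: `(positive - negative) / 2`, which preserves the
#' displacement amplitude encoded with opposite signs in the two series.
#'
#' @param positive,negative Arrays of equal shape.
#' @return Array of the same shape.
#' @export
combine_polarities <- function(positive, negative) {
  dp <- dim(positive) %||% length(positive)
  dn <- dim(negative) %||% length(negative)
  if (!identical(as.integer(dp), as.integer(dn)))
    stop("polarity shapes differ", call. = FALSE)
  (positive - negative) / 2
}
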