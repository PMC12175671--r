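#' Build a structured rectangular grid
#'
#' Defines the regular grid a masked field lives on, together with the
#' (possibly padded) Fourier period and the fundamental wavenumbers
#' `k0[i] = 2*pi / period[i]` used by every later stage. Padding enlarges
#' only the period, never the stored coordinates: a longer period keeps the
#' periodic basis from clamping extrapolation at the data boundary, and
#' masked-out ghost points would contribute nothing to any sum anyway.
#'
#' Two coordinate conventions are supported. `"inclusive"` places `L` points
#' on the closed interval (spacing `extent / (L - 1)`), the natural reading
#' of "discretized into L points". `"half-open"` places them at
#' `min + m * extent / L`, `m = 0..L-1`, the DFT-commensurate convention
#' under which the exact alias identity of the structure factors holds and
#' an FFT cross-check is possible.
#'
#' @param shape Integer vector (length 1-3): number of grid points per axis.
#' @param bounds Either a numeric `c(min, max)` applied to every axis or a
#'   list with one `c(min, max)` per axis.
#' @param padding_fraction Nonnegative scalar; the period is
#'   `(1 + padding_fraction) * (max - min)`. Default 0.1 (10% padding).
#' @param convention `"inclusive"` (default) or `"half-open"`.
#'
#' @return An object of class `ff_grid`: a list with `shape`, `ndim`,
#'   `axis_coords`, `bounds`, `data_extent`, `padding_fraction`, `period`,
#'   `k0` and `convention`.
#' @examples
#' g <- build_grid(200, c(-5, 5), padding_fraction = 0.1)
#' g$period      # 11
#' g$k0          # 2*pi/11
#' @export
build_grid <- function(shape, bounds, padding_fraction = 0.1,
                       convention = c("inclusive", "half-open")) {
  convention <- match.arg(convention)
  shape <- as.integer(shape)
  d <- length(shape)
  if (d < 1L || d > 3L)
    stop("invalid grid: dimensionality must be 1-3", call. = FALSE)
  if (any(is.na(shape)) || any(shape < 1L))
    stop("invalid grid: point counts must be positive integers", call. = FALSE)
  if (is.numeric(bounds) && length(bounds) == 2L)
    bounds <- rep(list(bounds), d)
  if (!is.list(bounds) || length(bounds) != d)
    stop("invalid grid: need one (min, max) pair per axis", call. = FALSE)
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(hi <= lo))
    stop("invalid grid: bounds must be finite with max > min", call. = FALSE)
  if (!is.finite(padding_fraction) || padding_fraction < 0)
    stop("invalid grid: padding_fraction must be >= 0", call. = FALSE)

  extent <- hi - lo
  coords <- lapply(seq_len(d), function(i) {
    L <- shape[i]
    if (convention == "inclusive") {
      if (L == 1L) lo[i] else seq(lo[i], hi[i], length.out = L)
    } else {
      lo[i] + (seq_len(L) - 1) * extent[i] / L
    }
  })
  period <- (1 + padding_fraction) * extent
  structure(list(
    shape = shape, ndim = d, axis_coords = coords,
    bounds = Map(c, lo, hi), data_extent = extent,
    padding_fraction = padding_fraction, period = period,
    k0 = 2 * pi / period, convention = convention
  ), class = "ff_grid")
}

#' @export
print.ff_grid <- function(x, ...) {
  cat("<ff_grid> ", paste(x$shape, collapse = " x "),
      " points, extent ", paste(signif(x$data_extent, 4), collapse = " x "),
      ", period ", paste(signif(x$period, 4), collapse = " x "),
      " (", x$convention, ", padding ", x$padding_fraction, ")\n", sep = "")
  invisible(x)
}

#' Build the truncated Fourier mode set
#'
#' Enumerates the full mode lattice `-N[i] <= n[i] <= N[i]` in a fixed
#' lexicographic order with the first axis fastest, so that lattice entry
#' `M + 1 - p` is the negation of entry `p` and the zero mode sits at
#' position `(M + 1) / 2`. This negation symmetry is what lets the reduced
#' half-size system be read off as the leading block of the full one.
#' The extended lattice `-2N <= n <= 2N` indexes the structure factors,
#' which are needed at every mode sum `m + n` and difference `m - n`.
#'
#' @param harmonics Nonnegative integer(s), recycled to the grid dimension:
#'   the per-axis harmonic cutoff `N[i]`.
#' @param grid An `ff_grid`.
#' @return An object of class `ff_modes`: `harmonics`, `M` (full lattice
#'   size `prod(2N+1)`), `lattice` (M x d integer matrix), `ext_shape`
#'   (`4N+1` per axis), `M_ext`, `zero_index`, `wavevectors` (M x d),
#'   plus the extended linear-index map `evec`/`eoffset` used by assembly.
#' @examples
#' g <- build_grid(200, c(-5, 5))
#' m <- build_mode_set(11, g)
#' m$M       # 23
#' m$M_ext   # 45
#' @export
build_mode_set <- function(harmonics, grid) {
  stopifnot(inherits(grid, "ff_grid"))
  d <- grid$ndim
  N <- as.integer(rep_len(harmonics, d))
  if (any(is.na(N)) || any(N < 0L))
    stop("harmonics must be nonnegative integers", call. = FALSE)
  lattice <- as.matrix(expand.grid(lapply(N, function(n) seq.int(-n, n)),
                                   KEEP.OUT.ATTRS = FALSE))
  dimnames(lattice) <- NULL
  storage.mode(lattice) <- "integer"
  M <- nrow(lattice)
  ext_shape <- 4L * N + 1L
  strides <- cumprod(c(1L, ext_shape[-d]))
  evec <- as.integer(lattice %*% strides + sum(2L * N * strides))
  wavevectors <- sweep(lattice, 2L, grid$k0, `*`)
  structure(list(
    harmonics = N, M = M, lattice = lattice,
    ext_shape = ext_shape, M_ext = prod(ext_shape),
    zero_index = (M + 1L) %/% 2L,
    wavevectors = wavevectors,
    evec = evec, eoffset = as.integer(sum(2L * N * strides))
  ), class = "ff_modes")
}

#' @export
print.ff_modes <- function(x, ...) {
  cat("<ff_modes> N = (", paste(x$harmonics, collapse = ", "),
      "), ", x$M, " modes (extended lattice ", x$M_ext, ")\n", sep = "")
  invisible(x)
}

# One axis of the exponential table: rows n = -2N..2N, columns the axis
# coordinates. When the half-open, zero-padding, origin-commensurate
# conditions hold, rows whose mode index differs by a multiple of L are
# identical (the DFT alias rule), so aliased rows are copied from the
# canonical representative rather than recomputed.
.ff_axis_exp <- function(coords, k0, N, alias_ok) {
  L <- length(coords)
  ns <- seq.int(-2L * N, 2L * N)
  if (alias_ok) {
    nred <- ((ns %% L) + L) %% L
    ured <- unique(nred)
    base <- exp(1i * k0 * outer(ured, coords))
    .ff_count("exp_evals", length(ured) * L)
    base[match(nred, ured), , drop = FALSE]
  } else {
    .ff_count("exp_evals", length(ns) * L)
    exp(1i * k0 * outer(ns, coords))
  }
}

#' Precompute the per-axis exponential tables
#'
#' Evaluates `E_i[n, m] = exp(1i * n * k0[i] * coord_i[m])` for
#' `n = -2N[i]..2N[i]` once per axis. All later stages (structure factors,
#' right-hand-side spectra, reconstruction on the grid) are contractions
#' against these tables, so the total number of complex-exponential
#' evaluations is `sum((4N+1) * L)` instead of one per (mode, point) pair.
#'
#' @param grid An `ff_grid`.
#' @param modes An `ff_modes` built for a grid of the same dimension.
#' @return Class `ff_exp_table`: list `E` of `(4N[i]+1) x L[i]` complex
#'   matrices plus bookkeeping (`harmonics`, `shape`).
#' @export
precompute_exponentials <- function(grid, modes) {
  stopifnot(inherits(grid, "ff_grid"), inherits(modes, "ff_modes"))
  d <- grid$ndim
  if (length(modes$harmonics) != d)
    stop("grid and mode set dimensionality differ", call. = FALSE)
  E <- lapply(seq_len(d), function(i) {
    L <- grid$shape[i]
    alias_ok <- grid$convention == "half-open" &&
      grid$padding_fraction == 0 && L > 1L &&
      {
        r <- L * grid$bounds[[i]][1] / grid$data_extent[i]
        abs(r - round(r)) < 1e-9
      }
    .ff_axis_exp(grid$axis_coords[[i]], grid$k0[i], modes$harmonics[i],
                 alias_ok)
  })
  structure(list(E = E, harmonics = modes$harmonics, shape = grid$shape),
            class = "ff_exp_table")
}

# Rows of axis table i covering the full (non-extended) lattice -N..N.
.ff_central_rows <- function(table, i) {
  N <- table$harmonics[i]
  table$E[[i]][seq.int(N + 1L, 3L * N + 1L), , drop = FALSE]
}
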