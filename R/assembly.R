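#' Bundle field values with their availability mask
#'
#' @param values Numeric array (1-3 dimensions) of field samples on the grid.
#' @param mask Logical array of identical shape; `TRUE` where data exist.
#'   Values at mask-`FALSE` points are ignored by every computation (they are
#'   zeroed before any reduction) and may be `NA`.
#' @return Class `ff_field`: list with `values` and `mask`.
#' @export
masked_field <- function(values, mask) {
  dv <- dim(values) %||% length(values)
  dm <- dim(mask) %||% length(mask)
  if (!identical(as.integer(dv), as.integer(dm)))
    stop("values and mask shapes differ", call. = FALSE)
  mask <- array(as.logical(mask), dim = dm)
  values <- array(as.double(values), dim = dv)
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  if (any(!is.finite(values[mask])))
    stop("non-finite values under the mask", call. = FALSE)
  structure(list(values = values, mask = mask), class = "ff_field")
}

# Separable reduction of a (possibly complex-valued) array against per-axis
# kernel tables, innermost axis first (z, then y, then x). Missing axes of
# 1D/2D inputs are treated as singletons so a single code path covers all
# dimensionalities, and the scalar-product counter reproduces the
# L_x*L_y*K_z + L_x*K_y*K_z + K_x*K_y*K_z contraction-cost accounting.
.ff_contract <- function(arr, shape3, tabs, counter) {
  Lx <- shape3[1]; Ly <- shape3[2]; Lz <- shape3[3]
  Kx <- nrow(tabs[[1]]); Ky <- nrow(tabs[[2]]); Kz <- nrow(tabs[[3]])
  m <- matrix(arr, Lx * Ly, Lz) %*% t(tabs[[3]])
  .ff_count(counter, Lx * Ly * Kz)
  a <- aperm(array(m, c(Lx, Ly, Kz)), c(1L, 3L, 2L))
  m <- matrix(a, Lx * Kz, Ly) %*% t(tabs[[2]])
  .ff_count(counter, Lx * Kz * Ky)
  a <- aperm(array(m, c(Lx, Kz, Ky)), c(2L, 3L, 1L))
  m <- matrix(a, Kz * Ky, Lx) %*% t(tabs[[1]])
  .ff_count(counter, Kz * Ky * Kx)
  aperm(array(m, c(Kz, Ky, Kx)), c(3L, 2L, 1L))
}

# Pad per-axis tables and an array up to 3 axes with singletons.
.ff_pad3 <- function(arr, tabs) {
  d <- length(tabs)
  shape3 <- c(vapply(tabs, ncol, 1L), rep(1L, 3L - d))
  tabs3 <- c(tabs, rep(list(matrix(1 + 0i, 1L, 1L)), 3L - d))
  list(arr = array(arr, shape3), shape3 = shape3, tabs = tabs3)
}

#' Compute the mask structure factors
#'
#' The structure factor `S[i] = sum_r M(r) * exp(1i * k_i . r)` over the
#' extended mode lattice `-2N <= i <= 2N` encodes the mask geometry; every
#' entry of the normal-equation matrix is generated from `S` evaluated at
#' mode sums `m + n` and differences `m - n`. The triple sum is evaluated as
#' three single-axis contractions against the precomputed exponential
#' tables, innermost axis first.
#'
#' @param mask Logical array matching the grid shape.
#' @param table An `ff_exp_table` from [precompute_exponentials()].
#' @param grid The `ff_grid` the mask lives on.
#' @return Class `ff_structfac`: `S` (complex array over the extended
#'   lattice), `harmonics`, `n_unmasked`.
#' @export
compute_structure_factors <- function(mask, table, grid) {
  stopifnot(inherits(table, "ff_exp_table"), inherits(grid, "ff_grid"))
  dm <- dim(mask) %||% length(mask)
  if (!identical(as.integer(dm), grid$shape))
    stop("mask shape does not match the grid", call. = FALSE)
  if (!any(mask)) stop("empty mask: no unmasked data points", call. = FALSE)
  p <- .ff_pad3(array(as.double(mask), dm), table$E)
  S <- .ff_contract(p$arr, p$shape3, p$tabs, "scalar_products_mask")
  S <- array(S, 4L * table$harmonics + 1L)
  structure(list(S = S, harmonics = table$harmonics,
                 n_unmasked = sum(mask)),
            class = "ff_structfac")
}

#' Compute the right-hand-side data spectrum
#'
#' Evaluates `F[m] = sum_r f(r) * M(r) * exp(1i * k_m . r)` over the full
#' mode lattice `-N <= m <= N` by the same separable contraction scheme as
#' the structure factors. Masked-out values are zeroed before the reduction.
#'
#' @param field An `ff_field` (see [masked_field()]).
#' @param table An `ff_exp_table`.
#' @return Complex array over the full lattice (dimension `2N+1` per axis).
#' @export
compute_rhs_spectrum <- function(field, table) {
  stopifnot(inherits(field, "ff_field"), inherits(table, "ff_exp_table"))
  if (!any(field$mask))
    stop("empty mask: no unmasked data points", call. = FALSE)
  v <- field$values
  v[!field$mask] <- 0
  d <- length(table$E)
  central <- lapply(seq_len(d), function(i) .ff_central_rows(table, i))
  p <- .ff_pad3(v, central)
  Fm <- .ff_contract(p$arr, p$shape3, p$tabs, "scalar_products_data")
  array(Fm, 2L * table$harmonics + 1L)
}

# Right-hand-side vector: interleaved (Re, Im) pairs of the spectrum in
# lattice order; entry 2p-1 belongs to the b-unknown of mode p, entry 2p to
# its c-unknown.
.ff_interleave_rhs <- function(spectrum) {
  f <- as.vector(spectrum)
  B <- numeric(2L * length(f))
  B[c(TRUE, FALSE)] <- Re(f)
  B[c(FALSE, TRUE)] <- Im(f)
  B
}

.ff_check_sf <- function(S, modes) {
  if (!inherits(S, "ff_structfac") || length(S$S) != modes$M_ext ||
      !identical(S$harmonics, modes$harmonics))
    stop("structure factors do not cover the extended lattice of this mode set",
         call. = FALSE)
}

#' Assemble the full real-valued normal-equation system
#'
#' Builds the `2M x 2M` matrix `A` whose interleaved b/c blocks are
#' `Re{S[m+n] + S[m-n]}`, `-Im{S[m+n] - S[m-n]}`, `Im{S[m+n] + S[m-n]}` and
#' `Re{S[m+n] - S[m-n]}`, together with the right-hand side `B` of
#' interleaved (Re, Im) pairs of the data spectrum. The full system is twice
#' redundant (conjugate mode pairs); it is materialized mainly for
#' cross-checks against direct summation, while production fits assemble the
#' reduced block directly via [reduce_system()]/[fit_masked_field()].
#'
#' @param S An `ff_structfac`.
#' @param spectrum Complex full-lattice array from [compute_rhs_spectrum()].
#' @param modes An `ff_modes`.
#' @return Class `ff_system` with elements `A`, `B`, `M` (`AA`, `BB` unset).
#' @export
assemble_full_system <- function(S, spectrum, modes) {
  stopifnot(inherits(modes, "ff_modes"))
  .ff_check_sf(S, modes)
  M <- modes$M
  A <- assemble_block_cpp(as.complex(S$S), modes$evec, modes$eoffset, 2L * M)
  structure(list(A = A, B = .ff_interleave_rhs(spectrum),
                 AA = NULL, BB = NULL, M = M),
            class = "ff_system")
}

#' Reduce the full system to the half-size independent block
#'
#' Because the lattice ordering is negation-symmetric, the unknown pairs
#' `(b, c)` of the last `(M-1)/2` modes duplicate those of the first
#' `(M-1)/2` (with `b_{-n} = b_n`, `c_{-n} = -c_n`), and the c-row/column of
#' the zero mode is identically zero. The independent `M x M` system is the
#' leading block of the full one: rows/columns 1..M-1 are the b/c pairs of
#' the first `(M-1)/2` lattice modes and row/column M is the b of the zero
#' mode.
#'
#' @param system An `ff_system` with `A`, `B` populated.
#' @param modes The matching `ff_modes`.
#' @return The system with `AA` (`M x M`) and `BB` (length `M`) populated.
#' @export
reduce_system <- function(system, modes) {
  stopifnot(inherits(system, "ff_system"), inherits(modes, "ff_modes"))
  M <- modes$M
  keep <- seq_len(M)
  system$AA <- system$A[keep, keep, drop = FALSE]
  system$BB <- system$B[keep]
  system
}

# Direct assembly of the reduced system without materializing the full A
# (the memory-relevant path for 3D problems).
assemble_reduced_system <- function(S, spectrum, modes) {
  stopifnot(inherits(modes, "ff_modes"))
  .ff_check_sf(S, modes)
  M <- modes$M
  AA <- assemble_block_cpp(as.complex(S$S), modes$evec, modes$eoffset, M)
  structure(list(A = NULL, B = NULL, AA = AA,
                 BB = .ff_interleave_rhs(spectrum)[seq_len(M)], M = M),
            class = "ff_system")
}

# Row signs mapping the reduced matrix onto its symmetric Gram form:
# b-rows (odd positions, and the trailing zero-mode b-row) keep their sign,
# c-rows (even positions) flip.
.ff_row_signs <- function(M) rep_len(c(1, -1), M)
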