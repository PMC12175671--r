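# Brute-force oracles: direct per-point summation, independent of the
# separable-contraction implementation. Only usable at tiny sizes.

# All grid points as a matrix (rows = points, cols = axes), column-major
# order (first axis fastest), matching R array linearization.
oracle_points <- function(grid) {
  as.matrix(expand.grid(grid$axis_coords, KEEP.OUT.ATTRS = FALSE))
}

# S_i = sum_r M(r) exp(1i k_i . r) over the extended lattice, direct loop.
oracle_structure_factors <- function(mask, grid, modes) {
  pts <- oracle_points(grid)
  m <- as.vector(mask)
  ext <- as.matrix(expand.grid(lapply(modes$harmonics,
                                      function(n) seq.int(-2L * n, 2L * n)),
                               KEEP.OUT.ATTRS = FALSE))
  S <- complex(nrow(ext))
  for (i in seq_len(nrow(ext))) {
    k <- ext[i, ] * grid$k0
    phase <- pts %*% k
    S[i] <- sum(m * exp(1i * phase))
  }
  array(S, 4L * modes$harmonics + 1L)
}

# Full-lattice data spectrum sum_r f M exp(1i k_m . r), direct loop.
oracle_spectrum <- function(values, mask, grid, modes) {
  pts <- oracle_points(grid)
  v <- as.vector(values) * as.vector(mask)
  Fm <- complex(modes$M)
  for (i in seq_len(modes$M)) {
    k <- modes$lattice[i, ] * grid$k0
    Fm[i] <- sum(v * exp(1i * drop(pts %*% k)))
  }
  array(Fm, 2L * modes$harmonics + 1L)
}

# Full real system assembled term-by-term from per-point kernels:
# the b_n column kernel at point r is e^{jk_m r}(e^{jk_n r} + e^{-jk_n r}),
# the c_n column kernel is j e^{jk_m r}(e^{jk_n r} - e^{-jk_n r}); the
# b-row takes the real part, the c-row the imaginary part.
oracle_full_system <- function(values, mask, grid, modes) {
  pts <- oracle_points(grid)
  msk <- as.vector(mask)
  v <- as.vector(values) * msk
  M <- modes$M
  ph <- pts %*% t(modes$lattice * rep(grid$k0, each = M))[, , drop = FALSE]
  # ph: points x modes phase matrix k_n . r
  E <- exp(1i * ph)
  A <- matrix(0, 2 * M, 2 * M)
  B <- numeric(2 * M)
  for (mi in seq_len(M)) {
    em <- E[, mi]
    lhs_b <- t(E + Conj(E)) %*% (msk * em)        # coeff of b_n, complex
    lhs_c <- t(1i * (E - Conj(E))) %*% (msk * em) # coeff of c_n
    rhs <- sum(v * em)
    A[2 * mi - 1, c(TRUE, FALSE)] <- Re(lhs_b)
    A[2 * mi - 1, c(FALSE, TRUE)] <- Re(lhs_c)
    A[2 * mi, c(TRUE, FALSE)] <- Im(lhs_b)
    A[2 * mi, c(FALSE, TRUE)] <- Im(lhs_c)
    B[2 * mi - 1] <- Re(rhs)
    B[2 * mi] <- Im(rhs)
  }
  list(A = A, B = B)
}

# Pointwise reconstruction sum (Eq-12 style), no contractions.
oracle_evaluate <- function(coeffs, grid) {
  pts <- oracle_points(grid)
  modes <- build_mode_set(coeffs$harmonics, grid)
  a <- as.vector(coeffs$a)
  out <- numeric(nrow(pts))
  for (i in seq_len(modes$M)) {
    k <- modes$lattice[i, ] * grid$k0
    out <- out + 2 * Re(a[i] * exp(1i * drop(pts %*% k)))
  }
  if (grid$ndim == 1L) out else array(out, grid$shape)
}

# Random conjugate-symmetric coefficient array for a mode set.
random_symmetric_coeffs <- function(modes) {
  M <- modes$M
  a <- complex(real = rnorm(M), imaginary = rnorm(M))
  a <- (a + Conj(rev(a))) / 2          # enforce a_{-n} = Conj(a_n)
  mid <- (M + 1L) %/% 2L
  a[mid] <- Re(a[mid])
  structure(list(a = array(a, 2L * modes$harmonics + 1L),
                 harmonics = modes$harmonics),
            class = "ff_coeffs")
}
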