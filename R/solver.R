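#' Configure the adaptive truncated-SVD regularizer
#'
#' Defaults follow the reference settings used for the benchmarks: singular
#' values below 0.1 are zeroed initially, the retained rank grows by 2% per
#' retry, and a retry is triggered while the system residual exceeds 3e-3.
#'
#' @param sv_threshold Initial truncation threshold. With
#'   `threshold_mode = "absolute"` (default) it applies to the raw singular
#'   values, with `"relative"` it is a fraction of the largest one.
#' @param residual_criterion Acceptance level for the system residual. With
#'   `residual_mode = "relative"` (default) the residual is
#'   `max|AA.xx - BB| / max|BB|`; `"absolute"` drops the normalization.
#' @param rank_growth Multiplicative retained-rank growth per retry
#'   (default 1.02, i.e. +2%); a floor of +1 keeps small ranks progressing.
#' @param max_iterations Optional cap on retries; by default the loop may
#'   reach full rank.
#' @param threshold_mode `"absolute"` or `"relative"`.
#' @param residual_mode `"relative"` or `"absolute"`.
#' @return Class `ff_config` list of the validated settings.
#' @export
regularizer_config <- function(sv_threshold = 0.1,
                               residual_criterion = 3e-3,
                               rank_growth = 1.02,
                               max_iterations = NULL,
                               threshold_mode = c("absolute", "relative"),
                               residual_mode = c("relative", "absolute")) {
  stopifnot(sv_threshold >= 0, residual_criterion > 0, rank_growth > 1)
  if (!is.null(max_iterations)) stopifnot(max_iterations >= 1)
  structure(list(sv_threshold = sv_threshold,
                 residual_criterion = residual_criterion,
                 rank_growth = rank_growth,
                 max_iterations = max_iterations,
                 threshold_mode = match.arg(threshold_mode),
                 residual_mode = match.arg(residual_mode)),
            class = "ff_config")
}

# Cheap randomized symmetry probe (full t(X) comparison would double memory
# for the 3D system).
.ff_probably_symmetric <- function(X, n = 200L, tol = 1e-8) {
  m <- nrow(X)
  if (m != ncol(X)) return(FALSE)
  if (m <= 30L) {
    return(max(abs(X - t(X))) <= tol * max(1, max(abs(X))))
  }
  i <- as.integer(seq(1L, m, length.out = min(n, m))) # deterministic probe
  sub <- X[i, i, drop = FALSE]
  max(abs(sub - t(sub))) <= tol * max(1, max(abs(sub)))
}

#' Factorize the reduced matrix by singular value decomposition
#'
#' For a general matrix this is a plain SVD. When `row_signs` is supplied
#' (the interleaved b/c layout of the reduced system), the matrix
#' `diag(row_signs) %*% AA` is the symmetric positive-semidefinite Gram
#' matrix of the masked cosine/sine basis, so the exact SVD of `AA` is
#' recovered from one symmetric eigendecomposition
#' (`AA = (D Q sign(lambda)) |lambda| Q^T`), which is substantially faster
#' and lighter than a general SVD for the large 3D systems.
#'
#' @param AA Square numeric matrix.
#' @param row_signs Optional +/-1 vector of length `nrow(AA)`; see
#'   `fourierfit:::.ff_row_signs`.
#' @param destroy If `TRUE` (sign-structured path only) the
#'   eigendecomposition overwrites `AA` in place, halving the peak memory
#'   for very large systems; `AA` is garbage afterwards and the caller
#'   must reassemble it if still needed.
#' @return Class `ff_svd`: `u`, `d` (descending), `v`, `method`.
#' @export
svd_factorize <- function(AA, row_signs = NULL, destroy = FALSE) {
  if (any(!is.finite(AA))) stop("non-finite entries in AA", call. = FALSE)
  .ff_count("svd_calls", 1)
  M <- nrow(AA)
  if (!is.null(row_signs)) {
    stopifnot(length(row_signs) == M)
    scale_rows_inplace(AA, row_signs)
    sym <- .ff_probably_symmetric(AA)
    if (sym) {
      if (destroy) {
        lam0 <- eig_sym_inplace(AA)      # dsyevd; AA now holds eigenvectors
        e <- list(values = lam0, vectors = AA)
      } else {
        e <- eigen(AA, symmetric = TRUE) # dsyevr: O(n) workspace
        scale_rows_inplace(AA, row_signs)
      }
      ord <- order(abs(e$values), decreasing = TRUE)
      lam <- e$values[ord]
      V <- e$vectors[, ord, drop = FALSE]
      col_signs <- ifelse(lam < 0, -1, 1)
      f <- structure(list(u = NULL, d = abs(lam), v = V,
                          row_signs = row_signs, col_signs = col_signs,
                          method = "sym-eig"), class = "ff_svd")
      # materialize U only when the extra n^2 doubles are cheap; large
      # systems apply U through V and the sign vectors instead
      if (M <= 4096L) {
        U <- row_signs * V
        for (j in which(col_signs < 0)) U[, j] <- -U[, j]
        f$u <- U
      }
      return(f)
    }
    scale_rows_inplace(AA, row_signs)
  }
  s <- svd(AA)
  structure(list(u = s$u, d = s$d, v = s$v, method = "svd"),
            class = "ff_svd")
}

# t(U) %*% b without materializing U (U = D V S for the sym-eig route).
.ff_ut_b <- function(f, b) {
  if (!is.null(f$u)) return(drop(crossprod(f$u, b)))
  f$col_signs * drop(crossprod(f$v, f$row_signs * b))
}

# U[, idx] %*% w, optionally unmaterialized.
.ff_u_mult <- function(f, idx, w) {
  if (!is.null(f$u))
    return(drop(f$u[, idx, drop = FALSE] %*% w))
  f$row_signs * drop(f$v[, idx, drop = FALSE] %*% (f$col_signs[idx] * w))
}

#' Minimal-norm least-squares solve of the reduced system
#'
#' Solves `AA . xx = BB` in the least-squares sense, returning the
#' minimal-norm solution when `AA` is singular (pseudo-inverse with the
#' conventional `max(dim) * eps * sigma_max` rank cutoff).
#'
#' @param AA Square numeric matrix.
#' @param BB Numeric vector.
#' @param factorization Optional precomputed [svd_factorize()] result.
#' @return Numeric solution vector `xx`.
#' @export
solve_direct <- function(AA, BB, factorization = NULL) {
  if (any(!is.finite(AA)) || any(!is.finite(BB)))
    stop("non-finite inputs", call. = FALSE)
  stopifnot(nrow(AA) == ncol(AA), length(BB) == nrow(AA))
  f <- factorization %||% svd_factorize(AA)
  tol <- max(dim(AA)) * .Machine$double.eps * max(f$d, 0)
  keep <- f$d > tol
  if (!any(keep)) return(numeric(length(BB)))
  ub <- .ff_ut_b(f, BB)
  drop(f$v[, keep, drop = FALSE] %*% (ub[keep] / f$d[keep]))
}

#' Solve the reduced system with adaptive truncated-SVD regularization
#'
#' One SVD is computed (or reused from `factorization`); singular values
#' below the threshold are zeroed; the truncated pseudo-inverse solution is
#' formed; and while the system residual exceeds the acceptance criterion
#' the retained rank is raised by the growth factor (at least +1) and the
#' back-substitution redone, until the criterion holds or full rank is
#' reached. Inside the loop the residual is evaluated through the
#' factorization identity `AA %*% xx = U[,1:k] %*% (U^T BB)[1:k]`, which is
#' exact linear algebra and avoids an `M^2` product per retry; the final
#' reported residual is recomputed against `AA` itself.
#'
#' @inheritParams solve_direct
#' @param config An [regularizer_config()].
#' @param row_signs Optional b/c sign layout enabling the symmetric fast
#'   factorization path (see [svd_factorize()]).
#' @return List with `xx` (solution) and `diagnostics` (class `ff_diag`):
#'   `retained_rank`, `iterations`, `converged`, `residual_trajectory` and
#'   `rank_trajectory` (the loop metric and retained rank per iteration), `relative_system_residual`,
#'   `absolute_system_residual`, `sv_threshold_used`, `sv_max`.
#' @export
solve_regularized <- function(AA, BB, config = regularizer_config(),
                              factorization = NULL, row_signs = NULL) {
  stopifnot(inherits(config, "ff_config"))
  if (any(!is.finite(AA)) || any(!is.finite(BB)))
    stop("non-finite inputs", call. = FALSE)
  M <- length(BB)
  stopifnot(nrow(AA) == ncol(AA), nrow(AA) == M)
  .ff_count("solve_calls", 1)
  f <- factorization %||% svd_factorize(AA, row_signs)

  diag_base <- function(rank, iters, conv, traj, xx, ranks) {
    rs <- drop(AA %*% xx) - BB
    structure(list(
      retained_rank = rank, iterations = iters, converged = conv,
      residual_trajectory = traj, rank_trajectory = ranks,
      absolute_system_residual = max(abs(rs)),
      relative_system_residual =
        if (all(BB == 0)) 0 else max(abs(rs)) / max(abs(BB)),
      sv_threshold_used = attr(traj, "thr"),
      sv_max = if (length(f$d)) f$d[1] else 0,
      factorization_method = f$method), class = "ff_diag")
  }

  if (all(BB == 0)) {
    xx <- numeric(M)
    traj <- numeric(0); attr(traj, "thr") <- NA_real_
    return(list(xx = xx,
                diagnostics = diag_base(0L, 0L, TRUE, traj, xx, integer(0)),
                factorization = f))
  }

  thr <- if (config$threshold_mode == "absolute") config$sv_threshold
         else config$sv_threshold * max(f$d, 0)
  denom <- if (config$residual_mode == "relative") max(abs(BB)) else 1
  ub <- .ff_ut_b(f, BB)
  # numerically-zero singular values (below the conventional pseudo-inverse
  # cutoff) are never inverted, whatever the user threshold; with
  # sv_threshold = 0 the converged solution is then exactly the
  # minimal-norm least-squares one
  dfloor <- M * .Machine$double.eps * max(f$d, 0)
  k <- sum(f$d >= thr)
  xx <- numeric(M)
  Bhat <- numeric(M)
  kprev <- 0L
  iters <- 0L
  traj <- numeric(0)
  ranks <- integer(0)
  converged <- FALSE
  repeat {
    iters <- iters + 1L
    ranks <- c(ranks, as.integer(k))
    if (k > kprev) {
      idx <- seq.int(kprev + 1L, k)
      idx <- idx[f$d[idx] > dfloor]
      # column-blocked updates bound the transient subset copies of V
      for (blk in unname(split(idx, ceiling(seq_along(idx) / 2048)))) {
        xx <- xx + drop(f$v[, blk, drop = FALSE] %*% (ub[blk] / f$d[blk]))
        Bhat <- Bhat + .ff_u_mult(f, blk, ub[blk])
      }
      kprev <- k
    }
    metric <- max(abs(Bhat - BB)) / denom
    traj <- c(traj, metric)
    if (metric <= config$residual_criterion) { converged <- TRUE; break }
    if (k >= M) break
    if (!is.null(config$max_iterations) && iters >= config$max_iterations)
      break
    k <- min(M, max(k + 1L, as.integer(ceiling(k * config$rank_growth))))
  }
  attr(traj, "thr") <- thr
  list(xx = xx, diagnostics = diag_base(as.integer(k), iters, converged,
                                        traj, xx, ranks),
       factorization = f)
}

#' Expand the reduced solution to the full interleaved coefficient vector
#'
#' Applies the index mapping that reinstates the conjugate-redundant half of
#' the unknowns: with `N = 2M`, the first `M - 1` entries are halved in
#' place, entry `M` (the zero-mode b) is copied unhalved, every mirrored
#' b-entry receives `+xx/2`, every mirrored c-entry `-xx/2`, and the
#' zero-mode c entry is zero. The result satisfies `b_{-n} = b_n`,
#' `c_{-n} = -c_n`.
#'
#' @param xx Reduced solution of length `M = prod(2N+1)`.
#' @param modes The matching `ff_modes`.
#' @return Numeric vector of length `2M`, interleaved `(b, c)` pairs in
#'   lattice order.
#' @export
expand_solution <- function(xx, modes) {
  stopifnot(inherits(modes, "ff_modes"))
  M <- modes$M
  if (length(xx) != M) stop("reduced solution has wrong length", call. = FALSE)
  x <- numeric(2L * M)
  if (M > 1L) x[seq_len(M - 1L)] <- xx[seq_len(M - 1L)] / 2
  x[M] <- xx[M]
  if (M > 2L) {
    i <- seq.int(1L, M - 2L, by = 2L)
    x[2L * M - i] <- xx[i] / 2
    x[2L * M - i + 1L] <- -xx[i + 1L] / 2
  }
  x
}

#' Complex Fourier coefficients from the interleaved real solution
#'
#' @param x Full solution vector (length `2M`) of interleaved `(b, c)`
#'   pairs; `a_n = b_n + 1i * c_n`.
#' @param modes The matching `ff_modes`.
#' @param tol Relative tolerance for the conjugate-symmetry consistency
#'   check `a_{-n} = Conj(a_n)`.
#' @return Class `ff_coeffs`: complex array `a` over the full lattice
#'   (dimension `2N+1` per axis) plus `harmonics`.
#' @export
coefficients_from_solution <- function(x, modes, tol = 1e-10) {
  stopifnot(inherits(modes, "ff_modes"))
  M <- modes$M
  if (length(x) != 2L * M) stop("solution vector has wrong length", call. = FALSE)
  a <- x[c(TRUE, FALSE)] + 1i * x[c(FALSE, TRUE)]
  scale <- max(1, max(abs(a)))
  if (max(abs(a - Conj(rev(a)))) > tol * scale)
    stop("coefficient conjugate symmetry violated", call. = FALSE)
  structure(list(a = array(a, 2L * modes$harmonics + 1L),
                 harmonics = modes$harmonics),
            class = "ff_coeffs")
}
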