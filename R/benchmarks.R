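# Default axis-aligned hole boxes per benchmark dimension. Each hole is a
# d x 2 matrix (rows = axes, columns = closed interval bounds). The first
# 2D hole and the first 3D hole are square/cubic boxes centred on the
# origin ([-0.5, 0.5] per axis).
.ff_default_holes <- function(dimension) {
  h <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  switch(dimension,
    list(h(-3.5, -2.5), h(-0.5, 0.5), h(2.5, 3.5)),
    list(h(-0.5, 0.5, -0.5, 0.5),
         h(-0.5, 0.5, 2, 3),
         h(2, 3, 2, 3)),
    list(h(-0.5, 0.5, -0.5, 0.5, -0.5, 0.5),
         h(-0.5, 0.5, 2, 3, -0.5, 0.5),
         h(2, 3, 2, 3, -0.5, 0.5),
         h(-0.5, 0.5, -0.5, 0.5, 2, 3)))
}

#' Specify an Ackley-type reconstruction benchmark
#'
#' The benchmarks fit a truncated Fourier basis to an Ackley-type test
#' function (exponential envelope plus cosine oscillations, min-max
#' normalized to [0, 1]) sampled on a regular grid from which axis-aligned
#' blocks ("holes") have been masked out, and measure the reconstruction
#' deviation inside and outside the mask.
#'
#' @param dimension 1, 2 or 3.
#' @param a,b,cpar Ackley parameters (defaults 5, 0.2, 1.5*pi).
#' @param bounds Per-axis domain, default `c(-5, 5)` on every axis.
#' @param resolution Grid points per axis (default 200).
#' @param holes List of `d x 2` matrices (closed intervals per axis);
#'   defaults to the standard three (1D/2D) or four (3D) blocks.
#' @param harmonics Harmonic cutoff per axis (default 11).
#' @param normalize Min-max normalize the sampled field to [0, 1] over the
#'   full grid, before masking (default `TRUE`).
#' @return Class `ff_benchmark_spec` list.
#' @export
benchmark_spec <- function(dimension, a = 5, b = 0.2, cpar = 1.5 * pi,
                           bounds = c(-5, 5), resolution = 200,
                           holes = NULL, harmonics = 11,
                           normalize = TRUE) {
  dimension <- as.integer(dimension)
  stopifnot(dimension %in% 1:3, a > 0, b > 0, cpar > 0)
  holes <- holes %||% .ff_default_holes(dimension)
  stopifnot(is.list(holes))
  for (hh in holes) {
    stopifnot(is.matrix(hh), nrow(hh) == dimension, ncol(hh) == 2)
    if (any(hh[, 1] < min(bounds)) || any(hh[, 2] > max(bounds)))
      stop("hole extends beyond the domain bounds", call. = FALSE)
  }
  structure(list(dimension = dimension, a = a, b = b, cpar = cpar,
                 bounds = bounds, resolution = rep_len(resolution, dimension),
                 holes = holes, harmonics = rep_len(harmonics, dimension),
                 normalize = normalize),
            class = "ff_benchmark_spec")
}

#' Evaluate the Ackley-type benchmark field on a grid
#'
#' In 1D: `-a*exp(-b*|x|) - exp(cos(c*x)/a) + a + exp(1)`.
#' In 2D: `-a*exp(-b*sqrt((x^2+y^2)/2)) - exp((cos(c*x)+cos(c*y))/2) + a + exp(1)`.
#' In 3D the same with three-way averages. With `normalize = TRUE` the
#' sampled field is mapped to [0, 1] by `(f - min) / (max - min)` computed
#' over the full grid (before any masking).
#'
#' @param spec An [benchmark_spec()].
#' @param grid An `ff_grid` consistent with the spec.
#' @return Numeric array (vector in 1D) of field samples.
#' @export
ackley_field <- function(spec, grid) {
  stopifnot(inherits(spec, "ff_benchmark_spec"), inherits(grid, "ff_grid"),
            grid$ndim == spec$dimension)
  a <- spec$a; b <- spec$b; cc <- spec$cpar
  cs <- grid$axis_coords
  d <- spec$dimension
  if (d == 1) {
    x <- cs[[1]]
    # 1D variant: envelope on |x|, cosine exponent scaled by 1/a
    f <- -a * exp(-b * abs(x)) - exp(cos(cc * x) / a) + a + exp(1)
  } else {
    add_outer <- function(parts) {
      acc <- outer(parts[[1]], parts[[2]], `+`)
      if (d >= 3) acc <- outer(acc, parts[[3]], `+`)
      acc
    }
    r2 <- add_outer(lapply(cs, function(x) x^2)) / d
    cm <- add_outer(lapply(cs, function(x) cos(cc * x))) / d
    f <- -a * exp(-b * sqrt(r2)) - exp(cm) + a + exp(1)
  }
  if (spec$normalize) f <- (f - min(f)) / (max(f) - min(f))
  if (d == 1) as.vector(f) else f
}

#' Build the benchmark mask
#'
#' Mask is `FALSE` at every grid point lying inside any hole box (closed
#' intervals: boundary points are masked out) and `TRUE` elsewhere.
#'
#' @param spec An [benchmark_spec()].
#' @param grid The matching `ff_grid`.
#' @return Logical array (vector dims in 1D kept as array).
#' @export
benchmark_mask <- function(spec, grid) {
  stopifnot(inherits(spec, "ff_benchmark_spec"), inherits(grid, "ff_grid"))
  d <- spec$dimension
  shape <- grid$shape
  mask <- array(TRUE, shape)
  for (hh in spec$holes) {
    inax <- lapply(seq_len(d), function(i) {
      x <- grid$axis_coords[[i]]
      x >= hh[i, 1] & x <= hh[i, 2]
    })
    inside <- inax[[1]]
    if (d >= 2) inside <- outer(inside, inax[[2]], `&`)
    if (d >= 3) inside <- outer(inside, inax[[3]], `&`)
    mask[inside] <- FALSE
  }
  mask
}

#' Reconstruction deviation metrics
#'
#' Maximum absolute deviation and standard deviation of
#' `truth - reconstruction`, restricted separately to the mask-`TRUE`
#' points (data present) and the mask-`FALSE` points (holes). The standard
#' deviations are population standard deviations of the signed deviations;
#' the `_abs` variants apply the same statistic to absolute deviations,
#' since conventions differ between reports.
#'
#' @param truth,reconstruction Arrays of equal shape.
#' @param mask Logical array of the same shape.
#' @return Class `ff_deviation`: `max_in_mask`, `std_in_mask`,
#'   `max_out_mask`, `std_out_mask`, `std_in_mask_abs`, `std_out_mask_abs`,
#'   `n_in`, `n_out`.
#' @export
deviation_metrics <- function(truth, reconstruction, mask) {
  dt <- dim(truth) %||% length(truth)
  dr <- dim(reconstruction) %||% length(reconstruction)
  if (!identical(as.integer(dt), as.integer(dr)))
    stop("truth and reconstruction shapes differ", call. = FALSE)
  dev <- truth - reconstruction
  sd_pop <- function(x) if (length(x) == 0) NA_real_
                        else sqrt(mean((x - mean(x))^2))
  din <- dev[mask]; dout <- dev[!mask]
  structure(list(
    max_in_mask = if (length(din)) max(abs(din)) else NA_real_,
    std_in_mask = sd_pop(din),
    max_out_mask = if (length(dout)) max(abs(dout)) else NA_real_,
    std_out_mask = sd_pop(dout),
    std_in_mask_abs = sd_pop(abs(din)),
    std_out_mask_abs = sd_pop(abs(dout)),
    n_in = length(din), n_out = length(dout)
  ), class = "ff_deviation")
}

#' @export
print.ff_deviation <- function(x, ...) {
  cat(sprintf(
    "<ff_deviation> in mask: max %.4g, std %.4g (n=%d) | holes: max %.4g, std %.4g (n=%d)\n",
    x$max_in_mask, x$std_in_mask, x$n_in,
    x$max_out_mask, x$std_out_mask, x$n_out))
  invisible(x)
}

#' Run an Ackley reconstruction benchmark end to end
#'
#' Wires spec -> grid -> field -> mask -> [fit_masked_field()] ->
#' [evaluate_field()] -> [deviation_metrics()]. Entirely deterministic:
#' repeated runs are bitwise identical.
#'
#' @param case `"1d"`, `"2d"` or `"3d"`.
#' @param resolution,harmonics,cpar,holes Overrides of the spec defaults.
#' @param padding_fraction Fourier period padding (default 0.1).
#' @param convention Grid coordinate convention (default `"inclusive"`).
#' @param config Solver settings ([regularizer_config()] defaults).
#' @param solver `"svd"` or `"direct"`.
#' @param cache Optional [factorization_cache()].
#' @return Class `ff_benchmark`: `report` (`ff_deviation`), `fit`
#'   (`ff_fit`), `truth`, `mask`, `grid`, `spec`, `settings`.
#' @export
run_benchmark <- function(case = c("1d", "2d", "3d"), resolution = NULL,
                          harmonics = NULL, cpar = NULL, holes = NULL,
                          padding_fraction = 0.1,
                          convention = c("inclusive", "half-open"),
                          config = regularizer_config(),
                          solver = c("svd", "direct"), cache = NULL) {
  case <- match.arg(case)
  convention <- match.arg(convention)
  solver <- match.arg(solver)
  dimension <- match(case, c("1d", "2d", "3d"))
  spec <- benchmark_spec(dimension,
                         cpar = cpar %||% (1.5 * pi),
                         resolution = resolution %||% 200,
                         harmonics = harmonics %||% 11,
                         holes = holes)
  grid <- build_grid(spec$resolution, spec$bounds,
                     padding_fraction = padding_fraction,
                     convention = convention)
  truth <- ackley_field(spec, grid)
  mask <- benchmark_mask(spec, grid)
  fit <- fit_masked_field(masked_field(truth, mask), grid, spec$harmonics,
                          config = config, solver = solver, cache = cache,
                          keep_fitted = TRUE)
  report <- deviation_metrics(truth, fit$fitted, mask)
  structure(list(report = report, fit = fit, truth = truth, mask = mask,
                 grid = grid, spec = spec,
                 settings = list(padding_fraction = padding_fraction,
                                 convention = convention, solver = solver,
                                 config = unclass(config))),
            class = "ff_benchmark")
}

#' @export
print.ff_benchmark <- function(x, ...) {
  cat("<ff_benchmark> ", x$spec$dimension, "D, ",
      paste(x$spec$resolution, collapse = " x "), " points, N = (",
      paste(x$spec$harmonics, collapse = ", "), ")\n", sep = "")
  print(x$report)
  invisible(x)
}
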