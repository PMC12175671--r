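#' Read a volume or volume series from disk
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) via RNifti and R-native serialized
#' arrays (`.rds`). NIfTI voxel spacing sets the grid bounds under the
#' inclusive convention (`extent = spacing * (count - 1)` per axis); for
#' `.rds` arrays the bounds default to unit spacing unless given. A 4D
#' input is interpreted as a series of 3D volumes along the last axis.
#'
#' @param path File path.
#' @param bounds Optional per-axis bounds overriding the derived ones.
#' @param padding_fraction,convention Passed to [build_grid()].
#' @return List with `data` (array, up to 4D), `spatial_shape`, `n_steps`
#'   (1 for a single volume), `spacing` (NIfTI only) and `grid` (an
#'   `ff_grid` over the spatial axes).
#' @export
read_volume <- function(path, bounds = NULL, padding_fraction = 0.1,
                        convention = c("inclusive", "half-open")) {
  convention <- match.arg(convention)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lower <- tolower(path)
  spacing <- NULL
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    data <- as.array(img)
    pd <- RNifti::pixdim(img)
    spacing <- pd[seq_len(min(3L, length(dim(data))))]
  } else if (grepl("\\.rds$", lower)) {
    data <- readRDS(path)
    if (!is.array(data) && !is.numeric(data))
      stop("rds file does not contain an array", call. = FALSE)
    data <- as.array(data)
  } else {
    stop("unknown volume format (expect .nii, .nii.gz or .rds): ", path,
         call. = FALSE)
  }
  nd <- length(dim(data))
  if (nd > 4L) stop("more than 4 dimensions are not supported", call. = FALSE)
  spatial <- dim(data)[seq_len(min(nd, 3L))]
  n_steps <- if (nd == 4L) dim(data)[4L] else 1L
  if (is.null(bounds)) {
    sp <- spacing %||% rep(1, length(spatial))
    bounds <- lapply(seq_along(spatial), function(i) {
      ext <- if (convention == "inclusive") sp[i] * (spatial[i] - 1L)
             else sp[i] * spatial[i]
      c(0, max(ext, sp[i])) # guard single-point axes
    })
  }
  grid <- build_grid(spatial, bounds, padding_fraction = padding_fraction,
                     convention = convention)
  list(data = data, spatial_shape = spatial, n_steps = n_steps,
       spacing = spacing, grid = grid)
}

.ff_coeffs_version <- 1L

#' Write a fit result to disk
#'
#' Stores coefficients, mode set, grid, diagnostics and provenance in one
#' R-native container with a content checksum, sufficient to reconstruct
#' the field on any machine with [read_coefficients()] plus
#' [evaluate_field()].
#'
#' @param fit An `ff_fit`.
#' @param path Output path (`.rds`).
#' @param grid The `ff_grid` the fit was computed on (stored for
#'   self-contained reconstruction).
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(fit, path, grid) {
  stopifnot(inherits(fit, "ff_fit"), inherits(grid, "ff_grid"))
  payload <- list(a = fit$coefficients$a,
                  harmonics = fit$coefficients$harmonics,
                  grid = unclass(grid),
                  diagnostics = unclass(fit$diagnostics),
                  provenance = fit$provenance)
  obj <- list(version = .ff_coeffs_version,
              checksum = .ff_checksum(payload),
              payload = payload)
  saveRDS(obj, path)
  invisible(path)
}

#' Read a fit result written by [write_coefficients()]
#'
#' @param path Input path.
#' @return List with `coefficients` (`ff_coeffs`), `grid` (`ff_grid`),
#'   `diagnostics`, `provenance`.
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- readRDS(path)
  if (!identical(obj$version, .ff_coeffs_version))
    stop("coefficient container version mismatch", call. = FALSE)
  if (!identical(obj$checksum, .ff_checksum(obj$payload)))
    stop("coefficient container failed its integrity check", call. = FALSE)
  p <- obj$payload
  list(coefficients = structure(list(a = p$a, harmonics = p$harmonics),
                                class = "ff_coeffs"),
       grid = structure(p$grid, class = "ff_grid"),
       diagnostics = p$diagnostics,
       provenance = p$provenance)
}

#' Default run configuration
#'
#' Collects every tunable of a fit run: harmonics, padding, solver
#' settings and the convention flags. The defaults are the reference
#' benchmark settings (11 harmonics per axis, 10% padding, singular-value
#' threshold 0.1, residual criterion 3e-3, rank growth 2%).
#'
#' @param ... Overrides of the defaults.
#' @return Class `ff_run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    harmonics = 11, padding_fraction = 0.1,
    convention = "inclusive",
    solver = "svd",
    sv_threshold = 0.1, threshold_mode = "absolute",
    residual_criterion = 3e-3, residual_mode = "relative",
    rank_growth = 1.02)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(modifyList(cfg, over), class = "ff_run_config")
}

#' Read / write a run configuration as YAML
#'
#' Round-trips losslessly through the YAML file.
#'
#' @param path File path.
#' @param config An `ff_run_config`.
#' @return `read_config` returns an `ff_run_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ff_run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.ff_solver_config <- function(cfg) {
  regularizer_config(sv_threshold = cfg$sv_threshold,
                     residual_criterion = cfg$residual_criterion,
                     rank_growth = cfg$rank_growth,
                     threshold_mode = cfg$threshold_mode,
                     residual_mode = cfg$residual_mode)
}
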