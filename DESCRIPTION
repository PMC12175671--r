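Package: fourierfit
Title: Fourier Base Fitting on Masked or Incomplete Structured Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a truncated Fourier basis to real-valued fields known only
    on a masked subset of a regular rectangular grid (1-3 spatial dimensions,
    optional time axis). Masking destroys the unitarity of the discrete
    Fourier transform, so the coefficients are obtained by solving a reduced
    real-valued least-squares system whose entries are generated from complex
    mask structure factors, assembled by separable single-axis tensor
    contractions. Ill-conditioned systems are regularized by adaptive
    truncated singular value decomposition. Supports smoothing,
    interpolation into masked-out holes, and extrapolation beyond the data
    extent via spectral padding, with cached factorizations for time series
    that share one mask (e.g. volumetric deformation-imaging data).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
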