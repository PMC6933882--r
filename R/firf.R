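#' Ideal low-pass impulse response coefficient
#'
#' Closed-form inverse discrete-time Fourier transform of the ideal low-pass
#' frequency response with cutoff `cutoff` (normalized angular frequency in
#' `(0, pi)`), evaluated at integer tap index `n` relative to the filter
#' center: `sin(cutoff * n) / (pi * n)` for `n != 0` and `cutoff / pi` at
#' `n = 0`.
#'
#' @param cutoff Normalized angular cutoff frequency, strictly inside `(0, pi)`.
#' @param n Integer tap index (vectorized), relative to the center tap.
#' @return Numeric vector of ideal impulse-response values.
#' @export
#' @examples
#' ideal_lowpass_coeff(pi / 2, 0)  # 0.5
ideal_lowpass_coeff <- function(cutoff, n) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff >= pi)
    stop("cutoff must lie strictly inside (0, pi)")
  ifelse(n == 0, cutoff / pi, sin(cutoff * n) / (pi * n))
}

.window_sequence <- function(window_kind, n) {
  switch(window_kind,
         rectangular = rep(1, n),
         hamming     = if (n == 1L) 1 else as.numeric(signal::hamming(n)),
         hann        = if (n == 1L) 1 else as.numeric(signal::hanning(n)),
         blackman    = if (n == 1L) 1 else as.numeric(signal::blackman(n)),
         stop(sprintf("unknown window kind '%s'", window_kind)))
}

#' Design a low-pass FIR filter by the window method
#'
#' Truncates the ideal low-pass impulse response to `order` taps centred at
#' `(order - 1) / 2` and multiplies elementwise by the chosen window sequence:
#' `h(n) = h_d(n - (order - 1) / 2) * w(n)`. For symmetric windows the
#' resulting taps are symmetric, giving a linear-phase filter.
#'
#' @param cutoff Normalized angular cutoff frequency in `(0, pi)`.
#' @param order Number of taps `N >= 1`; odd orders have an integer center.
#' @param window_kind One of `"rectangular"`, `"hamming"`, `"hann"`,
#'   `"blackman"`.
#' @return An object of class `"fir_filter"` with fields `coefficients`,
#'   `cutoff`, `window_kind`, `order`.
#' @export
#' @examples
#' f <- design_fir(0.3 * pi, 7, "hamming")
#' f$coefficients
design_fir <- function(cutoff, order, window_kind = c("hamming", "rectangular", "hann", "blackman")) {
  window_kind <- match.arg(window_kind)
  if (!is.numeric(order) || length(order) != 1L || order < 1 || order != round(order))
    stop("order must be a positive integer")
  order <- as.integer(order)
  center <- (order - 1) / 2
  hd <- ideal_lowpass_coeff(cutoff, (0:(order - 1)) - center)
  h <- hd * .window_sequence(window_kind, order)
  structure(list(coefficients = h, cutoff = cutoff,
                 window_kind = window_kind, order = order),
            class = "fir_filter")
}

#' @export
print.fir_filter <- function(x, ...) {
  cat(sprintf("FIR low-pass filter: %d taps, cutoff %.4g*pi, %s window\n",
              x$order, x$cutoff / pi, x$window_kind))
  invisible(x)
}

#' Frequency response of an FIR filter
#'
#' Evaluates the discrete-time Fourier transform
#' `H(e^{jw}) = sum_n h(n) exp(-j w n)` of the filter taps at each grid
#' frequency.
#'
#' @param filter A [design_fir()] filter (or any object with numeric
#'   `coefficients`).
#' @param grid Numeric vector of angular frequencies in `[-pi, pi]`.
#' @return List of class `"frequency_response"` with `grid` and complex
#'   `values`.
#' @export
frequency_response <- function(filter, grid) {
  h <- if (inherits(filter, "fir_filter")) filter$coefficients else as.numeric(filter)
  if (length(grid) == 0L) stop("frequency grid must be non-empty")
  if (any(grid < -pi - 1e-12 | grid > pi + 1e-12))
    stop("grid frequencies must lie in [-pi, pi]")
  n <- seq_along(h) - 1
  values <- vapply(grid, function(w) sum(h * exp(-1i * w * n)), complex(1))
  structure(list(grid = grid, values = values), class = "frequency_response")
}

#' Integral square error of a designed filter against the ideal low-pass
#'
#' Numerically evaluates
#' `(1 / 2pi) * integral over [-pi, pi] of |H_d(e^{jw}) - H(e^{jw})|^2 dw`,
#' where `H_d` is the ideal low-pass response (1 inside the cutoff band, 0
#' outside) and `H` is the designed response with its linear phase removed
#' (zero-phase alignment at the filter center), so that the error measures
#' magnitude approximation only. Used as a design-verification diagnostic: for
#' rectangular windows it decreases monotonically with the tap count, by
#' least-squares optimality of the truncated Fourier series.
#'
#' @param filter A [design_fir()] filter.
#' @param cutoff Cutoff of the ideal reference; defaults to the filter's own.
#' @param quadrature_points Number of quadrature nodes (`>= 64`).
#' @return Nonnegative scalar error.
#' @export
integral_square_error <- function(filter, cutoff = filter$cutoff,
                                  quadrature_points = 4096L) {
  stopifnot(inherits(filter, "fir_filter"))
  if (quadrature_points < 64L) stop("quadrature_points must be at least 64")
  w <- seq(-pi, pi, length.out = quadrature_points)
  center <- (filter$order - 1) / 2
  H <- frequency_response(filter, w)$values * exp(1i * w * center)
  Hd <- as.numeric(abs(w) <= cutoff)
  err <- abs(Hd - H)^2
  # trapezoidal rule over [-pi, pi], normalized by 2*pi
  sum((err[-1] + err[-length(err)]) / 2 * diff(w)) / (2 * pi)
}

#' Filter the amino-acid columns of a PSSM along the sequence
#'
#' Each of the 20 amino-acid columns of the PSSM is treated as a length-`H`
#' signal along the sequence and convolved with the filter taps. The output
#' has the same `H` rows: the convolution is zero-padded at both ends and the
#' filter center is aligned with the current position.
#'
#' @param pssm A [pssm()] object.
#' @param filter A [design_fir()] filter.
#' @return Numeric `H x 20` matrix of filtered scores.
#' @export
filter_columns <- function(pssm, filter) {
  stopifnot(inherits(pssm, "pssm"), inherits(filter, "fir_filter"))
  h <- filter$coefficients
  H <- nrow(pssm$scores)
  center <- floor((filter$order - 1) / 2)
  out <- apply(pssm$scores, 2, function(x) {
    # direct zero-padded convolution; exact for short tap vectors
    full <- numeric(H + filter$order - 1L)
    for (j in seq_along(h))
      full[j:(j + H - 1L)] <- full[j:(j + H - 1L)] + h[j] * x
    full[(1 + center):(center + H)]
  })
  matrix(out, nrow = H, ncol = 20L)
}

#' FIR-filtered Gram features of a PSSM
#'
#' The sequence-length-independent feature vector of the pipeline: the PSSM
#' columns are filtered along the sequence with [filter_columns()], the
#' 20 x 20 Gram matrix `t(F) %*% F` of the filtered columns is formed, and its
#' row-major flattening is returned. The result always has length 400
#' regardless of sequence length, and reshaped back to 20 x 20 it is symmetric
#' positive semi-definite.
#'
#' @param pssm A [pssm()] object.
#' @param filter A [design_fir()] filter; default 7-tap Hamming low-pass with
#'   cutoff `0.3 * pi`.
#' @return Numeric feature vector of length 400.
#' @export
#' @examples
#' p <- pssm("MKV", matrix(rnorm(60), 3, 20))
#' length(extract_features(p))
extract_features <- function(pssm, filter = design_fir(0.3 * pi, 7, "hamming")) {
  Fm <- filter_columns(pssm, filter)
  if (is.null(dim(Fm))) Fm <- matrix(Fm, nrow = 1L)  # H = 1 edge case
  G <- crossprod(Fm)
  as.numeric(t(G))  # row-major flattening
}

#' Feature matrix for a list of PSSMs
#'
#' Applies [extract_features()] to each PSSM and stacks the results.
#'
#' @param pssms List of [pssm()] objects.
#' @param filter Filter passed to [extract_features()].
#' @return Numeric `length(pssms) x 400` matrix.
#' @export
extract_feature_matrix <- function(pssms, filter = design_fir(0.3 * pi, 7, "hamming")) {
  t(vapply(pssms, extract_features, numeric(400), filter = filter))
}
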