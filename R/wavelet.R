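## Stationary (undecimated) wavelet transform, "algorithme a trous".
## Orthonormal analysis filters are applied without decimation; at level
## j the filters are upsampled by 2^(j-1). With this (toolbox-standard)
## normalization each level of white noise keeps unit coefficient
## variance and the tight-frame identity reads
##   sum_j 2^-j ||d_j||^2 + 2^-J ||a_J||^2 = ||x||^2
## for periodic convolution on a length divisible by 2^J.

## Orthonormal decomposition filter pairs (dec_lo, dec_hi); standard
## published coefficients for the Daubechies and least-asymmetric
## (symlet) families.
swt_filters <- function(wavelet) {
  switch(wavelet,
    "haar" = list(
      lo = c(0.70710678118654757, 0.70710678118654757),
      hi = c(-0.70710678118654757, 0.70710678118654757)),
    "db4" = list(
      lo = c(-0.010597401785069032, 0.032883011666885197,
             0.030841381835560764, -0.18703481171909309,
             -0.027983769416859854, 0.63088076792985892,
             0.71484657055291567, 0.23037781330889651),
      hi = c(-0.23037781330889651, 0.71484657055291567,
             -0.63088076792985892, -0.027983769416859854,
             0.18703481171909309, 0.030841381835560764,
             -0.032883011666885197, -0.010597401785069032)),
    "sym8" = list(
      lo = c(-0.0033824159510061256, -0.00054213233179114812,
             0.031695087811492981, 0.0076074873249176054,
             -0.14329423835080971, -0.061273359067658524,
             0.48135965125837221, 0.77718575170052351,
             0.3644418948353314, -0.051945838107709037,
             -0.027219029917056003, 0.049137179673607506,
             0.0038087520138906151, -0.014952258337048231,
             -0.0003029205147213668, 0.0018899503327594609),
      hi = c(-0.0018899503327594609, -0.0003029205147213668,
             0.014952258337048231, 0.0038087520138906151,
             -0.049137179673607506, -0.027219029917056003,
             0.051945838107709037, 0.3644418948353314,
             -0.77718575170052351, 0.48135965125837221,
             0.061273359067658524, -0.14329423835080971,
             -0.0076074873249176054, 0.031695087811492981,
             0.00054213233179114812, -0.0033824159510061256)),
    stop("unknown wavelet: ", wavelet, call. = FALSE))
}

## circular convolution of x with filter f upsampled by `up`
## y[i] = sum_k f[k+1] * x[(i - k*up) mod n]
circ_conv_up <- function(x, f, up) {
  n <- length(x)
  y <- numeric(n)
  idx <- seq_len(n)
  for (k in seq_along(f)) {
    s <- (k - 1L) * up
    src <- ((idx - 1L - s) %% n) + 1L
    y <- y + f[k] * x[src]
  }
  y
}

## symmetric (reflection) extension of x to length `len`
reflect_pad <- function(x, len) {
  n <- length(x)
  if (len <= n) return(x[seq_len(len)])
  out <- x
  cur <- x
  while (length(out) < len) {
    cur <- rev(cur)
    out <- c(out, cur)
  }
  out[seq_len(len)]
}

#' Stationary wavelet transform of a single series
#'
#' Undecimated dyadic decomposition with periodic convolution. The
#' input is padded to a multiple of `2^levels` by symmetric reflection;
#' padding is trimmed from the returned coefficient series, which
#' therefore all have the input's length. Level j is sensitive to the
#' band `[f_N / 2^j, f_N / 2^(j-1)]` with `f_N = 1/(2 TR)`.
#'
#' @param ts numeric series (length >= `2^levels`).
#' @param levels decomposition depth.
#' @param wavelet `"sym8"` (default), `"db4"`, or `"haar"`.
#' @return list of class `rsnec_swt`: `details` (list of length
#'   `levels`), `approx` (list, cumulative approximations), `levels`,
#'   `wavelet`, `n`, `pad_n` (internal padded length), and for the
#'   padded series `energy_input` / `energy_decomp` (the weighted
#'   tight-frame sums, equal to numerical precision).
#' @export
swt_decompose <- function(ts, levels, wavelet = "sym8") {
  ts <- as.numeric(ts)
  n <- length(ts)
  stopifnot(levels >= 1)
  if (n < 2^levels)
    stop(sprintf("series length %d < 2^%d", n, levels), call. = FALSE)
  flt <- swt_filters(wavelet)
  pad_n <- as.integer(ceiling(n / 2^levels) * 2^levels)
  x <- reflect_pad(ts, pad_n)
  details <- vector("list", levels)
  approx <- vector("list", levels)
  a <- x
  e_dec <- 0
  for (j in seq_len(levels)) {
    up <- 2L^(j - 1L)
    d <- circ_conv_up(a, flt$hi, up)
    a <- circ_conv_up(a, flt$lo, up)
    details[[j]] <- d[seq_len(n)]
    approx[[j]] <- a[seq_len(n)]
    e_dec <- e_dec + sum(d^2) / 2^j
  }
  e_dec <- e_dec + sum(a^2) / 2^levels
  f_n_unit <- 0.5  # in cycles/sample; caller rescales by 1/TR
  bands <- data.frame(level = seq_len(levels),
                      f_lo = f_n_unit / 2^seq_len(levels),
                      f_hi = f_n_unit / 2^(seq_len(levels) - 1))
  structure(list(details = details, approx = approx, levels = levels,
                 wavelet = wavelet, n = n, pad_n = pad_n,
                 bands_per_sample = bands,
                 energy_input = sum(x^2), energy_decomp = e_dec),
            class = "rsnec_swt")
}

#' Motion-contaminated coefficient indices per wavelet level
#'
#' The binary flag series is decomposed with the same stationary
#' transform as the signal; an index is contaminated at level j if the
#' magnitude of either the detail or the (cumulative) approximation
#' coefficient at that position exceeds `tol` — i.e. the flagged frames'
#' influence has propagated there through the filter cascade.
#'
#' @param flags binary (0/1) series.
#' @param levels decomposition depth.
#' @param wavelet filter name.
#' @param tol magnitude tolerance (default 1e-10).
#' @return list of length `levels`; element j is the sorted integer
#'   vector of contaminated (1-based) indices at level j.
#' @export
contaminate_indices <- function(flags, levels, wavelet = "sym8",
                                tol = 1e-10) {
  flags <- as.numeric(flags != 0)
  if (!any(flags > 0)) return(rep(list(integer(0)), levels))
  if (all(flags > 0)) return(rep(list(seq_along(flags)), levels))
  dec <- swt_decompose(flags, levels = levels, wavelet = wavelet)
  lapply(seq_len(levels), function(j)
    which(abs(dec$details[[j]]) > tol | abs(dec$approx[[j]]) > tol))
}
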