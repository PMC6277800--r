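## Lagged-pattern sample entropy on stationary-wavelet detail
## coefficients, with BayesShrink-informed tolerance and motion-aware
## pattern exclusion.

#' Robust noise level from the finest-scale detail coefficients
#'
#' Standard median-absolute-deviation estimator,
#' `sigma = median(|d|) / 0.6745`.
#'
#' @param finest_details numeric vector of level-1 detail coefficients.
#' @return Estimated noise standard deviation (>= 0).
#' @export
estimate_noise_sigma <- function(finest_details) {
  if (!length(finest_details)) stop("empty coefficient series", call. = FALSE)
  median(abs(finest_details)) / 0.6745
}

#' BayesShrink threshold for one wavelet level
#'
#' `t = sigma_noise^2 / sigma_signal` with
#' `sigma_signal = sqrt(max(var(d) - sigma_noise^2, 0))`; when the level
#' is all noise (`sigma_signal = 0`) the threshold saturates at
#' `max(|d|)`.
#'
#' @param level_coeffs detail coefficients of the level.
#' @param sigma_noise noise sd (from [estimate_noise_sigma()]).
#' @return Threshold t >= 0.
#' @export
bayes_shrink_threshold <- function(level_coeffs, sigma_noise) {
  stopifnot(sigma_noise >= 0)
  if (sigma_noise == 0) return(0)
  v <- mean(level_coeffs^2) - mean(level_coeffs)^2  # population variance
  s2 <- max(v - sigma_noise^2, 0)
  if (s2 > 0) sigma_noise^2 / sqrt(s2) else max(abs(level_coeffs))
}

#' Build the admissible lagged pattern set
#'
#' Pattern `p_i = (x[i], x[i+delta], ..., x[i+(m-1)delta])` (1-based
#' start indices) for every i whose indices all lie in range; a pattern
#' is inadmissible if any of its indices is contaminated.
#'
#' @param coeffs coefficient series.
#' @param m pattern length (>= 1).
#' @param delta lag in samples (>= 1).
#' @param contaminated integer vector of contaminated (1-based) indices.
#' @return list: `patterns` (N_m x m matrix), `starts`, `n` (= N_m).
#' @export
build_patterns <- function(coeffs, m, delta, contaminated = integer(0)) {
  stopifnot(m >= 1, delta >= 1)
  n <- length(coeffs)
  last_start <- n - (m - 1L) * delta
  if (last_start < 1L)
    return(list(patterns = matrix(numeric(0), 0, m), starts = integer(0),
                n = 0L))
  starts <- seq_len(last_start)
  if (length(contaminated)) {
    bad <- rep(FALSE, n)
    bad[contaminated] <- TRUE
    hit <- rep(FALSE, last_start)
    for (j in 0:(m - 1L)) hit <- hit | bad[starts + j * delta]
    starts <- starts[!hit]
  }
  pat <- matrix(NA_real_, length(starts), m)
  for (j in 0:(m - 1L)) pat[, j + 1L] <- coeffs[starts + j * delta]
  list(patterns = pat, starts = starts, n = length(starts))
}

## ordered pairs (p != q) at Chebyshev distance strictly below r,
## row-chunked to bound memory; exact floating-point comparisons so the
## result equals a naive double loop bit-for-bit.
count_matches <- function(pat, r, chunk = 256L) {
  n <- nrow(pat)
  if (n < 2 || r <= 0) return(0)
  m <- ncol(pat)
  total <- 0
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    ok <- abs(outer(pat[lo:hi, 1L], pat[, 1L], "-")) < r
    if (m > 1L) for (j in 2:m)
      ok <- ok & (abs(outer(pat[lo:hi, j], pat[, j], "-")) < r)
    total <- total + sum(ok)
  }
  total - n   # remove self-pairs (distance 0 < r)
}

#' Sample entropy from two admissible pattern sets
#'
#' `Cm` is the fraction of ordered pattern pairs (p != q) whose
#' Chebyshev distance is strictly below r at length m; `Cm1` the same at
#' length m+1; `H = -ln(Cm1 / Cm)`. The match predicate resolves the
#' boundary (distance exactly r) as a non-match. Fewer than
#' `min_patterns` admissible patterns at either length, or a zero match
#' count, makes H undefined (`NA` with a reason), never a numeric
#' sentinel.
#'
#' @param patterns_m output of [build_patterns()] at length m.
#' @param patterns_m1 output of [build_patterns()] at length m+1.
#' @param r tolerance distance (> 0 for a defined estimate).
#' @param min_patterns reliability floor on both pattern counts
#'   (default 50).
#' @return list: `H`, `Cm`, `Cm1`, `n_m`, `n_m1`, `status`
#'   ("ok", "too_few_patterns", "no_matches", "zero_tolerance").
#' @export
sample_entropy <- function(patterns_m, patterns_m1, r, min_patterns = 50L) {
  n_m <- patterns_m$n; n_m1 <- patterns_m1$n
  out <- list(H = NA_real_, Cm = NA_real_, Cm1 = NA_real_,
              n_m = n_m, n_m1 = n_m1, status = "ok")
  if (n_m < min_patterns || n_m1 < min_patterns) {
    out$status <- "too_few_patterns"; return(out)
  }
  if (!is.finite(r) || r <= 0) { out$status <- "zero_tolerance"; return(out) }
  cm <- count_matches(patterns_m$patterns, r) / (n_m * (n_m - 1))
  cm1 <- count_matches(patterns_m1$patterns, r) / (n_m1 * (n_m1 - 1))
  out$Cm <- cm; out$Cm1 <- cm1
  if (cm == 0 || cm1 == 0) { out$status <- "no_matches"; return(out) }
  out$H <- -log(cm1 / cm)
  out
}

#' Default pattern lag per wavelet level
#'
#' `2^j` at levels 1-2, `round(0.75 * 2^j)` deeper (6 at level 3, 12 at
#' level 4, ...). See [roi_entropy()] for the rationale.
#'
#' @param j level index (>= 1).
#' @return Integer lag in samples.
#' @export
default_lag <- function(j) {
  as.integer(ifelse(j <= 2, 2^j, round(0.75 * 2^j)))
}

#' Select wavelet levels covering a frequency band
#'
#' Level j of a dyadic decomposition at Nyquist `f_N = 1/(2 TR)` covers
#' `[f_N / 2^j, f_N / 2^(j-1)]`. Levels whose band overlaps
#' `[f_lo, f_hi]` by at least half the level band's width qualify; the
#' `n_scales` qualifying levels with the largest absolute overlap are
#' kept (the analysis averages entropy over two scales by default). At
#' TR = 2 s and band 0.01-0.10 Hz this selects levels 2
#' (0.0625-0.125 Hz) and 3 (0.03125-0.0625 Hz).
#'
#' @param tr_s repetition time, seconds.
#' @param band numeric length-2, Hz (default `c(0.01, 0.10)`).
#' @param n_scales number of levels to keep (default 2).
#' @param max_level deepest level considered (default 8).
#' @return data.frame `level`, `f_lo`, `f_hi`, ordered by level.
#' @export
select_scales <- function(tr_s, band = c(0.01, 0.10), n_scales = 2L,
                          max_level = 8L) {
  stopifnot(tr_s > 0, length(band) == 2, band[1] < band[2])
  f_n <- 1 / (2 * tr_s)
  lev <- seq_len(max_level)
  hi <- f_n / 2^(lev - 1)
  lo <- f_n / 2^lev
  ov <- pmax(0, pmin(hi, band[2]) - pmax(lo, band[1]))
  qual <- which(ov >= 0.5 * (hi - lo))
  if (!length(qual))
    stop("no dyadic level overlaps the requested band", call. = FALSE)
  keep <- qual[order(-ov[qual], lev[qual])][seq_len(min(n_scales,
                                                        length(qual)))]
  keep <- sort(keep)
  data.frame(level = keep, f_lo = lo[keep], f_hi = hi[keep])
}

#' Wavelet-scale sample entropy of one ROI series
#'
#' For each selected level: detail coefficients from the stationary
#' wavelet transform, tolerance `r = r0 * sigma + t` (sigma the level's
#' coefficient sd, t the BayesShrink threshold fed by the finest-level
#' noise estimate), lag `delta_j = 2^j`, patterns of length m and m+1
#' with motion-contaminated patterns removed, then sample entropy. The
#' ROI's H is the mean over levels with a defined estimate.
#'
#' @param ts single-ROI numeric series.
#' @param tr_s repetition time, seconds.
#' @param flags optional binary motion flags (length of `ts`).
#' @param r0 tolerance scaling (default 0.2).
#' @param m template length (default 1).
#' @param band analysis band in Hz (default `c(0.01, 0.10)`).
#' @param wavelet filter name (default `"sym8"`).
#' @param min_patterns reliability floor (default 50).
#' @param contamination how motion flags invalidate patterns:
#'   `"frames"` (default) removes a pattern when any of its own lagged
#'   indices falls on a flagged frame; `"swt"` additionally masks every
#'   coefficient index the flags reach through the wavelet filter
#'   cascade ([contaminate_indices()]) — conservative, but with wide
#'   filters (sym8) a single flagged frame contaminates ~100 indices at
#'   level 3, which empties realistic series.
#' @param delta_fun lag per level. The default, [default_lag()], is the
#'   dyadic lag `2^j` for levels 1-2 and `0.75 * 2^j` (rounded) for
#'   deeper levels: at the full dyadic lag the coefficients of deep
#'   levels are essentially decorrelated even for strongly
#'   autocorrelated inputs, which leaves the conditional match
#'   probability insensitive to signal regularity; pulling the lag back
#'   by a quarter keeps it inside the coefficients' serial-dependence
#'   range.
#' @return list: `H` (mean over defined levels, `NA` if none),
#'   `levels` data.frame (level, sigma, t, r, n_m, n_m1, H, status).
#' @export
roi_entropy <- function(ts, tr_s, flags = NULL, r0 = 0.2, m = 1L,
                        band = c(0.01, 0.10), wavelet = "sym8",
                        min_patterns = 50L,
                        contamination = c("frames", "swt"),
                        delta_fun = default_lag) {
  contamination <- match.arg(contamination)
  sc <- select_scales(tr_s, band)
  levels_needed <- max(sc$level)
  dec <- swt_decompose(ts, levels = levels_needed, wavelet = wavelet)
  sigma_noise <- estimate_noise_sigma(dec$details[[1L]])
  contam <- if (!is.null(flags) && any(flags != 0)) {
    if (contamination == "swt")
      contaminate_indices(flags, levels = levels_needed, wavelet = wavelet)
    else rep(list(which(flags != 0)), levels_needed)
  } else NULL
  rows <- list(); hs <- numeric(0)
  for (i in seq_len(nrow(sc))) {
    j <- sc$level[i]
    d <- dec$details[[j]]
    sigma <- sd(d)
    if (!is.finite(sigma) || sigma == 0) {
      rows[[i]] <- data.frame(level = j, sigma = sigma, t = NA_real_,
                              r = NA_real_, n_m = 0L, n_m1 = 0L,
                              H = NA_real_, status = "degenerate")
      next
    }
    t_j <- bayes_shrink_threshold(d, sigma_noise)
    r <- r0 * sigma + t_j
    delta <- as.integer(delta_fun(j))
    bad <- if (is.null(contam)) integer(0) else contam[[j]]
    pm <- build_patterns(d, m, delta, bad)
    pm1 <- build_patterns(d, m + 1L, delta, bad)
    se <- sample_entropy(pm, pm1, r, min_patterns = min_patterns)
    rows[[i]] <- data.frame(level = j, sigma = sigma, t = t_j, r = r,
                            n_m = se$n_m, n_m1 = se$n_m1, H = se$H,
                            status = se$status)
    if (!is.na(se$H)) hs <- c(hs, se$H)
  }
  list(H = if (length(hs)) mean(hs) else NA_real_,
       levels = do.call(rbind, rows))
}

#' Network-level entropy profile for one subject
#'
#' ROI entropies averaged (unweighted) within each network; ROIs with an
#' undefined H are dropped, and a network with no defined ROI is
#' reported missing.
#'
#' @param ts T x R matrix for one subject.
#' @param map a [network_map()].
#' @param tr_s repetition time, seconds.
#' @param flags optional binary motion flags.
#' @param ... forwarded to [roi_entropy()].
#' @return list: `network` (named vector over networks, may contain
#'   `NA`), `roi` (numeric per-ROI H).
#' @export
rsn_entropy <- function(ts, map, tr_s, flags = NULL, ...) {
  stopifnot(ncol(ts) == nrow(map))
  roi_h <- vapply(seq_len(ncol(ts)), function(i)
    roi_entropy(ts[, i], tr_s, flags = flags, ...)$H, numeric(1))
  nets <- map_networks(map)
  g <- factor(map$network_label, levels = nets)
  net_h <- vapply(split(roi_h, g), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  list(network = net_h, roi = roi_h)
}

#' Entropy profiles for a whole cohort
#'
#' @param cohort an `rsnec_cohort` with flags derived
#'   ([apply_exclusions()]).
#' @param r0 tolerance scaling, or a vector to compute a grid.
#' @param ... forwarded to [rsn_entropy()].
#' @return if `r0` is scalar, an N x K matrix (subjects x networks);
#'   otherwise a named list of such matrices, one per r0 value.
#' @export
cohort_entropy <- function(cohort, r0 = 0.2, ...) {
  ids <- as.character(cohort$manifest$subject_id)
  tr <- cohort$manifest$tr_s
  one_grid <- function(r0v) {
    prof <- lapply(seq_along(ids), function(i) {
      id <- ids[i]
      ## name map/tr_s exactly: partial matching would otherwise let a
      ## `m` in ... capture the `map` formal
      rsn_entropy(ts = cohort$series[[id]], map = cohort$map,
                  tr_s = tr[i], flags = cohort$motion[[id]]$flag,
                  r0 = r0v, ...)$network
    })
    out <- do.call(rbind, prof)
    rownames(out) <- ids
    out
  }
  if (length(r0) == 1L) return(one_grid(r0))
  res <- lapply(r0, one_grid)
  names(res) <- format(r0, trim = TRUE)
  res
}

#' Choose the tolerance scaling r0 maximizing the entropy range
#'
#' Given network-entropy matrices computed over a grid of r0 values, the
#' candidate with the largest range (max - min over all subjects'
#' network entropies) is selected; ties break toward 0.20 (then toward
#' the smaller r0).
#'
#' @param profiles_by_r0 named list (names = r0 values) of N x K
#'   entropy matrices.
#' @return list: `r0` (numeric), `ranges` (named vector).
#' @export
select_r0 <- function(profiles_by_r0) {
  stopifnot(length(profiles_by_r0) >= 1, !is.null(names(profiles_by_r0)))
  r0s <- as.numeric(names(profiles_by_r0))
  rng <- vapply(profiles_by_r0, function(m) {
    v <- m[is.finite(m)]
    if (!length(v)) return(-Inf)
    max(v) - min(v)
  }, numeric(1))
  best <- which(rng == max(rng))
  if (length(best) > 1L)
    best <- best[order(abs(r0s[best] - 0.2), r0s[best])][1L]
  list(r0 = r0s[best], ranges = setNames(rng, names(profiles_by_r0)))
}
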