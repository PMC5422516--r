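#' Locate the sample and internal-standard peaks in a flow-cytometry stream
#'
#' Peak means are found by kernel-density mode finding on the log
#' fluorescence-area values and refined by a trimmed mean of the events
#' within +/- 2 SD of each mode (trimming resists debris tails).  The
#' internal-standard peak is the mode falling inside `standard_window`;
#' the sample peak is the larger remaining mode.  When per-event cluster
#' labels are supplied the density step is skipped and per-cluster trimmed
#' means are returned directly.
#'
#' @param events data.frame with column `fl_area` (positive fluorescence
#'   area values, FL2-A-like) and optionally `cluster` (labels `"sample"`
#'   and `"standard"`).
#' @param standard_window numeric length-2 channel window containing the
#'   standard peak (ignored when cluster labels are present).
#' @param min_events minimum events attributed to each peak (default 200).
#' @param min_sep_sd required mode separation in units of pooled peak SD
#'   (default 2); closer modes raise an "overlapping" error.
#' @return list with `sample_mean`, `standard_mean`, `sample_cv`,
#'   `standard_cv` (coefficients of variation of the refined peaks).
#' @export
find_peaks <- function(events, standard_window = NULL, min_events = 200L,
                       min_sep_sd = 2) {
  fl <- events$fl_area
  if (is.null(fl)) stop("events must have a column 'fl_area'")
  if (any(!is.finite(fl)) || any(fl <= 0))
    stop("fluorescence values must be positive and finite")

  peak_stats <- function(v) {
    mu <- mean(v); sdv <- stats::sd(v)
    keep <- abs(v - mu) <= 2 * sdv
    m <- mean(v[keep])
    list(mean = m, cv = stats::sd(v[keep]) / m, n = sum(keep))
  }

  if (!is.null(events$cluster)) {
    cl <- split(fl, events$cluster)
    if (!all(c("sample", "standard") %in% names(cl)))
      stop("cluster labels must include 'sample' and 'standard'")
    s <- peak_stats(cl$sample); st <- peak_stats(cl$standard)
    return(list(sample_mean = s$mean, standard_mean = st$mean,
                sample_cv = s$cv, standard_cv = st$cv))
  }

  dens <- stats::density(log(fl), n = 1024L)
  y <- dens$y
  ismax <- which(diff(sign(diff(y))) == -2) + 1L
  # retain modes carrying real mass (>= 5% of the maximum density)
  ismax <- ismax[y[ismax] >= 0.05 * max(y)]
  if (length(ismax) < 2L)
    stop("peaks unresolved: fewer than two density modes found")
  ismax <- ismax[order(y[ismax], decreasing = TRUE)][1:2]
  modes <- sort(exp(dens$x[ismax]))
  # assign events to the nearest mode (log scale) and refine
  assign <- abs(log(fl) - log(modes[1L])) <= abs(log(fl) - log(modes[2L]))
  g1 <- fl[assign]; g2 <- fl[!assign]
  p1 <- peak_stats(g1); p2 <- peak_stats(g2)
  if (p1$n < min_events || p2$n < min_events)
    stop(sprintf("peak with fewer than %d events", min_events))
  pooled_sd <- sqrt((p1$cv * p1$mean)^2 + (p2$cv * p2$mean)^2) / sqrt(2)
  if ((p2$mean - p1$mean) < min_sep_sd * pooled_sd)
    stop("overlapping modes: peak separation below threshold")

  if (is.null(standard_window))
    stop("supply 'standard_window' (or cluster labels) to identify the internal standard")
  in_win <- c(p1$mean, p2$mean) >= standard_window[1L] &
    c(p1$mean, p2$mean) <= standard_window[2L]
  if (sum(in_win) != 1L)
    stop("standard peak not uniquely identified by the channel window")
  st <- list(p1, p2)[[which(in_win)]]
  sm <- list(p1, p2)[[which(!in_win)]]
  list(sample_mean = sm$mean, standard_mean = st$mean,
       sample_cv = sm$cv, standard_cv = st$cv)
}

#' Estimate 2C DNA content against the internal standard
#'
#' `sample_2c = sample_mean / standard_mean * standard_2c`.  The default
#' standard is chicken erythrocyte nuclei at 2.5 pg/2C.
#'
#' @param sample_mean,standard_mean positive peak means (same fluorescence
#'   units).
#' @param standard_2c DNA content of the internal standard, pg per 2C
#'   (default 2.5).
#' @return 2C DNA content of the sample in pg.
#' @export
estimate_2c <- function(sample_mean, standard_mean, standard_2c = 2.5) {
  if (!is.finite(sample_mean) || !is.finite(standard_mean) ||
      sample_mean <= 0 || standard_mean <= 0 || standard_2c <= 0)
    stop("peak means and standard 2C must be positive")
  sample_mean / standard_mean * standard_2c
}

#' Infer integer ploidy relative to a reference taxon
#'
#' Ploidy is called as the nearest integer to
#' `reference_ploidy * sample_2c / reference_2c`.  The inference is
#' explicitly relative: a reference 2C value with known ploidy (e.g. a
#' chromosome-counted diploid) anchors the scale.  Calls whose
#' pre-rounding value deviates from the nearest integer by more than 0.25
#' are flagged low-confidence.
#'
#' @param sample_2c sample 2C content, pg.
#' @param reference_2c reference-taxon 2C content, pg.
#' @param reference_ploidy integer ploidy of the reference (2, 3, 4, 6 or 8).
#' @return list of class `ploidy_call`: `sample_2c`, `ploidy`, `raw_ratio`,
#'   `low_confidence`.
#' @export
infer_ploidy <- function(sample_2c, reference_2c, reference_ploidy = 2L) {
  if (!reference_ploidy %in% c(2L, 3L, 4L, 6L, 8L))
    stop("reference_ploidy must be one of 2, 3, 4, 6, 8")
  if (sample_2c <= 0 || reference_2c <= 0)
    stop("2C values must be positive")
  raw <- reference_ploidy * sample_2c / reference_2c
  p <- max(1L, as.integer(round(raw)))
  structure(list(sample_2c = sample_2c, ploidy = p, raw_ratio = raw,
                 low_confidence = abs(raw - round(raw)) > 0.25),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("<ploidy_call> 2C = %.3f pg, ploidy = %d%s (ratio %.2f)\n",
              x$sample_2c, x$ploidy,
              if (x$low_confidence) " [low confidence]" else "", x$raw_ratio))
  invisible(x)
}

#' Full ploidy call from a raw event stream
#'
#' Convenience wrapper: [find_peaks()] then [estimate_2c()] then
#' [infer_ploidy()].
#'
#' @inheritParams find_peaks
#' @inheritParams estimate_2c
#' @inheritParams infer_ploidy
#' @return a `ploidy_call` with additional fields `cv` (sample-peak CV) and
#'   `standard_cv`.
#' @export
call_ploidy <- function(events, standard_window = NULL, standard_2c = 2.5,
                        reference_2c, reference_ploidy = 2L,
                        min_events = 200L) {
  pk <- find_peaks(events, standard_window, min_events = min_events)
  c2 <- estimate_2c(pk$sample_mean, pk$standard_mean, standard_2c)
  out <- infer_ploidy(c2, reference_2c, reference_ploidy)
  out$cv <- pk$sample_cv
  out$standard_cv <- pk$standard_cv
  out
}
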