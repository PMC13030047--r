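# An RRI series is a data.frame(beat_time [s], rri_ms, status) where status is
# one of "clean", "ectopic", "hampel", "quotient", "interpolated". The three
# artifact filters only ever escalate "clean" beats; interpolation replaces
# masked values and relabels them "interpolated".

as_rri_series <- function(series) {
  stopifnot(all(c("beat_time", "rri_ms") %in% names(series)))
  if (is.null(series$status)) series$status <- "clean"
  stopifnot(all(series$rri_ms > 0), !is.unsorted(series$beat_time, strictly = TRUE))
  series
}

# MAD -> Gaussian sigma scale, 1 / qnorm(3/4); quoted to 4 decimals in the
# robust-statistics literature as 1.4826.
HAMPEL_MAD_SCALE <- 1.4826

# Exact row-wise medians of a numeric matrix via an odd-even transposition
# sorting network: O(ncol^2) vectorized compare-exchanges, fast for the
# narrow window matrices used by the Hampel filter.
row_median <- function(m) {
  k <- ncol(m)
  cols <- lapply(seq_len(k), function(j) m[, j])
  for (pass in seq_len(k)) {
    start <- if (pass %% 2L == 1L) 1L else 2L
    j <- start
    while (j + 1L <= k) {
      a <- cols[[j]]
      b <- cols[[j + 1L]]
      cols[[j]] <- pmin(a, b)
      cols[[j + 1L]] <- pmax(a, b)
      j <- j + 2L
    }
  }
  if (k %% 2L == 1L) cols[[(k + 1L) %/% 2L]]
  else (cols[[k %/% 2L]] + cols[[k %/% 2L + 1L]]) / 2
}

#' Mask physiologically implausible RR intervals
#'
#' RR intervals shorter than `low` or longer than `high` milliseconds are
#' treated as ectopic beats and masked; the bounds themselves survive.
#'
#' @param series RRI data frame (`beat_time` s, `rri_ms`, optional `status`).
#' @param low,high Plausibility bounds in ms (defaults 300 and 1300).
#' @return The series with `status` set to `"ectopic"` on offending beats.
#' @export
remove_ectopic <- function(series, low = 300, high = 1300) {
  series <- as_rri_series(series)
  bad <- series$status == "clean" & (series$rri_ms < low | series$rri_ms > high)
  series$status[bad] <- "ectopic"
  series
}

#' Hampel outlier filter for RR intervals
#'
#' Within a sliding window of `window` unmasked beats, the local spread is
#' estimated robustly as sigma = 1.4826 x MAD about the window median; beats
#' deviating from the window median by more than `k` sigma are masked.
#' Already-masked (ectopic) beats are excluded from all window statistics.
#' A threshold floor (`mad_floor`, ms) guards the MAD = 0 degenerate case so
#' that constant stretches flag nothing. Beats whose usable window holds
#' fewer than 3 beats are left unjudged.
#'
#' @param series RRI data frame, ectopic-masked first.
#' @param window Window length in beats (odd; default 21, wide enough that
#'   the window MAD is a stable scale estimate).
#' @param k Deviation threshold in robust standard deviations (default 3).
#' @param mad_floor Minimum deviation threshold in ms (default 5).
#' @return The series with `status` set to `"hampel"` on flagged beats.
#' @export
hampel_filter <- function(series, window = 21, k = 3, mad_floor = 5) {
  series <- as_rri_series(series)
  usable <- which(series$status == "clean")
  n <- length(usable)
  if (n < 3) return(series)
  x <- series$rri_ms[usable]
  half <- window %/% 2
  flag <- logical(n)
  scale_k <- k * HAMPEL_MAD_SCALE
  interior <- n >= window
  if (interior) {
    # full windows, vectorized across beats: embed() gives one row per
    # window; row medians via a sorting network (exact order statistics)
    W <- embed(x, window) # row j = window centred on beat j + half
    ctr <- row_median(W)
    dev <- abs(W - ctr)
    thr <- pmax(scale_k * row_median(dev), mad_floor)
    centre_idx <- (half + 1):(n - half)
    flag[centre_idx] <- abs(x[centre_idx] - ctr) > thr
  }
  edge_idx <- if (interior) c(seq_len(half), (n - half + 1):n) else seq_len(n)
  for (i in edge_idx) {
    w <- x[max(1, i - half):min(n, i + half)]
    if (length(w) < 3) next
    ctr_i <- median(w)
    thr_i <- max(scale_k * median(abs(w - ctr_i)), mad_floor)
    flag[i] <- abs(x[i] - ctr_i) > thr_i
  }
  series$status[usable[flag]] <- "hampel"
  series
}

#' Quotient filter for abrupt RR-interval changes
#'
#' A beat changing by more than `frac` relative to the mean of its immediately
#' preceding and following unmasked beats is masked. Endpoints and beats with
#' a masked neighbour are left untested.
#'
#' @param series RRI data frame, ectopic- and Hampel-masked first.
#' @param frac Relative-change threshold (default 0.10).
#' @return The series with `status` set to `"quotient"` on flagged beats.
#' @export
quotient_filter <- function(series, frac = 0.10) {
  series <- as_rri_series(series)
  n <- nrow(series)
  if (n < 3) return(series)
  cl <- series$status == "clean"
  i <- 2:(n - 1)
  testable <- cl[i] & cl[i - 1] & cl[i + 1]
  m <- (series$rri_ms[i - 1] + series$rri_ms[i + 1]) / 2
  bad <- testable & abs(series$rri_ms[i] - m) / m > frac
  series$status[i][bad] <- "quotient"
  series
}

#' Interpolate masked RR intervals and summarise the cleaning chain
#'
#' Masked intervals are replaced by a cubic spline fitted over beat index on
#' the unmasked beats and evaluated at the masked positions; beat timestamps
#' are retained so temporal continuity is preserved. The report carries the
#' removal fraction per filter stage and the total; a participant whose total
#' exceeds `exclusion_frac` is flagged for exclusion. Fractions are computed
#' over `period` (`c(start, end)` seconds, e.g. the riding period) when given,
#' otherwise over the whole series.
#'
#' @param series RRI data frame with finalized masks
#'   (ectopic -> Hampel -> quotient).
#' @param period Optional time window for the removal fractions.
#' @param exclusion_frac Exclusion threshold on the total removal fraction
#'   (default 0.05).
#' @return List with elements `series` (masked values replaced, status
#'   `"interpolated"`) and `report` (per-stage fractions, `total_removed`,
#'   `participant_excluded`, `unreliable_spans`).
#' @export
interpolate_rri <- function(series, period = NULL, exclusion_frac = 0.05) {
  series <- as_rri_series(series)
  masked <- series$status %in% c("ectopic", "hampel", "quotient")
  in_period <- if (is.null(period)) rep(TRUE, nrow(series)) else {
    series$beat_time >= period[1] & series$beat_time < period[2]
  }
  denom <- sum(in_period)
  fractions <- c(
    ectopic  = sum(series$status == "ectopic" & in_period),
    hampel   = sum(series$status == "hampel" & in_period),
    quotient = sum(series$status == "quotient" & in_period)
  ) / max(denom, 1)
  total <- sum(fractions)

  # flag 60-s spans where cleaning removed too much to trust interpolation
  unreliable <- numeric(0)
  if (any(masked)) {
    span_id <- floor(series$beat_time / 60)
    frac_by_span <- tapply(masked, span_id, mean)
    unreliable <- as.numeric(names(frac_by_span))[frac_by_span > 0.20] * 60
    if (length(unreliable)) {
      warning(length(unreliable), " 60-s span(s) with >20% masked beats flagged unreliable")
    }
  }

  if (any(masked)) {
    idx <- seq_len(nrow(series))
    good <- !masked
    if (sum(good) < 4) stop("too few unmasked beats to spline-interpolate")
    interp <- spline(idx[good], series$rri_ms[good], xout = idx[masked],
                     method = "fmm")$y
    # clamp to the observed physiological range: the cubic can overshoot
    # badly when extrapolating past masked runs at the series edges
    interp <- pmin(pmax(interp, min(series$rri_ms[good])),
                   max(series$rri_ms[good]))
    series$rri_ms[masked] <- interp
    series$status[masked] <- "interpolated"
  }

  list(
    series = series,
    report = list(
      fractions = fractions,
      total_removed = total,
      participant_excluded = total > exclusion_frac,
      unreliable_spans = unreliable
    )
  )
}

#' Run the full RRI artifact-cleaning chain
#'
#' Applies, in order: ectopic-bound masking, Hampel filtering, quotient
#' filtering, and cubic-spline interpolation of the masked beats.
#'
#' @inheritParams remove_ectopic
#' @inheritParams hampel_filter
#' @inheritParams quotient_filter
#' @inheritParams interpolate_rri
#' @return As [interpolate_rri()]: list of `series` and `report`.
#' @export
clean_rri <- function(series, low = 300, high = 1300, window = 21, k = 3,
                      mad_floor = 5, frac = 0.10, period = NULL,
                      exclusion_frac = 0.05) {
  series <- remove_ectopic(series, low = low, high = high)
  series <- hampel_filter(series, window = window, k = k, mad_floor = mad_floor)
  series <- quotient_filter(series, frac = frac)
  interpolate_rri(series, period = period, exclusion_frac = exclusion_frac)
}

#' Time-domain HRV indices for one segment
#'
#' SDNN is the sample standard deviation (N - 1 denominator) of the RR
#' intervals in the window; RMSSD the root mean square of successive
#' differences; pNN50 the percentage of successive differences exceeding
#' 50 ms (N - 1 successive-difference pairs in the denominator). Beats are
#' selected by `beat_time` in the half-open window `[entry_time, exit_time)`.
#'
#' @param series Cleaned RRI data frame.
#' @param segment One-row data frame with `id`, `entry_time`, `exit_time`, or
#'   NULL to use the whole series.
#' @param participant Participant identifier carried into the record.
#' @return One-row data frame (`participant`, `segment_id`, `n_beats`,
#'   `mean_rr`, `sdnn`, `rmssd`, `pnn50`), or NULL when fewer than 2 beats
#'   fall in the window.
#' @examples
#' s <- data.frame(beat_time = c(0, 0.8, 1.8), rri_ms = c(800, 800, 1000))
#' compute_indices(s)
#' @export
compute_indices <- function(series, segment = NULL, participant = NA) {
  series <- as_rri_series(series)
  rr <- series$rri_ms
  seg_id <- NA_integer_
  if (!is.null(segment)) {
    rr <- rr[series$beat_time >= segment$entry_time &
               series$beat_time < segment$exit_time]
    seg_id <- segment$id
  }
  n <- length(rr)
  if (n < 2) return(NULL)
  d <- diff(rr)
  data.frame(
    participant = participant,
    segment_id = seg_id,
    n_beats = n,
    mean_rr = mean(rr),
    sdnn = sd(rr),
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * sum(abs(d) > 50) / (n - 1)
  )
}

#' Per-segment HRV table for one participant
#'
#' @param series Cleaned RRI data frame.
#' @param segments Segment table from [build_segments()].
#' @param participant Participant identifier.
#' @return Data frame of [compute_indices()] rows (segments with fewer than 2
#'   beats are omitted).
#' @export
compute_hrv_table <- function(series, segments, participant = 1) {
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    compute_indices(series, segments[i, ], participant)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(participant = participant[0], segment_id = integer(),
                      n_beats = integer(), mean_rr = numeric(),
                      sdnn = numeric(), rmssd = numeric(), pnn50 = numeric())
  }
  out
}

#' Z-score HRV indices within participant
#'
#' Standardizes each HRV metric to mean 0 and unit sample standard deviation
#' across each participant's segments, removing inter-individual baseline
#' differences so values are comparable across participants. Zero-variance
#' metrics yield z = 0 with a warning.
#'
#' @param records Data frame of HRV records with a `participant` column and
#'   metric columns `sdnn`, `rmssd`, `pnn50`.
#' @return `records` with added columns `z_sdnn`, `z_rmssd`, `z_pnn50`.
#' @export
zscore_indices <- function(records) {
  stopifnot(all(c("participant", "sdnn", "rmssd", "pnn50") %in% names(records)))
  for (metric in c("sdnn", "rmssd", "pnn50")) {
    zcol <- paste0("z_", metric)
    records[[zcol]] <- NA_real_
    for (p in unique(records$participant)) {
      sel <- records$participant == p
      if (sum(sel) < 2) {
        stop("participant ", p, " has fewer than 2 segments; cannot z-score")
      }
      v <- records[[metric]][sel]
      s <- sd(v)
      if (s == 0) {
        warning("zero variance in ", metric, " for participant ", p,
                "; z set to 0")
        records[[zcol]][sel] <- 0
      } else {
        records[[zcol]][sel] <- (v - mean(v)) / s
      }
    }
  }
  records
}
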