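# Stress-factor quantification, 3-level classification, and the Composite
# Stress Score (CSS). Factors carry a direction: +1 when larger values mean
# more stress (vibration RMS, encounter counts), -1 when smaller values do
# (sidewalk width).

FACTOR_DIRECTIONS <- c(vibration_rms = 1, encounter_count = 1, sidewalk_width = -1)

#' Aggregate one stress factor over a segment
#'
#' Representative per-segment values: mean of the 1 s vertical-RMS values
#' whose window start falls in `[entry, exit)` for `vibration_rms`; number of
#' unique persons first seen in the window for `encounter_count`; minimum
#' mapped width over the segment's chainage span for `sidewalk_width`.
#'
#' @param segment One-row segment data frame (see [build_segments()]).
#' @param stream For `vibration_rms` a data frame `timestamp`/`rms`; for
#'   `encounter_count` a data frame `time`/`person_id`; for `sidewalk_width`
#'   a data frame `chainage_start_m`/`chainage_end_m`/`width_m`.
#' @param factor One of `"vibration_rms"`, `"encounter_count"`,
#'   `"sidewalk_width"`.
#' @return One-row data frame (`segment_id`, `factor`, `value`, `direction`),
#'   or NULL when the window holds no data.
#' @export
aggregate_factor <- function(segment, stream, factor) {
  factor <- match.arg(factor, names(FACTOR_DIRECTIONS))
  value <- switch(factor,
    vibration_rms = {
      sel <- stream$timestamp >= segment$entry_time &
        stream$timestamp < segment$exit_time & !is.na(stream$rms)
      if (!any(sel)) NA_real_ else mean(stream$rms[sel])
    },
    encounter_count = as.numeric(count_encounters(stream, segment)),
    sidewalk_width = {
      sel <- stream$chainage_end_m > segment$start_chainage &
        stream$chainage_start_m < segment$end_chainage
      if (!any(sel)) NA_real_ else min(stream$width_m[sel])
    }
  )
  if (is.na(value)) return(NULL)
  data.frame(segment_id = segment$id, factor = factor, value = value,
             direction = unname(FACTOR_DIRECTIONS[factor]))
}

#' Aggregate all stress factors across segments
#'
#' @param segments Segment table from [build_segments()].
#' @param rms Per-second vertical RMS series (see [vertical_rms()]).
#' @param encounters Encounter stream (`time`, `person_id`).
#' @param widths Sidewalk-width map
#'   (`chainage_start_m`, `chainage_end_m`, `width_m`).
#' @param factors Subset of factor names to include.
#' @return Tidy data frame of factor measures.
#' @export
aggregate_factors <- function(segments, rms = NULL, encounters = NULL,
                              widths = NULL,
                              factors = names(FACTOR_DIRECTIONS)) {
  streams <- list(vibration_rms = rms, encounter_count = encounters,
                  sidewalk_width = widths)
  rows <- list()
  for (f in factors) {
    if (is.null(streams[[f]])) stop("no stream supplied for factor ", f)
    for (i in seq_len(nrow(segments))) {
      rows[[length(rows) + 1]] <- aggregate_factor(segments[i, ], streams[[f]], f)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify factor values into tertile stress levels
#'
#' Stress-oriented values (`value * direction`) are split at their 1/3 and
#' 2/3 quantiles (linear-interpolation quantiles): level 1 is the lowest
#' third of stress, level 3 the highest. Values exactly at a threshold take
#' the lower level. When all values are identical, every segment gets level 1
#' with a warning.
#'
#' @param values Numeric factor values across segments.
#' @param direction +1 (larger = more stress) or -1.
#' @return Integer levels in 1:3.
#' @export
classify_tertiles <- function(values, direction = 1) {
  stopifnot(direction %in% c(-1, 1), length(values) >= 3, !anyNA(values))
  sv <- values * direction
  if (length(unique(sv)) == 1) {
    warning("all factor values identical; every segment assigned level 1")
    return(rep(1L, length(sv)))
  }
  q <- quantile(sv, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  ifelse(sv <= q[1], 1L, ifelse(sv <= q[2], 2L, 3L))
}

#' Classify factor values against fixed thresholds
#'
#' For factors with established evaluation criteria: stress-oriented value
#' <= t1 gives level 1, in (t1, t2] level 2, above t2 level 3.
#'
#' @param values Numeric factor values.
#' @param thresholds Numeric `c(t1, t2)` on the stress-oriented scale,
#'   t1 < t2.
#' @param direction +1 or -1.
#' @return Integer levels in 1:3.
#' @export
classify_fixed <- function(values, thresholds, direction = 1) {
  stopifnot(length(thresholds) == 2, direction %in% c(-1, 1))
  if (thresholds[1] >= thresholds[2]) stop("thresholds must satisfy t1 < t2")
  sv <- values * direction
  ifelse(sv <= thresholds[1], 1L, ifelse(sv <= thresholds[2], 2L, 3L))
}

#' Classify per-segment factor levels from measures
#'
#' @param measures Tidy measures from [aggregate_factors()].
#' @param mode `"quantile"` (tertiles over the pooled segments) or `"fixed"`.
#' @param thresholds Named list of `c(t1, t2)` per factor (fixed mode only),
#'   on the stress-oriented scale.
#' @return `measures` with an added integer `level` column.
#' @export
classify_factor_levels <- function(measures, mode = c("quantile", "fixed"),
                                   thresholds = NULL) {
  mode <- match.arg(mode)
  measures$level <- NA_integer_
  for (f in unique(measures$factor)) {
    sel <- measures$factor == f
    dir <- measures$direction[sel][1]
    measures$level[sel] <- if (mode == "quantile") {
      classify_tertiles(measures$value[sel], dir)
    } else {
      if (is.null(thresholds[[f]])) stop("no fixed thresholds for factor ", f)
      classify_fixed(measures$value[sel], thresholds[[f]], dir)
    }
  }
  measures
}

#' Composite Stress Score per segment
#'
#' The CSS of a segment is the sum of its 1-3 factor levels over the `n`
#' factors in the chosen set, so it ranges over `[n, 3n]`. Segments missing
#' any factor level yield no record.
#'
#' @param levels Data frame with columns `segment_id`, `factor`, `level`.
#' @return Data frame (`segment_id`, `n`, `css`, `stress_level`).
#' @export
compute_css <- function(levels) {
  stopifnot(all(c("segment_id", "factor", "level") %in% names(levels)),
            all(levels$level %in% 1:3))
  n_factors <- length(unique(levels$factor))
  rows <- lapply(unique(levels$segment_id), function(sid) {
    sub <- levels[levels$segment_id == sid, ]
    if (nrow(sub) != n_factors || anyNA(sub$level)) return(NULL)
    css <- sum(sub$level)
    data.frame(segment_id = sid, n = n_factors, css = css,
               stress_level = classify_stress_level(css, n_factors))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map a Composite Stress Score to a Low/Moderate/High label
#'
#' The CSS range `[n, 3n]` is split into three equal bands: Low for
#' `css <= n`, Moderate for `n < css <= 2n`, High for `2n < css <= 3n`.
#' With two factors this gives Low <= 2, Moderate 3-4, High 5-6; with three
#' factors Moderate's upper bound is 6 and High spans 7-9.
#'
#' @param css Integer score(s).
#' @param n Number of stress factors summed.
#' @return Character vector in `c("Low", "Moderate", "High")`.
#' @export
classify_stress_level <- function(css, n) {
  stopifnot(n >= 1)
  if (any(css < n | css > 3 * n)) {
    stop("css outside the valid range [n, 3n]")
  }
  ifelse(css <= n, "Low", ifelse(css <= 2 * n, "Moderate", "High"))
}
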