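#' Pipeline configuration
#'
#' Defaults reproduce the study parameters the package is built around:
#' 100 m segments, a 0.5-45 Hz acceleration pass-band, 300/1300 ms ectopic
#' bounds, a 3-sigma Hampel filter, a 10% quotient filter, a 5% participant
#' exclusion threshold, 5000 bootstrap resamples, and alpha = 0.05.
#'
#' @param segment_interval Segment length, metres.
#' @param factors Stress-factor set used for the CSS.
#' @param classification `"quantile"` (tertiles) or `"fixed"`.
#' @param fixed_thresholds Named list of `c(t1, t2)` per factor (fixed mode).
#' @param accel_band Band-pass edges, Hz.
#' @param vertical_axis Accelerometer axis aligned vertically.
#' @param ectopic_bounds RRI plausibility bounds, ms.
#' @param hampel_window,hampel_k,hampel_mad_floor Hampel filter parameters.
#' @param quotient_frac Quotient filter relative-change threshold.
#' @param exclusion_frac Participant exclusion threshold on removed RRI
#'   fraction.
#' @param gap_max Longest interpolated GPS gap, seconds.
#' @param reject_radius Boundary-matching rejection radius, metres.
#' @param bootstrap_reps Bootstrap resamples for correlation CIs.
#' @param alpha Significance level.
#' @param tz_offset Seconds added to input timestamps at ingest.
#' @param seed Seed for the bootstrap resampling.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(segment_interval = 100,
                            factors = c("vibration_rms", "encounter_count",
                                        "sidewalk_width"),
                            classification = "quantile",
                            fixed_thresholds = NULL,
                            accel_band = c(0.5, 45), vertical_axis = "y",
                            ectopic_bounds = c(300, 1300),
                            hampel_window = 21, hampel_k = 3,
                            hampel_mad_floor = 5,
                            quotient_frac = 0.10, exclusion_frac = 0.05,
                            gap_max = 10, reject_radius = 50,
                            bootstrap_reps = 5000, alpha = 0.05,
                            tz_offset = 0, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

stage_log <- function(stage, n_in, n_out) {
  message(sprintf("[%s] in=%d kept=%d dropped=%d", stage, n_in, n_out,
                  n_in - n_out))
}

#' Run the full stress-location pipeline on a ride bundle
#'
#' Orchestrates: GPS resampling; boundary chainage and matching; segment
#' construction; environmental range cleaning; acceleration band-pass,
#' offset correction and per-second vertical RMS; factor aggregation and
#' 3-level classification; CSS scoring; per-participant RRI cleaning and
#' HRV indices with z-scoring; and CSS-HRV bootstrap Spearman correlations.
#' With five or more retained participants, the lowest-CSS segment is
#' compared against the highest-CSS segments within subject.
#'
#' @param ride An `lmd_ride` from [generate_ride()] or a bundle from
#'   [read_ride()].
#' @param config A [pipeline_config()].
#' @return List: `boundaries`, `segments`, `measures` (factor values +
#'   levels), `css`, `hrv` (per-participant, per-segment records with
#'   z-scores), `cleaning` (per-participant reports), `correlations`
#'   (per HRV index), `comparison` (or NULL), `stress_map` (GeoJSON list).
#' @export
run_pipeline <- function(ride, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))

  # --- GPS conditioning and segmentation ---
  gps <- resample_gps(ride$gps, gap_max = config$gap_max)
  stage_log("resample_gps", nrow(ride$gps), sum(!gps$excluded))
  boundaries <- chainage(ride$route, config$segment_interval)
  usable <- gps[!gps$excluded, ]
  boundaries <- match_boundaries(boundaries, usable,
                                 reject_radius = config$reject_radius)
  stage_log("match_boundaries", nrow(boundaries),
            sum(!is.na(boundaries$matched_time)))
  segments <- build_segments(boundaries)
  if (nrow(segments) < 3) stop("stage build_segments: fewer than 3 segments")
  riding_period <- c(min(segments$entry_time), max(segments$exit_time))

  # --- environmental streams ---
  measures_streams <- list()
  if ("vibration_rms" %in% config$factors) {
    if (is.null(ride$accel)) stop("stage accel: no acceleration stream")
    acc <- bandpass_accel(ride$accel, config$accel_band[1], config$accel_band[2])
    acc <- offset_correct(acc, gps = gps)
    measures_streams$rms <- vertical_rms(acc, axis = config$vertical_axis)
  }
  if ("encounter_count" %in% config$factors) {
    if (is.null(ride$encounters)) stop("stage encounters: no encounter stream")
    measures_streams$encounters <- ride$encounters
  }
  if ("sidewalk_width" %in% config$factors) {
    if (is.null(ride$widths)) stop("stage widths: no sidewalk-width map")
    measures_streams$widths <- ride$widths
  }
  env_clean <- if (!is.null(ride$env)) clean_env_stream(ride$env) else NULL

  # --- factor quantification, classification, CSS ---
  measures <- aggregate_factors(segments,
                                rms = measures_streams$rms,
                                encounters = measures_streams$encounters,
                                widths = measures_streams$widths,
                                factors = config$factors)
  measures <- classify_factor_levels(measures, mode = config$classification,
                                     thresholds = config$fixed_thresholds)
  css <- compute_css(measures)
  css <- css[order(css$segment_id), ]
  stage_log("compute_css", nrow(segments), nrow(css))

  # --- HRV ---
  hrv <- NULL
  cleaning <- NULL
  correlations <- NULL
  comparison <- NULL
  if (!is.null(ride$rri)) {
    per_part <- lapply(seq_along(ride$rri), function(p) {
      cleaned <- clean_rri(ride$rri[[p]]$series,
                           low = config$ectopic_bounds[1],
                           high = config$ectopic_bounds[2],
                           window = config$hampel_window, k = config$hampel_k,
                           mad_floor = config$hampel_mad_floor,
                           frac = config$quotient_frac,
                           period = riding_period,
                           exclusion_frac = config$exclusion_frac)
      list(records = compute_hrv_table(cleaned$series, segments, participant = p),
           report = cleaned$report)
    })
    cleaning <- lapply(per_part, `[[`, "report")
    retained <- which(!vapply(cleaning, `[[`, logical(1), "participant_excluded"))
    stage_log("rri_cleaning", length(per_part), length(retained))
    if (length(retained) >= 1) {
      hrv <- do.call(rbind, lapply(per_part[retained], `[[`, "records"))
      hrv <- zscore_indices(hrv)

      # per-segment across-participant mean z-scores, paired with CSS
      seg_ids <- sort(intersect(unique(hrv$segment_id), css$segment_id))
      mean_z <- function(col) {
        vapply(seg_ids, function(s) mean(hrv[[col]][hrv$segment_id == s]),
               numeric(1))
      }
      x <- css$css[match(seg_ids, css$segment_id)]
      correlations <- list(
        sdnn = spearman_bootstrap(x, mean_z("z_sdnn"),
                                  reps = config$bootstrap_reps,
                                  seed = config$seed),
        rmssd = spearman_bootstrap(x, mean_z("z_rmssd"),
                                   reps = config$bootstrap_reps,
                                   seed = config$seed + 1),
        pnn50 = spearman_bootstrap(x, mean_z("z_pnn50"),
                                   reps = config$bootstrap_reps,
                                   seed = config$seed + 2)
      )

      if (length(retained) >= 5) {
        ord <- css$segment_id[order(css$css)]
        sel <- c(ord[1], rev(tail(ord, 4))) # lowest-CSS reference + 4 highest
        mat <- sapply(sel, function(s) {
          v <- hrv$z_sdnn[hrv$segment_id == s]
          if (length(v) == length(retained)) v else rep(NA_real_, length(retained))
        })
        colnames(mat) <- paste0("S", sel)
        if (all(complete.cases(mat))) {
          comparison <- compare_segments(mat, reference = 1,
                                         alpha = config$alpha)
        }
      }
    }
  }

  stress_map <- export_stress_map(segments, css, ride$route,
                                  levels = measures)
  list(boundaries = boundaries, segments = segments, measures = measures,
       css = css, env = env_clean, hrv = hrv, cleaning = cleaning,
       correlations = correlations, comparison = comparison,
       stress_map = stress_map)
}

#' Export scored segments as a GeoJSON stress map
#'
#' One LineString feature per scored segment, tracing the route polyline
#' between the segment's start and end chainage, with properties
#' `segment_id`, `css`, `n`, `stress_level`, and the per-factor levels.
#'
#' @param segments Segment table from [build_segments()].
#' @param css CSS records from [compute_css()].
#' @param route Route polyline (`lat`/`lon` data frame).
#' @param levels Optional tidy factor-level table (adds
#'   `level_<factor>` properties).
#' @param path Optional file to write the GeoJSON to.
#' @return The GeoJSON structure as a list (invisibly written to `path` when
#'   given).
#' @export
export_stress_map <- function(segments, css, route, levels = NULL,
                              path = NULL) {
  cum <- route_chainage(route)
  features <- lapply(seq_len(nrow(css)), function(i) {
    rec <- css[i, ]
    seg <- segments[segments$id == rec$segment_id, ]
    if (nrow(seg) != 1) return(NULL)
    inner <- which(cum > seg$start_chainage & cum < seg$end_chainage)
    coords <- rbind(
      c(seg$start_lon, seg$start_lat),
      cbind(route$lon[inner], route$lat[inner]),
      c(seg$end_lon, seg$end_lat)
    )
    props <- list(segment_id = rec$segment_id, css = rec$css, n = rec$n,
                  stress_level = rec$stress_level)
    if (!is.null(levels)) {
      sub <- levels[levels$segment_id == rec$segment_id, ]
      for (j in seq_len(nrow(sub))) {
        props[[paste0("level_", sub$factor[j])]] <- sub$level[j]
      }
    }
    list(type = "Feature",
         geometry = list(type = "LineString", coordinates = unname(coords)),
         properties = props)
  })
  gj <- list(type = "FeatureCollection",
             features = Filter(Negate(is.null), features))
  if (!is.null(path)) {
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(gj)
}
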