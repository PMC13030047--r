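# Association of the Composite Stress Score with per-segment HRV:
# bootstrap Spearman correlations, Fisher-z power, and within-subject
# comparisons of selected segments.

spearman_p <- function(rho, x, y) {
  n <- length(x)
  if (n <= 10 && !anyDuplicated(x) && !anyDuplicated(y)) {
    ct <- cor.test(x, y, method = "spearman", exact = TRUE)
    return(unname(ct$p.value))
  }
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(t_stat), df = n - 2)
}

#' Spearman correlation with bootstrap percentile confidence interval
#'
#' Rank correlation between per-segment CSS and a per-segment HRV summary
#' (typically the across-participant mean z-score), with a nonparametric
#' bootstrap percentile CI obtained by resampling segment pairs. The p-value
#' is an exact permutation value for n <= 10 without ties, otherwise the
#' asymptotic t approximation.
#'
#' @param x,y Paired numeric vectors (at least 4 pairs).
#' @param reps Bootstrap resamples (default 5000).
#' @param seed Optional integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return List: `rho`, `ci_low`, `ci_high`, `p_value`, `n`, `strength`
#'   (see [strength_label()]). `rho` is NA when either input is constant.
#' @export
spearman_bootstrap <- function(x, y, reps = 5000, seed = NULL, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 4, !anyNA(x), !anyNA(y))
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input; Spearman correlation undefined")
    return(list(rho = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p_value = NA_real_, n = n, strength = NA_character_))
  }
  rho <- cor(x, y, method = "spearman")
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(reps), function(r) {
    idx <- sample.int(n, n, replace = TRUE)
    suppressWarnings(cor(x[idx], y[idx], method = "spearman"))
  }, numeric(1))
  boot <- boot[!is.na(boot)] # resamples that drew a constant vector
  alpha <- (1 - conf) / 2
  ci <- quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  list(rho = rho, ci_low = ci[1], ci_high = ci[2],
       p_value = spearman_p(rho, x, y), n = n,
       strength = strength_label(rho))
}

#' Smallest correlation detectable at given power
#'
#' Fisher-z approximation: the minimal |rho| detectable in a two-sided test
#' at level `alpha` with the requested power from `n` pairs satisfies
#' `atanh(rho) = (z_(1-alpha/2) + z_power) / sqrt(n - 3)`. With n = 23
#' segments this is approximately 0.56 at 80% power.
#'
#' @param n Number of pairs (> 3).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @return Detectable |rho|.
#' @export
detectable_rho <- function(n, alpha = 0.05, power = 0.80) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  if (n <= 3) stop("n must exceed 3 for the Fisher-z approximation")
  tanh((qnorm(1 - alpha / 2) + qnorm(power)) / sqrt(n - 3))
}

#' Qualitative strength label for a Spearman correlation
#'
#' Conventional interpretation bands on |rho|: 1.0 Perfect, \[0.7, 1.0)
#' Strong, \[0.4, 0.7) Moderate, \[0.1, 0.4) Weak, exactly 0 None. Values in
#' (0, 0.1) fall between the published bands and are labelled with
#' `gap_label` ("Negligible" by default).
#'
#' @param rho Correlation in \[-1, 1\].
#' @param gap_label Label for 0 < |rho| < 0.1.
#' @return Character label.
#' @export
strength_label <- function(rho, gap_label = "Negligible") {
  stopifnot(abs(rho) <= 1)
  a <- abs(rho)
  if (a == 1) "Perfect"
  else if (a >= 0.7) "Strong"
  else if (a >= 0.4) "Moderate"
  else if (a >= 0.1) "Weak"
  else if (a == 0) "None"
  else gap_label
}

#' Within-subject comparison of HRV across selected segments
#'
#' Normality of each segment's values is assessed with Shapiro-Wilk tests; if
#' every segment passes (p > alpha) a one-way repeated-measures ANOVA is the
#' omnibus test, otherwise the Friedman test. On omnibus significance, each
#' non-reference segment is compared with the reference (low-stress) segment
#' by paired t-tests (normal case) or Wilcoxon signed-rank tests, with
#' Bonferroni adjustment over the number of comparisons.
#'
#' @param hrv Numeric matrix, participants x segments (complete cases;
#'   column names identify segments); at least 5 participants.
#' @param reference Column (index or name) of the reference segment.
#' @param alpha Significance level (default 0.05).
#' @return List: `normality` (per-segment Shapiro p), `omnibus`
#'   (`test`, `statistic`, `p_value`), `posthoc` (data frame of comparisons
#'   with raw and Bonferroni-adjusted p; NULL when the omnibus is not
#'   significant or the data are degenerate), `alpha`.
#' @export
compare_segments <- function(hrv, reference = 1, alpha = 0.05) {
  hrv <- as.matrix(hrv)
  stopifnot(ncol(hrv) >= 2, all(complete.cases(hrv)))
  if (nrow(hrv) < 5) stop("fewer than 5 participants; omnibus testing refused")
  if (is.character(reference)) reference <- match(reference, colnames(hrv))
  stopifnot(!is.na(reference), reference >= 1, reference <= ncol(hrv))
  seg_names <- colnames(hrv)
  if (is.null(seg_names)) seg_names <- paste0("S", seq_len(ncol(hrv)))

  degenerate <- any(apply(hrv, 2, sd) == 0)
  normality <- if (degenerate) rep(NA_real_, ncol(hrv)) else {
    apply(hrv, 2, function(v) shapiro.test(v)$p.value)
  }
  all_normal <- !degenerate && all(normality > alpha)

  if (degenerate) {
    omnibus <- list(test = "none", statistic = NA_real_, p_value = NA_real_)
  } else if (all_normal) {
    long <- data.frame(
      value = as.vector(hrv),
      segment = factor(rep(seg_names, each = nrow(hrv))),
      subject = factor(rep(seq_len(nrow(hrv)), times = ncol(hrv)))
    )
    fit <- aov(value ~ segment + Error(subject / segment), data = long)
    tab <- summary(fit)[["Error: subject:segment"]][[1]]
    omnibus <- list(test = "rm_anova",
                    statistic = tab["segment", "F value"],
                    p_value = tab["segment", "Pr(>F)"])
  } else {
    ft <- friedman.test(hrv)
    omnibus <- list(test = "friedman",
                    statistic = unname(ft$statistic),
                    p_value = unname(ft$p.value))
  }

  posthoc <- NULL
  if (!degenerate && !is.na(omnibus$p_value) && omnibus$p_value < alpha) {
    others <- setdiff(seq_len(ncol(hrv)), reference)
    raw <- vapply(others, function(j) {
      if (all_normal) {
        t.test(hrv[, j], hrv[, reference], paired = TRUE)$p.value
      } else {
        wilcox.test(hrv[, j], hrv[, reference], paired = TRUE,
                    exact = FALSE)$p.value
      }
    }, numeric(1))
    posthoc <- data.frame(
      segment = seg_names[others],
      reference = seg_names[reference],
      test = if (all_normal) "paired_t" else "wilcoxon_signed_rank",
      p_raw = raw,
      p_adjusted = p.adjust(raw, method = "bonferroni")
    )
  }

  list(normality = setNames(normality, seg_names), omnibus = omnibus,
       posthoc = posthoc, alpha = alpha)
}
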