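#' Normalize breath gases to a nominal CO2 concentration
#'
#' End-expiratory breath samples are diluted to varying degrees by dead-space
#' air; gas readings are therefore rescaled to an assumed nominal alveolar
#' CO2 of 3.5 percent: \code{normalized = raw * 3.5 / co2_pct}.
#'
#' @param breath data.frame with columns \code{h2_ppm}, \code{ch4_ppm} and
#'   \code{co2_pct}.
#' @param nominal_co2 nominal CO2 percent.
#' @return the data.frame with added \code{h2_norm} and \code{ch4_norm}
#'   columns (ppm).
#' @export
normalize_breath <- function(breath, nominal_co2 = 3.5) {
  stopifnot(is.data.frame(breath),
            all(c("h2_ppm", "ch4_ppm", "co2_pct") %in% names(breath)))
  if (any(!is.finite(breath$co2_pct)) || any(breath$co2_pct <= 0)) {
    stop("CO2 percent must be > 0 for normalization", call. = FALSE)
  }
  if (any(breath$h2_ppm < 0) || any(breath$ch4_ppm < 0)) {
    stop("raw gas readings must be >= 0", call. = FALSE)
  }
  breath$h2_norm <- breath$h2_ppm * nominal_co2 / breath$co2_pct
  breath$ch4_norm <- breath$ch4_ppm * nominal_co2 / breath$co2_pct
  breath
}

#' Outlier exclusion by Tukey's fences
#'
#' Excludes values lying more than \code{k} interquartile ranges below the
#' lower quartile or above the upper quartile.  Quartiles use linear
#' interpolation (\code{stats::quantile} type 7) by default; the convention
#' is configurable.
#'
#' @param values numeric vector (NA not allowed).
#' @param k IQR multiplier (default 3).
#' @param type quantile type passed to \code{stats::quantile}.
#' @return list with \code{kept} (values inside the fences),
#'   \code{excluded} (logical mask, TRUE = excluded) and \code{fences}
#'   (lower, upper).
#' @examples
#' tukey_exclude(c(1, 2, 3, 4, 5, 100))
#' @export
tukey_exclude <- function(values, k = 3, type = 7) {
  if (length(values) == 0) stop("no values to screen", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  if (length(values) < 4) {
    warning("fewer than 4 values: quartiles are poorly defined; ",
            "no exclusion applied", call. = FALSE)
    return(list(kept = values, excluded = rep(FALSE, length(values)),
                fences = c(lower = -Inf, upper = Inf)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
  excluded <- values < fences["lower"] | values > fences["upper"]
  list(kept = values[!excluded], excluded = excluded, fences = fences)
}

#' Classify subjects as methanogenic from breath methane
#'
#' A subject-period is methanogenic (MG) when any baseline-corrected,
#' CO2-normalized breath CH4 reading strictly exceeds the threshold
#' (default 4 ppm).  In semesters flagged as having an elevated instrument
#' baseline, a fixed baseline (default 1 ppm) is subtracted from every
#' reading first, flooring at zero.  Classification is done separately for
#' the before and during periods.
#'
#' @param breath data.frame with columns \code{subject}, \code{period},
#'   \code{semester} and \code{ch4_norm} (run \code{\link{normalize_breath}}
#'   first).
#' @param threshold ppm; MG iff any corrected reading > threshold (strict).
#' @param baseline_semesters character vector of semester labels with the
#'   elevated baseline.
#' @param baseline_ppm baseline to subtract in those semesters.
#' @return data.frame: subject, period, status ("MG"/"non-MG"),
#'   max_ch4_corrected, baseline_applied.
#' @export
classify_methanogenic <- function(breath, threshold = 4,
                                  baseline_semesters = character(),
                                  baseline_ppm = 1) {
  stopifnot(is.data.frame(breath),
            all(c("subject", "period", "ch4_norm") %in% names(breath)))
  if (nrow(breath) == 0) stop("no breath samples to classify", call. = FALSE)
  sem <- if ("semester" %in% names(breath)) breath$semester else ""
  base <- ifelse(sem %in% baseline_semesters, baseline_ppm, 0)
  corrected <- pmax(breath$ch4_norm - base, 0)
  key <- interaction(breath$subject, breath$period, drop = TRUE)
  agg <- tapply(corrected, key, max)
  base_agg <- tapply(base, key, max)
  info <- unique(data.frame(subject = breath$subject,
                            period = breath$period,
                            key = as.character(key),
                            stringsAsFactors = FALSE))
  info <- info[match(names(agg), info$key), ]
  data.frame(subject = info$subject, period = info$period,
             status = ifelse(agg > threshold, "MG", "non-MG"),
             max_ch4_corrected = as.numeric(agg),
             baseline_applied = as.numeric(base_agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-subject period means after metric-wide outlier exclusion
#'
#' Applies \code{\link{tukey_exclude}} to all samples of one metric (across
#' subjects and periods, as the fences are defined metric-wide), then
#' averages the retained samples per subject and period.  Subjects whose
#' samples are all excluded in a period are dropped with a warning.
#'
#' @param samples data.frame with \code{subject}, \code{period} and the
#'   metric column.
#' @param metric name of the value column.
#' @param k Tukey fence multiplier; \code{Inf} disables exclusion.
#' @param type quantile convention.
#' @return data.frame: subject, period, mean, n_used, n_excluded.
#' @export
subject_period_means <- function(samples, metric, k = 3, type = 7) {
  stopifnot(is.data.frame(samples),
            all(c("subject", "period", metric) %in% names(samples)))
  v <- samples[[metric]]
  if (is.finite(k)) {
    excl <- tukey_exclude(v, k = k, type = type)$excluded
  } else {
    excl <- rep(FALSE, length(v))
  }
  keep <- samples[!excl, , drop = FALSE]
  key_all <- unique(paste(samples$subject, samples$period, sep = "\r"))
  key_kept <- paste(keep$subject, keep$period, sep = "\r")
  lost <- setdiff(key_all, key_kept)
  if (length(lost) > 0) {
    warning(length(lost), " subject-period(s) dropped: all samples excluded",
            call. = FALSE)
  }
  agg <- stats::aggregate(keep[[metric]],
                          by = list(subject = keep$subject,
                                    period = keep$period),
                          FUN = mean)
  names(agg)[3] <- "mean"
  n_used <- stats::aggregate(keep[[metric]],
                             by = list(subject = keep$subject,
                                       period = keep$period),
                             FUN = length)
  agg$n_used <- n_used$x
  agg$n_excluded <- vapply(seq_len(nrow(agg)), function(i) {
    sum(excl & samples$subject == agg$subject[i] &
          samples$period == agg$period[i])
  }, numeric(1))
  agg
}

#' Compare methanogenic and non-methanogenic subjects
#'
#' Two-sided two-sample Student's t-test on per-subject period means of a
#' metric between MG and non-MG subjects, within one period.  Individual
#' subjects can be excluded explicitly (e.g. a flagged extreme observation).
#'
#' @param means output of \code{\link{subject_period_means}}.
#' @param status output of \code{\link{classify_methanogenic}}.
#' @param period \code{"before"} or \code{"during"}.
#' @param exclude_subjects subjects to drop before testing.
#' @param var_equal pooled-variance Student's test (default) or Welch.
#' @return one-row data.frame: period, n and mean and SEM per group
#'   (MG, non-MG), t, df, p, stars.
#' @export
compare_mg_groups <- function(means, status, period,
                              exclude_subjects = character(),
                              var_equal = TRUE) {
  m <- means[means$period == period &
               !means$subject %in% exclude_subjects, , drop = FALSE]
  s <- status[status$period == period, c("subject", "status")]
  m$status <- s$status[match(m$subject, s$subject)]
  if (anyNA(m$status)) {
    stop("subjects without a methanogenesis classification: ",
         paste(unique(m$subject[is.na(m$status)]), collapse = ", "),
         call. = FALSE)
  }
  mg <- m$mean[m$status == "MG"]
  non <- m$mean[m$status == "non-MG"]
  if (length(mg) < 2 || length(non) < 2) {
    stop("need >= 2 subjects per group (MG: ", length(mg),
         ", non-MG: ", length(non), ")", call. = FALSE)
  }
  tt <- safe_t_test(mg, non, var_equal = var_equal)
  data.frame(period = period,
             n_mg = length(mg), mean_mg = mean(mg),
             sem_mg = stats::sd(mg) / sqrt(length(mg)),
             n_non_mg = length(non), mean_non_mg = mean(non),
             sem_non_mg = stats::sd(non) / sqrt(length(non)),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, stars = p_stars(tt$p.value),
             stringsAsFactors = FALSE)
}

#' Before-versus-during contrast of a metric
#'
#' Compares per-subject means during versus before supplementation, either
#' paired within subjects (subjects with both periods) or unpaired.  Both
#' are exposed because published cohort contrasts of this kind do not always
#' state which was used.
#'
#' @param means output of \code{\link{subject_period_means}}.
#' @param paired use a paired t-test on subjects observed in both periods.
#' @return one-row data.frame with means, t, df, p.
#' @export
before_during_contrast <- function(means, paired = TRUE) {
  before <- means[means$period == "before", c("subject", "mean")]
  during <- means[means$period == "during", c("subject", "mean")]
  if (paired) {
    common <- intersect(before$subject, during$subject)
    if (length(common) < 2) stop("need >= 2 paired subjects", call. = FALSE)
    b <- before$mean[match(common, before$subject)]
    d <- during$mean[match(common, during$subject)]
    diffs <- d - b
    if (stats::sd(diffs) == 0) {
      # constant shift: t.test refuses essentially-constant differences
      tt <- list(statistic = c(t = sign(mean(diffs)) * Inf),
                 parameter = c(df = length(diffs) - 1),
                 p.value = if (mean(diffs) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(d, b, paired = TRUE)
    }
    n <- length(common)
  } else {
    if (nrow(before) < 2 || nrow(during) < 2) {
      stop("need >= 2 subjects per period", call. = FALSE)
    }
    tt <- safe_t_test(during$mean, before$mean)
    b <- before$mean
    d <- during$mean
    n <- nrow(before) + nrow(during)
  }
  data.frame(mean_before = mean(b), mean_during = mean(d), n = n,
             paired = paired, t = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             stars = p_stars(tt$p.value), stringsAsFactors = FALSE)
}

#' Full cohort pipeline: normalization to MG contrasts
#'
#' Runs breath normalization, metric-wide Tukey exclusion, methanogen
#' classification, per-subject period averaging, and the MG versus non-MG
#' comparison for each requested metric and period.
#'
#' @param breath breath table: subject, period, semester, h2_ppm, ch4_ppm,
#'   co2_pct.
#' @param fecal fecal table: subject, period plus metabolite columns
#'   (e.g. \code{butyrate_umol_g}).
#' @param fecal_metrics fecal columns to analyze.
#' @param k Tukey fence multiplier.
#' @param threshold CH4 classification threshold, ppm.
#' @param baseline_semesters semesters with the elevated CH4 baseline.
#' @param baseline_ppm baseline subtracted in those semesters.
#' @param exclude_subjects subjects dropped from group comparisons.
#' @return data.frame with one row per metric and period: group means, SEM,
#'   t, p, stars.
#' @export
cohort_mg_comparison <- function(breath, fecal,
                                 fecal_metrics = "butyrate_umol_g",
                                 k = 3, threshold = 4,
                                 baseline_semesters = character(),
                                 baseline_ppm = 1,
                                 exclude_subjects = character()) {
  breath <- normalize_breath(breath)
  status <- classify_methanogenic(breath, threshold = threshold,
                                  baseline_semesters = baseline_semesters,
                                  baseline_ppm = baseline_ppm)
  metrics <- c(list(breath_h2 = list(data = breath, col = "h2_norm")),
               stats::setNames(
                 lapply(fecal_metrics,
                        function(mc) list(data = fecal, col = mc)),
                 paste0("fecal_", sub("_.*$", "", fecal_metrics))))
  out <- list()
  for (nm in names(metrics)) {
    mm <- subject_period_means(metrics[[nm]]$data, metrics[[nm]]$col, k = k)
    for (per in intersect(c("before", "during"), unique(mm$period))) {
      row <- compare_mg_groups(mm, status, per,
                               exclude_subjects = exclude_subjects)
      row <- cbind(metric = nm, row)
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}
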