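# Multi-metric habitat health index: metric categorisation, score
# aggregation, and the continuous / transect / vicinity assessment modes.
#
# Nine physical metrics are scored: channel gradient (M1, which only
# selects the high- vs mild-gradient threshold system), riparian
# vegetation buffer (M2), bank stability / erosion (M3), width-to-depth
# ratio (M4), sinuosity (M5), stream flow status (M6), coarse woody
# debris (M7), in-stream cover (M8) and channel bed forms / pools (M9).
# Categories map to scores excellent = 10, good = 7.5, fair = 5,
# poor = 2.5; the total over M2..M9 (two-sided metrics contribute the
# mean of their side scores) classifies the site.

CATEGORY_LEVELS <- c("poor", "fair", "good", "excellent")
CATEGORY_SCORES <- c(excellent = 10, good = 7.5, fair = 5, poor = 2.5)

#' Score of a health category
#' @param label category label (`excellent`, `good`, `fair`, `poor`).
#' @return numeric score 10 / 7.5 / 5 / 2.5.
#' @export
category_score <- function(label) {
  if (!all(label %in% names(CATEGORY_SCORES))) stop("unknown category label")
  unname(CATEGORY_SCORES[label])
}

#' Classify channel gradient
#'
#' High-gradient (`"H"`) when the slope strictly exceeds 0.02 m/m, mild
#' (`"M"`) otherwise.  A negative slope is classified on its absolute
#' value with a warning.
#'
#' @param slope channel slope (m/m).
#' @return `"H"` or `"M"`.
#' @export
classify_gradient <- function(slope) {
  stopifnot(is.finite(slope))
  if (slope < 0) {
    warning("negative slope classified on absolute value")
    slope <- abs(slope)
  }
  if (slope > 0.02) "H" else "M"
}

#' Categorise a metric value
#'
#' Applies the published threshold system for the metric, using the
#' high- or mild-gradient variant where the metric has both (M5, M7).
#' Interval closures follow the threshold table exactly, including the
#' non-monotone pool-percentage bins of M9.
#'
#' @param code metric code `"M2"` .. `"M9"`.
#' @param value metric value (metres for M2/M3, ratio for M4/M5,
#'   percentages for M6--M9).
#' @param gradient `"H"` or `"M"`.
#' @return list with `label` and `score`.
#' @export
score_value <- function(code, value, gradient = c("M", "H")) {
  gradient <- match.arg(gradient)
  if (!is.finite(value)) stop("metric value must be finite")
  lab <- switch(code,
    M2 = {
      if (value < 0) stop("M2 width cannot be negative")
      if (value >= 10) "excellent" else if (value >= 5) "good"
      else if (value >= 1) "fair" else "poor"
    },
    M3 = {
      if (value < 0) stop("M3 width cannot be negative")
      if (value < 0.2) "excellent" else if (value < 0.5) "good"
      else if (value < 1) "fair" else "poor"
    },
    M4 = score_ratio_bins(value),
    M5 = if (gradient == "H") score_ratio_bins(value) else {
      if (value > 3) "excellent" else if (value > 2) "good"
      else if (value > 1) "fair" else "poor"
    },
    M6 = {
      if (value < -1e-9 || value > 100 + 1e-9) stop("M6 percentage outside [0, 100]")
      if (value >= 100 - 1e-9) "excellent" else if (value >= 75) "good"
      else if (value >= 25) "fair" else "poor"
    },
    M7 = {
      if (value < -1e-9 || value > 100 + 1e-9) stop("M7 percentage outside [0, 100]")
      if (gradient == "H") {
        if (value >= 70) "excellent" else if (value >= 40) "good"
        else if (value >= 20) "fair" else "poor"
      } else {
        if (value >= 50) "excellent" else if (value >= 30) "good"
        else if (value >= 10) "fair" else "poor"
      }
    },
    M8 = {
      if (value < 0) stop("M8 percentage cannot be negative")
      if (value >= 12) "excellent" else if (value >= 7) "good"
      else if (value >= 2) "fair" else "poor"
    },
    M9 = {
      if (value < 0 || value > 100) stop("M9 percentage outside [0, 100]")
      if (value > 40 && value < 60) "excellent"
      else if ((value > 30 && value <= 40) || (value >= 60 && value < 70)) "good"
      else if ((value > 10 && value <= 30) || (value >= 70 && value < 90)) "fair"
      else "poor"
    },
    stop("unknown metric code: ", code))
  list(label = lab, score = category_score(lab))
}

score_ratio_bins <- function(value) {
  if (value < 0) stop("ratio cannot be negative")
  if (value < 7) "excellent" else if (value < 15) "good"
  else if (value < 25) "fair" else "poor"
}

#' Overall class from a total score
#' @param total total score over M2..M9.
#' @return class label.
#' @export
total_class <- function(total) {
  if (total >= 60) "excellent" else if (total >= 45) "good"
  else if (total >= 30) "fair" else "poor"
}

# Length weights of a station series: half-distance to each neighbour.
station_weights <- function(s) {
  n <- length(s)
  if (n == 1L) return(1)
  w <- numeric(n)
  w[1L] <- (s[2L] - s[1L]) / 2
  w[n] <- (s[n] - s[n - 1L]) / 2
  if (n > 2L) w[2:(n - 1L)] <- (s[3:n] - s[1:(n - 2L)]) / 2
  w
}

#' Score a spatially continuous metric over a station series
#'
#' Categorises every station, accumulates the length-weighted category
#' distribution, and derives the site-level category according to
#' `site_rule`: bin the length-weighted mean value (default), take the
#' weight-dominant station category, or the worst one.
#'
#' @param code metric code.
#' @param values per-station metric values.
#' @param weights station weights (defaults to arc-length weights are the
#'   caller's responsibility; equal weights when `NULL`).
#' @param gradient `"H"` or `"M"`.
#' @param site_rule `"mean"`, `"majority"` or `"worst"`.
#' @param site_value optional override of the site-level value (used for
#'   ratio metrics whose site value is a ratio of means, not a mean of
#'   ratios).
#' @return list with `code`, `site_value`, `label`, `score`,
#'   `station_labels` and `pct_by_category` (fractions summing to 1).
#' @export
score_stations <- function(code, values, weights = NULL,
                           gradient = "M", site_rule = "mean",
                           site_value = NULL) {
  if (length(values) == 0L) stop("empty station series")
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(weights) == length(values), all(weights >= 0), sum(weights) > 0)
  labs <- vapply(values, function(v) score_value(code, v, gradient)$label, "")
  pct <- vapply(CATEGORY_LEVELS, function(l) sum(weights[labs == l]), 1) / sum(weights)
  sv <- if (!is.null(site_value)) site_value
  else stats::weighted.mean(values, weights)
  lab <- switch(site_rule,
    mean = score_value(code, sv, gradient)$label,
    majority = CATEGORY_LEVELS[which.max(pct)],
    worst = CATEGORY_LEVELS[min(match(labs, CATEGORY_LEVELS))],
    stop("unknown site_rule: ", site_rule))
  list(code = code, site_value = sv, label = lab, score = category_score(lab),
       station_labels = labs, pct_by_category = pct)
}

#' Aggregate metric results into the total score and overall class
#'
#' Two-sided metrics (left/right entries) contribute the mean of their
#' side scores; the total is the plain sum over M2..M9.
#'
#' @param metrics named list with entries `M2` .. `M9`; each entry either
#'   has a `score`, or `left`/`right` components each with a `score`.
#' @return list with `total` and `overall`.
#' @export
aggregate_metrics <- function(metrics) {
  need <- paste0("M", 2:9)
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop("missing metric(s): ", paste(miss, collapse = ", "))
  total <- sum(vapply(need, function(code) {
    m <- metrics[[code]]
    if (!is.null(m$left)) (m$left$score + m$right$score) / 2 else m$score
  }, 1))
  list(total = total, overall = total_class(total))
}

#' Total score and class from plain category labels
#'
#' Convenience wrapper around [aggregate_metrics()] for the case where
#' only the per-metric health categories are known.  Two-sided entries are
#' given as `c(left = , right = )`.
#'
#' @param categories named list `M2` .. `M9` of category labels.
#' @return list with `total`, `overall` and the per-metric scores.
#' @export
aggregate_categories <- function(categories) {
  metrics <- lapply(categories, function(lab) {
    if (length(lab) == 2L && !is.null(names(lab)))
      list(left = list(score = category_score(lab[["left"]])),
           right = list(score = category_score(lab[["right"]])))
    else list(score = category_score(as.character(lab)))
  })
  res <- aggregate_metrics(metrics)
  res$scores <- vapply(paste0("M", 2:9), function(code) {
    m <- metrics[[code]]
    if (!is.null(m$left)) (m$left$score + m$right$score) / 2 else m$score
  }, 1)
  res
}

metric_entry <- function(sc) sc[c("code", "site_value", "label", "score",
                                  "pct_by_category", "station_labels")]

build_report <- function(mode, gradient_class, slope, metrics) {
  agg <- aggregate_metrics(metrics)
  structure(list(mode = mode, gradient_class = gradient_class, slope = slope,
                 metrics = metrics, total = agg$total, overall = agg$overall),
            class = "habitat_report")
}

# Shared metric computation over an arbitrary station subset.
score_metric_set <- function(records, weights, gradient, cfg,
                             sinuosity_value, pool_pct, cwd_pct) {
  m8_values <- 100 * (records$F_left + records$F_right) / records$W
  list(
    M2 = list(code = "M2", sided = TRUE,
              left = metric_entry(score_stations("M2", records$B_left, weights,
                                                 gradient, cfg$site_rule)),
              right = metric_entry(score_stations("M2", records$B_right, weights,
                                                  gradient, cfg$site_rule))),
    M3 = list(code = "M3", sided = TRUE,
              left = metric_entry(score_stations("M3", records$E_left, weights,
                                                 gradient, cfg$site_rule)),
              right = metric_entry(score_stations("M3", records$E_right, weights,
                                                  gradient, cfg$site_rule))),
    M4 = metric_entry(score_stations(
      "M4", records$W / records$D, weights, gradient, cfg$site_rule,
      site_value = stats::weighted.mean(records$W, weights) /
        stats::weighted.mean(records$D, weights))),
    M5 = c(list(code = "M5"), score_value("M5", sinuosity_value, gradient),
           list(site_value = sinuosity_value)),
    M6 = metric_entry(score_stations("M6", 100 * records$wet_fraction, weights,
                                     gradient, cfg$site_rule)),
    M7 = c(list(code = "M7"), score_value("M7", cwd_pct, gradient),
           list(site_value = cwd_pct)),
    M8 = metric_entry(score_stations("M8", m8_values, weights, gradient,
                                     cfg$site_rule)),
    M9 = c(list(code = "M9"), score_value("M9", pool_pct, gradient),
           list(site_value = pool_pct)))
}

pool_length_in <- function(pools, s_min, s_max) {
  if (is.null(pools) || nrow(pools) == 0L) return(0)
  sum(pmax(0, pmin(pools$s_end, s_max) - pmax(pools$s_start, s_min)))
}

#' Spatially continuous habitat health assessment
#'
#' Scores every metric from the full station series: riparian buffer and
#' erosion per side, width/depth from the ratio of length-weighted means,
#' sinuosity from the centerline, flow status from the wetted fractions,
#' woody debris from the supplied bank coverage, in-stream cover from the
#' per-station cover percentage, and bed forms from the pool fraction of
#' the stream length.
#'
#' @param records full station table (see [extract_stations()]).
#' @param pools pool intervals from [detect_pools()].
#' @param cl the `centerline`.
#' @param slope channel slope (m/m), e.g. from [channel_gradient()].
#' @param cfg an [assessment_config()].
#' @param cwd_coverage fraction of the banks covered by coarse woody
#'   debris (e.g. mean of [coverage_fraction()] over both banks).
#' @return a `habitat_report`.
#' @export
assess_continuous <- function(records, pools, cl, slope,
                              cfg = assessment_config(), cwd_coverage = 0) {
  records <- validate_stations(records)
  gradient <- classify_gradient(slope)
  L0 <- cl$s[length(cl$s)]
  metrics <- score_metric_set(
    records, station_weights(records$s), gradient, cfg,
    sinuosity_value = sinuosity(cl),
    pool_pct = 100 * pool_length_in(pools, 0, L0) / L0,
    cwd_pct = 100 * cwd_coverage)
  build_report("continuous", gradient, slope, metrics)
}

# Indices of the n (approximately) equally spaced transect stations.
transect_indices <- function(s, n) {
  if (n < 2L) stop("at least 2 transects required")
  if (n > length(s)) stop("more transects than stations")
  targets <- seq(s[1L], s[length(s)], length.out = n)
  idx <- vapply(targets, function(t) which.min(abs(s - t)), 1L)
  if (anyDuplicated(idx)) stop("transect spacing below station spacing")
  idx
}

#' Transect-based habitat health assessment
#'
#' Samples the station series at `n` equally spaced transects and scores
#' each metric from the transect means, mirroring a conventional
#' tape-and-wade survey.  Sinuosity and woody debris remain whole-channel
#' quantities; the pool percentage becomes the share of transects falling
#' inside a pool.
#'
#' @inheritParams assess_continuous
#' @param n number of transects.
#' @return a `habitat_report`.
#' @export
assess_transects <- function(records, n, pools, cl, slope,
                             cfg = assessment_config(), cwd_coverage = 0) {
  records <- validate_stations(records)
  idx <- transect_indices(records$s, n)
  sub <- records[idx, ]
  gradient <- classify_gradient(slope)
  in_pool <- vapply(sub$s, function(st)
    !is.null(pools) && nrow(pools) > 0L &&
      any(st >= pools$s_start & st <= pools$s_end), logical(1))
  metrics <- score_metric_set(
    sub, rep(1, nrow(sub)), gradient, cfg,
    sinuosity_value = sinuosity(cl),
    pool_pct = 100 * mean(in_pool),
    cwd_pct = 100 * cwd_coverage)
  build_report("transect", gradient, slope, metrics)
}

#' Vicinity-based (worst-in-window) assessment
#'
#' For each transect, reports the worst station category of every
#' spatially continuous metric within half a transect spacing on either
#' side, exposing localized impairments that transect means average away.
#'
#' @param records full station table.
#' @param n number of transects.
#' @param cfg an [assessment_config()]; `delta_L` overrides the derived
#'   transect spacing.
#' @return data frame with one row per transect and the worst category of
#'   M2 (left/right), M3 (left/right), M4, M6 and M8 in its window.
#' @export
assess_vicinity <- function(records, n, cfg = assessment_config()) {
  records <- validate_stations(records)
  idx <- transect_indices(records$s, n)
  sv <- records$s[idx]
  dL <- if (!is.null(cfg$delta_L)) cfg$delta_L
  else (records$s[nrow(records)] - records$s[1L]) / (n - 1L)
  worst <- function(code, values) {
    labs <- vapply(values, function(v) score_value(code, v, "M")$label, "")
    CATEGORY_LEVELS[min(match(labs, CATEGORY_LEVELS))]
  }
  out <- data.frame(transect = seq_len(n), s = sv)
  cols <- list(M2_left = list("M2", "B_left"), M2_right = list("M2", "B_right"),
               M3_left = list("M3", "E_left"), M3_right = list("M3", "E_right"),
               M6 = list("M6", NULL), M4 = list("M4", NULL), M8 = list("M8", NULL))
  for (nm in names(cols)) out[[nm]] <- NA_character_
  for (t in seq_len(n)) {
    win <- records[abs(records$s - sv[t]) <= dL / 2, ]
    out$M2_left[t] <- worst("M2", win$B_left)
    out$M2_right[t] <- worst("M2", win$B_right)
    out$M3_left[t] <- worst("M3", win$E_left)
    out$M3_right[t] <- worst("M3", win$E_right)
    out$M4[t] <- worst("M4", win$W / win$D)
    out$M6[t] <- worst("M6", 100 * win$wet_fraction)
    out$M8[t] <- worst("M8", 100 * (win$F_left + win$F_right) / win$W)
  }
  out
}

#' @export
print.habitat_report <- function(x, ...) {
  cat(sprintf("<habitat_report> %s assessment, %s-gradient channel (slope %.4f)\n",
              x$mode, x$gradient_class, x$slope))
  for (code in paste0("M", 2:9)) {
    m <- x$metrics[[code]]
    if (!is.null(m$left))
      cat(sprintf("  %s: left %s (%.4g), right %s (%.4g)\n", code,
                  m$left$label, m$left$site_value, m$right$label, m$right$site_value))
    else
      cat(sprintf("  %s: %s (%.4g)\n", code, m$label, m$site_value))
  }
  cat(sprintf("  total %.2f -> %s\n", x$total, x$overall))
  invisible(x)
}
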