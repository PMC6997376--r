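#' Fish condition factor
#'
#' `k = 100 * body weight (g) / fork length (cm)^3`.
#'
#' @param weight_g Body weight in grams (> 0).
#' @param length_cm Fork length in centimetres (> 0).
#' @return Condition factor, vectorized.
#' @export
condition_factor <- function(weight_g, length_cm) {
  if (any(weight_g <= 0) || any(length_cm <= 0)) {
    stop("weight and length must be positive")
  }
  100 * weight_g / length_cm^3
}

#' Hepatosomatic index
#'
#' `HSI = 100 * liver (mg) / (total weight (mg) - liver (mg))`.
#'
#' @param liver_mg Liver weight in mg (>= 0).
#' @param total_mg Total body weight in mg (> liver weight).
#' @return HSI, vectorized.
#' @export
hepatosomatic_index <- function(liver_mg, total_mg) {
  if (any(liver_mg < 0)) stop("liver weight must be >= 0")
  if (any(total_mg <= liver_mg)) stop("total weight must exceed liver weight")
  100 * liver_mg / (total_mg - liver_mg)
}

#' Brain-body ratio
#'
#' `BBR = 100 * brain (mg) / (total weight (mg) - liver (mg))`; the
#' denominator nets out the liver weight, matching the HSI denominator.
#'
#' @param brain_mg Brain weight in mg (> 0).
#' @param total_mg Total body weight in mg (> liver weight).
#' @param liver_mg Liver weight in mg (>= 0).
#' @return BBR, vectorized.
#' @export
brain_body_ratio <- function(brain_mg, total_mg, liver_mg) {
  if (any(brain_mg <= 0)) stop("brain weight must be positive")
  if (any(liver_mg < 0)) stop("liver weight must be >= 0")
  if (any(total_mg <= liver_mg)) stop("total weight must exceed liver weight")
  100 * brain_mg / (total_mg - liver_mg)
}

#' Derive health indices for a metrics table
#'
#' Adds `k`, `hsi` and `bbr` columns from the raw measures
#' (`weight_g`, `fork_length_cm`, `liver_mg`, `brain_mg`).
#'
#' @param metrics Data frame from [simulate_fish_metrics()] or equivalent.
#' @return The table with the derived columns appended.
#' @export
derive_health_indices <- function(metrics) {
  total_mg <- metrics$weight_g * 1000
  metrics$k <- condition_factor(metrics$weight_g, metrics$fork_length_cm)
  metrics$hsi <- hepatosomatic_index(metrics$liver_mg, total_mg)
  metrics$bbr <- brain_body_ratio(metrics$brain_mg, total_mg, metrics$liver_mg)
  metrics
}

#' Tank-position behaviour tests
#'
#' For each tank zone (bottom, middle, top) and assessment period
#' (spawning, feeding, general), a linear model of the per-session zone
#' count on exposure, sex and week, with days treated as independent
#' observations. Two analyses are available: the exposure ANOVA over the
#' three dose groups (F test for the 3-level factor) and the control
#' contrast regression over the water and vehicle groups (t test for the
#' 2-level factor). The Bonferroni threshold divides `alpha` by the number
#' of tests actually run (18 when both analyses cover all 9 zone-period
#' combinations).
#'
#' @param records Behaviour table (`fish_id`, `session_type`, `day`,
#'   `bottom`, `middle`, `top`).
#' @param design Sample design with `fish_id`, `exposure`, `sex`, `week`.
#' @param analyses Which analyses to run: `"anova"` (dose groups) and/or
#'   `"contrast"` (water vs vehicle).
#' @param dose_groups Exposure levels of the dose ANOVA (default: all
#'   non-water levels).
#' @param contrast_groups The two levels of the control contrast.
#' @param alpha Family-wise error rate.
#' @return Data frame: `zone`, `session`, `analysis`, `statistic`, `p`,
#'   `significant`; attributes `bonferroni` and `n_tests`.
#' @export
behaviour_tests <- function(records, design,
                            analyses = c("anova", "contrast"),
                            dose_groups = NULL,
                            contrast_groups = c("water", "control"),
                            alpha = 0.05) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  merged <- merge(records, design[, c("fish_id", "exposure", "sex", "week")],
                  by = "fish_id")
  if (nrow(merged) < nrow(records)) {
    warning("dropped ", nrow(records) - nrow(merged),
            " behaviour record(s) without a design entry")
  }
  if (is.null(dose_groups)) {
    dose_groups <- setdiff(levels(design$exposure), "water")
  }
  if ("contrast" %in% analyses &&
      !all(contrast_groups %in% levels(design$exposure))) {
    analyses <- setdiff(analyses, "contrast")
  }
  zones <- c("bottom", "middle", "top")
  sessions <- unique(merged$session_type)
  rows <- list()
  for (zone in zones) {
    for (sess in sessions) {
      sub <- merged[merged$session_type == sess, ]
      if (anyNA(sub[, c(zone, "exposure", "sex", "week")])) {
        warning("missing values in ", zone, "/", sess, "; rows excluded")
        sub <- sub[stats::complete.cases(sub[, c(zone, "exposure", "sex", "week")]), ]
      }
      if ("anova" %in% analyses) {
        d <- droplevels(sub[sub$exposure %in% dose_groups, ])
        if (stats::var(d[[zone]]) == 0) {
          # constant response: no detectable exposure effect
          stat <- 0; p <- 1
        } else {
          full <- stats::lm(stats::reformulate(c("exposure", "sex", "week"),
                                               response = zone), data = d)
          red <- stats::lm(stats::reformulate(c("sex", "week"),
                                              response = zone), data = d)
          an <- stats::anova(red, full)
          stat <- an$F[2]; p <- an$`Pr(>F)`[2]
        }
        rows[[length(rows) + 1]] <- data.frame(
          zone = zone, session = sess, analysis = "anova",
          statistic = stat, p = p, stringsAsFactors = FALSE)
      }
      if ("contrast" %in% analyses) {
        d <- droplevels(sub[sub$exposure %in% contrast_groups, ])
        d$exposure <- factor(as.character(d$exposure), levels = contrast_groups)
        if (stats::var(d[[zone]]) == 0) {
          stat <- 0; p <- 1
        } else {
          fit <- stats::lm(stats::reformulate(c("exposure", "sex", "week"),
                                              response = zone), data = d)
          sm <- stats::coef(summary(fit))
          cn <- paste0("exposure", contrast_groups[2])
          stat <- sm[cn, "t value"]; p <- sm[cn, "Pr(>|t|)"]
        }
        rows[[length(rows) + 1]] <- data.frame(
          zone = zone, session = sess, analysis = "contrast",
          statistic = stat, p = p, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  thr <- bonferroni_threshold(nrow(res), alpha)
  res$significant <- res$p < thr
  attr(res, "bonferroni") <- thr
  attr(res, "n_tests") <- nrow(res)
  res
}

#' Fish health-metric tests
#'
#' Per metric (weight, fork length, k, HSI, BBR) and per sex: the exposure
#' ANOVA over the dose groups with week as a covariate (F test for the
#' 3-level exposure factor), and optionally the water-vs-vehicle control
#' contrast by linear regression.
#'
#' @param metrics Metrics table including derived indices (see
#'   [derive_health_indices()]).
#' @param design Sample design with `fish_id`, `exposure`, `sex`, `week`.
#' @param metric_cols Metric columns to test.
#' @param analyses `"anova"` and/or `"contrast"`.
#' @param dose_groups,contrast_groups As in [behaviour_tests()].
#' @return Data frame: `metric`, `sex`, `analysis`, `statistic`, `p`.
#' @export
health_tests <- function(metrics, design,
                         metric_cols = c("weight_g", "fork_length_cm",
                                         "k", "hsi", "bbr"),
                         analyses = c("anova", "contrast"),
                         dose_groups = NULL,
                         contrast_groups = c("water", "control")) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  merged <- merge(metrics, design[, c("fish_id", "exposure", "sex", "week")],
                  by = "fish_id")
  if (is.null(dose_groups)) {
    dose_groups <- setdiff(levels(design$exposure), "water")
  }
  if ("contrast" %in% analyses &&
      !all(contrast_groups %in% levels(design$exposure))) {
    analyses <- setdiff(analyses, "contrast")
  }
  rows <- list()
  for (metric in metric_cols) {
    for (sx in levels(droplevels(merged$sex))) {
      sub <- merged[merged$sex == sx, ]
      if (stats::var(sub[[metric]]) == 0) {
        stop("metric '", metric, "' is constant; the ANOVA is degenerate")
      }
      if ("anova" %in% analyses) {
        d <- droplevels(sub[sub$exposure %in% dose_groups, ])
        check_health_design(d)
        full <- stats::lm(stats::reformulate(c("exposure", "week"),
                                             response = metric), data = d)
        red <- stats::lm(stats::reformulate("week", response = metric), data = d)
        an <- stats::anova(red, full)
        rows[[length(rows) + 1]] <- data.frame(
          metric = metric, sex = sx, analysis = "anova",
          statistic = an$F[2], p = an$`Pr(>F)`[2], stringsAsFactors = FALSE)
      }
      if ("contrast" %in% analyses) {
        d <- droplevels(sub[sub$exposure %in% contrast_groups, ])
        d$exposure <- factor(as.character(d$exposure), levels = contrast_groups)
        check_health_design(d)
        fit <- stats::lm(stats::reformulate(c("exposure", "week"),
                                            response = metric), data = d)
        sm <- stats::coef(summary(fit))
        cn <- paste0("exposure", contrast_groups[2])
        rows[[length(rows) + 1]] <- data.frame(
          metric = metric, sex = sx, analysis = "contrast",
          statistic = sm[cn, "t value"], p = sm[cn, "Pr(>|t|)"],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

check_health_design <- function(d) {
  if (nlevels(d$exposure) < 2 || any(table(d$exposure) < 2)) {
    stop("need at least 2 fish per exposure group within each sex")
  }
  X <- stats::model.matrix(~ exposure + week, data = d)
  if (qr(X)$rank < ncol(X)) stop("singular design for the health-metric model")
}
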