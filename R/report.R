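# Descriptive and inferential summaries of a completed sweep: feature
# robustness across multiverse settings, the correlation analysis
# (standardized mixed-model coefficients for SSQ/NA, Pearson on participant
# means for depression, Benjamini-Hochberg correction), and R^2
# distribution tables.

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment: sorted p values are scaled by m/i and the
#' running minimum from the largest down is taken, capped at 1.
#'
#' @param p Numeric vector of raw p values.
#' @return Adjusted p values in the original order.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Correlation analysis across features and outcomes
#'
#' For each feature x SSQ/NA pair (per sensor config and k): the
#' standardized fixed-effect coefficient from a random-intercept mixed
#' model of the standardized outcome on the standardized feature, with a
#' likelihood-ratio p value.  For depression: Pearson correlation on
#' participant mean features.  All p values are Benjamini-Hochberg
#' adjusted jointly.
#'
#' @param features Feature table from [compute_feature_table()].
#' @param outcomes An `outcome_table`.
#' @param configs Sensor config ids to analyse (default: all present).
#' @param k Run-length value to analyse.
#' @return `data.table` of correlation entries (feature, outcome, sensor,
#'   coefficient, p, p_adjusted, source, significant at adjusted p < .05).
#' @export
correlation_analysis <- function(features, outcomes,
                                 configs = NULL, k = 3L) {
  f <- data.table::as.data.table(features)[k_adjacent == k]
  if (is.null(configs)) configs <- unique(f$config_id)
  entries <- list(); e <- 0L
  daily <- outcomes$daily
  for (cid in configs) {
    fc <- f[config_id == cid]
    fc <- data.table::copy(fc)[, day := night_date + 1L]
    joined <- merge(fc, daily, by = c("participant_id", "day"))
    for (feat in intersect(FEATURES, names(fc))) {
      for (oc in c("ssq", "na")) {
        d <- joined[!is.na(get(feat)) & !is.na(get(oc)),
                    .(participant_id, x = get(feat), y = get(oc))]
        if (nrow(d) < 10L || sd(d$x) == 0 || sd(d$y) == 0) next
        d[, `:=`(x = as.numeric(scale(x)), y = as.numeric(scale(y)))]
        ans <- tryCatch({
          m1 <- lme4::lmer(y ~ x + (1 | participant_id), data = d,
                           REML = FALSE)
          m0 <- lme4::lmer(y ~ 1 + (1 | participant_id), data = d,
                           REML = FALSE)
          list(coefficient = lme4::fixef(m1)[["x"]],
               p = anova(m0, m1)[2L, "Pr(>Chisq)"])
        }, error = function(err) NULL, warning = function(w) NULL)
        if (is.null(ans)) next
        e <- e + 1L
        entries[[e]] <- data.table::data.table(
          feature = feat, outcome = oc, sensor = cid,
          coefficient = ans$coefficient, p = ans$p, source = "mixed model")
      }
      # depression: Pearson on participant means
      pm <- fc[!is.na(get(feat)),
               .(x = mean(get(feat))), by = participant_id]
      pm <- merge(pm, outcomes$participants, by = "participant_id")
      if (nrow(pm) >= 5L && sd(pm$x) > 0 && sd(pm$depression) > 0) {
        ct <- cor.test(pm$x, pm$depression)
        e <- e + 1L
        entries[[e]] <- data.table::data.table(
          feature = feat, outcome = "depression", sensor = cid,
          coefficient = unname(ct$estimate), p = ct$p.value,
          source = "pearson")
      }
    }
  }
  if (e == 0L) return(data.table::data.table())
  tab <- data.table::rbindlist(entries)
  tab[, p_adjusted := bh_adjust(p)]
  tab[, significant := p_adjusted < 0.05]
  tab[]
}

#' Feature robustness across multiverse settings
#'
#' For each feature and sensor: the distribution (quartiles and whiskers)
#' over multiverse settings (k and outlier method) of the across-night mean
#' feature value.  This quantifies robustness to analysis choices, not
#' across-participant variance.  UserActive is excluded from the per-sensor
#' breakdown because it varies with no multiverse parameter except outlier
#' handling.
#'
#' @param features Feature table.
#' @param outlier_methods Outlier kinds to include as settings.
#' @return `data.table` with one row per feature x sensor and columns
#'   q1/median/q3/lo/hi over settings.
#' @export
feature_distribution_summary <- function(features,
                                         outlier_methods = OUTLIER_KINDS) {
  f <- data.table::as.data.table(features)
  per_setting <- list(); i <- 0L
  for (om in outlier_methods) {
    for (feat in setdiff(intersect(FEATURES, names(f)), "user_active")) {
      kept <- suppressWarnings(remove_outliers(f, feat, om)$kept)
      i <- i + 1L
      per_setting[[i]] <- kept[!is.na(get(feat)),
                               .(feature = feat, outlier = om,
                                 value = mean(get(feat))),
                               by = .(config_id, k_adjacent)]
    }
  }
  ps <- data.table::rbindlist(per_setting)
  ps[, {
    q <- quantile(value, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    .(lo = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L], hi = q[5L],
      n_settings = .N)
  }, by = .(feature, config_id)]
}

#' R-squared distributions across the sweep
#'
#' Quartiles of train and validation R-squared grouped by model kind
#' crossed with sensor, and by model kind crossed with feature.  Groups
#' partition all operable results.
#'
#' @param results Sweep results from [run_multiverse()].
#' @return List with `by_sensor` and `by_feature` tables.
#' @export
r2_distribution_summary <- function(results) {
  res <- data.table::as.data.table(results)[status == "ok"]
  summarize <- function(g) {
    res[, {
      qv <- quantile(r2_validation, c(0.25, 0.5, 0.75), names = FALSE,
                     na.rm = TRUE)
      qt <- quantile(r2_train, c(0.25, 0.5, 0.75), names = FALSE,
                     na.rm = TRUE)
      .(n = .N, r2_val_q1 = qv[1L], r2_val_median = qv[2L],
        r2_val_q3 = qv[3L], r2_train_q1 = qt[1L], r2_train_median = qt[2L],
        r2_train_q3 = qt[3L])
    }, by = g]
  }
  list(by_sensor = summarize(c("outcome", "model", "sensor")),
       by_feature = summarize(c("outcome", "model", "feature")))
}
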