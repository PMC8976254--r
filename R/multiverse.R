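# The multiverse: enumerate the 12,600-point grid of analysis choices, run
# the hold-out workflow (train week 1; validate days 8-11; test days 12-14;
# participant-level 60/20/20 stratified split for depression), select up to
# five models within one standard error of the best, and evaluate them on
# the test set.

MODEL_COMPLEXITY <- c(mixed_effects = 1, linear = 1, knn = 2,
                      gam_splines = 3, svm_radial = 4, xgboost = 5)

#' Enumerate the multiverse grid
#'
#' Cartesian product of sensor configurations (10), features (7), outcomes
#' (3), model kinds (5), outlier methods (4) and run lengths k (3):
#' 12,600 combinations under the defaults, in deterministic order.
#'
#' @param sensors,features,outcomes,models,outlier_methods,k_adjacent
#'   Value sets for each multiverse axis.
#' @return A `data.table` with one row per configuration and a `config_id`
#'   ordinal.
#' @export
enumerate_grid <- function(sensors = sensor_configs()$config_id,
                           features = FEATURES,
                           outcomes = OUTCOMES,
                           models = MODEL_KINDS,
                           outlier_methods = OUTLIER_KINDS,
                           k_adjacent = K_ADJACENT) {
  g <- data.table::CJ(sensor = sensors, feature = features, outcome = outcomes,
                      model = models, outlier = outlier_methods,
                      k = as.integer(k_adjacent), sorted = FALSE)
  g[, config_id := .I]
  data.table::setcolorder(g, "config_id")
  g[]
}

#' Longitudinal train/validation/test split
#'
#' Assigns each row a study day on the participant's own clock (1 = the
#' participant's first observed day) and splits: days 1-7 train, 8-11
#' validation, 12-14 test.
#'
#' @param rows `data.table` with `participant_id` and a date column.
#' @param date_col Name of the date column.
#' @param split_days Named list of day-index vectors; the default is the
#'   two-week design and requires the data to span 14 days.
#' @return The rows with columns `day_idx` and `split` added.
#' @export
split_longitudinal <- function(rows, date_col = "night_date",
                               split_days = list(train = 1:7,
                                                 validation = 8:11,
                                                 test = 12:14)) {
  out <- data.table::copy(data.table::as.data.table(rows))
  out[, day_idx := as.integer(get(date_col) - min(get(date_col))) + 1L,
      by = participant_id]
  span <- max(unlist(split_days))
  if (max(out$day_idx) < span && identical(names(split_days),
                                           c("train", "validation", "test")) &&
      span == 14L)
    stop(sprintf("rows span only %d days; the default split needs 14 (pass a custom split_days)",
                 max(out$day_idx)))
  out[, split := NA_character_]
  for (s in names(split_days)) out[day_idx %in% split_days[[s]], split := s]
  out[]
}

# Largest-remainder integer allocation of n into proportions p.
allocate_counts <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Participant-level stratified split for depression
#'
#' 60/20/20 train/validation/test, stratified by gender with
#' largest-remainder rounding within each gender, after a seeded shuffle.
#'
#' @param participants `data.table` with `participant_id` and `gender`.
#' @param seed Integer seed for the shuffle.
#' @param props Train/validation/test proportions.
#' @return The participants table with a `split` column.
#' @export
split_depression <- function(participants, seed = 1L,
                             props = c(train = 0.6, validation = 0.2,
                                       test = 0.2)) {
  pp <- data.table::copy(data.table::as.data.table(participants))
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)
  pp[, split := {
    counts <- allocate_counts(.N, props)
    sample(rep(names(props), counts))
  }, by = gender]
  pp[]
}

# Assemble the modelling rows for one configuration: feature rows under the
# sensor config and k, outlier handling, outcome join and split assignment.
# The isolation forest is feature-independent, so its kept set is shared
# across the configs of one (sensor, k) slice via `cache`.
assemble_config_rows <- function(config, features, outcomes, seed,
                                 iso_seed = derive_seed(seed, 7L),
                                 cache = NULL) {
  f <- features[config_id == config$sensor & k_adjacent == config$k]
  if (config$outlier == "isolation_forest") {
    key <- paste(config$sensor, config$k, sep = "|")
    if (!is.null(cache) && !is.null(cache[[key]])) {
      f <- cache[[key]]
    } else {
      f <- suppressWarnings(
        remove_outliers(f, config$feature,
                        outlier_method("isolation_forest", seed = iso_seed))$kept)
      if (!is.null(cache)) cache[[key]] <- f
    }
  } else {
    om <- outlier_method(config$outlier, seed = iso_seed)
    f <- suppressWarnings(remove_outliers(f, config$feature, om)$kept)
  }
  if (config$outcome == "depression") {
    pm <- f[, lapply(.SD, function(v) mean(v, na.rm = TRUE)),
            by = participant_id,
            .SDcols = intersect(FEATURES, names(f))]
    rows <- merge(pm, outcomes$participants, by = "participant_id")
    rows[, y := depression]
    sp <- split_depression(rows[, .(participant_id, gender)],
                           seed = derive_seed(seed, 11L))
    rows <- merge(rows, sp[, .(participant_id, split)], by = "participant_id")
  } else {
    daily <- outcomes$daily[, .(participant_id, day,
                                y = get(config$outcome))]
    f[, day := night_date + 1L]  # night d pairs with morning/day d+1
    rows <- merge(f, daily, by = c("participant_id", "day"))
    rows <- split_longitudinal(rows, date_col = "night_date")
  }
  rows[!is.na(y) & !is.na(rows[[config$feature]])]
}

# Fit + evaluate one configuration; returns a result list.
eval_config <- function(config, features, outcomes, seed = 1L,
                        iso_seed = derive_seed(seed, 7L),
                        with_test = FALSE, return_rows = FALSE,
                        cache = NULL) {
  res <- c(as.list(config),
           list(n_train = 0L, n_validation = 0L, n_test = 0L,
                r2_train = NA_real_, r2_validation = NA_real_,
                r2_test = NA_real_, slope = NA_real_,
                slope_lo = NA_real_, slope_hi = NA_real_,
                status = "inoperable", note = "",
                val_obs = list(numeric()), val_pred = list(numeric())))
  kind <- if (config$outcome == "depression" &&
              config$model == "mixed_effects") "linear" else config$model
  rows <- tryCatch(assemble_config_rows(config, features, outcomes, seed,
                                        iso_seed = iso_seed, cache = cache),
                   error = function(e) { res$note <<- conditionMessage(e); NULL })
  if (is.null(rows) || nrow(rows) == 0L) {
    res$note <- if (nzchar(res$note)) res$note else "no rows"
    return(res)
  }
  tr <- rows[split == "train"]
  va <- rows[split == "validation"]
  te <- rows[split == "test"]
  res$n_train <- nrow(tr); res$n_validation <- nrow(va); res$n_test <- nrow(te)
  if (nrow(tr) < 5L || nrow(va) < 2L) { res$note <- "too few rows"; return(res) }
  fit <- tryCatch(fit_model(kind, tr, config$feature, "y",
                            seed = derive_seed(seed, 13L)),
                  error = function(e) { res$note <<- conditionMessage(e); NULL })
  if (is.null(fit) || fit$status != "ok") {
    res$note <- if (!is.null(fit)) fit$note %||% "fit failed" else res$note
    return(res)
  }
  out <- tryCatch({
    pr_tr <- predict(fit, tr)
    pr_va <- predict(fit, va)
    res$r2_train <- predicted_r2(tr$y, pr_tr)
    res$r2_validation <- predicted_r2(va$y, pr_va)
    res$slope <- fit$slope
    res$slope_lo <- fit$slope_ci[1L]; res$slope_hi <- fit$slope_ci[2L]
    res$val_obs <- list(va$y); res$val_pred <- list(pr_va)
    if (with_test && nrow(te) >= 2L)
      res$r2_test <- predicted_r2(te$y, predict(fit, te))
    res$status <- "ok"
    res
  }, error = function(e) { res$note <- conditionMessage(e); res })
  if (return_rows) out$rows <- rows
  out
}

#' Run the multiverse sweep
#'
#' Evaluates every configuration on the train/validation split.  Failures
#' (empty training sets, non-convergent mixed models, degenerate
#' predictors) are recorded as `status = "inoperable"` and never crash the
#' sweep.  Results are independent of evaluation order and reproducible
#' under a fixed seed.
#'
#' @param configs Grid rows from [enumerate_grid()].
#' @param features Feature table from [compute_feature_table()].
#' @param outcomes An `outcome_table`.
#' @param seed Integer seed (per-config child seeds are derived from it).
#' @param progress Print a heartbeat every 1,000 configurations.
#' @return `data.table` of one `EvalResult` row per configuration, with
#'   validation observation/prediction pairs as list columns (used by the
#'   1-SE bootstrap).
#' @export
run_multiverse <- function(configs, features, outcomes, seed = 1L,
                           progress = FALSE) {
  configs <- data.table::as.data.table(configs)
  features <- data.table::as.data.table(features)
  out <- vector("list", nrow(configs))
  iso_seed <- derive_seed(seed, 7L)   # one forest per (sensor, k) data slice
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(configs))) {
    cfg <- as.list(configs[i])
    out[[i]] <- eval_config(cfg, features, outcomes,
                            seed = derive_seed(seed, cfg$config_id),
                            iso_seed = iso_seed, cache = cache)
    if (progress && i %% 1000L == 0L)
      message(sprintf("multiverse: %d/%d configurations", i, nrow(configs)))
  }
  data.table::rbindlist(out, use.names = TRUE)
}

#' Bootstrap standard error of a validation R-squared
#'
#' Nonparametric bootstrap over the validation (observed, predicted) pairs;
#' resamples with a constant observed vector (R^2 undefined) are skipped.
#' This is the pluggable definition of "1 SE" used by [select_one_se()].
#'
#' @param obs,pred Validation observations and predictions.
#' @param n_boot Number of resamples.
#' @param seed Seed.
#' @return Standard deviation of the bootstrap R-squared distribution.
#' @export
bootstrap_r2_se <- function(obs, pred, n_boot = 1000L, seed = 1L) {
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)
  n <- length(obs)
  r2 <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    if (length(unique(obs[i])) < 2L) next
    r2[b] <- predicted_r2(obs[i], pred[i])
  }
  if (all(is.na(r2))) return(0)
  sd(r2, na.rm = TRUE)
}

#' One-standard-error model selection
#'
#' For one outcome's results: the best model is the operable configuration
#' with the highest validation R-squared; its SE is estimated by a seeded
#' bootstrap over its validation residual pairs; every configuration with
#' validation R-squared within one SE of the best is selected, capped at
#' five, ties broken by simpler model kind then configuration order.
#'
#' @param results Sweep results for a single outcome.
#' @param n_boot,seed Bootstrap settings.
#' @return The selected result rows (<= 5), best first, with an `se`
#'   attribute.
#' @export
select_one_se <- function(results, n_boot = 1000L, seed = 1L) {
  res <- data.table::as.data.table(results)
  stopifnot(length(unique(res$outcome)) <= 1L)
  ok <- res[status == "ok" & !is.na(r2_validation)]
  if (nrow(ok) == 0L) {
    warning("no operable results; empty selection")
    return(ok)
  }
  data.table::setorder(ok, -r2_validation)
  best <- ok[1L]
  se <- bootstrap_r2_se(best$val_obs[[1L]], best$val_pred[[1L]],
                        n_boot = n_boot, seed = seed)
  cand <- ok[r2_validation >= best$r2_validation - se]
  cand[, .complexity := MODEL_COMPLEXITY[model]]
  data.table::setorder(cand, -r2_validation, .complexity, config_id)
  cand[, .complexity := NULL]
  sel <- head(cand, 5L)
  data.table::setattr(sel, "se", se)
  sel[]
}

#' Evaluate selected models on the test set
#'
#' Refits each selected configuration on its training rows only (the same
#' derived seed as the sweep, so the fit is identical) and reports test
#' R-squared plus slope and 95% CI for mixed/linear fits.
#'
#' @param selected Rows returned by [select_one_se()].
#' @param features,outcomes The same inputs given to [run_multiverse()].
#' @param seed The sweep seed.
#' @return Final table with `r2_test` filled.
#' @export
evaluate_selected <- function(selected, features, outcomes, seed = 1L) {
  sel <- data.table::as.data.table(selected)
  features <- data.table::as.data.table(features)
  out <- vector("list", nrow(sel))
  cfg_cols <- c("config_id", "sensor", "feature", "outcome", "model",
                "outlier", "k")
  iso_seed <- derive_seed(seed, 7L)   # matches the sweep's shared forest
  for (i in seq_len(nrow(sel))) {
    cfg <- as.list(sel[i, cfg_cols, with = FALSE])
    out[[i]] <- eval_config(cfg, features, outcomes,
                            seed = derive_seed(seed, cfg$config_id),
                            iso_seed = iso_seed, with_test = TRUE)
  }
  data.table::rbindlist(out, use.names = TRUE)
}
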