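# Grid enumeration, splits, sweep robustness, 1-SE selection, leakage.

test_that("the default grid has 12,600 points and 21 feature-outcome pairs", {
  g <- enumerate_grid()
  expect_equal(nrow(g), 12600L)
  expect_equal(nrow(unique(g[, .(feature, outcome)])), 21L)
  expect_equal(nrow(enumerate_grid(outcomes = "ssq")), 4200L)
  expect_equal(anyDuplicated(g$config_id), 0L)
  # deterministic order
  expect_identical(g, enumerate_grid())
})

test_that("the longitudinal split follows the per-participant study clock", {
  rows <- data.table(participant_id = rep(c("a", "b"), each = 14),
                     night_date = c(as.Date("2018-03-05") + 0:13,
                                    as.Date("2018-03-07") + 0:13))
  sp <- split_longitudinal(rows)
  expect_equal(sp[participant_id == "a" & day_idx == 8, split], "validation")
  expect_equal(sp[participant_id == "a" & day_idx == 12, split], "test")
  expect_equal(sp[day_idx == 7, unique(split)], "train")
  # partition: every row in exactly one split
  expect_false(anyNA(sp$split))
  expect_equal(nrow(sp), nrow(rows))
  # participant b's clock starts at their own first day
  expect_equal(sp[participant_id == "b" & night_date == as.Date("2018-03-07"),
                  day_idx], 1L)
  # too-short span errors unless a custom split is configured
  short <- rows[night_date <= as.Date("2018-03-12")]
  expect_error(split_longitudinal(short), "span")
  custom <- split_longitudinal(short, split_days = list(train = 1:4,
                                                        validation = 5:6,
                                                        test = 7:8))
  expect_false(anyNA(custom$split))
})

test_that("the depression split is stratified 60/20/20 by gender", {
  pp <- data.table(participant_id = sprintf("p%02d", 1:50),
                   gender = rep(c("M", "F"), c(14, 36)))
  sp <- split_depression(pp, seed = 9)
  tab <- sp[, .N, by = split]
  expect_equal(tab[split == "train", N], 30L)
  expect_equal(tab[split == "validation", N], 10L)
  expect_equal(tab[split == "test", N], 10L)
  # per-gender largest-remainder counts
  expect_equal(sp[gender == "M" & split == "train", .N], 8L)
  expect_equal(sp[gender == "F" & split == "train", .N], 22L)
  # same seed, same split; all-one-gender degenerates to plain 60/20/20
  expect_identical(sp, split_depression(pp, seed = 9))
  one <- split_depression(pp[gender == "F"], seed = 3)
  expect_equal(one[split == "train", .N], 22L)
})

test_that("a small sweep runs, records failures, and is order-independent", {
  p <- tiny_params(n_participants = 8L, n_days = 14L)
  sch <- simulate_schedules(p)
  ev <- preprocess_events(simulate_sensor_streams(sch, p))$events
  feats <- compute_feature_table(
    ev, configs = sensor_configs()[config_id %in% c("charging", "light_8")],
    k_values = c(3L, 4L))
  oc <- simulate_outcomes(sch, p)
  grid <- enumerate_grid(sensors = c("charging", "light_8"),
                         features = c("sleep_time", "n_interruptions"),
                         outcomes = c("ssq", "na"),
                         models = c("mixed_effects", "knn"),
                         outlier_methods = c("none", "median_3mad"),
                         k_adjacent = c(3L, 4L))
  res <- run_multiverse(grid, feats, oc, seed = 5)
  expect_equal(nrow(res), nrow(grid))
  expect_true(all(res$status %in% c("ok", "inoperable")))
  expect_true(all(res$r2_validation[res$status == "ok"] <= 1))
  # determinism and order independence
  res2 <- run_multiverse(grid[rev(seq_len(.N))], feats, oc, seed = 5)
  data.table::setorder(res2, config_id)
  expect_equal(res[, .(config_id, r2_train, r2_validation, slope)],
               res2[, .(config_id, r2_train, r2_validation, slope)])
  # a config whose feature is entirely missing is inoperable, not fatal
  feats_broken <- data.table::copy(feats)[, n_interruptions := NA_integer_]
  res3 <- run_multiverse(grid[feature == "n_interruptions" & config_id <= grid$config_id[4]],
                         feats_broken, oc, seed = 5)
  expect_true(all(res3$status == "inoperable"))
})

test_that("one-SE selection caps at five and handles degenerate cases", {
  mk_res <- function(r2s) {
    n <- length(r2s)
    data.table(config_id = seq_len(n), sensor = "charging",
               feature = "sleep_time", outcome = "ssq",
               model = rep(c("xgboost", "mixed_effects"), length.out = n),
               outlier = "none", k = 3L, r2_validation = r2s, status = "ok",
               val_obs = rep(list(c(1, 2, 3, 4)), n),
               val_pred = rep(list(c(1.1, 1.9, 3.2, 3.8)), n))
  }
  # single operable result -> selected
  one <- select_one_se(mk_res(0.3), seed = 1)
  expect_equal(nrow(one), 1L)
  # ten results inside one SE -> exactly five, best first
  ten <- select_one_se(mk_res(seq(0.30, 0.301, length.out = 10)), seed = 1)
  expect_equal(nrow(ten), 5L)
  expect_equal(ten$r2_validation[1], 0.301)
  # perfect fit: bootstrap SE is 0, only exact ties selected
  perfect <- mk_res(c(1, 0.99))
  perfect$val_pred <- perfect$val_obs
  sel <- select_one_se(perfect, seed = 1)
  expect_equal(attr(sel, "se"), 0)
  expect_equal(sel$r2_validation, 1)
  # all inoperable -> empty with warning
  bad <- mk_res(c(0.1, 0.2))[, status := "inoperable"]
  expect_warning(empty <- select_one_se(bad), "no operable")
  expect_equal(nrow(empty), 0L)
  # tie break prefers the simpler model kind
  tied <- mk_res(c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3))
  sel2 <- select_one_se(tied, seed = 1)
  expect_equal(sel2$model[1], "mixed_effects")
})

test_that("models never see validation or test rows (leakage fingerprint)", {
  p <- tiny_params(n_participants = 6L, n_days = 14L)
  sch <- simulate_schedules(p)
  ev <- preprocess_events(simulate_sensor_streams(sch, p))$events
  feats <- compute_feature_table(ev, configs = sensor_configs()[config_id == "charging"],
                                 k_values = 3L)
  oc <- simulate_outcomes(sch, p)
  cfg <- as.list(enumerate_grid(sensors = "charging", features = "sleep_time",
                                outcomes = "ssq", models = "mixed_effects",
                                outlier_methods = "none", k_adjacent = 3L)[1])
  res <- sleepverse:::eval_config(cfg, feats, oc, seed = 1, with_test = TRUE,
                                  return_rows = TRUE)
  rows <- res$rows
  key <- function(d) paste(d$participant_id, d$night_date)
  expect_length(intersect(key(rows[split == "train"]),
                          key(rows[split != "train"])), 0L)
  # refitting on train rows only reproduces the reported metrics exactly
  fit <- fit_model("mixed_effects", rows[split == "train"], "sleep_time", "y",
                   seed = sleepverse:::derive_seed(
                     sleepverse:::derive_seed(1, cfg$config_id), 13L))
  pv <- predict(fit, rows[split == "validation"])
  expect_equal(predicted_r2(rows[split == "validation", y], pv),
               res$r2_validation)
})
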