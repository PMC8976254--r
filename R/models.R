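# Single-predictor model fitting and the predicted-R^2 metric.
#
# Five model families share one interface: a random-intercept mixed model
# (replaced by a plain linear model for the un-nested depression outcome),
# k-nearest neighbours, a radial-kernel support vector machine in its
# least-squares form (kernel ridge), gradient-boosted trees, and a
# smoothing-spline GAM.  Hyperparameters are chosen by internal 5-fold
# cross-validation over small fixed grids on the training set.

KNN_GRID <- c(3L, 5L, 7L, 9L, 15L)
SVM_COST_GRID <- c(0.25, 1, 4)
XGB_DEPTH_GRID <- c(2L, 3L)
XGB_TREES <- 100L
XGB_LR <- 0.1
GAM_BASIS_GRID <- c(5L, 10L)

#' Out-of-sample (predicted) R-squared
#'
#' `1 - sum((Y - Yhat)^2) / sum((Y - mean(Y))^2)` where the mean is taken
#' over the observed values of the evaluation set.  Can be negative when
#' predictions are worse than the held-out mean; always at most 1.
#'
#' @param observed,predicted Equal-length numeric vectors, >= 2 values.
#' @return A real number <= 1.
#' @export
predicted_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (length(observed) < 2L) stop("need at least 2 observations")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("predicted R^2 undefined for constant observed values")
  1 - sum((observed - predicted)^2) / sst
}

cv_folds <- function(n, folds = 5L, seed = 1L) {
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

cv_rmse <- function(x, y, folds, predict_fun) {
  pred <- numeric(length(y))
  for (f in unique(folds)) {
    i <- folds == f
    if (length(unique(x[!i])) < 2L) return(Inf)
    pred[i] <- predict_fun(x[!i], y[!i], x[i])
  }
  sqrt(mean((y - pred)^2))
}

knn_predict <- function(x_tr, y_tr, x_new, k) {
  knn_predict_multi(x_tr, y_tr, x_new, k)[, 1L]
}

# Predictions for several k at once: one distance sort per query point.
knn_predict_multi <- function(x_tr, y_tr, x_new, ks) {
  ks <- pmin(ks, length(x_tr))
  kmax <- max(ks)
  out <- matrix(0, length(x_new), length(ks))
  for (i in seq_along(x_new)) {
    d <- abs(x_tr - x_new[i])
    nn <- y_tr[order(d)[seq_len(kmax)]]
    cm <- cumsum(nn) / seq_len(kmax)
    out[i, ] <- cm[ks]
  }
  out
}

# Median-heuristic RBF bandwidth on the training feature.
rbf_gamma <- function(x) {
  xs <- if (length(x) > 400L) sort(x)[round(seq(1, length(x), length.out = 400L))] else x
  d <- abs(outer(xs, xs, "-"))
  med <- median(d[upper.tri(d)])
  if (!is.finite(med) || med <= 0) med <- sd(x)
  if (med <= 0) med <- 1
  1 / (2 * med^2)
}

krr_fit <- function(x, y, gamma, lambda) {
  K <- exp(-gamma * outer(x, x, "-")^2)
  n <- length(x)
  my <- mean(y)
  alpha <- solve(K + lambda * diag(n), y - my)
  list(x = x, alpha = alpha, gamma = gamma, my = my)
}

krr_predict <- function(fit, x_new) {
  Kn <- exp(-fit$gamma * outer(x_new, fit$x, "-")^2)
  drop(Kn %*% fit$alpha) + fit$my
}

#' Fit one single-predictor model
#'
#' @param kind One of `"mixed_effects"`, `"linear"`, `"knn"`,
#'   `"svm_radial"`, `"xgboost"`, `"gam_splines"`.
#' @param train Data frame / data.table of training rows.
#' @param feature,outcome Column names of the single predictor and response.
#' @param seed Seed for fold assignment and any stochastic fit.
#' @param folds Number of internal cross-validation folds.
#' @return An `sv_fit` object with fields `kind`, `status`
#'   (`"ok"`/`"inoperable"`), `slope` and `slope_ci` (mixed/linear only) and
#'   `hyper` (chosen hyperparameters); predict with [predict.sv_fit()].
#' @export
fit_model <- function(kind, train, feature, outcome, seed = 1L, folds = 5L) {
  stopifnot(kind %in% c(MODEL_KINDS, "linear"))
  tr <- data.table::as.data.table(train)
  tr <- tr[!is.na(tr[[feature]]) & !is.na(tr[[outcome]])]
  x <- tr[[feature]]; y <- tr[[outcome]]
  out <- structure(list(kind = kind, feature = feature, outcome = outcome,
                        status = "ok", slope = NA_real_,
                        slope_ci = c(NA_real_, NA_real_), hyper = list(),
                        n_train = nrow(tr)),
                   class = "sv_fit")
  if (nrow(tr) < 5L || length(unique(x)) < 2L) {
    out$status <- "inoperable"
    out$note <- "degenerate predictor"
    return(out)
  }
  out$x_center <- mean(x); out$x_scale <- sd(x)
  if (out$x_scale == 0) out$x_scale <- 1
  xs <- (x - out$x_center) / out$x_scale

  if (kind == "mixed_effects") {
    d <- data.frame(y = y, x_std = xs, participant_id = tr$participant_id)
    fit <- tryCatch({
      m <- lme4::lmer(y ~ x_std + (1 | participant_id), data = d, REML = FALSE,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular = "ignore"))
      if (length(m@optinfo$conv$lme4$messages %||% character()) > 0) stop("non-convergence")
      m
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) { out$status <- "inoperable"; out$note <- "non-convergence"; return(out) }
    out$model <- fit
    b <- lme4::fixef(fit)[["x_std"]]
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[2L]
    out$slope <- b
    out$slope_ci <- b + c(-1.96, 1.96) * se
  } else if (kind == "linear") {
    d <- data.frame(y = y, x_std = xs)
    m <- lm(y ~ x_std, data = d)
    out$model <- m
    out$slope <- coef(m)[["x_std"]]
    # suppress the "essentially perfect fit" note on exact lines
    se <- suppressWarnings(summary(m)$coefficients["x_std", "Std. Error"])
    out$slope_ci <- out$slope + c(-1.96, 1.96) * se
  } else if (kind == "knn") {
    fl <- cv_folds(length(y), folds, seed)
    grid <- KNN_GRID[KNN_GRID <= length(y) - max(table(fl))]
    if (!length(grid)) grid <- 3L
    sse <- numeric(length(grid))
    for (f in unique(fl)) {
      i <- fl == f
      pr <- knn_predict_multi(x[!i], y[!i], x[i], grid)
      sse <- sse + colSums((y[i] - pr)^2)
    }
    k <- grid[which.min(sse)]
    out$hyper <- list(k = k)
    out$train_x <- x; out$train_y <- y
  } else if (kind == "svm_radial") {
    gamma <- rbf_gamma(x)
    fl <- cv_folds(length(y), folds, seed)
    err <- vapply(SVM_COST_GRID, function(C)
      cv_rmse(x, y, fl, function(xt, yt, xn)
        krr_predict(krr_fit(xt, yt, gamma, 1 / C), xn)), 0)
    C <- SVM_COST_GRID[which.min(err)]
    out$hyper <- list(cost = C, gamma = gamma)
    out$model <- krr_fit(x, y, gamma, 1 / C)
  } else if (kind == "xgboost") {
    fl <- cv_folds(length(y), folds, seed)
    err <- vapply(XGB_DEPTH_GRID, function(dep)
      cv_rmse(x, y, fl, function(xt, yt, xn)
        .boost_fit_predict(xt, yt, xn, dep, XGB_TREES, XGB_LR, 5L)$test), 0)
    dep <- XGB_DEPTH_GRID[which.min(err)]
    out$hyper <- list(depth = dep, n_trees = XGB_TREES, learning_rate = XGB_LR)
    out$train_x <- x; out$train_y <- y
  } else if (kind == "gam_splines") {
    # with one predictor a spline GAM is a smoothing spline; the basis-size
    # grid becomes an equivalent-df grid, capped by the number of distinct
    # values (degenerates to a linear fit below 4 distinct values)
    fl <- cv_folds(length(y), folds, seed)
    grid <- unique(pmin(GAM_BASIS_GRID, length(unique(x)) - 1L))
    grid <- grid[grid >= 2L]
    if (!length(grid) || length(unique(x)) < 4L) {
      m <- lm(y ~ x, data = data.frame(x = x, y = y))
      out$hyper <- list(df = NA_integer_, degenerate = TRUE)
      out$model <- m
      return(out)
    }
    err <- vapply(grid, function(df)
      cv_rmse(x, y, fl, function(xt, yt, xn) {
        m <- tryCatch(ss_fit(xt, yt, df), error = function(e) NULL)
        if (is.null(m)) rep(mean(yt), length(xn)) else ss_predict(m, xn)
      }), 0)
    df <- grid[which.min(err)]
    out$hyper <- list(df = df)
    m <- tryCatch(ss_fit(x, y, df), error = function(e) NULL)
    if (is.null(m)) { out$status <- "inoperable"; out$note <- "spline failure"; return(out) }
    out$model <- m
  }
  out
}

# Smoothing-spline fit guarded against degenerate df.
ss_fit <- function(x, y, df) {
  df <- min(df, length(unique(x)) - 1L)
  stats::smooth.spline(x, y, df = max(df, 2L), cv = FALSE)
}

ss_predict <- function(fit, x_new) predict(fit, x_new)$y

#' Predict from a fitted single-predictor model
#'
#' @param object An `sv_fit`.
#' @param newdata Data frame with the feature column (and `participant_id`
#'   for mixed models; unseen participants get the population level).
#' @param ... Unused.
#' @return Numeric predictions (NA where the feature is missing).
#' @export
predict.sv_fit <- function(object, newdata, ...) {
  if (object$status != "ok") stop("cannot predict from an inoperable fit")
  x <- newdata[[object$feature]]
  pred <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  if (!any(ok)) return(pred)
  xs <- (x[ok] - object$x_center) / object$x_scale
  pred[ok] <- switch(object$kind,
    mixed_effects = predict(object$model,
                            newdata = data.frame(x_std = xs,
                                                 participant_id = newdata$participant_id[ok]),
                            allow.new.levels = TRUE),
    linear = predict(object$model, newdata = data.frame(x_std = xs)),
    knn = knn_predict(object$train_x, object$train_y, x[ok], object$hyper$k),
    svm_radial = krr_predict(object$model, x[ok]),
    xgboost = .boost_fit_predict(object$train_x, object$train_y, x[ok],
                                 object$hyper$depth, object$hyper$n_trees,
                                 object$hyper$learning_rate, 5L)$test,
    gam_splines = if (isTRUE(object$hyper$degenerate))
      predict(object$model, newdata = data.frame(x = x[ok]))
    else ss_predict(object$model, x[ok]))
  pred
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("<sv_fit %s: %s -> %s, status=%s", x$kind, x$feature,
              x$outcome, x$status))
  if (!is.na(x$slope)) cat(sprintf(", slope=%.3f", x$slope))
  cat(">\n")
  invisible(x)
}
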