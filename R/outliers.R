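# The four outlier-handling strategies applied to feature values before
# modelling: none, median +/- 3 SD per participant, median +/- 3 MAD per
# participant (MAD unscaled), and a pooled multivariate isolation forest.

#' Outlier method descriptor
#'
#' @param kind One of `"none"`, `"median_3sd"`, `"median_3mad"`,
#'   `"isolation_forest"`.
#' @param contamination Fraction removed by the isolation forest.
#' @param seed Seed for the isolation forest's randomized trees.
#' @return An `outlier_method` object.
#' @export
outlier_method <- function(kind = c("none", "median_3sd", "median_3mad",
                                    "isolation_forest"),
                           contamination = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  assert_prob(contamination, "contamination")
  structure(list(kind = kind, contamination = contamination,
                 seed = as.integer(seed)), class = "outlier_method")
}

#' Remove outlying feature values
#'
#' The median-based methods act per participant on the single feature
#' column: a value is kept when its absolute deviation from the
#' participant's median is at most 3 sample SDs (`median_3sd`) or 3
#' unscaled MADs (`median_3mad`).  Participants with fewer than 3
#' non-missing values are kept unfiltered with a warning (dispersion
#' undefined).  A zero MAD keeps only exact-median values (the literal
#' rule), with a loud warning.  The isolation forest is multivariate: it
#' scores rows jointly over all feature columns and removes the most
#' anomalous `contamination` fraction; rows with missing feature values
#' cannot be scored and are never removed by it.  `none` keeps everything.
#'
#' @param rows Feature `data.table` with a `participant_id` column.
#' @param feature Name of the feature column the model will use.
#' @param method An [outlier_method()] (or its kind as a string).
#' @param feature_cols Columns the isolation forest scores jointly
#'   (defaults to all seven features present in `rows`).
#' @return List with `kept` and `removed` (disjoint, union = input).
#' @export
remove_outliers <- function(rows, feature, method,
                            feature_cols = intersect(FEATURES, names(rows))) {
  if (is.character(method)) method <- outlier_method(method)
  stopifnot(inherits(method, "outlier_method"))
  dt <- data.table::as.data.table(rows)
  if (method$kind == "none")
    return(list(kept = dt, removed = dt[0L]))
  if (method$kind %in% c("median_3sd", "median_3mad")) {
    x <- dt[[feature]]
    keep <- rep(TRUE, nrow(dt))
    few <- FALSE; zero_mad <- FALSE
    for (p in unique(dt$participant_id)) {
      i <- which(dt$participant_id == p & !is.na(x))
      if (length(i) < 3L) { few <- few || length(i) > 0L; next }
      v <- x[i]
      ctr <- median(v)
      disp <- if (method$kind == "median_3sd") sd(v)
              else median(abs(v - ctr))          # unscaled MAD
      if (disp == 0 && method$kind == "median_3mad" && any(v != ctr))
        zero_mad <- TRUE
      keep[i] <- abs(v - ctr) <= 3 * disp
    }
    if (few)
      warning("participants with fewer than 3 non-missing values kept unfiltered")
    if (zero_mad)
      warning("zero MAD: only exact-median values kept for some participants")
    return(list(kept = dt[keep], removed = dt[!keep]))
  }
  # isolation forest, pooled over participants, multivariate
  X <- as.matrix(dt[, feature_cols, with = FALSE])
  scorable <- complete.cases(X)
  keep <- rep(TRUE, nrow(dt))
  if (sum(scorable) >= 10L) {
    sc <- isolation_score(X[scorable, , drop = FALSE], seed = method$seed)
    n_remove <- floor(sum(scorable) * method$contamination)
    if (n_remove > 0L) {
      cut <- sort(sc, decreasing = TRUE)[n_remove]
      drop <- sc >= cut
      # guard against score ties inflating past the contamination budget
      if (sum(drop) > n_remove)
        drop <- rank(-sc, ties.method = "first") <= n_remove
      keep[scorable][drop] <- FALSE
    }
  }
  list(kept = dt[keep], removed = dt[!keep])
}

# --- isolation forest ------------------------------------------------------
# Standard construction: trees grown on subsamples of size psi by splitting
# a random dimension at a random point; the anomaly score is
# 2^(-E[path length] / c(psi)).

iso_harmonic <- function(n) if (n <= 1) 0 else 2 * (log(n - 1) + 0.5772156649) -
  2 * (n - 1) / n

# Grow one tree; returns a list-of-lists node structure.
iso_tree <- function(X, depth, max_depth) {
  n <- nrow(X)
  if (n <= 1L || depth >= max_depth) return(list(size = n))
  ranges <- apply(X, 2L, range)
  splittable <- which(ranges[2L, ] > ranges[1L, ])
  if (!length(splittable)) return(list(size = n))
  d <- if (length(splittable) == 1L) splittable else sample(splittable, 1L)
  sv <- runif(1L, ranges[1L, d], ranges[2L, d])
  left <- X[, d] < sv
  list(dim = d, split = sv,
       left = iso_tree(X[left, , drop = FALSE], depth + 1L, max_depth),
       right = iso_tree(X[!left, , drop = FALSE], depth + 1L, max_depth))
}

iso_path <- function(tree, x, depth = 0L) {
  if (is.null(tree$dim)) return(depth + iso_harmonic(tree$size))
  if (x[tree$dim] < tree$split) iso_path(tree$left, x, depth + 1L)
  else iso_path(tree$right, x, depth + 1L)
}

#' Isolation-forest anomaly scores
#'
#' @param X Numeric matrix (rows = observations, complete cases).
#' @param n_trees Number of trees.
#' @param psi Subsample size per tree.
#' @param seed Seed for subsampling and splits.
#' @return Anomaly scores in (0, 1); higher = more anomalous.
#' @export
isolation_score <- function(X, n_trees = 100L, psi = 256L, seed = 1L) {
  n <- nrow(X)
  psi <- min(psi, n)
  max_depth <- ceiling(log2(psi))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(t)
    iso_tree(X[sample.int(n, psi), , drop = FALSE], 0L, max_depth))
  paths <- matrix(0, n, n_trees)
  for (t in seq_len(n_trees))
    paths[, t] <- apply(X, 1L, function(x) iso_path(trees[[t]], x))
  2^(-rowMeans(paths) / iso_harmonic(psi))
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
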