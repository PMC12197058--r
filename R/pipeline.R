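#' @importFrom randomForest randomForest
NULL

# Fixed flattening order of the 16-dimensional feature vector:
# four medians (component-wise X_M, unit medoid X_K, medoid X_O,
# geometric X_G), each contributing its r, x, y, z components.
MEDIAN_KINDS <- c("XM", "XK", "XO", "XG")

FEATURE_NAMES <- as.vector(t(outer(MEDIAN_KINDS, c("r", "x", "y", "z"),
                                   paste, sep = "_")))

compute_medians <- function(seq, geom_tol = 1e-9, geom_max_iter = 1000L) {
  list(XM = median_componentwise(seq),
       XK = median_unit_medoid(seq),
       XO = median_medoid(seq),
       XG = median_geometric(seq, tol = geom_tol, max_iter = geom_max_iter))
}

#' Extract quaternion-median features from a recording
#'
#' Forms the quaternion sequence sample-by-sample from the four channels,
#' computes the four quaternion medians (component-wise, unit medoid,
#' medoid, geometric), optionally denoises each by PCA projection onto the
#' first `pca_k` eigenvectors of the recording's channel covariance, and
#' flattens them into a 16-dimensional feature vector in the fixed order
#' `XM_r ... XM_z, XK_r ... XK_z, XO_r ... XO_z, XG_r ... XG_z`.
#'
#' @param rec A [ppg_recording()].
#' @param pca_k Subspace dimension 1..4, or `"none"` to skip denoising
#'   (default 1).  `pca_k = 4` reproduces the raw medians exactly (the
#'   full-rank projection is the identity).
#' @param basis Optional pre-fit [fit_basis()] (e.g. a pooled basis);
#'   defaults to a basis fit on this recording.
#' @param geom_tol,geom_max_iter Passed to [median_geometric()].
#' @return An object of class `"median_features"`: list with `raw` and
#'   `denoised` median lists (the latter `NULL` when `pca_k = "none"`),
#'   the feature `vector` (length 16, named), `pca_k` and the recording's
#'   `glucose`.
#' @export
extract_features <- function(rec, pca_k = 1L, basis = NULL,
                             geom_tol = 1e-9, geom_max_iter = 1000L) {
  stopifnot(inherits(rec, "ppg_recording"))
  if (all(rec$samples == 0))
    stop("degenerate recording: all samples are zero", call. = FALSE)
  pca_k <- check_pca_k(pca_k)
  seq <- as_quat_seq(rec)
  raw <- compute_medians(seq, geom_tol, geom_max_iter)
  denoised <- NULL
  final <- raw
  if (!identical(pca_k, "none")) {
    if (is.null(basis))
      basis <- suppressWarnings(fit_basis(rec))
    denoised <- lapply(raw, denoise_median, basis = basis, k = pca_k)
    final <- denoised
  }
  vec <- unlist(lapply(final, function(m) to_vector(m$value)))
  names(vec) <- FEATURE_NAMES
  structure(list(raw = raw, denoised = denoised, vector = vec,
                 pca_k = pca_k, glucose = rec$glucose),
            class = "median_features")
}

check_pca_k <- function(pca_k) {
  if (identical(pca_k, "none") || is.null(pca_k)) return("none")
  k <- suppressWarnings(as.integer(pca_k))
  if (length(k) != 1L || is.na(k) || k < 1L || k > 4L)
    stop("pca_k must be 1..4 or \"none\"", call. = FALSE)
  k
}

#' Stack feature sets into a model matrix
#'
#' @param featuresets List of `"median_features"` objects.
#' @return Numeric matrix, one row per recording, 16 named columns.
#' @export
feature_matrix <- function(featuresets) {
  m <- do.call(rbind, lapply(featuresets, function(f) f$vector))
  colnames(m) <- FEATURE_NAMES
  m
}

#' Random train/test split of a dataset
#'
#' Seeded uniform split at the recording level: `ceiling(train_fraction*n)`
#' recordings go to training, the remainder to test; the two index sets
#' are disjoint and cover all recordings.
#'
#' @param n Number of recordings (or a list, whose length is used).
#' @param train_fraction Fraction of recordings used for training,
#'   strictly between 0 and 1 (default 0.7).
#' @param seed Integer split seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(n, train_fraction = 0.7, seed = 1L) {
  if (is.list(n)) n <- length(n)
  n <- as.integer(n)
  if (n < 2L) stop("need at least 2 recordings to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  idx <- with_seed(seed, sample.int(n))
  n_train <- ceiling(train_fraction * n)
  list(train = sort(idx[seq_len(n_train)]),
       test = sort(idx[-seq_len(n_train)]))
}

#' Train the glucose regression forest
#'
#' Fits a random forest of `n_trees` regression trees (bootstrap-sampled
#' rows, random feature subsets at each split, minimum leaf size
#' `min_leaf`); the forest prediction is the mean of the tree predictions,
#' the regression analogue of a vote.  Defaults follow common practice:
#' 100 trees, leaves down to single samples.
#'
#' @param x Feature matrix (rows = recordings) or list of
#'   `"median_features"`.
#' @param y Numeric targets (glucose, mmol/L), one per row of `x`.
#' @param n_trees Number of trees (default 100).
#' @param min_leaf Minimum samples per leaf node (default 1).
#' @param seed Optional model seed controlling the forest's randomness.
#' @return An object of class `"bgl_model"` wrapping the fitted forest.
#' @export
train_model <- function(x, y, n_trees = 100L, min_leaf = 1L, seed = NULL) {
  if (is.list(x) && !is.data.frame(x)) x <- feature_matrix(x)
  x <- as.matrix(x)
  if (nrow(x) != length(y))
    stop("x and y must have matching lengths", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 training samples", call. = FALSE)
  stopifnot(n_trees >= 1L)
  fit <- function() randomForest::randomForest(
    x = x, y = as.numeric(y), ntree = n_trees, nodesize = min_leaf)
  forest <- if (is.null(seed)) fit() else with_seed(seed, fit())
  structure(list(forest = forest, feature_names = colnames(x),
                 n_trees = n_trees, min_leaf = min_leaf),
            class = "bgl_model")
}

#' Predict glucose from features
#'
#' @param object A `"bgl_model"`.
#' @param newdata Feature matrix or list of `"median_features"`.
#' @param ... Unused.
#' @return Numeric vector of glucose estimates (mmol/L).
#' @export
predict.bgl_model <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.data.frame(newdata))
    newdata <- feature_matrix(newdata)
  unname(stats::predict(object$forest, as.matrix(newdata)))
}

#' Evaluate a model on a test set
#'
#' @param model A `"bgl_model"`.
#' @param x Test features.
#' @param y Reference glucose values (mmol/L).
#' @return A [metrics_report()].
#' @export
evaluate_model <- function(model, x, y) {
  metrics_report(y, predict(model, x), unit = "mmol/L")
}

#' Subspace-dimension sweep over PCA conditions
#'
#' Reproduces the comparison protocol used to select the denoising
#' subspace dimension: for each condition in `ks` (`"none"` and/or k in
#' 1..4) and each of the four median kinds, the 4 components of that
#' median (denoised at that k) are used alone as features, and repeated
#' seeded 70/30 train/test evaluations yield a distribution of RMSE and
#' MAE values.  Splits and model seeds are shared across conditions, so
#' conditions are compared on identical resamples.  The raw medians and
#' the per-recording PCA bases are computed once and reused across
#' conditions.
#'
#' @param recs List of [ppg_recording()]s with reference glucose.
#' @param ks Character/integer vector of conditions, subset of
#'   `c("none", 1, 2, 3, 4)`.
#' @param n_repeats Number of repeated splits (default 30).
#' @param train_fraction Training fraction per split (default 0.7).
#' @param seed Base seed for splits and models.
#' @param n_trees,min_leaf Forest settings (defaults 100, 1).
#' @return An object of class `"k_sweep"`: list with `results` (long data
#'   frame: k, kind, repeat_id, rmse, mae) and `summary` (per k x kind:
#'   median and interquartile range of both errors; `length(ks) * 4`
#'   rows).
#' @export
run_k_sweep <- function(recs, ks = c("none", 1, 2, 3), n_repeats = 30L,
                        train_fraction = 0.7, seed = 1L,
                        n_trees = 100L, min_leaf = 1L) {
  ks <- vapply(ks, function(k) as.character(check_pca_k(k)), character(1))
  if (anyDuplicated(ks)) stop("duplicate entries in ks", call. = FALSE)
  glucose <- vapply(recs, function(r) r$glucose, numeric(1))
  meds <- lapply(recs, function(r) compute_medians(as_quat_seq(r)))
  bases <- lapply(recs, function(r) suppressWarnings(fit_basis(r)))

  # features[[condition]][[kind]]: n x 4 matrix of that median's components
  features <- lapply(ks, function(k) {
    lapply(MEDIAN_KINDS, function(kind) {
      do.call(rbind, lapply(seq_along(recs), function(i) {
        m <- meds[[i]][[kind]]
        if (k != "none")
          m <- denoise_median(m, bases[[i]], as.integer(k))
        to_vector(m$value)
      }))
    })
  })
  names(features) <- ks
  for (k in ks) names(features[[k]]) <- MEDIAN_KINDS

  rows <- list()
  for (r in seq_len(n_repeats)) {
    sp <- split_dataset(length(recs), train_fraction, seed = seed + r)
    for (k in ks) {
      for (kind in MEDIAN_KINDS) {
        x <- features[[k]][[kind]]
        model <- train_model(x[sp$train, , drop = FALSE], glucose[sp$train],
                             n_trees = n_trees, min_leaf = min_leaf,
                             seed = seed + 10000L + r)
        pred <- predict(model, x[sp$test, , drop = FALSE])
        rows[[length(rows) + 1L]] <-
          data.frame(k = k, kind = kind, repeat_id = r,
                     rmse = rmse(glucose[sp$test], pred),
                     mae = mae(glucose[sp$test], pred))
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(results, results[c("k", "kind")]),
    function(d) data.frame(
      k = d$k[1], kind = d$kind[1],
      rmse_median = stats::median(d$rmse), rmse_iqr = stats::IQR(d$rmse),
      mae_median = stats::median(d$mae), mae_iqr = stats::IQR(d$mae))))
  rownames(agg) <- NULL
  structure(list(results = results, summary = agg), class = "k_sweep")
}

#' @export
print.k_sweep <- function(x, ...) {
  cat("<k_sweep> median test errors by condition and median kind:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
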