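#' Labeled feature dataset
#'
#' Rows are walks, columns are catalog attributes; labels are binary with
#' hemiplegic = 1 (the positive class) and normal = 0. Subject ids allow
#' grouped splitting so that the two walks of one subject never straddle a
#' train/test boundary.
#'
#' @param matrix numeric matrix, walks x attributes, finite entries, unique
#'   column names.
#' @param labels binary vector (0/1 or logical), one per row.
#' @param subject_ids character vector, one per row (defaults to row names or
#'   one subject per row).
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(matrix, labels, subject_ids = NULL) {
  matrix <- as.matrix(matrix)
  labels <- as.integer(labels)
  if (nrow(matrix) != length(labels)) {
    abort_hg("labels must parallel matrix rows", "hemigait_validation_error")
  }
  if (!all(labels %in% c(0L, 1L))) {
    abort_hg("labels must be binary 0 (normal) / 1 (hemiplegic)",
             "hemigait_validation_error")
  }
  if (any(!is.finite(matrix))) {
    abort_hg("non-finite entries in feature matrix", "hemigait_validation_error")
  }
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- sprintf("attr%03d", seq_len(ncol(matrix)))
  }
  if (anyDuplicated(colnames(matrix))) {
    abort_hg("attribute names must be unique", "hemigait_validation_error")
  }
  subject_ids <- subject_ids %||% rownames(matrix) %||%
    sprintf("row%03d", seq_len(nrow(matrix)))
  structure(
    list(matrix = matrix, labels = labels,
         subject_ids = as.character(subject_ids)),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d walks x %d attributes (%d hemiplegic, %d normal, %d subjects)\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$labels),
              sum(x$labels == 0L), length(unique(x$subject_ids))))
  invisible(x)
}

# row subset keeping structure
ds_rows <- function(data, idx) {
  labeled_dataset(data$matrix[idx, , drop = FALSE], data$labels[idx],
                  data$subject_ids[idx])
}

# column subset by attribute name
ds_cols <- function(data, names) {
  miss <- setdiff(names, colnames(data$matrix))
  if (length(miss)) {
    abort_hg(paste0("unknown attribute(s): ", paste(miss, collapse = ", ")),
             "hemigait_validation_error")
  }
  labeled_dataset(data$matrix[, names, drop = FALSE], data$labels,
                  data$subject_ids)
}

#' Configuration of the bagged-tree ensemble
#'
#' Bagging always resamples `n` rows with replacement per tree. The tree
#' count is capped at 50 by default, the ceiling used for the final
#' classifier throughout the package.
#'
#' @param n_trees number of trees, `1..max_trees` (default 50).
#' @param features_per_split `"sqrt"` (default, floor of the square root of
#'   the attribute count), `"all"`, or a positive integer.
#' @param min_leaf minimum rows per leaf (default 1).
#' @param seed integer seed; fits are deterministic given it.
#' @param max_trees tree-count cap (default 50).
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_trees = 50L, features_per_split = "sqrt",
                          min_leaf = 1L, seed = 1L, max_trees = 50L) {
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L || n_trees > max_trees) {
    abort_hg(sprintf("n_trees must be in 1..%d", max_trees),
             "hemigait_validation_error")
  }
  if (!(identical(features_per_split, "sqrt") ||
        identical(features_per_split, "all") ||
        (is.numeric(features_per_split) && features_per_split >= 1))) {
    abort_hg("features_per_split must be 'sqrt', 'all', or a positive integer",
             "hemigait_validation_error")
  }
  structure(
    list(n_trees = n_trees, features_per_split = features_per_split,
         min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
    class = "forest_config"
  )
}

resolve_mtry <- function(features_per_split, p) {
  if (identical(features_per_split, "sqrt")) return(max(1L, as.integer(floor(sqrt(p)))))
  if (identical(features_per_split, "all")) return(as.integer(p))
  min(as.integer(features_per_split), as.integer(p))
}

# majority vote over an n x ntree prediction matrix; tie -> class 0 (normal)
vote_labels <- function(pred_matrix, n_trees = ncol(pred_matrix)) {
  votes1 <- rowSums(pred_matrix[, seq_len(n_trees), drop = FALSE])
  as.integer(2 * votes1 > n_trees)
}

#' Train a bagged classification-tree ensemble
#'
#' Each tree is fit on a bootstrap resample (size `n`, with replacement) of
#' the training rows; prediction is the majority vote with ties assigned to
#' the normal class. The out-of-bag (OOB) error is the fraction of training
#' rows misclassified by the vote of only those trees whose bootstrap did not
#' contain the row; rows that are in-bag for every tree are excluded from the
#' OOB denominator. `oob_error_by_ntrees[t]` is the same quantity using only
#' trees `1..t`.
#'
#' @param data a [labeled_dataset()] with both classes present.
#' @param cfg a [forest_config()].
#' @return A `trained_forest`: list with `trees` (opaque handle), `oob_error`,
#'   `oob_error_by_ntrees`, `attribute_names`, `config`.
#' @export
train_forest <- function(data, cfg = forest_config()) {
  if (length(unique(data$labels)) < 2L) {
    abort_hg("training data must contain both classes", "hemigait_degenerate_error")
  }
  if (nrow(data$matrix) < 2L) abort_hg("need >= 2 rows", "hemigait_validation_error")
  mtry <- resolve_mtry(cfg$features_per_split, ncol(data$matrix))
  fit <- rf_fit_cpp(data$matrix, data$labels, cfg$n_trees, mtry,
                    cfg$min_leaf, cfg$seed)
  oob <- oob_error_curve(fit$train_pred, fit$inbag, data$labels)
  structure(
    list(trees = fit$trees, oob_error = oob[cfg$n_trees],
         oob_error_by_ntrees = oob,
         attribute_names = colnames(data$matrix), config = cfg),
    class = "trained_forest"
  )
}

# OOB misclassification rate as a function of the number of trees used.
oob_error_curve <- function(train_pred, inbag, labels) {
  n <- nrow(train_pred); ntree <- ncol(train_pred)
  oob <- (inbag == 0L) * 1L
  cum <- upper.tri(diag(ntree), diag = TRUE) * 1L   # column t sums trees 1..t
  votes1 <- (train_pred * oob) %*% cum
  nvote <- oob %*% cum
  hat <- (2 * votes1 > nvote) * 1L           # tie or majority-0 -> 0
  err <- vapply(seq_len(ntree), function(t) {
    has <- nvote[, t] > 0L
    if (!any(has)) return(NA_real_)
    mean(hat[has, t] != labels[has])
  }, numeric(1))
  err
}

#' @export
print.trained_forest <- function(x, ...) {
  cat(sprintf("<trained_forest> %d trees on %d attribute(s); OOB error %.4f\n",
              x$config$n_trees, length(x$attribute_names), x$oob_error))
  invisible(x)
}

#' Predict walk labels with a trained ensemble
#'
#' @param object a `trained_forest`.
#' @param newdata numeric matrix (or [labeled_dataset()]) whose columns
#'   include the training attributes, matched by name.
#' @param ... unused.
#' @return Integer vector of 0/1 predictions (majority vote, tie -> 0).
#' @export
predict.trained_forest <- function(object, newdata, ...) {
  m <- if (inherits(newdata, "labeled_dataset")) newdata$matrix else as.matrix(newdata)
  if (is.null(colnames(m))) {
    if (ncol(m) != length(object$attribute_names)) {
      abort_hg("attribute mismatch: unnamed matrix with wrong column count",
               "hemigait_validation_error")
    }
    colnames(m) <- object$attribute_names
  }
  miss <- setdiff(object$attribute_names, colnames(m))
  if (length(miss)) {
    abort_hg(paste0("attribute mismatch: missing ", paste(miss, collapse = ", ")),
             "hemigait_validation_error")
  }
  m <- m[, object$attribute_names, drop = FALSE]
  pred <- rf_predict_cpp(object$trees, m)
  vote_labels(pred)
}

#' OOB error surface over attribute-prefix and tree count
#'
#' For each prefix of `attribute_order` (first 1, 2, ... attributes) a forest
#' of `max_trees` trees is trained and its OOB error recorded for every tree
#' count `1..max_trees`, reproducing the training-stage error-versus-trees
#' picture as attributes are added.
#'
#' @param data a [labeled_dataset()].
#' @param attribute_order character vector of attribute names, most important
#'   first.
#' @param max_trees number of trees (default 50).
#' @param cfg base [forest_config()]; its `n_trees` is replaced by
#'   `max_trees`.
#' @return Numeric matrix `length(attribute_order) x max_trees` of OOB
#'   errors; `dimnames` give the attribute count and tree count.
#' @export
error_curves <- function(data, attribute_order, max_trees = 50L,
                         cfg = forest_config()) {
  if (!length(attribute_order)) {
    abort_hg("attribute_order must be non-empty", "hemigait_validation_error")
  }
  out <- matrix(NA_real_, length(attribute_order), max_trees,
                dimnames = list(n_attributes = seq_along(attribute_order),
                                n_trees = seq_len(max_trees)))
  for (k in seq_along(attribute_order)) {
    sub <- ds_cols(data, attribute_order[seq_len(k)])
    cfg_k <- forest_config(n_trees = max_trees,
                           features_per_split = cfg$features_per_split,
                           min_leaf = cfg$min_leaf, seed = cfg$seed,
                           max_trees = max(max_trees, 50L))
    fit <- train_forest(sub, cfg_k)
    out[k, ] <- fit$oob_error_by_ntrees
  }
  out
}

#' Stratified train/test split
#'
#' Preserves the class ratio on both sides (to rounding). With
#' `group_by_subject = TRUE` the split is drawn over subjects within each
#' class, so both walks of a subject land on the same side.
#'
#' @param data a [labeled_dataset()] containing both classes.
#' @param train_frac fraction assigned to training (default 0.75).
#' @param seed integer seed.
#' @param group_by_subject keep all rows of a subject together
#'   (default `TRUE`).
#' @return List with `train` and `test` [labeled_dataset()]s.
#' @export
stratified_split <- function(data, train_frac = 0.75, seed = 1L,
                             group_by_subject = TRUE) {
  if (length(unique(data$labels)) < 2L) {
    abort_hg("both classes must be present to split", "hemigait_degenerate_error")
  }
  if (train_frac < 0 || train_frac > 1) {
    abort_hg("train_frac must be in [0, 1]", "hemigait_validation_error")
  }
  train_idx <- with_local_seed(seed, {
    idx <- integer(0)
    for (cls in c(0L, 1L)) {
      rows <- which(data$labels == cls)
      if (group_by_subject) {
        subj <- unique(data$subject_ids[rows])
        n_tr <- round(length(subj) * train_frac)
        pick <- sample(subj, n_tr)
        idx <- c(idx, rows[data$subject_ids[rows] %in% pick])
      } else {
        n_tr <- round(length(rows) * train_frac)
        idx <- c(idx, sample(rows, n_tr))
      }
    }
    sort(idx)
  })
  test_idx <- setdiff(seq_along(data$labels), train_idx)
  if (train_frac < 1 && (!length(train_idx) || !length(test_idx)) ) {
    abort_hg("class too small to split at this fraction", "hemigait_degenerate_error")
  }
  list(
    train = ds_rows(data, train_idx),
    test = if (length(test_idx)) ds_rows(data, test_idx) else
      structure(list(matrix = data$matrix[0, , drop = FALSE],
                     labels = integer(0), subject_ids = character(0)),
                class = "labeled_dataset")
  )
}

# Random k-fold assignment with equal sizes (+-1); redrawn (up to max_draws)
# until every training fold (the complement of each fold) contains both
# classes.
make_folds <- function(labels, k, seed, max_draws = 100L) {
  n <- length(labels)
  if (n < k) abort_hg("fewer rows than folds", "hemigait_validation_error")
  seeds <- derive_seeds(seed, max_draws)
  for (d in seq_len(max_draws)) {
    fold <- with_local_seed(seeds[d], sample(rep_len(seq_len(k), n)))
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(labels[fold != f])) == 2L
    }, logical(1)))
    if (ok) return(fold)
  }
  abort_hg("could not draw folds with both classes in every training fold",
           "hemigait_degenerate_error")
}

#' k-fold cross-validation of the bagged ensemble
#'
#' Random partition into `k` equal-size (+-1) folds; each fold serves once as
#' validation while a forest is trained on the rest. Per-fold confusion
#' matrices and metrics are reported along with their average (undefined
#' metrics are dropped from the average).
#'
#' @param data a [labeled_dataset()].
#' @param k number of folds (default 4).
#' @param cfg a [forest_config()].
#' @param seed integer seed controlling the partition and the per-fold fits.
#' @return A `cv_report`: list with `fold_assignment`, `per_fold`
#'   (confusion + metrics per fold), `mean_metrics`, `error` (mean
#'   misclassification rate over rows).
#' @export
kfold_cv <- function(data, k = 4L, cfg = forest_config(), seed = 1L) {
  fold <- make_folds(data$labels, k, seed)
  seeds <- derive_seeds(seed + 1L, k)
  per_fold <- vector("list", k)
  wrong <- 0L
  for (f in seq_len(k)) {
    tr <- ds_rows(data, which(fold != f))
    te <- ds_rows(data, which(fold == f))
    cfg_f <- cfg
    cfg_f$seed <- seeds[f]
    fit <- train_forest(tr, cfg_f)
    hat <- predict(fit, te)
    cm <- confusion(te$labels, hat)
    wrong <- wrong + cm$fp + cm$fn
    per_fold[[f]] <- list(confusion = cm, metrics = metrics(cm))
  }
  mm <- colMeans(do.call(rbind, lapply(per_fold, function(x) {
    unlist(x$metrics[c("se", "sp", "ac", "ppv")])
  })), na.rm = TRUE)
  structure(
    list(fold_assignment = fold, per_fold = per_fold,
         mean_metrics = as.list(mm),
         error = wrong / length(data$labels)),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds; mean AC %.1f%%, error %.4f\n",
              length(x$per_fold), x$mean_metrics$ac, x$error))
  invisible(x)
}
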