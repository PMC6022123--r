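#' Configuration of the sequential forward search
#'
#' The wrapper criterion is the k-fold cross-validated misclassification rate
#' of the bagged-tree classifier on the candidate attribute set, with the
#' fold assignment drawn once per search. The search stops when the best
#' achievable improvement falls below `termination_tolerance` (default
#' `1e-6`) or the criterion would increase.
#'
#' @param termination_tolerance positive stopping tolerance on the criterion
#'   improvement (default `1e-6`).
#' @param cv_folds folds of the wrapper cross-validation (default 4).
#' @param classifier_config [forest_config()] of the wrapper classifier. The
#'   default uses 10 trees: the training error-versus-trees curve plateaus by
#'   about 10 trees, and the wrapper is refit thousands of times per search.
#' @param max_features optional cap on the number of selected attributes.
#' @param seed integer seed (folds and wrapper fits).
#' @return An `sfs_config` list.
#' @export
sfs_config <- function(termination_tolerance = 1e-6, cv_folds = 4L,
                       classifier_config = forest_config(n_trees = 10L),
                       max_features = NULL, seed = 1L) {
  if (termination_tolerance <= 0) {
    abort_hg("termination_tolerance must be > 0", "hemigait_validation_error")
  }
  if (cv_folds < 2L) abort_hg("cv_folds must be >= 2", "hemigait_validation_error")
  structure(
    list(termination_tolerance = termination_tolerance,
         cv_folds = as.integer(cv_folds),
         classifier_config = classifier_config,
         max_features = max_features, seed = as.integer(seed)),
    class = "sfs_config"
  )
}

wrapper_mtry_fixed <- function(cfg_forest, k) {
  fps <- cfg_forest$features_per_split
  if (identical(fps, "sqrt")) return(0L)          # computed per round in C++
  if (identical(fps, "all")) return(as.integer(k))
  as.integer(fps)
}

#' Sequential forward search over catalog attributes
#'
#' Greedy wrapper selection: starting from the empty set (criterion
#' `+Inf`), every remaining attribute is tried in turn, the cross-validated
#' misclassification rate of the classifier on the enlarged set is computed
#' (fold assignment fixed for the whole search, per-fold classifier seeds
#' shared across candidates so comparisons are paired), and the attribute
#' with the lowest criterion is accepted — ties go to the lowest catalog
#' index. The first round always accepts one attribute; afterwards the search
#' stops as soon as the best improvement is below the termination tolerance,
#' the criterion would increase, or `max_features` is reached.
#'
#' @param data a [labeled_dataset()] with both classes and at least
#'   `cv_folds` rows per class.
#' @param cfg an [sfs_config()].
#' @return An `sfs_result`: `selected` (ordered attribute names),
#'   `criterion_trace` (criterion after each acceptance, non-increasing),
#'   `candidate_scores` (per round, named criterion of every tried
#'   attribute), `fold_assignment`.
#' @export
sequential_forward_search <- function(data, cfg = sfs_config()) {
  if (length(unique(data$labels)) < 2L) {
    abort_hg("need both classes for selection", "hemigait_degenerate_error")
  }
  if (min(table(data$labels)) < cfg$cv_folds) {
    abort_hg("need at least cv_folds rows per class", "hemigait_validation_error")
  }
  p <- ncol(data$matrix)
  fold <- make_folds(data$labels, cfg$cv_folds, cfg$seed)
  round_seeds <- derive_seeds(cfg$seed, p)
  max_feat <- cfg$max_features %||% p

  selected <- integer(0)
  trace <- numeric(0)
  scores <- list()
  current <- Inf
  repeat {
    cand <- setdiff(seq_len(p), selected)
    if (!length(cand) || length(selected) >= max_feat) break
    k <- length(selected) + 1L
    errs <- rf_sfs_round_cpp(
      data$matrix, data$labels,
      selected - 1L, cand - 1L, fold - 1L, cfg$cv_folds,
      cfg$classifier_config$n_trees, cfg$classifier_config$min_leaf,
      round_seeds[k],
      wrapper_mtry_fixed(cfg$classifier_config, k)
    )
    names(errs) <- colnames(data$matrix)[cand]
    scores[[k]] <- errs
    best_i <- which.min(errs)                     # ties -> lowest catalog index
    best <- errs[[best_i]]
    if (is.finite(current) && (current - best) < cfg$termination_tolerance) break
    selected <- c(selected, cand[best_i])
    trace <- c(trace, best)
    current <- best
    if (best == 0) break                          # cannot improve further
  }
  structure(
    list(selected = colnames(data$matrix)[selected],
         criterion_trace = trace, candidate_scores = scores,
         fold_assignment = fold),
    class = "sfs_result"
  )
}

#' @export
print.sfs_result <- function(x, ...) {
  cat(sprintf("<sfs_result> %d attribute(s): %s\n  criterion trace: %s\n",
              length(x$selected), paste(x$selected, collapse = ", "),
              paste(signif(x$criterion_trace, 4), collapse = " -> ")))
  invisible(x)
}

#' Stability ranking of attributes over repeated randomized searches
#'
#' Runs the forward search `n_iterations` times, each on a re-randomized
#' training set, and counts how often each attribute is selected; the most
#' frequently selected attributes are the stable (optimal) ones. The default
#' resampling (`"bootstrap_subjects"`) draws 75% of the subjects of each
#' class without replacement, so both walks of a subject stay together and
#' no walk leaks between resamples; `"reshuffle_split"` instead re-draws a
#' stratified grouped 75/25 split and uses its training side.
#'
#' @param data a [labeled_dataset()].
#' @param cfg an [sfs_config()]; each iteration runs with an
#'   iteration-derived seed.
#' @param n_iterations number of randomized searches (default 100).
#' @param resample resampling scheme, see above.
#' @param subject_frac fraction of subjects kept per iteration (default
#'   0.75).
#' @return A `stability_ranking`: `counts` (named selection counts over all
#'   attributes), `first_round` (earliest acceptance round per attribute),
#'   `ordered` (attribute names by descending count, ties by earlier first
#'   acceptance then name), `n_iterations`, `n_failed`.
#' @export
stability_rank <- function(data, cfg = sfs_config(), n_iterations = 100L,
                           resample = c("bootstrap_subjects", "reshuffle_split"),
                           subject_frac = 0.75) {
  resample <- match.arg(resample)
  attrs <- colnames(data$matrix)
  counts <- stats::setNames(integer(length(attrs)), attrs)
  first_round <- stats::setNames(rep(Inf, length(attrs)), attrs)
  seeds <- derive_seeds(cfg$seed, 2L * n_iterations)
  n_failed <- 0L
  for (it in seq_len(n_iterations)) {
    train <- switch(resample,
      bootstrap_subjects = with_local_seed(seeds[it], {
        keep <- unlist(lapply(c(0L, 1L), function(cls) {
          subj <- unique(data$subject_ids[data$labels == cls])
          sample(subj, max(1L, round(length(subj) * subject_frac)))
        }))
        ds_rows(data, which(data$subject_ids %in% keep))
      }),
      reshuffle_split = stratified_split(data, train_frac = subject_frac,
                                         seed = seeds[it],
                                         group_by_subject = TRUE)$train
    )
    cfg_it <- cfg
    cfg_it$seed <- seeds[n_iterations + it]
    res <- tryCatch(sequential_forward_search(train, cfg_it),
                    hemigait_error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    counts[res$selected] <- counts[res$selected] + 1L
    rounds <- seq_along(res$selected)
    first_round[res$selected] <- pmin(first_round[res$selected], rounds)
  }
  if (n_failed > 0.1 * n_iterations) {
    abort_hg(sprintf("%d/%d stability iterations failed", n_failed, n_iterations),
             "hemigait_degenerate_error")
  }
  ord <- order(-counts, first_round, attrs)
  structure(
    list(counts = counts, first_round = first_round,
         ordered = attrs[ord], n_iterations = n_iterations,
         n_failed = n_failed),
    class = "stability_ranking"
  )
}

#' @export
print.stability_ranking <- function(x, ...) {
  top <- utils::head(x$ordered, 5L)
  cat(sprintf("<stability_ranking> %d iterations; top attributes: %s\n",
              x$n_iterations,
              paste(sprintf("%s (%d)", top, x$counts[top]), collapse = ", ")))
  invisible(x)
}

#' Write a stability ranking as CSV
#'
#' Columns `name`, `count`, `rank` (1 = most frequently selected).
#'
#' @param ranking a `stability_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stability <- function(ranking, path) {
  df <- data.frame(name = ranking$ordered,
                   count = ranking$counts[ranking$ordered],
                   rank = seq_along(ranking$ordered))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
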