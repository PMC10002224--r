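## Wrapper feature selection (forward / bidirectional) and the repeated
## rebalanced 80/20 + k-fold evaluation protocol.

#' Classifier adapters for the selection / evaluation protocol
#'
#' Wraps the two classifiers behind a common `fit(X, y)` / `predict(model, X)`
#' interface so the wrapper selector and the evaluator are classifier-agnostic.
#'
#' @param method `"lda"` or `"nn"`.
#' @param ... options passed on to [nn_fit()] (e.g. `hidden`, `epochs`,
#'   `reg`, `seed`); ignored for `"lda"`.
#' @return List with elements `fit`, `predict`, `method`.
#' @export
make_classifier <- function(method = c("lda", "nn"), ...) {
  method <- match.arg(method)
  opts <- list(...)
  if (method == "lda") {
    fit <- function(X, y) {
      lev <- sort(unique(as.character(y)))
      lda_fit(X[y == lev[1], , drop = FALSE], X[y == lev[2], , drop = FALSE],
              labels = lev)
    }
    pred <- function(model, X) lda_predict(model, X)
  } else {
    fit <- function(X, y) do.call(nn_fit, c(list(X = X, y = y), opts))
    pred <- function(model, X) nn_predict(model, X)
  }
  list(fit = fit, predict = pred, method = method)
}

## stratified fold assignment; every fold contains both classes
make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (g in unique(y)) {
    i <- sample(which(y == g))
    fold[i] <- rep_len(seq_len(k), length(i))
  }
  fold
}

## mean k-fold cross-validated accuracy of a feature subset
cv_accuracy <- function(X, y, features, classifier, k) {
  fold <- make_folds(y, k)
  accs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    if (!any(!tr) || length(unique(y[tr])) < 2 || min(table(y[tr])) < 2)
      return(NA_real_)
    m <- classifier$fit(X[tr, features, drop = FALSE], y[tr])
    mean(classifier$predict(m, X[!tr, features, drop = FALSE]) == y[!tr])
  }, numeric(1))
  if (all(is.na(accs))) return(NA_real_)
  mean(accs, na.rm = TRUE)
}

#' Greedy forward wrapper feature selection
#'
#' Starts from the empty set and at each step adds the feature that maximises
#' the mean inner k-fold cross-validated accuracy of the classifier; stops
#' when no addition improves the accuracy by more than `tol`. At least one
#' feature (the best single one) is always returned.
#'
#' @param X feature matrix (columns named).
#' @param y class labels.
#' @param classifier a [make_classifier()] adapter.
#' @param k_folds inner cross-validation folds.
#' @param tol minimal accuracy improvement to accept an addition.
#' @param seed seed for the fold assignments.
#' @param max_features optional cap on the subset size.
#' @return Character vector of selected feature names.
#' @export
forward_select <- function(X, y, classifier, k_folds = 4, tol = 0.001,
                           seed = 1, max_features = Inf) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 1)
  set.seed(seed)
  cand <- colnames(X)
  sel <- character(0)
  best_acc <- -Inf
  while (length(cand) > 0 && length(sel) < max_features) {
    accs <- vapply(cand, function(f)
      cv_accuracy(X, y, c(sel, f), classifier, k_folds), numeric(1))
    accs[is.na(accs)] <- -Inf
    i <- which.max(accs)
    if (length(sel) > 0 && accs[i] <= best_acc + tol) break
    if (is.infinite(accs[i])) break
    sel <- c(sel, cand[i])
    best_acc <- accs[i]
    cand <- cand[-i]
  }
  if (length(sel) == 0) sel <- colnames(X)[1]
  sel
}

#' Bidirectional wrapper feature selection
#'
#' Forward steps as in [forward_select()], each followed by a backward pass
#' that removes any previously selected feature whose removal does not reduce
#' the cross-validated accuracy by more than `tol` (the just-added feature is
#' exempt). A visited-subset guard prevents cycling; the result is never
#' empty.
#'
#' @inheritParams forward_select
#' @return Character vector of selected feature names.
#' @export
bidirectional_select <- function(X, y, classifier, k_folds = 4, tol = 0.001,
                                 seed = 1, max_features = Inf) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 1)
  set.seed(seed)
  cand <- colnames(X)
  sel <- character(0)
  best_acc <- -Inf
  visited <- character(0)
  repeat {
    if (length(cand) == 0 || length(sel) >= max_features) break
    accs <- vapply(cand, function(f)
      cv_accuracy(X, y, c(sel, f), classifier, k_folds), numeric(1))
    accs[is.na(accs)] <- -Inf
    i <- which.max(accs)
    if (length(sel) > 0 && accs[i] <= best_acc + tol) break
    if (is.infinite(accs[i])) break
    added <- cand[i]
    sel <- c(sel, added)
    best_acc <- accs[i]
    cand <- cand[-i]
    visited <- c(visited, paste(sort(sel), collapse = "|"))
    ## backward pass: drop redundant features (never the one just added)
    repeat {
      if (length(sel) < 2) break
      removable <- setdiff(sel, added)
      accs_wo <- vapply(removable, function(f)
        cv_accuracy(X, y, setdiff(sel, f), classifier, k_folds), numeric(1))
      accs_wo[is.na(accs_wo)] <- -Inf
      j <- which.max(accs_wo)
      trial <- setdiff(sel, removable[j])
      key <- paste(sort(trial), collapse = "|")
      if (accs_wo[j] >= best_acc - tol && !(key %in% visited)) {
        cand <- c(cand, removable[j])
        sel <- trial
        best_acc <- max(best_acc, accs_wo[j])
        visited <- c(visited, key)
      } else break
    }
  }
  if (length(sel) == 0) sel <- colnames(X)[1]
  sel
}

#' Configuration of one evaluation run
#'
#' @param comparison the two group labels to compare.
#' @param dataset `"dataset1"` (spectral descriptors) or `"dataset2"`
#'   (Q-reduced wavelet statistics; the Q-index reduction is recomputed inside
#'   every run on the training portion only).
#' @param classifier `"lda"` or `"nn"`.
#' @param selector `"forward"` or `"bidirectional"`.
#' @param n_runs number of outer runs.
#' @param k_folds folds of the cross-validation (inner selection folds and
#'   per-run fold models).
#' @param test_fraction held-out fraction per run.
#' @param seed master seed; run r uses `seed + r`.
#' @param tol wrapper-selection tolerance.
#' @param alpha significance level of the per-run Q-index reduction.
#' @param classifier_opts list of options for [make_classifier()] (e.g. `list
#'   (epochs = 300)` for the network).
#' @param max_features cap on the wrapper-selected subset size; useful to
#'   bound runtime when the inner-CV accuracy is noisy.
#' @param select_once if `TRUE`, feature selection runs once on the first
#'   run's training data and the set is reused in later runs.
#' @return List of class `eval_config`.
#' @export
eval_config <- function(comparison, dataset = c("dataset1", "dataset2"),
                        classifier = c("lda", "nn"),
                        selector = c("forward", "bidirectional"),
                        n_runs = 150, k_folds = 4, test_fraction = 0.2,
                        seed = 1, tol = 0.001, alpha = 0.05,
                        classifier_opts = list(), select_once = FALSE,
                        max_features = Inf) {
  stopifnot(length(comparison) == 2, k_folds >= 2, n_runs >= 1,
            test_fraction > 0, test_fraction < 1)
  structure(list(comparison = comparison, dataset = match.arg(dataset),
                 classifier = match.arg(classifier),
                 selector = match.arg(selector), n_runs = n_runs,
                 k_folds = k_folds, test_fraction = test_fraction,
                 seed = seed, tol = tol, alpha = alpha,
                 classifier_opts = classifier_opts,
                 select_once = select_once, max_features = max_features),
            class = "eval_config")
}

## stratified train/test split; returns logical test mask
split_test <- function(y, test_fraction) {
  test <- logical(length(y))
  for (g in unique(y)) {
    i <- which(y == g)
    test[sample(i, max(1, round(length(i) * test_fraction)))] <- TRUE
  }
  test
}

#' Run the repeated rebalanced split / k-fold evaluation protocol
#'
#' Each run: reshuffle (seeded), equalise the two classes by random
#' undersampling, hold out `test_fraction` (stratified), run the wrapper
#' selector with inner k-fold cross-validation on the training portion only,
#' then train `k_folds` fold models (each on k-1 training folds) and score
#' each on the held-out set — `n_runs * k_folds` accuracies in total. For
#' `dataset = "dataset2"` the Q-index block reduction is recomputed inside the
#' run on the training rows, so no information from the held-out rows enters
#' the feature ranking.
#'
#' @param features full feature data.frame (`subject_id`, `group`, features):
#'   Dataset1 for `dataset = "dataset1"`, the full 640-column Dataset2 for
#'   `dataset = "dataset2"`.
#' @param config an [eval_config()].
#' @return Object of class `evaluation_report`: `accuracy_mean`, `accuracy_sd`,
#'   `accuracies`, `selected` (modal selected feature set), `selection_table`,
#'   `config`.
#' @export
evaluate <- function(features, config) {
  stopifnot(inherits(config, "eval_config"))
  keep <- features$group %in% config$comparison
  feats <- features[keep, , drop = FALSE]
  y_all <- feats$group
  fcols <- setdiff(colnames(feats), c("subject_id", "group"))
  classifier <- do.call(make_classifier,
                        c(list(method = config$classifier),
                          config$classifier_opts))
  accs <- numeric(0)
  sel_sets <- character(config$n_runs)
  fixed_sel <- NULL
  for (r in seq_len(config$n_runs)) {
    run_seed <- (config$seed + r) %% 2147483647
    bal <- rebalance(as.matrix(feats[, fcols, drop = FALSE]), y_all,
                     seed = run_seed)
    X <- bal$X
    y <- bal$y
    if (min(table(y)) < 3)
      stop("evaluate: need at least 3 subjects per class after rebalancing")
    for (attempt in seq_len(100)) {
      test <- split_test(y, config$test_fraction)
      if (length(unique(y[test])) == 2 && length(unique(y[!test])) == 2) break
      if (attempt == 100) stop("evaluate: could not form a non-degenerate split")
      message("evaluate: degenerate split, resampling")
    }
    Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
    Xte <- X[test, , drop = FALSE];  yte <- y[test]
    if (config$dataset == "dataset2") {
      df_tr <- data.frame(group = ytr, check.names = FALSE)
      df_tr[colnames(Xtr)] <- Xtr
      qt <- select_blocks(df_tr, config$comparison, alpha = config$alpha)
      Xtr <- Xtr[, qt$selected_features, drop = FALSE]
      Xte <- Xte[, qt$selected_features, drop = FALSE]
    }
    if (config$select_once && !is.null(fixed_sel)) {
      sel <- intersect(fixed_sel, colnames(Xtr))
    } else {
      selector <- if (config$selector == "forward") forward_select else
        bidirectional_select
      sel <- selector(Xtr, ytr, classifier, k_folds = config$k_folds,
                      tol = config$tol, seed = run_seed,
                      max_features = config$max_features)
      if (config$select_once) fixed_sel <- sel
    }
    if (length(sel) == 0) sel <- colnames(Xtr)[1]
    sel_sets[r] <- paste(sort(sel), collapse = ", ")
    ## k fold models, each trained on k-1 folds, all scored on the held-out set
    fold <- make_folds(ytr, config$k_folds)
    for (f in seq_len(config$k_folds)) {
      tr <- fold != f
      if (length(unique(ytr[tr])) < 2 || min(table(ytr[tr])) < 2)
        tr <- rep(TRUE, length(ytr))
      m <- classifier$fit(Xtr[tr, sel, drop = FALSE], ytr[tr])
      accs <- c(accs, mean(classifier$predict(m, Xte[, sel, drop = FALSE]) == yte))
    }
  }
  tab <- sort(table(sel_sets), decreasing = TRUE)
  structure(list(accuracy_mean = mean(accs), accuracy_sd = stats::sd(accs),
                 accuracies = accs,
                 selected = strsplit(names(tab)[1], ", ")[[1]],
                 selection_table = tab, config = config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s vs %s | %s | %s | %s\n", cfg$comparison[1], cfg$comparison[2],
              cfg$dataset, toupper(cfg$classifier), cfg$selector))
  cat(sprintf("  accuracy: %.2f%% +/- %.1f%% over %d trials\n",
              100 * x$accuracy_mean, 100 * x$accuracy_sd, length(x$accuracies)))
  cat("  modal selected features:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the full comparison x dataset x classifier x selector grid
#'
#' One row per configuration (3 pairwise comparisons x 2 datasets x 2
#' classifiers x 2 selectors = 24 rows for a three-group cohort), sorted
#' deterministically.
#'
#' @param ds1 Dataset1 feature table.
#' @param ds2 full Dataset2 feature table.
#' @param comparisons list of group-label pairs; default: all pairs present.
#' @param ... arguments passed to [eval_config()] (e.g. `n_runs`, `seed`,
#'   `classifier_opts`).
#' @return data.frame with the configuration columns, the modal selected
#'   features, and mean/SD accuracy; the reports themselves are attached as
#'   the `reports` attribute.
#' @export
run_all <- function(ds1, ds2, comparisons = NULL, ...) {
  groups <- sort(unique(ds1$group))
  if (is.null(comparisons)) {
    comparisons <- utils::combn(groups, 2, simplify = FALSE)
  }
  rows <- list(); reports <- list()
  for (cmp in comparisons) {
    for (ds in c("dataset1", "dataset2")) {
      for (cl in c("lda", "nn")) {
        for (se in c("forward", "bidirectional")) {
          cfg <- eval_config(comparison = cmp, dataset = ds, classifier = cl,
                             selector = se, ...)
          rep <- evaluate(if (ds == "dataset1") ds1 else ds2, cfg)
          key <- paste(paste(cmp, collapse = "-"), ds, cl, se, sep = "|")
          reports[[key]] <- rep
          rows[[key]] <- data.frame(
            comparison = paste(cmp, collapse = " vs "), dataset = ds,
            classifier = toupper(cl), selector = se,
            selected = paste(rep$selected, collapse = ", "),
            accuracy_mean = rep$accuracy_mean, accuracy_sd = rep$accuracy_sd)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$comparison, out$dataset, out$classifier, out$selector), ]
  attr(out, "reports") <- reports
  out
}
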