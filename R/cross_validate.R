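# deterministic 31-bit string hash (FNV-style, double arithmetic keeps it
# exact below 2^53); seeded so different seeds give different fold deals
hash_id <- function(id, seed = 0L) {
  vapply(id, function(s) {
    h <- 2166136261 + as.numeric(seed) * 2654435761
    h <- h %% 2147483647
    for (b in utf8ToInt(s)) {
      h <- (h * 31 + b) %% 2147483647
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Stratified fold assignment keyed by segment ids
#'
#' Folds are dealt round-robin within each class after ordering by a seeded
#' hash of the segment id, so the assignment is invariant to row order:
#' fold sizes differ by at most one and per-fold class proportions match
#' the table within one sample.
#'
#' @param ids Character segment ids (unique).
#' @param labels Class label per id.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed entering the hash.
#' @return Integer fold index (1-based) per row.
#' @export
assign_folds <- function(ids, labels, folds = 5L, seed = 1L) {
  stopifnot(!anyDuplicated(ids), length(ids) == length(labels))
  fold <- integer(length(ids))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds) {
      stop("class ", cl, " has fewer samples than folds", call. = FALSE)
    }
    ord <- idx[order(hash_id(ids[idx], seed), ids[idx])]
    fold[ord] <- rep_len(seq_len(folds), length(ord))
  }
  fold
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}

apply_standardizer <- function(X, st) {
  sweep(sweep(X, 2, st$mu, `-`), 2, st$sd, `/`)
}

fit_and_predict <- function(model_kind, params, train_X, train_y, test_X) {
  if (model_kind == "KNN") {
    knn_predict(train_X, train_y, test_X, k = params$k,
                metric = params$metric)
  } else {
    predict(svm_train(train_X, train_y, params$kernel_scale,
                      params$box_constraint), test_X)
  }
}

# mean misclassification of a configuration under a stratified inner split
inner_cv_error <- function(model_kind, params, X, y, ids, inner_folds,
                           seed) {
  fold <- assign_folds(ids, y, inner_folds, seed)
  errs <- vapply(seq_len(inner_folds), function(f) {
    tr <- fold != f
    st <- standardizer(X[tr, , drop = FALSE])
    pred <- fit_and_predict(model_kind, params,
                            apply_standardizer(X[tr, , drop = FALSE], st),
                            y[tr],
                            apply_standardizer(X[!tr, , drop = FALSE], st))
    mean(pred != y[!tr])
  }, numeric(1))
  mean(errs)
}

#' Cross-validated, Bayesian-tuned classification of a feature table
#'
#' Runs stratified `folds`-fold cross-validation. Within each training
#' fold: features are z-scored on training statistics, fuzzy-entropy
#' selection is optionally applied (recomputed on the training portion),
#' and the classifier's hyperparameters are tuned by [bayesian_optimize()]
#' against an inner stratified `inner_folds`-fold misclassification
#' objective; the tuned model is refit on the whole training fold and
#' evaluated on the held-out fold. With `paper_mode = TRUE` a single
#' configuration is instead tuned directly on the outer cross-validation
#' objective and shared across folds.
#'
#' @param table A labeled `feature_table`.
#' @param model_kind `"KNN"` or `"SVM"`.
#' @param space An [hyperparameter_space()] (defaults to the model's
#'   standard space).
#' @param folds Outer folds (default 5).
#' @param seed Integer seed controlling folds and the tuner.
#' @param select_fe Apply mean-threshold FE selection per fold?
#' @param bhpo_budget Tuner evaluations (default 30).
#' @param inner_folds Inner folds for the tuning objective (default 3).
#' @param paper_mode Tune one configuration on the outer objective.
#' @return An object of class `cv_report`: per-fold confusions, metrics,
#'   tuned parameters and selection summaries, aggregated
#'   mean-and-standard-deviation metrics, and the tuning traces.
#' @export
cross_validate <- function(table, model_kind = c("SVM", "KNN"), space = NULL,
                           folds = 5L, seed = 1L, select_fe = FALSE,
                           bhpo_budget = 30L, inner_folds = 3L,
                           paper_mode = FALSE) {
  model_kind <- match.arg(model_kind)
  if (is.null(space)) space <- hyperparameter_space(model_kind)
  stopifnot(identical(space$model_kind, model_kind))
  feats <- feature_names(table)
  X_all <- as.matrix(table[, feats, drop = FALSE])
  y <- table$label
  ids <- table$id
  fold <- assign_folds(ids, y, folds, seed)

  tune_for <- function(X, y_tr, ids_tr, fold_seed) {
    bayesian_optimize(
      function(p) inner_cv_error(model_kind, p, X, y_tr, ids_tr,
                                 inner_folds, fold_seed),
      space, budget = bhpo_budget, seed = fold_seed
    )
  }

  shared_trace <- NULL
  if (paper_mode) {
    # selection and standardisation do not depend on the hyperparameters:
    # precompute them per fold before the tuning loop
    prep <- lapply(seq_len(folds), function(f) {
      tr <- fold != f
      sel_feats <- feats
      if (select_fe) {
        sel <- select_features(table[tr, , drop = FALSE])
        sel_feats <- sel$feature[sel$selected]
      }
      st <- standardizer(X_all[tr, sel_feats, drop = FALSE])
      list(tr = tr,
           X_tr = apply_standardizer(X_all[tr, sel_feats, drop = FALSE], st),
           X_te = apply_standardizer(X_all[!tr, sel_feats, drop = FALSE], st))
    })
    outer_objective <- function(p) {
      errs <- vapply(prep, function(pr) {
        pred <- fit_and_predict(model_kind, p, pr$X_tr, y[pr$tr], pr$X_te)
        mean(pred != y[!pr$tr])
      }, numeric(1))
      mean(errs)
    }
    shared_trace <- bayesian_optimize(outer_objective, space,
                                      budget = bhpo_budget, seed = seed)
  }

  fold_results <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    tab_tr <- table[tr, , drop = FALSE]
    selection <- NULL
    sel_feats <- feats
    if (select_fe) {
      selection <- select_features(tab_tr)
      sel_feats <- selection$feature[selection$selected]
    }
    X_tr <- X_all[tr, sel_feats, drop = FALSE]
    X_te <- X_all[!tr, sel_feats, drop = FALSE]
    st <- standardizer(X_tr)
    X_tr_s <- apply_standardizer(X_tr, st)
    X_te_s <- apply_standardizer(X_te, st)
    if (paper_mode) {
      trace <- shared_trace
    } else {
      trace <- tune_for(X_tr_s, y[tr], ids[tr],
                        fold_seed = (seed * 131 + f) %% 2147483647)
    }
    pred <- fit_and_predict(model_kind, trace$best_params, X_tr_s, y[tr],
                            X_te_s)
    cc <- confusion(y[!tr], pred)
    list(fold = f, confusion = cc, metrics = compute_metrics(cc),
         params = trace$best_params, trace = trace,
         n_features = length(sel_feats), selection = selection)
  })

  structure(
    list(model_kind = model_kind, folds = folds, seed = seed,
         select_fe = select_fe, paper_mode = paper_mode,
         bhpo_budget = bhpo_budget,
         per_fold = fold_results,
         aggregate = aggregate_folds(lapply(fold_results, `[[`, "metrics")),
         tuned = lapply(fold_results, `[[`, "params"),
         n_features = vapply(fold_results, `[[`, integer(1), "n_features")),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %s, %d-fold, seed %d%s>\n", x$model_kind,
              x$folds, x$seed,
              if (x$select_fe) ", FE selection" else ""))
  for (f in metric_fields) {
    a <- x$aggregate[[f]]
    if (f == "mcc") {
      cat(sprintf("  %-12s %6.2f +/- %.2f\n", f, a["mean"], a["sd"]))
    } else {
      cat(sprintf("  %-12s %6.2f +/- %.2f %%\n", f, 100 * a["mean"],
                  100 * a["sd"]))
    }
  }
  invisible(x)
}

#' Serialise a cross-validation report to JSON
#'
#' Per fold: confusion cells, metrics and tuned hyperparameters; aggregate
#' block with mean and standard deviation per measure; seed and settings.
#'
#' @param report A `cv_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  payload <- list(
    model_kind = report$model_kind, folds = report$folds,
    seed = report$seed, select_fe = report$select_fe,
    paper_mode = report$paper_mode, bhpo_budget = report$bhpo_budget,
    n_features = report$n_features,
    per_fold = lapply(report$per_fold, function(fr) {
      list(fold = fr$fold,
           confusion = fr$confusion[c("TP", "FP", "FN", "TN")],
           metrics = fr$metrics[metric_fields],
           params = fr$params)
    }),
    aggregate = lapply(report$aggregate, as.list)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
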