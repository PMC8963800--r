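# Binary-classification evaluation: confusion counts, the five threshold
# metrics (accuracy, sensitivity, precision, specificity, MCC), ROC/AUC,
# the k-fold cross-validation driver and the (L, K) grid search.

#' Confusion counts for binary labels
#'
#' Class 1 is the positive class.
#'
#' @param y_true,y_pred Equal-length vectors of 0/1 labels.
#' @return Object of class `confusion_counts`: list `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    data_error("y_true and y_pred differ in length (", length(y_true),
               " vs ", length(y_pred), ")")
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L))) {
    data_error("labels must be 0 or 1")
  }
  structure(list(TP = sum(y_true == 1L & y_pred == 1L),
                 FP = sum(y_true == 0L & y_pred == 1L),
                 TN = sum(y_true == 0L & y_pred == 0L),
                 FN = sum(y_true == 1L & y_pred == 0L)),
            class = "confusion_counts")
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); reported as NA",
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Threshold metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, precision
#' `TP/(TP+FP)`, specificity `TN/(TN+FP)`, and the Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TP+FP)(TN+FP)(TP+FN)(TN+FN))`.
#' A metric with a zero denominator is reported as `NA` with a warning,
#' never silently coerced to 0.
#'
#' @param counts A [confusion_counts] object (or list with TP/FP/TN/FN).
#' @return Object of class `metrics_report`: list `accuracy`,
#'   `sensitivity`, `precision`, `specificity`, `mcc`, `auc` (NA here;
#'   filled by [cross_validate]). Rates are proportions in `[0, 1]`.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total <= 0) data_error("empty confusion matrix")
  mcc_den <- sqrt(prod(c(TP + FP, TN + FP, TP + FN, TN + FN)))
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator); reported as NA", call. = FALSE)
    NA_real_
  } else {
    (TP * TN - FP * FN) / mcc_den
  }
  structure(list(accuracy = (TP + TN) / total,
                 sensitivity = safe_ratio(TP, TP + FN, "sensitivity"),
                 precision = safe_ratio(TP, TP + FP, "precision"),
                 specificity = safe_ratio(TN, TN + FP, "specificity"),
                 mcc = mcc,
                 auc = NA_real_),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "   NA" else sprintf("%6.2f%%", 100 * v)
  cat(sprintf("Acc %s  Sen %s  Prec %s  Spec %s  MCC %s  AUC %s\n",
              pct(x$accuracy), pct(x$sensitivity), pct(x$precision),
              pct(x$specificity), pct(x$mcc),
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  invisible(x)
}

#' ROC curve and AUC
#'
#' TPR/FPR at every distinct score threshold (descending); tied scores are
#' grouped at a single threshold, so the trapezoidal area equals the
#' Mann-Whitney rank statistic (ties counted 1/2).
#'
#' @param y_true 0/1 labels, both classes present.
#' @param scores Numeric scores, larger = more positive.
#' @return List with `curve` (data frame `threshold`, `fpr`, `tpr`,
#'   starting at the (0, 0) point) and `auc`.
#' @export
roc_curve_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    data_error("y_true and scores differ in length")
  }
  y_true <- as.integer(y_true)
  P <- sum(y_true == 1L)
  N <- sum(y_true == 0L)
  if (P == 0L || N == 0L) {
    data_error("ROC needs both classes present")
  }
  o <- order(scores, decreasing = TRUE)
  y <- y_true[o]
  s <- scores[o]
  keep <- c(s[-length(s)] != s[-1], TRUE) # last index of each tie group
  tp <- cumsum(y == 1L)[keep]
  fp <- cumsum(y == 0L)[keep]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = c(Inf, s[keep]), fpr = fpr, tpr = tpr),
       auc = auc)
}

fold_metrics <- function(y_true, y_pred, scores) {
  rep <- compute_metrics(confusion_counts(y_true, y_pred))
  rep$auc <- roc_curve_auc(y_true, scores)$auc
  rep
}

metric_names <- c("accuracy", "sensitivity", "precision", "specificity",
                  "mcc", "auc")

#' k-fold cross-validation of the rotation forest
#'
#' Instances (pairs) are split at the pair level into k seeded random
#' folds; for each fold the model is fitted on the other k-1 folds and
#' scored on the held-out fold. The ROC score of a sample is its
#' confidence for class 1; predicted labels are the argmax. Per-fold
#' model seeds derive from `seed` and the fold index, so the whole run is
#' deterministic.
#'
#' @param dataset An `interaction_dataset` (or any list with `X`, `Y`).
#' @param config A [rof_config].
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold split and per-fold model seeds.
#' @return Object of class `cv_summary`: list with `per_fold` (data frame,
#'   one row per fold), `mean`, `sd` (named over the six metrics; sd is
#'   the sample standard deviation over folds), `k`, `config`.
#' @export
cross_validate <- function(dataset, config = rof_config(), k = 5L, seed = 1L) {
  X <- dataset$X
  Y <- dataset$Y
  N <- nrow(X)
  folds <- kfold_split(N, k, seed = seed)
  per <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(N), test_idx)
    if (length(unique(Y[train_idx])) < 2L) {
      data_error("fold ", f, " leaves a single-class training split; ",
                 "use a stratified split or rebalance the dataset")
    }
    cfg <- config
    cfg$seed <- derive_seed(seed, 900L, f, config$seed)
    model <- rof_fit(X[train_idx, , drop = FALSE], Y[train_idx], cfg)
    proba <- rof_predict_proba(model, X[test_idx, , drop = FALSE])
    pos_col <- match("1", colnames(proba))
    if (is.na(pos_col)) pos_col <- ncol(proba) # last = largest label
    scores <- proba[, pos_col]
    pred <- model$classes[max.col(proba, ties.method = "first")]
    m <- fold_metrics(Y[test_idx], pred, scores)
    per[[f]] <- data.frame(fold = f, as.data.frame(unclass(m)))
  }
  per_fold <- do.call(rbind, per)
  mean_v <- vapply(metric_names, function(nm) mean(per_fold[[nm]]), 0)
  sd_v <- vapply(metric_names, function(nm) stats::sd(per_fold[[nm]]), 0)
  structure(list(per_fold = per_fold, mean = mean_v, sd = sd_v,
                 k = as.integer(k), config = config, seed = as.integer(seed)),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (L = %d, K = %d)\n",
              x$k, x$config$L, x$config$K))
  fmt <- function(nm) {
    if (nm == "auc") sprintf("%.4f +/- %.4f", x$mean[nm], x$sd[nm])
    else sprintf("%.2f +/- %.2f %%", 100 * x$mean[nm], 100 * x$sd[nm])
  }
  for (nm in metric_names) {
    cat(sprintf("  %-12s %s\n", nm, fmt(nm)))
  }
  invisible(x)
}

#' Write a cross-validation report as TSV and JSON
#'
#' The TSV mirrors the usual presentation: one row per fold plus a
#' summary row, percentages to 2 decimals, AUC to 4. The JSON carries the
#' raw unrounded values.
#'
#' @param cv A [cross_validate] summary.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return The two paths, invisibly.
#' @export
write_cv_report <- function(cv, prefix) {
  pf <- cv$per_fold
  fmt_row <- function(label, vals, sds = NULL) {
    cells <- vapply(metric_names, function(nm) {
      v <- vals[[nm]]
      s <- if (is.null(sds)) NA_real_ else sds[[nm]]
      txt <- if (nm == "auc") sprintf("%.4f", v) else sprintf("%.2f", 100 * v)
      if (!is.null(sds)) {
        stxt <- if (nm == "auc") sprintf("%.4f", s) else sprintf("%.2f", 100 * s)
        txt <- paste0(txt, " +/- ", stxt)
      }
      txt
    }, character(1))
    paste(c(label, cells), collapse = "\t")
  }
  lines <- c(paste(c("fold", "accuracy_pct", "sensitivity_pct", "precision_pct",
                     "specificity_pct", "mcc_pct", "auc"), collapse = "\t"))
  for (i in seq_len(nrow(pf))) {
    lines <- c(lines, fmt_row(as.character(pf$fold[i]), pf[i, ]))
  }
  lines <- c(lines, fmt_row("average", as.list(cv$mean), as.list(cv$sd)))
  tsv <- paste0(prefix, ".tsv")
  writeLines(lines, tsv)
  js <- paste0(prefix, ".json")
  jsonlite::write_json(list(k = cv$k,
                            config = unclass(cv$config),
                            seed = cv$seed,
                            per_fold = pf,
                            mean = as.list(cv$mean),
                            sd = as.list(cv$sd)),
                       js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(tsv, js))
}

#' Grid search over (L, K)
#'
#' Cross-validated mean accuracy for every grid cell; the best cell is the
#' argmax, with ties resolved toward the smaller L, then the smaller K
#' (the cheaper model).
#'
#' @param dataset An `interaction_dataset`.
#' @param L_grid,K_grid Integer vectors of candidate values.
#' @param k Folds per evaluation.
#' @param seed Integer seed (shared across cells so they see the same
#'   folds).
#' @param bootstrap_fraction Passed to [rof_config].
#' @return List with `best_L`, `best_K`, `best_score`, and `table` (data
#'   frame `L`, `K`, `mean_accuracy`, `sd_accuracy`).
#' @export
grid_search <- function(dataset, L_grid, K_grid, k = 5L, seed = 1L,
                        bootstrap_fraction = 0.75) {
  if (length(L_grid) == 0L || length(K_grid) == 0L) {
    data_error("empty parameter grid")
  }
  rows <- expand.grid(L = as.integer(L_grid), K = as.integer(K_grid),
                      KEEP.OUT.ATTRS = FALSE)
  rows <- rows[order(rows$L, rows$K), , drop = FALSE]
  res <- lapply(seq_len(nrow(rows)), function(i) {
    cfg <- rof_config(rows$L[i], rows$K[i],
                      bootstrap_fraction = bootstrap_fraction, seed = seed)
    cv <- cross_validate(dataset, cfg, k = k, seed = seed)
    c(mean_accuracy = unname(cv$mean["accuracy"]),
      sd_accuracy = unname(cv$sd["accuracy"]))
  })
  tab <- cbind(rows, do.call(rbind, res))
  rownames(tab) <- NULL
  best <- tab[order(-tab$mean_accuracy, tab$L, tab$K), ][1, ]
  list(best_L = best$L, best_K = best$K,
       best_score = best$mean_accuracy, table = tab)
}
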