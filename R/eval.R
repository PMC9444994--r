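# Evaluation harness: repeated stratified k-fold cross-validation of risk
# models (pooled test-fold AUC / C-index per repeat) and Table-style model
# comparisons with rank-sum tests between configurations.

# Stratified fold assignment: cases and controls are split separately so
# every fold carries events (7% event rates leave unstratified folds
# frequently event-free).
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Train weights on `train`, score `test`, for a fixed variable set.
fold_scores <- function(data, variables, train, test, engine) {
  if (!length(variables)) return(rep(0, length(test)))
  x <- as.matrix(data[, variables, drop = FALSE])
  if (engine == "lda") {
    cls <- table(factor(data$mace[train], levels = 0:1))
    if (min(cls) < 2) {
      stop("event-free training fold after stratification")
    }
    w <- fisher_lda(x[train, , drop = FALSE], data$mace[train])$w
  } else {
    if (sum(data$event[train]) < 1) {
      stop("event-free training fold after stratification")
    }
    w <- cox_fit(x[train, , drop = FALSE], data$time[train],
                 data$event[train])$coef
  }
  drop(x[test, , drop = FALSE] %*% w)
}

#' Repeated stratified k-fold evaluation of a risk model
#'
#' For each of `repeats` random splits: stratified k folds (by MACE status);
#' model weights are refit on each training set and applied to the held-out
#' fold; the pooled held-out scores give one cross-validated AUC (LDA
#' weights) and one C-index (Cox weights) per repeat. The variable set is
#' fixed from full-data selection by default, mirroring how a single final
#' model is reported; `nested_selection` repeats the backward stepwise inside
#' every training fold instead.
#'
#' @param data Data frame with the variables plus `mace`, `time`, `event`.
#' @param variables Character vector of model variables (possibly empty).
#' @param k Folds (n must be >= k).
#' @param repeats Number of random splits.
#' @param seed RNG seed; the full 100-value distribution is reproducible.
#' @param engines Subset of `c("lda", "cox")` to evaluate.
#' @param nested_selection Re-select variables inside each training fold.
#' @param alpha Threshold for nested selection.
#' @return Object of class `lv_eval` with per-repeat `auc_k` / `cindex_k`
#'   distributions, their medians and IQRs, and resubstitution values.
#' @export
repeated_kfold_eval <- function(data, variables, k = 10, repeats = 100,
                                seed = 1, engines = c("lda", "cox"),
                                nested_selection = FALSE, alpha = 0.05) {
  n <- nrow(data)
  if (n < k) stop("n must be at least k")
  set.seed(seed)
  auc_k <- if ("lda" %in% engines) numeric(repeats) else NULL
  cindex_k <- if ("cox" %in% engines) numeric(repeats) else NULL
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(data$mace, k)
    scores_lda <- numeric(n)
    scores_cox <- numeric(n)
    for (f in seq_len(k)) {
      test <- which(fold == f)
      train <- which(fold != f)
      vars_f <- variables
      if (nested_selection && length(variables)) {
        for (eng in engines) {
          sel <- backward_stepwise(data[train, , drop = FALSE], variables,
                                   engine = eng, alpha = alpha)$selected
          if (eng == "lda") vars_lda_f <- sel else vars_cox_f <- sel
        }
      }
      if ("lda" %in% engines) {
        v <- if (nested_selection) vars_lda_f else vars_f
        scores_lda[test] <- fold_scores(data, v, train, test, "lda")
      }
      if ("cox" %in% engines) {
        v <- if (nested_selection) vars_cox_f else vars_f
        scores_cox[test] <- fold_scores(data, v, train, test, "cox")
      }
    }
    if ("lda" %in% engines) auc_k[r] <- auc(scores_lda, data$mace)
    if ("cox" %in% engines) {
      cindex_k[r] <- c_index(scores_cox, data$time, data$event)
    }
  }
  rs_lda <- if ("lda" %in% engines) {
    auc(fold_scores(data, variables, seq_len(n), seq_len(n), "lda"),
        data$mace)
  }
  rs_cox <- if ("cox" %in% engines) {
    c_index(fold_scores(data, variables, seq_len(n), seq_len(n), "cox"),
            data$time, data$event)
  }
  structure(
    list(variables = variables, k = k, repeats = repeats, seed = seed,
         auc_k = auc_k, auc_rs = rs_lda,
         auc_k_median = if (!is.null(auc_k)) stats::median(auc_k),
         auc_k_iqr = if (!is.null(auc_k)) {
           unname(stats::quantile(auc_k, c(.25, .75)))
         },
         cindex_k = cindex_k, cindex_rs = rs_cox,
         cindex_k_median = if (!is.null(cindex_k)) stats::median(cindex_k),
         cindex_k_iqr = if (!is.null(cindex_k)) {
           unname(stats::quantile(cindex_k, c(.25, .75)))
         }),
    class = "lv_eval"
  )
}

#' @method print lv_eval
#' @export
print.lv_eval <- function(x, ...) {
  cat(sprintf("Cross-validated evaluation (k = %d, %d repeats)\n", x$k,
              x$repeats))
  cat(sprintf("  variables: %s\n",
              if (length(x$variables)) paste(x$variables, collapse = ", ")
              else "(none)"))
  if (!is.null(x$auc_k)) {
    cat(sprintf("  AUC_k  %.3f (IQR %.3f-%.3f), AUC_rs %.3f\n",
                x$auc_k_median, x$auc_k_iqr[1], x$auc_k_iqr[2], x$auc_rs))
  }
  if (!is.null(x$cindex_k)) {
    cat(sprintf("  C-index_k %.3f (IQR %.3f-%.3f), C-index_rs %.3f\n",
                x$cindex_k_median, x$cindex_k_iqr[1], x$cindex_k_iqr[2],
                x$cindex_rs))
  }
  invisible(x)
}

#' Compare candidate-variable configurations
#'
#' For every named candidate pool: backward stepwise selection on the full
#' data under both engines, repeated stratified k-fold evaluation of the
#' selected sets, and pairwise rank-sum comparisons of the per-repeat
#' cross-validated AUC distributions between configurations.
#'
#' @param data Data frame with candidates plus `mace`, `time`, `event`.
#' @param configs Named list of character vectors (candidate pools), e.g.
#'   `list(esv = "esv", contraction = c("c_mode_1", ...))`.
#' @param k,repeats,seed Cross-validation settings.
#' @param alpha Stepwise threshold.
#' @param nested_selection Passed to [repeated_kfold_eval()].
#' @return Object of class `lv_model_comparison`: `table` (one row per
#'   config), `auc_k` (repeats x configs matrix), `wilcoxon_p` (pairwise
#'   matrix), `evals` and `selections`.
#' @export
compare_models <- function(data, configs, k = 10, repeats = 100, seed = 1,
                           alpha = 0.05, nested_selection = FALSE) {
  stopifnot(length(configs) >= 1, !is.null(names(configs)))
  rows <- list()
  evals <- list()
  selections <- list()
  auc_mat <- matrix(NA_real_, repeats, length(configs),
                    dimnames = list(NULL, names(configs)))
  for (nm in names(configs)) {
    pool <- configs[[nm]]
    sel_lda <- backward_stepwise(data, pool, engine = "lda",
                                 alpha = alpha)$selected
    sel_cox <- backward_stepwise(data, pool, engine = "cox",
                                 alpha = alpha)$selected
    ev_lda <- repeated_kfold_eval(data, sel_lda, k = k, repeats = repeats,
                                  seed = seed, engines = "lda",
                                  nested_selection = nested_selection,
                                  alpha = alpha)
    ev_cox <- repeated_kfold_eval(data, sel_cox, k = k, repeats = repeats,
                                  seed = seed, engines = "cox",
                                  nested_selection = nested_selection,
                                  alpha = alpha)
    auc_mat[, nm] <- ev_lda$auc_k
    selections[[nm]] <- list(lda = sel_lda, cox = sel_cox)
    evals[[nm]] <- list(lda = ev_lda, cox = ev_cox)
    rows[[nm]] <- data.frame(
      model = nm,
      lda_selection = paste(sel_lda, collapse = "+"),
      auc_k = ev_lda$auc_k_median,
      auc_k_q1 = ev_lda$auc_k_iqr[1], auc_k_q3 = ev_lda$auc_k_iqr[2],
      auc_rs = ev_lda$auc_rs,
      cox_selection = paste(sel_cox, collapse = "+"),
      cindex_k = ev_cox$cindex_k_median,
      cindex_k_q1 = ev_cox$cindex_k_iqr[1],
      cindex_k_q3 = ev_cox$cindex_k_iqr[2],
      cindex_rs = ev_cox$cindex_rs
    )
  }
  nm <- names(configs)
  wp <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (i < j) {
        wp[i, j] <- wp[j, i] <-
          wilcoxon_rank_sum(auc_mat[, i], auc_mat[, j])
      }
    }
  }
  structure(
    list(table = do.call(rbind, rows), auc_k = auc_mat, wilcoxon_p = wp,
         evals = evals, selections = selections,
         settings = list(k = k, repeats = repeats, seed = seed,
                         alpha = alpha)),
    class = "lv_model_comparison"
  )
}

#' @method print lv_model_comparison
#' @export
print.lv_model_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Model comparison (k = %d, %d repeats, seed %d)\n",
              x$settings$k, x$settings$repeats, x$settings$seed))
  tab <- x$table
  tab$auc_k <- sprintf("%.3f (%.3f-%.3f)", tab$auc_k, tab$auc_k_q1,
                       tab$auc_k_q3)
  tab$cindex_k <- sprintf("%.3f (%.3f-%.3f)", tab$cindex_k, tab$cindex_k_q1,
                          tab$cindex_k_q3)
  print(tab[, c("model", "lda_selection", "auc_k", "auc_rs",
                "cox_selection", "cindex_k", "cindex_rs")],
        row.names = FALSE, digits = digits)
  invisible(x)
}

# Plain-text rendering used by the pipeline report writer.
format_comparison_text <- function(x) {
  out <- utils::capture.output(print(x))
  wp <- x$wilcoxon_p
  out <- c(out, "", "Pairwise rank-sum p (cross-validated AUC):")
  out <- c(out, utils::capture.output(print(signif(wp, 3))))
  paste(out, collapse = "\n")
}
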