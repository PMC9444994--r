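# Backward stepwise variable selection with LDA (logistic-Wald significance)
# and Cox engines, the two-stage PCA-mode selection, and the `lv_risk_model`
# fitting interface.

# Per-variable p-values of a multivariable fit under one engine.
engine_pvalues <- function(data, variables, engine, outcome) {
  x <- as.matrix(data[, variables, drop = FALSE])
  if (engine == "lda") {
    suppressWarnings(as.numeric(logistic_wald_p(x, data[[outcome$y]])))
  } else {
    as.numeric(cox_fit(x, data[[outcome$time]], data[[outcome$event]])$p)
  }
}

#' Backward stepwise variable selection
#'
#' All candidates enter the multivariable model; the least significant
#' variable with p above `alpha` is removed and the model refitted, until
#' every remaining variable meets the threshold (possibly none). Significance
#' is the two-sided Wald p of the multivariable logistic fit (LDA engine) or
#' of the Cox partial-likelihood fit. Ties in the largest p are broken by
#' dropping the later variable in candidate order, making the procedure
#' deterministic.
#'
#' @param data Data frame holding candidates and outcome columns.
#' @param candidates Character vector of candidate column names (non-empty).
#' @param engine `"lda"` (binary MACE) or `"cox"` (time to MACE).
#' @param alpha Significance threshold.
#' @param outcome Outcome column names: list with `y` (LDA) or
#'   `time`/`event` (Cox); defaults to `mace`, `time`, `event`.
#' @return Object of class `lv_risk_model`.
#' @export
backward_stepwise <- function(data, candidates, engine = c("lda", "cox"),
                              alpha = 0.05,
                              outcome = list(y = "mace", time = "time",
                                             event = "event")) {
  engine <- match.arg(engine)
  if (!length(candidates)) stop("candidates must be non-empty")
  current <- candidates
  trace <- list()
  while (length(current)) {
    p <- engine_pvalues(data, current, engine, outcome)
    p[is.na(p)] <- 1
    trace[[length(trace) + 1L]] <- stats::setNames(p, current)
    if (all(p <= alpha)) break
    worst <- max(p)
    drop_idx <- max(which(p == worst))   # later candidate drops on ties
    current <- current[-drop_idx]
  }
  fit_risk_model(data, current, engine, alpha, outcome,
                 candidates = candidates, trace = trace)
}

# Final weights and reporting for a selected variable set.
fit_risk_model <- function(data, selected, engine, alpha, outcome,
                           candidates = selected, trace = list()) {
  model <- list(engine = engine, selected = selected,
                candidates = candidates, alpha = alpha, outcome = outcome,
                trace = trace)
  if (length(selected)) {
    x <- as.matrix(data[, selected, drop = FALSE])
    if (engine == "lda") {
      ld <- fisher_lda(x, data[[outcome$y]])
      model$weights <- stats::setNames(ld$w, selected)
      model$p <- suppressWarnings(logistic_wald_p(x, data[[outcome$y]]))
    } else {
      cx <- cox_fit(x, data[[outcome$time]], data[[outcome$event]])
      model$weights <- cx$coef
      model$hr <- cx$hr
      model$ci_low <- cx$ci_low
      model$ci_high <- cx$ci_high
      model$p <- cx$p
    }
  } else {
    model$weights <- numeric(0)
    model$p <- numeric(0)
  }
  class(model) <- "lv_risk_model"
  model
}

#' Fit an LV risk model
#'
#' Formula interface to backward stepwise risk-model fitting: the left-hand
#' side is the binary MACE indicator (LDA engine) or a `Surv(time, event)`
#' object (Cox engine); right-hand-side terms are the candidate variables.
#'
#' @param formula Model formula, e.g. `mace ~ esv + lvef` or
#'   `survival::Surv(time, event) ~ esv + age`.
#' @param data Data frame.
#' @param engine `"lda"` or `"cox"`; inferred from the response when
#'   omitted.
#' @param alpha Stepwise significance threshold.
#' @param stepwise Run backward selection (TRUE) or fit all terms (FALSE).
#' @return An `lv_risk_model` with `print`, `summary`, `coef` and `predict`
#'   methods.
#' @export
lv_risk_model <- function(formula, data, engine = NULL, alpha = 0.05,
                          stepwise = TRUE) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  resp <- stats::model.response(mf)
  terms_x <- attr(stats::terms(mf), "term.labels")
  work <- as.data.frame(mf[, terms_x, drop = FALSE])
  names(work) <- terms_x
  if (survival::is.Surv(resp)) {
    if (is.null(engine)) engine <- "cox"
    work$.time <- resp[, 1]
    work$.event <- resp[, 2]
    outcome <- list(time = ".time", event = ".event")
  } else {
    if (is.null(engine)) engine <- "lda"
    work$.y <- as.integer(resp)
    outcome <- list(y = ".y", time = ".time", event = ".event")
  }
  if (stepwise) {
    backward_stepwise(work, terms_x, engine = engine, alpha = alpha,
                      outcome = outcome)
  } else {
    fit_risk_model(work, terms_x, engine, alpha, outcome)
  }
}

#' @export
coef.lv_risk_model <- function(object, ...) object$weights

#' @method print lv_risk_model
#' @export
print.lv_risk_model <- function(x, ...) {
  cat(sprintf("LV risk model (%s engine, alpha = %.2f)\n",
              toupper(x$engine), x$alpha))
  if (!length(x$selected)) {
    cat("  no variable retained by backward stepwise selection\n")
    return(invisible(x))
  }
  cat(sprintf("  selected (%d of %d candidates): %s\n", length(x$selected),
              length(x$candidates), paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' @method summary lv_risk_model
#' @export
summary.lv_risk_model <- function(object, ...) {
  if (!length(object$selected)) {
    cat("Empty risk model (nothing selected)\n")
    return(invisible(object))
  }
  print(object)
  tab <- data.frame(variable = object$selected,
                    weight = unname(object$weights),
                    p = unname(object$p[object$selected]))
  if (object$engine == "cox") {
    tab$hr <- unname(object$hr)
    tab$ci <- sprintf("%.2f-%.2f", object$ci_low, object$ci_high)
  }
  print(tab, row.names = FALSE, digits = 3)
  invisible(tab)
}

#' Risk scores for new data
#'
#' @param object An `lv_risk_model`.
#' @param newdata Data frame with the selected variables.
#' @param ... Unused.
#' @return Numeric risk scores (`w'x`; constant 0 for an empty model).
#' @export
predict.lv_risk_model <- function(object, newdata, ...) {
  if (!length(object$selected)) return(rep(0, nrow(newdata)))
  drop(as.matrix(newdata[, object$selected, drop = FALSE]) %*%
         object$weights)
}

#' Two-stage selection of risk-related PCA modes
#'
#' Stage 1 runs backward stepwise selection separately within the ES shape
#' modes and within the contraction modes (each truncated at the configured
#' variance fraction); stage 2 reruns the selection on the union of the
#' stage-1 survivors, capturing cross-family redundancy.
#'
#' @param es_scores Matrix of ES shape mode scores (columns `es_mode_k`
#'   assigned if unnamed).
#' @param contraction_scores Matrix of contraction mode scores.
#' @param y Binary MACE labels.
#' @param alpha Stepwise threshold.
#' @return List with `selected` (final column names), `stage1_es`,
#'   `stage1_contraction`, `model` (final `lv_risk_model`) and `data` (the
#'   combined score frame used).
#' @export
two_stage_mode_selection <- function(es_scores, contraction_scores, y,
                                     alpha = 0.05) {
  es_scores <- as.matrix(es_scores)
  contraction_scores <- as.matrix(contraction_scores)
  colnames(es_scores) <- paste0("es_mode_", seq_len(ncol(es_scores)))
  colnames(contraction_scores) <-
    paste0("c_mode_", seq_len(ncol(contraction_scores)))
  df <- data.frame(es_scores, contraction_scores, mace = as.integer(y))
  s_es <- backward_stepwise(df, colnames(es_scores), engine = "lda",
                            alpha = alpha)$selected
  s_c <- backward_stepwise(df, colnames(contraction_scores), engine = "lda",
                           alpha = alpha)$selected
  union_vars <- c(s_es, s_c)
  if (!length(union_vars)) {
    model <- fit_risk_model(df, character(0), "lda", alpha,
                            list(y = "mace"))
  } else {
    model <- backward_stepwise(df, union_vars, engine = "lda", alpha = alpha)
  }
  list(selected = model$selected, stage1_es = s_es, stage1_contraction = s_c,
       model = model, data = df)
}
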