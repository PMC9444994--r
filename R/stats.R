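# Statistical engines: Fisher LDA, logistic Wald significance, Cox fits,
# AUC / concordance index, Wilcoxon / Spearman utilities, Kaplan-Meier.

#' Fisher linear discriminant direction
#'
#' `w` proportional to `Sw^-1 (mu1 - mu0)` with the pooled within-class
#' covariance `Sw` (n - 2 denominator), normalized to unit length. A ridge of
#' `1e-8 * mean diagonal` is added when `Sw` is numerically singular.
#'
#' @param x Numeric matrix (subjects x features).
#' @param y Binary class labels (0/1), each class with >= 2 subjects.
#' @return List with `w` (unit direction) and `scores` (`x %*% w`).
#' @export
fisher_lda <- function(x, y) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) != 2) stop("two classes required")
  if (min(table(y)) < 2) stop("each class needs at least 2 subjects")
  x1 <- x[y == 1, , drop = FALSE]
  x0 <- x[y == 0, , drop = FALSE]
  sw <- (crossprod(sweep(x1, 2, colMeans(x1))) +
           crossprod(sweep(x0, 2, colMeans(x0)))) / (nrow(x) - 2)
  delta <- colMeans(x1) - colMeans(x0)
  w <- tryCatch(solve(sw, delta), error = function(e) {
    ridge <- 1e-8 * mean(diag(sw)) + 1e-12
    solve(sw + diag(ridge, ncol(sw)), delta)
  })
  w <- w / sqrt(sum(w^2))
  list(w = w, scores = drop(x %*% w))
}

# Ridge-penalized IRLS logistic fit; fallback under separation.
penalized_logistic <- function(x, y, ridge = 1e-3) {
  xm <- cbind(1, x)
  beta <- rep(0, ncol(xm))
  pen <- diag(c(0, rep(ridge, ncol(x))), ncol(xm))
  for (it in 1:50) {
    eta <- drop(xm %*% beta)
    p <- stats::plogis(eta)
    wt <- pmax(p * (1 - p), 1e-10)
    info <- crossprod(xm, xm * wt) + pen
    score <- crossprod(xm, y - p) - pen %*% beta
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  se <- sqrt(diag(solve(info)))
  list(coef = drop(beta), se = se)
}

#' Per-variable Wald p-values from a multivariable logistic fit
#'
#' Significance of features in the linear discriminant is approximated as
#' significance in the binomial GLM with logit link (intercept included).
#' Complete or quasi-separation triggers a flagged ridge-penalized refit;
#' duplicated (aliased) columns are flagged as collinear.
#'
#' @param x Numeric matrix (subjects x features).
#' @param y Binary outcome (0/1).
#' @return Named vector of two-sided Wald p-values (one per column of `x`),
#'   with attributes `separation` and `collinear`.
#' @export
logistic_wald_p <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  df <- data.frame(.y = y, x, check.names = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  collinear <- anyNA(stats::coef(fit))
  if (collinear) {
    warning("collinear features detected (aliased coefficients)")
  }
  if (separation) {
    pf <- penalized_logistic(x, y)
    z <- pf$coef / pf$se
    p <- 2 * stats::pnorm(-abs(z))[-1]
  } else {
    sm <- summary(fit)$coefficients
    p <- rep(NA_real_, ncol(x))
    rn <- rownames(sm)
    for (j in seq_len(ncol(x))) {
      hit <- match(make.names(colnames(x)[j]), make.names(rn))
      if (!is.na(hit)) p[j] <- sm[hit, 4]
    }
    p[is.na(p)] <- 1  # aliased columns cannot be significant
  }
  names(p) <- colnames(x)
  attr(p, "separation") <- separation
  attr(p, "collinear") <- collinear
  p
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling (day-resolution
#' times make ties common). Hazard ratios are `exp(beta)` with Wald 95% CIs.
#'
#' @param x Numeric matrix (subjects x covariates).
#' @param time Follow-up times (> 0).
#' @param event Event indicator (0/1), at least one event.
#' @return List with `coef`, `hr`, `ci_low`, `ci_high`, `p` (named vectors)
#'   and `flags` (monotone-likelihood warnings).
#' @export
cox_fit <- function(x, time, event) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (sum(event) < 1) stop("at least one event required")
  if (any(!is.finite(time))) stop("infinite times")
  flags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "efron"),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  beta <- sm[, "coef"]
  se <- sm[, "se(coef)"]
  names(beta) <- colnames(x)
  list(coef = beta,
       hr = stats::setNames(exp(beta), colnames(x)),
       ci_low = stats::setNames(exp(beta - 1.96 * se), colnames(x)),
       ci_high = stats::setNames(exp(beta + 1.96 * se), colnames(x)),
       p = stats::setNames(sm[, "Pr(>|z|)"], colnames(x)),
       flags = flags, fit = fit)
}

#' Area under the ROC curve
#'
#' Mann-Whitney statistic: the probability that a random case scores above a
#' random control, with half credit for ties.
#'
#' @param scores Risk scores (higher = riskier).
#' @param y Binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Concordance index for survival data
#'
#' Fraction of comparable pairs (the subject with the shorter observed time
#' has the event) in which the riskier-scored subject fails earlier, with
#' half credit for tied scores.
#'
#' @param scores Risk scores (higher = riskier).
#' @param time Follow-up times.
#' @param event Event indicator (0/1).
#' @return C-index in `[0, 1]`.
#' @export
c_index <- function(scores, time, event) {
  cc <- survival::concordance(survival::Surv(time, event) ~ scores,
                              reverse = TRUE)
  n_comp <- sum(cc$count[1:3])
  if (n_comp == 0) stop("no comparable pairs")
  unname(cc$concordance)
}

#' Wilcoxon rank-sum test (two-sided p)
#'
#' Exact for small samples without ties, normal approximation with tie
#' correction otherwise (the `stats::wilcox.test` conventions).
#'
#' @param a,b Numeric samples.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("non-empty samples required")
  if (identical(sort(a), sort(b))) return(1)
  suppressWarnings(stats::wilcox.test(a, b, exact = NULL)$p.value)
}

#' Spearman rank correlation
#'
#' @param a,b Numeric vectors of equal length.
#' @return `r_s` (rank Pearson with average ranks).
#' @export
spearman <- function(a, b) {
  stats::cor(a, b, method = "spearman")
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator via `survival::survfit`, one stratum per group,
#' with censoring marks retained.
#'
#' @param time Follow-up times.
#' @param event Event indicator (0/1).
#' @param groups Optional group labels (single curve when omitted).
#' @return A `survfit` object.
#' @export
kaplan_meier <- function(time, event, groups = NULL) {
  if (is.null(groups)) groups <- rep(1L, length(time))
  df <- data.frame(time = time, event = event, g = factor(groups))
  survival::survfit(survival::Surv(time, event) ~ g, data = df)
}
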