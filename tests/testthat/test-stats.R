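# Statistical engines against independent brute-force oracles.

brute_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

brute_c_index <- function(scores, time, event) {
  n <- length(time)
  num <- den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (time[i] < time[j] && event[i] == 1) {
        den <- den + 1
        num <- num + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
      }
    }
  }
  num / den
}

test_that("AUC equals brute-force pair enumeration, with ties", {
  y <- c(1, 0, 1, 0, 0, 1, 0, 1, 0, 0)
  s <- c(2.5, 1.0, 3.0, 2.5, 0.5, 2.0, 2.0, 4.0, 3.0, 1.5)
  expect_equal(auc(s, y), brute_auc(s, y))
  s2 <- c(9, 1, 8, 2, 3, 7, 4, 6, 5, 0)
  expect_equal(auc(s2, y), brute_auc(s2, y))
  expect_error(auc(s, rep(1, 10)), "both classes")
})

test_that("AUC is bounded and invariant under increasing transforms", {
  set.seed(21)
  y <- rbinom(60, 1, 0.3)
  y[1:2] <- c(0, 1)
  s <- rnorm(60) + y
  a0 <- auc(s, y)
  expect_gte(a0, 0)
  expect_lte(a0, 1)
  expect_equal(auc(exp(s), y), a0)
  expect_equal(auc(qlogis(plogis(2 * s + 5)), y), a0, tolerance = 1e-12)
  expect_equal(auc(-s, y), 1 - a0)
})

test_that("C-index equals brute-force enumeration over comparable pairs", {
  time <- c(5, 8, 12, 3, 9, 20, 15, 7, 11, 2)
  event <- c(1, 0, 1, 1, 0, 0, 1, 1, 0, 0)
  s <- c(3.2, 1.1, 2.0, 4.0, 0.5, 0.2, 1.5, 2.0, 1.0, 3.0)
  expect_equal(c_index(s, time, event), brute_c_index(s, time, event))
  # no-censoring case with distinct everything
  time2 <- 1:8
  s3 <- c(8, 6, 7, 5, 4, 2, 3, 1)
  expect_equal(c_index(s3, time2, rep(1, 8)),
               brute_c_index(s3, time2, rep(1, 8)))
  expect_error(c_index(s3, rep(1, 8), rep(0, 8)), "no comparable")
})

test_that("Wilcoxon rank-sum matches the exact reference", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3)
  a <- c(1.2, 3.4, 2.2, 5.1)
  b <- c(0.4, 2.9, 1.1)
  expect_equal(wilcoxon_rank_sum(a, b), wilcox.test(a, b, exact = TRUE)$p.value)
  expect_equal(wilcoxon_rank_sum(a, a), 1)
  expect_error(wilcoxon_rank_sum(numeric(0), a), "non-empty")
})

test_that("Cox beta matches a 1-D brute-force partial likelihood", {
  set.seed(31)
  n <- 40
  x <- rnorm(n)
  time <- round(rexp(n, exp(0.7 * x)) * 100) + seq_len(n) / n  # untied
  event <- rbinom(n, 1, 0.7)
  event[1] <- 1
  fit <- cox_fit(matrix(x), time, event)
  neg_pl <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    -ll
  }
  beta_hat <- optimize(neg_pl, c(-5, 5), tol = 1e-10)$minimum
  expect_equal(unname(fit$coef), beta_hat, tolerance = 1e-6)
  expect_equal(unname(fit$hr), exp(beta_hat), tolerance = 1e-5)
  expect_true(unname(fit$ci_low) < unname(fit$hr) &
                unname(fit$hr) < unname(fit$ci_high))
  expect_error(cox_fit(matrix(x), time, rep(0, n)), "at least one event")
})

test_that("Kaplan-Meier matches hand product-limit values", {
  time <- c(1, 2, 3, 4, 5)
  event <- c(1, 0, 1, 1, 0)
  km <- kaplan_meier(time, event)
  s_hand <- c(4 / 5, 4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2,
              4 / 5 * 2 / 3 * 1 / 2)
  expect_equal(summary(km, times = time)$surv, s_hand)
  km2 <- kaplan_meier(c(time, time), c(event, event),
                      groups = rep(c("a", "b"), each = 5))
  expect_equal(length(km2$strata), 2L)
})

test_that("Fisher LDA matches the closed form and logistic ordering", {
  set.seed(41)
  n <- 300
  y <- rep(0:1, each = n / 2)
  mu <- rbind(c(0, 0, 0), c(1, 0.5, -0.5))
  x <- mu[y + 1, ] + matrix(rnorm(3 * n), n, 3) %*%
    chol(matrix(c(1, .3, 0, .3, 1, .2, 0, .2, 1), 3))
  ld <- fisher_lda(x, y)
  expect_equal(sum(ld$w^2), 1)
  # closed form: Sw^-1 (mu1 - mu0), pooled within-class covariance
  x1 <- x[y == 1, ]; x0 <- x[y == 0, ]
  sw <- (crossprod(scale(x1, scale = FALSE)) +
           crossprod(scale(x0, scale = FALSE))) / (n - 2)
  w_ref <- solve(sw, colMeans(x1) - colMeans(x0))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_equal(unname(ld$w), unname(w_ref), tolerance = 1e-9)
  expect_equal(unname(ld$scores), unname(drop(x %*% w_ref)), tolerance = 1e-9)
  # equal-covariance Gaussian limit: LDA and logistic scores agree in rank
  glm_scores <- predict(glm(y ~ x, family = binomial()))
  expect_gt(cor(rank(ld$scores), rank(glm_scores)), 0.99)
  expect_error(fisher_lda(x, rep(1, n)), "two classes")
  expect_error(fisher_lda(x[1:3, ], c(0, 1, 1)), "at least 2")
})

test_that("logistic Wald p-values match glm and flag pathologies", {
  set.seed(51)
  n <- 200
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, plogis(-1 + x[, 1]))
  p <- logistic_wald_p(x, y)
  ref <- summary(glm(y ~ x, family = binomial()))$coefficients[-1, 4]
  expect_equal(as.numeric(p), unname(ref))
  expect_false(attr(p, "separation"))
  # complete separation: finite p from the penalized fallback
  ysep <- as.integer(x[, 1] > 0)
  psep <- logistic_wald_p(x, ysep)
  expect_true(attr(psep, "separation"))
  expect_true(all(is.finite(psep)))
  expect_lt(psep[1], 0.05)
  # duplicated column is flagged collinear and cannot be significant
  xdup <- cbind(x, a2 = x[, 1])
  expect_warning(pdup <- logistic_wald_p(xdup, y), "collinear")
  expect_equal(unname(pdup[3]), 1)
})

test_that("spearman equals the reference rank correlation", {
  set.seed(61)
  a <- rnorm(50)
  b <- a + rnorm(50)
  expect_equal(spearman(a, b), cor(a, b, method = "spearman"))
  expect_equal(spearman(a, exp(a)), 1)
})
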