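test_that("univariate logistic OR equals the 2x2 cross-product ratio", {
  # counts: y=1&x=1: 20, y=1&x=0: 10, y=0&x=1: 10, y=0&x=0: 20
  x <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  y <- c(rep(1, 30), rep(0, 30))
  fm <- fm_from_matrix(matrix(x, dimnames = list(NULL, "f")), target = y)
  row <- univariate_logistic(fm, "f")
  expect_equal(row$estimate, (20 * 20) / (10 * 10), tolerance = 1e-6)
  expect_true(row$ci_lo < row$estimate && row$estimate < row$ci_hi)
  # exactly proportional counts -> OR 1
  x2 <- rep(c(1, 1, 0, 0), 10); y2 <- rep(c(1, 0), 20)
  fm2 <- fm_from_matrix(matrix(x2, dimnames = list(NULL, "f")),
                        target = y2)
  expect_equal(univariate_logistic(fm2, "f")$estimate, 1,
               tolerance = 1e-6)
  # complete separation flagged with unbounded CI
  x3 <- rep(c(1, 0), each = 15); y3 <- x3
  fm3 <- fm_from_matrix(matrix(x3, dimnames = list(NULL, "f")),
                        target = y3)
  row3 <- univariate_logistic(fm3, "f")
  expect_true(row3$separation)
  expect_equal(row3$ci_hi, Inf)
  # constant feature rejected
  fm4 <- fm_from_matrix(matrix(1, 30, 1, dimnames = list(NULL, "f")),
                        target = y3)
  expect_error(univariate_logistic(fm4, "f"), "no variation")
})

test_that("planted odds ratios are recovered with near-nominal coverage", {
  # generator plants an epistatic OR of 5 on SAD; the univariate logistic
  # CI should cover 5 in >= 90% of replicates at n = 500
  hits <- 0; reps <- 40
  for (s in seq_len(reps)) {
    set.seed(s)
    n <- 500
    carrier <- rbinom(n, 1, 0.18)
    y <- rbinom(n, 1, plogis(qlogis(0.15) + log(5) * carrier))
    if (length(unique(y)) < 2) next
    fm <- fm_from_matrix(matrix(carrier, dimnames = list(NULL, "f")),
                         target = y)
    row <- univariate_logistic(fm, "f")
    if (!row$separation && row$ci_lo <= 5 && 5 <= row$ci_hi) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / reps, 0.9)
})

test_that("BH adjustment follows the hand step-up computation", {
  expect_equal(adjust_p(0.04), 0.04)
  expect_equal(adjust_p(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_p(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.01, 0.04, 0.8)
  expect_true(all(adjust_p(p) >= p))
  expect_error(adjust_p(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(adjust_p(c(0.01, 0.5), method = "bonferroni"),
               c(0.02, 1.0))
  expect_equal(adjust_p(c(0.01, 0.5), method = "none"), c(0.01, 0.5))
})

test_that("stepwise AIC keeps true predictors and never raises AIC", {
  found <- 0; reps <- 20
  for (s in seq_len(reps)) {
    set.seed(s + 100)
    n <- 400
    true <- rbinom(n, 1, 0.5)
    noise <- matrix(rbinom(n * 9, 1, 0.5), n,
                    dimnames = list(NULL, paste0("z", 1:9)))
    y <- rbinom(n, 1, plogis(1.6 * true - 0.8))
    x <- cbind(true = true, noise)
    fm <- fm_from_matrix(x, target = y)
    res <- stepwise_multivariate(fm, family = "logistic")
    if ("true" %in% res$report$feature) found <- found + 1
    expect_true(all(diff(res$aic_trace) <= 1e-9))
  }
  expect_gte(found / reps, 0.95)
})

test_that("stepwise with no improving move returns the full model", {
  set.seed(9)
  n <- 300
  a <- rnorm(n); b <- rnorm(n)
  y <- a + b + rnorm(n, 0, 0.2)   # both indispensable
  fm <- fm_from_matrix(cbind(a = a, b = b), target = NULL,
                       type = "numeric")
  res <- stepwise_multivariate(fm, outcome = y, family = "linear")
  expect_setequal(res$report$feature, c("a", "b"))
  expect_equal(length(res$aic_trace), 1)
})

test_that("candidate sets larger than 20 are rejected", {
  x <- matrix(rnorm(25 * 30), 30)
  colnames(x) <- paste0("f", 1:25)
  fm <- fm_from_matrix(x, target = rbinom(30, 1, 0.5))
  expect_error(stepwise_multivariate(fm, family = "logistic"),
               "at most 20")
})

test_that("type-III ANOVA matches an OLS contrast oracle", {
  # cell means (10, 10, 10, 14), sd 1, n = 20/cell
  set.seed(11)
  ncell <- 20
  g <- factor(rep(c(0, 1), each = 2 * ncell))
  s <- factor(rep(rep(c("F", "M"), each = ncell), 2))
  mu <- ifelse(g == 1 & s == "M", 14, 10)
  y <- mu + rnorm(4 * ncell)
  rep_ <- anova_typeIII(y, g, s)
  # independent oracle: full-rank OLS with sum contrasts; each type-III F
  # is the Wald test of the corresponding coefficient (1 df each)
  gi <- ifelse(g == 1, 1, -1); si <- ifelse(s == "M", 1, -1)
  X <- cbind(1, gi, si, gi * si)
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df2 <- length(y) - 4
  XtXinv <- solve(crossprod(X))
  se2 <- diag(XtXinv) * rss / df2
  F_oracle <- fit$coefficients^2 / se2
  expect_equal(rep_$table$F, unname(F_oracle[2:4]), tolerance = 1e-8)
  expect_equal(rep_$table$df2, rep(df2, 3))
  # balanced design: type-III equals sequential type-I
  a1 <- anova(lm(y ~ g * s))
  expect_equal(rep_$table$F, a1$`F value`[1:3], tolerance = 1e-8)
  # Tukey rows cover the 4x3/2 cell pairs
  expect_equal(nrow(rep_$tukey), 6)
})

test_that("ANOVA on identical groups gives F near zero", {
  set.seed(12)
  y <- rnorm(200)
  g <- factor(rep(0:1, 100)); s <- factor(rep(c("F", "M"), each = 100))
  rep_ <- anova_typeIII(y, g, s)
  expect_true(all(rep_$table$p > 0.01))
})

test_that("empty cells downgrade to the additive model with a warning", {
  y <- rnorm(60)
  g <- factor(c(rep(0, 40), rep(1, 20)))
  s <- factor(c(rep("F", 20), rep("M", 20), rep("F", 20)))  # no g=1,M
  expect_warning(rep_ <- anova_typeIII(y, g, s), "interaction")
  expect_equal(nrow(rep_$table), 2)
})

test_that("univariate logistic is null-calibrated at the 5% level", {
  # type-I error over replicates of a null cohort-like draw
  reps <- 300; alpha_hits <- 0
  for (s in seq_len(reps)) {
    set.seed(s + 500)
    n <- 300
    x <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, 0.3)
    fm <- fm_from_matrix(matrix(x, dimnames = list(NULL, "f")),
                         target = y)
    row <- univariate_logistic(fm, "f")
    if (!is.na(row$p) && row$p < 0.05) alpha_hits <- alpha_hits + 1
  }
  expect_lt(abs(alpha_hits / reps - 0.05), 0.03)
})
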