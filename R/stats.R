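#' Univariate logistic regression for one feature
#'
#' Maximum-likelihood logit of a binary outcome on a single encoded
#' feature; for a binary 0/1 predictor the fitted odds ratio equals the
#' 2x2 contingency cross-product ratio exactly. Wald 95% confidence
#' intervals by default. Complete separation is flagged and the CI reported
#' as unbounded.
#'
#' @param fm A `feature_matrix` (its `target` is the outcome), or a plain
#'   list with `values` and `target`.
#' @param feature Encoded feature (column) name.
#' @param outcome Optional outcome vector overriding `fm$target`.
#' @param ci One of `"wald"` (default) or `"profile"`.
#' @param stratum,analysis Labels carried into the report row.
#' @return One-row data.frame: feature, stratum, outcome, analysis, or,
#'   ci_lo, ci_hi, p, separation flag.
#' @export
univariate_logistic <- function(fm, feature, outcome = NULL,
                                ci = c("wald", "profile"),
                                stratum = "all", analysis = "univariate-logistic") {
  ci <- match.arg(ci)
  x <- fm$values[, feature]
  y <- outcome %||% fm$target
  if (length(unique(y[!is.na(y)])) != 2) {
    stop("binary outcome required", call. = FALSE)
  }
  if (stats::var(x, na.rm = TRUE) == 0) {
    stop("feature '", feature, "' has no variation", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  fit <- suppressWarnings(
    stats::glm(y[ok] ~ x[ok], family = stats::binomial()))
  beta <- stats::coef(fit)[2]
  se <- sqrt(diag(stats::vcov(fit)))[2]
  separated <- !fit$converged || se > 10 || abs(beta) > 15
  if (separated) {
    lo <- 0; hi <- Inf; p <- NA_real_
  } else if (ci == "wald") {
    lo <- exp(beta - 1.96 * se); hi <- exp(beta + 1.96 * se)
    p <- 2 * stats::pnorm(-abs(beta / se))
  } else {
    cf <- suppressWarnings(suppressMessages(stats::confint(fit)))[2, ]
    lo <- exp(cf[1]); hi <- exp(cf[2])
    p <- 2 * stats::pnorm(-abs(beta / se))
  }
  data.frame(feature = feature, stratum = stratum,
             outcome = fm$target_name %||% "outcome",
             analysis = analysis,
             estimate = unname(exp(beta)), ci_lo = unname(lo),
             ci_hi = unname(hi), p = unname(p), separation = separated,
             stringsAsFactors = FALSE)
}

#' Univariate logistic screen over a feature set with adjusted p-values
#'
#' Runs [univariate_logistic()] per feature (features without variation or
#' with complete separation are flagged, not dropped) and appends adjusted
#' p-values within the family.
#'
#' @param fm A `feature_matrix`.
#' @param features Character vector of encoded feature names (defaults to
#'   all columns).
#' @param method Adjustment method: `"BH"` (default), `"bonferroni"`, or
#'   `"none"`.
#' @inheritParams univariate_logistic
#' @return Data.frame with one row per feature and an `adj_p` column.
#' @export
univariate_screen <- function(fm, features = colnames(fm$values),
                              method = c("BH", "bonferroni", "none"),
                              stratum = "all") {
  method <- match.arg(method)
  rows <- lapply(features, function(f) {
    if (stats::var(fm$values[, f], na.rm = TRUE) == 0) return(NULL)
    univariate_logistic(fm, f, stratum = stratum)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$adj_p <- adjust_p(out$p, method = method)
  out
}

#' Benjamini-Hochberg (or Bonferroni) p-value adjustment
#'
#' Thin validated wrapper around [stats::p.adjust()]; `NA`s (e.g. from
#' separated fits) are passed through.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @param method `"BH"` (default), `"bonferroni"` or `"none"`.
#' @return Adjusted p-values, each at least the raw value.
#' @export
adjust_p <- function(pvalues, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (method == "none") return(pvalues)
  stats::p.adjust(pvalues, method = method)
}

#' Stepwise-AIC multivariate regression
#'
#' Fits the full model on the supplied features (at most 20; the
#' consensus top-20 is the intended input) and applies bidirectional
#' stepwise selection by AIC (via [MASS::stepAIC()]): at each step the
#' single add/drop most reducing AIC is taken, stopping when no move
#' improves. Logistic for binary outcomes, linear for score outcomes.
#'
#' @param fm A `feature_matrix` restricted to (or intersected with) the
#'   candidate features.
#' @param outcome Outcome vector (binary for logistic, numeric for linear);
#'   defaults to `fm$target`.
#' @param family `"logistic"` or `"linear"`.
#' @param features Candidate feature names (default: all columns, capped
#'   at 20).
#' @param stratum Label carried into the report.
#' @return List with `report` (data.frame of the final model's terms:
#'   estimate = OR for logistic, coefficient for linear, Wald 95% CI, p)
#'   and `aic_trace` (AIC at each accepted step, non-increasing).
#' @export
stepwise_multivariate <- function(fm, outcome = NULL,
                                  family = c("logistic", "linear"),
                                  features = NULL, stratum = "all") {
  family <- match.arg(family)
  y <- outcome %||% fm$target
  feats <- features %||% colnames(fm$values)
  if (length(feats) > 20) {
    stop("at most 20 candidate features (use the consensus top-20)",
         call. = FALSE)
  }
  x <- fm$values[, feats, drop = FALSE]
  ok <- stats::complete.cases(x) & !is.na(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok]
  # syntactic aliases for encoded names like "CRY2=AA|PER3VNTR=4,5"
  alias <- paste0("f", seq_along(feats))
  df <- as.data.frame(x)
  names(df) <- alias
  df$.y <- y
  # drop non-varying candidates (cannot enter any model)
  keep <- vapply(alias, function(a) stats::var(df[[a]]) > 0, TRUE)
  alias_kept <- alias[keep]
  form <- stats::as.formula(
    paste(".y ~", paste(alias_kept, collapse = " + ")))
  full <- if (family == "logistic") {
    suppressWarnings(stats::glm(form, data = df,
                                family = stats::binomial()))
  } else {
    stats::lm(form, data = df)
  }
  sel <- suppressWarnings(
    MASS::stepAIC(full, direction = "both", trace = 0))
  aic_trace <- sel$anova$AIC
  cf <- summary(sel)$coefficients
  terms_kept <- setdiff(rownames(cf), "(Intercept)")
  est <- cf[terms_kept, 1]; se <- cf[terms_kept, 2]
  p <- cf[terms_kept, 4]
  if (family == "logistic") {
    estimate <- exp(est); lo <- exp(est - 1.96 * se); hi <- exp(est + 1.96 * se)
    tag <- "multivariate-logistic"
  } else {
    estimate <- est; lo <- est - 1.96 * se; hi <- est + 1.96 * se
    tag <- "multivariate-linear"
  }
  report <- data.frame(
    feature = feats[match(terms_kept, alias)],
    stratum = stratum, outcome = fm$target_name %||% "outcome",
    analysis = tag, estimate = unname(estimate),
    ci_lo = unname(lo), ci_hi = unname(hi), p = unname(p),
    separation = FALSE, stringsAsFactors = FALSE)
  report$adj_p <- adjust_p(report$p)
  list(report = report, aic_trace = aic_trace, model = sel)
}

#' Type-III two-way ANOVA with Tukey post hoc
#'
#' Marginal (type-III) sums of squares with sum-to-zero contrasts for a
#' score outcome on a genotype indicator crossed with gender, plus Tukey
#' HSD over the four genotype x gender cells. If a cell is empty the
#' interaction test is skipped with a warning.
#'
#' @param scores Numeric outcome (e.g. SPAQ).
#' @param genotype Binary factor/indicator (carrier vs non-carrier).
#' @param gender Factor with two levels.
#' @return An `anova_report`: data.frame `table` (term, F, df, p) and
#'   `tukey` (pairwise cell differences with adjusted p).
#' @export
anova_typeIII <- function(scores, genotype, gender) {
  g <- factor(genotype); s <- factor(gender)
  ok <- !is.na(scores) & !is.na(g) & !is.na(s)
  scores <- scores[ok]; g <- droplevels(g[ok]); s <- droplevels(s[ok])
  cells <- table(g, s)
  has_interaction <- all(cells > 0)
  df <- data.frame(y = scores, g = g, s = s)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  if (has_interaction) {
    fit <- stats::lm(y ~ g * s, data = df)
  } else {
    warning("empty genotype x gender cell; interaction test skipped",
            call. = FALSE)
    fit <- stats::lm(y ~ g + s, data = df)
  }
  a3 <- car::Anova(fit, type = 3)
  terms <- setdiff(rownames(a3), c("(Intercept)", "Residuals"))
  tab <- data.frame(
    term = c("genotype", "gender", "genotype:gender")[seq_along(terms)],
    F = a3[terms, "F value"],
    df1 = a3[terms, "Df"],
    df2 = a3["Residuals", "Df"],
    p = a3[terms, "Pr(>F)"],
    stringsAsFactors = FALSE)
  cell <- interaction(g, s, sep = ":")
  tk <- if (nlevels(cell) > 1) {
    stats::TukeyHSD(stats::aov(y ~ cell, data = data.frame(y = scores,
                                                           cell = cell)))$cell
  } else NULL
  structure(list(table = tab, tukey = tk, cells = cells),
            class = "anova_report")
}

#' @export
#' @method print anova_report
print.anova_report <- function(x, ...) {
  cat("<anova_report>\n")
  for (i in seq_len(nrow(x$table))) {
    cat(sprintf("  %-16s F_%d,%d = %.3f, p = %.4g\n",
                x$table$term[i], x$table$df1[i], x$table$df2[i],
                x$table$F[i], x$table$p[i]))
  }
  invisible(x)
}

#' Run the regression battery per stratum
#'
#' Convenience wrapper reproducing the reporting shape of the headline
#' association table: univariate logistic on the stable set plus stepwise
#' multivariate logistic (and linear for score outcomes) on the top-20,
#' each run for all participants and per gender.
#'
#' @param cohort The cohort (needed for gender stratification).
#' @param fm The encoded `feature_matrix` built from `cohort`.
#' @param selection A `selection_result`.
#' @param score Optional numeric score outcome for the linear arm (e.g.
#'   `cohort$spaq`); skipped when `NULL`.
#' @param strata Subset of `c("all", "M", "F")`.
#' @return Data.frame stacking all report rows.
#' @export
regression_battery <- function(cohort, fm, selection, score = NULL,
                               strata = c("all", "M", "F")) {
  rows <- list()
  stable <- intersect(selection$stable, colnames(fm$values))
  top20 <- intersect(selection$top20, colnames(fm$values))
  for (st in strata) {
    idx <- if (st == "all") seq_len(nrow(fm$values)) else {
      which(as.character(cohort$gender) == st)
    }
    sub <- fm
    sub$values <- fm$values[idx, , drop = FALSE]
    sub$target <- fm$target[idx]
    if (length(stable)) {
      uni <- univariate_screen(sub, stable, stratum = st)
      rows[[length(rows) + 1L]] <- uni
    }
    varying <- top20[apply(sub$values[, top20, drop = FALSE], 2,
                           function(v) stats::var(v, na.rm = TRUE) > 0)]
    if (length(varying) >= 2 && length(unique(sub$target)) == 2) {
      mv <- stepwise_multivariate(sub, family = "logistic",
                                  features = varying, stratum = st)
      rows[[length(rows) + 1L]] <- mv$report
      if (!is.null(score)) {
        lin <- stepwise_multivariate(sub, outcome = score[idx],
                                     family = "linear",
                                     features = varying, stratum = st)
        rows[[length(rows) + 1L]] <- lin$report
      }
    }
  }
  do.call(rbind, rows)
}
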