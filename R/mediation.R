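#' Bootstrap causal mediation through a chronotype mediator
#'
#' Fits the two linear models
#' \deqn{M = \alpha_0 + a T (+ covariates)}
#' \deqn{Y = \beta_0 + c' T + b M (+ covariates)}
#' and reports the average causal mediation effect `ACME = a * b`, the
#' average direct effect `ADE = c'`, and the total effect
#' `ACME + ADE` (which, for nested linear models on the same rows, equals
#' the coefficient of `T` in the reduced regression of `Y` on `T` exactly).
#' Uncertainty comes from a non-parametric bootstrap: rows are resampled
#' with replacement, both models refit, and percentile confidence
#' intervals with two-sided sign-based p-values computed.
#'
#' @param data A cohort or data.frame.
#' @param treatment Column name of the (binary or numeric) treatment, or a
#'   numeric vector of length `nrow(data)`.
#' @param mediator Column name of the numeric mediator (`"meq"` or
#'   `"msf"` in cohort data).
#' @param outcome Column name of the numeric outcome (e.g. `"spaq"`).
#' @param covariates Optional character vector of adjustment columns
#'   included in both models (default none).
#' @param n_boot Bootstrap replicates (default 1000, minimum 100).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed; identical seeds give identical results.
#' @return A `mediation_result` with `acme`, `ade`, `total` (each a list
#'   of `estimate`, `ci`, `p`), the `label` from [classify_mediation()],
#'   and bookkeeping fields.
#' @examples
#' coh <- simulate_cohort(
#'   n = 400,
#'   effects = list(planted_effect("mediated", "PER2", "GG",
#'                                 beta = 0.2, a = 2, b = 0.4)),
#'   seed = 3)
#' fit_mediation(coh, treatment = ifelse(coh$PER2 == "GG", 1, 0),
#'               mediator = "meq", outcome = "spaq", n_boot = 200, seed = 1)
#' @export
fit_mediation <- function(data, treatment, mediator, outcome,
                          covariates = NULL, n_boot = 1000, conf = 0.95,
                          seed = 1) {
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  tr <- if (is.character(treatment) && length(treatment) == 1L) {
    tname <- treatment
    as.numeric(data[[treatment]])
  } else {
    tname <- "treatment"
    as.numeric(treatment)
  }
  m <- as.numeric(data[[mediator]])
  y <- as.numeric(data[[outcome]])
  cv <- if (length(covariates)) {
    as.matrix(as.data.frame(lapply(data[covariates], as.numeric)))
  } else NULL
  ok <- !is.na(tr) & !is.na(m) & !is.na(y)
  if (!is.null(cv)) ok <- ok & stats::complete.cases(cv)
  tr <- tr[ok]; m <- m[ok]; y <- y[ok]
  if (!is.null(cv)) cv <- cv[ok, , drop = FALSE]
  if (stats::var(m) == 0) stop("mediator has zero variance", call. = FALSE)

  n <- length(y)
  point <- mediation_coefs(tr, m, y, cv)
  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, c("acme", "ade", "total")))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[b, ] <- mediation_coefs(tr[idx], m[idx], y[idx],
                                 if (is.null(cv)) NULL else
                                   cv[idx, , drop = FALSE])
  }
  alpha <- 1 - conf
  summarize <- function(nm) {
    bs <- boot[, nm]
    ci <- stats::quantile(bs, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                          na.rm = TRUE)
    # two-sided sign-based bootstrap p-value
    p <- 2 * min(mean(bs <= 0, na.rm = TRUE), mean(bs >= 0, na.rm = TRUE))
    p <- min(max(p, 2 / n_boot), 1)
    list(estimate = unname(point[nm]), ci = ci, p = p)
  }
  res <- structure(list(treatment = tname, mediator = mediator,
                        outcome = outcome,
                        acme = summarize("acme"), ade = summarize("ade"),
                        total = summarize("total"),
                        n = n, n_boot = n_boot, conf = conf, seed = seed),
                   class = "mediation_result")
  res$label <- classify_mediation(res)
  res
}

# product-of-coefficients estimates for one sample
mediation_coefs <- function(tr, m, y, cv = NULL) {
  xm <- cbind(1, tr, cv)
  a <- tryCatch(stats::lm.fit(xm, m)$coefficients[2], error = function(e) NA)
  xy <- cbind(1, tr, m, cv)
  cf <- tryCatch(stats::lm.fit(xy, y)$coefficients,
                 error = function(e) rep(NA_real_, 3))
  cp <- cf[2]; b <- cf[3]
  c(acme = unname(a * b), ade = unname(cp), total = unname(a * b + cp))
}

#' Full/partial/none mediation call
#'
#' Mediation is confirmed when the ACME p-value is below 0.10; it is full
#' if additionally the direct-effect p-value is at least 0.10, partial if
#' the direct effect is also below 0.10, and absent otherwise. A pure
#' function of the two p-values.
#'
#' @param result A `mediation_result`, or a list with `acme$p` and `ade$p`.
#' @param alpha Gate for both tests (default 0.10).
#' @return `"full"`, `"partial"` or `"none"`.
#' @export
classify_mediation <- function(result, alpha = 0.10) {
  p_acme <- result$acme$p
  p_ade <- result$ade$p
  if (is.na(p_acme) || p_acme >= alpha) return("none")
  if (is.na(p_ade) || p_ade >= alpha) return("full")
  "partial"
}

#' @export
#' @method print mediation_result
print.mediation_result <- function(x, ...) {
  fmt <- function(e) {
    sprintf("%8.4f [%8.4f, %8.4f]  p = %.4g", e$estimate, e$ci[1], e$ci[2],
            e$p)
  }
  cat("<mediation_result> ", x$treatment, " -> ", x$mediator, " -> ",
      x$outcome, "  (n = ", x$n, ", ", x$n_boot, " bootstraps)\n", sep = "")
  cat("  ACME  ", fmt(x$acme), "\n")
  cat("  ADE   ", fmt(x$ade), "\n")
  cat("  Total ", fmt(x$total), "\n")
  cat("  label:", x$label, "\n")
  invisible(x)
}

#' Mediation table across features and mediators
#'
#' Runs [fit_mediation()] for each (treatment feature, mediator) pair and
#' assembles a table of ACME/ADE/total with CIs, p-values and the
#' full/partial/none label.
#'
#' @param cohort A cohort.
#' @param fm The encoded `feature_matrix` on the same rows (treatment
#'   indicators are taken from its columns).
#' @param features Encoded feature names to treat as treatments.
#' @param mediators Mediator columns (default `c("meq", "msf")`).
#' @param outcome Outcome column (default `"spaq"`).
#' @param stratum `"all"`, `"M"` or `"F"`.
#' @inheritParams fit_mediation
#' @return Data.frame, one row per feature x mediator.
#' @export
mediation_table <- function(cohort, fm, features,
                            mediators = c("meq", "msf"),
                            outcome = "spaq", stratum = "all",
                            n_boot = 1000, seed = 1) {
  idx <- if (stratum == "all") seq_len(nrow(cohort)) else {
    which(as.character(cohort$gender) == stratum)
  }
  rows <- list()
  for (f in features) {
    tr <- fm$values[idx, f]
    if (is.na(stats::var(tr, na.rm = TRUE)) ||
        stats::var(tr, na.rm = TRUE) == 0) next
    for (md in mediators) {
      res <- fit_mediation(cohort[idx, , drop = FALSE], treatment = tr,
                           mediator = md, outcome = outcome,
                           n_boot = n_boot, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, mediator = md, outcome = outcome, stratum = stratum,
        acme = res$acme$estimate, acme_lo = res$acme$ci[1],
        acme_hi = res$acme$ci[2], acme_p = res$acme$p,
        ade = res$ade$estimate, ade_lo = res$ade$ci[1],
        ade_hi = res$ade$ci[2], ade_p = res$ade$p,
        total = res$total$estimate, total_p = res$total$p,
        label = res$label, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
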