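#' Run the full screening pipeline
#'
#' Orchestrates simulate/load -> encode -> consensus feature selection ->
#' classifier benchmark -> regression battery -> mediation -> association
#' rules -> ARACNE network for one outcome, writing every stage artifact
#' (CSV/JSON/GraphML) under the output directory and returning a
#' `run_report`. Fully deterministic under the config seed.
#'
#' @param config Named list (or path to a YAML file) with fields:
#'   `input` (cohort CSV path) or `synthgen` (a list passed to
#'   [simulate_cohort()]); `outcome` (`"SPAQ"`, `"SAD"` or `"BDI"`);
#'   `strata` (subset of `c("all", "M", "F")`); `seed` (mandatory);
#'   `outdir`; optional stage parameters `repeats`, `folds`, `per_fold_k`,
#'   `n_boot_mediation`, `n_boot_network`, `support_threshold`,
#'   `min_support`, `min_confidence`, `max_rule_size`, `classify`
#'   (logical), `twoway` (logical).
#' @return A `run_report` list: `selection`, `benchmark`, `regression`,
#'   `mediation`, `rules`, `network`, `risk`, `protective`, per stratum.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must set a seed", call. = FALSE)
  seed <- as.integer(config$seed)
  outcome <- match.arg(config$outcome %||% "SPAQ", c("SPAQ", "SAD", "BDI"))
  strata <- config$strata %||% "all"
  outdir <- config$outdir %||% tempfile("chronomood_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  logf("run_pipeline: outcome=%s seed=%d strata=%s", outcome, seed,
       paste(strata, collapse = ","))

  cohort <- if (!is.null(config$input)) {
    read_cohort(config$input)
  } else {
    sg <- config$synthgen %||% list(n = 300)
    do.call(simulate_cohort, utils::modifyList(sg, list(seed = seed)))
  }
  write_cohort(cohort, file.path(outdir, "cohort.csv"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  report <- list(outcome = outcome, seed = seed, outdir = outdir,
                 strata = list())
  for (st in strata) {
    logf("stratum %s", st)
    idx <- if (st == "all") seq_len(nrow(cohort)) else {
      which(as.character(cohort$gender) == st)
    }
    coh_s <- cohort[idx, , drop = FALSE]
    attr(coh_s, "loci") <- attr(cohort, "loci")
    class(coh_s) <- class(cohort)

    fm <- stage("encode", build_feature_matrix(
      coh_s, outcome, twoway = config$twoway %||% TRUE))
    write_feature_matrix(fm, file.path(outdir, paste0("features_", st,
                                                      ".csv")))
    sel <- stage("select", cv_consensus(
      fm, repeats = config$repeats %||% 10, folds = config$folds %||% 10,
      per_fold_k = config$per_fold_k %||% 20, seed = seed))
    write_selection(sel, file.path(outdir, paste0("selection_", st,
                                                  ".json")))
    logf("  selected top-%d; %d stable", length(sel$top20),
         length(sel$stable))

    bench <- NULL
    if (isTRUE(config$classify %||% TRUE)) {
      bench <- stage("classify", evaluate_classifiers(
        fm, sel, repeats = config$classify_repeats %||% 1,
        folds = config$folds %||% 10, seed = seed, label = st))
      write_benchmark(bench, file.path(outdir, paste0("benchmark_", st)))
    }

    score <- if (outcome == "SPAQ") coh_s$spaq else if (outcome == "BDI") {
      coh_s$bdi
    } else NULL
    reg <- stage("stats", regression_battery(coh_s, fm, sel, score = score,
                                             strata = "all"))
    if (!is.null(reg)) {
      reg$stratum <- st
      utils::write.csv(reg, file.path(outdir, paste0("regression_", st,
                                                     ".csv")),
                       row.names = FALSE)
    }

    med_feats <- utils::head(intersect(sel$top20, colnames(fm$values)), 5)
    ycol <- switch(outcome, SPAQ = "spaq", BDI = "bdi", SAD = "sad")
    med <- stage("mediation", mediation_table(
      coh_s, fm, med_feats, outcome = ycol,
      n_boot = config$n_boot_mediation %||% 1000, seed = seed))
    if (!is.null(med)) {
      utils::write.csv(med, file.path(outdir, paste0("mediation_", st,
                                                     ".csv")),
                       row.names = FALSE)
    }

    tx <- stage("rules", make_transactions(coh_s, outcome))
    rules <- stage("rules", apriori_mine(
      tx, min_support = config$min_support %||% 0.04,
      min_confidence = config$min_confidence %||% 0.7,
      max_size = config$max_rule_size %||% 6))
    utils::write.csv(rules, file.path(outdir, paste0("rules_", st,
                                                     ".csv")),
                     row.names = FALSE)
    if (nrow(rules)) {
      write_rule_network(rule_network(rules),
                         file.path(outdir, paste0("rule_network_", st)))
    }

    net <- stage("network", bootstrap_network(
      aracne_table(coh_s, outcome),
      disorder = ycol,
      n_boot = config$n_boot_network %||% 100,
      threshold = config$support_threshold %||% 0.46, seed = seed))
    write_mi_network(net, file.path(outdir, paste0("mi_network_", st)))

    # risk / protective labeling from the regression battery
    risk <- protective <- character()
    if (!is.null(reg)) {
      sig <- reg[!is.na(reg$adj_p) & reg$adj_p < 0.05, , drop = FALSE]
      up <- (sig$analysis == "multivariate-linear" & sig$estimate > 0) |
        (sig$analysis != "multivariate-linear" & sig$estimate > 1)
      risk <- unique(sig$feature[up])
      protective <- unique(sig$feature[!up])
    }
    report$strata[[st]] <- list(selection = sel, benchmark = bench,
                                regression = reg, mediation = med,
                                rules = rules, network = net,
                                risk = risk, protective = protective)
  }
  summary_json <- file.path(outdir, "report.json")
  jsonlite::write_json(
    lapply(report$strata, function(s) {
      list(top20 = s$selection$top20, stable = s$selection$stable,
           baseline = s$benchmark$baseline,
           accuracy = if (!is.null(s$benchmark)) {
             as.list(s$benchmark$accuracy)
           },
           risk = s$risk, protective = s$protective,
           n_rules = nrow(s$rules),
           path_labels = as.list(s$network$path_labels))
    }), summary_json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("done; report at %s", summary_json)
  class(report) <- "run_report"
  report
}

#' @export
#' @method print run_report
print.run_report <- function(x, ...) {
  cat("<run_report> outcome ", x$outcome, ", strata: ",
      paste(names(x$strata), collapse = ", "), "\n", sep = "")
  for (st in names(x$strata)) {
    s <- x$strata[[st]]
    cat("  [", st, "] stable: ", length(s$selection$stable),
        "; rules: ", nrow(s$rules),
        "; risk: ", length(s$risk),
        "; protective: ", length(s$protective), "\n", sep = "")
  }
  invisible(x)
}

#' Shared and exclusive factor sets
#'
#' Set-algebra comparison of risk/protective factor sets across strata or
#' outcomes (the tabular content behind a Venn diagram).
#'
#' @param sets Named list of two or more character vectors.
#' @return List with `shared` (intersection of all sets) and, per set,
#'   `<name>_only` (items exclusive to it).
#' @export
compare_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) {
    stop("need at least two factor sets", call. = FALSE)
  }
  shared <- Reduce(intersect, sets)
  out <- list(shared = sort(shared))
  for (nm in names(sets)) {
    others <- unlist(sets[setdiff(names(sets), nm)], use.names = FALSE)
    out[[paste0(nm, "_only")]] <- sort(setdiff(sets[[nm]], others))
  }
  out
}
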