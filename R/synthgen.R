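#' Define a genotyped locus
#'
#' A locus is described by its minor-allele frequency and the names of its
#' three genotype levels, ordered major-homozygote, heterozygote,
#' minor-homozygote. Genotypes are later drawn under Hardy-Weinberg
#' equilibrium: \eqn{(1-q)^2, 2q(1-q), q^2} for minor-allele frequency q.
#'
#' @param name Locus identifier (e.g. `"CRY2"`).
#' @param maf Minor-allele frequency, strictly inside (0, 1).
#' @param labels Character vector of three distinct genotype level names
#'   (major-homozygote, heterozygote, minor-homozygote).
#' @return An object of class `locus_spec`.
#' @examples
#' locus_spec("CRY2", 0.3, c("GG", "GA", "AA"))
#' @export
locus_spec <- function(name, maf = 0.3, labels = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) ||
      maf <= 0 || maf >= 1) {
    stop("minor-allele frequency for locus '", name,
         "' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0(name, c("-MM", "-Mm", "-mm"))
  labels <- as.character(labels)
  if (length(labels) != 3L || anyDuplicated(labels)) {
    stop("locus '", name, "' needs three distinct genotype labels",
         call. = FALSE)
  }
  structure(list(name = name, maf = maf, labels = labels),
            class = "locus_spec")
}

#' The nine circadian candidate loci used throughout the package
#'
#' CLOCK3111, CRY1, CRY2, PER2, PER3A, PER3B, PER3C, the PER3 VNTR
#' length polymorphism (4- vs 5-repeat alleles) and ZBTB20, each with three
#' genotype levels and a configurable minor-allele frequency.
#'
#' @param maf Minor-allele frequency applied to every locus (default 0.3),
#'   or a named numeric vector giving per-locus frequencies.
#' @return A named list of [locus_spec()] objects.
#' @export
default_loci <- function(maf = 0.3) {
  labs <- list(
    CLOCK3111 = c("TT", "TC", "CC"),
    CRY1      = c("CC", "CG", "GG"),
    CRY2      = c("GG", "GA", "AA"),
    PER2      = c("AA", "AG", "GG"),
    PER3A     = c("CC", "CG", "GG"),
    PER3B     = c("GG", "AG", "AA"),
    PER3C     = c("TT", "TG", "GG"),
    PER3VNTR  = c("4,4", "4,5", "5,5"),
    ZBTB20    = c("AA", "AT", "TT")
  )
  nm <- names(labs)
  if (length(maf) == 1L) {
    maf <- stats::setNames(rep(maf, length(nm)), nm)
  }
  out <- lapply(nm, function(l) locus_spec(l, unname(maf[[l]]), labs[[l]]))
  stats::setNames(out, nm)
}

#' Declare a planted genotype effect
#'
#' Effects act additively on a latent predictor: for the bounded seasonality
#' (SPAQ) and depression (BDI) scores the latent scale is score points; for
#' the binary SAD label the same contribution is applied on the log-odds
#' scale, so `beta = log(5)` plants an odds ratio of 5. An epistatic pair
#' contributes only to carriers of BOTH target genotype levels. A mediated
#' effect first shifts the chronotype mediator (`mediator` gains
#' `a` x carrier indicator plus noise) and the outcome receives `b` x
#' mediator, so the indirect effect is `a * b`; `beta` is then the direct
#' (unmediated) path.
#'
#' @param kind One of `"main"`, `"epistatic"`, `"mediated"`.
#' @param loci Character vector of one (main/mediated) or two (epistatic)
#'   locus names.
#' @param levels Target genotype level(s), one per locus.
#' @param beta Additive effect on the latent scale (log-odds for SAD,
#'   score points for SPAQ/BDI); for mediated effects this is the direct path.
#' @param sex Optional restriction: `"none"` (default), `"M"` or `"F"`.
#' @param on Which outcomes receive the effect: `"both"` (default),
#'   `"score"` or `"sad"`.
#' @param a,b Mediated-path slopes (locus -> mediator, mediator -> outcome);
#'   required when `kind = "mediated"`.
#' @param mediator Mediator variable for mediated effects, `"meq"` or `"msf"`.
#' @return An object of class `planted_effect`.
#' @examples
#' planted_effect("epistatic", c("PER2", "PER3B"), c("GG", "AG"),
#'                beta = log(5))
#' planted_effect("mediated", "PER2", "GG", beta = 0.2, a = 0.5, b = 0.6)
#' @export
planted_effect <- function(kind = c("main", "epistatic", "mediated"),
                           loci, levels, beta = 0,
                           sex = c("none", "M", "F"),
                           on = c("both", "score", "sad"),
                           a = NULL, b = NULL,
                           mediator = c("meq", "msf")) {
  kind <- match.arg(kind)
  sex <- match.arg(sex)
  on <- match.arg(on)
  mediator <- match.arg(mediator)
  loci <- as.character(loci)
  levels <- as.character(levels)
  n_loci <- if (kind == "epistatic") 2L else 1L
  if (length(loci) != n_loci) {
    stop("a ", kind, " effect takes exactly ", n_loci, " locus name(s)",
         call. = FALSE)
  }
  if (length(levels) != length(loci)) {
    stop("one target genotype level per locus is required", call. = FALSE)
  }
  if (!is.finite(beta)) stop("effect size must be finite", call. = FALSE)
  if (kind == "mediated") {
    if (is.null(a) || is.null(b) || !is.finite(a) || !is.finite(b)) {
      stop("a mediated effect needs finite slopes `a` and `b`",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, loci = loci, levels = levels, beta = beta,
                 sex = sex, on = on, a = a, b = b, mediator = mediator),
            class = "planted_effect")
}

genotype_cols <- function(cohort) {
  attr(cohort, "loci") %||% intersect(names(default_loci()), names(cohort))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Draw Hardy-Weinberg genotypes
#'
#' Each locus is drawn i.i.d. with genotype probabilities
#' \eqn{(1-q)^2, 2q(1-q), q^2}.
#'
#' @param loci List of [locus_spec()] objects.
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed; the draw is reproducible.
#' @return A data.frame of factor genotype columns, one per locus, with an
#'   attribute `"loci"` naming them.
#' @export
generate_genotypes <- function(loci, n, seed) {
  if (!is.list(loci) || !length(loci)) stop("need at least one locus")
  if (inherits(loci, "locus_spec")) loci <- list(loci)
  stopifnot(n >= 1)
  lapply(loci, function(l) {
    if (!inherits(l, "locus_spec")) stop("loci must be locus_spec objects")
  })
  set.seed(as.integer(seed))
  cols <- lapply(loci, function(l) {
    q <- l$maf
    p <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    factor(sample(l$labels, n, replace = TRUE, prob = p), levels = l$labels)
  })
  names(cols) <- vapply(loci, `[[`, "", "name")
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  attr(out, "loci") <- names(cols)
  out
}

# per-subject 0/1 carrier indicator for an effect's target level(s)
effect_indicator <- function(cohort, effect) {
  ind <- rep(1, nrow(cohort))
  for (i in seq_along(effect$loci)) {
    loc <- effect$loci[i]
    if (!loc %in% names(cohort)) {
      stop("effect refers to unknown locus '", loc, "'", call. = FALSE)
    }
    g <- as.character(cohort[[loc]])
    ind <- ind * as.numeric(!is.na(g) & g == effect$levels[i])
  }
  if (effect$sex != "none") {
    ind <- ind * as.numeric(cohort$gender == effect$sex)
  }
  ind
}

#' Generate clinical covariates and outcomes for a cohort
#'
#' Fills `gender`, `age_group`, `ses`, `anxiety`, `sleep_disturbance`,
#' the chronotype measures `meq` (diurnal preference, higher = morningness)
#' and `msf` (mid-sleep on free days, hours), the seasonality score `spaq`
#' (integer 0-24), depression score `bdi` (integer 0-60) and the binary
#' `sad` label. Scores are clipped, rounded Gaussians around a linear
#' predictor; SAD is Bernoulli with a logistic link. With an empty effect
#' list the outcomes carry no genotype signal.
#'
#' @param cohort Data.frame of genotype columns (see [generate_genotypes()]).
#' @param effects List of [planted_effect()] objects (may be empty).
#' @param noise_sd Residual SD of the latent score (default 3 points).
#' @param base_rate Baseline SAD probability (default 0.125, the prevalence
#'   of seasonal symptoms the generator emulates).
#' @param seed Integer seed.
#' @param female_prop Proportion of females (default 197/273, the sex
#'   imbalance the sex-stratified analyses face).
#' @param mediator_sd Residual SD of the chronotype mediators around their
#'   population centres (default 8 for MEQ-like dispersion; use 1 for a
#'   unit-scale mediation study).
#' @return The cohort with clinical and outcome columns appended, class
#'   `cohort`.
#' @export
generate_outcomes <- function(cohort, effects = list(), noise_sd = 3,
                              base_rate = 0.125, seed = 1,
                              female_prop = 197 / 273, mediator_sd = 8) {
  stopifnot(is.data.frame(cohort), noise_sd > 0,
            base_rate > 0, base_rate < 1)
  if (inherits(effects, "planted_effect")) effects <- list(effects)
  n <- nrow(cohort)
  set.seed(as.integer(seed))
  cohort$gender <- factor(
    ifelse(stats::runif(n) < female_prop, "F", "M"), levels = c("F", "M"))
  cohort$age_group <- factor(
    sample(c("<=22", ">22"), n, TRUE, prob = c(0.85, 0.15)),
    levels = c("<=22", ">22"))
  cohort$ses <- factor(
    sample(c("poor", "lower-middle", "upper-middle", "affluent"), n, TRUE,
           prob = c(0.08, 0.27, 0.45, 0.20)),
    levels = c("poor", "lower-middle", "upper-middle", "affluent"))
  cohort$anxiety <- round(pmin(pmax(stats::rnorm(n, 40, 10), 20), 80), 1)
  cohort$sleep_disturbance <- round(pmin(pmax(stats::rnorm(n, 50, 8), 25), 75), 1)

  # chronotype mediators; mediated effects shift them before outcomes accrue
  meq <- stats::rnorm(n, 50, mediator_sd)
  msf <- stats::rnorm(n, 4.5, mediator_sd / 8)
  eta <- rep(0, n)        # latent contribution shared by score and log-odds
  eta_score <- rep(0, n)  # score-only channel
  eta_sad <- rep(0, n)    # sad-only channel
  for (ef in effects) {
    ind <- effect_indicator(cohort, ef)
    contrib <- ef$beta * ind
    if (ef$kind == "mediated") {
      if (ef$mediator == "meq") meq <- meq + ef$a * ind
      else msf <- msf + ef$a * ind
    }
    if (ef$on == "both") eta <- eta + contrib
    else if (ef$on == "score") eta_score <- eta_score + contrib
    else eta_sad <- eta_sad + contrib
  }
  # mediator -> outcome paths, centred so intercepts stay at their baseline
  for (ef in effects) {
    if (ef$kind != "mediated") next
    med <- if (ef$mediator == "meq") meq - 50 else msf - 4.5
    if (ef$on %in% c("both", "score")) eta_score <- eta_score + ef$b * med
    if (ef$on %in% c("both", "sad")) eta_sad <- eta_sad + ef$b * med
  }
  cohort$meq <- round(pmin(pmax(meq, 16), 86), 1)
  cohort$msf <- round(pmin(pmax(msf, 0), 12), 2)

  lp_spaq <- 7 + eta + eta_score
  lp_bdi <- 10 + 1.2 * (eta + eta_score)
  cohort$spaq <- as.integer(pmin(pmax(round(
    lp_spaq + stats::rnorm(n, 0, noise_sd)), 0), 24))
  cohort$bdi <- as.integer(pmin(pmax(round(
    lp_bdi + stats::rnorm(n, 0, 2 * noise_sd)), 0), 60))
  logit <- stats::qlogis(base_rate) + eta + eta_sad
  cohort$sad <- as.integer(stats::runif(n) < stats::plogis(logit))

  class(cohort) <- c("cohort", "data.frame")
  validate_cohort(cohort)
  cohort
}

#' Validate a cohort table
#'
#' Checks the bounded-score, binary-label and genotype-level invariants.
#'
#' @param cohort A cohort data.frame.
#' @return The cohort, invisibly; errors on violation.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  sp <- cohort$spaq
  if (!is.null(sp) && any(!is.na(sp) & (sp < 0 | sp > 24))) {
    stop("spaq must lie in [0, 24]")
  }
  bd <- cohort$bdi
  if (!is.null(bd) && any(!is.na(bd) & (bd < 0 | bd > 60))) {
    stop("bdi must lie in [0, 60]")
  }
  sd_ <- cohort$sad
  if (!is.null(sd_) && any(!is.na(sd_) & !sd_ %in% 0:1)) {
    stop("sad must be binary 0/1")
  }
  invisible(cohort)
}

#' Mask genotype and clinical cells completely at random
#'
#' Each genotype/clinical cell is independently set missing with the given
#' probability; outcome columns (`spaq`, `bdi`, `sad`) are never masked.
#'
#' @param cohort A cohort.
#' @param rate Missingness probability in \[0, 1).
#' @param seed Integer seed; identical seeds give identical masks.
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, rate, seed) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("missingness rate must lie in [0, 1)", call. = FALSE)
  }
  if (rate == 0) return(cohort)
  maskable <- setdiff(names(cohort), c("spaq", "bdi", "sad"))
  set.seed(as.integer(seed))
  for (cl in maskable) {
    hit <- stats::runif(nrow(cohort)) < rate
    cohort[[cl]][hit] <- NA
  }
  cohort
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: Hardy-Weinberg genotypes for the supplied loci,
#' clinical covariates, planted effects, outcomes and optional missingness.
#'
#' @inheritParams generate_genotypes
#' @inheritParams generate_outcomes
#' @param missing_rate MCAR masking rate for genotype/clinical cells.
#' @return A `cohort` data.frame.
#' @examples
#' coh <- simulate_cohort(n = 100, seed = 7)
#' table(coh$sad)
#' @export
simulate_cohort <- function(n, loci = default_loci(), effects = list(),
                            noise_sd = 3, base_rate = 0.125,
                            missing_rate = 0, female_prop = 197 / 273,
                            mediator_sd = 8, seed = 1) {
  seed <- as.integer(seed)
  g <- generate_genotypes(loci, n, seed = seed)
  coh <- generate_outcomes(g, effects = effects, noise_sd = noise_sd,
                           base_rate = base_rate, seed = seed + 1L,
                           female_prop = female_prop,
                           mediator_sd = mediator_sd)
  attr(coh, "loci") <- attr(g, "loci")
  if (missing_rate > 0) {
    coh <- inject_missingness(coh, missing_rate, seed = seed + 2L)
  }
  coh
}

#' Write / read a cohort as CSV with a JSON data dictionary
#'
#' The sidecar `<path>.dict.json` records column types and genotype levels
#' so a round-trip restores factors faithfully.
#'
#' @param cohort A cohort.
#' @param path CSV path to write.
#' @return `write_cohort` returns the path invisibly; `read_cohort` the
#'   restored cohort.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  dict <- lapply(cohort, function(col) {
    if (is.factor(col)) list(type = "factor", levels = levels(col))
    else list(type = class(col)[1])
  })
  meta <- list(columns = dict, loci = genotype_cols(cohort))
  jsonlite::write_json(meta, paste0(path, ".dict.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  dict_path <- paste0(path, ".dict.json")
  if (file.exists(dict_path)) {
    meta <- jsonlite::read_json(dict_path, simplifyVector = TRUE)
    for (nm in names(meta$columns)) {
      spec <- meta$columns[[nm]]
      if (identical(spec$type, "factor") && nm %in% names(df)) {
        df[[nm]] <- factor(df[[nm]], levels = spec$levels)
      }
    }
    attr(df, "loci") <- meta$loci
  }
  class(df) <- c("cohort", "data.frame")
  validate_cohort(df)
  df
}

#' Simulate a cohort from a YAML configuration
#'
#' The config declares `n`, `seed`, and optionally `loci` (name, maf,
#' labels), `effects` (kind, loci, levels, beta, sex, on, a, b, mediator),
#' `noise_sd`, `base_rate`, `missing_rate`.
#'
#' @param path Path to a YAML file.
#' @return A `cohort`.
#' @export
simulate_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `n` key as boolean FALSE; recover it
  if (is.null(cfg$n) && !is.null(cfg[["FALSE"]])) cfg$n <- cfg[["FALSE"]]
  if (is.null(cfg$n)) stop("config must declare n", call. = FALSE)
  loci <- if (is.null(cfg$loci)) default_loci() else {
    lapply(cfg$loci, function(l) {
      locus_spec(l$name, l$maf %||% 0.3, l$labels %||% NULL)
    })
  }
  effects <- lapply(cfg$effects %||% list(), function(e) {
    planted_effect(e$kind, unlist(e$loci), unlist(e$levels),
                   beta = e$beta %||% 0, sex = e$sex %||% "none",
                   on = e$on %||% "both", a = e$a, b = e$b,
                   mediator = e$mediator %||% "meq")
  })
  simulate_cohort(n = cfg$n, loci = loci, effects = effects,
                  noise_sd = cfg$noise_sd %||% 3,
                  base_rate = cfg$base_rate %||% 0.125,
                  missing_rate = cfg$missing_rate %||% 0,
                  seed = cfg$seed %||% 1)
}
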