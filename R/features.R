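#' Assemble the 14 one-way features
#'
#' The one-way feature space is the nine genotype columns plus five
#' behavioural/clinical features: gender, diurnal preference (MEQ),
#' chronotype (MSF), age group, and socioeconomic status.
#'
#' @param cohort A cohort data.frame.
#' @return A 14-column data.frame (unencoded), with attribute `"genotypes"`
#'   naming the genotype columns.
#' @export
assemble_oneway <- function(cohort) {
  geno <- genotype_cols(cohort)
  if (length(geno) < 1) stop("cohort carries no genotype columns")
  clinical <- c("gender", "meq", "msf", "age_group", "ses")
  missing <- setdiff(c(geno, clinical), names(cohort))
  if (length(missing)) {
    stop("cohort is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- cohort[, c(geno, clinical), drop = FALSE]
  out <- as.data.frame(out)
  attr(out, "genotypes") <- geno
  out
}

#' Append pairwise genotype-combination (two-way) features
#'
#' For each unordered pair of genotype features one categorical feature is
#' added whose levels are the joint genotype combinations
#' (`"lvlA|lvlB"`); with three levels per locus each pair carries 9
#' combinations, so g loci give choose(g,2) x 9 two-way (feature, level)
#' combinations (324 for the nine default loci).
#'
#' @param oneway Output of [assemble_oneway()].
#' @return The table with `choose(g, 2)` pair columns appended; pair columns
#'   are named `"LOCUSA|LOCUSB"`.
#' @export
expand_twoway <- function(oneway) {
  geno <- attr(oneway, "genotypes")
  if (is.null(geno) || length(geno) < 2) {
    stop("need at least two genotype features to build pairs")
  }
  for (g in geno) {
    lv <- levels(factor(oneway[[g]]))
    if (length(lv) > 3) {
      stop("genotype feature '", g, "' has more than 3 observed levels")
    }
  }
  pairs <- utils::combn(geno, 2)
  out <- oneway
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    la <- levels(factor(oneway[[a]])); lb <- levels(factor(oneway[[b]]))
    joint <- as.vector(outer(la, lb, paste, sep = "|"))
    val <- ifelse(is.na(oneway[[a]]) | is.na(oneway[[b]]), NA,
                  paste(as.character(oneway[[a]]),
                        as.character(oneway[[b]]), sep = "|"))
    out[[paste(a, b, sep = "|")]] <- factor(val, levels = joint)
  }
  attr(out, "genotypes") <- geno
  attr(out, "pairs") <- paste(pairs[1, ], pairs[2, ], sep = "|")
  out
}

#' Binarize an outcome column
#'
#' Seasonality: SPAQ >= 11 is seasonal; depression: BDI >= 14 is depressed;
#' SAD is already binary.
#'
#' @param cohort A cohort.
#' @param outcome One of `"SPAQ"`, `"SAD"`, `"BDI"`.
#' @return Integer 0/1 vector.
#' @export
binarize_outcome <- function(cohort, outcome = c("SPAQ", "SAD", "BDI")) {
  outcome <- match.arg(outcome)
  switch(outcome,
         SPAQ = as.integer(cohort$spaq >= 11),
         BDI = as.integer(cohort$bdi >= 14),
         SAD = as.integer(cohort$sad))
}

new_feature_matrix <- function(values, map, target = NULL,
                               target_name = NULL) {
  stopifnot(is.matrix(values), nrow(map) == ncol(values))
  structure(list(values = values, map = map, target = target,
                 target_name = target_name),
            class = "feature_matrix")
}

#' @export
#' @method print feature_matrix
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " subjects x ",
      ncol(x$values), " encoded features", sep = "")
  if (!is.null(x$target_name)) cat("; target:", x$target_name)
  cat("\n")
  n_na <- sum(is.na(x$values))
  if (n_na) cat("  ", n_na, " missing cells\n", sep = "")
  invisible(x)
}

#' Reference-removed one-hot encoding
#'
#' Non-binary categorical features expand to (observed levels - 1) indicator
#' columns; the most frequent observed level of each feature is dropped as
#' the reference (ties broken by the lexicographically first tied level).
#' Numeric features pass through. Features with a single observed level are
#' dropped with a warning. Indicator columns are named `FEATURE=LEVEL`
#' (pair features yield `LOCUSA=LVL|LOCUSB=LVL`).
#'
#' @param table Feature table from [assemble_oneway()] / [expand_twoway()].
#' @param target Optional outcome vector to carry along.
#' @param target_name Optional outcome label.
#' @return A `feature_matrix` whose `map` records, per encoded column, the
#'   source feature, the level, and each feature's reference level.
#' @export
one_hot_reference <- function(table, target = NULL, target_name = NULL) {
  cols <- list(); map <- list()
  for (nm in names(table)) {
    col <- table[[nm]]
    if (is.numeric(col)) {
      cols[[nm]] <- as.numeric(col)
      map[[length(map) + 1L]] <- data.frame(
        column = nm, source = nm, level = NA_character_,
        reference = NA_character_, type = "numeric",
        stringsAsFactors = FALSE)
      next
    }
    col <- as.character(col)
    tab <- table(col)           # observed levels only
    if (length(tab) < 2L) {
      warning("feature '", nm, "' has a single observed level; dropped",
              call. = FALSE)
      next
    }
    # reference = most frequent; ties -> lexicographically first tied level
    top <- max(tab)
    ref <- sort(names(tab)[tab == top])[1]
    keep <- setdiff(names(tab), ref)
    # encode pair features as LOCUSA=LVL|LOCUSB=LVL
    enc_name <- function(level) {
      if (grepl("|", nm, fixed = TRUE)) {
        srcs <- strsplit(nm, "|", fixed = TRUE)[[1]]
        lvls <- strsplit(level, "|", fixed = TRUE)[[1]]
        paste(paste0(srcs, "=", lvls), collapse = "|")
      } else paste0(nm, "=", level)
    }
    for (lv in keep) {
      cn <- enc_name(lv)
      cols[[cn]] <- ifelse(is.na(col), NA_real_, as.numeric(col == lv))
      map[[length(map) + 1L]] <- data.frame(
        column = cn, source = nm, level = lv, reference = ref,
        type = "indicator", stringsAsFactors = FALSE)
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- NULL
  new_feature_matrix(values, do.call(rbind, map), target, target_name)
}

#' Drop encoded features absent from every sample
#'
#' Removes indicator columns that are zero in all observed entries and
#' updates the encoding map.
#'
#' @param fm A `feature_matrix`.
#' @return The pruned `feature_matrix`.
#' @export
prune_absent <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  is_ind <- fm$map$type == "indicator"
  sums <- colSums(fm$values, na.rm = TRUE)
  seen <- colSums(!is.na(fm$values)) > 0
  drop <- is_ind & sums == 0 & seen
  if (any(drop)) {
    fm$values <- fm$values[, !drop, drop = FALSE]
    fm$map <- fm$map[!drop, , drop = FALSE]
    rownames(fm$map) <- NULL
  }
  fm
}

#' Recover a subject's original categorical value from its indicators
#'
#' Round-trip check for the reference-removed encoding: the level whose
#' indicator is 1, or the reference level if all of the feature's
#' indicators are 0.
#'
#' @param fm A `feature_matrix`.
#' @param row Subject index.
#' @param source Source feature name.
#' @return The reconstructed level as a character scalar.
#' @export
decode_feature <- function(fm, row, source) {
  m <- fm$map[fm$map$source == source & fm$map$type == "indicator", ]
  if (!nrow(m)) stop("no encoded columns for source '", source, "'")
  v <- fm$values[row, m$column]
  if (anyNA(v)) return(NA_character_)
  hit <- which(v == 1)
  if (length(hit) == 1L) m$level[hit] else m$reference[1]
}

#' k-nearest-neighbour imputation
#'
#' Each missing cell is replaced by the mean of that column over the k
#' nearest rows (Euclidean distance over mutually observed, standardized
#' columns, scaled for the number of shared columns); observed cells are
#' never altered.
#'
#' @param fm A `feature_matrix` (may contain `NA`s).
#' @param k Neighbour count (default 5).
#' @return The completed `feature_matrix`.
#' @export
knn_impute <- function(fm, k = 5) {
  stopifnot(inherits(fm, "feature_matrix"), k >= 1)
  x <- fm$values
  if (!anyNA(x)) return(fm)
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing)) {
    stop("column(s) entirely missing: ",
         paste(colnames(x)[all_missing], collapse = ", "), call. = FALSE)
  }
  # standardize for the distance only
  mu <- colMeans(x, na.rm = TRUE)
  sg <- apply(x, 2, stats::sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sg, "/")
  obs <- !is.na(z)
  z0 <- z; z0[!obs] <- 0
  need <- which(rowSums(!obs) > 0)
  p <- ncol(x)
  filled <- x
  for (i in need) {
    # squared distance over mutually observed columns, scaled to p columns
    zi <- z0[i, ]; oi <- obs[i, ]
    shared <- as.vector(obs %*% oi)            # count of shared columns
    diff <- sweep(z0, 2, zi)
    diff[!obs] <- 0
    diff[, !oi] <- 0
    d2 <- rowSums(diff^2)
    d2 <- ifelse(shared > 0, d2 * p / pmax(shared, 1), Inf)
    d2[i] <- Inf
    for (j in which(!oi)) {
      donors <- which(obs[, j] & is.finite(d2))
      if (!length(donors)) next
      ord <- donors[order(d2[donors], donors)]
      nn <- ord[seq_len(min(k, length(ord)))]
      filled[i, j] <- mean(x[nn, j])
    }
  }
  fm$values <- filled
  fm
}

#' SMOTE class balancing
#'
#' Oversamples the minority class of a binary target to parity: each
#' synthetic row is `x + lambda * (x_nn - x)` with `lambda ~ Uniform(0,1)`,
#' `x` a minority row, and `x_nn` one of its `k` minority-class nearest
#' neighbours (Euclidean). Synthetic rows receive the minority label.
#'
#' @param fm A `feature_matrix` with a complete (no `NA`) value matrix and a
#'   binary target.
#' @param k Neighbour count (default 5).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return The balanced `feature_matrix`.
#' @export
smote_balance <- function(fm, k = 5, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  y <- fm$target
  if (is.null(y) || length(unique(y)) != 2) {
    stop("SMOTE needs a binary target", call. = FALSE)
  }
  if (anyNA(fm$values)) stop("impute before SMOTE", call. = FALSE)
  tab <- table(y)
  if (tab[1] == tab[2]) return(fm)
  minority <- names(tab)[which.min(tab)]
  n_syn <- abs(diff(as.integer(tab)))
  idx_min <- which(y == minority)
  if (length(idx_min) < 2) {
    stop("minority class of size 1: no neighbour to interpolate",
         call. = FALSE)
  }
  xm <- fm$values[idx_min, , drop = FALSE]
  k_eff <- min(k, nrow(xm) - 1L)
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- matrix(apply(d, 1, function(r) order(r)[seq_len(k_eff)]),
               ncol = k_eff, byrow = TRUE)
  set.seed(as.integer(seed))
  base_i <- sample(nrow(xm), n_syn, replace = TRUE)
  pick <- sample(k_eff, n_syn, replace = TRUE)
  lambda <- stats::runif(n_syn)
  nn_i <- nn[cbind(base_i, pick)]
  syn <- xm[base_i, , drop = FALSE] +
    lambda * (xm[nn_i, , drop = FALSE] - xm[base_i, , drop = FALSE])
  fm$values <- rbind(fm$values, syn)
  tgt <- if (is.numeric(y)) as.numeric(minority) else minority
  fm$target <- c(y, rep(tgt, n_syn))
  fm
}

#' Standardize numeric columns
#'
#' Numeric (non-indicator) columns are centred and scaled to unit SD
#' (constant columns become all-zero); 0/1 indicator columns are left
#' untouched. Applying it twice equals applying it once.
#'
#' @param fm A complete `feature_matrix`.
#' @return The normalized `feature_matrix`.
#' @export
normalize_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  num <- which(fm$map$type == "numeric")
  for (j in num) {
    v <- fm$values[, j]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      fm$values[, j] <- 0
    } else {
      fm$values[, j] <- (v - mean(v)) / s
    }
  }
  fm
}

#' Build the encoded design matrix for an outcome
#'
#' One-way assembly, optional two-way expansion, reference-removed one-hot
#' encoding, pruning of absent combinations, and target attachment. Rows
#' with a missing outcome are dropped (mirroring per-outcome stratification
#' of the expanded data).
#'
#' @param cohort A cohort.
#' @param outcome `"SPAQ"`, `"SAD"` or `"BDI"`.
#' @param twoway Include pairwise genotype-combination features?
#' @return A pruned `feature_matrix` with binary target.
#' @export
build_feature_matrix <- function(cohort, outcome = c("SPAQ", "SAD", "BDI"),
                                 twoway = TRUE) {
  outcome <- match.arg(outcome)
  y <- binarize_outcome(cohort, outcome)
  keep <- !is.na(y)
  cohort <- cohort[keep, , drop = FALSE]
  tab <- assemble_oneway(cohort)
  if (twoway) tab <- expand_twoway(tab)
  fm <- one_hot_reference(tab, target = y[keep], target_name = outcome)
  prune_absent(fm)
}

#' Write an encoded matrix as CSV plus a JSON encoding map
#'
#' @param fm A `feature_matrix`.
#' @param path CSV path; the map goes to `<path>.map.json`.
#' @return The path, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(fm$values, check.names = FALSE)
  if (!is.null(fm$target)) df[[fm$target_name %||% "target"]] <- fm$target
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(fm$map, paste0(path, ".map.json"), pretty = TRUE)
  invisible(path)
}
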