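#' Empirical mutual information in bits
#'
#' Plug-in estimator over the joint empirical distribution:
#' \eqn{\sum p(x,y) \log_2 (p(x,y) / (p(x) p(y)))}, with `0 log 0 = 0`.
#' Symmetric and non-negative. Shared by mRMR, JMI and the ARACNE module.
#'
#' @param x,y Discrete vectors (factor, character or integer) of equal
#'   length.
#' @return MI in bits.
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)) # 1 bit
#' @export
mutual_information <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty vectors", call. = FALSE)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  xi <- as.integer(factor(x)); yi <- as.integer(factor(y))
  ok <- !is.na(xi) & !is.na(yi)
  mi_codes(xi[ok], yi[ok], max(xi[ok]), max(yi[ok]))
}

# MI in bits from integer codes 1..nx / 1..ny (fast path, no NA)
mi_codes <- function(xi, yi, nx, ny) {
  n <- length(xi)
  if (!n) stop("empty vectors", call. = FALSE)
  joint <- tabulate((xi - 1L) * ny + yi, nx * ny)
  px <- tabulate(xi, nx) / n
  py <- tabulate(yi, ny) / n
  pj <- joint / n
  # joint is laid out in x-major blocks of size ny; match p(x)p(y) to it
  eij <- rep(px, each = ny) * rep.int(py, nx)
  idx <- pj > 0
  sum(pj[idx] * log2(pj[idx] / eij[idx]))
}

# Shannon entropy in bits of integer codes
entropy_codes <- function(xi, nx) {
  p <- tabulate(xi, nx) / length(xi)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Discretize a numeric vector into equal-frequency bins
#'
#' Columns with at most `bins` distinct values are kept as-is (coded);
#' otherwise cut at empirical quantiles (duplicate breakpoints collapsed,
#' so fewer bins may result).
#'
#' @param x Numeric vector.
#' @param bins Number of bins (default 3, matching genotype cardinality).
#' @return Integer codes in `1..nbins`.
#' @export
discretize_ef <- function(x, bins = 3) {
  ux <- unique(x[!is.na(x)])
  if (length(ux) <= bins) return(as.integer(factor(x, levels = sort(ux))))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               na.rm = TRUE, type = 7))
  if (length(br) < 3) {
    # zero-inflated column: quantiles collapse; fall back to presence
    return(as.integer(x > br[1]) + 1L)
  }
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

# discretize every column of a numeric matrix; returns list(codes, nlev)
discretize_matrix <- function(x, bins = 3) {
  codes <- matrix(0L, nrow(x), ncol(x))
  nlev <- integer(ncol(x))
  for (j in seq_len(ncol(x))) {
    cj <- discretize_ef(x[, j], bins)
    codes[, j] <- cj
    nlev[j] <- max(cj, 1L)
  }
  colnames(codes) <- colnames(x)
  list(codes = codes, nlev = nlev)
}

#' Chi-squared feature ranking
#'
#' Per-feature Pearson chi-squared statistic of the feature x class
#' contingency table (0/1 indicators give the classic 2x2 statistic
#' \eqn{N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))}; other columns are
#' discretized into 3 equal-frequency bins first). Features are ranked by
#' descending statistic; single-level (e.g. constant) features score 0.
#'
#' @param fm A `feature_matrix` with binary target, or a numeric matrix via
#'   `values`/`target`.
#' @return A data.frame `feature`, `score`, sorted descending (ties by
#'   feature name).
#' @export
chi2_rank <- function(fm) {
  x <- fm$values; y <- fm$target
  if (any(x < 0, na.rm = TRUE)) {
    stop("chi-squared ranking needs non-negative feature values",
         call. = FALSE)
  }
  yi <- as.integer(factor(y))
  ny <- max(yi)
  dm <- fm$disc %||% discretize_matrix(x)
  scores <- vapply(seq_len(ncol(x)), function(j) {
    cj <- dm$codes[, j]; nxj <- dm$nlev[j]
    ok <- !is.na(cj)
    if (nxj < 2 || ny < 2) return(0)
    tab <- matrix(tabulate((cj[ok] - 1L) * ny + yi[ok], nxj * ny),
                  nrow = nxj, byrow = TRUE)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2 || any(colSums(tab) == 0)) return(0)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }, 0)
  out <- data.frame(feature = colnames(x), score = scores,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$feature), , drop = FALSE]
}

#' ReliefF feature weighting
#'
#' For each of `m` sampled instances, the `k` nearest hits (same class) and
#' `k` nearest misses (other class) are found by Euclidean distance; each
#' feature's weight accumulates the normalized difference
#' `|x_i - x_j| / range` over misses minus over hits, divided by `m * k`.
#' Constant features receive weight 0.
#'
#' @param fm A `feature_matrix` with binary target.
#' @param k Neighbours per class (default 10; reduced with a warning if a
#'   class has fewer than `k + 1` members).
#' @param m Instances to sample; default `NULL` uses every instance.
#' @param seed Seed used only when `m < n`.
#' @return A data.frame `feature`, `score` (the weight), sorted descending.
#' @export
relieff_rank <- function(fm, k = 10, m = NULL, seed = 1) {
  x <- fm$values; y <- fm$target
  stopifnot(k >= 1)
  n <- nrow(x); p <- ncol(x)
  yi <- as.integer(factor(y))
  min_class <- min(table(yi))
  if (min_class < k + 1) {
    k <- max(1L, min_class - 1L)
    warning("class smaller than k+1; k reduced to ", k, call. = FALSE)
  }
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- Inf   # constant feature -> zero diff contribution
  xs <- sweep(x, 2, rng, "/")
  if (is.null(m) || m >= n) {
    use <- seq_len(n)
  } else {
    set.seed(as.integer(seed))
    use <- sample(n, m)
  }
  m_eff <- length(use)
  d2 <- as.matrix(stats::dist(x))
  diag(d2) <- Inf
  w <- numeric(p)
  for (i in use) {
    same <- which(yi == yi[i]); same <- same[same != i]
    other <- which(yi != yi[i])
    hits <- same[order(d2[i, same])][seq_len(min(k, length(same)))]
    miss <- other[order(d2[i, other])][seq_len(min(k, length(other)))]
    di <- abs(sweep(xs[c(hits, miss), , drop = FALSE], 2, xs[i, ]))
    nh <- length(hits)
    w <- w - colSums(di[seq_len(nh), , drop = FALSE]) / (m_eff * k) +
      colSums(di[nh + seq_len(length(miss)), , drop = FALSE]) / (m_eff * k)
  }
  out <- data.frame(feature = colnames(x), score = w,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$feature), , drop = FALSE]
}

# symmetrical uncertainty 2*MI / (H(x)+H(y)) on integer codes
su_codes <- function(xi, yi, nx, ny) {
  hx <- entropy_codes(xi, nx); hy <- entropy_codes(yi, ny)
  if (hx + hy == 0) return(0)
  2 * mi_codes(xi, yi, nx, ny) / (hx + hy)
}

#' CFS: correlation-based feature subset selection
#'
#' Best-first forward search maximizing the CFS merit
#' \deqn{merit(S) = k \bar r_{cf} / \sqrt{k + k(k-1) \bar r_{ff}}}
#' where correlations are symmetrical uncertainties on discretized columns.
#' The search expands the incumbent by its best single addition and stops
#' after `patience` consecutive expansions that fail to improve the best
#' merit seen (or when features are exhausted).
#'
#' @param fm A `feature_matrix` with binary target.
#' @param patience Consecutive non-improving expansions tolerated
#'   (default 5).
#' @param max_size Cap on the subset size (default 20).
#' @return Character vector: the selected subset (in inclusion order of the
#'   best subset found).
#' @export
cfs_select <- function(fm, patience = 5, max_size = 20) {
  x <- fm$values; y <- fm$target
  if (!ncol(x)) stop("empty feature matrix", call. = FALSE)
  dm <- fm$disc %||% discretize_matrix(x)
  yi <- as.integer(factor(y)); ny <- max(yi)
  p <- ncol(x)
  su_y <- vapply(seq_len(p), function(j) {
    su_codes(dm$codes[, j], yi, dm$nlev[j], ny)
  }, 0)
  su_ff <- new.env(parent = emptyenv())  # pair cache
  get_ff <- function(a, b) {
    key <- if (a < b) paste0(a, ":", b) else paste0(b, ":", a)
    v <- su_ff[[key]]
    if (is.null(v)) {
      v <- su_codes(dm$codes[, a], dm$codes[, b], dm$nlev[a], dm$nlev[b])
      su_ff[[key]] <- v
    }
    v
  }
  merit <- function(S, sum_cf, sum_ff) {
    kk <- length(S)
    if (!kk) return(0)
    rcf <- sum_cf / kk
    rff <- if (kk > 1) sum_ff / (kk * (kk - 1) / 2) else 0
    kk * rcf / sqrt(kk + kk * (kk - 1) * rff)
  }
  current <- integer(0); sum_cf <- 0; sum_ff <- 0
  best_subset <- integer(0); best_merit <- 0
  stall <- 0
  while (length(current) < min(max_size, p) && stall < patience) {
    cand <- setdiff(seq_len(p), current)
    if (!length(cand)) break
    scores <- vapply(cand, function(f) {
      add_ff <- if (length(current)) {
        sum(vapply(current, function(s) get_ff(f, s), 0))
      } else 0
      merit(c(current, f), sum_cf + su_y[f], sum_ff + add_ff)
    }, 0)
    pickj <- which.max(scores)
    f <- cand[pickj]
    add_ff <- if (length(current)) {
      sum(vapply(current, function(s) get_ff(f, s), 0))
    } else 0
    current <- c(current, f)
    sum_cf <- sum_cf + su_y[f]
    sum_ff <- sum_ff + add_ff
    if (scores[pickj] > best_merit + 1e-12) {
      best_merit <- scores[pickj]
      best_subset <- current
      stall <- 0
    } else {
      stall <- stall + 1
    }
  }
  colnames(x)[best_subset]
}

#' mRMR: maximum relevance, minimum redundancy
#'
#' Greedy forward selection: the first feature maximizes `I(f; y)`; each
#' subsequent feature maximizes
#' `I(f; y) - mean_{s in S} I(f; s)` over the already-selected set S.
#' All MI terms use the empirical plug-in estimator on discretized columns.
#'
#' @param fm A `feature_matrix` with binary target.
#' @param d Subset size (clamped to the feature count with a warning).
#' @return Character vector of `d` features in selection order.
#' @export
mrmr_select <- function(fm, d = 20) {
  x <- fm$values; y <- fm$target
  stopifnot(d >= 1)
  p <- ncol(x)
  if (d > p) {
    warning("d exceeds feature count; clamped to ", p, call. = FALSE)
    d <- p
  }
  dm <- fm$disc %||% discretize_matrix(x)
  yi <- as.integer(factor(y)); ny <- max(yi)
  rel <- vapply(seq_len(p), function(j) {
    mi_codes(dm$codes[, j], yi, dm$nlev[j], ny)
  }, 0)
  selected <- integer(0)
  red_sum <- numeric(p)
  avail <- rep(TRUE, p)
  for (step in seq_len(d)) {
    score <- if (length(selected)) {
      rel - red_sum / length(selected)
    } else rel
    score[!avail] <- -Inf
    # tie-break by name for order stability
    best <- which(score == max(score))
    f <- best[order(colnames(x)[best])][1]
    selected <- c(selected, f)
    avail[f] <- FALSE
    if (step < d) {
      upd <- which(avail)
      red_sum[upd] <- red_sum[upd] + vapply(upd, function(j) {
        mi_codes(dm$codes[, j], dm$codes[, f], dm$nlev[j], dm$nlev[f])
      }, 0)
    }
  }
  colnames(x)[selected]
}

#' JMI: joint mutual information selection
#'
#' Greedy forward selection: the first feature maximizes `I(f; y)`; each
#' subsequent feature maximizes `sum_{s in S} I((f, s); y)`, the joint MI
#' of the candidate paired with each already-selected feature against the
#' class.
#'
#' @inheritParams mrmr_select
#' @return Character vector of `d` features in selection order.
#' @export
jmi_select <- function(fm, d = 20) {
  x <- fm$values; y <- fm$target
  stopifnot(d >= 1)
  p <- ncol(x)
  if (d > p) {
    warning("d exceeds feature count; clamped to ", p, call. = FALSE)
    d <- p
  }
  dm <- fm$disc %||% discretize_matrix(x)
  yi <- as.integer(factor(y)); ny <- max(yi)
  rel <- vapply(seq_len(p), function(j) {
    mi_codes(dm$codes[, j], yi, dm$nlev[j], ny)
  }, 0)
  joint_with <- function(j, s) {
    # joint code of features j and s
    cj <- (dm$codes[, j] - 1L) * dm$nlev[s] + dm$codes[, s]
    mi_codes(cj, yi, dm$nlev[j] * dm$nlev[s], ny)
  }
  selected <- integer(0)
  jmi_sum <- numeric(p)
  avail <- rep(TRUE, p)
  for (step in seq_len(d)) {
    score <- if (length(selected)) jmi_sum else rel
    score[!avail] <- -Inf
    best <- which(score == max(score))
    f <- best[order(colnames(x)[best])][1]
    selected <- c(selected, f)
    avail[f] <- FALSE
    if (step < d) {
      upd <- which(avail)
      jmi_sum[upd] <- jmi_sum[upd] +
        vapply(upd, function(j) joint_with(j, f), 0)
    }
  }
  colnames(x)[selected]
}

# stratified fold assignment: returns integer fold id per row
stratified_folds <- function(y, folds, seed) {
  set.seed(as.integer(seed))
  id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < folds) {
      stop("class '", cl, "' has fewer members (", length(idx),
           ") than folds (", folds, ")", call. = FALSE)
    }
    id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  id
}

# fold-local preprocessing: impute -> normalize -> SMOTE
prep_fold <- function(fm, rows, smote = TRUE, seed = 1) {
  sub <- fm
  sub$values <- fm$values[rows, , drop = FALSE]
  sub$target <- fm$target[rows]
  if (anyNA(sub$values)) sub <- knn_impute(sub, k = 5)
  sub <- normalize_features(sub)
  if (smote && length(unique(sub$target)) == 2 &&
      diff(range(table(sub$target))) > 0) {
    sub <- smote_balance(sub, k = 5, seed = seed)
  }
  # selectors share one discretization of the balanced fold
  sub$disc <- discretize_matrix(sub$values)
  sub
}

run_selector <- function(method, fm, per_fold_k) {
  switch(method,
    CHI2 = {
      # chi2 requires non-negative values; normalization may have centred
      # numeric columns, and the statistic is shift-invariant after binning
      sh <- fm
      mins <- apply(sh$values, 2, min)
      neg <- mins < 0
      if (any(neg)) {
        sh$values[, neg] <- sweep(sh$values[, neg, drop = FALSE], 2,
                                  mins[neg])
      }
      utils::head(chi2_rank(sh)$feature, per_fold_k)
    },
    ReliefF = utils::head(relieff_rank(fm)$feature, per_fold_k),
    CFS = cfs_select(fm),
    MRMR = mrmr_select(fm, d = per_fold_k),
    JMI = jmi_select(fm, d = per_fold_k),
    stop("unknown selection method '", method, "'"))
}

#' Repeated cross-validated consensus feature selection
#'
#' Runs each selection method on every training fold of a repeated
#' stratified k-fold split (after fold-local imputation, normalization and
#' SMOTE balancing), aggregates per-method selection frequencies over the
#' `repeats x folds` fold-runs, and derives:
#' * `top20` — the `top_k` features with the highest mean selection
#'   frequency across methods (ties by name);
#' * `stable` — features selected in at least `stable_freq` of the
#'   fold-runs by at least `stable_methods` methods.
#'
#' @param fm A `feature_matrix` with binary target.
#' @param methods Character subset of
#'   `c("CHI2", "ReliefF", "CFS", "MRMR", "JMI")`.
#' @param repeats,folds CV geometry (default 10 x 10).
#' @param per_fold_k Features each ranking method contributes per fold
#'   (default 20; subset methods contribute their subsets).
#' @param top_k Width of the consensus list (default 20).
#' @param stable_freq,stable_methods Stability rule (defaults 0.8 and 3).
#' @param seed Integer seed controlling folds and fold-local SMOTE.
#' @return A `selection_result`: `records` (method/repeat/fold/feature),
#'   `frequency` (feature x method matrix), `top20`, `stable`.
#' @export
cv_consensus <- function(fm,
                         methods = c("CHI2", "ReliefF", "CFS", "MRMR",
                                     "JMI"),
                         repeats = 10, folds = 10, per_fold_k = 20,
                         top_k = 20, stable_freq = 0.8, stable_methods = 3,
                         seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  methods <- match.arg(methods, several.ok = TRUE)
  y <- fm$target
  if (length(unique(y)) != 2) stop("binary target required", call. = FALSE)
  feats <- colnames(fm$values)
  counts <- matrix(0, length(feats), length(methods),
                   dimnames = list(feats, methods))
  rec <- vector("list", repeats * folds * length(methods))
  ri <- 0L
  n_runs <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(y, folds, seed = seed * 1000L + r)
    for (f in seq_len(folds)) {
      train <- which(fold_id != f)
      sub <- prep_fold(fm, train, smote = TRUE,
                       seed = seed * 100000L + r * 100L + f)
      n_runs <- n_runs + 1L
      for (m in methods) {
        sel <- run_selector(m, sub, per_fold_k)
        counts[sel, m] <- counts[sel, m] + 1
        ri <- ri + 1L
        rec[[ri]] <- data.frame(method = m, rep = r, fold = f,
                                feature = sel, stringsAsFactors = FALSE)
      }
    }
  }
  freq <- counts / n_runs
  mean_freq <- rowMeans(freq)
  ord <- order(-mean_freq, feats)
  top20 <- feats[ord][seq_len(min(top_k, sum(mean_freq > 0)))]
  stable <- feats[rowSums(freq >= stable_freq) >= stable_methods]
  structure(list(records = do.call(rbind, rec[seq_len(ri)]),
                 frequency = freq, top20 = top20, stable = sort(stable),
                 repeats = repeats, folds = folds, methods = methods,
                 seed = seed),
            class = "selection_result")
}

#' @export
#' @method print selection_result
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", length(x$methods), " methods x ",
      x$repeats * x$folds, " fold-runs\n", sep = "")
  cat("  top-", length(x$top20), ": ",
      paste(utils::head(x$top20, 5), collapse = ", "),
      if (length(x$top20) > 5) ", ..." else "", "\n", sep = "")
  cat("  stable set (", length(x$stable), "): ",
      paste(x$stable, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' @param sel A `selection_result`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(
    list(frequency = as.data.frame(sel$frequency),
         features = rownames(sel$frequency),
         top20 = sel$top20, stable = sel$stable,
         repeats = sel$repeats, folds = sel$folds, seed = sel$seed),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
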