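#' Pairwise mutual-information matrix
#'
#' Empirical plug-in MI (bits) between every pair of discretized columns.
#' Continuous columns are cut into 3 equal-frequency bins first (matching
#' genotype cardinality); single-level columns yield a zero row with a
#' warning.
#'
#' @param data Data.frame of discrete/continuous variables.
#' @param bins Bins for continuous columns (default 3).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
mi_matrix <- function(data, bins = 3) {
  stopifnot(is.data.frame(data) || is.matrix(data))
  data <- as.data.frame(data)
  p <- ncol(data)
  codes <- vector("list", p)
  nlev <- integer(p)
  for (j in seq_len(p)) {
    col <- data[[j]]
    cj <- if (is.numeric(col)) discretize_ef(col, bins) else {
      as.integer(factor(col))
    }
    codes[[j]] <- cj
    nlev[j] <- max(cj, na.rm = TRUE)
    if (nlev[j] < 2) {
      warning("variable '", names(data)[j],
              "' has a single level; its MI row is zero", call. = FALSE)
    }
  }
  mi <- matrix(0, p, p, dimnames = list(names(data), names(data)))
  for (i in seq_len(p - 1)) {
    for (j in seq((i + 1), p)) {
      if (nlev[i] < 2 || nlev[j] < 2) next
      ok <- !is.na(codes[[i]]) & !is.na(codes[[j]])
      mi[i, j] <- mi[j, i] <- mi_codes(codes[[i]][ok], codes[[j]][ok],
                                       nlev[i], nlev[j])
    }
  }
  mi
}

#' Data-processing-inequality edge pruning
#'
#' For every triplet of mutually connected variables the weakest edge is
#' removed when its MI is strictly below `(1 - epsilon)` times both other
#' edges — the ARACNE rule that an indirect interaction X–Y in a chain
#' X -> M -> Y cannot carry more information than either direct link.
#' All triplets are evaluated against the original matrix, so the result
#' does not depend on traversal order; at most one edge is removed per
#' fully connected triplet, and exact three-way ties remove nothing.
#'
#' @param mi Symmetric non-negative MI matrix.
#' @param epsilon DPI tolerance in \[0, 1) (default 0 = strict).
#' @param min_mi Edges at or below this MI are treated as absent before
#'   pruning (default 0; the empirical estimator is almost surely positive
#'   on finite samples, so a small floor suppresses estimation noise).
#' @return Logical adjacency matrix of retained edges.
#' @export
dpi_prune <- function(mi, epsilon = 0, min_mi = 0) {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi))
  if (max(abs(mi - t(mi))) > 1e-10) stop("MI matrix must be symmetric")
  p <- nrow(mi)
  present <- mi > min_mi
  diag(present) <- FALSE
  keep <- present
  if (p < 3) return(keep)
  for (i in seq_len(p - 2)) {
    for (j in seq(i + 1, p - 1)) {
      if (!present[i, j]) next
      for (k in seq(j + 1, p)) {
        if (!present[i, k] || !present[j, k]) next
        e <- c(mi[i, j], mi[i, k], mi[j, k])
        w <- which.min(e)
        others <- e[-w]
        if (e[w] < (1 - epsilon) * others[1] &&
            e[w] < (1 - epsilon) * others[2]) {
          if (w == 1) { keep[i, j] <- keep[j, i] <- FALSE }
          else if (w == 2) { keep[i, k] <- keep[k, i] <- FALSE }
          else { keep[j, k] <- keep[k, j] <- FALSE }
        }
      }
    }
  }
  keep
}

#' Bootstrap ARACNE network with edge-support filtering
#'
#' Resamples subjects with replacement `n_boot` times; each replicate gets
#' an MI matrix and DPI pruning, and an edge's support is the fraction of
#' replicates in which it is retained. Edges with support at or above the
#' threshold (46% by default) form the final network. Edge weights are the
#' MI on the full data.
#'
#' @param data Data.frame of network variables (genotypes, mediators,
#'   disorder).
#' @param mediators Chronotype mediator column names present in `data`.
#' @param disorder The outcome column name.
#' @param n_boot Bootstrap replicates (default 100, minimum 50).
#' @param threshold Bootstrap support threshold (default 0.46).
#' @param epsilon DPI tolerance (default 0).
#' @param min_mi MI floor below which edges are absent (default 0).
#' @param bins Discretization bins (default 3).
#' @param seed Integer seed.
#' @return An `mi_network`: `nodes`, `edges` (data.frame from/to/weight/
#'   support over retained edges), `support` (full matrix), `mediators`,
#'   `disorder`, and `path_labels` from [classify_paths()].
#' @export
bootstrap_network <- function(data, mediators = intersect(c("meq", "msf"),
                                                          names(data)),
                              disorder, n_boot = 100, threshold = 0.46,
                              epsilon = 0, min_mi = 0, bins = 3,
                              seed = 1) {
  if (n_boot < 50) stop("n_boot must be at least 50", call. = FALSE)
  stopifnot(disorder %in% names(data))
  n <- nrow(data)
  p <- ncol(data)
  support <- matrix(0, p, p, dimnames = list(names(data), names(data)))
  set.seed(as.integer(seed))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    mi_b <- suppressWarnings(mi_matrix(data[idx, , drop = FALSE], bins))
    support <- support + dpi_prune(mi_b, epsilon, min_mi)
  }
  support <- support / n_boot
  mi_full <- suppressWarnings(mi_matrix(data, bins))
  retained <- support >= threshold
  diag(retained) <- FALSE
  ut <- which(upper.tri(retained) & retained, arr.ind = TRUE)
  edges <- data.frame(
    from = rownames(retained)[ut[, 1]],
    to = colnames(retained)[ut[, 2]],
    weight = mi_full[ut],
    support = support[ut],
    stringsAsFactors = FALSE)
  net <- structure(list(nodes = names(data), edges = edges,
                        support = support, mi = mi_full,
                        mediators = mediators, disorder = disorder,
                        threshold = threshold, n_boot = n_boot,
                        seed = seed),
                   class = "mi_network")
  net$path_labels <- classify_paths(net)
  net
}

has_edge <- function(net, a, b) {
  any((net$edges$from == a & net$edges$to == b) |
        (net$edges$from == b & net$edges$to == a))
}

#' Direct vs chronotype-mediated path labels
#'
#' A genotype node is `direct` if it retains an edge to the disorder node;
#' `mediated` if it has no direct edge but connects to a mediator that
#' itself connects to the disorder; `none` otherwise.
#'
#' @param net An `mi_network`.
#' @return Named character vector over the genotype (non-mediator,
#'   non-disorder) nodes.
#' @export
classify_paths <- function(net) {
  if (!net$disorder %in% net$nodes) stop("disorder node missing")
  genos <- setdiff(net$nodes, c(net$mediators, net$disorder))
  med_to_y <- net$mediators[vapply(net$mediators, function(md) {
    has_edge(net, md, net$disorder)
  }, TRUE)]
  labels <- vapply(genos, function(g) {
    if (has_edge(net, g, net$disorder)) return("direct")
    via <- any(vapply(med_to_y, function(md) has_edge(net, g, md), TRUE))
    if (length(med_to_y) && via) "mediated" else "none"
  }, "")
  labels
}

#' @export
#' @method print mi_network
print.mi_network <- function(x, ...) {
  cat("<mi_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges retained at support >= ", x$threshold, "\n", sep = "")
  if (length(x$path_labels)) {
    for (lb in c("direct", "mediated")) {
      who <- names(x$path_labels)[x$path_labels == lb]
      if (length(who)) cat("  ", lb, ": ",
                           paste(who, collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Export an MI network
#'
#' @param net An `mi_network`.
#' @param path Base path; writes `<path>.graphml`, edge-list `<path>.csv`
#'   and path labels `<path>_labels.csv`.
#' @return The base path, invisibly.
#' @export
write_mi_network <- function(net, path) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  utils::write.csv(net$edges, paste0(path, ".csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(node = names(net$path_labels),
               label = unname(net$path_labels)),
    paste0(path, "_labels.csv"), row.names = FALSE)
  invisible(path)
}

#' Assemble the ARACNE variable table from a cohort
#'
#' One column per genotype locus plus the chronotype mediators and the
#' disorder score/label.
#'
#' @param cohort A cohort.
#' @param outcome `"SPAQ"`, `"SAD"` or `"BDI"`; score outcomes keep their
#'   numeric scale (discretized later), SAD enters as 0/1.
#' @param stratum `"all"`, `"M"` or `"F"`.
#' @return Data.frame ready for [bootstrap_network()].
#' @export
aracne_table <- function(cohort, outcome = c("SPAQ", "SAD", "BDI"),
                         stratum = "all") {
  outcome <- match.arg(outcome)
  idx <- if (stratum == "all") seq_len(nrow(cohort)) else {
    which(as.character(cohort$gender) == stratum)
  }
  geno <- genotype_cols(cohort)
  out <- cohort[idx, geno, drop = FALSE]
  out$meq <- cohort$meq[idx]
  out$msf <- cohort$msf[idx]
  ycol <- switch(outcome, SPAQ = "spaq", BDI = "bdi", SAD = "sad")
  out[[ycol]] <- cohort[[ycol]][idx]
  out <- out[stats::complete.cases(out), , drop = FALSE]
  as.data.frame(out)
}
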