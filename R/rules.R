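#' Build per-subject transaction item sets
#'
#' Categorical features become `FEATURE=LEVEL` items; continuous clinical
#' columns are quartile-binned (`FEATURE=Q1..Q4`) before itemization. The
#' binary disorder outcome becomes the designated consequent item
#' (e.g. `"SPAQ=seasonal"`).
#'
#' @param cohort A cohort.
#' @param outcome `"SPAQ"`, `"SAD"` or `"BDI"`.
#' @param features Columns to itemize; defaults to the one-way features
#'   plus anxiety and sleep disturbance.
#' @return List with `transactions` (logical subject x item matrix),
#'   `consequent` (the disorder item name).
#' @export
make_transactions <- function(cohort, outcome = c("SPAQ", "SAD", "BDI"),
                              features = NULL) {
  outcome <- match.arg(outcome)
  y <- binarize_outcome(cohort, outcome)
  if (is.null(features)) {
    ow <- assemble_oneway(cohort)
    features <- c(names(ow), "anxiety", "sleep_disturbance")
    features <- intersect(features, names(cohort))
  }
  items <- list()
  for (f in features) {
    col <- cohort[[f]]
    if (is.numeric(col)) {
      q <- unique(stats::quantile(col, probs = seq(0, 1, 0.25),
                                  na.rm = TRUE))
      if (length(q) < 3) next
      lev <- cut(col, breaks = q, include.lowest = TRUE,
                 labels = paste0("Q", seq_len(length(q) - 1)))
      col <- as.character(lev)
    } else {
      col <- as.character(col)
    }
    for (lv in sort(unique(col[!is.na(col)]))) {
      items[[paste0(f, "=", lv)]] <- !is.na(col) & col == lv
    }
  }
  cons <- paste0(outcome, "=", switch(outcome, SPAQ = "seasonal",
                                      BDI = "depressed", SAD = "1"))
  items[[cons]] <- !is.na(y) & y == 1
  tm <- do.call(cbind, items)
  keep <- !is.na(y)
  list(transactions = tm[keep, , drop = FALSE], consequent = cons)
}

#' Apriori association-rule mining toward a disorder consequent
#'
#' Classic level-wise apriori: frequent antecedent itemsets are grown one
#' item at a time with downward-closure pruning, where frequency is
#' measured jointly with the consequent (`support(X -> Y) = P(X and Y)`).
#' Rules keep `support >= min_support`, `confidence = P(Y|X) >=
#' min_confidence`, and total size (antecedent + consequent) at most
#' `max_size`; they are sorted by descending lift (`confidence / P(Y)`),
#' ties by descending support then lexicographic antecedent.
#'
#' @param transactions Logical subject x item matrix (or the list from
#'   [make_transactions()]).
#' @param consequent The disorder item name (taken from the list input if
#'   omitted).
#' @param min_support Minimum joint support (default 0.04; must be > 0).
#' @param min_confidence Minimum confidence (default 0.7).
#' @param max_size Maximum rule size including the consequent (default 6).
#' @return Data.frame of class `rule_set`: `antecedent` (items joined by
#'   `" & "`), `size`, `support`, `confidence`, `lift`.
#' @export
apriori_mine <- function(transactions, consequent = NULL,
                         min_support = 0.04, min_confidence = 0.7,
                         max_size = 6) {
  if (is.list(transactions) && !is.matrix(transactions)) {
    consequent <- consequent %||% transactions$consequent
    transactions <- transactions$transactions
  }
  if (min_support <= 0) stop("min_support must be > 0", call. = FALSE)
  stopifnot(is.matrix(transactions), !is.null(consequent),
            consequent %in% colnames(transactions))
  n <- nrow(transactions)
  ycol <- transactions[, consequent]
  p_y <- mean(ycol)
  items <- setdiff(colnames(transactions), consequent)
  max_ante <- max_size - 1L

  # level 1: single items frequent jointly with the consequent
  joint_supp <- colSums(transactions[, items, drop = FALSE] & ycol) / n
  frequent <- lapply(items[joint_supp >= min_support], function(i) i)
  all_levels <- list()
  if (length(frequent)) all_levels[[1]] <- frequent
  level <- frequent
  k <- 1L
  while (length(level) >= 2 && k < max_ante) {
    prev_keys <- vapply(level, paste, "", collapse = "\r")
    cand <- list()
    # join step: pairs sharing the first k-1 items
    for (i in seq_along(level)) {
      for (j in seq_along(level)) {
        if (j <= i) next
        a <- level[[i]]; b <- level[[j]]
        if (k == 1L || identical(a[seq_len(k - 1)], b[seq_len(k - 1)])) {
          un <- sort(union(a, b))
          if (length(un) == k + 1L) {
            cand[[paste(un, collapse = "\r")]] <- un
          }
        }
      }
    }
    # prune step: every k-subset must be frequent
    cand <- Filter(function(cs) {
      subs <- utils::combn(cs, k, simplify = FALSE)
      all(vapply(subs, function(s) {
        paste(sort(s), collapse = "\r") %in% prev_keys
      }, TRUE))
    }, cand)
    # count step
    level <- Filter(function(cs) {
      mean(rowSums(transactions[, cs, drop = FALSE]) == length(cs) &
             ycol) >= min_support
    }, cand)
    level <- lapply(level, sort)
    if (length(level)) all_levels[[k + 1L]] <- unname(level)
    k <- k + 1L
  }

  rules <- list()
  for (lev in all_levels) {
    for (ante in lev) {
      hitx <- rowSums(transactions[, ante, drop = FALSE]) == length(ante)
      supp_x <- mean(hitx)
      supp <- mean(hitx & ycol)
      conf <- supp / supp_x
      if (conf < min_confidence) next
      rules[[length(rules) + 1L]] <- data.frame(
        antecedent = paste(sort(ante), collapse = " & "),
        size = length(ante) + 1L,
        support = supp, confidence = conf, lift = conf / p_y,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rules)) do.call(rbind, rules) else {
    data.frame(antecedent = character(), size = integer(),
               support = numeric(), confidence = numeric(),
               lift = numeric(), stringsAsFactors = FALSE)
  }
  out <- out[order(-out$lift, -out$support, out$antecedent), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "consequent") <- consequent
  attr(out, "p_consequent") <- p_y
  class(out) <- c("rule_set", "data.frame")
  out
}

#' Rule network graph
#'
#' Items and the consequent become nodes; each antecedent item gains an
#' edge to the consequent. Node `size` is the maximum support of any rule
#' containing the item; edge `width` is the maximum confidence of rules
#' containing the item.
#'
#' @param rules A `rule_set` from [apriori_mine()].
#' @return An [igraph::graph] with `size` vertex and `width` edge
#'   attributes.
#' @export
rule_network <- function(rules) {
  if (!nrow(rules)) stop("empty rule list", call. = FALSE)
  consequent <- attr(rules, "consequent")
  ante_items <- strsplit(rules$antecedent, " & ", fixed = TRUE)
  item_support <- list(); item_conf <- list()
  for (i in seq_len(nrow(rules))) {
    for (it in ante_items[[i]]) {
      item_support[[it]] <- max(item_support[[it]] %||% 0,
                                rules$support[i])
      item_conf[[it]] <- max(item_conf[[it]] %||% 0, rules$confidence[i])
    }
  }
  items <- sort(names(item_support))
  g <- igraph::graph_from_data_frame(
    data.frame(from = items, to = consequent,
               width = unlist(item_conf[items]),
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(
      name = c(items, consequent),
      size = c(unlist(item_support[items]), max(rules$support)),
      stringsAsFactors = FALSE))
  g
}

#' Export a rule network
#'
#' @param graph An igraph object from [rule_network()].
#' @param path Base path; writes `<path>.graphml` and an edge-list
#'   `<path>.csv`.
#' @return The base path, invisibly.
#' @export
write_rule_network <- function(graph, path) {
  igraph::write_graph(graph, paste0(path, ".graphml"), format = "graphml")
  el <- igraph::as_data_frame(graph, what = "edges")
  utils::write.csv(el, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
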