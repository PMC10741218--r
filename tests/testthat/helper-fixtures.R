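# small builders shared across test files

# bare feature_matrix from a numeric matrix (all columns typed as given)
fm_from_matrix <- function(x, target = NULL, type = "indicator",
                           target_name = "SAD") {
  if (is.null(colnames(x)) && ncol(x) > 0) {
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  }
  map <- data.frame(column = colnames(x), source = colnames(x),
                    level = NA_character_, reference = NA_character_,
                    type = rep(type, length.out = ncol(x)),
                    stringsAsFactors = FALSE)
  structure(list(values = x, map = map, target = target,
                 target_name = target_name),
            class = "feature_matrix")
}

# independent plug-in MI oracle (natural direct summation over a table)
mi_oracle <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) {
        mi <- mi + pij * log2(pij / ((sum(tab[i, ]) / n) *
                                       (sum(tab[, j]) / n)))
      }
    }
  }
  mi
}

# independent entropy oracle (bits)
entropy_oracle <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# independent symmetrical-uncertainty oracle
su_oracle <- function(x, y) {
  hx <- entropy_oracle(x); hy <- entropy_oracle(y)
  if (hx + hy == 0) return(0)
  2 * mi_oracle(x, y) / (hx + hy)
}

# independent CFS merit oracle over discrete columns
cfs_merit_oracle <- function(cols, y) {
  k <- length(cols)
  rcf <- mean(vapply(cols, function(f) su_oracle(f, y), 0))
  rff <- if (k > 1) {
    prs <- utils::combn(k, 2)
    mean(vapply(seq_len(ncol(prs)), function(c2) {
      su_oracle(cols[[prs[1, c2]]], cols[[prs[2, c2]]])
    }, 0))
  } else 0
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

# brute-force association rule oracle: enumerate every antecedent subset
brute_force_rules <- function(tm, consequent, min_support, min_confidence,
                              max_size) {
  items <- setdiff(colnames(tm), consequent)
  ycol <- tm[, consequent]
  p_y <- mean(ycol)
  out <- list()
  for (sz in seq_len(max_size - 1L)) {
    if (sz > length(items)) break
    subs <- utils::combn(items, sz, simplify = FALSE)
    for (s in subs) {
      hit <- rowSums(tm[, s, drop = FALSE]) == length(s)
      supp <- mean(hit & ycol)
      if (supp < min_support) next
      conf <- supp / mean(hit)
      if (conf < min_confidence) next
      out[[length(out) + 1L]] <- data.frame(
        antecedent = paste(sort(s), collapse = " & "),
        size = sz + 1L, support = supp, confidence = conf,
        lift = conf / p_y, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(antecedent = character(), size = integer(),
               support = numeric(), confidence = numeric(),
               lift = numeric())
  }
  res[order(-res$lift, -res$support, res$antecedent), , drop = FALSE]
}

# tiny deterministic transaction matrix over a small item alphabet
random_transactions <- function(n, items, p, seed, y_from = NULL) {
  set.seed(seed)
  tm <- matrix(runif(n * length(items)) < p, n, length(items),
               dimnames = list(NULL, items))
  if (!is.null(y_from)) {
    yy <- rowSums(tm[, y_from, drop = FALSE]) == length(y_from)
    flip <- runif(n) < 0.15
    tm <- cbind(tm, Y = xor(yy, flip))
  } else {
    tm <- cbind(tm, Y = runif(n) < 0.4)
  }
  tm
}
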