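test_that("one-way assembly yields the 14 named features", {
  coh <- simulate_cohort(n = 50, seed = 1)
  ow <- assemble_oneway(coh)
  expect_equal(ncol(ow), 14)
  expect_equal(length(attr(ow, "genotypes")), 9)
  expect_true(all(c("gender", "meq", "msf", "age_group", "ses") %in%
                    names(ow)))
  coh2 <- coh; coh2$msf <- NULL
  expect_error(assemble_oneway(coh2), "msf")
})

test_that("two-way expansion enumerates choose(g,2) x 9 combinations", {
  coh <- simulate_cohort(n = 200, seed = 2)
  tw <- expand_twoway(assemble_oneway(coh))
  pairs <- attr(tw, "pairs")
  expect_equal(length(pairs), choose(9, 2))
  n_comb <- sum(vapply(pairs, function(p) nlevels(tw[[p]]), 0L))
  expect_equal(n_comb, 324)
  # small-g cases: C(2,2)*9 and C(3,2)*9
  loci3 <- default_loci()[1:3]
  coh3 <- simulate_cohort(n = 100, loci = loci3, seed = 3)
  tw3 <- expand_twoway(assemble_oneway(coh3))
  expect_equal(sum(vapply(attr(tw3, "pairs"),
                          function(p) nlevels(tw3[[p]]), 0L)), 27)
  loci2 <- default_loci()[1:2]
  coh2 <- simulate_cohort(n = 100, loci = loci2, seed = 3)
  tw2 <- expand_twoway(assemble_oneway(coh2))
  expect_equal(length(attr(tw2, "pairs")), 1)
  expect_equal(nlevels(tw2[[attr(tw2, "pairs")]]), 9)
})

test_that("reference removal drops the most frequent level, ties by name", {
  tab <- data.frame(
    g = rep(c("hi", "mid", "lo"), times = c(50, 30, 20)),
    stringsAsFactors = FALSE)
  fm <- one_hot_reference(tab)
  expect_setequal(colnames(fm$values), c("g=mid", "g=lo"))
  expect_equal(unique(fm$map$reference), "hi")
  # tie: "a" and "b" both 10 -> lexicographically first is reference
  tie <- data.frame(g = rep(c("b", "a"), each = 10),
                    stringsAsFactors = FALSE)
  fm2 <- one_hot_reference(tie)
  expect_equal(unique(fm2$map$reference), "a")
  expect_equal(colnames(fm2$values), "g=b")
  # binary feature -> one indicator; numeric passes through
  mixed <- data.frame(b = c("x", "y", "x", "x"), z = c(1, 2, 3, 4),
                      stringsAsFactors = FALSE)
  fm3 <- one_hot_reference(mixed)
  expect_setequal(colnames(fm3$values), c("b=y", "z"))
  # single observed level -> dropped with warning
  expect_warning(one_hot_reference(
    data.frame(s = rep("only", 5), z = 1:5)), "single observed level")
})

test_that("encoding round-trips through the map", {
  coh <- simulate_cohort(n = 120, seed = 4)
  tab <- expand_twoway(assemble_oneway(coh))
  fm <- one_hot_reference(tab)
  for (src in c("CRY1", "ses", "CLOCK3111|CRY2")) {
    for (row in c(1, 57, 120)) {
      expect_identical(decode_feature(fm, row, src),
                       as.character(tab[[src]][row]),
                       info = paste(src, row))
    }
  }
})

test_that("pruning removes exactly the all-zero indicators", {
  x <- cbind(a = c(1, 0, 1), b = c(0, 0, 0), z = c(0.5, 1, 2))
  fm <- fm_from_matrix(x, type = c("indicator", "indicator", "numeric"))
  pr <- prune_absent(fm)
  expect_setequal(colnames(pr$values), c("a", "z"))
  expect_identical(prune_absent(pr)$values, pr$values)  # idempotent
})

test_that("rare genotype pairs vanish from small encoded cohorts", {
  # at n = 50 and maf 0.15, a double-minor-homozygote pair (p ~ 5e-4)
  # is essentially never observed, so its indicator must be absent
  coh <- simulate_cohort(n = 50, loci = default_loci(maf = 0.15), seed = 5)
  fm <- build_feature_matrix(coh, "SPAQ")
  rare <- "CLOCK3111=CC|CRY1=GG"
  tab <- expand_twoway(assemble_oneway(coh))
  observed <- sum(tab[["CLOCK3111|CRY1"]] == "CC|GG", na.rm = TRUE)
  if (observed == 0) {
    expect_false(rare %in% colnames(fm$values))
  } else {
    expect_true(rare %in% colnames(fm$values))
  }
})

test_that("kNN imputation fills holes from nearest rows only", {
  # k = 1 with a unique nearest row copies that row's value
  x <- rbind(c(1, 1, 0), c(1, 1, 1), c(10, 10, 1))
  x[1, 3] <- NA
  fm <- fm_from_matrix(x)
  out <- knn_impute(fm, k = 1)
  expect_equal(unname(out$values[1, 3]), 1)
  # duplicate-row fixture: hole filled with the duplicate's value
  d <- rbind(c(0, 0, 5), c(0, 0, 5), c(0, 0, 5), c(9, 9, 0))
  d[2, 3] <- NA
  for (k in 1:2) {
    expect_equal(unname(knn_impute(fm_from_matrix(d), k = k)$values[2, 3]), 5)
  }
  # observed cells never altered; no-NA input is identity
  full <- fm_from_matrix(rbind(c(1, 2), c(3, 4)))
  expect_identical(knn_impute(full, 1)$values, full$values)
  miss <- fm_from_matrix(rbind(c(1, NA), c(NA, NA), c(0, 1)))
  expect_error(knn_impute(fm_from_matrix(cbind(c(NA, NA), c(1, 2))), 1),
               "entirely missing")
})

test_that("SMOTE balances classes with convex synthetic points", {
  set.seed(1)
  x <- rbind(matrix(rnorm(18, 0), 9), matrix(rnorm(6, 5), 3))
  fm <- fm_from_matrix(x, target = c(rep(0, 9), rep(1, 3)))
  out <- smote_balance(fm, k = 5, seed = 2)
  expect_equal(as.integer(table(out$target)), c(9L, 9L))
  expect_equal(nrow(out$values), 18)
  # synthetic rows lie in the minority's bounding box (convexity)
  syn <- out$values[13:18, , drop = FALSE]
  mino <- x[10:12, , drop = FALSE]
  expect_true(all(syn[, 1] >= min(mino[, 1]) - 1e-9 &
                    syn[, 1] <= max(mino[, 1]) + 1e-9))
  # two-point minority, k = 1: all points on the segment
  x2 <- rbind(matrix(0, 6, 2), c(0, 0), c(1, 1))
  fm2 <- fm_from_matrix(x2, target = c(rep(0, 6), 1, 1))
  out2 <- smote_balance(fm2, k = 1, seed = 3)
  syn2 <- out2$values[9:12, ]
  expect_true(all(abs(syn2[, 1] - syn2[, 2]) < 1e-12))
  # determinism & already-balanced identity
  expect_identical(smote_balance(fm, 5, seed = 2)$values, out$values)
  bal <- fm_from_matrix(x2, target = rep(c(0, 1), 4))
  expect_identical(smote_balance(bal, 1, seed = 1), bal)
  # minority of one errors
  fm1 <- fm_from_matrix(x2, target = c(rep(0, 7), 1))
  expect_error(smote_balance(fm1, 1, 1), "minority")
})

test_that("normalization standardizes numeric columns idempotently", {
  x <- cbind(ind = c(0, 1, 0, 1), z = c(1, 2, 3, 4), const = rep(7, 4))
  fm <- fm_from_matrix(x, type = c("indicator", "numeric", "numeric"))
  out <- normalize_features(fm)
  expect_equal(mean(out$values[, "z"]), 0)
  expect_equal(sd(out$values[, "z"]), 1)
  expect_identical(out$values[, "ind"], x[, "ind"])
  expect_true(all(out$values[, "const"] == 0))
  expect_equal(normalize_features(out)$values, out$values)
})

test_that("targets binarize at the published thresholds", {
  coh <- data.frame(spaq = c(0, 10, 11, 24), bdi = c(0, 13, 14, 60),
                    sad = c(0, 1, 0, 1))
  expect_equal(binarize_outcome(coh, "SPAQ"), c(0, 0, 1, 1))
  expect_equal(binarize_outcome(coh, "BDI"), c(0, 0, 1, 1))
  expect_equal(binarize_outcome(coh, "SAD"), c(0, 1, 0, 1))
})
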