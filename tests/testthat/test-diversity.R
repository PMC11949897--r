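test_that("alpha diversity matches hand-computed values", {
  tbl <- make_table(rbind(c(10, 10, 10, 10), c(40, 0, 0, 0), c(5, 0, 1, 0)))
  a <- alphaDiversity(tbl)
  expect_equal(a$observed, c(4L, 1L, 2L))
  expect_equal(a$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(a$shannon[2], 0)
  ## entropy bounded by log(observed), equality iff uniform
  expect_lt(a$shannon[3], log(2))
  ## scale invariance: duplicating all counts leaves shannon unchanged
  expect_equal(alphaDiversity(make_table(2 * countsMatrix(tbl)))$shannon,
               a$shannon)
})

test_that("rarefaction preserves totals, drops shallow samples and is unbiased", {
  tbl <- make_table(rbind(c(30, 20, 10), c(5, 3, 2)))
  r <- suppressWarnings(rarefyCounts(tbl, 10, seed = 1))
  expect_true(all(rowSums(countsMatrix(r)) == 10))
  expect_warning(rarefyCounts(tbl, 20, seed = 1), "dropped 1 sample")
  expect_error(rarefyCounts(tbl, 100), "fewer than")
  ## sample at exactly its total is returned unchanged
  r2 <- rarefyCounts(make_table(matrix(c(4, 6), 1, 2)), 10, seed = 1)
  expect_equal(unname(countsMatrix(r2)[1, ]), c(4, 6))

  ## depth = total - 1: per-ASV means match the hypergeometric expectation
  x <- c(12, 7, 3)
  tb <- make_table(matrix(x, 1, 3))
  draws <- vapply(1:1000, function(s)
    countsMatrix(rarefyCounts(tb, 21, seed = s))[1, ], numeric(3))
  mu <- x * 21 / 22
  se <- sqrt(x * (21 / 22) * (1 / 22) * ((22 - x) / 21)) / sqrt(1000)
  expect_true(all(abs(rowMeans(draws) - mu) < pmax(3 * se, 0.02)))
})

test_that("rarefaction curves are monotone and hit the exact endpoints", {
  tbl <- make_table(rbind(c(50, 30, 20, 0), c(10, 0, 0, 1)))
  rc <- rarefactionCurve(tbl, depths = c(1, 5, 11, 100), reps = 50, seed = 2)
  expect_equal(rc["s1", "1"], 1)
  expect_equal(rc["s2", "11"], 2)       # full-sample observed
  expect_true(is.na(rc["s2", "100"]))
  mono <- apply(rc, 1, function(x) all(diff(x[!is.na(x)]) >= 0))
  expect_true(all(mono))
  expect_error(rarefactionCurve(tbl, numeric(0)), "empty")
})

test_that("Bray-Curtis matches the formula and the double-loop oracle", {
  tbl <- make_table(rbind(c(1, 1), c(1, 3), c(1, 1)))
  d <- as.matrix(brayCurtisMatrix(tbl, normalize = FALSE))
  expect_equal(d["s1", "s2"], 2 / 6, tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 0)
  ## disjoint supports
  d2 <- as.matrix(brayCurtisMatrix(make_table(rbind(c(5, 0), c(0, 9))),
                                   normalize = FALSE))
  expect_equal(d2["s1", "s2"], 1)

  set.seed(7)
  for (i in 1:100) {
    m <- matrix(rpois(5 * 4, 8) + 1, 5, 4)
    tb <- make_table(m)
    d <- as.matrix(brayCurtisMatrix(tb, normalize = FALSE))
    expect_true(isSymmetric(d))
    expect_true(all(d >= 0 & d <= 1))
    i1 <- sample(5, 1); i2 <- sample(5, 1)
    expect_equal(d[i1, i2], if (i1 == i2) 0 else oracle_bray(m[i1, ], m[i2, ]),
                 tolerance = 1e-12)
  }
})

test_that("NMDS recovers embeddable configurations and reports true stress", {
  set.seed(3)
  pts <- matrix(rnorm(12), 6, 2)
  d <- dist(pts)
  attr(d, "Labels") <- paste0("s", 1:6)
  fit <- nmdsOrdination(d, k = 2, n_starts = 10, seed = 1)
  expect_lt(fit$stress, 0.01)

  ## stress equals an independent recomputation from the coordinates
  noisy <- dist(pts + rnorm(12, sd = 0.4))
  fit2 <- nmdsOrdination(noisy, k = 2, n_starts = 10, seed = 2)
  expect_equal(fit2$stress, stress1(noisy, fit2$coordinates),
               tolerance = 1e-3)

  ## two well-separated clusters stay separated in the ordination
  cl <- rbind(matrix(rnorm(10, 0, 0.2), 5, 2),
              matrix(rnorm(10, 8, 0.2), 5, 2))
  fit3 <- nmdsOrdination(dist(cl), seed = 3, n_starts = 5)
  co <- fit3$coordinates
  within <- mean(c(dist(co[1:5, ]), dist(co[6:10, ])))
  between <- mean(as.matrix(dist(co))[1:5, 6:10])
  expect_gt(between, within)

  expect_error(nmdsOrdination(dist(matrix(0, 4, 2))), "degenerate")
})

test_that("PERMANOVA pseudo-F agrees with vegan and detects extreme separation", {
  set.seed(11)
  m <- matrix(rpois(12 * 6, 12) + 1, 12, 6)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- brayCurtisMatrix(make_table(m), normalize = TRUE)
  mine <- permanovaTest(d, g, n_perm = 199, seed = 1)
  ref <- vegan::adonis2(d ~ gg, data = data.frame(gg = g), permutations = 199)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$df_between, 2)
  expect_equal(mine$df_within, 9)
  expect_gte(mine$p, 1 / 200)

  ## extreme separation: the p value attains its permutation floor (with
  ## 10 + 10 samples the original partition recurring among 999 sampled
  ## permutations is vanishingly unlikely)
  sep <- rbind(matrix(rpois(30, 3), 10, 3),
               matrix(rpois(30, 3) + 500, 10, 3))
  ds <- brayCurtisMatrix(make_table(sep), normalize = FALSE)
  res <- permanovaTest(ds, rep(c("lo", "hi"), each = 10), n_perm = 999,
                       seed = 5)
  expect_equal(res$p, 1 / 1000)

  expect_error(permanovaTest(d, c(rep("a", 11), "b")), ">= 2 members")
})

test_that("duplicating every sample preserves the PERMANOVA SS partition", {
  set.seed(21)
  m <- matrix(rpois(9 * 5, 10) + 1, 9, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  f1 <- permanovaTest(dist(m), g, n_perm = 99, seed = 1)$pseudo_F
  m2 <- m[rep(1:9, each = 2), ]
  rownames(m2) <- paste0("r", 1:18)
  f2 <- permanovaTest(dist(m2), rep(g, each = 2), n_perm = 99,
                      seed = 1)$pseudo_F
  ## the SS_between / SS_within ratio is duplication-invariant, so the two
  ## pseudo-Fs differ only through their residual degrees of freedom
  r1 <- f1 * 2 / (9 - 3)
  r2 <- f2 * 2 / (18 - 3)
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("rank-based group tests match exact enumeration and Holm adjustment", {
  ## all values equal: H = 0
  same <- groupDifferenceTests(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$omnibus$H, 0)

  ## exhaustive one-sided rank-sum: [1,2,3] vs [4,5,6] -> 1/20
  w <- groupDifferenceTests(1:6, rep(c("a", "b"), each = 3),
                            alternative = "less")
  expect_true(w$exact)
  expect_equal(w$p, 0.05)

  ## Holm on [0.01, 0.04]
  expect_equal(holmAdjust(c(0.01, 0.04)), c(0.02, 0.04))

  ## Dunn pairwise z recomputed from first principles on a small case
  vals <- c(1, 3, 5, 7, 9, 11, 2, 4, 6)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- groupDifferenceTests(vals, grp)
  rk <- rank(vals)
  s2 <- length(vals) * (length(vals) + 1) / 12   # no ties
  mr <- tapply(rk, grp, mean)
  z_ab <- (mr["a"] - mr["b"]) / sqrt(s2 * (2 / 3))
  row_ab <- res$pairwise[res$pairwise$group1 == "a" &
                           res$pairwise$group2 == "b", ]
  expect_equal(row_ab$z, unname(z_ab), tolerance = 1e-12)
  expect_equal(row_ab$p, 2 * pnorm(-abs(unname(z_ab))), tolerance = 1e-12)
  expect_equal(res$pairwise$p_adj, oracle_holm(res$pairwise$p))

  expect_error(groupDifferenceTests(1:3, factor(c("a", "a", "a"),
                                                levels = c("a", "b"))),
               "non-empty")
})
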