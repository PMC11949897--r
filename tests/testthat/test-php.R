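test_that("percent identity matches hand-built cases", {
  s <- random_dna(300)
  expect_equal(pairwiseIdentity(s, s)$identity, 100)

  ## 3 substitutions in 100 aligned bp, no gaps -> 97.0
  q <- random_dna(100)
  qm <- q
  for (pos in c(10, 50, 90)) {
    old <- substr(qm, pos, pos)
    substr(qm, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  r <- pairwiseIdentity(qm, q)
  expect_equal(r$identity, 97)
  expect_equal(r$alignment_columns, 100L)

  ## containment: 150 bp query inside a 600 bp reference scores 100, and the
  ## exhaustive ungapped offset scan agrees
  ref <- random_dna(600)
  qq <- substr(ref, 201, 350)
  expect_equal(pairwiseIdentity(qq, ref)$identity, 100)
  best_offset <- max(vapply(0:(600 - 150), function(o) {
    sum(strsplit(qq, "")[[1]] ==
          strsplit(substr(ref, o + 1, o + 150), "")[[1]])
  }, 0))
  expect_equal(best_offset, 150)

  ## symmetry in the arguments
  a <- random_dna(80); b <- random_dna(120)
  expect_equal(pairwiseIdentity(a, b)$identity,
               pairwiseIdentity(b, a)$identity)

  ## IUPAC ambiguity codes match iff base sets intersect
  expect_equal(pairwiseIdentity("ACGR", "ACGA")$identity, 100)  # R = A/G
  expect_equal(pairwiseIdentity("ACGY", "ACGA")$identity, 75)   # Y = C/T
  expect_equal(pairwiseIdentity("NNNN", "ACGT")$identity, 100)

  expect_error(pairwiseIdentity("", "ACGT"), "empty")
})

test_that("alignment scores agree with a full Gotoh DP oracle on random pairs", {
  set.seed(99)
  for (i in 1:200) {
    n1 <- sample(10:60, 1); n2 <- sample(10:60, 1)
    a <- random_dna(n1)
    b <- if (i %% 2 == 0) random_dna(n2) else {
      ## related pair: substitutions plus a small indel
      bb <- mutateSequence(a, 0.1, seed = i)
      if (nchar(bb) > 12) paste0(substr(bb, 1, 5), substr(bb, 9, nchar(bb)))
      else bb
    }
    got <- pairwiseIdentity(a, b)$score
    want <- if (nchar(a) <= nchar(b)) oracle_fit_score(a, b)
      else oracle_fit_score(b, a)
    expect_equal(got, want, info = sprintf("pair %d", i))
  }
})

test_that("identity screening separates planted producers from divergent ASVs", {
  set.seed(5)
  refs <- Biostrings::DNAStringSet(setNames(
    vapply(1:3, function(i) random_dna(300), ""), paste0("strain", 1:3)))
  near <- vapply(1:6, function(i)
    mutateSequence(refs[[(i %% 3) + 1]], 0.02, seed = i), "")
  far <- vapply(1:6, function(i)
    mutateSequence(refs[[(i %% 3) + 1]], 0.15, seed = 100 + i), "")
  seqs <- Biostrings::DNAStringSet(setNames(c(near, far), paste0("ASV", 1:12)))
  hits <- screenByIdentity(seqs, refs, identity_min = 97)
  expect_setequal(hits$asv_id, paste0("ASV", 1:6))
  expect_true(all(hits$alignment_columns >=
                    pmin(Biostrings::width(seqs[hits$asv_id]), 300)))

  ## inclusive threshold: exactly 97.0 is retained
  q <- random_dna(100)
  qm <- q
  for (pos in c(3, 44, 88)) {
    old <- substr(qm, pos, pos)
    substr(qm, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  h <- screenByIdentity(Biostrings::DNAStringSet(c(x = qm)),
                        Biostrings::DNAStringSet(c(ref = q)),
                        identity_min = 97)
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 97)
})

test_that("tissue-mean abundance averages percentages within tissue", {
  tbl <- make_table(rbind(c(10, 90), c(30, 70), c(50, 50)),
                    samples = c("s1", "s2", "s3"))
  meta <- data.frame(sample_id = c("s1", "s2", "s3"), species = "sp",
                     tissue = c("a", "a", "b"), replicate = c(1, 2, 1))
  tm <- tissueMeanAbundance(tbl, meta)
  expect_equal(tm["a", "ASV1"], 20)    # mean of 10% and 30%
  expect_equal(tm["b", ], c(ASV1 = 50, ASV2 = 50))
  ## permuting sample order changes nothing
  tbl2 <- make_table(countsMatrix(tbl)[c(3, 1, 2), ],
                     samples = c("s3", "s1", "s2"))
  expect_equal(tissueMeanAbundance(tbl2, meta)[rownames(tm), ], tm)
  expect_error(tissueMeanAbundance(tbl, meta[1:2, ]), "without a tissue")
})

test_that("Kendall tau-b matches exhaustive pair counting including ties", {
  expect_equal(kendallTauB(1:3, 1:3), 1)
  expect_equal(kendallTauB(1:3, 3:1), -1)
  expect_equal(kendallTauB(c(1, 2, 2, 3), c(1, 2, 3, 3)), 0.8)
  expect_true(is.na(kendallTauB(c(2, 2, 2), 1:3)))

  set.seed(31)
  for (i in 1:500) {
    n <- sample(3:30, 1)
    x <- sample(1:8, n, replace = TRUE)   # plenty of ties
    y <- sample(1:8, n, replace = TRUE)
    want <- oracle_tau_b(x, y)
    got <- kendallTauB(x, y)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the correlation screen applies a strict threshold over tissues", {
  tm <- rbind(t1 = c(p1 = 30, p2 = 1, flat = 5),
              t2 = c(20, 2, 5),
              t3 = c(10, 3, 5),
              t4 = c(5, 4, 5),
              t5 = c(1, 5, 5))
  met <- data.frame(tissue = paste0("t", 1:5), compound = "HupA",
                    mean_concentration = c(300, 200, 150, 120, 100))
  sc <- screenByCorrelation(tm, met)
  expect_identical(sc$asv_id, "p1")
  expect_equal(sc$tau, 1)
  ## constant-abundance column yields NA tau and is never retained
  expect_true(is.na(attr(sc, "all_tau")["flat"]))

  ## tau exactly 0.4 is NOT retained (strict >)
  tm2 <- cbind(tm, border = c(4, 5, 2, 1, 3))
  sc2 <- screenByCorrelation(tm2, met)
  expect_equal(unname(attr(sc2, "all_tau")["border"]), 0.4, tolerance = 1e-12)
  expect_false("border" %in% sc2$asv_id)

  expect_error(screenByCorrelation(tm[1:2, ], met), ">= 3 tissues")
  expect_error(screenByCorrelation(tm, met[-1, ]), "lacks tissue")
})

test_that("PHP call merging obeys union arithmetic", {
  ids <- function(k, pre) paste0(pre, seq_len(k))
  A <- data.frame(asv_id = c(ids(23, "a"), "both"), strain_id = "s1",
                  identity = 99, alignment_columns = 300L)
  B <- data.frame(asv_id = c(ids(3, "b"), "both"), tau = 0.9)
  calls <- mergePhpCalls(A, B)
  cc <- phpCalls(calls)
  expect_equal(nrow(cc), 27)
  expect_equal(sum(cc$evidence_clustering & cc$evidence_correlation), 1)
  expect_equal(sum(cc$evidence_clustering), 24)
  expect_equal(sum(cc$evidence_correlation), 4)

  ## B subset of A collapses to |A|
  B2 <- data.frame(asv_id = "a1", tau = 0.5)
  expect_equal(nrow(phpCalls(mergePhpCalls(A, B2))), 24)

  ## property: random set triples
  set.seed(8)
  for (i in 1:50) {
    u <- paste0("x", 1:30)
    a <- sample(u, sample(0:20, 1))
    b <- sample(u, sample(1:20, 1))
    A <- data.frame(asv_id = a, strain_id = "s", identity = 98,
                    alignment_columns = 10L)
    B <- data.frame(asv_id = b, tau = 0.8)
    cc <- phpCalls(mergePhpCalls(A, B))
    expect_equal(nrow(cc), length(union(a, b)))
    expect_equal(sum(cc$evidence_clustering & cc$evidence_correlation),
                 length(intersect(a, b)))
  }
})

test_that("per-tissue PHP percentages use half-up rounding on detected ASVs", {
  ## 56 detected ASVs, 9 of them PHP -> 16.07%
  m <- matrix(0, 2, 60, dimnames = list(c("s1", "s2"), paste0("ASV", 1:60)))
  m[1, 1:56] <- 1
  m[2, 57:60] <- 1
  tbl <- AsvCountTable(m)
  meta <- data.frame(sample_id = c("s1", "s2"), species = "sp",
                     tissue = c("bulbil", "other"), replicate = 1)
  php <- mergePhpCalls(
    data.frame(asv_id = paste0("ASV", 1:9), strain_id = "s", identity = 99,
               alignment_columns = 10L),
    data.frame(asv_id = character(), tau = numeric()))
  s <- phpTissueSummary(php, tbl, meta)
  expect_equal(s$n_asvs_detected[s$tissue == "bulbil"], 56L)
  expect_equal(s$percent_php[s$tissue == "bulbil"], 16.07)
  expect_equal(s$percent_php[s$tissue == "other"], 0)

  ## all PHP -> 100.00
  php2 <- mergePhpCalls(
    data.frame(asv_id = paste0("ASV", 57:60), strain_id = "s", identity = 99,
               alignment_columns = 10L),
    data.frame(asv_id = character(), tau = numeric()))
  s2 <- phpTissueSummary(php2, tbl, meta)
  expect_equal(s2$percent_php[s2$tissue == "other"], 100)
})

test_that("dual-evidence discovery recovers planted producers on one dataset", {
  sim <- simulateDataset(simulationConfig(
    seed = 303, n_tissues = 4, replicates_per_tissue = 3, n_asvs = 80,
    n_producers = 8, n_modules = 4, module_size = 5, n_refs = 4,
    depth_log_mean = log(20000), seq_length_mean = 220,
    pool_fractions = c(0.4, 0.6, 0.8, 1), gradient = c(300, 200, 150, 100),
    tissue_names = paste0("t", 1:4)))
  calls <- phpDiscovery(sim$sequences, sim$refs, sim$counts, sim$metadata,
                        sim$metabolites)
  got <- phpCalls(calls)$asv_id
  tr <- sim$truth$producer_asv_ids
  expect_gte(length(intersect(got, tr)) / length(tr), 0.75)
  expect_gte(length(intersect(got, tr)) / length(got), 0.75)

  ## without a metabolite table the identity evidence alone is produced
  calls2 <- phpDiscovery(sim$sequences, sim$refs, sim$counts, sim$metadata,
                         metabolites = NULL)
  expect_true(all(phpCalls(calls2)$evidence_clustering))
  expect_false(any(phpCalls(calls2)$evidence_correlation))
})
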