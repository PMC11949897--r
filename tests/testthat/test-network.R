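test_that("category filtering applies a strict read threshold and conserves counts", {
  m <- rbind(c(25, 26, 0, 5), c(0, 0, 10, 5))
  tbl <- make_table(m)
  expect_warning(ft <- filterCategoryAsvs(tbl, c("s1", "s2"), min_reads = 25),
                 "dropped sample")
  expect_identical(asvIds(ft), "ASV2")          # 25 dropped, 26 kept
  expect_equal(sum(countsMatrix(ft)), 26)
  ft0 <- filterCategoryAsvs(tbl, c("s1", "s2"), min_reads = 0)
  expect_setequal(asvIds(ft0), paste0("ASV", 1:4))
  ## totals of kept ASVs are untouched
  expect_equal(colSums(countsMatrix(ft0)), colSums(m)[colSums(m) > 0],
               ignore_attr = TRUE)
  expect_error(filterCategoryAsvs(tbl, character()), "empty category")
  expect_error(filterCategoryAsvs(tbl, "nope"), "not in table")
})

test_that("the default backend finds proportional pairs and never self-edges", {
  set.seed(2)
  base <- rlnorm(12, 3, 1)
  m <- cbind(A = rpois(12, 50 * base), B = rpois(12, 30 * base),
             C = rpois(12, 40), D = rpois(12, 40))
  m[m == 0] <- 1
  tbl <- make_table(m, asvs = colnames(m))
  net <- inferNetwork(tbl, n_perm = 500, q_max = 0.05, seed = 1)
  ed <- networkEdges(net)
  expect_true(nrow(ed) >= 1)
  ab <- ed[(ed$from == "A" & ed$to == "B") | (ed$from == "B" & ed$to == "A"), ]
  expect_equal(nrow(ab), 1)
  expect_gt(ab$weight, 0)
  expect_equal(ab$q, min(ed$q))
  expect_false(any(ed$from == ed$to))
  expect_error(inferNetwork(tbl, method = "nope"),
               "registered backends.*clr-spearman-perm")
  expect_error(inferNetwork(make_table(m[1:4, ])), ">= 8 samples")
})

test_that("fast-greedy modules split disconnected cliques with Q = 0.5", {
  net <- make_net(rbind(clique_edges(paste0("a", 1:5)),
                        clique_edges(paste0("b", 1:5))))
  part <- fastGreedyModules(net)
  expect_equal(part$modularity_Q, 0.5, tolerance = 1e-12)
  mem <- part$membership
  expect_length(unique(mem[paste0("a", 1:5)]), 1)
  expect_length(unique(mem[paste0("b", 1:5)]), 1)
  expect_false(mem["a1"] == mem["b1"])
  ## single clique collapses to one module
  one <- fastGreedyModules(make_net(clique_edges(paste0("x", 1:6))))
  expect_length(unique(one$membership), 1)
  ## reported Q matches an oracle recomputation from the partition
  set.seed(4)
  g <- igraph::sample_gnp(25, 0.15)
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    edges <- data.frame(from = paste0("n", el[, 1]), to = paste0("n", el[, 2]),
                        weight = 0.3, q = 0.01)
    net2 <- make_net(edges, nodes = paste0("n", 1:25))
    p2 <- fastGreedyModules(net2)
    expect_equal(p2$modularity_Q, oracle_modularity(edges, p2$membership),
                 tolerance = 1e-12)
  }
})

test_that("Zi-Pi matches hand cases and the double-loop oracle", {
  ## all links inside the module: Pi = 0
  net <- make_net(clique_edges(paste0("a", 1:4)))
  part <- list(membership = setNames(rep(1L, 4), paste0("a", 1:4)))
  zp <- ziPi(net, part)
  expect_true(all(zp$pi == 0))
  expect_true(all(zp$zi == 0))          # identical within-module degrees

  ## even split across two modules: Pi = 0.5
  net2 <- make_net(data.frame(from = c("x", "x"), to = c("m1", "m2")))
  part2 <- list(membership = c(x = 1L, m1 = 1L, m2 = 2L))
  zp2 <- ziPi(net2, part2)
  expect_equal(zp2$pi[zp2$node == "x"], 0.5)

  ## two K4s joined by one bridge: bridge endpoints Pi = 0.375, all Zi = 0
  eK <- rbind(clique_edges(paste0("a", 1:4)), clique_edges(paste0("b", 1:4)),
              data.frame(from = "a1", to = "b1", weight = 0.5, q = 0.01))
  netK <- make_net(eK)
  partK <- list(membership = setNames(rep(1:2, each = 4),
                                      c(paste0("a", 1:4), paste0("b", 1:4))))
  zpK <- ziPi(netK, partK)
  expect_equal(zpK$pi[zpK$node == "a1"], 1 - (9 / 16 + 1 / 16))
  expect_true(all(zpK$zi == 0))
  ## isolated node
  netI <- make_net(data.frame(from = "p", to = "q"), nodes = c("p", "q", "r"))
  zpI <- ziPi(netI, list(membership = c(p = 1L, q = 1L, r = 2L)))
  expect_equal(zpI[zpI$node == "r", c("zi", "pi")],
               data.frame(zi = 0, pi = 0), ignore_attr = TRUE)

  ## oracle agreement on random graphs
  set.seed(12)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.08, 0.3))
    el <- igraph::as_edgelist(g)
    ids <- paste0("n", seq_len(n))
    edges <- if (nrow(el))
      data.frame(from = paste0("n", el[, 1]), to = paste0("n", el[, 2]),
                 weight = 0.5, q = 0.01, stringsAsFactors = FALSE)
    else data.frame(from = character(), to = character(), weight = numeric(),
                    q = numeric())
    net <- make_net(edges, nodes = ids)
    mem <- setNames(sample(1:3, n, replace = TRUE), ids)
    got <- ziPi(net, list(membership = mem))
    want <- oracle_zipi(edges, mem)
    expect_equal(got$zi, want$zi[match(got$node, want$node)],
                 tolerance = 1e-9)
    expect_equal(got$pi, want$pi[match(got$node, want$node)],
                 tolerance = 1e-9)
  }
})

test_that("role classification uses strict thresholds with peripheral boundaries", {
  df <- data.frame(node = paste0("n", 1:5), degree = 1,
                   zi = c(3.0, 1.0, 3.0, 2.5, 2.6),
                   pi = c(0.5, 0.7, 0.7, 0.62, 0.62))
  out <- classifyRoles(df)
  expect_equal(out$role, c("module_hub", "connector", "network_hub",
                           "peripheral", "peripheral"))
  ## partition: every node gets exactly one label
  set.seed(3)
  rnd <- data.frame(node = paste0("r", 1:200), degree = 1,
                    zi = rnorm(200, 0, 2), pi = runif(200))
  lab <- classifyRoles(rnd)$role
  expect_true(all(lab %in% c("network_hub", "module_hub", "connector",
                             "peripheral")))
  expect_length(lab, 200)
})

test_that("random-graph baselines recover clustering extremes and planted modularity", {
  tri <- make_net(clique_edges(c("a", "b", "c")))
  s <- randomGraphBaseline(tri, R = 5, seed = 1)
  expect_equal(s$avg_clustering, 1)
  star <- make_net(data.frame(from = "h", to = paste0("l", 1:5)))
  expect_equal(randomGraphBaseline(star, R = 5, seed = 1)$avg_clustering, 0)
  expect_error(randomGraphBaseline(
    make_net(data.frame(from = "a", to = "b")), R = 0), "R >= 1")

  ## modular planted graph: observed Q beats G(n, m) by > 2 sd
  edges <- do.call(rbind, lapply(0:3, function(k)
    clique_edges(paste0("m", k, "_", 1:6))))
  bridges <- data.frame(from = paste0("m", 0:2, "_1"),
                        to = paste0("m", 1:3, "_1"), weight = 0.5, q = 0.01)
  modnet <- make_net(rbind(edges, bridges))
  sm <- randomGraphBaseline(modnet, R = 60, seed = 2)
  expect_gt(sm$modularity_Q,
            sm$random_modularity_mean + 2 * sm$random_modularity_sd)
})

test_that("power-law fits are exact on exact power laws and undefined otherwise", {
  ## frequencies proportional to k^-2 for k = 1..5: build a degree sequence
  ## by fitting on a constructed network is awkward, so check the regression
  ## arithmetic through a network with three distinct degrees and compare
  ## against a direct lm on its degree table
  net <- make_net(rbind(clique_edges(paste0("c", 1:4)),
                        data.frame(from = "c1", to = paste0("t", 1:3),
                                   weight = 0.5, q = 0.01)))
  fit <- degreePowerlawFit(net)
  g <- asIgraph(net)
  tab <- table(igraph::degree(g))
  ref <- lm(log10(as.numeric(tab)) ~ log10(as.numeric(names(tab))))
  expect_equal(fit$gamma, -unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(fit$R2, summary(ref)$r.squared, tolerance = 1e-12)
  ## regular graph: single degree value -> undefined
  reg <- make_net(data.frame(from = "a", to = "b"))
  expect_false(degreePowerlawFit(reg)$defined)
})

test_that("exact log-log linear degree frequencies give R2 = 1 and the true exponent", {
  ## synthetic degree table k = 1..5 with f = 240 / k^2, checked through the
  ## same OLS the package applies
  k <- 1:5
  f <- 240 / k^2
  fit <- lm(log10(f) ~ log10(k))
  expect_equal(summary(fit)$r.squared, 1)
  expect_equal(unname(-coef(fit)[2]), 2)
  ## R2 is invariant to rescaling all frequencies
  fit2 <- lm(log10(10 * f) ~ log10(k))
  expect_equal(summary(fit2)$r.squared, summary(fit)$r.squared)
})

test_that("facilitator ranking flags producer-network genera and cautions others", {
  mk <- function(ids, php) make_net(clique_edges(ids), php = php)
  ids_b <- paste0("n", 1:20)
  php_b <- paste0("n", c(1, 6, 11, 16, 20))
  net_b <- mk(ids_b, php = php_b)
  part_b <- list(membership = setNames(rep(1:5, each = 4), ids_b))
  ids_c <- paste0("c", 1:8)
  net_c <- mk(ids_c, php = "c1")
  part_c <- list(membership = setNames(rep(1:2, each = 4), ids_c))
  tax <- data.frame(
    asv_id = c(ids_b, ids_c),
    genus = c(rep(c("Penicillium", "Trichoderma", "Rare", "Other"), 5),
              rep("Phaeosphaeria", 8)),
    stringsAsFactors = FALSE)
  ## non-PHP Penicillium members n5, n9, n13, n17 sit in 4 of the 5
  ## PHP-containing modules of the producer network; Phaeosphaeria only in
  ## the non-producer network
  fac <- facilitatorRanking(list(B = net_b, C = net_c),
                            list(B = part_b, C = part_c),
                            php_ids = c(php_b, "c1"),
                            taxonomy = tax, flag_min = 4,
                            producer_networks = "B")
  pen <- fac[fac$genus == "Penicillium", ]
  expect_true(pen$flagged)
  expect_gte(pen$n_php_modules, 4)
  pha <- fac[fac$genus == "Phaeosphaeria", ]
  expect_true(pha$cautioned)
  expect_false(pha$flagged)

  ## no PHP calls anywhere: empty report
  fac0 <- facilitatorRanking(list(B = net_b), list(B = part_b),
                             php_ids = character(), taxonomy = tax)
  expect_equal(nrow(fac0), 0)
})

test_that("graph exports round-trip nodes, edges and attributes", {
  net <- make_net(rbind(clique_edges(paste0("a", 1:4)),
                        data.frame(from = "a1", to = "b1", weight = -0.4,
                                   q = 0.02)))
  part <- fastGreedyModules(net)
  roles <- classifyRoles(ziPi(net, part))
  d <- withr::local_tempdir()

  gml <- file.path(d, "net.graphml")
  exportGraph(net, gml, "graphml", partition = part, roles = roles)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 5)
  expect_equal(igraph::ecount(back), 7)
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(key(back), key(asIgraph(net)))
  expect_true(all(c("name", "genus", "php", "degree", "module", "zi", "pi",
                    "role") %in% igraph::vertex_attr_names(back)))

  tsv <- file.path(d, "net.tsv")
  exportGraph(net, tsv, "tsv")
  ed <- read.delim(tsv)
  expect_equal(nrow(ed), 7)
  expect_equal(sort(unique(ed$sign)), c(-1, 1))

  gexf <- file.path(d, "net.gexf")
  exportGraph(net, gexf, "gexf", partition = part, roles = roles)
  if (requireNamespace("xml2", quietly = TRUE)) {
    doc <- xml2::read_xml(gexf)
    ns <- xml2::xml_ns_strip(doc)
    expect_equal(length(xml2::xml_find_all(doc, "//node")), 5)
    expect_equal(length(xml2::xml_find_all(doc, "//edge")), 7)
  }

  ## empty network still exports a valid file
  empty <- new("CoocNetwork",
               nodes = data.frame(asv_id = character(), genus = character(),
                                  php = logical()),
               edges = data.frame(from = character(), to = character(),
                                  weight = numeric(), q = numeric()),
               category = "empty")
  f0 <- file.path(d, "empty.graphml")
  exportGraph(empty, f0, "graphml")
  expect_equal(igraph::vcount(igraph::read_graph(f0, format = "graphml")), 0)
  expect_error(exportGraph(net, file.path(d, "x"), "dot"), "unknown format")
})

test_that("planted co-abundance modules are recovered on the homogeneous benchmark", {
  sim <- simulateDataset(moduleBenchmarkConfig(seed = 105))
  ft <- filterCategoryAsvs(sim$counts, sampleIds(sim$counts), min_reads = 25)
  net <- inferNetwork(ft, n_perm = 1000, q_max = 0.05, seed = 1)
  part <- fastGreedyModules(net)
  tr <- sim$truth$module_assignment
  common <- intersect(names(part$membership), names(tr)[!is.na(tr)])
  ari <- mclust::adjustedRandIndex(part$membership[common], tr[common])
  expect_gte(ari, 0.6)
})
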