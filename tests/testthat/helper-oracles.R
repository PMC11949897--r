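## Independent oracles: deliberately naive re-implementations used only to
## check the package's fast paths.

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) return(NA_real_)
  (C - D) / den
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

oracle_nodf <- function(m) {
  score_pairs <- function(mm) {
    tot <- rowSums(mm)
    out <- c()
    for (i in seq_len(nrow(mm) - 1)) for (j in (i + 1):nrow(mm)) {
      if (tot[i] == tot[j]) { out <- c(out, 0); next }
      hi <- if (tot[i] > tot[j]) i else j
      lo <- if (tot[i] > tot[j]) j else i
      ov <- sum(mm[hi, ] == 1 & mm[lo, ] == 1)
      out <- c(out, if (tot[lo] == 0) 0 else 100 * ov / tot[lo])
    }
    out
  }
  mean(c(score_pairs(m), score_pairs(t(m))))
}

## per-node double loop over the edge list
oracle_zipi <- function(edges, membership) {
  ids <- names(membership)
  deg_to <- function(v, mod) {
    n <- 0
    if (nrow(edges)) for (e in seq_len(nrow(edges))) {
      if (edges$from[e] == v && membership[edges$to[e]] == mod) n <- n + 1
      if (edges$to[e] == v && membership[edges$from[e]] == mod) n <- n + 1
    }
    n
  }
  mods <- unique(membership)
  kin <- vapply(ids, function(v) deg_to(v, membership[v]), 0)
  k <- vapply(ids, function(v) sum(vapply(mods, function(mo) deg_to(v, mo), 0)), 0)
  zi <- numeric(length(ids)); pi_ <- numeric(length(ids))
  for (i in seq_along(ids)) {
    peers <- which(membership == membership[ids[i]])
    mu <- mean(kin[peers])
    sdev <- sqrt(mean((kin[peers] - mu)^2))
    zi[i] <- if (k[i] == 0 || sdev == 0) 0 else (kin[i] - mu) / sdev
    pi_[i] <- if (k[i] > 0)
      1 - sum(vapply(mods, function(mo) (deg_to(ids[i], mo) / k[i])^2, 0))
    else 0
  }
  data.frame(node = ids, zi = zi, pi = pi_, stringsAsFactors = FALSE)
}

oracle_modularity <- function(edges, membership) {
  m <- nrow(edges)
  if (m == 0) return(NA_real_)
  deg <- table(factor(c(edges$from, edges$to), levels = names(membership)))
  q <- 0
  for (mo in unique(membership)) {
    inside <- sum(membership[edges$from] == mo & membership[edges$to] == mo)
    dmod <- sum(deg[names(membership)[membership == mo]])
    q <- q + inside / m - (dmod / (2 * m))^2
  }
  q
}

## full Gotoh DP for the fit (semi-global) alignment: pattern q aligned end
## to end, subject r overhangs free; gap of length L costs open + L * ext
oracle_fit_score <- function(q, r, match = 1, mismatch = -1, open = 2,
                             ext = 1) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends with qc[i] ~ rc[j]
  P <- matrix(NEG, n + 1, m + 1)   # ends with qc[i] ~ gap
  Q <- matrix(NEG, n + 1, m + 1)   # ends with gap ~ rc[j]
  M[1, ] <- 0                      # free leading subject skip
  for (i in 2:(n + 1)) {
    P[i, 1] <- max(M[i - 1, 1] - open - ext, P[i - 1, 1] - ext)
    for (j in 2:(m + 1)) {
      s <- if (qc[i - 1] == rc[j - 1]) match else mismatch
      M[i, j] <- s + max(M[i - 1, j - 1], P[i - 1, j - 1], Q[i - 1, j - 1],
                         if (i == 2) 0 else NEG)
      P[i, j] <- max(M[i - 1, j] - open - ext, P[i - 1, j] - ext,
                     Q[i - 1, j] - open - ext)
      Q[i, j] <- max(M[i, j - 1] - open - ext, Q[i, j - 1] - ext)
    }
  }
  max(M[n + 1, ], P[n + 1, ])      # free trailing subject skip
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

## small count-table fixture
make_table <- function(m, samples = NULL, asvs = NULL) {
  m <- as.matrix(m)
  rownames(m) <- if (is.null(samples)) paste0("s", seq_len(nrow(m))) else samples
  colnames(m) <- if (is.null(asvs)) paste0("ASV", seq_len(ncol(m))) else asvs
  AsvCountTable(m)
}

## minimal CoocNetwork from an edge list
make_net <- function(edges, nodes = NULL, php = character()) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  if (is.null(edges$weight)) edges$weight <- rep(0.5, nrow(edges))
  if (is.null(edges$q)) edges$q <- rep(0.01, nrow(edges))
  new("CoocNetwork",
      nodes = data.frame(asv_id = nodes, genus = "", php = nodes %in% php,
                         stringsAsFactors = FALSE),
      edges = edges, category = "test")
}

clique_edges <- function(ids) {
  pr <- t(combn(ids, 2))
  data.frame(from = pr[, 1], to = pr[, 2], weight = 0.5, q = 0.01,
             stringsAsFactors = FALSE)
}
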