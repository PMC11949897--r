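#' Rarefy a count table to fixed depth
#'
#' Each retained sample is subsampled without replacement to exactly
#' \code{depth} reads (a multivariate hypergeometric draw); samples whose
#' total is below the depth are dropped with a warning, mirroring rarefaction
#' to the lowest observed library size.
#'
#' @param table an \linkS4class{AsvCountTable}.
#' @param depth target reads per sample (>= 1).
#' @param seed RNG seed; the result is deterministic given the seed.
#' @return rarefied \linkS4class{AsvCountTable}.
#' @export
rarefyCounts <- function(table, depth, seed = 1) {
  stopifnot(is(table, "AsvCountTable"), depth >= 1)
  m <- countsMatrix(table)
  tot <- rowSums(m)
  keep <- tot >= depth
  if (!any(keep)) stop("all samples have fewer than ", depth, " reads")
  if (any(!keep))
    warning(sprintf("dropped %d sample(s) below depth %d: %s", sum(!keep),
                    depth, paste(rownames(m)[!keep], collapse = ", ")))
  m <- m[keep, , drop = FALSE]
  set.seed(seed)
  out <- t(apply(m, 1, function(x) {
    if (sum(x) == depth) return(x)
    picked <- sample.int(sum(x), depth)
    hits <- findInterval(picked - 1, cumsum(x)) + 1
    tabulate(hits, nbins = length(x))
  }))
  dimnames(out) <- dimnames(m)
  AsvCountTable(out)
}

#' Alpha diversity per sample
#'
#' Observed richness (count of nonzero ASVs) and Shannon entropy in nats
#' (natural-log base, the common ecology-package default) computed on
#' per-sample proportions.
#'
#' @param table an \linkS4class{AsvCountTable}.
#' @return data.frame with sample_id, observed, shannon.
#' @export
alphaDiversity <- function(table) {
  stopifnot(is(table, "AsvCountTable"))
  m <- countsMatrix(table)
  sh <- apply(m, 1, function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p))
  })
  data.frame(sample_id = rownames(m),
             observed = as.integer(rowSums(m > 0)),
             shannon = as.numeric(sh), stringsAsFactors = FALSE)
}

#' Rarefaction curve (mean observed richness per depth)
#'
#' @param table an \linkS4class{AsvCountTable}.
#' @param depths non-empty increasing grid of depths.
#' @param reps subsamples averaged per depth.
#' @param seed RNG seed.
#' @return matrix samples x depths of mean observed richness; NA where a
#'   sample's total is below the depth.
#' @export
rarefactionCurve <- function(table, depths, reps = 20, seed = 1) {
  stopifnot(is(table, "AsvCountTable"))
  if (!length(depths)) stop("empty depth grid")
  m <- countsMatrix(table)
  set.seed(seed)
  out <- matrix(NA_real_, nrow(m), length(depths),
                dimnames = list(rownames(m), as.character(depths)))
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    tot <- sum(x)
    cs <- cumsum(x)
    for (j in seq_along(depths)) {
      d <- depths[j]
      if (d > tot) next
      if (d == tot) { out[i, j] <- sum(x > 0); next }
      obs <- replicate(reps, {
        hits <- findInterval(sample.int(tot, d) - 1, cs) + 1
        length(unique(hits))
      })
      out[i, j] <- mean(obs)
    }
  }
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), computed on per-sample
#' percentage-normalized rows by default (raw-read normalization to
#' percentage per sample).
#'
#' @param table an \linkS4class{AsvCountTable}.
#' @param normalize normalize rows to percentages first.
#' @return a \code{dist} object with sample labels.
#' @export
brayCurtisMatrix <- function(table, normalize = TRUE) {
  stopifnot(is(table, "AsvCountTable"))
  m <- countsMatrix(table)
  if (normalize) m <- 100 * m / rowSums(m)
  vegan::vegdist(m, method = "bray")
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS (monotone regression of configuration distances on
#' dissimilarities, alternating with configuration updates), best of
#' \code{n_starts} random starts.
#'
#' @param d a \code{dist} of dissimilarities.
#' @param k embedding dimension.
#' @param n_starts random starts; the lowest-stress solution is returned.
#' @param max_iter iterations per start.
#' @param seed RNG seed.
#' @return list of class \code{OrdinationResult} with coordinates (samples x
#'   k), stress (stress-1, in [0, 1]), n_starts and converged flag.
#' @export
nmdsOrdination <- function(d, k = 2, n_starts = 20, max_iter = 200, seed = 1) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < k + 1) stop("need at least k + 1 points")
  if (all(d == 0)) stop("degenerate distance matrix: all zero")
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts,
                        maxit = max_iter, trace = 0, autotransform = FALSE,
                        wascores = FALSE)
  res <- list(coordinates = fit$points, stress = fit$stress,
              n_starts = n_starts, converged = isTRUE(fit$converged) ||
                (is.numeric(fit$converged) && fit$converged > 0))
  class(res) <- "OrdinationResult"
  res
}

#' Kruskal stress-1 of a configuration
#'
#' Recomputes stress-1 from scratch for given coordinates against the input
#' dissimilarities via pool-adjacent-violators monotone regression.
#'
#' @param d a \code{dist} of dissimilarities.
#' @param coordinates configuration matrix (points x k).
#' @return stress-1 value.
#' @export
stress1 <- function(d, coordinates) {
  dd <- as.vector(stats::as.dist(d))
  cd <- as.vector(stats::dist(coordinates))
  o <- order(dd)
  fitted <- stats::isoreg(cd[o])$yf
  sqrt(sum((cd[o] - fitted)^2) / sum(cd[o]^2))
}

#' PERMANOVA from a distance matrix
#'
#' Pseudo-F from the Gower-centered partition of squared dissimilarities:
#' SS_total = sum_{i<j} d_ij^2 / N, SS_within summed per group analogously,
#' F = (SS_between/(a-1)) / (SS_within/(N-a)). The p value permutes group
#' labels and uses the add-one convention p = (1 + #{F* >= F}) / (n_perm + 1).
#'
#' @param d a \code{dist} over samples.
#' @param groups factor (or vector) of group labels, >= 2 groups with >= 2
#'   members each.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return list of class \code{PermanovaResult}: pseudo_F, p, n_perm,
#'   df_between, df_within.
#' @export
permanovaTest <- function(d, groups, n_perm = 999, seed = 1) {
  d <- stats::as.dist(d)
  groups <- factor(groups)
  N <- attr(d, "Size")
  if (length(groups) != N) stop("groups length must match distance size")
  a <- nlevels(groups)
  if (a < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 members")
  D2 <- as.matrix(d)^2
  ss_total <- sum(D2) / (2 * N)
  lev <- levels(groups)
  ng <- as.vector(table(groups))
  f_stat <- function(gidx_list) {
    ssw <- 0
    for (g in seq_along(gidx_list)) {
      idx <- gidx_list[[g]]
      ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
    }
    ((ss_total - ssw) / (a - 1)) / (ssw / (N - a))
  }
  obs <- f_stat(split(seq_len(N), groups))

  set.seed(seed)
  ## batched permutations: per-group indicator matrices, quadratic forms by BLAS
  perm_labels <- replicate(n_perm, sample.int(N))
  ssw_perm <- numeric(n_perm)
  gint <- as.integer(groups)
  for (g in seq_len(a)) {
    X <- matrix(0, N, n_perm)
    sel <- which(gint == g)
    for (b in seq_len(n_perm)) X[perm_labels[sel, b], b] <- 1
    ssw_perm <- ssw_perm + colSums(X * (D2 %*% X)) / (2 * ng[g])
  }
  f_perm <- ((ss_total - ssw_perm) / (a - 1)) / (ssw_perm / (N - a))
  p <- (1 + sum(f_perm >= obs - 1e-12)) / (n_perm + 1)
  res <- list(pseudo_F = obs, p = p, n_perm = n_perm,
              df_between = a - 1, df_within = N - a)
  class(res) <- "PermanovaResult"
  res
}

#' Nonparametric group-difference tests for a per-sample metric
#'
#' Two groups: Wilcoxon rank-sum (exact enumeration when both groups have
#' <= 8 tie-free observations, normal approximation with tie correction
#' otherwise). More groups: Kruskal-Wallis omnibus with tie correction
#' followed by Dunn pairwise z tests on mean ranks, Holm-Bonferroni adjusted.
#'
#' @param values numeric per-sample metric.
#' @param groups group labels, every group non-empty.
#' @param alternative alternative hypothesis for the two-group path.
#' @return list: for two groups, method/statistic/p; otherwise
#'   omnibus (H, df, p) and pairwise data.frame (group1, group2, z, p,
#'   p_adj).
#' @export
groupDifferenceTests <- function(values, groups, alternative = "two.sided") {
  groups <- factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2)
    stop("need >= 2 non-empty groups")
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) == 2) {
    x <- values[groups == levels(groups)[1]]
    y <- values[groups == levels(groups)[2]]
    tiefree <- !anyDuplicated(c(x, y))
    use_exact <- length(x) <= 8 && length(y) <= 8 && tiefree
    wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact,
                                       correct = FALSE,
                                       alternative = alternative))
    return(list(method = "wilcoxon_rank_sum", statistic = unname(wt$statistic),
                p = wt$p.value, exact = use_exact))
  }
  all_tied <- length(unique(values)) == 1
  kw <- if (all_tied) list(statistic = c(H = 0),
                           parameter = c(df = nlevels(groups) - 1), p.value = 1)
    else kruskal.test(values, groups)
  N <- length(values)
  rk <- rank(values)
  tie <- table(rk)
  tie_term <- sum(tie^3 - tie)
  s2 <- (N * (N + 1) / 12) - tie_term / (12 * (N - 1))
  mean_rank <- tapply(rk, groups, mean)
  ns <- table(groups)
  lev <- levels(groups)
  pair <- utils::combn(lev, 2)
  z <- apply(pair, 2, function(pr) {
    if (s2 <= 0) return(0)   # every observation tied: no rank differences
    (mean_rank[pr[1]] - mean_rank[pr[2]]) /
      sqrt(s2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
  })
  p <- 2 * pnorm(-abs(z))
  pw <- data.frame(group1 = pair[1, ], group2 = pair[2, ], z = as.numeric(z),
                   p = as.numeric(p),
                   p_adj = p.adjust(as.numeric(p), method = "holm"),
                   stringsAsFactors = FALSE)
  list(method = "kruskal_dunn_holm",
       omnibus = list(H = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       pairwise = pw)
}

#' Holm-Bonferroni step-down adjustment
#' @param p vector of raw p values in [0, 1].
#' @return adjusted p values.
#' @export
holmAdjust <- function(p) p.adjust(p, method = "holm")
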