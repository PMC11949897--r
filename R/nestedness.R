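#' Build the tissue x ASV presence/absence matrix
#'
#' Entry 1 iff the ASV has a nonzero count in at least one sample of the
#' tissue; ASVs absent from every tissue are dropped.
#'
#' @param table an \linkS4class{AsvCountTable}.
#' @param meta sample metadata.
#' @param level metadata column defining the rows (default tissue).
#' @return a \linkS4class{PresenceMatrix}.
#' @export
buildPresenceMatrix <- function(table, meta, level = "tissue") {
  stopifnot(is(table, "AsvCountTable"))
  m <- countsMatrix(table)
  grp <- meta[[level]][match(rownames(m), meta$sample_id)]
  if (any(is.na(grp))) stop("sample(s) without metadata")
  gl <- unique(grp)
  pm <- t(vapply(gl, function(g)
    as.numeric(colSums(m[grp == g, , drop = FALSE] > 0) > 0),
    numeric(ncol(m))))
  dimnames(pm) <- list(gl, colnames(m))
  pm <- pm[, colSums(pm) > 0, drop = FALSE]
  PresenceMatrix(pm)
}

.as_binary_matrix <- function(x) {
  m <- if (is(x, "PresenceMatrix")) x@m else as.matrix(x)
  stopifnot(all(m %in% c(0, 1)))
  m
}

.nodf_pairs <- function(m) {
  ## paired scores over all pairs along one margin (rows of m):
  ## score = 100 * overlap / smaller total when totals strictly differ, else 0
  tot <- rowSums(m)
  ov <- m %*% t(m)
  mn <- outer(tot, tot, pmin)
  sc <- matrix(0, nrow(m), nrow(m))
  ok <- outer(tot, tot, "!=") & mn > 0
  sc[ok] <- 100 * ov[ok] / mn[ok]
  sc[upper.tri(sc)]
}

#' NODF nestedness metric
#'
#' Nestedness based on Overlap and Decreasing Fill: for every row pair and
#' every column pair whose marginal totals strictly differ, the paired score
#' is 100 x overlap / smaller total (pairs with equal totals score 0, per
#' the decreasing-fill requirement); NODF is the mean over all row and
#' column pairs. Ranges from 0 (no nesting) to 100 (perfect nesting).
#'
#' @param x a \linkS4class{PresenceMatrix} or binary matrix with >= 2 rows
#'   and >= 2 columns.
#' @return NODF in [0, 100].
#' @export
nodf <- function(x) {
  m <- .as_binary_matrix(x)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 rows and >= 2 columns")
  mean(c(.nodf_pairs(m), .nodf_pairs(t(m))))
}

.row_worst_term <- function(r, C) {
  ## the row fully right-packed: maximal squared relative displacement
  if (r == 0 || r == C) return(0)
  wp <- (C - r + seq_len(r))
  wp <- wp[wp > r]
  wa <- seq_len(min(r, C - r))
  sum(((wp - r) / (C - r))^2) + sum(((r - wa + 1) / r)^2)
}

#' Packed-matrix nestedness temperature
#'
#' Columns are packed by decreasing totals; in a perfectly nested matrix
#' each row's presences then occupy its leftmost columns. Unexpected cells
#' (absences left of the row boundary at the row total, presences right of
#' it) contribute their squared relative displacement. Within blocks of
#' tied column totals a row's presences have no distinguished positions, so
#' the contribution is taken in expectation over a uniform placement of the
#' row's presences inside each tied block, which makes the statistic
#' invariant under row and column permutation of the input. The sum is
#' normalized by the maximally disordered (fully right-packed) arrangement
#' of the same row totals, giving a temperature in [0, 100]: 0 for a
#' perfectly nested matrix, larger the more disordered; all-ones and
#' all-zeros matrices are 0 by convention. This is a documented in-house
#' variant of the classic matrix-temperature construction; its contract is
#' the behaviour (range, zero at perfect nestedness, growth under
#' de-nesting moves), not numeric equality with legacy programs.
#'
#' @param x a \linkS4class{PresenceMatrix} or binary matrix.
#' @return temperature in [0, 100].
#' @export
nestednessTemperature <- function(x) {
  m <- .as_binary_matrix(x)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 rows and >= 2 columns")
  if (all(m == 1) || all(m == 0)) return(0)
  C <- ncol(m)
  ct <- colSums(m)
  ord <- order(ct, decreasing = TRUE)
  m <- m[, ord, drop = FALSE]
  ct <- ct[ord]
  bid <- match(ct, unique(ct))              # tied-total block per column
  bsize <- tabulate(bid)[bid]
  pos <- seq_len(C)
  obs <- 0; worst <- 0
  for (i in seq_len(nrow(m))) {
    r <- sum(m[i, ])
    if (r == 0 || r == C) next
    ## occupancy probability of each column under uniform placement of the
    ## row's presences within its tied block
    pr <- (tapply(m[i, ], bid, sum)[bid] / bsize)
    right <- pos > r
    obs <- obs + sum(pr[right] * ((pos[right] - r) / (C - r))^2) +
      sum((1 - pr[!right]) * ((r - pos[!right] + 1) / r)^2)
    worst <- worst + .row_worst_term(r, C)
  }
  if (worst == 0) return(0)
  100 * obs / worst
}

#' Occurrence-preserving null model
#'
#' Each column's presences are reassigned to rows uniformly at random
#' without replacement: per-ASV occurrence counts (column totals) are
#' preserved, row totals are free. Returns the chosen statistic for each
#' simulated matrix.
#'
#' @param x a \linkS4class{PresenceMatrix} or binary matrix.
#' @param n_sims number of simulations.
#' @param seed RNG seed.
#' @param statistic "temperature" (default) or "nodf".
#' @return numeric vector of length n_sims.
#' @export
nullModelOccurrence <- function(x, n_sims = 1000, seed = 1,
                                statistic = c("temperature", "nodf")) {
  statistic <- match.arg(statistic)
  m <- .as_binary_matrix(x)
  ct <- colSums(m)
  if (any(ct > nrow(m))) stop("column total exceeds the number of rows")
  stat_fun <- if (statistic == "temperature") nestednessTemperature else nodf
  R <- nrow(m)
  set.seed(seed)
  vapply(seq_len(n_sims), function(b) {
    sim <- matrix(0, R, ncol(m), dimnames = dimnames(m))
    for (j in seq_len(ncol(m)))
      if (ct[j] > 0) sim[sample.int(R, ct[j]), j] <- 1
    stat_fun(sim)
  }, 0)
}

#' One-sided nestedness significance
#'
#' Lower temperature means more nested; p = (1 + #{null <= observed}) /
#' (n_sims + 1).
#'
#' @param observed observed temperature.
#' @param null_temperatures null-model temperature sample.
#' @return one-sided p value in (0, 1].
#' @export
nestednessSignificance <- function(observed, null_temperatures) {
  if (!length(null_temperatures)) stop("empty null sample")
  (1 + sum(null_temperatures <= observed)) / (length(null_temperatures) + 1)
}

#' Full nestedness analysis
#'
#' Builds the presence matrix, computes NODF, temperature and fill, runs the
#' occurrence-preserving null model and reports the one-sided p value.
#'
#' @param table an \linkS4class{AsvCountTable}.
#' @param meta sample metadata.
#' @param n_sims null-model simulations.
#' @param seed RNG seed.
#' @param level metadata column defining matrix rows.
#' @return a \linkS4class{NestednessResult}; the presence matrix is attached
#'   as attribute \code{presence}.
#' @export
nestednessAnalysis <- function(table, meta, n_sims = 1000, seed = 1,
                               level = "tissue") {
  pm <- buildPresenceMatrix(table, meta, level = level)
  temp <- nestednessTemperature(pm)
  nulls <- nullModelOccurrence(pm, n_sims = n_sims, seed = seed)
  res <- new("NestednessResult", nodf = nodf(pm), temperature = temp,
             fill = matrixFill(pm), nullTemperatures = nulls,
             pValue = nestednessSignificance(temp, nulls))
  attr(res, "presence") <- pm
  res
}
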