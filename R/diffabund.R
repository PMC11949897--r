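#' Median-of-ratios size factors
#'
#' Reference profile = per-ASV geometric mean over samples (ASVs with any
#' zero excluded); a sample's size factor is the median over ASVs of
#' count / reference.
#'
#' @param table an \linkS4class{AsvCountTable}.
#' @param pseudo_reference when no ASV is nonzero in every sample, fall back
#'   to a +0.5 pseudocount reference over all ASVs instead of erroring
#'   (useful for sparse cross-species tables).
#' @return named positive numeric vector, one per sample.
#' @export
sizeFactorsMedianRatios <- function(table, pseudo_reference = FALSE) {
  stopifnot(is(table, "AsvCountTable"))
  m <- countsMatrix(table)
  allpos <- colSums(m == 0) == 0
  if (!any(allpos)) {
    if (!pseudo_reference)
      stop("no ASV is nonzero in all samples; rerun with ",
           "pseudo_reference = TRUE to use a +0.5 pseudocount reference")
    m <- m + 0.5
    allpos <- rep(TRUE, ncol(m))
  }
  sub <- m[, allpos, drop = FALSE]
  ref <- exp(colMeans(log(sub)))
  sf <- apply(sub, 1, function(x) median(x / ref))
  if (any(sf <= 0)) stop("non-positive size factor")
  sf
}

#' Method-of-moments NB dispersion per ASV
#'
#' On size-factor-normalized counts, alpha = (s^2 - m) / m^2 is estimated
#' within each group and pooled with (n_g - 1) weights, floored at
#' \code{floor}.
#'
#' @param table an \linkS4class{AsvCountTable}.
#' @param size_factors per-sample size factors.
#' @param groups two-level grouping of samples.
#' @param floor dispersion floor.
#' @return named numeric vector of per-ASV dispersions (>= floor).
#' @export
estimateDispersion <- function(table, size_factors, groups, floor = 1e-8) {
  stopifnot(is(table, "AsvCountTable"))
  m <- countsMatrix(table)
  k <- m / size_factors
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop("need >= 2 samples per group")
  alpha <- vapply(seq_len(ncol(k)), function(j) {
    est <- w <- numeric(0)
    for (g in levels(groups)) {
      x <- k[groups == g, j]
      mu <- mean(x)
      if (mu <= 0) next
      est <- c(est, (var(x) - mu) / mu^2)
      w <- c(w, length(x) - 1)
    }
    if (!length(est)) return(floor)
    max(floor, sum(est * w) / sum(w))
  }, 0)
  names(alpha) <- colnames(m)
  alpha
}

#' Negative-binomial Wald test per ASV
#'
#' Fits, per ASV, a log-link NB GLM with a two-level group indicator and
#' log size factors as offset, at fixed per-ASV dispersion (iteratively
#' reweighted least squares); the Wald statistic is the group coefficient
#' over its standard error with dispersion fixed at 1, and the p value comes
#' from the standard normal. Positive log2 fold change means higher
#' abundance in the second group level. When one group is all zeros, the
#' ASV is refit with a +0.5 pseudocount and flagged.
#'
#' @param table an \linkS4class{AsvCountTable}.
#' @param groups factor with exactly two levels, >= 2 samples each.
#' @param size_factors per-sample size factors.
#' @param dispersions per-ASV dispersions.
#' @param max_iter IRLS iteration cap; non-converged fits are flagged and
#'   their p set to NA.
#' @return data.frame, one row per ASV: asv_id, base_mean, log2fc, se, wald,
#'   p, pseudo, converged.
#' @export
nbWaldTest <- function(table, groups, size_factors, dispersions,
                       max_iter = 100) {
  stopifnot(is(table, "AsvCountTable"))
  m <- countsMatrix(table)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("need >= 2 samples per group")
  off <- log(size_factors)
  norm <- m / size_factors
  out <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    y <- m[, j]
    pseudo <- FALSE
    if (any(tapply(y, groups, max) == 0)) { y <- y + 0.5; pseudo <- TRUE }
    rec <- data.frame(asv_id = colnames(m)[j], base_mean = mean(norm[, j]),
                      log2fc = NA_real_, se = NA_real_, wald = NA_real_,
                      p = NA_real_, pseudo = pseudo, converged = FALSE,
                      stringsAsFactors = FALSE)
    if (max(y) > 0) {
      theta <- min(1 / max(dispersions[j], 1e-8), 1e8)
      fit <- tryCatch(suppressWarnings(
        glm(y ~ groups + offset(off),
            family = MASS::negative.binomial(theta = theta, link = "log"),
            control = glm.control(maxit = max_iter))), error = function(e) NULL)
      if (!is.null(fit)) {
        co <- suppressWarnings(summary(fit, dispersion = 1)$coefficients)
        if (nrow(co) == 2 && is.finite(co[2, 2]) && co[2, 2] > 0) {
          rec$converged <- fit$converged
          rec$log2fc <- co[2, 1] / log(2)
          rec$se <- co[2, 2] / log(2)
          rec$wald <- co[2, 1] / co[2, 2]
          rec$p <- if (fit$converged) 2 * pnorm(-abs(rec$wald)) else NA_real_
        }
      }
    }
    out[[j]] <- rec
  }
  do.call(rbind, out)
}

#' Benjamini-Hochberg step-up adjustment
#' @param p vector of raw p values in [0, 1].
#' @return BH-adjusted p values (monotone in the sorted order).
#' @export
bhAdjust <- function(p) p.adjust(p, method = "BH")

#' Differential abundance between two sample groups
#'
#' Composes median-of-ratios size factors, method-of-moments dispersion, the
#' NB Wald test and BH adjustment; an ASV is significant iff
#' padj < \code{padj_max} and |log2fc| > \code{lfc_min}, reported per
#' direction (positive log2fc = more abundant in the second group level).
#'
#' @param table an \linkS4class{AsvCountTable} restricted to the contrasted
#'   samples.
#' @param groups factor with exactly two levels over the table's samples.
#' @param padj_max adjusted-p threshold (strict <).
#' @param lfc_min |log2fc| threshold (strict >).
#' @param pseudo_reference passed to \code{\link{sizeFactorsMedianRatios}}.
#' @return list: records (data.frame with padj and significant columns),
#'   n_up, n_down, direction (text note on the sign convention).
#' @export
differentialAbundance <- function(table, groups, padj_max = 0.01,
                                  lfc_min = 2, pseudo_reference = FALSE) {
  groups <- factor(groups)
  sf <- sizeFactorsMedianRatios(table, pseudo_reference = pseudo_reference)
  disp <- estimateDispersion(table, sf, groups)
  rec <- nbWaldTest(table, groups, sf, disp)
  rec$padj <- NA_real_
  ok <- !is.na(rec$p)
  rec$padj[ok] <- bhAdjust(rec$p[ok])
  rec$significant <- !is.na(rec$padj) & rec$padj < padj_max &
    abs(rec$log2fc) > lfc_min
  list(records = rec,
       n_up = sum(rec$significant & rec$log2fc > 0),
       n_down = sum(rec$significant & rec$log2fc < 0),
       direction = sprintf("positive log2fc = more abundant in '%s'",
                           levels(groups)[2]))
}
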