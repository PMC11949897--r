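.iupac_matrix_cache <- new.env(parent = emptyenv())

#' Binary IUPAC scoring matrix
#'
#' Substitution matrix over the 15 IUPAC DNA codes in which two codes score
#' \code{match} iff their base sets intersect, else \code{mismatch}.
#'
#' @param match,mismatch scores.
#' @return square numeric matrix.
#' @export
iupacScoringMatrix <- function(match = 1, mismatch = -1) {
  key <- paste(match, mismatch)
  if (!is.null(.iupac_matrix_cache[[key]])) return(.iupac_matrix_cache[[key]])
  map <- Biostrings::IUPAC_CODE_MAP
  codes <- names(map)
  sets <- strsplit(map, "")
  m <- matrix(mismatch, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (i in seq_along(codes)) for (j in seq_along(codes))
    if (length(intersect(sets[[i]], sets[[j]]))) m[i, j] <- match
  .iupac_matrix_cache[[key]] <- m
  m
}

.iupac_match <- function(a, b) {
  m <- iupacScoringMatrix()
  ok <- a %in% rownames(m) & b %in% rownames(m)
  out <- logical(length(a))
  out[ok] <- m[cbind(a[ok], b[ok])] > 0
  out
}

.identity_from_alignment <- function(pat, sub) {
  ## pat/sub: equal-length aligned strings (terminal gaps already trimmed by
  ## the overlap alignment); internal gaps "-" count as columns, not matches
  p <- strsplit(pat, "")[[1]]
  s <- strsplit(sub, "")[[1]]
  cols <- length(p)
  if (cols == 0) return(list(identity = 0, alignment_columns = 0L, matches = 0L))
  matches <- sum(.iupac_match(p, s))
  list(identity = 100 * matches / cols, alignment_columns = cols,
       matches = as.integer(matches))
}

.DEFAULT_SCORING <- list(match = 1, mismatch = -1, gap_open = -2,
                         gap_extend = -1)

#' Semi-global percent identity between two sequences
#'
#' Affine-gap semi-global (fit) alignment: the shorter sequence is aligned
#' end to end, terminal gaps on the longer sequence are free, so the
#' alignment always spans at least the shorter sequence. Identity is
#' 100 x matches / alignment columns, where columns exclude terminal gaps
#' but include internal gaps, and IUPAC ambiguity codes match iff their base
#' sets intersect. A gap of length L costs gap_open + L x gap_extend. The
#' definition is symmetric in its arguments.
#'
#' @param query,reference non-empty DNA sequences (character or DNAString).
#' @param scoring list with match, mismatch, gap_open, gap_extend.
#' @return list with identity, alignment_columns, matches, score.
#' @export
pairwiseIdentity <- function(query, reference, scoring = .DEFAULT_SCORING) {
  q <- toupper(as.character(query)); r <- toupper(as.character(reference))
  if (!nzchar(q) || !nzchar(r)) stop("empty sequence")
  if (nchar(q) > nchar(r)) { tmp <- q; q <- r; r <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(r), type = "global-local",
    substitutionMatrix = iupacScoringMatrix(scoring$match, scoring$mismatch),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  out <- .identity_from_alignment(
    as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)))
  out$score <- Biostrings::score(aln)
  out
}

#' Screen ASVs by sequence identity against reference producer strains
#'
#' For each ASV, the best hit over all references (ties broken by higher
#' identity, then longer alignment, then lexicographic strain id); retained
#' iff identity >= \code{identity_min} (inclusive threshold).
#'
#' @param asv_seqs named DNAStringSet of ASV sequences.
#' @param refs reference set as returned by \code{\link{readReferenceStrains}}
#'   (list with sequences and info), or a named DNAStringSet.
#' @param identity_min percent identity cutoff (inclusive).
#' @param scoring alignment scoring parameters.
#' @return data.frame of passing hits: asv_id, strain_id, identity,
#'   alignment_columns; the best hit of every ASV (passing or not) is
#'   attached as attribute \code{all_best}.
#' @export
screenByIdentity <- function(asv_seqs, refs, identity_min = 97,
                             scoring = .DEFAULT_SCORING) {
  ref_seqs <- if (is.list(refs) && !is.null(refs$sequences)) refs$sequences
    else refs
  if (!length(asv_seqs) || !length(ref_seqs)) stop("empty input sequences")
  n <- length(asv_seqs)
  ## pure-ACGT inputs take the fast C accessors (exact character matches =
  ## the IUPAC intersection rule); ambiguity codes fall back to the
  ## per-pair path of pairwiseIdentity()
  plain <- !any(grepl("[^ACGT]", c(as.character(asv_seqs),
                                   as.character(ref_seqs))))
  best <- data.frame(asv_id = names(asv_seqs), strain_id = NA_character_,
                     identity = -Inf, alignment_columns = 0L,
                     stringsAsFactors = FALSE)
  qlen <- Biostrings::width(asv_seqs)
  for (sid in names(ref_seqs)) {
    if (plain) {
      rlen <- length(ref_seqs[[sid]])
      shorter <- qlen <= rlen
      id <- cols <- numeric(n)
      for (part in c(TRUE, FALSE)) {
        idx <- which(shorter == part)
        if (!length(idx)) next
        ## pattern-global when the ASV is the shorter sequence, else
        ## subject-global (fit of the reference inside the ASV)
        aln <- Biostrings::pairwiseAlignment(
          asv_seqs[idx], ref_seqs[[sid]],
          type = if (part) "global-local" else "local-global",
          substitutionMatrix = iupacScoringMatrix(scoring$match,
                                                  scoring$mismatch),
          gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
        cols[idx] <- Biostrings::nchar(aln)
        id[idx] <- 100 * Biostrings::nmatch(aln) / cols[idx]
      }
    } else {
      res <- lapply(seq_len(n), function(i)
        pairwiseIdentity(asv_seqs[[i]], ref_seqs[[sid]], scoring))
      id <- vapply(res, `[[`, 0, "identity")
      cols <- vapply(res, `[[`, 0, "alignment_columns")
    }
    better <- id > best$identity + 1e-9 |
      (abs(id - best$identity) <= 1e-9 &
         (cols > best$alignment_columns |
            (cols == best$alignment_columns &
               (is.na(best$strain_id) | sid < best$strain_id))))
    best$strain_id[better] <- sid
    best$identity[better] <- id[better]
    best$alignment_columns[better] <- as.integer(cols[better])
  }
  hits <- best[best$identity >= identity_min - 1e-9, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "all_best") <- best
  hits
}

#' Tissue-mean relative abundance
#'
#' Per-sample percentage normalization followed by the arithmetic mean within
#' each tissue.
#'
#' @param table an \linkS4class{AsvCountTable}.
#' @param meta sample metadata with sample_id and tissue.
#' @param normalize normalize samples to percentages first.
#' @return matrix tissues x ASVs of mean relative abundance (percent).
#' @export
tissueMeanAbundance <- function(table, meta, normalize = TRUE) {
  stopifnot(is(table, "AsvCountTable"))
  m <- countsMatrix(table)
  tis <- meta$tissue[match(rownames(m), meta$sample_id)]
  if (any(is.na(tis))) stop("sample(s) without a tissue label: ",
    paste(rownames(m)[is.na(tis)], collapse = ", "))
  if (normalize) m <- 100 * m / rowSums(m)
  tl <- unique(tis)
  out <- vapply(tl, function(t) colMeans(m[tis == t, , drop = FALSE]),
                numeric(ncol(m)))
  t(out)
}

#' Kendall tau-b rank correlation
#'
#' tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2)) with tie corrections in both
#' margins; returns NA when either vector is entirely tied (undefined).
#'
#' @param x,y equal-length numeric vectors (length >= 2).
#' @return tau-b in [-1, 1] or NA.
#' @export
kendallTauB <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  unname(cor(x, y, method = "kendall"))
}

#' Screen ASVs by abundance-metabolite correlation
#'
#' Kendall tau-b between per-ASV tissue-mean abundance (zeros included) and
#' the metabolite concentration across tissues; retained iff
#' tau > \code{tau_min} (strict).
#'
#' @param tissue_means tissues x ASVs matrix from
#'   \code{\link{tissueMeanAbundance}}.
#' @param metabolites metabolite table (tissue, compound,
#'   mean_concentration).
#' @param compound compound to screen against.
#' @param tau_min strict tau cutoff.
#' @return data.frame of passing ASVs (asv_id, tau); all taus attached as
#'   attribute \code{all_tau}.
#' @export
screenByCorrelation <- function(tissue_means, metabolites, compound = "HupA",
                                tau_min = 0.4) {
  met <- metabolites[metabolites$compound == compound, , drop = FALSE]
  if (!nrow(met)) stop("compound not in metabolite table: ", compound)
  tissues <- rownames(tissue_means)
  if (length(tissues) < 3) stop("need >= 3 tissues for the correlation screen")
  if (!all(tissues %in% met$tissue))
    stop("metabolite table lacks tissue(s): ",
         paste(setdiff(tissues, met$tissue), collapse = ", "))
  conc <- met$mean_concentration[match(tissues, met$tissue)]
  taus <- apply(tissue_means, 2, function(ab) kendallTauB(ab, conc))
  pass <- !is.na(taus) & taus > tau_min
  out <- data.frame(asv_id = colnames(tissue_means)[pass],
                    tau = unname(taus[pass]), stringsAsFactors = FALSE)
  attr(out, "all_tau") <- taus
  out
}

#' Merge identity and correlation evidence into a PHP call set
#'
#' Union of both screens; an ASV found by both carries both evidence flags,
#' and |union| = |A| + |B| - |A intersect B| by construction.
#'
#' @param from_identity data.frame from \code{\link{screenByIdentity}}.
#' @param from_correlation data.frame from
#'   \code{\link{screenByCorrelation}}.
#' @param thresholds list recording identity_min and tau_min.
#' @return a \linkS4class{PhpCallSet}.
#' @export
mergePhpCalls <- function(from_identity, from_correlation,
                          thresholds = list(identity_min = 97, tau_min = 0.4)) {
  ids <- union(from_identity$asv_id, from_correlation$asv_id)
  i1 <- match(ids, from_identity$asv_id)
  i2 <- match(ids, from_correlation$asv_id)
  calls <- data.frame(
    asv_id = ids,
    evidence_clustering = !is.na(i1),
    evidence_correlation = !is.na(i2),
    best_identity = ifelse(is.na(i1), NA_real_, from_identity$identity[i1]),
    best_strain = ifelse(is.na(i1), NA_character_, from_identity$strain_id[i1]),
    tau = ifelse(is.na(i2), NA_real_, from_correlation$tau[i2]),
    stringsAsFactors = FALSE)
  new("PhpCallSet", calls = calls, thresholds = thresholds)
}

.round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

#' Per-tissue summary of PHP calls
#'
#' An ASV counts as detected in a tissue iff it has a nonzero count in at
#' least one sample of that tissue; percent_php = 100 x n_php /
#' n_asvs_detected, rounded half-up to 2 decimals.
#'
#' @param calls a \linkS4class{PhpCallSet}.
#' @param table an \linkS4class{AsvCountTable}.
#' @param meta sample metadata with sample_id and tissue.
#' @return data.frame: tissue, n_asvs_detected, n_php, percent_php.
#' @export
phpTissueSummary <- function(calls, table, meta) {
  stopifnot(is(calls, "PhpCallSet"), is(table, "AsvCountTable"))
  m <- countsMatrix(table)
  tis <- meta$tissue[match(rownames(m), meta$sample_id)]
  php <- phpCalls(calls)$asv_id
  tl <- unique(tis)
  rows <- lapply(tl, function(t) {
    det <- colnames(m)[colSums(m[tis == t, , drop = FALSE] > 0) > 0]
    n_php <- length(intersect(det, php))
    pct <- if (length(det)) .round_half_up(100 * n_php / length(det), 2) else 0
    data.frame(tissue = t, n_asvs_detected = length(det), n_php = n_php,
               percent_php = pct, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full dual-evidence PHP discovery
#'
#' Convenience wrapper: identity screen + correlation screen + merge.
#'
#' @param asv_seqs named DNAStringSet of ASV sequences.
#' @param refs reference strains (\code{\link{readReferenceStrains}} shape).
#' @param table an \linkS4class{AsvCountTable}.
#' @param meta sample metadata.
#' @param metabolites metabolite table, or NULL to skip the correlation
#'   screen.
#' @param compound compound label.
#' @param identity_min inclusive identity threshold (percent).
#' @param tau_min strict tau threshold.
#' @return a \linkS4class{PhpCallSet}.
#' @export
phpDiscovery <- function(asv_seqs, refs, table, meta, metabolites,
                         compound = "HupA", identity_min = 97,
                         tau_min = 0.4) {
  hits <- screenByIdentity(asv_seqs, refs, identity_min = identity_min)
  corr <- if (is.null(metabolites))
    data.frame(asv_id = character(), tau = numeric())
  else
    screenByCorrelation(tissueMeanAbundance(table, meta), metabolites,
                        compound = compound, tau_min = tau_min)
  mergePhpCalls(hits, corr,
                thresholds = list(identity_min = identity_min,
                                  tau_min = tau_min))
}
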