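#' @import methods
#' @importFrom stats cor sd median var rnorm rlnorm rgamma rmultinom rbinom
#'   runif quantile pnorm setNames complete.cases glm glm.control coef
#'   kruskal.test wilcox.test p.adjust dist as.dist lm
#' @importFrom utils read.delim write.table head
NULL

#' ASV count table
#'
#' Central container of the package: a samples x ASVs matrix of non-negative
#' integer read counts with unique sample and ASV identifiers. Rows are
#' biological samples, columns are amplicon sequence variants (ASVs).
#'
#' @slot counts numeric matrix (samples x ASVs) of non-negative integers with
#'   unique, non-empty dimnames.
#' @export
setClass("AsvCountTable", representation(counts = "matrix"))

setValidity("AsvCountTable", function(object) {
  m <- object@counts
  msg <- character()
  if (!is.numeric(m)) msg <- c(msg, "counts must be numeric")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must have sample and ASV identifiers as dimnames")
  else {
    if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate sample identifiers")
    if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate ASV identifiers")
  }
  if (is.numeric(m)) {
    if (any(m < 0)) msg <- c(msg, "negative count")
    if (any(m != round(m))) msg <- c(msg, "non-integer count")
    if (nrow(m) > 0 && any(rowSums(m) <= 0))
      msg <- c(msg, sprintf("sample(s) with zero total reads: %s",
                            paste(rownames(m)[rowSums(m) <= 0], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AsvCountTable
#'
#' @param counts samples x ASVs matrix of non-negative integer counts with
#'   dimnames.
#' @return An \linkS4class{AsvCountTable}.
#' @export
AsvCountTable <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  new("AsvCountTable", counts = counts)
}

#' Tissue x ASV presence/absence matrix
#'
#' Binary occurrence matrix with tissues (or other grouping level) as rows and
#' ASVs as columns, used by the nestedness analysis.
#'
#' @slot m binary matrix with row and column identifiers.
#' @export
setClass("PresenceMatrix", representation(m = "matrix"))

setValidity("PresenceMatrix", function(object) {
  m <- object@m
  msg <- character()
  if (!all(m %in% c(0, 1))) msg <- c(msg, "entries must be 0 or 1")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "row and column identifiers required")
  if (length(msg)) msg else TRUE
})

#' Construct a PresenceMatrix
#' @param m binary matrix (rows = tissues, columns = ASVs) with dimnames.
#' @return A \linkS4class{PresenceMatrix}.
#' @export
PresenceMatrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  new("PresenceMatrix", m = m)
}

#' Nestedness analysis result
#'
#' Holds the NODF statistic, the packed-matrix nestedness temperature, the
#' matrix fill, the null-model temperature sample and the one-sided p value
#' (lower temperature = more nested).
#'
#' @slot nodf NODF in [0, 100].
#' @slot temperature nestedness temperature in [0, 100].
#' @slot fill fraction of ones in the matrix.
#' @slot nullTemperatures numeric vector of null-model temperatures.
#' @slot pValue one-sided permutation p value.
#' @export
setClass("NestednessResult",
  representation(nodf = "numeric", temperature = "numeric", fill = "numeric",
                 nullTemperatures = "numeric", pValue = "numeric"))

setValidity("NestednessResult", function(object) {
  msg <- character()
  if (object@nodf < 0 || object@nodf > 100) msg <- c(msg, "nodf out of [0,100]")
  if (object@temperature < 0 || object@temperature > 100)
    msg <- c(msg, "temperature out of [0,100]")
  if (length(object@pValue) && !is.na(object@pValue) &&
      (object@pValue <= 0 || object@pValue > 1))
    msg <- c(msg, "p value out of (0,1]")
  if (length(msg)) msg else TRUE
})

#' Producer-ASV (PHP) call set
#'
#' Per-ASV evidence for potential metabolite-producing status: sequence
#' identity to a reference producer strain and/or Kendall tau-b correlation of
#' tissue-mean abundance with the metabolite gradient.
#'
#' @slot calls data.frame with columns asv_id, evidence_clustering,
#'   evidence_correlation, best_identity, best_strain, tau.
#' @slot thresholds list with identity_min (percent, inclusive) and tau_min
#'   (strict).
#' @export
setClass("PhpCallSet", representation(calls = "data.frame", thresholds = "list"))

setValidity("PhpCallSet", function(object) {
  msg <- character()
  need <- c("asv_id", "evidence_clustering", "evidence_correlation",
            "best_identity", "best_strain", "tau")
  if (!all(need %in% names(object@calls)))
    msg <- c(msg, "calls lacks required columns")
  else {
    if (anyDuplicated(object@calls$asv_id)) msg <- c(msg, "duplicate asv_id")
    if (nrow(object@calls) &&
        !all(object@calls$evidence_clustering | object@calls$evidence_correlation))
      msg <- c(msg, "every call needs at least one evidence flag")
  }
  if (length(msg)) msg else TRUE
})

#' Signed co-occurrence network
#'
#' Nodes are ASVs (with genus and producer flag); edges carry the signed
#' association weight and the BH-adjusted permutation q value.
#'
#' @slot nodes data.frame with columns asv_id, genus, php.
#' @slot edges data.frame with columns from, to, weight, q.
#' @slot category label of the sample category the network was inferred from.
#' @export
setClass("CoocNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 category = "character"))

setValidity("CoocNetwork", function(object) {
  msg <- character()
  if (!all(c("asv_id", "genus", "php") %in% names(object@nodes)))
    msg <- c(msg, "nodes lacks required columns")
  if (!all(c("from", "to", "weight", "q") %in% names(object@edges)))
    msg <- c(msg, "edges lacks required columns")
  else if (nrow(object@edges)) {
    if (any(object@edges$from == object@edges$to)) msg <- c(msg, "self-edge")
    key <- paste(pmin(object@edges$from, object@edges$to),
                 pmax(object@edges$from, object@edges$to))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edge")
    bad <- !(object@edges$from %in% object@nodes$asv_id &
             object@edges$to %in% object@nodes$asv_id)
    if (any(bad)) msg <- c(msg, "edge endpoint not among nodes")
  }
  if (length(msg)) msg else TRUE
})

## ---- generics & accessors ----

#' @rdname AsvCountTable-class
#' @param x an object with sample identifiers.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname AsvCountTable-class
#' @export
setGeneric("asvIds", function(x) standardGeneric("asvIds"))

#' @rdname AsvCountTable-class
#' @export
setGeneric("countsMatrix", function(x) standardGeneric("countsMatrix"))

#' @rdname AsvCountTable-class
setMethod("sampleIds", "AsvCountTable", function(x) rownames(x@counts))
#' @rdname AsvCountTable-class
setMethod("asvIds", "AsvCountTable", function(x) colnames(x@counts))
#' @rdname AsvCountTable-class
setMethod("countsMatrix", "AsvCountTable", function(x) x@counts)
setMethod("dim", "AsvCountTable", function(x) dim(x@counts))

#' @rdname PresenceMatrix-class
#' @param x a PresenceMatrix.
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))
#' @rdname PresenceMatrix-class
setMethod("presenceMatrix", "PresenceMatrix", function(x) x@m)

#' Fraction of ones of a presence matrix
#' @param x a \linkS4class{PresenceMatrix}.
#' @return fill in [0, 1].
#' @export
matrixFill <- function(x) {
  m <- if (is(x, "PresenceMatrix")) x@m else as.matrix(x)
  sum(m) / length(m)
}

#' @rdname PhpCallSet-class
#' @param x a PhpCallSet.
#' @export
setGeneric("phpCalls", function(x) standardGeneric("phpCalls"))
#' @rdname PhpCallSet-class
setMethod("phpCalls", "PhpCallSet", function(x) x@calls)

#' @rdname CoocNetwork-class
#' @param x a CoocNetwork.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname CoocNetwork-class
setMethod("networkEdges", "CoocNetwork", function(x) x@edges)
#' @rdname CoocNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname CoocNetwork-class
setMethod("networkNodes", "CoocNetwork", function(x) x@nodes)

setMethod("show", "AsvCountTable", function(object) {
  cat(sprintf("AsvCountTable: %d samples x %d ASVs, %s reads\n",
              nrow(object@counts), ncol(object@counts),
              format(sum(object@counts), big.mark = ",")))
})

setMethod("show", "PresenceMatrix", function(object) {
  cat(sprintf("PresenceMatrix: %d tissues x %d ASVs, fill %.3f\n",
              nrow(object@m), ncol(object@m), matrixFill(object)))
})

setMethod("show", "NestednessResult", function(object) {
  cat(sprintf(paste0("NestednessResult: NODF %.2f, temperature %.3f, ",
                     "fill %.3f, %d null sims, p = %.4g\n"),
              object@nodf, object@temperature, object@fill,
              length(object@nullTemperatures), object@pValue))
})

setMethod("show", "PhpCallSet", function(object) {
  cc <- object@calls
  cat(sprintf(paste0("PhpCallSet: %d calls (%d identity, %d correlation, ",
                     "%d dual evidence); identity >= %s%%, tau > %s\n"),
              nrow(cc), sum(cc$evidence_clustering), sum(cc$evidence_correlation),
              sum(cc$evidence_clustering & cc$evidence_correlation),
              object@thresholds$identity_min, object@thresholds$tau_min))
})

setMethod("show", "CoocNetwork", function(object) {
  cat(sprintf("CoocNetwork [%s]: %d nodes, %d edges (%d negative)\n",
              object@category, nrow(object@nodes), nrow(object@edges),
              sum(object@edges$weight < 0)))
})

#' Convert a CoocNetwork to an igraph graph
#'
#' The graph is undirected and simple; isolated nodes are retained. Edge
#' attributes weight, sign and q and node attributes genus and php are
#' attached.
#'
#' @param net a \linkS4class{CoocNetwork}.
#' @return an \code{igraph} object.
#' @export
asIgraph <- function(net) {
  stopifnot(is(net, "CoocNetwork"))
  g <- igraph::graph_from_data_frame(
    net@edges[, c("from", "to"), drop = FALSE], directed = FALSE,
    vertices = net@nodes[, "asv_id", drop = FALSE])
  if (nrow(net@edges)) {
    igraph::E(g)$weight <- net@edges$weight
    igraph::E(g)$sign <- ifelse(net@edges$weight >= 0, 1, -1)
    igraph::E(g)$q <- net@edges$q
  }
  igraph::V(g)$genus <- net@nodes$genus
  igraph::V(g)$php <- net@nodes$php
  g
}
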