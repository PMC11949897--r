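#' Select the samples of a network category
#'
#' Categories are defined by species and tissue predicates, e.g. the
#' metabolite-rich tissues of the producer plant, or leaves plus stems of
#' either species.
#'
#' @param meta sample metadata.
#' @param species species label(s), or NULL for all.
#' @param tissues tissue label(s), or NULL for all.
#' @return character vector of sample ids.
#' @export
categorySamples <- function(meta, species = NULL, tissues = NULL) {
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(species)) keep <- keep & meta$species %in% species
  if (!is.null(tissues)) keep <- keep & meta$tissue %in% tissues
  meta$sample_id[keep]
}

#' Filter a count table to one category's abundant ASVs
#'
#' Keeps ASVs with strictly more than \code{min_reads} total reads within the
#' category's samples ("more than 25 sequences"). Samples left with zero
#' reads after the column filter are dropped with a warning.
#'
#' @param table an \linkS4class{AsvCountTable}.
#' @param sample_ids the category's samples.
#' @param min_reads strict lower bound on per-category ASV totals.
#' @return filtered \linkS4class{AsvCountTable}.
#' @export
filterCategoryAsvs <- function(table, sample_ids, min_reads = 25) {
  stopifnot(is(table, "AsvCountTable"))
  if (!length(sample_ids)) stop("empty category")
  m <- countsMatrix(table)
  miss <- setdiff(sample_ids, rownames(m))
  if (length(miss)) stop("category sample(s) not in table: ",
                         paste(miss, collapse = ", "))
  m <- m[sample_ids, , drop = FALSE]
  m <- m[, colSums(m) > min_reads, drop = FALSE]
  if (!ncol(m)) stop("no ASV exceeds ", min_reads, " reads in the category")
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warning("dropped sample(s) with no reads on retained ASVs: ",
            paste(rownames(m)[empty], collapse = ", "))
    m <- m[!empty, , drop = FALSE]
  }
  AsvCountTable(m)
}

.clr <- function(m, pseudocount = 0.5) {
  y <- log((m + pseudocount) / rowSums(m + pseudocount))
  y - rowMeans(y)
}

.backend_clr_spearman <- function(m, n_perm, q_max, seed, pseudocount = 0.5) {
  n <- nrow(m); p <- ncol(m)
  z <- apply(.clr(m, pseudocount), 2, rank)
  z <- scale(z)
  z[is.nan(z)] <- 0
  obs <- crossprod(z) / (n - 1)
  set.seed(seed)
  exceed <- matrix(0, p, p)
  aobs <- abs(obs) - 1e-12
  for (b in seq_len(n_perm)) {
    zp <- apply(z, 2, sample)
    exceed <- exceed + (abs(crossprod(zp) / (n - 1)) >= aobs)
  }
  pv <- (1 + exceed) / (n_perm + 1)
  ut <- which(upper.tri(pv), arr.ind = TRUE)
  q <- p.adjust(pv[upper.tri(pv)], method = "BH")
  keep <- which(q <= q_max)
  data.frame(from = colnames(m)[ut[keep, 1]], to = colnames(m)[ut[keep, 2]],
             weight = obs[upper.tri(obs)][keep], q = q[keep],
             stringsAsFactors = FALSE)
}

.network_backends <- new.env(parent = emptyenv())
assign("clr-spearman-perm", .backend_clr_spearman, envir = .network_backends)

#' Register a network-inference backend
#'
#' A backend is a function(counts_matrix, n_perm, q_max, seed, ...) returning
#' an edge data.frame (from, to, weight, q).
#'
#' @param name backend name.
#' @param fun backend function.
#' @export
registerNetworkBackend <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .network_backends)
  invisible(name)
}

#' Infer a signed co-occurrence network
#'
#' Default backend "clr-spearman-perm": add pseudocount 0.5, close samples to
#' proportions, centered-log-ratio transform, Spearman correlation per ASV
#' pair, permutation p values from column-independent shuffles, BH adjustment
#' over all pairs, and retention of edges with q <= \code{q_max} with the
#' signed correlation as weight. The backend interface is pluggable
#' (\code{\link{registerNetworkBackend}}).
#'
#' @param table an \linkS4class{AsvCountTable} (>= 8 samples, >= 2 ASVs).
#' @param method backend name.
#' @param n_perm permutations for the p values.
#' @param q_max BH q-value cutoff for edges.
#' @param seed RNG seed.
#' @param taxonomy optional taxonomy table providing node genus.
#' @param php_ids optional ids flagged as producer calls.
#' @param category label stored on the network.
#' @return a \linkS4class{CoocNetwork}.
#' @export
inferNetwork <- function(table, method = "clr-spearman-perm", n_perm = 1000,
                         q_max = 0.05, seed = 1, taxonomy = NULL,
                         php_ids = character(), category = "all") {
  stopifnot(is(table, "AsvCountTable"))
  m <- countsMatrix(table)
  if (nrow(m) < 8) stop("need >= 8 samples to infer a network")
  if (ncol(m) < 2) stop("need >= 2 ASVs")
  if (!exists(method, envir = .network_backends))
    stop("unknown method '", method, "'; registered backends: ",
         paste(ls(.network_backends), collapse = ", "))
  backend <- get(method, envir = .network_backends)
  edges <- backend(m, n_perm = n_perm, q_max = q_max, seed = seed)
  genus <- rep("", ncol(m))
  if (!is.null(taxonomy)) {
    gi <- taxonomy$genus[match(colnames(m), taxonomy$asv_id)]
    genus <- ifelse(is.na(gi), "", gi)
  }
  nodes <- data.frame(asv_id = colnames(m), genus = genus,
                      php = colnames(m) %in% php_ids,
                      stringsAsFactors = FALSE)
  new("CoocNetwork", nodes = nodes, edges = edges, category = category)
}

#' Fast-greedy module detection
#'
#' Agglomerative modularity maximization (Clauset-Newman-Moore) on the
#' unweighted graph over all edges regardless of sign; isolated nodes become
#' singleton modules.
#'
#' @param net a \linkS4class{CoocNetwork}.
#' @return list of class \code{ModulePartition}: membership (named integer)
#'   and modularity_Q (NA for an edgeless network).
#' @export
fastGreedyModules <- function(net) {
  stopifnot(is(net, "CoocNetwork"))
  if (!nrow(net@nodes)) stop("empty network")
  g <- asIgraph(net)
  if (igraph::ecount(g) == 0) {
    mem <- seq_len(igraph::vcount(g))
    names(mem) <- igraph::V(g)$name
    out <- list(membership = mem, modularity_Q = NA_real_)
  } else {
    cl <- igraph::cluster_fast_greedy(g, weights = NA)
    w1 <- rep(1, igraph::ecount(g))
    n <- igraph::vcount(g)
    ## guard against floating-point noise in the greedy merge path: the
    ## returned partition must dominate the trivial ones
    cands <- list(as.integer(igraph::membership(cl)), seq_len(n),
                  rep(1L, n))
    qs <- vapply(cands, function(mm) igraph::modularity(g, mm, weights = w1),
                 0)
    best <- cands[[which.max(qs)]]
    out <- list(membership = setNames(best, igraph::V(g)$name),
                modularity_Q = max(qs))
  }
  class(out) <- "ModulePartition"
  out
}

#' Within-module degree z-score (Zi) and participation coefficient (Pi)
#'
#' Unweighted degrees over all edges. Zi standardizes the within-module
#' degree against its module's mean and (population) standard deviation
#' (sd 0 gives Zi 0); Pi = 1 - sum_t (k_it / k_i)^2; isolated nodes get
#' Zi = Pi = 0.
#'
#' @param net a \linkS4class{CoocNetwork}.
#' @param partition a \code{ModulePartition} covering all nodes.
#' @return data.frame: node, degree, zi, pi.
#' @export
ziPi <- function(net, partition) {
  stopifnot(is(net, "CoocNetwork"))
  mem <- partition$membership
  ids <- net@nodes$asv_id
  if (!all(ids %in% names(mem))) stop("partition does not cover all nodes")
  mem <- mem[ids]
  mods <- sort(unique(mem))
  ## per-node edges into each module
  kit <- matrix(0, length(ids), length(mods),
                dimnames = list(ids, as.character(mods)))
  if (nrow(net@edges)) for (e in seq_len(nrow(net@edges))) {
    a <- net@edges$from[e]; b <- net@edges$to[e]
    kit[a, as.character(mem[b])] <- kit[a, as.character(mem[b])] + 1
    kit[b, as.character(mem[a])] <- kit[b, as.character(mem[a])] + 1
  }
  k <- rowSums(kit)
  kin <- kit[cbind(seq_along(ids), match(mem, mods))]
  zi <- numeric(length(ids))
  for (mo in mods) {
    idx <- which(mem == mo)
    mu <- mean(kin[idx])
    sdev <- sqrt(mean((kin[idx] - mu)^2))
    zi[idx] <- if (sdev > 0) (kin[idx] - mu) / sdev else 0
  }
  pi_ <- ifelse(k > 0, 1 - rowSums((kit / pmax(k, 1))^2), 0)
  zi[k == 0] <- 0
  data.frame(node = ids, degree = as.integer(k), zi = zi, pi = as.numeric(pi_),
             stringsAsFactors = FALSE)
}

#' Classify node roles from Zi and Pi
#'
#' Strict thresholds: network hubs (Zi > 2.5 and Pi > 0.62), module hubs
#' (Zi > 2.5 and Pi < 0.62), connectors (Zi < 2.5 and Pi > 0.62), all other
#' nodes (including exact boundary values) peripheral.
#'
#' @param roles data.frame from \code{\link{ziPi}}.
#' @param zi_thresh,pi_thresh role thresholds.
#' @return the input with a \code{role} column.
#' @export
classifyRoles <- function(roles, zi_thresh = 2.5, pi_thresh = 0.62) {
  role <- ifelse(roles$zi > zi_thresh & roles$pi > pi_thresh, "network_hub",
          ifelse(roles$zi > zi_thresh & roles$pi < pi_thresh, "module_hub",
          ifelse(roles$zi < zi_thresh & roles$pi > pi_thresh, "connector",
                 "peripheral")))
  roles$role <- role
  roles
}

.avg_clustering <- function(g) {
  if (igraph::vcount(g) == 0) return(NA_real_)
  mean(igraph::transitivity(g, type = "local", isolates = "zero"))
}

.graph_modularity <- function(g) {
  if (igraph::ecount(g) == 0) return(NA_real_)
  cl <- igraph::cluster_fast_greedy(g, weights = NA)
  igraph::modularity(g, igraph::membership(cl), weights = rep(1, igraph::ecount(g)))
}

#' Random-graph baseline for network summary statistics
#'
#' Compares the observed fast-greedy modularity and average local clustering
#' coefficient against R uniform random graphs with the same numbers of
#' nodes and edges (Erdos-Renyi G(n, m); degree-preserving rewiring
#' available behind a flag).
#'
#' @param net a \linkS4class{CoocNetwork}.
#' @param R number of random graphs (>= 1).
#' @param seed RNG seed.
#' @param degree_preserving rewire preserving the degree sequence instead of
#'   uniform G(n, m).
#' @return list of class \code{NetworkSummary}: n_nodes, n_edges,
#'   modularity_Q, avg_clustering, random_modularity_mean/sd,
#'   random_clustering_mean/sd, z_modularity, z_clustering, R.
#' @export
randomGraphBaseline <- function(net, R = 100, seed = 1,
                                degree_preserving = FALSE) {
  stopifnot(is(net, "CoocNetwork"), R >= 1)
  g <- asIgraph(net)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  if (m > n * (n - 1) / 2) stop("edge count exceeds n(n-1)/2")
  set.seed(seed)
  qs <- numeric(R); cs <- numeric(R)
  for (r in seq_len(R)) {
    gr <- if (degree_preserving)
      igraph::rewire(g, igraph::keeping_degseq(niter = max(10 * m, 100)))
    else igraph::sample_gnm(n, m)
    qs[r] <- .graph_modularity(gr)
    cs[r] <- .avg_clustering(gr)
  }
  obs_q <- .graph_modularity(g)
  obs_c <- .avg_clustering(g)
  out <- list(n_nodes = n, n_edges = m, modularity_Q = obs_q,
              avg_clustering = obs_c,
              random_modularity_mean = mean(qs, na.rm = TRUE),
              random_modularity_sd = sd(qs),
              random_clustering_mean = mean(cs, na.rm = TRUE),
              random_clustering_sd = sd(cs),
              z_modularity = if (isTRUE(sd(qs) > 0))
                (obs_q - mean(qs, na.rm = TRUE)) / sd(qs) else NA_real_,
              z_clustering = if (isTRUE(sd(cs) > 0))
                (obs_c - mean(cs, na.rm = TRUE)) / sd(cs) else NA_real_,
              R = R)
  class(out) <- "NetworkSummary"
  out
}

#' Power-law fit of the degree distribution
#'
#' Ordinary least squares of log10 frequency on log10 degree over degrees
#' k >= 1 with nonzero frequency; gamma is the negated slope and R2 the
#' goodness of fit. Undefined (NA) with fewer than 3 distinct degrees.
#'
#' @param net a \linkS4class{CoocNetwork}.
#' @return list with gamma, R2 and defined flag.
#' @export
degreePowerlawFit <- function(net) {
  stopifnot(is(net, "CoocNetwork"))
  g <- asIgraph(net)
  deg <- igraph::degree(g)
  tab <- table(deg[deg >= 1])
  if (length(tab) < 3) return(list(gamma = NA_real_, R2 = NA_real_,
                                   defined = FALSE))
  k <- as.numeric(names(tab)); f <- as.numeric(tab)
  fit <- lm(log10(f) ~ log10(k))
  list(gamma = -unname(coef(fit)[2]), R2 = summary(fit)$r.squared,
       defined = TRUE)
}

#' Rank facilitator genera by module co-membership with producer ASVs
#'
#' Within each network, a module is producer-containing iff it holds at
#' least one PHP call; a genus supports facilitation there if a non-PHP
#' member of the genus occurs in such a module. Genera reaching
#' \code{flag_min} producer-containing modules in at least one
#' producer-plant network are flagged as candidate facilitators; genera
#' whose support occurs only in non-producer networks are cautioned.
#' Nodes without a genus are grouped as "unclassified" and never flagged.
#'
#' @param networks named list of \linkS4class{CoocNetwork}s.
#' @param partitions named list of matching \code{ModulePartition}s.
#' @param php_ids producer (PHP) ASV ids.
#' @param taxonomy taxonomy table supplying genus per ASV.
#' @param flag_min modules-with-producers threshold for flagging.
#' @param producer_networks names of the producer-plant networks.
#' @return data.frame: genus, n_php_modules (max over producer networks),
#'   networks_supporting, flagged, cautioned; empty when no module contains
#'   a producer call.
#' @export
facilitatorRanking <- function(networks, partitions, php_ids, taxonomy,
                               flag_min = 4,
                               producer_networks = names(networks)) {
  stopifnot(identical(names(networks), names(partitions)))
  per_net <- list()
  for (nm in names(networks)) {
    net <- networks[[nm]]
    mem <- partitions[[nm]]$membership[net@nodes$asv_id]
    is_php <- net@nodes$asv_id %in% php_ids
    php_modules <- unique(mem[is_php])
    if (!length(php_modules)) next
    gi <- taxonomy$genus[match(net@nodes$asv_id, taxonomy$asv_id)]
    gi[is.na(gi) | !nzchar(gi)] <- "unclassified"
    sel <- mem %in% php_modules & !is_php
    if (!any(sel)) next
    cnt <- tapply(mem[sel], gi[sel], function(x) length(unique(x)))
    per_net[[nm]] <- data.frame(network = nm, genus = names(cnt),
                                n_modules = as.integer(cnt),
                                stringsAsFactors = FALSE)
  }
  if (!length(per_net))
    return(data.frame(genus = character(), n_php_modules = integer(),
                      networks_supporting = character(), flagged = logical(),
                      cautioned = logical(), stringsAsFactors = FALSE))
  long <- do.call(rbind, per_net)
  genera <- sort(unique(long$genus))
  rows <- lapply(genera, function(g) {
    sub <- long[long$genus == g, , drop = FALSE]
    prod_counts <- sub$n_modules[sub$network %in% producer_networks]
    data.frame(
      genus = g,
      n_php_modules = if (length(prod_counts)) max(prod_counts)
        else as.integer(0),
      networks_supporting = paste(sort(unique(sub$network)), collapse = ","),
      flagged = g != "unclassified" && length(prod_counts) &&
        max(prod_counts) >= flag_min,
      cautioned = !any(sub$network %in% producer_networks),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "per_network") <- long
  out[order(-out$n_php_modules, out$genus), ]
}

#' Export a network with node and edge attributes
#'
#' Node attributes: genus, php flag, module, zi, pi, role, degree; edge
#' attributes: weight, sign (+1/-1), q. Formats: GraphML, GEXF or an edge
#' TSV.
#'
#' @param net a \linkS4class{CoocNetwork}.
#' @param path output file path.
#' @param format one of "graphml", "gexf", "tsv".
#' @param partition optional \code{ModulePartition}.
#' @param roles optional classified roles data.frame from
#'   \code{\link{classifyRoles}}.
#' @return invisible path.
#' @export
exportGraph <- function(net, path, format = c("graphml", "gexf", "tsv"),
                        partition = NULL, roles = NULL) {
  stopifnot(is(net, "CoocNetwork"))
  if (!is.character(format) || !all(format %in% c("graphml", "gexf", "tsv")))
    stop("unknown format; supported: graphml, gexf, tsv")
  format <- match.arg(format)
  g <- asIgraph(net)
  igraph::V(g)$degree <- igraph::degree(g)
  if (!is.null(partition))
    igraph::V(g)$module <- as.integer(
      partition$membership[igraph::V(g)$name])
  if (!is.null(roles)) {
    idx <- match(igraph::V(g)$name, roles$node)
    igraph::V(g)$zi <- roles$zi[idx]
    igraph::V(g)$pi <- roles$pi[idx]
    if (!is.null(roles$role)) igraph::V(g)$role <- roles$role[idx]
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "tsv") {
    ed <- net@edges
    ed$sign <- ifelse(ed$weight >= 0, 1L, -1L)
    .write_tsv(ed[, c("from", "to", "weight", "sign", "q")], path)
  } else {
    .write_gexf(g, path)
  }
  invisible(path)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.write_gexf <- function(g, path) {
  vat <- setdiff(igraph::vertex_attr_names(g), "name")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://gexf.net/1.2" version="1.2">')
  w('  <graph defaultedgetype="undirected">')
  w('    <attributes class="node">')
  for (i in seq_along(vat)) {
    type <- if (is.numeric(igraph::vertex_attr(g, vat[i]))) "double"
      else if (is.logical(igraph::vertex_attr(g, vat[i]))) "boolean"
      else "string"
    w('      <attribute id="%d" title="%s" type="%s"/>', i - 1,
      .xml_escape(vat[i]), type)
  }
  w('    </attributes>')
  w('    <nodes>')
  for (v in seq_len(igraph::vcount(g))) {
    w('      <node id="%s" label="%s">', .xml_escape(igraph::V(g)$name[v]),
      .xml_escape(igraph::V(g)$name[v]))
    if (length(vat)) {
      w('        <attvalues>')
      for (i in seq_along(vat)) {
        val <- igraph::vertex_attr(g, vat[i])[v]
        w('          <attvalue for="%d" value="%s"/>', i - 1,
          .xml_escape(as.character(val)))
      }
      w('        </attvalues>')
    }
    w('      </node>')
  }
  w('    </nodes>')
  w('    <edges>')
  el <- igraph::as_edgelist(g)
  has_w <- "weight" %in% igraph::edge_attr_names(g)
  for (e in seq_len(nrow(el))) {
    wt <- if (has_w) sprintf(' weight="%.6g"', abs(igraph::E(g)$weight[e]))
      else ""
    w('      <edge id="%d" source="%s" target="%s"%s/>', e - 1,
      .xml_escape(el[e, 1]), .xml_escape(el[e, 2]), wt)
  }
  w('    </edges>')
  w('  </graph>')
  w('</gexf>')
  invisible(path)
}
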