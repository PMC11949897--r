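#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the post-denoising state of a tissue-resolved phyllosphere mycobiome
#' survey: 6 tissue categories x 6 replicates, 300 ASVs with nested tissue
#' occupancy (young tissues host the poorest communities), lognormal
#' sequencing depths around 70,000 reads, a monotone decreasing metabolite
#' gradient from the youngest tissue, 20 producer ASVs whose sequences sit
#' ~2% from reference producer strains and whose tissue-mean abundance tracks
#' the gradient, and 8 latent-factor co-abundance modules of 10 ASVs.
#'
#' @param seed integer RNG seed; the whole dataset is a deterministic
#'   function of the configuration including the seed.
#' @param n_tissues number of tissue categories.
#' @param replicates_per_tissue replicates per tissue (>= 3).
#' @param n_asvs total number of ASVs (= size of the richest tissue pool).
#' @param depth_log_mean,depth_log_sd lognormal sequencing-depth parameters.
#' @param pool_fractions strictly increasing per-tissue pool sizes as
#'   fractions of \code{n_asvs}, youngest (poorest) first; last must be 1.
#' @param n_producers number of planted producer ASVs (drawn from the ASVs
#'   present in every tissue).
#' @param producer_divergence per-site substitution rate of producer ASV
#'   sequences from their source reference strain.
#' @param nonproducer_divergence substitution rate of all other ASVs from a
#'   random reference strain.
#' @param gradient named (by tissue) metabolite means in micrograms per gram
#'   fresh weight, monotone decreasing from the youngest tissue; default is
#'   log-spaced from 360.27 down to 135.9.
#' @param tau_link_strength 0..1, scales the producer abundance-gradient
#'   link; at 1 with all noise off the link is perfectly rank-concordant.
#' @param gradient_exponent exponent amplifying the producer tissue
#'   enrichment (multiplier = (gradient/min)^(exponent * tau_link_strength)).
#' @param n_modules,module_size planted co-abundance modules; members are the
#'   widest-occupancy ASVs.
#' @param factor_sd lognormal sd of the shared per-(module, sample) latent
#'   factor.
#' @param dispersion gamma overdispersion of per-sample ASV intensities
#'   (0 = multinomial only).
#' @param shell_scale geometric down-scaling of the base abundance of ASVs
#'   restricted to older tissues (tissue specialists are rare taxa).
#' @param tissue_effect_sd lognormal sd of the per-(tissue, ASV) abundance
#'   effect decoupling tissue means from the gradient for non-producers.
#' @param pool_swap_noise probability that a pool member is swapped with a
#'   non-member, per tissue (degrades nestedness).
#' @param n_refs number of reference producer strains.
#' @param seq_length_mean mean ITS2-like sequence length (bp).
#' @param compound metabolite label.
#' @param species_label species tag used in sample ids and metadata.
#' @param tissue_names optional tissue names, youngest first.
#' @return validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1,
                             n_tissues = 6,
                             replicates_per_tissue = 6,
                             n_asvs = 300,
                             depth_log_mean = log(70000),
                             depth_log_sd = 0.35,
                             pool_fractions = NULL,
                             n_producers = 20,
                             producer_divergence = 0.02,
                             nonproducer_divergence = 0.15,
                             gradient = NULL,
                             tau_link_strength = 1,
                             gradient_exponent = 3,
                             n_modules = 8,
                             module_size = 10,
                             factor_sd = 1,
                             dispersion = 0.1,
                             shell_scale = 0.4,
                             tissue_effect_sd = 0.2,
                             pool_swap_noise = 0,
                             n_refs = 8,
                             seq_length_mean = 300,
                             compound = "HupA",
                             species_label = "producer",
                             tissue_names = NULL) {
  if (is.null(tissue_names)) {
    tissue_names <- if (n_tissues == 6)
      c("apical_shoot", "bulbil", "young_leaf", "sporangium", "mature_leaf",
        "stem")
    else paste0("tissue_", seq_len(n_tissues))
  }
  stopifnot(length(tissue_names) == n_tissues)
  if (is.null(pool_fractions)) {
    pool_fractions <- if (n_tissues == 6) c(0.3, 0.35, 0.45, 0.6, 0.8, 1)
    else seq(0.15, 1, length.out = n_tissues)
  }
  if (is.null(gradient))
    gradient <- exp(seq(log(360.27), log(135.9), length.out = n_tissues))
  names(gradient) <- tissue_names
  cfg <- list(seed = as.integer(seed), n_tissues = n_tissues,
              replicates_per_tissue = replicates_per_tissue, n_asvs = n_asvs,
              depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
              pool_fractions = pool_fractions, n_producers = n_producers,
              producer_divergence = producer_divergence,
              nonproducer_divergence = nonproducer_divergence,
              gradient = gradient, tau_link_strength = tau_link_strength,
              gradient_exponent = gradient_exponent, n_modules = n_modules,
              module_size = module_size, factor_sd = factor_sd,
              dispersion = dispersion, shell_scale = shell_scale,
              tissue_effect_sd = tissue_effect_sd,
              pool_swap_noise = pool_swap_noise, n_refs = n_refs,
              seq_length_mean = seq_length_mean, compound = compound,
              species_label = species_label, tissue_names = tissue_names)
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

#' @rdname simulationConfig
#' @param cfg a SimulationConfig.
#' @export
validateSimulationConfig <- function(cfg) {
  with(cfg, {
    if (replicates_per_tissue < 3) stop("replicates_per_tissue must be >= 3")
    if (n_asvs < 2 || n_tissues < 2) stop("need >= 2 ASVs and >= 2 tissues")
    if (producer_divergence < 0 || producer_divergence > 1 ||
        nonproducer_divergence < 0 || nonproducer_divergence > 1)
      stop("divergences must lie in [0, 1]")
    if (n_modules * module_size > n_asvs)
      stop("infeasible config: module_size x n_modules > n_asvs")
    if (length(pool_fractions) != n_tissues ||
        any(diff(pool_fractions) <= 0) || pool_fractions[n_tissues] != 1)
      stop("pool_fractions must be strictly increasing and end at 1")
    if (any(diff(gradient) >= 0))
      stop("gradient must be strictly decreasing from the youngest tissue")
    if (n_producers > floor(pool_fractions[1] * n_asvs))
      stop("n_producers exceeds the size of the youngest tissue pool")
    if (tau_link_strength < 0 || tau_link_strength > 1)
      stop("tau_link_strength must lie in [0, 1]")
  })
  invisible(cfg)
}

#' Simulate i.i.d. random DNA sequences
#'
#' Uniform ACGT composition; lengths are normal(length_mean, length_sd)
#' rounded and truncated at 150 bp.
#'
#' @param n number of sequences (>= 1).
#' @param length_mean,length_sd length distribution parameters (bp).
#' @param seed RNG seed.
#' @param prefix id prefix.
#' @return named \code{DNAStringSet}.
#' @export
simulateSequences <- function(n, length_mean = 300, length_sd = 30,
                              seed = 1, prefix = "seq") {
  stopifnot(n >= 1)
  set.seed(seed)
  lens <- pmax(150L, as.integer(round(rnorm(n, length_mean, length_sd))))
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0(prefix, seq_len(n))
  out
}

#' Mutate a DNA sequence by i.i.d. substitutions
#'
#' Each position is independently substituted to one of the three other bases
#' with probability \code{rate}; length is preserved.
#'
#' @param seq DNAString or character DNA sequence (ACGT).
#' @param rate substitution probability in [0, 1].
#' @param seed RNG seed.
#' @return character sequence of the same length.
#' @export
mutateSequence <- function(seq, rate, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  set.seed(seed)
  hit <- runif(length(s)) < rate
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    s[hit] <- vapply(s[hit], function(b)
      sample(setdiff(bases, b), 1), "", USE.NAMES = FALSE)
  }
  paste(s, collapse = "")
}

.GENUS_POOL <- c("Penicillium", "Trichoderma", "Colletotrichum", "Fusarium",
                 "Acremonium", "Cladosporium", "Dioszegia", "Exobasidium",
                 "Lycoperdon", "Alternaria", "Epicoccum", "Mucor",
                 "Phaeosphaeria", "Leptosphaeria", "Aureobasidium",
                 "Mycosphaerella", "Phoma", "Ramularia")

#' Simulate a full single-species dataset with planted ground truth
#'
#' Draws nested per-tissue ASV pools (pool of each younger tissue contained
#' in every older one), per-sample counts as multinomial draws at lognormal
#' depth from intensities combining a lognormal base abundance, a geometric
#' rarity penalty for tissue specialists, per-(tissue, ASV) lognormal
#' effects, shared per-(module, sample) latent factors and optional gamma
#' overdispersion. Producer ASVs are additionally enriched along the
#' metabolite gradient so that their tissue-mean abundance is
#' rank-concordant with it, and their sequences are derived from reference
#' strains at the configured divergence.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return list with counts (\linkS4class{AsvCountTable}), metadata,
#'   taxonomy, sequences, refs (list sequences + info), metabolites and
#'   truth (producer_asv_ids, module_assignment, tissue_pools,
#'   reference_map).
#' @export
simulateDataset <- function(cfg = simulationConfig()) {
  validateSimulationConfig(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_asvs
  Tn <- cfg$n_tissues
  asv_ids <- paste0("ASV", seq_len(n))
  pool_sizes <- round(cfg$pool_fractions * n)

  ## occupancy rank: ASVs with rank <= pool_sizes[t] belong to tissue t's pool
  occ_rank <- sample(n)
  shell <- vapply(occ_rank, function(r) which(pool_sizes >= r)[1], 0L)
  pools <- lapply(seq_len(Tn), function(t) asv_ids[occ_rank <= pool_sizes[t]])
  names(pools) <- cfg$tissue_names
  mask <- vapply(seq_len(Tn), function(t) as.numeric(occ_rank <= pool_sizes[t]),
                 numeric(n))  # n x T

  if (cfg$pool_swap_noise > 0) {
    for (t in seq_len(Tn)) {
      present <- which(mask[, t] == 1)
      absent <- which(mask[, t] == 0)
      if (!length(absent)) next
      swap <- present[runif(length(present)) < cfg$pool_swap_noise]
      if (length(swap)) {
        into <- sample(absent, min(length(swap), length(absent)))
        swap <- swap[seq_along(into)]
        mask[swap, t] <- 0
        mask[into, t] <- 1
      }
    }
    pools <- lapply(seq_len(Tn), function(t) asv_ids[mask[, t] == 1])
    names(pools) <- cfg$tissue_names
  }

  base <- rlnorm(n, 0, 1) * cfg$shell_scale^(shell - 1)

  producers <- sort(sample(which(occ_rank <= pool_sizes[1]), cfg$n_producers))
  n_mod_members <- cfg$n_modules * cfg$module_size
  module <- rep(NA_integer_, n)
  module[occ_rank <= n_mod_members] <-
    sample(rep(seq_len(cfg$n_modules), each = cfg$module_size))

  grad <- cfg$gradient
  boost <- outer(rep(1, n), rep(1, Tn))
  boost[producers, ] <- matrix(
    (grad / min(grad))^(cfg$gradient_exponent * cfg$tau_link_strength),
    length(producers), Tn, byrow = TRUE)

  tis_eff <- if (cfg$tissue_effect_sd > 0)
    matrix(rlnorm(n * Tn, 0, cfg$tissue_effect_sd), n, Tn) else
    matrix(1, n, Tn)

  reps <- cfg$replicates_per_tissue
  n_samp <- Tn * reps
  counts <- matrix(0, n_samp, n)
  smp_ids <- character(n_samp)
  meta <- data.frame(sample_id = character(n_samp), species = cfg$species_label,
                     tissue = character(n_samp), replicate = integer(n_samp),
                     stringsAsFactors = FALSE)
  k <- 0
  for (t in seq_len(Tn)) for (r in seq_len(reps)) {
    k <- k + 1
    lam <- base * mask[, t] * tis_eff[, t] * boost[, t]
    if (cfg$factor_sd > 0 && cfg$n_modules > 0) {
      f <- rlnorm(cfg$n_modules, 0, cfg$factor_sd)
      in_mod <- !is.na(module)
      lam[in_mod] <- lam[in_mod] * f[module[in_mod]]
    }
    if (cfg$dispersion > 0)
      lam <- lam * rgamma(n, shape = 1 / cfg$dispersion,
                          rate = 1 / cfg$dispersion)
    depth <- max(1L, as.integer(round(rlnorm(1, cfg$depth_log_mean,
                                             cfg$depth_log_sd))))
    if (sum(lam) <= 0) lam <- mask[, t] + (sum(mask[, t]) == 0)
    counts[k, ] <- rmultinom(1, depth, lam / sum(lam))
    smp_ids[k] <- sprintf("%s_%s_r%d", cfg$species_label, cfg$tissue_names[t], r)
    meta$sample_id[k] <- smp_ids[k]
    meta$tissue[k] <- cfg$tissue_names[t]
    meta$replicate[k] <- r
  }
  dimnames(counts) <- list(smp_ids, asv_ids)

  ## sequences: producers near their source strain, others far from a random one
  refs_seq <- simulateSequences(cfg$n_refs, cfg$seq_length_mean, 30,
                                seed = sample.int(2^31 - 2, 1),
                                prefix = "strain")
  ref_info <- data.frame(
    strain_id = names(refs_seq),
    genus = sample(.GENUS_POOL[1:8], cfg$n_refs, replace = cfg$n_refs > 8),
    source_tag = paste0("literature_report_", seq_len(cfg$n_refs)),
    stringsAsFactors = FALSE)
  src <- integer(n)
  src[producers] <- sample(cfg$n_refs, length(producers), replace = TRUE)
  nonprod <- setdiff(seq_len(n), producers)
  src[nonprod] <- sample(cfg$n_refs, length(nonprod), replace = TRUE)
  seq_seeds <- sample.int(2^31 - 2, n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    rate <- if (i %in% producers) cfg$producer_divergence else
      cfg$nonproducer_divergence
    seqs[i] <- mutateSequence(refs_seq[[src[i]]], rate, seed = seq_seeds[i])
  }
  seqset <- Biostrings::DNAStringSet(seqs)
  names(seqset) <- asv_ids

  genus <- ref_info$genus[src]
  genus[nonprod] <- ifelse(runif(length(nonprod)) < 0.6,
                           sample(.GENUS_POOL, length(nonprod), replace = TRUE),
                           genus[nonprod])
  taxonomy <- data.frame(
    asv_id = asv_ids, kingdom = "Fungi",
    phylum = sample(c("Ascomycota", "Basidiomycota"), n, TRUE, c(0.8, 0.2)),
    class = sample(c("Sordariomycetes", "Dothideomycetes", "Tremellomycetes"),
                   n, TRUE, c(0.5, 0.35, 0.15)),
    order = "", family = "", genus = genus,
    species = ifelse(runif(n) < 0.3, paste0(tolower(genus), "_sp"), ""),
    stringsAsFactors = FALSE)

  metabolites <- data.frame(tissue = cfg$tissue_names, compound = cfg$compound,
                            mean_concentration = round(unname(grad), 2),
                            stringsAsFactors = FALSE)

  truth <- list(
    producer_asv_ids = asv_ids[producers],
    module_assignment = setNames(module, asv_ids),
    tissue_pools = pools,
    reference_map = setNames(names(refs_seq)[src[producers]],
                             asv_ids[producers]))

  list(counts = AsvCountTable(counts), metadata = meta, taxonomy = taxonomy,
       sequences = seqset, refs = list(sequences = refs_seq, info = ref_info),
       metabolites = metabolites, truth = truth, config = cfg)
}

#' Presence matrix of the planted tissue pools
#'
#' @param truth the truth component of \code{\link{simulateDataset}} output.
#' @return a \linkS4class{PresenceMatrix} of the planted (noise-free) pools.
#' @export
truthPresenceMatrix <- function(truth) {
  asvs <- sort(unique(unlist(truth$tissue_pools)))
  m <- vapply(asvs, function(a)
    vapply(truth$tissue_pools, function(p) as.numeric(a %in% p), 0),
    numeric(length(truth$tissue_pools)))
  rownames(m) <- names(truth$tissue_pools)
  PresenceMatrix(m)
}

#' Simulate the two-species study layout
#'
#' Builds a producer-species dataset from \code{cfg} plus a non-producer
#' companion dataset (two tissues, leaf and stem; no abundance-gradient link,
#' a few reference-similar ASVs) whose ASV ids are disjoint except for a
#' small shared set renamed to producer-species ids, mirroring a cross-plant
#' survey in which only a handful of ASVs are shared.
#'
#' @param cfg producer-species \code{\link{simulationConfig}}.
#' @param n_shared number of ASVs shared between the species.
#' @param nonproducer_label species tag of the companion dataset.
#' @return list with elements \code{producer}, \code{nonproducer} (each as
#'   \code{\link{simulateDataset}}) and \code{shared_asv_ids}.
#' @export
simulateStudy <- function(cfg = simulationConfig(), n_shared = 13,
                          nonproducer_label = "nonproducer") {
  prod <- simulateDataset(cfg)
  np_cfg <- simulationConfig(
    seed = cfg$seed + 1000003L, n_tissues = 2,
    replicates_per_tissue = cfg$replicates_per_tissue,
    n_asvs = cfg$n_asvs, depth_log_mean = cfg$depth_log_mean,
    depth_log_sd = cfg$depth_log_sd, pool_fractions = c(0.7, 1),
    n_producers = max(3, round(cfg$n_producers / 3)),
    producer_divergence = cfg$producer_divergence,
    nonproducer_divergence = cfg$nonproducer_divergence,
    gradient = c(2, 1), tau_link_strength = 0,
    n_modules = cfg$n_modules, module_size = cfg$module_size,
    factor_sd = cfg$factor_sd, dispersion = cfg$dispersion,
    shell_scale = cfg$shell_scale, tissue_effect_sd = cfg$tissue_effect_sd,
    n_refs = cfg$n_refs, seq_length_mean = cfg$seq_length_mean,
    compound = cfg$compound, species_label = nonproducer_label,
    tissue_names = c("leaf", "stem"))
  np <- simulateDataset(np_cfg)
  ## no metabolite gradient in the non-producer plant
  np$metabolites <- NULL

  ## rename ASVs: disjoint id spaces except n_shared ids carried over
  set.seed(cfg$seed + 2000029L)
  n_shared <- min(n_shared, cfg$n_asvs)
  from_prod <- sample(asvIds(prod$counts), n_shared)
  keep <- sample(asvIds(np$counts), n_shared)
  map <- setNames(paste0("B_", asvIds(np$counts)), asvIds(np$counts))
  map[keep] <- from_prod
  .remap <- function(x) unname(map[x])
  cm <- countsMatrix(np$counts)
  colnames(cm) <- .remap(colnames(cm))
  np$counts <- AsvCountTable(cm)
  np$taxonomy$asv_id <- .remap(np$taxonomy$asv_id)
  names(np$sequences) <- .remap(names(np$sequences))
  ## shared ASVs are the same organisms: copy producer-species sequences/taxonomy
  np$sequences[from_prod] <- prod$sequences[from_prod]
  np$taxonomy[match(from_prod, np$taxonomy$asv_id), ] <-
    prod$taxonomy[match(from_prod, prod$taxonomy$asv_id), ]
  np$truth$producer_asv_ids <- .remap(np$truth$producer_asv_ids)
  np$truth$module_assignment <-
    setNames(np$truth$module_assignment, .remap(names(np$truth$module_assignment)))
  np$truth$tissue_pools <- lapply(np$truth$tissue_pools, .remap)
  np$truth$reference_map <-
    setNames(np$truth$reference_map, .remap(names(np$truth$reference_map)))

  list(producer = prod, nonproducer = np, shared_asv_ids = sort(from_prod))
}

#' Write a simulated dataset to a directory
#'
#' Emits the exact input formats of the readers plus the planted truth
#' (JSON).
#'
#' @param sim output of \code{\link{simulateDataset}}.
#' @param dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
writeSyntheticDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeAsvTable(sim$counts, p("asv_table.tsv"))
  writeTable(sim$metadata, p("metadata.tsv"))
  writeTable(sim$taxonomy, p("taxonomy.tsv"))
  writeFasta(sim$sequences, p("asv_sequences.fasta"))
  writeFasta(sim$refs$sequences, p("reference_strains.fasta"))
  writeTable(sim$refs$info, p("reference_strains.tsv"))
  files <- c("asv_table.tsv", "metadata.tsv", "taxonomy.tsv",
             "asv_sequences.fasta", "reference_strains.fasta",
             "reference_strains.tsv")
  if (!is.null(sim$metabolites)) {
    writeTable(sim$metabolites, p("metabolites.tsv"))
    files <- c(files, "metabolites.tsv")
  }
  truth <- sim$truth
  truth$module_assignment <- as.list(truth$module_assignment)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(file.path(dir, c(files, "truth.json")))
}

#' Benchmark configuration for module recovery
#'
#' Co-abundance modules are only identifiable from co-occurrence networks
#' when the sample set is ecologically homogeneous: tissue-driven occupancy
#' differences (habitat filtering) otherwise induce correlations between all
#' ASV pairs sharing a tissue profile and swamp the latent-factor signal.
#' This preset therefore plants the default 8 x 10 modules in a
#' two-tissue, near-uniform-occupancy design with 10 replicates per tissue
#' and no tissue effects, which is the condition under which the
#' network-module recovery of the pipeline is benchmarked.
#'
#' @param seed RNG seed.
#' @param dispersion overdispersion (low by design).
#' @return a \code{\link{simulationConfig}}.
#' @export
moduleBenchmarkConfig <- function(seed = 1, dispersion = 0.05) {
  simulationConfig(seed = seed, n_tissues = 2, replicates_per_tissue = 10,
                   n_asvs = 150, pool_fractions = c(0.99, 1),
                   tissue_effect_sd = 0, dispersion = dispersion,
                   factor_sd = 1, tau_link_strength = 0, gradient = c(2, 1),
                   tissue_names = c("tissue_1", "tissue_2"))
}
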