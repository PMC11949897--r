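#' Derive a stable per-stage seed
#'
#' Hashes the stage label and mixes it with the global seed so that adding a
#' stage never shifts another stage's randomness; the result is a positive
#' integer below 2^31 - 1.
#'
#' @param seed global integer seed.
#' @param label stage label.
#' @return integer seed.
#' @export
deriveSeed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 2654435 %% 2147483647) %% 2147483629 + 1)
}

.PIPELINE_DEFAULTS <- list(
  seed = 1,
  simulate = TRUE,
  input_dir = NULL,
  n_shared = 13,
  rarefy_depth = NULL,        # NULL = lowest sample total
  identity_min = 97,
  tau_min = 0.4,
  compound = "HupA",
  min_reads = 25,
  n_perm_permanova = 999,
  network_method = "clr-spearman-perm",
  n_perm_network = 1000,
  q_max = 0.05,
  n_sims = 1000,
  padj_max = 0.01,
  lfc_min = 2,
  zi_thresh = 2.5,
  pi_thresh = 0.62,
  flag_min = 4,
  sim = list())

#' Pipeline configuration
#'
#' Stage parameters default to the study values (rarefaction to the lowest
#' library, identity 97, tau 0.4, min_reads 25, 999/1000 permutations, 1000
#' null simulations, padj 0.01, |log2fc| 2, Zi 2.5, Pi 0.62, flag_min 4).
#' \code{sim} holds overrides for \code{\link{simulationConfig}}. Unknown
#' keys are rejected.
#'
#' @param ... overrides of the defaults.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.PIPELINE_DEFAULTS))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.PIPELINE_DEFAULTS, over)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file path.
#' @return list of class \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.json_out <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

.log_stage <- function(log, msg) {
  message("[mycohub] ", msg)
  c(log, msg)
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: simulate (or load) inputs, validate,
#' diversity (alpha, rarefaction-based alpha at fixed depth, Bray-Curtis,
#' NMDS, PERMANOVA, alpha-diversity group tests), PHP discovery, nestedness,
#' co-occurrence networks for the three study categories (A: metabolite-rich
#' tissues of the producer; B: producer leaves + stems; C: non-producer
#' leaves + stems), differential abundance between the species' leaves, and
#' facilitator ranking. Every output file is listed in a manifest with its
#' md5 hash; a rerun with the same configuration reproduces identical
#' hashes.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param out_dir run directory (created).
#' @return invisible list with the manifest, the log and key in-memory
#'   results.
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  log <- character()

  ## ---- inputs ----
  if (isTRUE(config$simulate)) {
    log <- .log_stage(log, "stage simulate: generating synthetic study")
    sim_args <- utils::modifyList(
      list(seed = deriveSeed(config$seed, "simulate")), config$sim)
    study <- simulateStudy(do.call(simulationConfig, sim_args),
                           n_shared = config$n_shared)
    writeSyntheticDataset(study$producer, p("inputs", "producer"))
    writeSyntheticDataset(study$nonproducer, p("inputs", "nonproducer"))
    prod <- study$producer; np <- study$nonproducer
  } else {
    if (is.null(config$input_dir)) stop("input_dir required when simulate = FALSE")
    log <- .log_stage(log, paste("stage load:", config$input_dir))
    read_side <- function(d) list(
      counts = readAsvTable(file.path(d, "asv_table.tsv")),
      metadata = readMetadata(file.path(d, "metadata.tsv")),
      taxonomy = readTaxonomy(file.path(d, "taxonomy.tsv")),
      sequences = readFasta(file.path(d, "asv_sequences.fasta")),
      refs = readReferenceStrains(file.path(d, "reference_strains.fasta"),
                                  file.path(d, "reference_strains.tsv")),
      metabolites = if (file.exists(file.path(d, "metabolites.tsv")))
        readMetabolites(file.path(d, "metabolites.tsv")) else NULL)
    prod <- read_side(file.path(config$input_dir, "producer"))
    np <- read_side(file.path(config$input_dir, "nonproducer"))
  }
  producer_species <- prod$metadata$species[1]
  nonproducer_species <- np$metadata$species[1]
  meta_all <- rbind(prod$metadata, np$metadata)
  tax_all <- unique(rbind(prod$taxonomy, np$taxonomy))

  ## ---- validate ----
  log <- .log_stage(log, "stage validate")
  val <- validateDataset(prod$counts, prod$metadata, prod$taxonomy,
                         prod$sequences)
  .json_out(val, p("validation.json"))
  if (!val$ok) stop("validation failed: ",
                    paste(val$samples_without_metadata,
                          val$asvs_without_sequence, collapse = ", "))

  ## ---- diversity (producer species) ----
  log <- .log_stage(log, "stage diversity")
  depth <- config$rarefy_depth
  if (is.null(depth)) depth <- min(rowSums(countsMatrix(prod$counts)))
  rar <- rarefyCounts(prod$counts, depth, seed = deriveSeed(config$seed, "rarefy"))
  alpha <- alphaDiversity(rar)
  writeTable(alpha, p("alpha_diversity.tsv"))
  bc <- brayCurtisMatrix(prod$counts)
  bm <- as.matrix(bc)
  writeTable(cbind(data.frame(sample_id = rownames(bm)),
                   as.data.frame(bm, check.names = FALSE)),
             p("bray_curtis.tsv"))
  ord <- nmdsOrdination(bc, seed = deriveSeed(config$seed, "nmds"))
  writeTable(data.frame(sample_id = rownames(ord$coordinates),
                        round(ord$coordinates, 8),
                        check.names = FALSE),
             p("nmds_coordinates.tsv"))
  tissues <- prod$metadata$tissue[match(sampleIds(prod$counts),
                                        prod$metadata$sample_id)]
  pmv <- permanovaTest(bc, tissues, n_perm = config$n_perm_permanova,
                       seed = deriveSeed(config$seed, "permanova"))
  .json_out(list(pseudo_F = pmv$pseudo_F, p = pmv$p, n_perm = pmv$n_perm,
                 df_between = pmv$df_between, df_within = pmv$df_within,
                 nmds_stress = ord$stress),
            p("permanova.json"))
  atis <- prod$metadata$tissue[match(alpha$sample_id, prod$metadata$sample_id)]
  gt <- groupDifferenceTests(alpha$shannon, atis)
  .json_out(gt, p("alpha_tests.json"))

  ## ---- PHP discovery (producer species) ----
  log <- .log_stage(log, "stage php")
  if (is.null(prod$metabolites))
    log <- .log_stage(log,
      "stage php: metabolite table missing, correlation screen skipped")
  calls <- phpDiscovery(prod$sequences, prod$refs, prod$counts, prod$metadata,
                        prod$metabolites, compound = config$compound,
                        identity_min = config$identity_min,
                        tau_min = config$tau_min)
  writeTable(phpCalls(calls), p("php_calls.tsv"))
  writeTable(phpTissueSummary(calls, prod$counts, prod$metadata),
             p("php_tissue_summary.tsv"))
  ## identity screen on the non-producer side feeds its network annotation
  np_hits <- screenByIdentity(np$sequences, np$refs,
                              identity_min = config$identity_min)
  php_all <- union(phpCalls(calls)$asv_id, np_hits$asv_id)

  ## ---- nestedness (producer species) ----
  log <- .log_stage(log, "stage nestedness")
  nest <- nestednessAnalysis(prod$counts, prod$metadata,
                             n_sims = config$n_sims,
                             seed = deriveSeed(config$seed, "nestedness"))
  pm <- attr(nest, "presence")
  writeTable(cbind(data.frame(tissue = rownames(presenceMatrix(pm))),
                   as.data.frame(presenceMatrix(pm), check.names = FALSE)),
             p("presence_matrix.tsv"))
  .json_out(list(nodf = nest@nodf, temperature = nest@temperature,
                 fill = nest@fill, p_value = nest@pValue,
                 n_sims = length(nest@nullTemperatures),
                 null_temperature_mean = mean(nest@nullTemperatures),
                 null_temperature_sd = sd(nest@nullTemperatures)),
            p("nestedness.json"))

  ## ---- networks A / B / C ----
  prod_tissues <- unique(prod$metadata$tissue)
  rich <- prod_tissues[seq_len(min(3, length(prod_tissues)))]
  leafstem_prod <- intersect(c("young_leaf", "mature_leaf", "stem", "leaf"),
                             prod_tissues)
  if (!length(leafstem_prod)) leafstem_prod <- prod_tissues
  cats <- list(
    A = list(table = prod$counts,
             samples = categorySamples(prod$metadata, tissues = rich)),
    B = list(table = prod$counts,
             samples = categorySamples(prod$metadata,
                                       tissues = leafstem_prod)),
    C = list(table = np$counts,
             samples = categorySamples(np$metadata)))
  networks <- list(); partitions <- list()
  for (nm in names(cats)) {
    smp <- cats[[nm]]$samples
    if (length(smp) < 8) {
      log <- .log_stage(log, sprintf(
        "stage network %s: skipped (%d samples < 8)", nm, length(smp)))
      next
    }
    log <- .log_stage(log, paste("stage network", nm))
    ft <- filterCategoryAsvs(cats[[nm]]$table, smp,
                             min_reads = config$min_reads)
    net <- inferNetwork(ft, method = config$network_method,
                        n_perm = config$n_perm_network, q_max = config$q_max,
                        seed = deriveSeed(config$seed, paste0("network_", nm)),
                        taxonomy = tax_all, php_ids = php_all, category = nm)
    part <- fastGreedyModules(net)
    roles <- classifyRoles(ziPi(net, part), zi_thresh = config$zi_thresh,
                           pi_thresh = config$pi_thresh)
    summ <- randomGraphBaseline(net, R = 100,
                                seed = deriveSeed(config$seed,
                                                  paste0("baseline_", nm)))
    pl <- degreePowerlawFit(net)
    exportGraph(net, p(sprintf("network_%s.graphml", nm)), "graphml",
                partition = part, roles = roles)
    ed <- networkEdges(net)
    ed$sign <- ifelse(ed$weight >= 0, 1L, -1L)
    writeTable(ed, p(sprintf("network_%s_edges.tsv", nm)))
    writeTable(data.frame(node = names(part$membership),
                          module = as.integer(part$membership)),
               p(sprintf("network_%s_modules.tsv", nm)))
    writeTable(roles, p(sprintf("network_%s_roles.tsv", nm)))
    .json_out(c(unclass(summ),
                list(modularity_fast_greedy = part$modularity_Q,
                     powerlaw_gamma = pl$gamma, powerlaw_R2 = pl$R2,
                     role_counts = as.list(table(roles$role)))),
              p(sprintf("network_%s_summary.json", nm)))
    networks[[nm]] <- net; partitions[[nm]] <- part
  }

  ## ---- differential abundance: leaves, producer vs non-producer ----
  leaf_prod <- categorySamples(prod$metadata, tissues = intersect(
    c("young_leaf", "mature_leaf", "leaf"), prod_tissues))
  leaf_np <- categorySamples(np$metadata, tissues = intersect(
    c("leaf", "young_leaf", "mature_leaf"), unique(np$metadata$tissue)))
  da <- NULL
  if (length(leaf_prod) >= 2 && length(leaf_np) >= 2) {
    log <- .log_stage(log, "stage diffabund")
    merged <- mergeSpeciesTables(prod$counts, np$counts)
    .json_out(merged$overlap, p("species_overlap.json"))
    mm <- countsMatrix(merged$table)[c(leaf_prod, leaf_np), , drop = FALSE]
    mm <- mm[, colSums(mm) > 0, drop = FALSE]
    grp <- factor(rep(c(producer_species, nonproducer_species),
                      c(length(leaf_prod), length(leaf_np))),
                  levels = c(nonproducer_species, producer_species))
    da <- differentialAbundance(AsvCountTable(mm), grp,
                                padj_max = config$padj_max,
                                lfc_min = config$lfc_min,
                                pseudo_reference = TRUE)
    writeTable(da$records, p("diffabund.tsv"))
    .json_out(list(n_up = da$n_up, n_down = da$n_down,
                   direction = da$direction),
              p("diffabund_summary.json"))
  } else {
    log <- .log_stage(log, "stage diffabund: skipped (missing leaf samples)")
  }

  ## ---- facilitators ----
  fac <- NULL
  if (length(networks)) {
    log <- .log_stage(log, "stage facilitators")
    fac <- facilitatorRanking(networks, partitions, php_all, tax_all,
                              flag_min = config$flag_min,
                              producer_networks = intersect(c("A", "B"),
                                                            names(networks)))
    writeTable(fac, p("facilitators.tsv"))
  }

  writeLines(log, p("run_log.txt"))
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        c("manifest.json", "run_log.txt")))
  manifest <- lapply(files, function(f)
    unname(tools::md5sum(file.path(out_dir, f))))
  names(manifest) <- files
  .json_out(manifest, p("manifest.json"))
  invisible(list(manifest = manifest, log = log, php = calls, nestedness = nest,
                 networks = networks, partitions = partitions,
                 diffabund = da, facilitators = fac))
}

#' Render a Markdown report for a pipeline run
#'
#' Assembles the stage outputs of \code{\link{runPipeline}} into a single
#' human-readable report; sections whose outputs are missing are marked
#' absent. Regeneration is idempotent.
#'
#' @param run_dir directory produced by \code{\link{runPipeline}}.
#' @param path output file (default report.md inside run_dir).
#' @return invisible path.
#' @export
renderReport <- function(run_dir, path = file.path(run_dir, "report.md")) {
  if (!file.exists(file.path(run_dir, "manifest.json")))
    stop("manifest.json not found; not a pipeline run directory?")
  out <- c("# Mycobiome pipeline report", "")
  md_table <- function(df) {
    if (!nrow(df)) return("(empty table)")
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      vapply(seq_len(nrow(df)), function(i)
        paste("|", paste(vapply(df[i, ], function(x)
          if (is.numeric(x)) format(x, digits = 4) else as.character(x), ""),
          collapse = " | "), "|"), ""))
  }
  section <- function(title, file, render) {
    fp <- file.path(run_dir, file)
    c(paste("##", title), "",
      if (file.exists(fp)) render(fp) else "*section absent*", "")
  }
  out <- c(out,
    section("Detected ASVs per tissue and producer calls",
            "php_tissue_summary.tsv",
            function(f) md_table(.read_tsv(f))),
    section("PHP evidence", "php_calls.tsv", function(f) {
      df <- .read_tsv(f)
      both <- sum(df$evidence_clustering & df$evidence_correlation)
      c(sprintf(paste0("%d calls = %d identity + %d correlation - %d dual ",
                       "(|A u B| = |A| + |B| - |A n B|)"),
                nrow(df), sum(df$evidence_clustering),
                sum(df$evidence_correlation), both), "", md_table(df))
    }),
    section("Nestedness", "nestedness.json", function(f) {
      x <- jsonlite::read_json(f)
      sprintf("NODF %.2f, temperature %.3f, fill %.3f, p = %.4g (%d null sims; null mean %.2f)",
              x$nodf, x$temperature, x$fill, x$p_value, x$n_sims,
              x$null_temperature_mean)
    }))
  for (nm in c("A", "B", "C")) {
    out <- c(out, section(paste("Network", nm),
                          sprintf("network_%s_summary.json", nm), function(f) {
      x <- jsonlite::read_json(f)
      rc <- unlist(x$role_counts)
      c(sprintf("%d nodes, %d edges; Q = %.3f (random %.3f +/- %.3f); clustering %.3f (random %.3f +/- %.3f)",
                x$n_nodes, x$n_edges, x$modularity_Q,
                x$random_modularity_mean, x$random_modularity_sd,
                x$avg_clustering, x$random_clustering_mean,
                x$random_clustering_sd),
        sprintf("power-law gamma %.2f, R2 %.3f",
                if (is.null(x$powerlaw_gamma)) NA else x$powerlaw_gamma,
                if (is.null(x$powerlaw_R2)) NA else x$powerlaw_R2),
        paste("roles:", paste(names(rc), rc, sep = "=", collapse = ", ")))
    }))
  }
  out <- c(out,
    section("Differential abundance (leaves)", "diffabund_summary.json",
            function(f) {
      x <- jsonlite::read_json(f)
      sprintf("%d ASVs up, %d down (%s)", x$n_up, x$n_down, x$direction)
    }),
    section("Facilitator genera", "facilitators.tsv",
            function(f) md_table(.read_tsv(f))))
  writeLines(out, path)
  invisible(path)
}
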