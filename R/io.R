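## Tab-separated, UTF-8, header row is the canonical table dialect throughout;
## no quoting inside cells, so writers use quote = FALSE and readers keep
## strings as-is.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, quote = "", comment.char = "")
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

.require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")))
  invisible(TRUE)
}

#' Read an ASV count table
#'
#' Expects a TSV whose first column holds sample identifiers and whose header
#' names the ASVs; every body cell must parse as a non-negative integer.
#'
#' @param path TSV file path.
#' @return An \linkS4class{AsvCountTable} preserving input ordering.
#' @export
readAsvTable <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("ASV table needs a sample id column and >= 1 ASV")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!grepl("^\\s*-?[0-9.eE+-]+\\s*$", m) | is.na(suppressWarnings(
      as.numeric(m))), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("non-numeric count at sample '%s', ASV '%s'",
                 ids[bad[1]], colnames(m)[bad[2]]))
  }
  storage.mode(m) <- "double"
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', ASV '%s'",
                 ids[bad[1]], colnames(m)[bad[2]]))
  }
  if (any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at sample '%s', ASV '%s'",
                 ids[bad[1]], colnames(m)[bad[2]]))
  }
  if (anyDuplicated(ids)) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate ASV identifiers")
  rownames(m) <- ids
  AsvCountTable(m)
}

#' Write an ASV count table
#' @param x an \linkS4class{AsvCountTable}.
#' @param path output TSV path.
#' @export
writeAsvTable <- function(x, path) {
  stopifnot(is(x, "AsvCountTable"))
  df <- data.frame(sample_id = sampleIds(x), check.names = FALSE)
  df <- cbind(df, as.data.frame(countsMatrix(x), check.names = FALSE))
  .write_tsv(df, path)
}

.IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")

#' Read DNA sequences from FASTA
#'
#' Record ids are the first whitespace token of each header; sequences are
#' upper-cased and validated against the IUPAC DNA alphabet, with the record
#' and position of any illegal character reported.
#'
#' @param path FASTA file path.
#' @return A named \code{DNAStringSet}.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(raw), "\\s+"), `[`, "", 1)
  if (anyDuplicated(ids)) stop("duplicate FASTA record ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) stop("empty sequence for record '", ids[i], "'")
    ch <- strsplit(seqs[i], "")[[1]]
    bad <- which(!(ch %in% .IUPAC))
    if (length(bad))
      stop(sprintf("illegal character '%s' in record '%s' at position %d",
                   ch[bad[1]], ids[i], bad[1]))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write DNA sequences to FASTA
#' @param seqs named \code{DNAStringSet} (or named character vector).
#' @param path output path.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read sample metadata
#'
#' Required columns: sample_id, species, tissue, replicate.
#' @param path TSV file path.
#' @return data.frame of validated metadata.
#' @export
readMetadata <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("sample_id", "species", "tissue", "replicate"),
                   "metadata")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (any(df$replicate != round(df$replicate))) stop("replicate must be integer")
  df$sample_id <- as.character(df$sample_id)
  df
}

.TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
                "species")

#' Read an ASV taxonomy table
#'
#' Required columns: asv_id plus the seven ranks kingdom..species; rank values
#' may be empty (classifiers leave gaps).
#' @param path TSV file path.
#' @return data.frame with asv_id and the seven rank columns.
#' @export
readTaxonomy <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("asv_id", .TAX_RANKS), "taxonomy")
  if (anyDuplicated(df$asv_id)) stop("duplicate asv_id in taxonomy")
  for (r in .TAX_RANKS) df[[r]][is.na(df[[r]])] <- ""
  df[, c("asv_id", .TAX_RANKS)]
}

#' Read a tissue metabolite concentration table
#'
#' Required columns: tissue, compound, mean_concentration (micrograms per gram
#' fresh weight, non-negative); one row per (tissue, compound).
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
readMetabolites <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("tissue", "compound", "mean_concentration"),
                   "metabolites")
  if (any(df$mean_concentration < 0)) stop("negative concentration")
  if (anyDuplicated(df[, c("tissue", "compound")]))
    stop("duplicate (tissue, compound) row")
  df
}

#' Read reference producer strains
#'
#' @param fasta_path FASTA of reference ITS sequences.
#' @param meta_path TSV with columns strain_id, genus, source_tag; genus must
#'   be non-empty.
#' @return list with elements \code{sequences} (DNAStringSet) and \code{info}
#'   (data.frame).
#' @export
readReferenceStrains <- function(fasta_path, meta_path) {
  seqs <- readFasta(fasta_path)
  info <- .read_tsv(meta_path)
  .require_columns(info, c("strain_id", "genus", "source_tag"),
                   "reference strains")
  if (anyDuplicated(info$strain_id)) stop("duplicate strain_id")
  if (any(!nzchar(info$genus))) stop("empty genus for reference strain")
  miss <- setdiff(info$strain_id, names(seqs))
  if (length(miss)) stop("strain(s) without sequence: ",
                         paste(miss, collapse = ", "))
  list(sequences = seqs[info$strain_id], info = info)
}

#' Write sample metadata / taxonomy / metabolites
#' @param df the table to write.
#' @param path output TSV path.
#' @export
writeTable <- function(df, path) .write_tsv(df, path)

#' Cross-validate a dataset
#'
#' Cross-references sample and ASV identifiers across the count table,
#' metadata, taxonomy and sequences. The report passes only when every sample
#' of the count table has metadata and every ASV has a sequence; ASVs without
#' taxonomy are warnings (taxonomy is optional per ASV).
#'
#' @param counts an \linkS4class{AsvCountTable}.
#' @param meta sample metadata data.frame.
#' @param tax optional taxonomy data.frame.
#' @param seqs optional named DNAStringSet of ASV sequences.
#' @return list with \code{ok} flag, per-direction orphan id vectors and
#'   \code{warnings}.
#' @export
validateDataset <- function(counts, meta, tax = NULL, seqs = NULL) {
  stopifnot(is(counts, "AsvCountTable"))
  rep <- list(
    samples_without_metadata = setdiff(sampleIds(counts), meta$sample_id),
    metadata_without_sample = setdiff(meta$sample_id, sampleIds(counts)),
    asvs_without_sequence = if (is.null(seqs)) character()
      else setdiff(asvIds(counts), names(seqs)),
    warnings = character())
  if (!is.null(tax)) {
    orphan <- setdiff(asvIds(counts), tax$asv_id)
    if (length(orphan))
      rep$warnings <- c(rep$warnings,
        sprintf("%d ASV(s) without taxonomy: %s", length(orphan),
                paste(head(orphan, 5), collapse = ", ")))
  }
  rep$ok <- length(rep$samples_without_metadata) == 0 &&
    length(rep$asvs_without_sequence) == 0
  rep
}

#' Merge the count tables of two species
#'
#' Takes the union of the ASV columns (zero-filling absences) and stacks the
#' samples; sample identifiers must not overlap. Total reads are conserved and
#' the overlap summary obeys n_union = n_a + n_b - n_shared.
#'
#' @param a,b \linkS4class{AsvCountTable}s sharing one ASV id scheme.
#' @return list with \code{table} (merged AsvCountTable) and \code{overlap}
#'   (n_a, n_b, n_shared, n_union).
#' @export
mergeSpeciesTables <- function(a, b) {
  stopifnot(is(a, "AsvCountTable"), is(b, "AsvCountTable"))
  if (length(intersect(sampleIds(a), sampleIds(b))))
    stop("duplicate sample ids between tables")
  ua <- asvIds(a); ub <- asvIds(b)
  shared <- intersect(ua, ub)
  all_ids <- c(ua, setdiff(ub, ua))
  fill <- function(x) {
    m <- matrix(0, nrow(countsMatrix(x)), length(all_ids),
                dimnames = list(sampleIds(x), all_ids))
    m[, asvIds(x)] <- countsMatrix(x)
    m
  }
  merged <- AsvCountTable(rbind(fill(a), fill(b)))
  list(table = merged,
       overlap = list(n_a = length(ua), n_b = length(ub),
                      n_shared = length(shared),
                      n_union = length(all_ids)))
}
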