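#' @importFrom utils read.delim write.table
NULL

# assign contiguous 0-based ranks by ascending start within each contig;
# messages when the input was not already start-sorted
.assignRanks <- function(genes, quiet = FALSE) {
  if (!nrow(genes)) {
    genes$rank <- integer(0)
    return(genes)
  }
  key <- paste(genes$genome_id, genes$contig_id, sep = "\r")
  if (!quiet && any(vapply(split(genes$start, key), is.unsorted, logical(1))))
    message("gene table not sorted by start within contig(s); sorting before ranking")
  ord <- order(key, genes$start, genes$gene_id, method = "radix")
  genes <- genes[ord, , drop = FALSE]
  key <- key[ord]
  genes$rank <- as.integer(stats::ave(seq_along(key), key, FUN = seq_along)) - 1L
  rownames(genes) <- NULL
  genes
}

#' Read a gene table
#'
#' Reads per-genome gene annotations and assigns each gene a contiguous
#' 0-based rank by ascending start coordinate within its contig. Gene
#' ranks -- not base-pair distances -- are the coordinate on which all
#' neighborhood arithmetic operates. Coordinates are 1-based inclusive.
#'
#' @param path file path. For `dialect = "tsv"`, a tab-separated file with
#'   header columns genome_id, contig_id, gene_id, start, end, strand and
#'   optionally protein_id (empty or "." = non-coding). For
#'   `dialect = "gff3"`, a GFF3 file whose CDS features carry `ID` and
#'   optionally `protein_id` attributes.
#' @param dialect input dialect.
#' @param genomeId genome label used for GFF3 input (a single GFF3 file is
#'   one genome); ignored for TSV.
#' @return data.frame with columns genome_id, contig_id, gene_id, start,
#'   end, strand, protein_id, rank, ordered by genome, contig, rank.
#'   Duplicated gene ids are an error; unsorted input is sorted with a
#'   message.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("genome_id\tcontig_id\tgene_id\tstart\tend\tstrand\tprotein_id",
#'              "g1\tc1\tgA\t10\t90\t+\tP1",
#'              "g1\tc1\tgB\t200\t290\t-\tP2"), tf)
#' readGeneTable(tf)
#' @export
readGeneTable <- function(path, dialect = c("tsv", "gff3"), genomeId = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    genes <- read.delim(path, header = TRUE, sep = "\t",
                        colClasses = "character", comment.char = "#")
    if (!nrow(genes)) {
      genes <- .df(genome_id = character(), contig_id = character(),
                   gene_id = character(), start = integer(), end = integer(),
                   strand = character(), protein_id = character())
    }
    .assertColumns(genes, c("genome_id", "contig_id", "gene_id", "start",
                            "end", "strand"), "gene table")
    if (!"protein_id" %in% names(genes)) genes$protein_id <- NA_character_
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
    genes$protein_id[genes$protein_id %in% c("", ".", "NA")] <- NA_character_
  } else {
    gr <- rtracklayer::import(path)
    gr <- gr[as.character(gr$type) == "CDS"]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
      paste0("gene", seq_along(gr))
    pid <- if (!is.null(gr$protein_id)) as.character(gr$protein_id) else ids
    genes <- .df(genome_id = genomeId %||% "genome1",
                 contig_id = as.character(GenomicRanges::seqnames(gr)),
                 gene_id = ids,
                 start = BiocGenerics::start(gr),
                 end = BiocGenerics::end(gr),
                 strand = as.character(BiocGenerics::strand(gr)),
                 protein_id = pid)
    genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  }
  if (nrow(genes) && any(genes$start > genes$end))
    stop("gene(s) with start > end: ",
         paste(utils::head(genes$gene_id[genes$start > genes$end], 3), collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)])[1:min(3, sum(duplicated(genes$gene_id)))],
               collapse = ", "))
  if (nrow(genes) && !all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  .assignRanks(genes)
}

#' Write a gene table
#'
#' Writes the TSV dialect read by [readGeneTable()]. The rank column is
#' omitted (it is a derived quantity, recomputed on read).
#'
#' @param genes gene table as returned by [readGeneTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  cols <- c("genome_id", "contig_id", "gene_id", "start", "end", "strand",
            "protein_id")
  .assertColumns(genes, cols, "gene table")
  out <- genes[, cols]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a protein table
#'
#' @param path TSV with header protein_id, length and optional taxon.
#' @return data.frame(protein_id, length, taxon).
#' @export
readProteinTable <- function(path) {
  p <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  .assertColumns(p, c("protein_id", "length"), "protein table")
  p$length <- as.integer(p$length)
  if (!"taxon" %in% names(p)) p$taxon <- NA_character_
  if (any(p$length < 1)) stop("protein length < 1")
  p[, c("protein_id", "length", "taxon")]
}

#' @rdname readProteinTable
#' @param proteins protein table.
#' @export
writeProteinTable <- function(proteins, path) {
  write.table(proteins[, c("protein_id", "length", "taxon")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file; record ids are protein ids.
#' @return list with `proteins` (data.frame protein_id/length/taxon) and
#'   `sequences` (named [Biostrings::AAStringSet]).
#' @export
readProteinFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  list(proteins = .df(protein_id = names(seqs),
                      length = Biostrings::width(seqs),
                      taxon = NA_character_),
       sequences = seqs)
}

#' Read a domain-hit table
#'
#' Accepts either a plain TSV with header (protein_id, domain_acc,
#' optional score, optional meets_threshold) or the HMMER `--tblout`
#' per-target dialect (whitespace-separated, '#' comments; target name,
#' query accession and full-sequence score are used, accession versions
#' are stripped). `meets_threshold` defaults to TRUE so hit tables already
#' filtered at the Pfam gathering threshold work unchanged.
#'
#' @param path input file.
#' @return data.frame(protein_id, domain_acc, score, meets_threshold).
#' @export
readDomainHits <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(body))
    return(.df(protein_id = character(), domain_acc = character(),
               score = numeric(), meets_threshold = logical()))
  if (grepl("\t", body[1])) {
    h <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    comment.char = "#")
    .assertColumns(h, c("protein_id", "domain_acc"), "domain-hit table")
    h$score <- if ("score" %in% names(h)) suppressWarnings(as.numeric(h$score)) else NA_real_
    h$meets_threshold <- if ("meets_threshold" %in% names(h))
      toupper(h$meets_threshold) %in% c("TRUE", "T", "1", "YES") else TRUE
    keep <- c("protein_id", "domain_acc", "score", "meets_threshold")
    if (all(c("env_from", "env_to") %in% names(h))) {
      h$env_from <- as.integer(h$env_from)
      h$env_to <- as.integer(h$env_to)
      keep <- c(keep, "env_from", "env_to")
    }
    h <- h[, keep]
  } else {
    fields <- strsplit(trimws(body), "[[:space:]]+")
    n <- lengths(fields)
    if (any(n < 6)) {
      bad <- which(n < 6)[1]
      stop("unrecognized domain-hit dialect at line: ", body[bad])
    }
    acc <- vapply(fields, `[[`, "", 4L)
    nm <- vapply(fields, `[[`, "", 3L)
    acc <- ifelse(acc == "-", nm, sub("\\.\\d+$", "", acc))
    h <- .df(protein_id = vapply(fields, `[[`, "", 1L),
             domain_acc = acc,
             score = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 6L))),
             meets_threshold = TRUE)
  }
  if (anyNA(h$domain_acc) || any(!nzchar(h$domain_acc))) {
    bad <- which(is.na(h$domain_acc) | !nzchar(h$domain_acc))[1]
    stop("empty domain accession at data row ", bad)
  }
  h
}

#' @rdname readDomainHits
#' @param hits hit table.
#' @export
writeDomainHits <- function(hits, path) {
  cols <- intersect(c("protein_id", "domain_acc", "score", "meets_threshold",
                      "env_from", "env_to"), names(hits))
  write.table(hits[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read/write 3-state secondary-structure strings
#'
#' FASTA-like format: `>protein_id` followed by a string over H/E/C
#' (helix / strand / coil).
#'
#' @param path input or output file.
#' @return data.frame(protein_id, ss).
#' @export
readSecondaryStructure <- function(path) {
  s <- Biostrings::readBStringSet(path)
  out <- .df(protein_id = sub("\\s.*$", "", names(s)), ss = as.character(s))
  if (any(grepl("[^HEC]", out$ss)))
    stop("secondary-structure strings must use only H, E, C")
  rownames(out) <- NULL
  out
}

#' @rdname readSecondaryStructure
#' @param ss data.frame(protein_id, ss).
#' @export
writeSecondaryStructure <- function(ss, path) {
  writeLines(paste0(">", ss$protein_id, "\n", ss$ss), path)
  invisible(path)
}

#' Read/write beta-barrel topology annotations
#'
#' @param path TSV with header protein_id, strand_count, localization
#'   (OM / other / unknown).
#' @return data.frame(protein_id, strand_count, localization).
#' @export
readTopology <- function(path) {
  tp <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  .assertColumns(tp, c("protein_id", "strand_count", "localization"),
                 "topology table")
  tp$strand_count <- as.integer(tp$strand_count)
  if (any(tp$strand_count < 0, na.rm = TRUE)) stop("negative strand_count")
  if (!all(tp$localization %in% c("OM", "other", "unknown")))
    stop("localization must be one of OM, other, unknown")
  tp[, c("protein_id", "strand_count", "localization")]
}

#' @rdname readTopology
#' @param topology topology table.
#' @export
writeTopology <- function(topology, path) {
  write.table(topology[, c("protein_id", "strand_count", "localization")],
              path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

# fixed column order and types of the classification table; shared by
# writer and reader so round-trips are lossless
.CLASS_COLS <- c(
  protein_id = "character", gene_id = "character", genome_id = "character",
  contig_id = "character", length = "integer", context_ok = "logical",
  pathway = "character", pathway_ambiguous = "logical",
  pcp2_context = "logical", context_gene_id = "character",
  cluster_id = "integer", is_representative = "logical",
  short = "logical", cterm_helix = "logical", coupled = "logical",
  partner_gene_id = "character", partner_protein_id = "character",
  category = "character")

#' Write / read the OPX classification table
#'
#' Deterministic column order; `writeClassification()` then
#' [readClassification()] is lossless (identical records and types).
#'
#' @param records OPX classification table (see [opxTable()]).
#' @param path file path.
#' @return The written path (writer, invisibly) or the table (reader).
#' @export
writeClassification <- function(records, path) {
  for (nm in names(.CLASS_COLS))
    if (!nm %in% names(records))
      records[[nm]] <- vector(.CLASS_COLS[[nm]], nrow(records))
  out <- records[, names(.CLASS_COLS)]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeClassification
#' @export
readClassification <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   na.strings = "NA")
  .assertColumns(df, names(.CLASS_COLS), "classification table")
  for (nm in names(.CLASS_COLS)) {
    df[[nm]] <- switch(.CLASS_COLS[[nm]],
                       integer = as.integer(df[[nm]]),
                       logical = as.logical(df[[nm]]),
                       df[[nm]])
  }
  df
}
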