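#' @import methods
#' @importFrom Biostrings AAStringSet
NULL

#' Screening thresholds
#'
#' Bundles every tunable cutoff of the screen. Defaults reproduce the
#' published procedure: a five-gene neighborhood on either side of an OPX
#' gene, a 280-aa inclusive size cutoff for short OPX proteins, a
#' C-terminal helix rule evaluated over the last 20 residues (more than
#' nine helical residues, at most one non-helical gap of at most two
#' residues), a minimum of 16 beta-strands plus outer-membrane
#' localization for a verified barrel, 90% identity for redundancy
#' removal, and the pulldown enrichment rule (peptide count >= 3 in every
#' replicate, log2 fold change >= 3, P <= 0.001).
#'
#' @slot windowGenes integer, neighborhood half-width in gene ranks.
#' @slot shortCutoffAa integer, inclusive upper length bound (aa) for
#'   "short" OPX proteins.
#' @slot helixWindowAa integer, C-terminal window (aa) scanned for a helix.
#' @slot helixMinResidues integer, minimum helical residues in a
#'   qualifying segment ("more than nine" = 10).
#' @slot helixMaxGaps integer, maximum number of non-helical gaps allowed
#'   inside a qualifying segment.
#' @slot helixMaxGapLen integer, maximum length (aa) of each gap.
#' @slot minStrands integer, minimum beta-strand count of a verified barrel.
#' @slot clusterIdentity numeric in (0,1], identity threshold for greedy
#'   clustering.
#' @slot enrichMinPeptides integer, minimum peptide count per replicate.
#' @slot enrichMinLog2fc numeric, minimum log2 fold change for enrichment.
#' @slot enrichMaxP numeric, maximum Welch-test P value for enrichment.
#'
#' @seealso [screenThresholds()]
#' @exportClass ScreenThresholds
setClass("ScreenThresholds",
  representation(
    windowGenes       = "integer",
    shortCutoffAa     = "integer",
    helixWindowAa     = "integer",
    helixMinResidues  = "integer",
    helixMaxGaps      = "integer",
    helixMaxGapLen    = "integer",
    minStrands        = "integer",
    clusterIdentity   = "numeric",
    enrichMinPeptides = "integer",
    enrichMinLog2fc   = "numeric",
    enrichMaxP        = "numeric"),
  prototype(
    windowGenes       = 5L,
    shortCutoffAa     = 280L,
    helixWindowAa     = 20L,
    helixMinResidues  = 10L,
    helixMaxGaps      = 1L,
    helixMaxGapLen    = 2L,
    minStrands        = 16L,
    clusterIdentity   = 0.90,
    enrichMinPeptides = 3L,
    enrichMinLog2fc   = 3.0,
    enrichMaxP        = 0.001))

setValidity("ScreenThresholds", function(object) {
  msgs <- character()
  for (s in slotNames(object)) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v)) msgs <- c(msgs, paste0(s, " must be a single non-NA value"))
    else if (v <= 0 && s != "helixMaxGaps") msgs <- c(msgs, paste0(s, " must be positive"))
    else if (v < 0) msgs <- c(msgs, paste0(s, " must be non-negative"))
  }
  ci <- object@clusterIdentity
  if (length(ci) == 1L && !is.na(ci) && (ci <= 0 || ci > 1))
    msgs <- c(msgs, "clusterIdentity must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ScreenThresholds object
#'
#' @param windowGenes,shortCutoffAa,helixWindowAa,helixMinResidues,helixMaxGaps,helixMaxGapLen,minStrands,clusterIdentity,enrichMinPeptides,enrichMinLog2fc,enrichMaxP
#'   see the class documentation; defaults are the published values.
#' @return A [ScreenThresholds-class] object.
#' @examples
#' screenThresholds()
#' screenThresholds(windowGenes = 10)
#' @export
screenThresholds <- function(windowGenes = 5L, shortCutoffAa = 280L,
                             helixWindowAa = 20L, helixMinResidues = 10L,
                             helixMaxGaps = 1L, helixMaxGapLen = 2L,
                             minStrands = 16L, clusterIdentity = 0.90,
                             enrichMinPeptides = 3L, enrichMinLog2fc = 3.0,
                             enrichMaxP = 0.001) {
  new("ScreenThresholds",
      windowGenes = as.integer(windowGenes),
      shortCutoffAa = as.integer(shortCutoffAa),
      helixWindowAa = as.integer(helixWindowAa),
      helixMinResidues = as.integer(helixMinResidues),
      helixMaxGaps = as.integer(helixMaxGaps),
      helixMaxGapLen = as.integer(helixMaxGapLen),
      minStrands = as.integer(minStrands),
      clusterIdentity = as.numeric(clusterIdentity),
      enrichMinPeptides = as.integer(enrichMinPeptides),
      enrichMinLog2fc = as.numeric(enrichMinLog2fc),
      enrichMaxP = as.numeric(enrichMaxP))
}

#' Input container for a polysaccharide-export screen
#'
#' Holds every annotation table the pipeline consumes: per-genome gene
#' tables with contiguous 0-based gene ranks per contig, a protein table
#' (lengths, optional taxon), optional amino-acid sequences, domain hits,
#' 3-state secondary-structure strings, beta-barrel topology calls, and
#' (for synthetic screens) the planted ground truth.
#'
#' @slot genes data.frame with columns genome_id, contig_id, gene_id,
#'   start, end, strand, protein_id, rank.
#' @slot proteins data.frame with columns protein_id, length and optional
#'   taxon.
#' @slot sequences [Biostrings::AAStringSet] named by protein_id; may
#'   cover only a subset of proteins.
#' @slot hits data.frame with columns protein_id, domain_acc, score,
#'   meets_threshold.
#' @slot ss data.frame with columns protein_id, ss (strings over H/E/C).
#' @slot topology data.frame with columns protein_id, strand_count,
#'   localization (OM/other/unknown).
#' @slot truth data.frame of planted-system labels (may have zero rows).
#' @slot metadata list (e.g. generator seed and parameters).
#'
#' @seealso [PolysaccharideScreen()], [simulateScreen()], [runScreen()]
#' @exportClass PolysaccharideScreen
setClass("PolysaccharideScreen",
  representation(
    genes     = "data.frame",
    proteins  = "data.frame",
    sequences = "AAStringSet",
    hits      = "data.frame",
    ss        = "data.frame",
    topology  = "data.frame",
    truth     = "data.frame",
    metadata  = "list"))

setValidity("PolysaccharideScreen", function(object) {
  msgs <- character()
  g <- object@genes
  need <- c("genome_id", "contig_id", "gene_id", "start", "end", "strand",
            "protein_id", "rank")
  miss <- setdiff(need, names(g))
  if (length(miss))
    return(paste("genes table missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(g)) {
    if (any(g$start > g$end)) msgs <- c(msgs, "genes with start > end")
    if (anyDuplicated(g$gene_id)) msgs <- c(msgs, "duplicate gene_id in genes table")
    bad <- vapply(split(g$rank, paste(g$genome_id, g$contig_id, sep = "\r")),
                  function(r) !identical(sort(r), seq_along(r) - 1L), logical(1))
    if (any(bad)) msgs <- c(msgs, "gene ranks are not contiguous 0..n-1 within every contig")
  }
  p <- object@proteins
  miss <- setdiff(c("protein_id", "length"), names(p))
  if (length(miss))
    return(paste("proteins table missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(p) && any(p$length < 1)) msgs <- c(msgs, "protein length < 1")
  if (nrow(p) && anyDuplicated(p$protein_id)) msgs <- c(msgs, "duplicate protein_id")
  sq <- object@sequences
  if (length(sq)) {
    if (is.null(names(sq)) || anyNA(names(sq)))
      msgs <- c(msgs, "sequences must be named by protein_id")
    else {
      m <- match(names(sq), p$protein_id)
      if (anyNA(m)) msgs <- c(msgs, "sequences present for unknown protein_id")
      else if (any(Biostrings::width(sq) != p$length[m]))
        msgs <- c(msgs, "sequence width disagrees with protein length")
    }
  }
  h <- object@hits
  miss <- setdiff(c("protein_id", "domain_acc", "meets_threshold"), names(h))
  if (length(miss))
    return(paste("hits table missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(h) && (anyNA(h$domain_acc) || any(!nzchar(h$domain_acc))))
    msgs <- c(msgs, "empty domain accession in hits")
  s <- object@ss
  if (nrow(s)) {
    miss <- setdiff(c("protein_id", "ss"), names(s))
    if (length(miss)) msgs <- c(msgs, "ss table missing protein_id/ss")
    else if (any(grepl("[^HEC]", s$ss))) msgs <- c(msgs, "ss strings contain letters outside {H,E,C}")
  }
  tp <- object@topology
  if (nrow(tp)) {
    miss <- setdiff(c("protein_id", "strand_count", "localization"), names(tp))
    if (length(miss)) msgs <- c(msgs, "topology table missing column(s)")
    else {
      if (any(tp$strand_count < 0, na.rm = TRUE)) msgs <- c(msgs, "negative strand_count")
      if (!all(tp$localization %in% c("OM", "other", "unknown")))
        msgs <- c(msgs, "localization outside {OM, other, unknown}")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PolysaccharideScreen input container
#'
#' @param genes gene table (see [readGeneTable()] for the column contract);
#'   a `rank` column is recomputed if absent.
#' @param proteins protein table with protein_id and length.
#' @param hits domain-hit table; `meets_threshold` defaults to TRUE.
#' @param ss optional secondary-structure table (protein_id, ss).
#' @param topology optional topology table (protein_id, strand_count,
#'   localization).
#' @param sequences optional named [Biostrings::AAStringSet].
#' @param truth optional planted-truth table.
#' @param metadata list of free-form metadata.
#' @return A [PolysaccharideScreen-class] object.
#' @export
PolysaccharideScreen <- function(genes, proteins, hits,
                                 ss = NULL, topology = NULL,
                                 sequences = NULL, truth = NULL,
                                 metadata = list()) {
  if (!"rank" %in% names(genes)) genes <- .assignRanks(genes)
  if (!"score" %in% names(hits)) hits$score <- NA_real_
  if (!"meets_threshold" %in% names(hits)) hits$meets_threshold <- TRUE
  if (!"taxon" %in% names(proteins)) proteins$taxon <- NA_character_
  new("PolysaccharideScreen",
      genes = genes, proteins = proteins, hits = hits,
      ss = ss %||% .df(protein_id = character(), ss = character()),
      topology = topology %||% .df(protein_id = character(),
                                   strand_count = integer(),
                                   localization = character()),
      sequences = if (is.null(sequences)) Biostrings::AAStringSet() else sequences,
      truth = truth %||% .df(),
      metadata = metadata)
}

#' Result container of a full screen
#'
#' @slot opx data.frame, one row per OPX candidate gene with context,
#'   pathway, clustering, helix, coupling and dichotomy annotations.
#' @slot barrels data.frame, one row per (OPX neighborhood, barrel
#'   candidate) pair with verification columns.
#' @slot clusters data.frame mapping members to cluster representatives.
#' @slot helixCalls data.frame of C-terminal helix calls.
#' @slot summary list of headline counts and fractions (see
#'   [summarizeScreen()]).
#' @slot thresholds the [ScreenThresholds-class] used.
#' @seealso [runScreen()]
#' @exportClass OpxScreenResult
setClass("OpxScreenResult",
  representation(
    opx        = "data.frame",
    barrels    = "data.frame",
    clusters   = "data.frame",
    helixCalls = "data.frame",
    summary    = "list",
    thresholds = "ScreenThresholds"))

setValidity("OpxScreenResult", function(object) {
  ok <- TRUE
  b <- object@barrels
  if (nrow(b)) {
    bad <- b$verified & !(b$strand_count >= object@thresholds@minStrands &
                          b$localization == "OM")
    if (any(bad, na.rm = TRUE))
      return("verified barrel violating (strand_count >= minStrands & OM)")
  }
  ok
})
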