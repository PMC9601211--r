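#' Index domain hits by protein
#'
#' Builds a fast lookup (protein_id -> character vector of domain
#' accessions) from a hit table. Only hits with `meets_threshold = TRUE`
#' are indexed: hits below the curated family threshold never count, in
#' detection or in context/barrel searches.
#'
#' @param hits data.frame(protein_id, domain_acc, meets_threshold, ...).
#' @return environment mapping protein_id to accession vectors.
#' @export
hitIndex <- function(hits) {
  .assertColumns(hits, c("protein_id", "domain_acc"), "hit table")
  if (!"meets_threshold" %in% names(hits)) hits$meets_threshold <- TRUE
  hits <- hits[hits$meets_threshold, , drop = FALSE]
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(hits)) {
    sp <- split(hits$domain_acc, hits$protein_id)
    for (nm in names(sp)) assign(nm, unique(sp[[nm]]), envir = idx)
  }
  idx
}

.accsOf <- function(idx, protein_id) {
  if (is.na(protein_id)) return(character(0))
  get0(protein_id, envir = idx, ifnotfound = character(0))
}

#' Find OPX candidate genes from Poly_export domain hits
#'
#' A protein is an OPX candidate if it carries at least one hit to the
#' Poly_export family (PF02563 by default) that meets the family
#' threshold; candidates are deduplicated per protein. Hits referencing
#' proteins absent from the protein table are skipped with a warning.
#'
#' @param hits domain-hit table.
#' @param genes gene table with ranks (see [readGeneTable()]).
#' @param proteins protein table.
#' @param opxAcc accession defining the OPX family.
#' @return data.frame of candidate genes (gene table columns plus
#'   `length`), one row per candidate protein, ordered by genome, contig,
#'   rank.
#' @export
findOpxCandidates <- function(hits, genes, proteins, opxAcc = "PF02563") {
  .assertColumns(hits, c("protein_id", "domain_acc"), "hit table")
  if (!"meets_threshold" %in% names(hits)) hits$meets_threshold <- TRUE
  cand <- unique(hits$protein_id[hits$domain_acc == opxAcc & hits$meets_threshold])
  unknown <- setdiff(cand, proteins$protein_id)
  if (length(unknown)) {
    warning(length(unknown), " OPX hit(s) reference unknown proteins; skipped")
    cand <- setdiff(cand, unknown)
  }
  g <- genes[!is.na(genes$protein_id) & genes$protein_id %in% cand, , drop = FALSE]
  # one candidate per protein: keep the first gene in table order
  g <- g[!duplicated(g$protein_id), , drop = FALSE]
  g$length <- proteins$length[match(g$protein_id, proteins$protein_id)]
  rownames(g) <- NULL
  g
}

#' Extract the gene-rank neighborhood of a focal gene
#'
#' Neighbors are the genes on the focal contig whose rank offset from the
#' focal gene lies in [-k, +k] excluding 0; the neighborhood is truncated
#' at contig ends (or wraps around when `circular = TRUE`). Strand plays
#' no role. Distances are counted in genes, never in base pairs.
#'
#' @param focalGeneId gene id of the focal gene.
#' @param genes gene table with ranks.
#' @param k neighborhood half-width (genes up- and downstream).
#' @param circular treat the focal contig as circular (rank wrap-around).
#' @return list of class `OpxNeighborhood` with elements `focal` (1-row
#'   data.frame) and `neighbors` (gene rows plus an `offset` column,
#'   sorted by ascending offset).
#' @export
extractNeighborhood <- function(focalGeneId, genes, k = 5L, circular = FALSE) {
  i <- match(focalGeneId, genes$gene_id)
  if (is.na(i)) stop("focal gene not found: ", focalGeneId)
  focal <- genes[i, , drop = FALSE]
  contig <- genes[genes$genome_id == focal$genome_id &
                  genes$contig_id == focal$contig_id, , drop = FALSE]
  n <- nrow(contig)
  offs <- setdiff(seq(-k, k), 0L)
  if (circular && n > 1L) {
    ranks <- (focal$rank + offs) %% n
    keep <- !duplicated(ranks) & ranks != focal$rank
    offs <- offs[keep]; ranks <- ranks[keep]
  } else {
    keep <- (focal$rank + offs) >= 0L & (focal$rank + offs) <= (n - 1L)
    offs <- offs[keep]
    ranks <- focal$rank + offs
  }
  nb <- contig[match(ranks, contig$rank), , drop = FALSE]
  nb$offset <- as.integer(offs)
  nb <- nb[order(nb$offset), , drop = FALSE]
  rownames(nb) <- NULL
  structure(list(focal = focal, neighbors = nb), class = "OpxNeighborhood")
}

#' Polysaccharide-context filter
#'
#' TRUE iff at least one neighbor's protein carries at least one hit to a
#' polysaccharide-biosynthesis context domain. Candidates failing this
#' filter are excluded from further analysis.
#'
#' @param nb an `OpxNeighborhood` from [extractNeighborhood()].
#' @param idx a [hitIndex()].
#' @param contextAccs context accessions (default [contextAccessions()]).
#' @return logical scalar.
#' @export
contextFilter <- function(nb, idx, contextAccs = contextAccessions()) {
  stopifnot(length(contextAccs) > 0)
  for (pid in nb$neighbors$protein_id)
    if (any(.accsOf(idx, pid) %in% contextAccs)) return(TRUE)
  FALSE
}

# pathway vote of a single neighbor protein from its context domains:
# "wzx_wzy", "abc", "conflict" (both definitive classes), "pcp" (Wzz
# only) or NA (no context domain)
.neighborVote <- function(accs, contextAccs) {
  ctx <- intersect(accs, contextAccs)
  if (!length(ctx)) return(NA_character_)
  wzx <- any(ctx %in% .WZX_WZY_ACCS)
  abc <- any(ctx %in% .ABC_ACCS)
  if (wzx && abc) "conflict"
  else if (wzx) "wzx_wzy"
  else if (abc) "abc"
  else "pcp"
}

#' Assign an export pathway from the closest context gene
#'
#' The context-domain-bearing neighbor at minimal |rank offset| decides
#' the pathway: Wzy_C, Polysacc_synt or Polysacc_synt3 vote Wzx/Wzy;
#' ABC_tran, ABC2_membrane or Wzt_C vote ABC; a neighbor carrying only
#' Wzz (a polysaccharide copolymerase, PCP) leaves the pathway
#' unassigned (`pcp_unassigned`). Ties at equal distance: if the tied
#' closest neighbors yield exactly one definitive (non-PCP) pathway it is
#' used; two conflicting definitive pathways give `none` with
#' `ambiguous = TRUE`; all-PCP ties give `pcp_unassigned`. `pcp2_context`
#' is TRUE iff some Wzz-bearing neighbor also carries the configured
#' tyrosine-kinase accession (PCP-2 typing).
#'
#' @inheritParams contextFilter
#' @param kinaseAcc tyrosine-kinase accession used for PCP-2 typing.
#' @return list(pathway, pcp2_context, ambiguous, context_gene_id,
#'   context_offset). `pathway` is one of "wzx_wzy", "abc",
#'   "pcp_unassigned", "none".
#' @export
assignPathway <- function(nb, idx, contextAccs = contextAccessions(),
                          kinaseAcc = kinaseAccession()) {
  nbs <- nb$neighbors
  votes <- character(nrow(nbs))
  for (i in seq_len(nrow(nbs)))
    votes[i] <- .neighborVote(.accsOf(idx, nbs$protein_id[i]), contextAccs)
  has_ctx <- !is.na(votes)
  pcp2 <- FALSE
  for (i in which(has_ctx)) {
    accs <- .accsOf(idx, nbs$protein_id[i])
    if (.PCP_ACC %in% accs && kinaseAcc %in% accs) pcp2 <- TRUE
  }
  if (!any(has_ctx))
    return(list(pathway = "none", pcp2_context = FALSE, ambiguous = FALSE,
                context_gene_id = NA_character_, context_offset = NA_integer_))
  d <- min(abs(nbs$offset[has_ctx]))
  closest <- which(has_ctx & abs(nbs$offset) == d)
  v <- votes[closest]
  defin <- unique(unlist(lapply(v, function(x)
    switch(x, wzx_wzy = "wzx_wzy", abc = "abc",
           conflict = c("wzx_wzy", "abc"), character(0)))))
  # report the context gene: the closest one; on a two-sided tie prefer
  # the one that decided the pathway, else downstream
  pick <- function(want) {
    ok <- closest[v %in% want]
    if (!length(ok)) ok <- closest
    ok[order(-sign(nbs$offset[ok]))][1]
  }
  if (length(defin) == 1L) {
    cg <- pick(c(defin, "conflict"))
    list(pathway = defin, pcp2_context = pcp2, ambiguous = FALSE,
         context_gene_id = nbs$gene_id[cg],
         context_offset = nbs$offset[cg])
  } else if (length(defin) >= 2L) {
    cg <- pick(c("wzx_wzy", "abc", "conflict"))
    list(pathway = "none", pcp2_context = pcp2, ambiguous = TRUE,
         context_gene_id = nbs$gene_id[cg],
         context_offset = nbs$offset[cg])
  } else {
    cg <- pick("pcp")
    list(pathway = "pcp_unassigned", pcp2_context = pcp2, ambiguous = FALSE,
         context_gene_id = nbs$gene_id[cg],
         context_offset = nbs$offset[cg])
  }
}
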