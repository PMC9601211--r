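#' Run the full OPX / beta-barrel coupling screen
#'
#' Orchestrates the published procedure end-to-end on a
#' [PolysaccharideScreen-class]: (1) OPX candidate detection from
#' Poly_export hits; (2) five-gene neighborhood construction and the
#' polysaccharide-context filter; (3) pathway assignment from the closest
#' context gene; (4) barrel-partner search and verification plus coupling
#' (evaluated per OPX gene, before clustering); (5) redundancy removal by
#' greedy clustering of candidate sequences at the identity threshold;
#' (6) C-terminal helix scan; (7) dichotomy classification of cluster
#' representatives; (8) summary statistics. Stage order is fixed; the
#' result is deterministic given the input.
#'
#' @param screen a [PolysaccharideScreen-class].
#' @param thresholds a [ScreenThresholds-class].
#' @param contextAccs polysaccharide-context accessions.
#' @param opxAcc OPX family accession.
#' @param barrelAccs barrel-family accessions.
#' @param kinaseAcc tyrosine-kinase accession for PCP-2 typing.
#' @param helixMode see [scanCtermHelix()].
#' @param contextFilterEnabled disable to audit the effect of the context
#'   filter (all candidates pass).
#' @param outDir optional directory; when given, every intermediate table
#'   plus a JSON run summary is written there (see Details).
#' @details With `outDir` set the following files are written:
#'   `opx_classified.tsv` ([writeClassification()] format), `barrels.tsv`,
#'   `clusters.tsv`, `helix_calls.tsv`, `rings.tsv`
#'   ([ringAnnotations()]), `motif_regions.fasta` (the PF02563 hit
#'   envelope per representative when envelope columns are present in the
#'   hit table, otherwise the full representative sequence) and
#'   `run_summary.json` (seed, thresholds, per-stage record counts).
#' @return an [OpxScreenResult-class].
#' @examples
#' sc <- simulateScreen(nGenomes = 2, seed = 42)
#' res <- runScreen(sc)
#' screenSummary(res)$categories
#' @export
runScreen <- function(screen, thresholds = screenThresholds(),
                      contextAccs = contextAccessions(),
                      opxAcc = "PF02563",
                      barrelAccs = barrelAccessions(),
                      kinaseAcc = kinaseAccession(),
                      helixMode = c("h_residues", "span"),
                      contextFilterEnabled = TRUE,
                      outDir = NULL) {
  stopifnot(is(screen, "PolysaccharideScreen"))
  helixMode <- match.arg(helixMode)
  genes <- screen@genes
  proteins <- screen@proteins
  idx <- hitIndex(screen@hits)
  cands <- findOpxCandidates(screen@hits, genes, proteins, opxAcc = opxAcc)
  k <- thresholds@windowGenes

  nc <- nrow(cands)
  context_ok <- logical(nc)
  pathway <- character(nc); ambiguous <- logical(nc); pcp2 <- logical(nc)
  ctx_gene <- rep(NA_character_, nc)
  coupled <- rep(NA, nc)
  partner_g <- rep(NA_character_, nc); partner_p <- rep(NA_character_, nc)
  barrel_rows <- vector("list", nc)
  for (i in seq_len(nc)) {
    nb <- extractNeighborhood(cands$gene_id[i], genes, k = k)
    pass <- contextFilter(nb, idx, contextAccs)
    context_ok[i] <- pass
    if (!pass && contextFilterEnabled) {
      pathway[i] <- "none"
      next
    }
    pw <- assignPathway(nb, idx, contextAccs, kinaseAcc)
    pathway[i] <- pw$pathway
    ambiguous[i] <- pw$ambiguous
    pcp2[i] <- pw$pcp2_context
    ctx_gene[i] <- pw$context_gene_id
    b <- findBarrelCandidates(nb, idx, screen@topology, thresholds, barrelAccs)
    cp <- coupleOpx(b)
    coupled[i] <- cp$coupled
    partner_g[i] <- cp$partner_gene_id
    partner_p[i] <- cp$partner_protein_id
    if (nrow(cp$barrels)) {
      br <- cp$barrels
      br$focal_gene_id <- cands$gene_id[i]
      br$focal_protein_id <- cands$protein_id[i]
      br$focal_length <- cands$length[i]
      barrel_rows[[i]] <- br
    }
  }
  barrels <- if (length(barrel_rows) && any(!vapply(barrel_rows, is.null, logical(1))))
    do.call(rbind, barrel_rows[!vapply(barrel_rows, is.null, logical(1))])
  else .df(protein_id = character(), gene_id = character(), offset = integer(),
           hit_source = character(), strand_count = integer(),
           localization = character(), verified = logical(),
           primary = logical(), focal_gene_id = character(),
           focal_protein_id = character(), focal_length = integer())

  analysed <- if (contextFilterEnabled) context_ok else rep(TRUE, nc)

  # redundancy removal on the context-supported candidates
  sq <- screen@sequences
  with_seq <- cands$protein_id[analysed][cands$protein_id[analysed] %in% names(sq)]
  without_seq <- setdiff(cands$protein_id[analysed], with_seq)
  clusters <- greedyCluster(
    if (length(with_seq)) sq[with_seq] else Biostrings::AAStringSet(),
    threshold = thresholds@clusterIdentity,
    passthrough = without_seq)

  # helix scan for analysed candidates with an SS string
  ssub <- screen@ss[screen@ss$protein_id %in% cands$protein_id[analysed], ,
                    drop = FALSE]
  hx <- if (nrow(ssub)) scanCtermHelix(ssub, thresholds, mode = helixMode)
        else .df(protein_id = character(), has_cterm_helix = logical(),
                 helical_residues_in_window = integer(), gaps_used = integer())

  opx <- .df(protein_id = cands$protein_id, gene_id = cands$gene_id,
             genome_id = cands$genome_id, contig_id = cands$contig_id,
             length = cands$length,
             context_ok = context_ok, pathway = pathway,
             pathway_ambiguous = ambiguous, pcp2_context = pcp2,
             context_gene_id = ctx_gene)
  opx$taxon <- proteins$taxon[match(opx$protein_id, proteins$protein_id)]
  m <- match(opx$protein_id, clusters$member)
  opx$cluster_id <- clusters$cluster_id[m]
  opx$is_representative <- !is.na(m) &
    clusters$representative[m] == opx$protein_id
  opx$short <- opx$length <= thresholds@shortCutoffAa
  opx$cterm_helix <- hx$has_cterm_helix[match(opx$protein_id, hx$protein_id)]
  opx$coupled <- coupled
  opx$partner_gene_id <- partner_g
  opx$partner_protein_id <- partner_p
  opx$category <- rep(NA_character_, nrow(opx))
  cls <- which(opx$is_representative & !is.na(opx$cterm_helix) &
               !is.na(opx$coupled))
  if (length(cls))
    opx$category[cls] <- classifyOpx(opx$length[cls], opx$coupled[cls],
                                     opx$cterm_helix[cls], thresholds)
  skipped <- sum(opx$is_representative, na.rm = TRUE) - length(cls)
  if (skipped > 0)
    message(skipped, " representative(s) lack an SS string or coupling ",
            "call and were not classified")

  summ <- summarizeScreen(opx, barrels, thresholds)
  summ$stages <- list(
    n_genes = nrow(genes), n_proteins = nrow(proteins),
    n_hits = nrow(screen@hits), n_candidates = nc,
    n_context_ok = sum(context_ok), n_analysed = sum(analysed),
    n_clusters = length(unique(clusters$cluster_id)),
    n_helix_calls = nrow(hx), n_barrel_candidates = nrow(barrels),
    n_classified = length(cls))

  res <- new("OpxScreenResult", opx = opx, barrels = barrels,
             clusters = clusters, helixCalls = hx, summary = summ,
             thresholds = thresholds)
  if (!is.null(outDir)) .writeResult(res, screen, outDir)
  res
}

# persist every intermediate table plus the JSON run summary
.writeResult <- function(res, screen, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeClassification(res@opx, file.path(outDir, "opx_classified.tsv"))
  write.table(res@barrels, file.path(outDir, "barrels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  write.table(res@clusters, file.path(outDir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  write.table(res@helixCalls, file.path(outDir, "helix_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  ringAnnotations(res@opx, file.path(outDir, "rings.tsv"))
  .writeMotifRegions(res, screen, file.path(outDir, "motif_regions.fasta"))
  t <- res@thresholds
  run <- list(
    seed = screen@metadata$seed,
    thresholds = stats::setNames(
      lapply(slotNames(t), function(s) slot(t, s)), slotNames(t)),
    stages = res@summary$stages)
  jsonlite::write_json(run, file.path(outDir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

# representative PES-motif regions: the PF02563 hit envelope when
# env_from/env_to are available, else the full sequence
.writeMotifRegions <- function(res, screen, path, opxAcc = "PF02563") {
  reps <- res@opx$protein_id[res@opx$is_representative]
  sq <- screen@sequences
  reps <- reps[reps %in% names(sq)]
  if (!length(reps)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- sq[reps]
  h <- screen@hits
  if (all(c("env_from", "env_to") %in% names(h))) {
    h <- h[h$domain_acc == opxAcc & h$protein_id %in% reps &
           !is.na(h$env_from) & !is.na(h$env_to), , drop = FALSE]
    h <- h[!duplicated(h$protein_id), , drop = FALSE]
    m <- match(names(out), h$protein_id)
    sub <- !is.na(m)
    if (any(sub))
      out[sub] <- Biostrings::subseq(out[sub],
                                     start = h$env_from[m[sub]],
                                     end = pmin(h$env_to[m[sub]],
                                                Biostrings::width(out[sub])))
  }
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Aggregate classified OPX records into headline summary statistics
#'
#' @param opx OPX classification table (see [opxTable()]).
#' @param barrels barrel table (see [barrelTable()]).
#' @param thresholds a [ScreenThresholds-class].
#' @return list with: n_candidates (all OPX-domain candidates),
#'   n_opx_total (context-supported), n_representatives, n_short (short
#'   representatives), n_barrels_verified (unique verified barrel
#'   proteins), categories (named counts over the six dichotomy
#'   categories for representatives), pathways (pathway counts over
#'   representatives), pathways_short_coupled_nohelix (pathway breakdown
#'   within that category), fraction_barrels_coupled_to_short (fraction
#'   of unique verified barrels whose closest in-window OPX gene is
#'   short; omitted when there are no verified barrels),
#'   fraction_barrels_coupled_to_short_representatives (same, counting
#'   only neighborhoods of representative OPX), length_histogram (bin
#'   edges and counts, 20-aa bins over representative lengths),
#'   per_taxon (category counts per taxon label).
#' @export
summarizeScreen <- function(opx, barrels, thresholds = screenThresholds()) {
  rep_rows <- opx[which(opx$is_representative), , drop = FALSE]
  cats <- stats::setNames(integer(length(.CATEGORIES)), .CATEGORIES)
  tb <- table(rep_rows$category[!is.na(rep_rows$category)])
  cats[names(tb)] <- as.integer(tb)
  pw_levels <- c("wzx_wzy", "abc", "pcp_unassigned", "none")
  pws <- stats::setNames(integer(4), pw_levels)
  tb <- table(factor(rep_rows$pathway, levels = pw_levels))
  pws[names(tb)] <- as.integer(tb)
  scn <- rep_rows[!is.na(rep_rows$category) &
                  rep_rows$category == "short_coupled_nohelix", , drop = FALSE]
  pws_scn <- stats::setNames(integer(4), pw_levels)
  tb <- table(factor(scn$pathway, levels = pw_levels))
  pws_scn[names(tb)] <- as.integer(tb)

  out <- list(
    n_candidates = nrow(opx),
    n_opx_total = sum(opx$context_ok, na.rm = TRUE),
    n_representatives = nrow(rep_rows),
    n_short = sum(rep_rows$short, na.rm = TRUE),
    n_barrels_verified = length(unique(barrels$protein_id[barrels$verified])),
    categories = as.list(cats),
    pathways = as.list(pws),
    pathways_short_coupled_nohelix = as.list(pws_scn))

  vb <- barrels[barrels$verified, , drop = FALSE]
  if (nrow(vb)) {
    closestShort <- function(b) {
      sp <- split(seq_len(nrow(b)), b$protein_id)
      mean(vapply(sp, function(ii) {
        i <- ii[which.min(abs(b$offset[ii]))]
        b$focal_length[i] <= thresholds@shortCutoffAa
      }, logical(1)))
    }
    out$fraction_barrels_coupled_to_short <- closestShort(vb)
    vbr <- vb[vb$focal_protein_id %in% rep_rows$protein_id, , drop = FALSE]
    if (nrow(vbr))
      out$fraction_barrels_coupled_to_short_representatives <- closestShort(vbr)
  }
  if (nrow(rep_rows)) {
    edges <- seq(0, 20 * ceiling(max(rep_rows$length) / 20), by = 20)
    out$length_histogram <- list(
      breaks = edges,
      counts = as.integer(graphics::hist(rep_rows$length, breaks = edges,
                                         plot = FALSE)$counts))
    if (!all(is.na(rep_rows$taxon))) {
      pt <- table(rep_rows$taxon,
                  factor(rep_rows$category, levels = .CATEGORIES))
      out$per_taxon <- as.data.frame.matrix(pt)
    }
  }
  out
}

#' Per-representative ring annotation table
#'
#' One row per cluster representative with the classification columns
#' used to annotate a phylogenetic tree of the PES motifs: pathway,
#' coupling, size class and C-terminal helix (the four outer rings),
#' plus the combined dichotomy category. Values are explicit labels,
#' never blank.
#'
#' @param opx OPX classification table.
#' @param path optional output TSV path.
#' @return data.frame(protein_id, pathway, coupled, short, cterm_helix,
#'   category), invisibly written to `path` when given.
#' @export
ringAnnotations <- function(opx, path = NULL) {
  r <- opx[which(opx$is_representative), , drop = FALSE]
  lab <- function(x, yes, no) ifelse(is.na(x), "undetermined",
                                     ifelse(x, yes, no))
  out <- .df(protein_id = r$protein_id,
             pathway = ifelse(is.na(r$pathway), "none", r$pathway),
             coupled = lab(r$coupled, "coupled", "uncoupled"),
             short = lab(r$short, "short", "long"),
             cterm_helix = lab(r$cterm_helix, "helix", "nohelix"),
             category = ifelse(is.na(r$category), "undetermined", r$category))
  rownames(out) <- NULL
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
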