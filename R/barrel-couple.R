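#' Find and verify beta-barrel partner candidates in a neighborhood
#'
#' Every neighbor protein hit by one of the barrel-family accessions (or
#' named in `annotatedBarrels`) becomes a barrel record, then
#' verification is applied: a candidate is `verified` iff its predicted
#' strand count is at least `minStrands` (default 16; barrels with fewer
#' strands are classified false positive) and its localization is the
#' outer membrane. Candidates without a topology annotation get
#' localization "unknown" and `verified = FALSE` (logged).
#'
#' @param nb an `OpxNeighborhood` from [extractNeighborhood()].
#' @param idx a [hitIndex()].
#' @param topology topology table (protein_id, strand_count, localization).
#' @param thresholds a [ScreenThresholds-class].
#' @param barrelAccs accessions marking barrel-family hits
#'   (default [barrelAccessions()]).
#' @param annotatedBarrels protein ids asserted to be barrels by external
#'   annotation (hit_source "annotation").
#' @return data.frame with one row per barrel candidate: protein_id,
#'   gene_id, offset, hit_source, strand_count, localization, verified.
#' @export
findBarrelCandidates <- function(nb, idx, topology,
                                 thresholds = screenThresholds(),
                                 barrelAccs = barrelAccessions(),
                                 annotatedBarrels = character()) {
  nbs <- nb$neighbors
  rows <- list()
  for (i in seq_len(nrow(nbs))) {
    pid <- nbs$protein_id[i]
    if (is.na(pid)) next
    accs <- .accsOf(idx, pid)
    hit <- barrelAccs[barrelAccs %in% accs]
    src <- if (length(hit)) names(barrelAccs)[match(hit[1], barrelAccs)] %||% hit[1]
           else if (pid %in% annotatedBarrels) "annotation"
           else next
    j <- match(pid, topology$protein_id)
    sc <- if (is.na(j)) NA_integer_ else topology$strand_count[j]
    loc <- if (is.na(j)) "unknown" else topology$localization[j]
    if (is.na(j))
      message("no topology for barrel candidate ", pid, "; left unverified")
    rows[[length(rows) + 1L]] <- .df(
      protein_id = pid, gene_id = nbs$gene_id[i], offset = nbs$offset[i],
      hit_source = src, strand_count = sc, localization = loc,
      verified = !is.na(sc) && sc >= thresholds@minStrands && loc == "OM")
  }
  if (!length(rows))
    return(.df(protein_id = character(), gene_id = character(),
               offset = integer(), hit_source = character(),
               strand_count = integer(), localization = character(),
               verified = logical()))
  do.call(rbind, rows)
}

#' Decide coupling of an OPX gene to a verified barrel
#'
#' An OPX gene is coupled iff at least one verified barrel candidate lies
#' in its neighborhood. The partner is the verified barrel closest by
#' |offset|; on a two-sided tie the downstream (positive-offset) one is
#' primary. All verified barrels are returned with a `primary` flag.
#'
#' @param barrels barrel-candidate table from [findBarrelCandidates()].
#' @return list(coupled, partner_gene_id, partner_protein_id, barrels)
#'   where `barrels` carries the added `primary` column.
#' @export
coupleOpx <- function(barrels) {
  if (nrow(barrels)) barrels$primary <- FALSE
  ver <- which(barrels$verified)
  if (!length(ver))
    return(list(coupled = FALSE, partner_gene_id = NA_character_,
                partner_protein_id = NA_character_, barrels = barrels))
  cand <- ver[order(abs(barrels$offset[ver]), -sign(barrels$offset[ver]))]
  best <- cand[1]
  barrels$primary[best] <- TRUE
  list(coupled = TRUE,
       partner_gene_id = barrels$gene_id[best],
       partner_protein_id = barrels$protein_id[best],
       barrels = barrels)
}

.CATEGORIES <- c("short_coupled_nohelix", "short_uncoupled_helix",
                 "short_coupled_helix", "short_uncoupled_nohelix",
                 "long_coupled", "long_uncoupled")

#' Classify an OPX protein into the size/coupling/helix dichotomy
#'
#' Short means length <= `shortCutoffAa` (inclusive, default 280 aa).
#' Short proteins fall into four categories from (coupled, helix); long
#' proteins collapse helix status into long_coupled / long_uncoupled.
#' Vectorized over its first three arguments.
#'
#' @param length protein length(s) in aa.
#' @param coupled logical, coupling call(s).
#' @param helix logical, C-terminal helix call(s).
#' @param thresholds a [ScreenThresholds-class].
#' @return character vector of categories; any NA input is an error
#'   (stage-ordering violation).
#' @examples
#' classifyOpx(217, TRUE, FALSE)   # short_coupled_nohelix
#' classifyOpx(280, FALSE, TRUE)   # short_uncoupled_helix (280 is short)
#' classifyOpx(281, TRUE, FALSE)   # long_coupled
#' @export
classifyOpx <- function(length, coupled, helix,
                        thresholds = screenThresholds()) {
  n <- max(base::length(length), base::length(coupled), base::length(helix))
  length <- rep_len(length, n); coupled <- rep_len(coupled, n)
  helix <- rep_len(helix, n)
  if (anyNA(length) || anyNA(coupled) || anyNA(helix))
    stop("length, coupled and helix must all be determined before classification")
  short <- length <= thresholds@shortCutoffAa
  ifelse(short,
         paste0("short_",
                ifelse(coupled, "coupled_", "uncoupled_"),
                ifelse(helix, "helix", "nohelix")),
         ifelse(coupled, "long_coupled", "long_uncoupled"))
}

#' The six dichotomy categories
#' @return character vector of the category labels in canonical order.
#' @export
dichotomyCategories <- function() .CATEGORIES
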