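#' Peptide-count filter for pulldown tables
#'
#' Removes proteins whose peptide count falls below
#' `enrichMinPeptides` (default 3) in at least one replicate. By default
#' all replicates of both arms are checked (`arms = "both"`); set
#' `arms = "bait"` to require the minimum only in the bait (sample) arm.
#' The filter is idempotent.
#'
#' @param table long-format pulldown table with columns protein_id, arm
#'   ("bait" or "control"), replicate, peptide_count, log2_intensity.
#' @param thresholds a [ScreenThresholds-class].
#' @param arms which replicates the count requirement applies to.
#' @return the filtered table (a subset of the input rows).
#' @export
peptideFilter <- function(table, thresholds = screenThresholds(),
                          arms = c("both", "bait")) {
  arms <- match.arg(arms)
  .assertColumns(table, c("protein_id", "arm", "replicate", "peptide_count"),
                 "pulldown table")
  stopifnot(all(table$arm %in% c("bait", "control")))
  checked <- if (arms == "both") table else table[table$arm == "bait", ]
  ok <- tapply(checked$peptide_count >= thresholds@enrichMinPeptides,
               checked$protein_id, all)
  keep <- names(ok)[ok]
  table[table$protein_id %in% keep, , drop = FALSE]
}

#' Enrichment calls on replicate log2 intensities
#'
#' For each protein computes the log2 fold change (mean bait minus mean
#' control log2 intensity) and a two-sided Welch (unequal-variance) t
#' test across replicates; a protein is `enriched` iff log2fc >=
#' `enrichMinLog2fc` (default 3) and p <= `enrichMaxP` (default 0.001).
#' Proteins with missing intensities in any replicate are dropped with a
#' message. Degenerate zero-variance cases: equal means give p = 1,
#' unequal means give p = 0.
#'
#' @inheritParams peptideFilter
#' @return data.frame(protein_id, log2fc, p, enriched), one row per
#'   protein, ordered by protein_id.
#' @export
callEnriched <- function(table, thresholds = screenThresholds()) {
  .assertColumns(table, c("protein_id", "arm", "replicate", "log2_intensity"),
                 "pulldown table")
  sp <- split(table, table$protein_id)
  dropped <- 0L
  rows <- lapply(names(sp), function(pid) {
    d <- sp[[pid]]
    x <- d$log2_intensity[d$arm == "bait"]
    y <- d$log2_intensity[d$arm == "control"]
    if (length(x) < 2L || length(y) < 2L)
      stop("protein ", pid, ": need >= 2 replicates per arm")
    if (anyNA(x) || anyNA(y)) {
      dropped <<- dropped + 1L
      return(NULL)
    }
    fc <- mean(x) - mean(y)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      p <- if (fc == 0) 1 else 0
    } else {
      p <- stats::t.test(x, y, var.equal = FALSE)$p.value
    }
    .df(protein_id = pid, log2fc = fc, p = p,
        enriched = fc >= thresholds@enrichMinLog2fc & p <= thresholds@enrichMaxP)
  })
  if (dropped)
    message(dropped, " protein(s) with missing intensities dropped")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(.df(protein_id = character(), log2fc = numeric(), p = numeric(),
               enriched = logical()))
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id), ]
  rownames(out) <- NULL
  out
}
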