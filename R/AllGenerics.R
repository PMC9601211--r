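#' @include AllClasses.R
NULL

#' Accessors for screen containers
#'
#' Slot accessors for [PolysaccharideScreen-class] and
#' [OpxScreenResult-class] objects; use these instead of `@`.
#'
#' @param x a screen or result object.
#' @return The corresponding table ([geneTable()], [proteinTable()],
#'   [domainHits()], [ssTable()], [topologyTable()], [truthTable()],
#'   [opxTable()], [barrelTable()], [clusterTable()], [helixCalls()]),
#'   the [Biostrings::AAStringSet] ([proteinSequences()]), the summary
#'   list ([screenSummary()]) or the [ScreenThresholds-class]
#'   ([thresholds()]).
#' @name accessors
#' @aliases geneTable proteinTable domainHits ssTable topologyTable
#'   truthTable proteinSequences opxTable barrelTable clusterTable
#'   helixCalls screenSummary thresholds
NULL

#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname accessors
#' @export
setGeneric("proteinTable", function(x) standardGeneric("proteinTable"))
#' @rdname accessors
#' @export
setGeneric("domainHits", function(x) standardGeneric("domainHits"))
#' @rdname accessors
#' @export
setGeneric("ssTable", function(x) standardGeneric("ssTable"))
#' @rdname accessors
#' @export
setGeneric("topologyTable", function(x) standardGeneric("topologyTable"))
#' @rdname accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setGeneric("proteinSequences", function(x) standardGeneric("proteinSequences"))
#' @rdname accessors
#' @export
setGeneric("opxTable", function(x) standardGeneric("opxTable"))
#' @rdname accessors
#' @export
setGeneric("barrelTable", function(x) standardGeneric("barrelTable"))
#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @rdname accessors
#' @export
setGeneric("helixCalls", function(x) standardGeneric("helixCalls"))
#' @rdname accessors
#' @export
setGeneric("screenSummary", function(x) standardGeneric("screenSummary"))
#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname accessors
setMethod("geneTable", "PolysaccharideScreen", function(x) x@genes)
#' @rdname accessors
setMethod("proteinTable", "PolysaccharideScreen", function(x) x@proteins)
#' @rdname accessors
setMethod("domainHits", "PolysaccharideScreen", function(x) x@hits)
#' @rdname accessors
setMethod("ssTable", "PolysaccharideScreen", function(x) x@ss)
#' @rdname accessors
setMethod("topologyTable", "PolysaccharideScreen", function(x) x@topology)
#' @rdname accessors
setMethod("truthTable", "PolysaccharideScreen", function(x) x@truth)
#' @rdname accessors
setMethod("proteinSequences", "PolysaccharideScreen", function(x) x@sequences)

#' @rdname accessors
setMethod("opxTable", "OpxScreenResult", function(x) x@opx)
#' @rdname accessors
setMethod("barrelTable", "OpxScreenResult", function(x) x@barrels)
#' @rdname accessors
setMethod("clusterTable", "OpxScreenResult", function(x) x@clusters)
#' @rdname accessors
setMethod("helixCalls", "OpxScreenResult", function(x) x@helixCalls)
#' @rdname accessors
setMethod("screenSummary", "OpxScreenResult", function(x) x@summary)
#' @rdname accessors
setMethod("thresholds", "OpxScreenResult", function(x) x@thresholds)

setMethod("show", "ScreenThresholds", function(object) {
  cat("ScreenThresholds\n")
  for (s in slotNames(object))
    cat(sprintf("  %-18s %s\n", s, format(slot(object, s))))
})

setMethod("show", "PolysaccharideScreen", function(object) {
  g <- object@genes
  cat("PolysaccharideScreen\n")
  cat(sprintf("  genomes:   %d\n", length(unique(g$genome_id))))
  cat(sprintf("  contigs:   %d\n", length(unique(paste(g$genome_id, g$contig_id)))))
  cat(sprintf("  genes:     %d\n", nrow(g)))
  cat(sprintf("  proteins:  %d (%d with sequence)\n",
              nrow(object@proteins), length(object@sequences)))
  cat(sprintf("  hits:      %d | ss strings: %d | topology calls: %d\n",
              nrow(object@hits), nrow(object@ss), nrow(object@topology)))
  if (nrow(object@truth))
    cat(sprintf("  planted truth: %d records\n", nrow(object@truth)))
})

setMethod("show", "OpxScreenResult", function(object) {
  s <- object@summary
  cat("OpxScreenResult\n")
  cat(sprintf("  OPX candidates:       %d\n", s$n_candidates %||% nrow(object@opx)))
  cat(sprintf("  context-supported:    %d\n", s$n_opx_total %||% NA))
  cat(sprintf("  representatives:      %d\n", s$n_representatives %||% NA))
  cat(sprintf("  short (<= cutoff):    %d\n", s$n_short %||% NA))
  cat(sprintf("  verified barrels:     %d\n", s$n_barrels_verified %||% NA))
  if (!is.null(s$categories)) {
    cat("  dichotomy categories:\n")
    for (nm in names(s$categories))
      cat(sprintf("    %-24s %d\n", nm, s$categories[[nm]]))
  }
})
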