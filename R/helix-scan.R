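#' Scan secondary-structure strings for a C-terminal alpha-helix
#'
#' Applies the C-terminal helix rule to 3-state (H/E/C) secondary
#' structure: the final `helixWindowAa` residues (default 20) are searched
#' for a qualifying helix segment -- runs of 'H' interrupted by at most
#' `helixMaxGaps` (default 1) non-helical gaps of at most `helixMaxGapLen`
#' (default 2) residues each, totalling at least `helixMinResidues`
#' (default 10, i.e. "more than nine") helical residues. A protein is
#' called positive iff any such segment exists wholly inside the window.
#'
#' Two readings of "extended over more than nine residues" are supported:
#' `mode = "h_residues"` (default) counts helical residues only; `mode =
#' "span"` counts the full segment span including internal gaps. Strings
#' shorter than the window are evaluated whole (with a message). 'E' and
#' 'C' are equally non-helical.
#'
#' @param ss a data.frame with columns protein_id and ss, or a character
#'   vector of H/E/C strings (optionally named by protein id).
#' @param thresholds a [ScreenThresholds-class] object.
#' @param mode segment-size reading, see Details.
#' @return data.frame with one row per input: protein_id,
#'   has_cterm_helix, helical_residues_in_window (helical residues of the
#'   best segment found under the gap constraints), gaps_used (gaps in
#'   that segment).
#' @examples
#' scanCtermHelix(c(strrep("C", 30), paste0(strrep("C", 10), strrep("H", 20))))
#' @export
scanCtermHelix <- function(ss, thresholds = screenThresholds(),
                           mode = c("h_residues", "span")) {
  mode <- match.arg(mode)
  if (is.data.frame(ss)) {
    .assertColumns(ss, c("protein_id", "ss"), "ss table")
    ids <- ss$protein_id
    strs <- ss$ss
  } else {
    strs <- as.character(ss)
    ids <- names(ss) %||% paste0("seq", seq_along(strs))
  }
  if (length(strs) && any(grepl("[^HEC]", strs)))
    stop("secondary-structure strings must use only letters H, E, C")
  w <- thresholds@helixWindowAa
  if (any(nchar(strs) < w))
    message(sum(nchar(strs) < w),
            " string(s) shorter than the scan window; evaluated whole")
  win <- substr(strs, pmax(1L, nchar(strs) - w + 1L), nchar(strs))
  res <- lapply(win, .scanWindow,
                minH = thresholds@helixMinResidues,
                maxGaps = thresholds@helixMaxGaps,
                maxGapLen = thresholds@helixMaxGapLen,
                mode = mode)
  out <- .df(protein_id = ids,
             has_cterm_helix = vapply(res, `[[`, logical(1), "positive"),
             helical_residues_in_window = vapply(res, `[[`, integer(1), "h"),
             gaps_used = vapply(res, `[[`, integer(1), "gaps"))
  rownames(out) <- NULL
  out
}

# Evaluate one window. Runs are computed on the binary helical /
# non-helical string (E and C collapse together), so runs strictly
# alternate. Candidate segments combine up to maxGaps+1 consecutive
# H-runs whose intervening gaps are all <= maxGapLen; the best segment
# (largest size measure, then fewest gaps) is reported.
.scanWindow <- function(win, minH, maxGaps, maxGapLen, mode) {
  r <- rle(strsplit(win, "", fixed = TRUE)[[1]] == "H")
  hidx <- which(r$values)
  if (!length(hidx))
    return(list(positive = FALSE, h = 0L, gaps = 0L))
  best_size <- -1L
  best <- list(h = 0L, gaps = 0L)
  nruns <- length(r$lengths)
  for (i in hidx) {
    h <- r$lengths[i]
    span <- r$lengths[i]
    gaps <- 0L
    j <- i
    repeat {
      size <- if (mode == "h_residues") h else span
      if (size > best_size || (size == best_size && gaps < best$gaps)) {
        best_size <- as.integer(size)
        best <- list(h = as.integer(h), gaps = gaps)
      }
      gap_run <- j + 1L
      nxt <- j + 2L
      if (gaps >= maxGaps || nxt > nruns || r$lengths[gap_run] > maxGapLen)
        break
      gaps <- gaps + 1L
      h <- h + r$lengths[nxt]
      span <- span + r$lengths[gap_run] + r$lengths[nxt]
      j <- nxt
    }
  }
  list(positive = best_size >= minH, h = best$h, gaps = best$gaps)
}
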