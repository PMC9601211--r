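# Independent oracles and fixture builders used across test files.
# These deliberately avoid the package's own code paths (rle-based run
# combination, Biostrings alignment, neighborhood indexing) so that
# agreement is a real cross-check.

# --- C-terminal helix rule: exhaustive segment enumeration -------------
# Walks every candidate segment start (each helical run start) and grows
# the segment residue by residue, tracking gap count and gap length.
oracleHelix <- function(s, minH = 10L, maxGaps = 1L, maxGapLen = 2L,
                        window = 20L) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  ch <- ch[max(1L, n - window + 1L):n]
  n <- length(ch)
  for (i in seq_len(n)) {
    if (ch[i] != "H" || (i > 1L && ch[i - 1L] == "H")) next
    h <- 0L; gaps <- 0L; cur <- 0L
    for (j in i:n) {
      if (ch[j] == "H") {
        if (cur > 0L) {
          gaps <- gaps + 1L
          cur <- 0L
          if (gaps > maxGaps) break
        }
        h <- h + 1L
        if (h >= minH) return(TRUE)
      } else {
        cur <- cur + 1L
        if (cur > maxGapLen) break
      }
    }
  }
  FALSE
}

# --- identity: longest-common-subsequence dynamic program --------------
lcsIdentity <- function(a, b) {
  x <- utf8ToInt(a); y <- utf8ToInt(b)
  m <- length(x); n <- length(y)
  stopifnot(m > 0, n > 0)
  prev <- integer(n + 1L)
  for (i in seq_len(m)) {
    cur <- integer(n + 1L)
    for (j in seq_len(n)) {
      cur[j + 1L] <- if (x[i] == y[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[n + 1L] / min(m, n)
}

# fraction of equal positions; sequences must have equal length
positionalIdentity <- function(a, b) {
  x <- utf8ToInt(a); y <- utf8ToInt(b)
  stopifnot(length(x) == length(y))
  mean(x == y)
}

# --- greedy clustering re-implementation over the same sorted order ----
oracleGreedy <- function(seqs, threshold) {
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]
  reps <- character(0)
  assign <- character(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- NA_character_
    for (r in reps) {
      if (lcsIdentity(seqs[[i]], seqs[[r]]) >= threshold) {
        placed <- r
        break
      }
    }
    if (is.na(placed)) {
      reps <- c(reps, names(seqs)[i])
      placed <- names(seqs)[i]
    }
    assign[i] <- placed
  }
  data.frame(member = names(seqs), representative = assign,
             stringsAsFactors = FALSE)
}

# --- pathway assignment: brute-force closest-context re-scan -----------
WZX_ORACLE <- c("PF04932", "PF01943", "PF13440")
ABC_ORACLE <- c("PF00005", "PF01061", "PF14524")
PCP_ORACLE <- "PF02706"

oraclePathway <- function(neighbors, accsOf, kinaseAcc = "PF13614") {
  ctx_accs <- c(WZX_ORACLE, ABC_ORACLE, PCP_ORACLE)
  accs <- lapply(neighbors$protein_id, accsOf)
  has <- vapply(accs, function(a) any(a %in% ctx_accs), logical(1))
  pcp2 <- any(vapply(accs, function(a)
    PCP_ORACLE %in% a && kinaseAcc %in% a, logical(1)))
  if (!any(has))
    return(list(pathway = "none", ambiguous = FALSE, pcp2 = pcp2))
  d <- min(abs(neighbors$offset[has]))
  close <- which(has & abs(neighbors$offset) == d)
  defs <- unique(unlist(lapply(close, function(i) {
    a <- accs[[i]]
    c(if (any(a %in% WZX_ORACLE)) "wzx_wzy",
      if (any(a %in% ABC_ORACLE)) "abc")
  })))
  if (length(defs) == 1L) list(pathway = defs, ambiguous = FALSE, pcp2 = pcp2)
  else if (length(defs) >= 2L) list(pathway = "none", ambiguous = TRUE, pcp2 = pcp2)
  else list(pathway = "pcp_unassigned", ambiguous = FALSE, pcp2 = pcp2)
}

# --- fixture builders --------------------------------------------------
makeGenes <- function(n, genome = "g1", contig = "c1") {
  data.frame(genome_id = genome, contig_id = contig,
             gene_id = sprintf("%s_%s_gene%02d", genome, contig, seq_len(n)),
             start = (seq_len(n) - 1L) * 100L + 1L,
             end = (seq_len(n) - 1L) * 100L + 90L,
             strand = "+",
             protein_id = sprintf("%s_%s_prot%02d", genome, contig, seq_len(n)),
             rank = seq_len(n) - 1L,
             stringsAsFactors = FALSE)
}

makeHits <- function(protein_id, domain_acc, meets_threshold = TRUE) {
  data.frame(protein_id = protein_id, domain_acc = domain_acc,
             score = rep(50, length(protein_id)),
             meets_threshold = rep_len(meets_threshold,
                                       length(protein_id)),
             stringsAsFactors = FALSE)
}

# many random H/E/C strings, cheaply (single paste + substring)
randomSSStrings <- function(n, minLen = 20L, maxLen = 400L,
                            probs = c(H = 0.25, E = 0.3, C = 0.45)) {
  lens <- sample(minLen:maxLen, n, replace = TRUE)
  big <- paste(sample(c("H", "E", "C"), sum(lens), replace = TRUE,
                      prob = probs), collapse = "")
  ends <- cumsum(lens)
  substring(big, ends - lens + 1L, ends)
}

# all 2^len H/C strings of length len, planted at the C terminus after a
# coil prefix that fills the scan window
allBinaryWindows <- function(len = 14L, prefix = 6L) {
  idx <- 0:(2^len - 1L)
  cols <- lapply(seq_len(len) - 1L, function(b)
    ifelse(bitwAnd(idx, bitwShiftL(1L, b)) > 0L, "H", "C"))
  paste0(strrep("C", prefix), do.call(paste0, cols))
}

# a random neighborhood fixture: genes on one contig with a focal gene,
# random context/noise/kinase accession assignments; returns pieces
# needed both by assignPathway and the oracle
randomNeighborhoodCase <- function(case_id, k = 5L) {
  n <- sample(1:12, 1L)
  genes <- makeGenes(n, genome = sprintf("f%06d", case_id))
  focal <- sample(n, 1L)
  pool <- c(WZX_ORACLE, ABC_ORACLE, PCP_ORACLE, "PF13614",
            "PF99901", "PF99902")
  hit_rows <- list()
  for (i in seq_len(n)) {
    if (i == focal || runif(1) > 0.55) next
    accs <- unique(sample(pool, sample(1:3, 1L), replace = TRUE))
    hit_rows[[length(hit_rows) + 1L]] <-
      makeHits(rep(genes$protein_id[i], length(accs)), accs)
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows)
          else makeHits(character(0), character(0))
  list(genes = genes, focal_gene = genes$gene_id[focal], hits = hits, k = k)
}
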