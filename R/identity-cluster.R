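#' Pairwise sequence identity (shorter-sequence denominator)
#'
#' Global alignment identity in the convention of greedy incremental
#' clustering tools: the number of identical aligned positions in a
#' global alignment scored with match +1, mismatch 0 and free linear
#' gaps, divided by the length of the shorter sequence. Symmetric and in
#' [0, 1]. With free gaps the identity count equals the longest common
#' subsequence, which is what the scoring scheme maximizes.
#'
#' @param a,b amino-acid sequences (character scalars or
#'   [Biostrings::AAString]).
#' @return identity fraction in [0, 1].
#' @examples
#' pairwiseIdentity("ACDEFGHIK", "ACDEFGHIV")  # 8/9
#' @export
pairwiseIdentity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  .identityToSet(Biostrings::AAStringSet(a), b)[1]
}

# vectorized identity of one query against a set of subjects
.identityToSet <- function(subjects, query) {
  if (!length(subjects)) return(numeric(0))
  letters <- unique(strsplit(paste0(paste(as.character(subjects), collapse = ""),
                                    query), "", fixed = TRUE)[[1]])
  m <- diag(1, length(letters))
  dimnames(m) <- list(letters, letters)
  aln <- Biostrings::pairwiseAlignment(subjects, query, type = "global",
                                       substitutionMatrix = m,
                                       gapOpening = 0, gapExtension = 0,
                                       scoreOnly = TRUE)
  aln / pmin(Biostrings::width(subjects), nchar(query))
}

#' Greedy incremental clustering at an identity threshold
#'
#' Collapses sequences to representatives the way incremental clustering
#' tools do: sequences are sorted by decreasing length (ties broken by id,
#' ascending); each sequence joins the first existing cluster whose
#' representative it matches at `threshold` identity (see
#' [pairwiseIdentity()]), otherwise it founds a new cluster and becomes
#' its representative. Representatives are therefore always a longest
#' member of their cluster, and the clusters partition the input.
#' No word-filter prefiltering is used; every comparison is an exact
#' alignment.
#'
#' @param sequences named [Biostrings::AAStringSet] (names = protein ids),
#'   or a character vector named by protein id.
#' @param threshold identity threshold in (0, 1], default 0.90.
#' @param passthrough character vector of protein ids without sequences;
#'   each becomes its own singleton cluster (logged).
#' @return data.frame(cluster_id, representative, member,
#'   identity_to_representative), one row per member, ordered by
#'   cluster_id then processing order.
#' @examples
#' sq <- Biostrings::AAStringSet(c(p1 = "MKLVTTT", p2 = "MKLVTTT", p3 = "AAAAAAA"))
#' greedyCluster(sq, threshold = 1.0)
#' @export
greedyCluster <- function(sequences, threshold = 0.90,
                          passthrough = character()) {
  if (is.character(sequences)) sequences <- Biostrings::AAStringSet(sequences)
  stopifnot(threshold > 0, threshold <= 1)
  if (!length(sequences) && !length(passthrough))
    return(.df(cluster_id = integer(), representative = character(),
               member = character(), identity_to_representative = numeric()))
  ids <- names(sequences) %||% character(0)
  if (length(sequences) && (is.null(ids) || anyNA(ids) || anyDuplicated(ids)))
    stop("sequences must have unique names")
  ord <- order(-Biostrings::width(sequences), ids, method = "radix")
  sequences <- sequences[ord]
  ids <- ids[ord]
  rep_idx <- integer(0)           # indices (into sorted order) of representatives
  assign_cluster <- integer(length(ids))
  ident <- numeric(length(ids))
  for (i in seq_along(ids)) {
    if (length(rep_idx)) {
      idents <- .identityToSet(sequences[rep_idx], as.character(sequences[[i]]))
      j <- which(idents >= threshold)
    } else j <- integer(0)
    if (length(j)) {
      assign_cluster[i] <- j[1]
      ident[i] <- idents[j[1]]
    } else {
      rep_idx <- c(rep_idx, i)
      assign_cluster[i] <- length(rep_idx)
      ident[i] <- 1
    }
  }
  out <- .df(cluster_id = assign_cluster,
             representative = ids[rep_idx][assign_cluster],
             member = ids,
             identity_to_representative = ident)
  if (length(passthrough)) {
    message(length(passthrough),
            " protein(s) without sequence kept as singleton clusters")
    extra <- .df(cluster_id = length(rep_idx) + seq_along(passthrough),
                 representative = passthrough,
                 member = passthrough,
                 identity_to_representative = NA_real_)
    out <- rbind(out, extra)
  }
  out <- out[order(out$cluster_id), ]
  rownames(out) <- NULL
  out
}
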