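#' @importFrom Biostrings AAStringSet
NULL

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

.randomAA <- function(n) paste(sample(.AA20, n, replace = TRUE), collapse = "")

# irrelevant accessions used as background domain noise; deliberately
# disjoint from every screened accession so filters must key on identity
.NOISE_ACCS <- sprintf("PF999%02d", 1:20)

.ARCHETYPES <- c("composite", "wza_like", "decoy_opx_no_context",
                 "decoy_barrel_alone", "decoy_barrel_few_strands",
                 "pcp_only_context")

#' Specify a planted export system
#'
#' @param archetype one of "composite" (short OPX, no C-terminal helix,
#'   verified barrel partner in-window), "wza_like" (short OPX with
#'   C-terminal helix, no barrel), "decoy_opx_no_context" (OPX hit but no
#'   polysaccharide context in-window), "decoy_barrel_alone" (verified-
#'   quality barrel gene with no OPX nearby), "decoy_barrel_few_strands"
#'   (OPX whose only barrel neighbor has 14 strands, just below the
#'   verification cutoff), "pcp_only_context" (OPX whose only context
#'   gene is a Wzz-domain PCP).
#' @param count plants per genome.
#' @return list of class `PlantSpec`.
#' @export
plantSpec <- function(archetype = .ARCHETYPES, count = 1L) {
  archetype <- match.arg(archetype)
  stopifnot(count >= 0)
  structure(list(archetype = archetype, count = as.integer(count)),
            class = "PlantSpec")
}

#' Default plant configuration: one system of every archetype per genome
#' @return list of [plantSpec()] objects.
#' @export
defaultPlantSpecs <- function() lapply(.ARCHETYPES, plantSpec, count = 1L)

#' Generate a secondary-structure string with a controlled C-terminal helix
#'
#' Builds an H/E/C string of the requested length whose C-terminal window
#' passes the helix rule iff `withCtermHelix`; the constructed string is
#' verified against [scanCtermHelix()] before being returned. Negative
#' strings use only helical runs shorter than the minimum separated by
#' gaps longer than the allowed gap length, so no qualifying segment can
#' be formed.
#'
#' @param length protein length in residues; must be at least the scan
#'   window.
#' @param withCtermHelix logical.
#' @param seed optional integer seed (RNG state is restored).
#' @param thresholds a [ScreenThresholds-class].
#' @return a single secondary-structure string.
#' @export
generateSS <- function(length, withCtermHelix, seed = NULL,
                       thresholds = screenThresholds()) {
  w <- thresholds@helixWindowAa
  if (length < w)
    stop("length must be >= the helix scan window (", w, ")")
  withSeed(seed, {
    for (try in 1:50) {
      sstr <- paste0(.randomSSPrefix(length - w), .ssWindow(withCtermHelix, thresholds))
      call <- scanCtermHelix(sstr, thresholds)$has_cterm_helix
      if (identical(call, withCtermHelix)) return(sstr)
    }
    stop("could not construct a secondary-structure string matching the ",
         "requested helix flag under these thresholds")
  })
}

.randomSSPrefix <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("H", "E", "C"), n, replace = TRUE, prob = c(0.2, 0.3, 0.5)),
        collapse = "")
}

.nonH <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("E", "C"), n, replace = TRUE), collapse = "")
}

.ssWindow <- function(positive, t) {
  w <- t@helixWindowAa
  minH <- t@helixMinResidues
  if (positive) {
    split_it <- t@helixMaxGaps >= 1L && stats::runif(1) < 0.5 && minH >= 2L
    if (split_it) {
      g <- sample(seq_len(t@helixMaxGapLen), 1L)
      nH <- sample(minH:max(minH, w - g - 1L), 1L)
      nH <- min(nH, w - g)
      a <- sample(seq_len(nH - 1L), 1L)
      core <- paste0(strrep("H", a), .nonH(g), strrep("H", nH - a))
    } else {
      nH <- sample(minH:w, 1L)
      core <- strrep("H", nH)
    }
    pad <- w - nchar(core)
    left <- if (pad > 0L) sample(0:pad, 1L) else 0L
    paste0(.nonH(left), core, .nonH(pad - left))
  } else {
    # H runs too short to qualify alone, gaps too long to be bridged
    maxRun <- min(4L, minH - 1L)
    gapLen <- t@helixMaxGapLen + 1L
    out <- character(0)
    len <- 0L
    while (len < w) {
      g <- sample(gapLen:(gapLen + 2L), 1L)
      out <- c(out, .nonH(g)); len <- len + g
      if (len >= w) break
      h <- sample(0:maxRun, 1L)
      out <- c(out, strrep("H", h)); len <- len + h
    }
    substr(paste(out, collapse = ""), 1L, w)
  }
}

#' Generate a family of point-mutated protein sequences
#'
#' Draws a random parent of `parentLength` residues and returns
#' `nMembers` independent copies in which each position is substituted
#' (to a different residue) with probability `substitutionRate`; the
#' expected positional identity of each member to the parent is
#' 1 - substitutionRate. Used to exercise identity clustering.
#'
#' @param parentLength parent length in aa.
#' @param nMembers number of members.
#' @param substitutionRate per-position substitution probability in [0, 1).
#' @param seed optional integer seed.
#' @param prefix id prefix for member names.
#' @param includeParent also return the unmutated parent as member
#'   `<prefix>_m00` (so that, all lengths being equal, it sorts first and
#'   founds the cluster in [greedyCluster()]).
#' @return named [Biostrings::AAStringSet] of the members; the parent is
#'   attached as `attr(, "parent")`.
#' @export
generateFamily <- function(parentLength, nMembers, substitutionRate,
                           seed = NULL, prefix = "fam",
                           includeParent = FALSE) {
  stopifnot(substitutionRate >= 0, substitutionRate < 1, parentLength >= 1)
  withSeed(seed, {
    parent <- sample(.AA20, parentLength, replace = TRUE)
    members <- vapply(seq_len(nMembers), function(i) {
      mut <- stats::runif(parentLength) < substitutionRate
      m <- parent
      if (any(mut))
        m[mut] <- vapply(parent[mut], function(aa)
          sample(setdiff(.AA20, aa), 1L), "")
      paste(m, collapse = "")
    }, "")
    names(members) <- sprintf("%s_m%02d", prefix, seq_len(nMembers))
    if (includeParent) {
      members <- c(stats::setNames(paste(parent, collapse = ""),
                                   sprintf("%s_m00", prefix)), members)
    }
    out <- Biostrings::AAStringSet(members)
    attr(out, "parent") <- paste(parent, collapse = "")
    out
  })
}

#' Simulate a genome screen with planted export systems
#'
#' Generates `nGenomes` single-contig genome annotations of
#' `genesPerContig` genes each, plants the requested export-system
#' archetypes with ground-truth labels, and returns a complete
#' [PolysaccharideScreen-class] plus truth table. Each OPX-forming plant
#' occupies its own non-overlapping neighborhood block of `2k + 1` genes
#' (k = `windowGenes`), so planted systems never contaminate one
#' another's windows; `decoy_barrel_alone` genes are placed more than `k`
#' genes away from every planted OPX. Background genes carry no screened
#' domain; a `noiseRate` fraction of them carry an irrelevant accession
#' so that filters must key on accession identity, not hit presence.
#'
#' Planted OPX lengths are drawn from 150-250 aa (under the 280-aa
#' cutoff); background protein lengths from a 50/50 mixture of 150-250
#' and 350-800 aa, straddling the cutoff. Composite and few-strand-decoy
#' systems draw their pathway context uniformly from the definitive
#' Wzx/Wzy and ABC context domains; `pcp_only_context` plants a Wzz gene.
#' Verified-quality barrels get 16-18 strands and OM localization; the
#' few-strand decoy gets 14 strands (just below the cutoff) and OM.
#'
#' @param nGenomes number of genomes (>= 1).
#' @param genesPerContig genes per (single-contig) genome.
#' @param plants list of [plantSpec()]s; counts are per genome.
#' @param seed integer seed; output is deterministic given the seed.
#' @param thresholds a [ScreenThresholds-class].
#' @param noiseRate fraction of background genes carrying an irrelevant
#'   domain hit.
#' @return a [PolysaccharideScreen-class]; the planted labels are in
#'   [truthTable()] (columns gene_id, genome_id, protein_id, archetype,
#'   partner_gene_id, pathway, cterm_helix, length_class, category).
#' @examples
#' sc <- simulateScreen(nGenomes = 2, seed = 7)
#' table(truthTable(sc)$archetype)
#' @export
simulateScreen <- function(nGenomes = 50L, genesPerContig = 60L,
                           plants = defaultPlantSpecs(), seed = 1L,
                           thresholds = screenThresholds(),
                           noiseRate = 0.10) {
  stopifnot(nGenomes >= 1L)
  k <- thresholds@windowGenes
  block <- 2L * k + 1L
  counts <- integer(length(.ARCHETYPES))
  names(counts) <- .ARCHETYPES
  for (p in plants) counts[p$archetype] <- counts[p$archetype] + p$count
  focal_arch <- setdiff(.ARCHETYPES, "decoy_barrel_alone")
  nFocal <- sum(counts[focal_arch])
  nBlocks <- genesPerContig %/% block
  if (nFocal > nBlocks)
    stop("planted systems exceed contig capacity: ", nFocal,
         " focal plants need ", nFocal * block, " genes, contig has ",
         genesPerContig)
  withSeed(seed, {
    genes <- vector("list", nGenomes)
    prot <- vector("list", nGenomes)
    hit <- vector("list", nGenomes)
    ssl <- vector("list", nGenomes)
    topo <- vector("list", nGenomes)
    truth <- vector("list", nGenomes)
    seqs <- list()
    for (g in seq_len(nGenomes)) {
      gid <- sprintf("gen%03d", g)
      ctg <- sprintf("%s_ctg1", gid)
      n <- genesPerContig
      gene_id <- sprintf("%s_g%04d", gid, seq_len(n))
      protein_id <- sprintf("%s_p%04d", gid, seq_len(n))
      glen <- ifelse(stats::runif(n) < 0.5,
                     sample(150:250, n, replace = TRUE),
                     sample(350:800, n, replace = TRUE))
      gtab <- .df(genome_id = gid, contig_id = ctg, gene_id = gene_id,
                  start = (seq_len(n) - 1L) * 1000L + 1L,
                  end = (seq_len(n) - 1L) * 1000L + 900L,
                  strand = sample(c("+", "-"), n, replace = TRUE),
                  protein_id = protein_id,
                  rank = seq_len(n) - 1L)
      hrows <- list()
      srows <- list()
      trows <- list()
      xrows <- list()
      planted <- logical(n)  # gene carries a planted role
      # assign focal archetypes to shuffled blocks
      foci <- integer(0)
      arche_list <- rep(focal_arch, counts[focal_arch])
      if (length(arche_list)) {
        bl <- sample(nBlocks, length(arche_list))
        foci <- (bl - 1L) * block + k  # 0-based focal ranks
      }
      addHit <- function(pid, acc) hrows[[length(hrows) + 1L]] <<-
        .df(protein_id = pid, domain_acc = acc, score = round(stats::runif(1, 30, 300), 1),
            meets_threshold = TRUE)
      addTopo <- function(pid, strands, loc) trows[[length(trows) + 1L]] <<-
        .df(protein_id = pid, strand_count = strands, localization = loc)
      for (ai in seq_along(arche_list)) {
        arch <- arche_list[ai]
        f <- foci[ai] + 1L  # 1-based index of focal gene
        planted[f] <- TRUE
        opx_len <- sample(150:250, 1L)
        glen[f] <- opx_len
        addHit(protein_id[f], "PF02563")
        has_helix <- arch == "wza_like"
        srows[[length(srows) + 1L]] <- .df(
          protein_id = protein_id[f],
          ss = generateSS(opx_len, has_helix, thresholds = thresholds))
        seqs[[protein_id[f]]] <- .randomAA(opx_len)
        ctx_gene <- NA_character_
        partner <- NA_character_
        pathway <- "none"
        offs <- sample(setdiff(seq(-k, k), 0L))
        if (arch %in% c("composite", "wza_like", "decoy_barrel_few_strands")) {
          co <- offs[1L]
          ci <- f + co
          planted[ci] <- TRUE
          pw <- sample(c("wzx_wzy", "abc"), 1L)
          acc <- if (pw == "wzx_wzy") sample(.WZX_WZY_ACCS, 1L) else sample(.ABC_ACCS, 1L)
          addHit(protein_id[ci], acc)
          ctx_gene <- gene_id[ci]
          pathway <- pw
        } else if (arch == "pcp_only_context") {
          co <- offs[1L]
          ci <- f + co
          planted[ci] <- TRUE
          addHit(protein_id[ci], .PCP_ACC)
          ctx_gene <- gene_id[ci]
          pathway <- "pcp_unassigned"
        }
        if (arch %in% c("composite", "decoy_barrel_few_strands")) {
          bo <- offs[2L]
          bi <- f + bo
          planted[bi] <- TRUE
          addHit(protein_id[bi], sample(unname(barrelAccessions()), 1L))
          strands <- if (arch == "composite") sample(16:18, 1L) else 14L
          addTopo(protein_id[bi], strands, "OM")
          if (arch == "composite") partner <- gene_id[bi]
        }
        category <- switch(arch,
          composite = "short_coupled_nohelix",
          wza_like = "short_uncoupled_helix",
          decoy_barrel_few_strands = "short_uncoupled_nohelix",
          pcp_only_context = "short_uncoupled_nohelix",
          decoy_opx_no_context = NA_character_)
        xrows[[length(xrows) + 1L]] <- .df(
          gene_id = gene_id[f], genome_id = gid, protein_id = protein_id[f],
          archetype = arch, partner_gene_id = partner,
          pathway = if (arch == "decoy_opx_no_context") "none" else pathway,
          cterm_helix = has_helix, length_class = "short",
          category = category)
      }
      # lone barrels: anywhere > k ranks from every focal, on unplanted genes
      nAlone <- counts[["decoy_barrel_alone"]]
      if (nAlone > 0L) {
        ok <- which(!planted)
        if (length(foci))
          ok <- ok[vapply(ok, function(i) all(abs((i - 1L) - foci) > k), logical(1))]
        if (length(ok) < nAlone)
          stop("no room for decoy_barrel_alone plants outside OPX windows")
        pick <- if (length(ok) == 1L) ok else sample(ok, nAlone)
        for (i in pick) {
          planted[i] <- TRUE
          addHit(protein_id[i], sample(unname(barrelAccessions()), 1L))
          addTopo(protein_id[i], 18L, "OM")
        }
      }
      # background noise: irrelevant accessions on a fraction of the rest
      bg <- which(!planted)
      noisy <- bg[stats::runif(length(bg)) < noiseRate]
      for (i in noisy) addHit(protein_id[i], sample(.NOISE_ACCS, 1L))
      genes[[g]] <- gtab
      prot[[g]] <- .df(protein_id = protein_id, length = as.integer(glen),
                       taxon = sprintf("taxon%02d", (g - 1L) %% 10L + 1L))
      hit[[g]] <- if (length(hrows)) do.call(rbind, hrows) else NULL
      ssl[[g]] <- if (length(srows)) do.call(rbind, srows) else NULL
      topo[[g]] <- if (length(trows)) do.call(rbind, trows) else NULL
      truth[[g]] <- if (length(xrows)) do.call(rbind, xrows) else NULL
    }
    comb <- function(l, empty) if (any(!vapply(l, is.null, logical(1))))
      do.call(rbind, l[!vapply(l, is.null, logical(1))]) else empty
    sq <- Biostrings::AAStringSet(unlist(seqs))
    PolysaccharideScreen(
      genes = do.call(rbind, genes),
      proteins = do.call(rbind, prot),
      hits = comb(hit, .df(protein_id = character(), domain_acc = character(),
                           score = numeric(), meets_threshold = logical())),
      ss = comb(ssl, NULL),
      topology = comb(topo, NULL),
      sequences = sq,
      truth = comb(truth, NULL),
      metadata = list(seed = as.integer(seed), nGenomes = nGenomes,
                      genesPerContig = genesPerContig,
                      noiseRate = noiseRate,
                      plants = stats::setNames(as.list(counts), names(counts))))
  })
}
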