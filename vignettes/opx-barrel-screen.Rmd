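---
title: "Screening genomes for short OPX proteins coupled to outer-membrane beta-barrels"
author: "OpxScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genomes for short OPX proteins coupled to outer-membrane beta-barrels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OpxScreen)
```

## The biological question

Gram-negative bacteria export capsular and biofilm polysaccharides across
the outer membrane (OM) by two canonical routes: an OPX protein
(outer-membrane polysaccharide export, Wza-like) whose C-terminal
α-helical barrel spans the OM, used by Wzx/Wzy- and ABC
transporter-dependent pathways; or a 16-18-stranded OM β-barrel, used by
synthase-dependent pathways. A third, composite architecture exists:
a *short, periplasmic* OPX protein that lacks the OM-spanning helical
domain works together with a dedicated OM β-barrel translocon encoded
nearby in the same gene cluster. Because the partnership is genetic —
the two genes sit within a few genes of each other — it can be detected
from genome annotation alone.

`OpxScreen` implements that detection end to end as a reusable,
deterministic pipeline:

1. **OPX detection.** Proteins carrying the Poly_export domain
   (Pfam PF02563, the PES motif of the OPX D1 domain) are candidates.
   Hits are consumed from a table (plain TSV or HMMER `--tblout`); hits
   below the family's curated threshold never count.
2. **Context corroboration.** A candidate is kept only if, within five
   genes up- or downstream on its contig, some neighbor carries one of
   seven polysaccharide-biosynthesis Pfam domains (ABC2_membrane,
   ABC_tran, Polysacc_synt, Polysacc_synt3, Wzt_C, Wzy_C, Wzz).
   Distances are counted in *gene ranks* — positions in the gene order
   of the contig — never in base pairs.
3. **Pathway assignment.** The context-bearing neighbor closest by
   |rank offset| decides the pathway: Wzy_C and the flippase-family
   domains (Polysacc_synt, Polysacc_synt3) vote Wzx/Wzy; ABC_tran,
   ABC2_membrane and Wzt_C vote ABC; a neighbor carrying only Wzz (a
   polysaccharide copolymerase, PCP) leaves the pathway unassigned.
   Wzz neighbors that also carry a tyrosine-kinase domain mark a PCP-2
   context.
4. **Redundancy removal.** Candidate sequences are collapsed at 90%
   identity by greedy incremental clustering; all downstream reporting
   is per cluster representative.
5. **C-terminal helix scan.** The last 20 residues of a 3-state
   secondary-structure string are searched for a helix of more than nine
   helical residues containing at most one non-helical gap of at most
   two residues.
6. **Barrel coupling.** Neighbors hit by either barrel-family model (an
   EpsX/ExoB-homolog HMM and a VpsM-orthology HMM, consumed as hit
   accessions) are barrel candidates; a candidate is *verified* only
   with at least 16 predicted β-strands and OM localization. An OPX gene
   is *coupled* when a verified barrel lies in its window.
7. **Dichotomy classification.** Representatives of length ≤ 280 aa
   (inclusive) are "short" and fall into four categories from the
   (coupled, helix) pair; longer proteins collapse into
   `long_coupled` / `long_uncoupled`. The biologically salient split is
   `short_coupled_nohelix` (composite translocon candidates) versus
   `short_uncoupled_helix` (Wza-like proteins).

The companion decision rule from interaction proteomics — peptide count
at least 3 in every replicate, log2 fold change at least 3, Welch-test
P at most 0.001 — is implemented in `peptideFilter()` / `callEnriched()`.

## A worked run

```{r}
sc <- simulateScreen(nGenomes = 10, seed = 1)
sc
res <- runScreen(sc)
res
unlist(screenSummary(res)$categories)
```

On synthetic data every planted system is recovered and the recovered
categories can be checked record by record against `truthTable(sc)`.

## Tunable thresholds

All cutoffs live in a single `ScreenThresholds` object:

| parameter | default | unit | meaning |
|---|---|---|---|
| `windowGenes` | 5 | genes | neighborhood half-width either side of the OPX gene |
| `shortCutoffAa` | 280 | aa | inclusive upper bound for "short" OPX proteins |
| `helixWindowAa` | 20 | aa | C-terminal window scanned for a helix |
| `helixMinResidues` | 10 | aa | minimum helical residues ("more than nine") |
| `helixMaxGaps` | 1 | — | non-helical gaps allowed inside a segment |
| `helixMaxGapLen` | 2 | aa | maximum length of each gap |
| `minStrands` | 16 | strands | minimum β-strand count of a verified barrel |
| `clusterIdentity` | 0.90 | fraction | greedy clustering threshold |
| `enrichMinPeptides` | 3 | peptides | per-replicate minimum in pulldowns |
| `enrichMinLog2fc` | 3 | log2 | minimum fold change for enrichment |
| `enrichMaxP` | 0.001 | — | maximum Welch P for enrichment |

## Design choices in detail

Several points of the procedure are underdetermined by its verbal
description; the package fixes them as follows, and flags each where it
matters.

**Helix extent.** "Extended over more than nine residues" is read as
*ten or more helical (H) residues*, not a ten-residue span including
gaps. Counting H residues is the stricter and more reproducible reading
(a segment of 5 H + 2-residue gap + 4 H spans 11 residues but contains
only 9 helical ones and is called negative). The span reading remains
available via `scanCtermHelix(mode = "span")`. Similarly, "not more
than one gap of two residues" is read as *at most one gap of length at
most two* — a one-residue gap also counts as a gap; a rule that allowed
two-residue gaps but forbade one-residue gaps would be incoherent.
Qualifying segments must lie wholly inside the 20-residue window;
helices beginning upstream contribute only their in-window residues.
'E' and 'C' are equally non-helical.

**Identity convention.** Pairwise identity is the number of identical
aligned positions in a global alignment with free gaps, divided by the
*shorter* sequence length — the convention of greedy incremental
clustering tools. With free gaps the identity count equals the longest
common subsequence, so the implementation scores match = 1, mismatch =
0, gap = 0 and divides by the shorter length. No word-filter heuristics
are used: at the scale this package targets, exact all-vs-representative
comparison is affordable and far easier to verify. Results on borderline
pairs may therefore differ from heuristic tools.

**Pathway ties.** The closest-gene rule is silent on ties. When context
genes sit at equal distance on both sides: exactly one definitive
(non-PCP) pathway among them wins; two conflicting definitive pathways
give `none` with an `ambiguous` flag (silent misassignment would be
worse than an explicit flag); all-PCP ties leave the pathway
unassigned. The flippase-family domains Polysacc_synt/Polysacc_synt3
vote Wzx/Wzy because Wzx flippases belong to Wzx/Wzy pathways. The
tyrosine-kinase accession used for PCP-2 typing is configurable
(`kinaseAcc`, default "PF13614" as a BY-kinase-family placeholder)
because no single canonical accession exists for it.

**Coupling bookkeeping.** Coupling is evaluated per OPX gene before
clustering; a representative then carries its own gene's coupling. The
partner is the closest verified barrel, with two-sided ties resolved
downstream; all verified barrels of a neighborhood are retained in the
barrel table with one flagged primary. The 280-aa cutoff is inclusive.
Helix status of long proteins is retained in the record but not in the
category, since the dichotomy concerns the short set only.

**Enrichment statistics.** The stated test is Welch's unequal-variance
t test on replicate log2 intensities, and that is what `callEnriched()`
computes; moderated-variance alternatives are deliberately not
implemented. Proteins with missing intensities in any used replicate
are dropped (with a message) rather than imputed. Degenerate
zero-variance tables get p = 1 for equal means and p = 0 otherwise. The
peptide-count filter applies to all replicates of both arms by default;
`arms = "bait"` restricts it, since the verbal rule ("in at least one
sample replicate") admits both readings.

## What the synthetic generator emulates — and what it does not

`simulateScreen()` produces single-contig genome annotations with six
plantable archetypes: `composite` (short OPX, no C-terminal helix,
verified barrel in-window), `wza_like` (short OPX with helix, no
barrel), `pcp_only_context` (OPX whose only context gene is Wzz), and
three decoys that each violate exactly one rule —
`decoy_opx_no_context` (no context in-window),
`decoy_barrel_few_strands` (partner barrel with 14 strands, just below
the 16-strand cutoff, to stress the boundary), and
`decoy_barrel_alone` (verified-quality barrel with no OPX within the
window).

Numerical choices: each OPX-forming plant occupies its own block of
`2k + 1` genes so planted systems cannot contaminate one another's
neighborhoods (a 60-gene contig with window 5 holds five such blocks
plus a tail for lone barrels; over-planting errors out). Planted OPX
lengths are uniform on 150-250 aa; background protein lengths come from
a 50/50 mixture of 150-250 and 350-800 aa so that the population
straddles the 280-aa cutoff with two modes, mimicking the bimodal
length structure of real OPX sets without copying any specific
histogram. Ten percent of background genes carry an irrelevant
accession so that filters are exercised on accession identity rather
than hit presence. Context domains for definitive plants are drawn
uniformly from the Wzx/Wzy and ABC accession sets; verified barrels get
16-18 strands. All randomness flows through a single seeded integer RNG
stream, so output is byte-reproducible.

What it does *not* emulate: nucleotide sequences, operon structure and
strand correlation, phylogenetic relatedness between genomes, Pfam
score distributions, secondary-structure prediction error, or partial /
noisy annotations. A clean pass on synthetic data therefore shows the
*logic* of the screen is correct — it does not validate robustness to
upstream prediction errors, which real inputs inherit from HMMER,
secondary-structure and topology predictors.

## Verification strategy and problem sizes

Every non-trivial rule is checked against an independent oracle:
the helix scanner against an exhaustive segment-enumeration oracle on
all 16,384 binary H/C windows of length 14 plus 100,000 random H/E/C
strings of lengths 20-400; alignment identity against a longest-common-
subsequence dynamic program; greedy clustering against an independent
re-implementation on instances of up to 12 sequences; pathway
assignment against a brute-force closest-context re-scan on 10,000
fuzzed neighborhoods; the enrichment null against Monte-Carlo
calibration with 10,000 proteins and 4 + 4 replicates. The end-to-end
recovery condition is 50 genomes of 60 genes with one plant of every
archetype per genome — small enough to run in seconds, large enough
that every archetype, offset sign and boundary case occurs many times.
These sizes are the package's chosen verification scale; all of them
are re-derived from scratch by `scripts/acceptance.R`.

## Known limitations

* The screen trusts its input annotations; it does not run HMMER,
  secondary-structure or topology predictors, and never rescores hits.
* Greedy clustering is order-dependent by construction (longest first,
  ties by id); borderline pairs near the 90% threshold may cluster
  differently than under other tools' heuristics.
* The motif-region FASTA uses the PF02563 hit envelope only when the
  hit table provides envelope coordinates; otherwise it falls back to
  the full representative sequence.
* Tree building from the motif regions (alignment, ML inference,
  rendering) is out of scope; the package emits the per-representative
  ring annotation table and motif FASTA for external tools.
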