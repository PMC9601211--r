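test_that("OPX candidates require a threshold-passing Poly_export hit, deduplicated", {
  genes <- makeGenes(4)
  prot <- data.frame(protein_id = genes$protein_id, length = c(200L, 300L, 250L, 180L),
                     taxon = NA_character_, stringsAsFactors = FALSE)
  hits <- rbind(
    makeHits(genes$protein_id[1], "PF02563"),
    makeHits(genes$protein_id[1], "PF02563"),                      # duplicate hit
    makeHits(genes$protein_id[2], "PF02563", meets_threshold = FALSE),
    makeHits(genes$protein_id[3], "PF99901"))
  cand <- findOpxCandidates(hits, genes, prot)
  expect_equal(cand$protein_id, genes$protein_id[1])
  expect_equal(cand$length, 200L)

  # hit referencing an unknown protein: warning, skipped
  hits2 <- rbind(hits, makeHits("ghost", "PF02563"))
  expect_warning(cand2 <- findOpxCandidates(hits2, genes, prot), "unknown")
  expect_equal(nrow(cand2), 1L)
})

test_that("neighborhoods truncate at contig ends and never contain the focal gene", {
  g1 <- makeGenes(1)
  nb <- extractNeighborhood(g1$gene_id[1], g1, k = 5)
  expect_equal(nrow(nb$neighbors), 0L)

  g12 <- makeGenes(12)
  nb <- extractNeighborhood(g12$gene_id[1], g12, k = 5)  # rank 0
  expect_equal(nb$neighbors$offset, 1:5)

  g10 <- makeGenes(10)
  nb <- extractNeighborhood(g10$gene_id[8], g10, k = 5)  # rank 7
  expect_equal(nb$neighbors$offset, c(-5:-1, 1:2))
  expect_false(nb$focal$gene_id %in% nb$neighbors$gene_id)
  expect_lte(nrow(nb$neighbors), 10L)
})

test_that("circular contigs wrap ranks around", {
  g6 <- makeGenes(6)
  nb <- extractNeighborhood(g6$gene_id[1], g6, k = 2, circular = TRUE)
  expect_setequal(nb$neighbors$gene_id, g6$gene_id[c(5, 6, 2, 3)])
  # wrap never duplicates genes on tiny contigs
  g3 <- makeGenes(3)
  nb <- extractNeighborhood(g3$gene_id[2], g3, k = 5, circular = TRUE)
  expect_lte(nrow(nb$neighbors), 2L)
  expect_false(any(duplicated(nb$neighbors$gene_id)))
})

test_that("context filter keys on the context accessions only", {
  genes <- makeGenes(7)
  focal <- genes$gene_id[4]
  nb <- extractNeighborhood(focal, genes, k = 5)

  idx <- hitIndex(makeHits(genes$protein_id[6], "PF04932"))
  expect_true(contextFilter(nb, idx))

  idx <- hitIndex(makeHits(genes$protein_id[c(1, 6)], c("PF99901", "PF99902")))
  expect_false(contextFilter(nb, idx))

  expect_false(contextFilter(extractNeighborhood(makeGenes(1)$gene_id[1],
                                                 makeGenes(1), k = 5),
                             hitIndex(makeHits("x", "PF04932"))))
})

test_that("enlarging the window never turns the context filter off", {
  set.seed(140)
  for (trial in 1:40) {
    case <- randomNeighborhoodCase(trial)
    idx <- hitIndex(case$hits)
    small <- contextFilter(extractNeighborhood(case$focal_gene, case$genes, k = 2), idx)
    large <- contextFilter(extractNeighborhood(case$focal_gene, case$genes, k = 6), idx)
    if (small) expect_true(large)
  }
})

test_that("the closest context gene decides the pathway", {
  genes <- makeGenes(11)
  focal <- genes$gene_id[6]  # rank 5, full window both sides
  nb <- extractNeighborhood(focal, genes, k = 5)
  pid <- function(off) genes$protein_id[6 + off]

  # Wzz at -1 beats Wzy_C at +3: PCP leaves the pathway unassigned
  idx <- hitIndex(rbind(makeHits(pid(-1), "PF02706"),
                        makeHits(pid(+3), "PF04932")))
  pw <- assignPathway(nb, idx)
  expect_equal(pw$pathway, "pcp_unassigned")
  expect_false(pw$pcp2_context)

  # ABC_tran at +2, nothing closer
  idx <- hitIndex(makeHits(pid(+2), "PF00005"))
  expect_equal(assignPathway(nb, idx)$pathway, "abc")

  # flippase-family domains vote Wzx/Wzy
  idx <- hitIndex(makeHits(pid(-4), "PF01943"))
  expect_equal(assignPathway(nb, idx)$pathway, "wzx_wzy")

  # Wzz neighbor also carrying the BY-kinase accession: PCP-2 context
  idx <- hitIndex(rbind(makeHits(pid(+1), "PF02706"),
                        makeHits(pid(+1), "PF13614")))
  pw <- assignPathway(nb, idx)
  expect_equal(pw$pathway, "pcp_unassigned")
  expect_true(pw$pcp2_context)

  # no context at all
  idx <- hitIndex(makeHits(pid(+1), "PF99901"))
  expect_equal(assignPathway(nb, idx)$pathway, "none")
})

test_that("equal-distance ties follow the documented rule", {
  genes <- makeGenes(11)
  nb <- extractNeighborhood(genes$gene_id[6], genes, k = 5)
  pid <- function(off) genes$protein_id[6 + off]

  # one definitive side wins over a PCP side
  idx <- hitIndex(rbind(makeHits(pid(-2), "PF02706"),
                        makeHits(pid(+2), "PF04932")))
  pw <- assignPathway(nb, idx)
  expect_equal(pw$pathway, "wzx_wzy")
  expect_false(pw$ambiguous)

  # conflicting definitive pathways at equal distance: none + flagged
  idx <- hitIndex(rbind(makeHits(pid(-3), "PF04932"),
                        makeHits(pid(+3), "PF00005")))
  pw <- assignPathway(nb, idx)
  expect_equal(pw$pathway, "none")
  expect_true(pw$ambiguous)

  # both sides PCP only
  idx <- hitIndex(rbind(makeHits(pid(-1), "PF02706"),
                        makeHits(pid(+1), "PF02706")))
  expect_equal(assignPathway(nb, idx)$pathway, "pcp_unassigned")
})

test_that("pathway assignment matches the brute-force re-scan on fuzzed neighborhoods", {
  set.seed(2024)
  for (trial in 1:1500) {
    case <- randomNeighborhoodCase(trial)
    idx <- hitIndex(case$hits)
    nb <- extractNeighborhood(case$focal_gene, case$genes, k = case$k)
    got <- assignPathway(nb, idx)
    accsOf <- function(p) case$hits$domain_acc[case$hits$protein_id == p]
    want <- oraclePathway(nb$neighbors, accsOf)
    expect_identical(got$pathway, want$pathway)
    expect_identical(got$ambiguous, want$ambiguous)
    expect_identical(got$pcp2_context, want$pcp2)
  }
})
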