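test_that("generation is deterministic under a fixed seed", {
  a <- simulateScreen(nGenomes = 3, seed = 99)
  b <- simulateScreen(nGenomes = 3, seed = 99)
  expect_identical(geneTable(a), geneTable(b))
  expect_identical(domainHits(a), domainHits(b))
  expect_identical(ssTable(a), ssTable(b))
  expect_identical(topologyTable(a), topologyTable(b))
  expect_identical(truthTable(a), truthTable(b))
  expect_identical(as.character(proteinSequences(a)),
                   as.character(proteinSequences(b)))
  c <- simulateScreen(nGenomes = 3, seed = 100)
  expect_false(identical(domainHits(a), domainHits(c)))
})

test_that("zero plants yield no OPX hits; plants have the promised structure", {
  empty <- simulateScreen(nGenomes = 2, seed = 1,
                          plants = list(plantSpec("composite", 0L)))
  expect_false(any(domainHits(empty)$domain_acc == "PF02563"))

  sc <- simulateScreen(nGenomes = 10, seed = 7,
                       plants = list(plantSpec("composite", 1L)))
  tt <- truthTable(sc)
  expect_equal(nrow(tt), 10L)
  expect_true(all(tt$archetype == "composite"))
  expect_true(all(!is.na(tt$partner_gene_id)))
  # the partner lies within the window of the planted OPX gene
  g <- geneTable(sc)
  fr <- g$rank[match(tt$gene_id, g$gene_id)]
  pr <- g$rank[match(tt$partner_gene_id, g$gene_id)]
  expect_true(all(abs(fr - pr) >= 1 & abs(fr - pr) <= 5))
})

test_that("planted systems exceeding contig capacity raise an error", {
  expect_error(
    simulateScreen(nGenomes = 1, genesPerContig = 30,
                   plants = list(plantSpec("composite", 3L)), seed = 1),
    "capacity")
})

test_that("generated SS strings obey the requested helix flag", {
  set.seed(31)
  for (i in 1:200) {
    flag <- i %% 2 == 0
    s <- generateSS(sample(20:300, 1), flag)
    expect_identical(scanCtermHelix(s)$has_cterm_helix, flag)
    expect_identical(oracleHelix(s), flag)
  }
  expect_error(generateSS(10, TRUE), "helix scan window")
})

test_that("mutated families have the expected identity structure", {
  fam0 <- generateFamily(120, 5, 0, seed = 3)
  expect_true(all(as.character(fam0) == attr(fam0, "parent")))

  # rate 0.05, length 200, n = 50: mean positional identity to the parent
  # within 1.65 standard errors of 0.95 (binomial sampling bound)
  fam <- generateFamily(200, 50, 0.05, seed = 11)
  ids <- vapply(as.character(fam), positionalIdentity, numeric(1),
                b = attr(fam, "parent"))
  se <- sqrt(0.05 * 0.95 / 200) / sqrt(50)
  expect_lt(abs(mean(ids) - 0.95), 1.65 * se)

  # unrelated families never reach the 0.90 clustering threshold
  f1 <- generateFamily(200, 6, 0.5, seed = 21, prefix = "a")
  f2 <- generateFamily(200, 6, 0.5, seed = 22, prefix = "b")
  cross <- outer(seq_len(6), seq_len(6), Vectorize(function(i, j)
    lcsIdentity(as.character(f1[[i]]), as.character(f2[[j]]))))
  expect_lt(max(cross), 0.9)
})

test_that("planted neighborhoods are isolated and decoys violate one condition each", {
  sc <- simulateScreen(nGenomes = 6, seed = 17)
  tt <- truthTable(sc)
  g <- geneTable(sc)
  h <- domainHits(sc)
  tp <- topologyTable(sc)
  ctx <- unname(contextAccessions())
  brl <- unname(barrelAccessions())

  for (i in seq_len(nrow(tt))) {
    nb <- extractNeighborhood(tt$gene_id[i], g, k = 5)
    naccs <- h$domain_acc[h$protein_id %in% nb$neighbors$protein_id]
    if (tt$archetype[i] == "decoy_opx_no_context") {
      expect_false(any(naccs %in% ctx))
    } else {
      expect_true(any(naccs %in% ctx))
    }
    barrel_prots <- h$protein_id[h$domain_acc %in% brl &
                                 h$protein_id %in% nb$neighbors$protein_id]
    if (tt$archetype[i] == "composite") {
      expect_true(all(tp$strand_count[tp$protein_id %in% barrel_prots] >= 16))
    } else if (tt$archetype[i] == "decoy_barrel_few_strands") {
      expect_equal(unique(tp$strand_count[tp$protein_id %in% barrel_prots]), 14L)
    } else {
      expect_length(barrel_prots, 0L)
    }
  }
  # lone barrels sit more than k genes from every planted OPX of their genome
  partner_prots <- g$protein_id[match(tt$partner_gene_id[!is.na(tt$partner_gene_id)],
                                      g$gene_id)]
  few_strand <- tp$protein_id[tp$strand_count < 16L]
  lone_prots <- setdiff(unique(h$protein_id[h$domain_acc %in% brl]),
                        c(partner_prots, few_strand))
  expect_gt(length(lone_prots), 0L)
  for (p in lone_prots) {
    gi <- g[match(p, g$protein_id), ]
    focal_ranks <- g$rank[match(tt$gene_id[tt$genome_id == gi$genome_id],
                                g$gene_id)]
    expect_true(all(abs(gi$rank - focal_ranks) > 5L))
  }
})
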