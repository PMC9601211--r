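test_that("gene ranks are assigned by ascending start within each contig", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tcontig_id\tgene_id\tstart\tend\tstrand\tprotein_id",
               "g1\tc1\tgA\t10\t50\t+\tP1",
               "g1\tc1\tgB\t200\t250\t+\tP2",
               "g1\tc1\tgC\t90\t150\t-\tP3"), tf)
  expect_message(g <- readGeneTable(tf), "not sorted")
  expect_equal(g$gene_id, c("gA", "gC", "gB"))
  expect_equal(g$rank, 0:2)

  # two contigs: ranks restart at 0 per contig
  writeLines(c("genome_id\tcontig_id\tgene_id\tstart\tend\tstrand\tprotein_id",
               "g1\tc1\tgA\t10\t50\t+\tP1",
               "g1\tc1\tgB\t60\t90\t+\tP2",
               "g1\tc2\tgC\t10\t50\t+\tP3",
               "g1\tc2\tgD\t60\t90\t+\tP4"), tf)
  g <- readGeneTable(tf)
  expect_equal(g$rank, c(0L, 1L, 0L, 1L))

  # empty file -> empty table
  writeLines("genome_id\tcontig_id\tgene_id\tstart\tend\tstrand\tprotein_id", tf)
  expect_equal(nrow(readGeneTable(tf)), 0L)
})

test_that("duplicate gene ids and inverted coordinates are hard errors", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tcontig_id\tgene_id\tstart\tend\tstrand\tprotein_id",
               "g1\tc1\tgA\t10\t50\t+\tP1",
               "g1\tc1\tgA\t60\t90\t+\tP2"), tf)
  expect_error(readGeneTable(tf), "duplicate gene_id")
  writeLines(c("genome_id\tcontig_id\tgene_id\tstart\tend\tstrand\tprotein_id",
               "g1\tc1\tgA\t50\t10\t+\tP1"), tf)
  expect_error(readGeneTable(tf), "start > end")
})

test_that("GFF3 CDS features are read with protein ids and ranks", {
  tf <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tCDS\t300\t500\t.\t+\t0\tID=gB;protein_id=P2",
               "c1\tsrc\tCDS\t10\t200\t.\t-\t0\tID=gA;protein_id=P1",
               "c1\tsrc\tgene\t10\t200\t.\t-\t.\tID=parentA"), tf)
  g <- readGeneTable(tf, dialect = "gff3", genomeId = "gen1")
  expect_equal(nrow(g), 2L)
  expect_equal(g$protein_id, c("P1", "P2"))
  expect_equal(g$rank, 0:1)
  expect_equal(g$genome_id, rep("gen1", 2))
})

test_that("writer/reader pairs round-trip generated tables losslessly", {
  sc <- simulateScreen(nGenomes = 2, seed = 5)
  d <- tempfile(); dir.create(d)

  writeGeneTable(geneTable(sc), file.path(d, "genes.tsv"))
  g2 <- readGeneTable(file.path(d, "genes.tsv"))
  expect_equal(g2, geneTable(sc))

  writeDomainHits(domainHits(sc), file.path(d, "hits.tsv"))
  h2 <- readDomainHits(file.path(d, "hits.tsv"))
  expect_equal(h2, domainHits(sc), ignore_attr = TRUE)

  writeSecondaryStructure(ssTable(sc), file.path(d, "ss.fasta"))
  s2 <- readSecondaryStructure(file.path(d, "ss.fasta"))
  expect_equal(s2, ssTable(sc), ignore_attr = TRUE)

  writeTopology(topologyTable(sc), file.path(d, "topo.tsv"))
  t2 <- readTopology(file.path(d, "topo.tsv"))
  expect_equal(t2, topologyTable(sc), ignore_attr = TRUE)

  writeProteinTable(proteinTable(sc), file.path(d, "prot.tsv"))
  p2 <- readProteinTable(file.path(d, "prot.tsv"))
  expect_equal(p2, proteinTable(sc), ignore_attr = TRUE)
})

test_that("classification table round-trips with identical records and types", {
  res <- runScreen(simulateScreen(nGenomes = 2, seed = 8))
  tf <- tempfile(fileext = ".tsv")
  writeClassification(opxTable(res), tf)
  back <- readClassification(tf)
  keep <- intersect(names(back), names(opxTable(res)))
  expect_identical(back[, keep], opxTable(res)[, keep])

  # zero records -> header-only file; n records -> n + 1 lines
  writeClassification(opxTable(res)[0, ], tf)
  expect_length(readLines(tf), 1L)
  writeClassification(opxTable(res)[1:2, ], tf)
  expect_length(readLines(tf), 3L)
})

test_that("domain-hit reader handles HMMER tblout, comments and bad rows", {
  tf <- tempfile(fileext = ".tbl")
  writeLines(c(
    "# comment line",
    "P1  -  Poly_export  PF02563.19  1.2e-30  105.5  0.1  1.3e-30  104.9  0.1  1.0  1  0  0  1  1  1  1  desc",
    "P2  -  SomeFam      -           2.0e-05   20.1  0.0  2.1e-05   19.8  0.0  1.0  1  0  0  1  1  1  1  desc"),
    tf)
  h <- readDomainHits(tf)
  expect_equal(h$protein_id, c("P1", "P2"))
  expect_equal(h$domain_acc, c("PF02563", "SomeFam"))
  expect_equal(h$score, c(105.5, 20.1))
  expect_true(all(h$meets_threshold))

  # plain TSV dialect, threshold column respected
  writeLines(c("protein_id\tdomain_acc\tscore\tmeets_threshold",
               "P1\tPF02563\t55.2\tTRUE",
               "P2\tPF02563\t10.0\tFALSE"), tf)
  h <- readDomainHits(tf)
  expect_equal(h$meets_threshold, c(TRUE, FALSE))

  # empty accession is an error
  writeLines(c("protein_id\tdomain_acc", "P1\t"), tf)
  expect_error(readDomainHits(tf), "empty domain accession")

  # unparseable dialect names the offending line
  writeLines(c("just a few words"), tf)
  expect_error(readDomainHits(tf), "unrecognized.*just a few words")
})

test_that("FASTA protein input yields consistent lengths and sequences", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "MKLVV", ">P2", "ACDEFGHIK"), tf)
  p <- readProteinFasta(tf)
  expect_equal(p$proteins$protein_id, c("P1", "P2"))
  expect_equal(p$proteins$length, c(5L, 9L))
  expect_equal(as.character(p$sequences[["P2"]]), "ACDEFGHIK")
})

test_that("screen container validity rejects non-contiguous ranks", {
  sc <- simulateScreen(nGenomes = 1, seed = 2)
  g <- geneTable(sc)
  g$rank[2] <- 99L
  expect_error(
    PolysaccharideScreen(genes = g, proteins = proteinTable(sc),
                         hits = domainHits(sc)),
    "contiguous")
})
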