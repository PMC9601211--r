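test_that("pairwise identity uses the shorter-sequence denominator", {
  expect_equal(pairwiseIdentity("MKLVTT", "MKLVTT"), 1.0)
  expect_equal(pairwiseIdentity("AAAA", "TTTT"), 0.0)
  expect_equal(pairwiseIdentity("ACDEFGHIK", "ACDEFGHIV"), 8 / 9)
  # symmetric, and a contained subsequence scores on the shorter length
  expect_equal(pairwiseIdentity("ACDEFGHIK", "ACDE"), 1.0)
  expect_equal(pairwiseIdentity("ACDE", "ACDEFGHIK"), 1.0)
  expect_error(pairwiseIdentity("", "AA"), "non-empty")
})

test_that("alignment identity agrees with the LCS dynamic program", {
  set.seed(52)
  for (i in 1:40) {
    a <- paste(sample(c("A", "C", "D", "E", "G"), sample(3:25, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "D", "E", "G"), sample(3:25, 1), TRUE),
               collapse = "")
    expect_equal(pairwiseIdentity(a, b), lcsIdentity(a, b))
  }
})

test_that("identical sequences form one cluster; empty input gives none", {
  sq <- Biostrings::AAStringSet(setNames(rep("MKLVTTACDE", 5),
                                         paste0("p", 1:5)))
  cl <- greedyCluster(sq)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_equal(nrow(cl), 5L)
  expect_equal(unique(cl$representative), "p1")

  expect_equal(nrow(greedyCluster(Biostrings::AAStringSet())), 0L)
})

test_that("two mutated families separate into exactly two clusters", {
  f1 <- generateFamily(200, 8, 0.05, seed = 61, prefix = "famA",
                       includeParent = TRUE)
  f2 <- generateFamily(200, 8, 0.05, seed = 62, prefix = "famB",
                       includeParent = TRUE)
  # oracle check that no cross-family pair reaches the threshold
  cross <- outer(seq_along(f1), seq_along(f2), Vectorize(function(i, j)
    lcsIdentity(as.character(f1[[i]]), as.character(f2[[j]]))))
  expect_lt(max(cross), 0.9)
  cl <- greedyCluster(c(f1, f2), threshold = 0.9)
  expect_equal(length(unique(cl$cluster_id)), 2L)
  fam_of <- substr(cl$member, 1, 4)
  expect_true(all(tapply(substr(cl$representative, 1, 4), fam_of,
                         function(x) length(unique(x)) == 1)))
})

test_that("clusters partition the input and members match their representative", {
  set.seed(71)
  pool <- c(generateFamily(150, 6, 0.03, seed = 81, prefix = "fa",
                           includeParent = TRUE),
            generateFamily(240, 4, 0.02, seed = 82, prefix = "fb",
                           includeParent = TRUE),
            generateFamily(90, 3, 0.4, seed = 83, prefix = "fc"))
  cl <- greedyCluster(pool, threshold = 0.9)
  # partition: every input exactly once
  expect_setequal(cl$member, names(pool))
  expect_false(anyDuplicated(cl$member) > 0)
  # representative is a member of its own cluster and a longest member
  for (cid in unique(cl$cluster_id)) {
    sub <- cl[cl$cluster_id == cid, ]
    expect_true(sub$representative[1] %in% sub$member)
    expect_equal(max(nchar(as.character(pool[sub$member]))),
                 nchar(as.character(pool[[sub$representative[1]]])))
  }
  # post-hoc identity assertion
  for (i in seq_len(nrow(cl)))
    expect_gte(pairwiseIdentity(as.character(pool[[cl$member[i]]]),
                                as.character(pool[[cl$representative[i]]])),
               0.9)
})

test_that("greedy result matches the independent oracle on small instances", {
  set.seed(91)
  for (trial in 1:8) {
    n <- sample(4:12, 1)
    seqs <- character(n)
    base <- paste(sample(c("A", "C", "D", "E", "F", "G", "K"), 40, TRUE),
                  collapse = "")
    for (i in seq_len(n)) {
      if (runif(1) < 0.5) {
        # mutated copy of the base
        ch <- strsplit(base, "")[[1]]
        mut <- runif(40) < 0.08
        ch[mut] <- sample(c("A", "C", "D", "E", "F", "G", "K"), sum(mut), TRUE)
        seqs[i] <- paste(ch, collapse = "")
      } else {
        seqs[i] <- paste(sample(c("A", "C", "D", "E", "F", "G", "K"),
                                sample(25:45, 1), TRUE), collapse = "")
      }
    }
    names(seqs) <- sprintf("s%02d", seq_len(n))
    got <- greedyCluster(Biostrings::AAStringSet(seqs), threshold = 0.9)
    want <- oracleGreedy(seqs, threshold = 0.9)
    expect_equal(got$representative[match(want$member, got$member)],
                 want$representative)
  }
})

test_that("threshold 1.0 groups exactly the duplicate sequences", {
  seqs <- c(a1 = "MKLVTTACDE", a2 = "MKLVTTACDE", b1 = "MKLVTTACDF",
            c1 = "GGGGGGGGGG", c2 = "GGGGGGGGGG", c3 = "GGGGGGGGGG")
  cl <- greedyCluster(Biostrings::AAStringSet(seqs), threshold = 1.0)
  grp <- vapply(split(cl$member, cl$cluster_id),
                function(x) paste(sort(x), collapse = ","), "")
  expect_setequal(unname(grp), c("a1,a2", "b1", "c1,c2,c3"))
})

test_that("proteins without sequences pass through as logged singletons", {
  sq <- Biostrings::AAStringSet(c(p1 = "MKLVTTACDE", p2 = "MKLVTTACDE"))
  expect_message(cl <- greedyCluster(sq, passthrough = c("x1", "x2")),
                 "without sequence")
  expect_equal(nrow(cl), 4L)
  expect_equal(sum(cl$member %in% c("x1", "x2") &
                   cl$member == cl$representative), 2L)
})
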