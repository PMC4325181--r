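test_that("clusters are exact-identity groups in count order", {
  reads <- c(rep("ACGT", 5), rep("AGGT", 2), "TTTT")
  cl <- cluster_reads(reads)
  expect_identical(cl$sequence, c("ACGT", "AGGT", "TTTT"))
  expect_identical(cl$count, c(5L, 2L, 1L))
  expect_equal(sum(cl$count), length(reads))
  expect_equal(cl$frequency, cl$count / 8)

  one <- cluster_reads(rep("AAAA", 7))
  expect_identical(nrow(one), 1L)
  expect_equal(one$frequency, 1)

  tied <- cluster_reads(c(rep("TTTT", 3), rep("AAAA", 3), "GGGG"))
  expect_identical(tied$sequence[1:2], c("AAAA", "TTTT"))  # lexicographic tie
})

test_that("chimera detection finds all prefix+suffix joins", {
  hits <- detect_chimera("AAAACCCC", c("AAAAAAAA", "CCCCCCCC"))
  expect_true(nrow(hits) > 0)
  expect_true(any(hits$parent_a == 1 & hits$parent_b == 2 &
                    hits$breakpoint == 4))
  # all reported joins really reconstruct the query
  parents <- c("AAAAAAAA", "CCCCCCCC")
  for (r in seq_len(nrow(hits))) {
    A <- parents[hits$parent_a[r]]; B <- parents[hits$parent_b[r]]
    k <- hits$breakpoint[r]
    expect_identical(paste0(substr(A, 1, k),
                            substr(B, nchar(B) - (8 - k) + 1, nchar(B))),
                     "AAAACCCC")
  }

  expect_identical(nrow(detect_chimera("AAGACCCC",
                                       c("AAAAAAAA", "CCCCCCCC"))), 0L)
  # a parent identical to the query is ignored, single parent cannot join
  expect_identical(nrow(detect_chimera("AAAAAAAA",
                                       c("AAAAAAAA", "CCCCCCCC"))), 0L)
})

test_that("chimera detector agrees with the brute-force oracle", {
  set.seed(42)
  mism <- 0
  for (case in 1:400) {
    L <- sample(6:24, 1)
    n <- sample(2:6, 1)
    base <- paste(sample(c("A", "C"), L, replace = TRUE), collapse = "")
    seqs <- unique(vapply(seq_len(n), function(i) {
      s <- strsplit(base, "")[[1]]
      flip <- sample.int(L, sample(0:3, 1))
      s[flip] <- ifelse(s[flip] == "A", "C", "A")
      paste(s, collapse = "")
    }, character(1)))
    if (length(seqs) < 2) next
    query <- seqs[1]
    parents <- seqs[-1]
    got <- nrow(detect_chimera(query, parents)) > 0
    expect_identical(got, oracle_chimera(query, parents))
    # and the fast path used inside step 1 agrees as well
    qc <- strsplit(query, "")[[1]]
    pc <- lapply(parents, function(p) strsplit(p, "")[[1]])
    fast <- mhctyper:::is_chimeric(
      mhctyper:::lcp_lengths(qc, pc),
      mhctyper:::lcp_lengths(rev(qc), lapply(pc, rev)), nchar(query))
    expect_identical(fast, oracle_chimera(query, parents))
  }
})

test_that("step 1 labels clusters by precedence: top, singleton, chimera, distance", {
  X <- strrep("ACGT", 5)
  W <- X; substr(W, 3, 3) <- "T"
  cl <- classify_step1(c(rep(X, 10), rep(W, 2)))
  expect_identical(cl$label, c("putative_allele", "diff_1_2bp"))

  Y <- X
  substr(Y, 1, 1) <- "T"; substr(Y, 6, 6) <- "A"; substr(Y, 11, 11) <- "T"
  Z <- paste0(substr(X, 1, 10), substr(Y, 11, 20))   # chimera of X and Y
  V <- strrep("GTCA", 5)
  stopifnot(Z != X, Z != Y)
  cl2 <- classify_step1(c(rep(X, 10), rep(Y, 6), rep(Z, 3), V))
  got <- setNames(cl2$label, cl2$sequence)
  expect_identical(unname(got[X]), "putative_allele")
  expect_identical(unname(got[Y]), "diff_gt2bp")
  expect_identical(unname(got[Z]), "chimera")
  expect_identical(unname(got[V]), "singleton_discard")

  solo <- classify_step1(rep("AAAA", 4))
  expect_identical(solo$label, "putative_allele")
})

test_that("tied top clusters are all putative alleles", {
  cl <- classify_step1(c(rep("AAAA", 5), rep("TTTT", 5), rep("AATT", 2)))
  expect_identical(sum(cl$label == "putative_allele"), 2L)
})

test_that("step 2 applies the three artefact rules", {
  X <- strrep("ACGT", 5); W <- X; substr(W, 3, 3) <- "T"
  U <- strrep("TGCA", 5)
  # r1 has W (1-2bp) and U (>2bp); r2 lacks both
  r1 <- classify_step1(c(rep(X, 10), rep(W, 3), rep(U, 2)))
  r2 <- classify_step1(rep(X, 10))
  dc <- setNames(c(2L, 1L, 1L), c(X, W, U))  # U unique dataset-wide
  out <- classify_step2(r1, r2, dc)
  st <- setNames(out$r1$state, out$r1$sequence)
  expect_identical(unname(st[W]), "artefact")   # absent from replicate
  expect_identical(unname(st[U]), "artefact")   # unique to one amplicon

  # >2bp cluster found in another amplicon dataset-wide is retained
  dc2 <- setNames(c(2L, 1L, 3L), c(X, W, U))
  out2 <- classify_step2(r1, r2, dc2)
  expect_identical(unname(setNames(out2$r1$state, out2$r1$sequence)[U]),
                   "retained")

  # chimeras flagged in both replicates are artefacts even when shared
  Y <- X
  substr(Y, 1, 1) <- "T"; substr(Y, 6, 6) <- "A"; substr(Y, 11, 11) <- "T"
  Z <- paste0(substr(X, 1, 10), substr(Y, 11, 20))
  a1 <- classify_step1(c(rep(X, 10), rep(Y, 6), rep(Z, 3)))
  a2 <- classify_step1(c(rep(X, 12), rep(Y, 5), rep(Z, 2)))
  dc3 <- setNames(c(2L, 2L, 2L), c(X, Y, Z))
  outc <- classify_step2(a1, a2, dc3)
  expect_identical(unname(setNames(outc$r1$state, outc$r1$sequence)[Z]),
                   "artefact")
  expect_identical(unname(setNames(outc$r2$state, outc$r2$sequence)[Z]),
                   "artefact")
})

test_that("step 3 compares retained clusters against the artefact ceiling", {
  mk <- function(freqs, labels, states) {
    n <- 100
    clusters_df(sequence = paste0(strrep("A", 6), seq_along(freqs)),
                count = as.integer(freqs * n), label = labels, state = states,
                n_assigned = n)
  }
  # shared sequence must be literally identical across replicates
  top <- strrep("ACGT", 5)
  v <- top; substr(v, 2, 2) <- "A"
  art <- strrep("GGCA", 5)
  r1 <- clusters_df(c(top, v, art), c(80L, 8L, 3L),
                    c("putative_allele", "diff_1_2bp", "diff_gt2bp"),
                    c("putative_allele", "retained", "artefact"),
                    n_assigned = 100)
  r2 <- r1
  out <- classify_step3(r1, r2, "S1", list())
  expect_identical(out$r1$state[2], "allele")       # 0.08 > 0.03

  r1b <- r1; r1b$count[2] <- 2L; r1b$frequency[2] <- 0.02
  out2 <- classify_step3(r1b, r2, "S1", list())
  expect_identical(out2$r1$state[2], "unclassified")  # 0.02 < 0.03

  # empty artefact list: comparison passes vacuously
  r1c <- r1b; r1c$state[3] <- "retained"; r1c$label[3] <- "diff_1_2bp"
  r2c <- r1c
  out3 <- classify_step3(r1c, r2c, "S1", list())
  expect_identical(out3$r1$state[2], "allele")

  # >2bp retained, absent from replicate: fate depends on other individuals
  solo <- strrep("TTAC", 5)
  r1d <- clusters_df(c(top, solo), c(90L, 10L),
                     c("putative_allele", "diff_gt2bp"),
                     c("putative_allele", "retained"), n_assigned = 100)
  r2d <- clusters_df(top, 100L, "putative_allele", "putative_allele",
                     n_assigned = 100)
  known <- list(); known[[solo]] <- "S9"
  outd <- classify_step3(r1d, r2d, "S1", known)
  expect_identical(outd$r1$state[2], "unclassified")
  oute <- classify_step3(r1d, r2d, "S1", list())
  expect_identical(oute$r1$state[2], "artefact")

  # retained chimera: allele elsewhere -> allele, otherwise unclassified
  r1f <- r1d; r1f$label[2] <- "chimera"
  outf <- classify_step3(r1f, r2d, "S1", known)
  expect_identical(outf$r1$state[2], "allele")
  outg <- classify_step3(r1f, r2d, "S1", list())
  expect_identical(outg$r1$state[2], "unclassified")
})

test_that("repeatability is the shared-allele percentage over the union", {
  expect_equal(repeatability(letters[1:4], letters[1:4]), 100)
  expect_equal(repeatability(letters[1:8], letters[c(1:4, 9:13)]),
               100 * 4 / 13)
  r <- repeatability(c("a", "b", "c", "d", "e", "f", "g"),
                     c("a", "b", "c", "d", "x", "y"))
  expect_equal(r, 100 * 4 / 9, tolerance = 1e-12)
  expect_equal(round(r, 1), 44.4)
  expect_equal(repeatability("a", "b"), 0)
  expect_error(repeatability(character(0), character(0)), "empty")
  expect_equal(repeatability(c("a", "b"), c("a", "b"), denominator = "mean"),
               100)
})
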