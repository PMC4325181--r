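test_that("diversity matches hand counts on tiny alignments", {
  d <- diversity(allele_alignment(c(a = "ACGT", b = "ACGA", c = "ACGA")))
  expect_identical(c(d$S, d$eta), c(1L, 1L))
  expect_equal(d$k, 2 / 3)
  expect_equal(d$pi, (2 / 3) / 4)

  d2 <- diversity(allele_alignment(c(a = "AAA", b = "AAC", c = "AAG")))
  expect_identical(c(d2$S, d2$eta), c(1L, 2L))      # triallelic site
  expect_equal(d2$k, 1)

  d3 <- diversity(allele_alignment(c(a = "ACGACT", b = "ACGACT")))
  expect_identical(c(d3$S, d3$eta), c(0L, 0L))
  expect_equal(c(d3$k, d3$pi), c(0, 0))

  expect_error(diversity(allele_alignment(c(a = "ACG"))), "at least 2")
})

test_that("diversity invariants hold on random alignments", {
  set.seed(7)
  for (i in 1:20) {
    m <- random_recomb_alignment(n_seq = 10, n_sites = 24)
    aln <- allele_alignment(setNames(apply(m, 1, paste, collapse = ""),
                                     sprintf("s%02d", 1:10)))
    d <- diversity(aln)
    expect_equal(d$pi * d$L, d$k, tolerance = 1e-12)
    expect_gte(d$eta, d$S)
    a <- sum(1 / seq_len(d$n - 1))
    expect_equal(d$theta_w, d$S / a)
    expect_equal(d$theta_w_eta, d$eta / a)
  }
})

test_that("gap columns are excluded by complete deletion", {
  aln <- allele_alignment(c(a = "A-GT", b = "ACGA", c = "ACGA"))
  d <- diversity(aln)
  expect_identical(d$L, 3L)       # gapped column dropped for everyone
  expect_identical(d$S, 1L)
})

test_that("four-gamete counts match the canonical examples", {
  expect_identical(
    four_gamete_rm(allele_alignment(c(a = "AA", b = "AT", c = "TA",
                                      d = "TT"))), 1L)
  expect_identical(
    four_gamete_rm(allele_alignment(c(a = "AA", b = "AT", c = "TT"))), 0L)
  expect_identical(
    four_gamete_rm(allele_alignment(c(a = "AAAA", b = "AAAA"))), 0L)
})

test_that("Rm equals the exhaustive interval-cover oracle", {
  set.seed(13)
  for (i in 1:40) {
    m <- random_recomb_alignment(n_seq = 20, n_sites = 30,
                                 n_founders = sample(2:4, 1),
                                 n_cross = sample(1:3, 1))
    aln <- allele_alignment(setNames(apply(m, 1, paste, collapse = ""),
                                     sprintf("s%02d", 1:20)))
    expect_identical(four_gamete_rm(aln), as.integer(oracle_rm(m)))
  }
})

test_that("sequences from a perfect phylogeny have Rm = 0", {
  # star-like descent without recombination: each tip mutates private sites
  set.seed(5)
  anc <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
  tips <- lapply(1:12, function(i) {
    s <- anc
    own <- ((i - 1) %% 15) * 2 + 1
    s[own] <- setdiff(c("A", "C", "G", "T"), s[own])[1]
    paste(s, collapse = "")
  })
  aln <- allele_alignment(setNames(unlist(tips), sprintf("t%02d", 1:12)))
  expect_identical(four_gamete_rm(aln), 0L)
})

test_that("NG86 reproduces the worked single-difference example", {
  ng <- nei_gojobori(strrep("GGG", 10), paste0("AGG", strrep("GGG", 9)))
  cts <- attr(ng, "counts")
  expect_equal(unname(cts["N_sites"]), 20.16667, tolerance = 1e-5)
  expect_equal(unname(cts["Nd"]), 1)
  expect_equal(unname(ng["dN"]), 0.0513, tolerance = 1e-3)
  expect_equal(unname(ng["dS"]), 0)

  same <- nei_gojobori("ATGGCTAAA", "ATGGCTAAA")
  expect_equal(unname(same), c(0, 0), ignore_attr = TRUE)
})

test_that("NG86 agrees with an independent brute-force implementation", {
  set.seed(99)
  for (i in 1:20) {
    s1 <- random_codons(30)
    s2 <- s1
    # mutate a few codons, rejecting stops
    for (j in sample(1:30, 8)) {
      repeat {
        cand <- random_codons(1)
        tmp <- s2
        substr(tmp, 3 * j - 2, 3 * j) <- cand
        if (!mhctyper:::has_stop(tmp)) { s2 <- tmp; break }
      }
    }
    a <- nei_gojobori(s1, s2)
    b <- oracle_ng86(s1, s2)
    expect_equal(unname(a["dN"]), unname(b["dN"]), tolerance = 1e-10)
    expect_equal(unname(a["dS"]), unname(b["dS"]), tolerance = 1e-10)
    # symmetry
    r <- nei_gojobori(s2, s1)
    expect_equal(unname(a), unname(r), tolerance = 1e-12)
  }
})

test_that("the Jukes-Cantor correction is increasing and bounded", {
  jc <- function(p) -3 / 4 * log(1 - 4 / 3 * p)
  p <- seq(0, 0.7, by = 0.05)
  expect_true(all(diff(jc(p)) > 0))
  # p >= 3/4 undefined -> NA propagated
  long1 <- strrep("AAA", 20)
  long2 <- strrep("CCC", 20)    # every position differs
  v <- nei_gojobori(long1, long2)
  expect_true(anyNA(v))
})

test_that("partition site and difference counts tile the exon", {
  set.seed(17)
  s <- lapply(1:6, function(i) random_codons(20))
  # enforce no stops and equal length (random_codons guarantees both)
  aln <- allele_alignment(setNames(unlist(s), sprintf("q%d", 1:6)))
  pbr <- c(2, 5, 6, 11, 17)
  dd <- dnds_summary(aln, partition = pbr)
  pairs <- utils::combn(6, 2)
  for (pp in seq_len(ncol(pairs))) {
    seqs <- unclass(aln)
    full <- attr(nei_gojobori(seqs[pairs[1, pp]], seqs[pairs[2, pp]]),
                 "counts")
    sub <- function(idx) {
      pick <- function(x) paste(mhctyper:::split_codons(x)[idx],
                                collapse = "")
      attr(nei_gojobori(pick(seqs[pairs[1, pp]]),
                        pick(seqs[pairs[2, pp]])), "counts")
    }
    a <- sub(pbr); b <- sub(setdiff(1:20, pbr))
    expect_equal(unname(full["Nd"]), unname(a["Nd"] + b["Nd"]),
                 tolerance = 1e-10)
    expect_equal(unname(full["S_sites"]), unname(a["S_sites"] + b["S_sites"]),
                 tolerance = 1e-10)
  }
  # the full partition matches plain pairwise NG86
  plain <- nei_gojobori(unclass(aln)[1], unclass(aln)[2])
  expect_equal(dd$full$dN[1], unname(plain["dN"]), tolerance = 1e-12)
})

test_that("purely synonymous variation yields dN = 0 in every partition", {
  base <- strrep("CTTGGTCCTCGT", 5)   # L G P R x 5, all 4-fold degenerate
  v1 <- base; substr(v1, 3, 3) <- "A"
  v2 <- base; substr(v2, 6, 6) <- "C"
  aln <- allele_alignment(c(a = base, b = v1, c = v2))
  dd <- dnds_summary(aln, partition = 1:5)
  expect_equal(dd$full$mean_dN, 0)
  expect_equal(dd$PBR$mean_dN, 0)
  expect_equal(dd$full$ratio, 0)
})

test_that("a planted nonsynonymous block elevates the local dN/dS", {
  set.seed(31)
  n_codon <- 40
  block <- 10:24
  anc <- random_codons(n_codon)
  mutate_at <- function(seq, codon_idx, nonsyn) {
    gc <- Biostrings::GENETIC_CODE
    old <- substr(seq, codon_idx * 3 - 2, codon_idx * 3)
    if (!nonsyn && !any(gc == gc[[old]] & names(gc) != old))
      return(seq)  # single-codon amino acid: no synonymous change exists
    repeat {
      cand <- random_codons(1)
      if (cand == old) next
      if ((gc[[cand]] != gc[[old]]) == nonsyn) {
        substr(seq, codon_idx * 3 - 2, codon_idx * 3) <- cand
        return(seq)
      }
    }
  }
  seqs <- vapply(1:8, function(i) {
    s <- anc
    for (j in sample(block, 6)) s <- mutate_at(s, j, nonsyn = TRUE)
    for (j in sample(setdiff(1:n_codon, block), 4))
      s <- mutate_at(s, j, nonsyn = FALSE)
    s
  }, character(1))
  aln <- allele_alignment(setNames(seqs, sprintf("p%d", 1:8)))
  dd <- dnds_summary(aln, partition = block)
  expect_gt(dd$PBR$ratio, dd$nonPBR$ratio)
})

test_that("translation collapses synonymous variants and counts aa changes", {
  expect_identical(
    translate_and_collapse(allele_alignment(c(x = "TTTTTC")))$proteins[[1]],
    "FF")
  tr <- translate_and_collapse(allele_alignment(c(x = "ATGGCT",
                                                  y = "ATGGCC")))
  expect_identical(tr$n_unique, 1L)
  expect_identical(tr$variable_sites, 0L)

  # column with three residues: one variable site, two aa changes
  tr3 <- translate_and_collapse(allele_alignment(
    c(a = "ATGGCT", b = "ATGTCT", c = "ATGACT")))  # M+A / M+S / M+T
  expect_identical(tr3$variable_sites, 1L)
  expect_identical(tr3$aa_changes, 2L)

  expect_error(
    translate_and_collapse(allele_alignment(c(bad = "ATGTAAGCT"))),
    "internal stop.*bad")
})

test_that("an in-frame 3-nt insertion adds one residue against a gap", {
  pool <- make_allele_pool(6, 60, 2, n_insertion_alleles = 1, seed = 3)
  aln <- allele_alignment(pool_alignment(pool))
  tr <- translate_and_collapse(aln)
  lens <- nchar(gsub("-", "", tr$proteins))
  ins <- pool$insertion_alleles
  expect_true(all(lens[ins] == 21))
  expect_true(all(lens[setdiff(names(lens), ins)] == 20))
})
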