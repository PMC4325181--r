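# Independent oracles, coded directly from the definitions and kept separate
# from the package implementations they check.

# Brute-force chimera test: try every breakpoint and every ordered pair of
# distinct parents, comparing raw substrings.
oracle_chimera <- function(query, parents) {
  parents <- parents[parents != query]
  L <- nchar(query)
  if (L < 2 || length(parents) < 2) {
    if (length(parents) < 2 && length(parents) == 1) return(FALSE)
  }
  for (i in seq_along(parents)) {
    for (j in seq_along(parents)) {
      if (i == j || parents[i] == parents[j]) next
      A <- parents[i]; B <- parents[j]
      for (k in 1:(L - 1)) {
        if (k > nchar(A) || (L - k) > nchar(B)) next
        if (substr(query, 1, k) == substr(A, 1, k) &&
            substr(query, k + 1, L) ==
            substr(B, nchar(B) - (L - k) + 1, nchar(B)))
          return(TRUE)
      }
    }
  }
  FALSE
}

# Exhaustive minimum interval cover: the fewest breakpoints stabbing every
# four-gamete-incompatible site pair, found by trying all candidate subsets
# of increasing size.
oracle_rm <- function(aln_chars) {
  m <- aln_chars
  biall <- which(apply(m, 2, function(col) length(unique(col))) == 2)
  if (length(biall) < 2) return(0L)
  iv <- list()
  for (ii in seq_along(biall)[-length(biall)]) {
    for (jj in (ii + 1):length(biall)) {
      g <- unique(paste(m[, biall[ii]], m[, biall[jj]]))
      if (length(g) == 4) iv[[length(iv) + 1L]] <- c(ii, jj)
    }
  }
  if (!length(iv)) return(0L)
  iv <- do.call(rbind, iv)
  cand <- sort(unique(iv[, 2]))  # stab just left of each right endpoint
  stabs <- function(points) {
    all(vapply(seq_len(nrow(iv)), function(r)
      any(points > iv[r, 1] & points <= iv[r, 2]), logical(1)))
  }
  for (size in 1:length(cand)) {
    combs <- utils::combn(cand, size)
    for (cc in seq_len(ncol(combs)))
      if (stabs(combs[, cc])) return(size)
  }
  length(cand)
}

# NG86 from first principles: site fractions by enumerating every non-stop
# single-base change, pathway averages by recursing over substitution orders.
oracle_ng86 <- function(s1, s2) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons1 <- regmatches(s1, gregexpr(".{3}", s1))[[1]]
  codons2 <- regmatches(s2, gregexpr(".{3}", s2))[[1]]
  keep <- !grepl("[-N]", codons1) & !grepl("[-N]", codons2)
  codons1 <- codons1[keep]; codons2 <- codons2[keep]

  syn_sites <- function(cd) {
    tot <- 0
    for (pos in 1:3) {
      ref <- substr(cd, pos, pos)
      syn <- 0; valid <- 0
      for (b in setdiff(bases, ref)) {
        alt <- cd
        substr(alt, pos, pos) <- b
        if (gc[[alt]] == "*") next
        valid <- valid + 1
        if (gc[[alt]] == gc[[cd]]) syn <- syn + 1
      }
      if (valid > 0) tot <- tot + syn / valid
    }
    tot
  }

  paths <- function(from, to) {
    pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(pos)) return(list(c(0, 0)))
    out <- list()
    for (p in pos) {
      mid <- from
      substr(mid, p, p) <- substr(to, p, p)
      if (gc[[mid]] == "*") next
      step <- if (gc[[from]] == gc[[mid]]) c(1, 0) else c(0, 1)
      for (tail in paths(mid, to))
        out[[length(out) + 1L]] <- step + tail
    }
    out
  }
  paths_any <- function(from, to) {  # fallback ignoring stop exclusion
    pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(pos)) return(list(c(0, 0)))
    out <- list()
    for (p in pos) {
      mid <- from
      substr(mid, p, p) <- substr(to, p, p)
      step <- if (gc[[from]] == gc[[mid]]) c(1, 0) else c(0, 1)
      for (tail in paths_any(mid, to))
        out[[length(out) + 1L]] <- step + tail
    }
    out
  }

  S1 <- sum(vapply(codons1, syn_sites, numeric(1)))
  S2 <- sum(vapply(codons2, syn_sites, numeric(1)))
  Ssites <- (S1 + S2) / 2
  Nsites <- 3 * length(codons1) - Ssites
  Sd <- 0; Nd <- 0
  for (i in seq_along(codons1)) {
    if (codons1[i] == codons2[i]) next
    pp <- paths(codons1[i], codons2[i])
    if (!length(pp)) pp <- paths_any(codons1[i], codons2[i])
    avg <- Reduce(`+`, pp) / length(pp)
    Sd <- Sd + avg[1]; Nd <- Nd + avg[2]
  }
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  c(dN = jc(Nd / Nsites), dS = jc(Sd / Ssites))
}

# random codon sequence without stop codons
random_codons <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  ok <- names(gc)[gc != "*"]
  paste(sample(ok, n_codons, replace = TRUE), collapse = "")
}

# mosaic alignments: founder haplotypes recombined with crossovers, so the
# four-gamete structure stays tractable for the exhaustive oracle
random_recomb_alignment <- function(n_seq = 20, n_sites = 30, n_founders = 4,
                                    n_cross = 2) {
  founders <- matrix(sample(c("A", "C", "G", "T"), n_founders * n_sites,
                            replace = TRUE), nrow = n_founders)
  rows <- t(vapply(seq_len(n_seq), function(i) {
    cuts <- sort(sample(1:(n_sites - 1), sample(0:n_cross, 1)))
    bounds <- c(0, cuts, n_sites)
    out <- character(n_sites)
    for (s in seq_len(length(bounds) - 1)) {
      f <- sample.int(n_founders, 1)
      idx <- (bounds[s] + 1):bounds[s + 1]
      out[idx] <- founders[f, idx]
    }
    out
  }, character(n_sites)))
  rows
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
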