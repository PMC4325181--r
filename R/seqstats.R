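#' Construct an allele alignment
#'
#' @param x named character vector of equal-length aligned nucleotide
#'   sequences (alphabet A/C/G/T/-), a \code{DNAStringSet}, or a FASTA path.
#' @param frame 1-based offset of the first codon (default 1); the aligned
#'   length from the offset must be divisible by 3.
#' @return object of class \code{allele_alignment} (named character vector
#'   with a \code{frame} attribute).
#' @export
allele_alignment <- function(x, frame = 1) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  if (inherits(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  x <- toupper(x)
  w <- unique(nchar(x))
  if (length(w) != 1) stop("aligned sequences must have equal length")
  if (!all(grepl("^[ACGTN-]*$", x))) stop("alphabet must be A/C/G/T/N/-")
  # codon-based operations check divisibility themselves; nucleotide-level
  # statistics accept any length
  if (is.null(names(x))) names(x) <- sprintf("seq%02d", seq_along(x))
  structure(x, frame = frame, class = "allele_alignment")
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unclass(aln), ""))
}

#' Nucleotide diversity statistics for an allele set
#'
#' Gap-containing columns are excluded (complete deletion). Reports the
#' number of variable (segregating) sites S, the minimum number of
#' mutations eta (per column, distinct states minus one), the mean number
#' of pairwise differences k, nucleotide diversity pi = k / L, and
#' Watterson's theta from S (default; the eta-based variant is also
#' returned): theta = S / a, a = sum_{i=1}^{n-1} 1/i.
#'
#' @param aln an \code{allele_alignment} (n >= 2 sequences).
#' @return object of class \code{diversity_stats}: list with n, L, S, eta,
#'   k, pi, theta_w (S-based), theta_w_eta.
#' @export
diversity <- function(aln) {
  if (!inherits(aln, "allele_alignment")) aln <- allele_alignment(aln)
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 sequences")
  keep <- colSums(m == "-" | m == "N") == 0
  m <- m[, keep, drop = FALSE]
  L <- ncol(m)
  states <- apply(m, 2, function(col) length(unique(col)))
  S <- sum(states >= 2)
  eta <- sum(states - 1L)
  diffs <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      diffs <- diffs + sum(m[i, ] != m[j, ])
  k <- diffs / (n * (n - 1) / 2)
  a <- sum(1 / seq_len(n - 1))
  structure(list(n = n, L = L, S = S, eta = eta, k = k, pi = k / L,
                 theta_w = S / a, theta_w_eta = eta / a),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf(paste0("Diversity over %d sequences, %d gap-free sites:\n",
                     "  S = %d variable sites, eta = %d mutations\n",
                     "  k = %.4g mean pairwise differences, pi = %.4g\n",
                     "  theta_w = %.4g (S-based; eta-based %.4g)\n"),
              x$n, x$L, x$S, x$eta, x$k, x$pi, x$theta_w, x$theta_w_eta))
  invisible(x)
}

#' Hudson-Kaplan minimum number of recombination events
#'
#' Scans all pairs of biallelic gap-free sites for four-gamete violations
#' (all four haplotypes present), then returns the minimum number of
#' non-overlapping intervals needed to cover every incompatible pair -- the
#' lower bound Rm on recombination events.
#'
#' @param aln an \code{allele_alignment}.
#' @return integer Rm (0 when no pair violates the four-gamete test).
#' @export
four_gamete_rm <- function(aln) {
  if (!inherits(aln, "allele_alignment")) aln <- allele_alignment(aln)
  m <- aln_matrix(aln)
  keep <- which(colSums(m == "-" | m == "N") == 0 &
                  apply(m, 2, function(col) length(unique(col))) == 2)
  if (length(keep) < 2) return(0L)
  b <- m[, keep, drop = FALSE]
  ns <- length(keep)
  iv <- list()
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      if (length(unique(paste(b[, i], b[, j]))) == 4)
        iv[[length(iv) + 1L]] <- c(i, j)
    }
  }
  if (!length(iv)) return(0L)
  iv <- do.call(rbind, iv)
  # minimum stabbing of intervals (i, j): greedy by right endpoint
  iv <- iv[order(iv[, 2], iv[, 1]), , drop = FALSE]
  rm_count <- 0L
  covered_until <- -1L
  for (r in seq_len(nrow(iv))) {
    if (iv[r, 1] >= covered_until) {  # gap (i, j) not yet stabbed
      rm_count <- rm_count + 1L
      covered_until <- iv[r, 2]
    }
  }
  rm_count
}

# ---- Nei-Gojobori (1986) machinery ----------------------------------------

ng_env <- new.env(parent = emptyenv())

codon_aa <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

# per-codon synonymous site count: sum over positions of the fraction of
# non-stop single-base changes that preserve the amino acid
ng_sites <- function() {
  if (!is.null(ng_env$sites)) return(ng_env$sites)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  s <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    aa <- gc[[cd]]
    tot <- 0
    for (pos in 1:3) {
      alts <- vapply(setdiff(DNA_BASES, substr(cd, pos, pos)), function(bb) {
        x <- cd
        substr(x, pos, pos) <- bb
        x
      }, character(1))
      aas <- gc[alts]
      valid <- aas != "*"
      if (any(valid)) tot <- tot + sum(aas[valid] == aa) / sum(valid)
    }
    s[cd] <- tot
  }
  ng_env$sites <- s
  s
}

# all orderings of substitutions between two codons; pathways through stop
# codons are excluded (all pathways used as fallback when every one is
# blocked); returns averaged (syn steps, nonsyn steps)
ng_path_diffs <- function(c1, c2) {
  key <- paste(c1, c2)
  hit <- ng_env$paths[[key]]
  if (!is.null(hit)) return(hit)
  gc <- Biostrings::GENETIC_CODE
  pos <- which(chars(c1) != chars(c2))
  d <- length(pos)
  perms <- if (d == 1) list(pos) else if (d == 2)
    list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) pos[o])
  walk <- function(order) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*") return(NULL)
      if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk))
  if (!length(res)) {  # every pathway blocked by a stop: ignore exclusion
    res <- lapply(perms, function(order) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    })
  }
  out <- colMeans(do.call(rbind, res))
  if (is.null(ng_env$paths)) ng_env$paths <- new.env(parent = emptyenv())
  assign(key, out, ng_env$paths)
  out
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n - 2, 3), seq(3, n, 3))
}

#' Pairwise dN and dS by the Nei-Gojobori / Jukes-Cantor method
#'
#' NG86 counting: per-codon synonymous/nonsynonymous site counts averaged
#' between the two sequences; codon differences resolved by averaging over
#' all minimal substitution pathways (pathways through stop codons
#' excluded); proportions corrected with the Jukes-Cantor formula
#' d = -(3/4) ln(1 - (4/3) p). Codon pairs containing a gap or N are
#' skipped (pairwise deletion).
#'
#' @param seq1,seq2 aligned nucleotide strings of equal length divisible
#'   by 3 (gaps allowed as full or partial codons, which are skipped).
#' @return named numeric: \code{dN}, \code{dS} (NA where p >= 3/4 makes the
#'   correction undefined), plus attributes \code{Nd}, \code{Sd},
#'   \code{N_sites}, \code{S_sites}.
#' @export
nei_gojobori <- function(seq1, seq2) {
  stopifnot(nchar(seq1) == nchar(seq2), nchar(seq1) %% 3 == 0)
  cd1 <- split_codons(toupper(seq1))
  cd2 <- split_codons(toupper(seq2))
  ok <- !grepl("[-N]", cd1) & !grepl("[-N]", cd2)
  cd1 <- cd1[ok]; cd2 <- cd2[ok]
  if (!length(cd1)) stop("no comparable codons")
  sites <- ng_sites()
  if (any(!cd1 %in% names(sites)) || any(!cd2 %in% names(sites)))
    stop("in-frame stop codon in input")
  S1 <- sum(sites[cd1]); S2 <- sum(sites[cd2])
  S_sites <- (S1 + S2) / 2
  N_sites <- 3 * length(cd1) - S_sites
  Sd <- 0; Nd <- 0
  for (i in which(cd1 != cd2)) {
    sn <- ng_path_diffs(cd1[i], cd2[i])
    Sd <- Sd + sn[1]; Nd <- Nd + sn[2]
  }
  jc <- function(p) if (is.nan(p)) NaN else if (p >= 3 / 4) NA_real_ else
    -3 / 4 * log(1 - 4 / 3 * p)
  pS <- Sd / S_sites
  pN <- Nd / N_sites
  out <- c(dN = jc(pN), dS = jc(pS))
  attr(out, "counts") <- c(Nd = Nd, Sd = Sd, N_sites = N_sites,
                           S_sites = S_sites)
  out
}

#' Mean dN/dS over full, PBR and non-PBR codon partitions
#'
#' Computes pairwise dN and dS over every sequence pair, restricted to each
#' codon partition, and reports means, the dN/dS ratio, and two-sided
#' Mann-Whitney U tests comparing the off-diagonal pairwise dN values with
#' the dS values within each partition, and each rate between partitions.
#' The pairwise values in these tests are not independent; the tests are
#' reported as descriptive summaries, as is customary for such data.
#'
#' @param aln an \code{allele_alignment}.
#' @param partition integer vector of 1-based PBR codon indices (relative to
#'   the alignment's codon frame), or NULL for the full-exon summary only.
#' @return object of class \code{dnds_summary}: per-partition list with
#'   mean_dN, mean_dS, ratio, the pairwise vectors and the test p-values.
#' @export
dnds_summary <- function(aln, partition = NULL) {
  if (!inherits(aln, "allele_alignment")) aln <- allele_alignment(aln)
  frame <- attr(aln, "frame")
  seqs <- substring(unclass(aln), frame, nchar(aln))
  n_codon <- nchar(seqs[1]) %/% 3
  parts <- list(full = seq_len(n_codon))
  if (!is.null(partition)) {
    partition <- as.integer(partition)
    if (!length(partition)) stop("empty partition")
    if (any(partition < 1 | partition > n_codon))
      stop("partition indices outside codon range")
    parts$PBR <- sort(partition)
    parts$nonPBR <- setdiff(seq_len(n_codon), partition)
  }
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  pairs <- utils::combn(n, 2)

  subset_codons <- function(seq, idx) {
    paste(split_codons(seq)[idx], collapse = "")
  }
  res <- lapply(parts, function(idx) {
    sub <- vapply(seqs, subset_codons, character(1), idx = idx)
    dn <- ds <- numeric(ncol(pairs))
    for (pp in seq_len(ncol(pairs))) {
      v <- nei_gojobori(sub[pairs[1, pp]], sub[pairs[2, pp]])
      dn[pp] <- v["dN"]; ds[pp] <- v["dS"]
    }
    mw <- if (sum(!is.na(dn)) > 0 && sum(!is.na(ds)) > 0)
      suppressWarnings(wilcox.test(dn, ds)$p.value) else NA_real_
    list(mean_dN = mean(dn, na.rm = TRUE), mean_dS = mean(ds, na.rm = TRUE),
         ratio = mean(dn, na.rm = TRUE) / mean(ds, na.rm = TRUE),
         dN = dn, dS = ds, p_dn_vs_ds = mw)
  })
  if (!is.null(partition)) {
    res$comparisons <- list(
      p_dN_pbr_vs_nonpbr = suppressWarnings(
        wilcox.test(res$PBR$dN, res$nonPBR$dN)$p.value),
      p_dS_pbr_vs_nonpbr = suppressWarnings(
        wilcox.test(res$PBR$dS, res$nonPBR$dS)$p.value))
  }
  structure(res, class = "dnds_summary")
}

#' @export
print.dnds_summary <- function(x, ...) {
  for (nm in setdiff(names(x), "comparisons")) {
    p <- x[[nm]]
    cat(sprintf("%-7s mean dN = %.4f  mean dS = %.4f  dN/dS = %.3f  (MW p = %.3g)\n",
                nm, p$mean_dN, p$mean_dS, p$ratio, p$p_dn_vs_ds))
  }
  if (!is.null(x$comparisons))
    cat(sprintf("PBR vs non-PBR: dN p = %.3g, dS p = %.3g\n",
                x$comparisons$p_dN_pbr_vs_nonpbr,
                x$comparisons$p_dS_pbr_vs_nonpbr))
  invisible(x)
}

#' Translate an allele alignment and collapse to unique proteins
#'
#' Translates each sequence with the standard genetic code (codons
#' containing gaps become the gap residue "-", so a 3-nt insertion allele
#' contributes one extra residue aligned against gap in the others), counts
#' unique protein sequences, variable amino-acid sites (columns with two or
#' more distinct non-gap residues) and amino-acid changes (per column,
#' distinct non-gap residues minus one).
#'
#' @param aln an \code{allele_alignment}.
#' @return list with \code{proteins} (aligned, named), \code{n_unique},
#'   \code{variable_sites}, \code{aa_changes} and
#'   \code{variable_positions}.
#' @export
translate_and_collapse <- function(aln) {
  if (!inherits(aln, "allele_alignment")) aln <- allele_alignment(aln)
  frame <- attr(aln, "frame")
  gc <- Biostrings::GENETIC_CODE
  prot <- vapply(names(aln), function(nm) {
    cds <- split_codons(substring(aln[[nm]], frame))
    aas <- vapply(cds, function(cd) {
      if (grepl("[-N]", cd)) return("-")
      aa <- gc[[cd]]
      if (identical(aa, "*"))
        stop("internal stop codon in sequence '", nm, "'")
      aa
    }, character(1))
    paste(aas, collapse = "")
  }, character(1))
  pm <- do.call(rbind, strsplit(prot, ""))
  nres <- apply(pm, 2, function(col) length(unique(col[col != "-"])))
  list(proteins = prot, n_unique = length(unique(prot)),
       variable_sites = sum(nres >= 2),
       aa_changes = sum(pmax(nres - 1L, 0L)),
       variable_positions = which(nres >= 2))
}

#' Read a codon-partition file (one 1-based codon index per line)
#' @param path text file of integers.
#' @return sorted integer vector.
#' @export
read_partition <- function(path) {
  sort(unique(as.integer(readLines(path))))
}
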