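#' Forward (DG2) and reverse (GENDG) template-specific primers
#'
#' Degenerate primer pair amplifying MHC class I exon 3 in pipits; the
#' forward primer carries two IUPAC Y positions.
#' @format character scalars.
#' @export
DG2 <- "TTGCGCTCYAGCTCYTTCTGCT"

#' @rdname DG2
#' @export
GENDG <- "TCCCCACAGGTCTCCACAC"

#' Roche 10-bp extended multiplex identifiers used for dual barcoding
#'
#' The nine standard MIDs (numbers 1, 2, 3, 4, 5, 7, 8, 10, 11) with pairwise
#' distance >= 3, giving 9 x 9 = 81 forward/reverse combinations per pool.
#' @format named character vector of length 9.
#' @export
ROCHE_MIDS <- c(
  MID01 = "ACGAGTGCGT", MID02 = "ACGCTCGACA", MID03 = "AGACGCACTC",
  MID04 = "AGCACTGTAG", MID05 = "ATCAGACACG", MID07 = "CGTGTCTCTA",
  MID08 = "CTCGCGTGTC", MID10 = "TCTCTATGCG", MID11 = "TGATACGTCT"
)

#' PCR + pyrosequencing error model for amplicon simulation
#'
#' Parameterises the artefact classes the replicate-validated filtering
#' pipeline is designed to remove. Two channels generate artefacts:
#' \describe{
#'   \item{late (per-read) errors}{independent substitutions at
#'     \code{sub_rate} per base and 1-2 bp indel events at \code{indel_rate}
#'     per read; these overwhelmingly produce singleton clusters.}
#'   \item{amplified (early-PCR) artefact lineages}{a Poisson number
#'     (\code{lineage_mean}) of 1-2 bp mutant lineages per amplicon, each
#'     amplified to an intra-amplicon frequency drawn from
#'     \code{lineage_freq}; chimeric reads (a \code{chimera_fraction} of the
#'     amplicon) are likewise concentrated into a few recurrent
#'     parent/breakpoint lineages (\code{chimera_lineage_mean}). Early-cycle
#'     errors are amplified by later cycles, which is how real amplicon data
#'     acquire artefact clusters at frequencies of several percent.}
#' }
#' Singleton noise (\code{singleton_rate}) injects one-off mutant reads, and
#' the two-state quality profile emits Phred \code{q_high} bases with
#' probability \code{1 - low_q_fraction} and \code{q_low} otherwise.
#'
#' @param sub_rate per-base substitution rate (late channel).
#' @param indel_rate per-read probability of one 1-2 bp indel event.
#' @param chimera_fraction fraction of reads with chimeric provenance.
#' @param singleton_rate fraction of reads that are one-off noise sequences.
#' @param lineage_mean Poisson mean of amplified 1-2 bp mutant lineages per
#'   amplicon.
#' @param lineage_freq length-2 range of intra-amplicon frequencies for
#'   amplified mutant lineages.
#' @param chimera_lineage_mean Poisson mean of distinct chimeric lineages an
#'   amplicon's chimeric reads are drawn from.
#' @param q_high,q_low Phred scores of the two quality states.
#' @param low_q_fraction fraction of low-quality bases.
#' @return object of class \code{error_model}.
#' @export
error_model <- function(sub_rate = 5e-4, indel_rate = 0.01,
                        chimera_fraction = 0.05, singleton_rate = 0.01,
                        lineage_mean = 4, lineage_freq = c(0.005, 0.035),
                        chimera_lineage_mean = 3,
                        q_high = 37, q_low = 12, low_q_fraction = 0.02) {
  rates <- c(sub_rate, indel_rate, chimera_fraction, singleton_rate,
             low_q_fraction, lineage_freq)
  if (any(rates < 0) || any(rates > 1))
    stop("all rates must lie in [0, 1]")
  structure(list(sub_rate = sub_rate, indel_rate = indel_rate,
                 chimera_fraction = chimera_fraction,
                 singleton_rate = singleton_rate,
                 lineage_mean = lineage_mean, lineage_freq = lineage_freq,
                 chimera_lineage_mean = chimera_lineage_mean,
                 q_high = q_high, q_low = q_low,
                 low_q_fraction = low_q_fraction),
            class = "error_model")
}

#' Error-free model (all artefact channels off)
#' @rdname error_model
#' @export
error_model_off <- function() {
  error_model(sub_rate = 0, indel_rate = 0, chimera_fraction = 0,
              singleton_rate = 0, lineage_mean = 0, chimera_lineage_mean = 0,
              low_q_fraction = 0)
}

# substitute k random positions of a sequence (new base always differs)
mutate_seq <- function(seq, k) {
  s <- chars(seq)
  pos <- sample.int(length(s), k)
  for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1)
  paste(s, collapse = "")
}

# apply a 1-2 bp indel at a random internal position
indel_seq <- function(seq) {
  n <- nchar(seq)
  w <- sample(1:2, 1)
  if (runif(1) < 0.5 && n > w + 2) {      # deletion
    p <- sample.int(n - w, 1)
    paste0(substr(seq, 1, p - 1), substr(seq, p + w, n))
  } else {                                 # insertion
    p <- sample.int(n, 1)
    paste0(substr(seq, 1, p), random_dna(w), substr(seq, p + 1, n))
  }
}

make_chimera <- function(a, b, k) {
  paste0(substr(a, 1, k), substr(b, k + 1, nchar(b)))
}

#' Simulate one amplicon (one PCR replicate of one sample)
#'
#' Read counts for error-free reads follow a multinomial with probabilities
#' proportional to copy number times relative amplification efficiency,
#' \eqn{p_i = c_i e_i / \sum_j c_j e_j}. Chimeric reads are prefix+suffix
#' joins of two distinct co-amplified parent sequences (parents drawn
#' proportionally to read share, breakpoint uniform over internal positions).
#' Every read receives exactly one provenance record in the truth table.
#'
#' @param genotype a genotype entry from \code{\link{make_population}} (or a
#'   list with \code{sample_id}, \code{alleles}, \code{copies}).
#' @param pool the \code{allele_pool} providing allele sequences.
#' @param eff named efficiency vector (see \code{\link{assign_efficiencies}}).
#' @param n_reads number of reads to emit (>= 1).
#' @param error an \code{error_model}.
#' @param seed integer seed.
#' @param force_single_copy if TRUE, copy numbers are all set to 1 (matches
#'   the efficiency estimator's modelling assumption).
#' @return object of class \code{sim_amplicon}: list with \code{reads}
#'   (template-only sequences) and \code{truth} (one provenance row per
#'   read: class is one of allele/error/chimera/noise).
#' @export
simulate_amplicon <- function(genotype, pool, eff, n_reads, error = error_model(),
                              seed = 1, force_single_copy = FALSE) {
  stopifnot(n_reads >= 1)
  alleles <- genotype$alleles
  if (!all(alleles %in% names(eff)))
    stop("efficiency missing for allele(s): ",
         paste(setdiff(alleles, names(eff)), collapse = ", "))
  if (!all(alleles %in% names(pool$alleles)))
    stop("genotype allele absent from pool")
  set.seed(seed)

  copies <- genotype$copies[alleles]
  if (force_single_copy) copies[] <- 1L
  p <- copies * eff[alleles]
  p <- p / sum(p)
  seqs <- pool$alleles[alleles]
  L <- nchar(seqs)

  n_sing <- rbinom(1, n_reads, error$singleton_rate)
  n_chim <- rbinom(1, n_reads, error$chimera_fraction)

  # amplified 1-2 bp mutant lineages
  n_lin <- if (error$lineage_mean > 0) rpois(1, error$lineage_mean) else 0L
  lin_counts <- integer(0); lin_seqs <- character(0); lin_src <- character(0)
  lin_edits <- integer(0)
  if (n_lin > 0) {
    for (l in seq_len(n_lin)) {
      src <- sample(alleles, 1, prob = p)
      k <- sample(1:2, 1, prob = c(0.7, 0.3))
      f <- runif(1, error$lineage_freq[1], error$lineage_freq[2])
      cnt <- rbinom(1, n_reads, f)
      if (cnt == 0) next
      lin_seqs <- c(lin_seqs, mutate_seq(seqs[src], k))
      lin_src <- c(lin_src, src)
      lin_counts <- c(lin_counts, cnt)
      lin_edits <- c(lin_edits, k)
    }
  }

  budget <- n_sing + n_chim + sum(lin_counts)
  if (budget > n_reads) {  # degenerate parameterisation; scale artefacts down
    keep <- n_reads
    n_sing <- min(n_sing, keep); keep <- keep - n_sing
    n_chim <- min(n_chim, keep); keep <- keep - n_chim
    while (sum(lin_counts) > keep && length(lin_counts))
      lin_counts[which.max(lin_counts)] <- lin_counts[which.max(lin_counts)] - 1L
  }
  n_clean <- n_reads - n_sing - n_chim - sum(lin_counts)

  # error-free source reads: multinomial over alleles, then a late-error
  # subset is mutated read-by-read
  clean_counts <- if (n_clean > 0) as.integer(rmultinom(1, n_clean, p)) else
    integer(length(alleles))
  names(clean_counts) <- alleles

  racc <- list(); tacc <- list()
  add <- function(seqv, class, source = NA_character_,
                  parent_a = NA_character_, parent_b = NA_character_,
                  breakpoint = NA_integer_, n_edits = 0L) {
    if (!length(seqv)) return()
    j <- length(racc) + 1L
    racc[[j]] <<- seqv
    tacc[[j]] <<- c(class = class, source = source, parent_a = parent_a,
                    parent_b = parent_b, breakpoint = breakpoint,
                    n_edits = n_edits, n = length(seqv))
  }

  for (i in seq_along(alleles)) {
    ni <- clean_counts[i]
    if (ni == 0) next
    p_sub <- 1 - (1 - error$sub_rate)^L[i]
    n_sub <- rbinom(1, ni, p_sub)
    n_ind <- rbinom(1, ni - n_sub, error$indel_rate)
    n_ok <- ni - n_sub - n_ind
    if (n_ok > 0) add(rep(unname(seqs[i]), n_ok), "allele", alleles[i])
    if (n_sub > 0) {
      ks <- 1L + rbinom(n_sub, L[i] - 1L, error$sub_rate)
      mut <- vapply(ks, function(k) mutate_seq(seqs[i], k), character(1))
      for (u in seq_len(n_sub))
        add(mut[u], "error", alleles[i], n_edits = ks[u])
    }
    if (n_ind > 0)
      for (u in seq_len(n_ind))
        add(indel_seq(seqs[i]), "error", alleles[i], n_edits = 1L)
  }

  if (length(lin_counts))
    for (l in seq_along(lin_counts))
      add(rep(lin_seqs[l], lin_counts[l]), "error", lin_src[l],
          n_edits = lin_edits[l])

  if (n_chim > 0) {
    n_cl <- max(1L, rpois(1, max(error$chimera_lineage_mean, 1e-9)))
    w <- stats::rgamma(n_cl, 1)
    cl_counts <- as.integer(rmultinom(1, n_chim, w / sum(w)))
    for (l in seq_len(n_cl)) {
      if (cl_counts[l] == 0) next
      if (length(alleles) >= 2) {
        pa <- sample(alleles, 2, prob = p)
      } else {
        pa <- c(alleles, alleles)  # single-allele genotype: self-join
      }
      k <- sample.int(min(nchar(seqs[pa[1]]), nchar(seqs[pa[2]])) - 1L, 1)
      add(rep(make_chimera(seqs[pa[1]], seqs[pa[2]], k), cl_counts[l]),
          "chimera", parent_a = pa[1], parent_b = pa[2], breakpoint = k)
    }
  }

  if (n_sing > 0)
    for (u in seq_len(n_sing)) {
      src <- sample(alleles, 1, prob = p)
      add(mutate_seq(seqs[src], 1L), "noise", src, n_edits = 1L)
    }

  reads <- unlist(racc, use.names = FALSE)
  ev <- do.call(rbind, tacc)  # character matrix, one row per provenance event
  rep_n <- as.integer(ev[, "n"])
  ex <- rep(seq_len(nrow(ev)), rep_n)
  tt <- data.frame(class = ev[ex, "class"], source = ev[ex, "source"],
                   parent_a = ev[ex, "parent_a"], parent_b = ev[ex, "parent_b"],
                   breakpoint = as.integer(ev[ex, "breakpoint"]),
                   n_edits = as.integer(ev[ex, "n_edits"]),
                   stringsAsFactors = FALSE)
  ord <- sample.int(length(reads))
  reads <- reads[ord]
  tt <- tt[ord, , drop = FALSE]
  tt$read_id <- sprintf("R%06d", seq_along(reads))
  rownames(tt) <- NULL

  structure(list(sample_id = genotype$sample_id, reads = reads, truth = tt,
                 genotype = genotype, n_reads = length(reads)),
            class = "sim_amplicon")
}

#' Describe a replicated, pooled amplicon sequencing run
#'
#' Defaults reproduce the study design this package emulates: 320 samples
#' (screened twice, 640 amplicons) in eight pools of 80, dual 10-bp MIDs from
#' a 9 x 9 set (81 combinations per pool), ~240 bp templates between the
#' DG2/GENDG primers, six loci with 4-12 alleles per individual, per-allele
#' relative efficiencies, and a negative-binomial read depth with mean 1,430
#' reads per amplicon.
#'
#' @param n_samples number of individuals (each sequenced in two replicates).
#' @param n_pools number of pools (even; replicates of a sample are placed in
#'   different pools with different MID combinations).
#' @param n_loci loci per genotype.
#' @param pool optional \code{allele_pool}; by default a 22-allele, 240-bp
#'   pool with two insertion alleles is generated at simulation time.
#' @param n_alleles,n_insertion_alleles pool parameters used when
#'   \code{pool} is NULL.
#' @param efficiency_range range of relative amplification efficiencies.
#' @param mean_reads,reads_dispersion negative-binomial depth per amplicon
#'   (mu / size); depths are truncated below at \code{min_reads}.
#' @param min_reads lower truncation for per-amplicon depth.
#' @param error an \code{error_model}.
#' @param fwd_mids,rev_mids MID sets (default the nine Roche MIDs).
#' @param fwd_primer,rev_primer template-specific primers.
#' @return object of class \code{study_design}.
#' @export
study_design <- function(n_samples = 320, n_pools = 8, n_loci = 6,
                         pool = NULL, n_alleles = 22, n_insertion_alleles = 2,
                         efficiency_range = c(0.5, 2),
                         mean_reads = 1430, reads_dispersion = 5,
                         min_reads = 30,
                         error = error_model(),
                         fwd_mids = ROCHE_MIDS, rev_mids = ROCHE_MIDS,
                         fwd_primer = DG2, rev_primer = GENDG) {
  stopifnot(n_pools %% 2 == 0, n_samples >= 1)
  pool_size <- 2 * n_samples / n_pools
  if (pool_size != round(pool_size))
    stop("2 * n_samples must be divisible by n_pools")
  if (pool_size > length(fwd_mids) * length(rev_mids))
    stop("pool size exceeds the number of MID combinations (",
         length(fwd_mids) * length(rev_mids), ")")
  structure(list(n_samples = n_samples, n_pools = n_pools,
                 pool_size = pool_size, n_loci = n_loci, pool = pool,
                 n_alleles = n_alleles,
                 n_insertion_alleles = n_insertion_alleles,
                 efficiency_range = efficiency_range,
                 mean_reads = mean_reads, reads_dispersion = reads_dispersion,
                 min_reads = min_reads, error = error,
                 fwd_mids = fwd_mids, rev_mids = rev_mids,
                 fwd_primer = fwd_primer, rev_primer = rev_primer),
            class = "study_design")
}

# Dual-MID layout: replicate 1 of each sample in the first half of the pools,
# replicate 2 in the second half, with a shifted MID-combination index so the
# two replicates never share a (fwd, rev) pair.
mid_layout <- function(design) {
  ns <- design$n_samples
  half <- design$n_pools / 2
  block <- ns / half
  combos <- expand.grid(fwd = seq_along(design$fwd_mids),
                        rev = seq_along(design$rev_mids))
  n_combo <- nrow(combos)
  rows <- vector("list", 2 * ns)
  for (s in seq_len(ns)) {
    p1 <- (s - 1) %/% block + 1
    i <- (s - 1) %% block + 1
    c1 <- i
    c2 <- ((i - 1 + 37) %% n_combo) + 1
    sid <- sprintf("S%03d", s)
    rows[[2 * s - 1]] <- data.frame(
      pool = p1, sample_id = sid, replicate = 1L,
      fwd_mid = names(design$fwd_mids)[combos$fwd[c1]],
      rev_mid = names(design$rev_mids)[combos$rev[c1]],
      stringsAsFactors = FALSE)
    rows[[2 * s]] <- data.frame(
      pool = half + p1, sample_id = sid, replicate = 2L,
      fwd_mid = names(design$fwd_mids)[combos$fwd[c2]],
      rev_mid = names(design$rev_mids)[combos$rev[c2]],
      stringsAsFactors = FALSE)
  }
  m <- do.call(rbind, rows)
  m$amplicon_id <- sprintf("%s_r%d", m$sample_id, m$replicate)
  m
}

#' Simulate a full replicated study with ground truth
#'
#' Generates (or reuses) the allele pool, samples the population and the
#' per-allele efficiencies, lays out dual-MID barcodes, and simulates every
#' amplicon. All stochastic draws derive from named substreams of the master
#' seed, so pools, genotypes and reads are independently reproducible.
#'
#' @param design a \code{study_design}.
#' @param seed master seed.
#' @param keep_reads if FALSE, per-amplicon raw reads are dropped after
#'   cluster tables are computed (memory saver for large runs).
#' @return object of class \code{sim_study}: pool, population, efficiencies,
#'   mid_map and a list of \code{sim_amplicon} objects.
#' @export
simulate_study <- function(design, seed = 1, keep_reads = TRUE) {
  stopifnot(inherits(design, "study_design"))
  pool <- design$pool %||% make_allele_pool(
    design$n_alleles, 240, 3, design$n_insertion_alleles,
    seed = derive_seed(seed, "pool"))
  popn <- make_population(pool, design$n_samples, design$n_loci,
                          seed = derive_seed(seed, "genotypes"))
  eff <- assign_efficiencies(pool, range = design$efficiency_range,
                             seed = derive_seed(seed, "efficiency"))
  mid_map <- mid_layout(design)

  set.seed(derive_seed(seed, "depth"))
  depth <- pmax(design$min_reads,
                rnbinom(nrow(mid_map), mu = design$mean_reads,
                        size = design$reads_dispersion))

  sample_index <- setNames(seq_along(popn),
                           vapply(popn, `[[`, character(1), "sample_id"))
  amplicons <- vector("list", nrow(mid_map))
  for (a in seq_len(nrow(mid_map))) {
    g <- popn[[sample_index[[mid_map$sample_id[a]]]]]
    amp <- simulate_amplicon(g, pool, eff, depth[a], design$error,
                             seed = derive_seed(seed, "reads", a))
    amp$amplicon_id <- mid_map$amplicon_id[a]
    amp$replicate <- mid_map$replicate[a]
    amp$pool <- mid_map$pool[a]
    if (!keep_reads) {
      amp$clusters <- cluster_reads(amp$reads)
      amp$reads <- NULL
    }
    amplicons[[a]] <- amp
  }
  names(amplicons) <- mid_map$amplicon_id
  structure(list(design = design, pool = pool, population = popn,
                 efficiencies = eff, mid_map = mid_map,
                 amplicons = amplicons, seed = seed),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Simulated amplicon study:", x$design$n_samples, "samples x 2 replicates,",
      length(x$amplicons), "amplicons in", x$design$n_pools, "pools\n")
  cat("  pool:", length(x$pool$alleles), "alleles; mean depth",
      round(mean(vapply(x$amplicons, `[[`, numeric(1), "n_reads"))), "reads\n")
  invisible(x)
}

# resolve IUPAC degeneracies to concrete bases, independently per read
resolve_iupac <- function(primer, n) {
  out <- rep(primer, n)
  bases <- chars(primer)
  for (pos in which(!bases %in% DNA_BASES)) {
    substr(out, pos, pos) <- sample(IUPAC[[bases[pos]]], n, replace = TRUE)
  }
  out
}

quality_strings <- function(lens, error) {
  total <- sum(lens)
  q <- ifelse(runif(total) < error$low_q_fraction, error$q_low, error$q_high)
  ch <- intToUtf8(q + 33L, multiple = TRUE)
  idx <- rep(seq_along(lens), lens)
  unname(vapply(split(ch, idx), paste, character(1), collapse = ""))
}

#' Serialise a simulated study to FASTQ plus truth tables
#'
#' Each read is written as forward MID + forward primer + template +
#' reverse-complemented reverse primer + reverse-complemented reverse MID,
#' with two-state per-base qualities, one FASTQ per pool (Sanger Phred+33,
#' written via Biostrings). Truth tables and the MID map are written as TSV.
#'
#' @param study a \code{sim_study} (simulated with \code{keep_reads = TRUE}).
#' @param out_dir output directory (created if needed).
#' @param seed seed for quality strings and primer-degeneracy resolution.
#' @return invisibly, a character vector of files written.
#' @export
write_run <- function(study, out_dir, seed = 1) {
  stopifnot(inherits(study, "sim_study"))
  design <- study$design
  m <- study$mid_map
  key <- paste(m$pool, m$fwd_mid, m$rev_mid)
  if (anyDuplicated(key))
    stop("duplicate MID pair within a pool")
  by_sample <- split(m$pool, m$sample_id)
  if (any(vapply(by_sample, function(p) length(unique(p)) != 2L, logical(1))))
    stop("the two replicates of a sample must be in different pools")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(seed, "serialise"))

  files <- character(0)
  rcp <- revcomp(design$rev_primer)
  for (p in sort(unique(m$pool))) {
    rows <- which(m$pool == p)
    seqs <- character(0); ids <- character(0)
    for (a in rows) {
      amp <- study$amplicons[[m$amplicon_id[a]]]
      if (is.null(amp$reads))
        stop("study was simulated with keep_reads = FALSE; reads unavailable")
      n <- length(amp$reads)
      fwd <- unname(study$design$fwd_mids[m$fwd_mid[a]])
      rev <- unname(study$design$rev_mids[m$rev_mid[a]])
      full <- paste0(fwd, resolve_iupac(design$fwd_primer, n), amp$reads,
                     resolve_iupac(rcp, n), revcomp(rev))
      seqs <- c(seqs, full)
      ids <- c(ids, paste0(m$amplicon_id[a], "_", amp$truth$read_id))
    }
    quals <- quality_strings(nchar(seqs), design$error)
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- ids
    fq <- file.path(out_dir, sprintf("pool%02d.fastq", p))
    Biostrings::writeXStringSet(dss, fq, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
    files <- c(files, fq)
  }

  truth <- do.call(rbind, lapply(names(study$amplicons), function(id) {
    tt <- study$amplicons[[id]]$truth
    cbind(amplicon_id = id, tt[, c("read_id", "class", "source", "parent_a",
                                   "parent_b", "breakpoint", "n_edits")])
  }))
  tf <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  mf <- file.path(out_dir, "mid_map.tsv")
  utils::write.table(m, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, tf, mf))
}
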