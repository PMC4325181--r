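# Internal container built by call_genotypes(): for each sample a list
# (r1, r2) of cluster data.frames carrying label + state columns.

allele_states <- c("putative_allele", "allele")

# samples in which a sequence has allele status in >= 1 amplicon
seq_sample_sets <- function(samples, states) {
  acc <- new.env(parent = emptyenv())
  for (sid in names(samples)) {
    pr <- samples[[sid]]
    for (a in c("r1", "r2")) {
      cl <- pr[[a]]
      hit <- unique(cl$sequence[cl$state %in% states])
      for (s in hit) assign(s, union(get0(s, acc, ifnotfound = character(0)),
                                     sid), acc)
    }
  }
  as.list(acc)
}

# samples in which a sequence is present (non-discarded) in BOTH amplicons
both_amplicon_sets <- function(samples) {
  acc <- new.env(parent = emptyenv())
  for (sid in names(samples)) {
    pr <- samples[[sid]]
    hit <- intersect(present_seqs(pr$r1), present_seqs(pr$r2))
    for (s in hit) assign(s, c(get0(s, acc, ifnotfound = character(0)), sid),
                          acc)
  }
  as.list(acc)
}

#' Post-process classifications for a large data set
#'
#' Applies, in order: (a) putative alleles confirmed in only one individual
#' are dropped; (b) unclassified variants matching a surviving catalog allele
#' are promoted in those amplicons; (d) artefact entries matching a catalog
#' allele, present in both of a sample's amplicons with intra-amplicon
#' frequency above the least frequent entry of the dataset-wide
#' putative-allele list, are
#' promoted; (c) variants that occur in both amplicons of more than
#' \code{prevalence_threshold} of individuals while remaining unclassified
#' there are added to the catalog as low-efficiency alleles (the
#' allelic-dropout signature: consistently present, always at read counts
#' below the artefact background). Promotions
#' (b) and (d) never resurrect alleles dropped in (a).
#'
#' @param samples named list (by sample_id) of lists \code{r1}, \code{r2}
#'   of cluster data.frames after step 3.
#' @param min_individuals minimum individuals for a putative allele to be
#'   kept (default 2).
#' @param prevalence_threshold both-amplicon prevalence (strictly greater
#'   than) for the low-efficiency flag; default 0.8.
#' @return list with \code{samples} (updated states), \code{catalog}
#'   (sequences) and \code{low_efficiency} (flagged subset).
#' @export
postprocess_large <- function(samples, min_individuals = 2,
                              prevalence_threshold = 0.8) {
  n_ind <- length(samples)
  allele_by <- seq_sample_sets(samples, allele_states)
  uncl_by <- seq_sample_sets(samples, "unclassified")
  both_by <- both_amplicon_sets(samples)
  # dropout signature, recorded before any promotion: present in both
  # amplicons of a bird yet unclassified in at least one of them
  uncl_both_by <- lapply(setNames(nm = names(uncl_by)), function(s)
    intersect(uncl_by[[s]], both_by[[s]] %||% character(0)))

  # (a) drop single-individual alleles
  catalog <- names(allele_by)[vapply(allele_by, length, integer(1)) >=
                                min_individuals]
  dropped <- setdiff(names(allele_by), catalog)
  for (sid in names(samples)) {
    for (a in c("r1", "r2")) {
      cl <- samples[[sid]][[a]]
      hit <- cl$state %in% allele_states & cl$sequence %in% dropped
      cl$state[hit] <- "artefact"
      samples[[sid]][[a]] <- cl
    }
  }

  # least frequent entry of the (surviving) putative-allele list, dataset-wide
  min_allele_freq <- min(unlist(lapply(samples, function(pr)
    lapply(pr, function(cl)
      cl$frequency[cl$state %in% allele_states &
                     cl$sequence %in% catalog]))), Inf)

  # (b) promote unclassified matches of surviving catalog alleles
  # (d) promote qualifying artefact matches
  for (sid in names(samples)) {
    pr <- samples[[sid]]
    in_both <- intersect(present_seqs(pr$r1), present_seqs(pr$r2))
    for (a in c("r1", "r2")) {
      cl <- pr[[a]]
      promote <- cl$state == "unclassified" & cl$sequence %in% catalog
      cl$state[promote] <- "allele"
      pr[[a]] <- cl
    }
    ok_d <- vapply(in_both, function(s) {
      all(vapply(c("r1", "r2"), function(a) {
        cl <- pr[[a]]
        q <- which(cl$sequence == s)
        cl$state[q] == "artefact" && s %in% catalog &&
          cl$frequency[q] > min_allele_freq
      }, logical(1)))
    }, logical(1))
    for (s in in_both[ok_d]) {
      for (a in c("r1", "r2")) {
        cl <- pr[[a]]
        cl$state[cl$sequence == s] <- "allele"
        pr[[a]] <- cl
      }
    }
    samples[[sid]] <- pr
  }

  # (c) low-efficiency alleles pulled from the unclassified list: variants
  # that sit in both amplicons of more than prevalence_threshold of birds
  # while failing the step-3 frequency criterion there
  low_eff <- character(0)
  for (s in names(uncl_both_by)) {
    prev <- length(uncl_both_by[[s]]) / n_ind
    if (prev > prevalence_threshold) low_eff <- c(low_eff, s)
  }
  for (s in low_eff) {
    for (sid in both_by[[s]]) {
      for (a in c("r1", "r2")) {
        cl <- samples[[sid]][[a]]
        hit <- cl$sequence == s & !cl$state %in% c(allele_states, "discarded")
        cl$state[hit] <- "allele"
        samples[[sid]][[a]] <- cl
      }
    }
  }
  catalog <- union(catalog, low_eff)
  list(samples = samples, catalog = catalog, low_efficiency = low_eff)
}

#' Post-process classifications for a small data set
#'
#' Small-sample rules: a variant that is a putative allele in both replicates
#' of even a single sample is kept; a variant that is an allele in only one
#' amplicon but occurs as an unclassified variant in other samples is kept;
#' unclassified variants present in both replicates of at least
#' \code{min_individuals} birds are promoted to alleles. Unclassified
#' instances of catalog alleles are promoted.
#'
#' @inheritParams postprocess_large
#' @param min_individuals birds required for the unclassified-promotion rule.
#' @return list with \code{samples}, \code{catalog}, \code{low_efficiency}
#'   (always empty here).
#' @export
postprocess_small <- function(samples, min_individuals = 2) {
  uncl_by <- seq_sample_sets(samples, "unclassified")
  both_by <- both_amplicon_sets(samples)

  keep <- character(0)
  # rule 1: allele status in both replicates of >= 1 sample
  for (sid in names(samples)) {
    pr <- samples[[sid]]
    a1 <- pr$r1$sequence[pr$r1$state %in% allele_states]
    a2 <- pr$r2$sequence[pr$r2$state %in% allele_states]
    keep <- union(keep, intersect(a1, a2))
  }
  # rule 2: allele in one amplicon + unclassified elsewhere
  allele_by <- seq_sample_sets(samples, allele_states)
  for (s in names(allele_by)) {
    if (s %in% keep) next
    others <- setdiff(uncl_by[[s]] %||% character(0), allele_by[[s]])
    if (length(others)) keep <- union(keep, s)
  }
  # rule 3: unclassified in both replicates of >= min_individuals birds
  for (s in names(uncl_by)) {
    if (s %in% keep) next
    n_both <- length(both_by[[s]] %||% character(0))
    if (n_both >= min_individuals) keep <- union(keep, s)
  }

  for (sid in names(samples)) {
    for (a in c("r1", "r2")) {
      cl <- samples[[sid]][[a]]
      cl$state[cl$state == "unclassified" & cl$sequence %in% keep] <- "allele"
      cl$state[cl$state %in% allele_states & !cl$sequence %in% keep] <-
        "artefact"
      samples[[sid]][[a]] <- cl
    }
  }
  list(samples = samples, catalog = keep, low_efficiency = character(0))
}

#' Call genotypes from per-amplicon read sets
#'
#' Runs the full classification cascade: per-amplicon clustering and step-1
#' labelling, cross-replicate step 2, frequency-based step 3, and the
#' large- or small-sample post-processing, then assembles the allele catalog
#' and per-sample genotype calls with repeatability.
#'
#' @param amplicons list of amplicons; each needs \code{sample_id},
#'   \code{replicate} and \code{reads} (or a precomputed \code{clusters}
#'   data.frame). \code{\link{simulate_study}} amplicons and
#'   \code{\link{demultiplex}} records both qualify.
#' @param mode "large" (confirmation across individuals required) or
#'   "small" (single-sample confirmation rules).
#' @param min_individuals,prevalence_threshold see
#'   \code{\link{postprocess_large}}.
#' @param allele_prefix prefix for catalog allele names.
#' @return object of class \code{genotype_calls}: \code{catalog} data.frame
#'   (allele, sequence, n_samples, low_efficiency), \code{calls} data.frame
#'   (sample_id, alleles, repeatability, flags), per-amplicon states and a
#'   per-step classification report.
#' @export
call_genotypes <- function(amplicons, mode = c("large", "small"),
                           min_individuals = 2, prevalence_threshold = 0.8,
                           allele_prefix = "ALC") {
  mode <- match.arg(mode)
  sids <- vapply(amplicons, `[[`, character(1), "sample_id")
  reps <- vapply(amplicons, function(a) as.integer(a$replicate), integer(1))

  # step 1 everywhere
  step1 <- lapply(amplicons, function(a) {
    cl <- a$clusters %||% cluster_reads(a$reads)
    classify_step1(cl)
  })

  # dataset-wide presence counts and step-1 putative-allele index
  all_seq <- unlist(lapply(step1, present_seqs), use.names = FALSE)
  dataset_count <- table(all_seq)
  dataset_count <- setNames(as.integer(dataset_count), names(dataset_count))

  pa_acc <- new.env(parent = emptyenv())
  for (k in seq_along(step1)) {
    cl <- step1[[k]]
    for (s in cl$sequence[cl$label == "putative_allele"])
      assign(s, union(get0(s, pa_acc, ifnotfound = character(0)), sids[k]),
             pa_acc)
  }
  allele_samples <- as.list(pa_acc)

  # pair replicates
  samples <- list()
  incomplete <- character(0)
  for (sid in unique(sids)) {
    i1 <- which(sids == sid & reps == 1L)
    i2 <- which(sids == sid & reps == 2L)
    if (length(i1) != 1 || length(i2) != 1) {
      incomplete <- c(incomplete, sid)
      next
    }
    p2 <- classify_step2(step1[[i1]], step1[[i2]], dataset_count)
    p3 <- classify_step3(p2$r1, p2$r2, sid, allele_samples)
    samples[[sid]] <- p3
  }

  post <- if (mode == "large")
    postprocess_large(samples, min_individuals, prevalence_threshold)
  else postprocess_small(samples, min_individuals)
  samples <- post$samples

  # name catalog alleles by decreasing number of carriers
  carrier <- seq_sample_sets(samples, allele_states)
  carrier <- carrier[intersect(names(carrier), post$catalog)]
  n_car <- vapply(post$catalog, function(s)
    length(carrier[[s]] %||% character(0)), integer(1))
  ord <- order(-n_car, post$catalog)
  catalog <- data.frame(
    allele = sprintf("%s%02d", allele_prefix, seq_along(post$catalog)),
    sequence = post$catalog[ord], n_samples = n_car[ord],
    low_efficiency = post$catalog[ord] %in% post$low_efficiency,
    stringsAsFactors = FALSE)
  rownames(catalog) <- NULL
  seq2name <- setNames(catalog$allele, catalog$sequence)

  calls <- lapply(names(samples), function(sid) {
    pr <- samples[[sid]]
    set_of <- function(cl)
      unname(seq2name[intersect(cl$sequence[cl$state %in% allele_states],
                                catalog$sequence)])
    a1 <- set_of(pr$r1); a2 <- set_of(pr$r2)
    rep_pc <- if (length(a1) || length(a2)) repeatability(a1, a2) else NA_real_
    list(sample_id = sid, alleles = sort(union(a1, a2)), r1 = a1, r2 = a2,
         repeatability = rep_pc,
         low_efficiency_flags =
           intersect(union(a1, a2),
                     catalog$allele[catalog$low_efficiency]),
         excluded = FALSE, exclusion_reason = NA_character_)
  })
  names(calls) <- names(samples)

  state_counts <- table(unlist(lapply(samples, function(pr)
    c(pr$r1$state, pr$r2$state)), use.names = FALSE))

  structure(list(catalog = catalog, calls = calls, samples = samples,
                 incomplete_samples = incomplete,
                 report = state_counts, mode = mode),
            class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat("Genotype calls (", x$mode, " data set): ", length(x$calls),
      " samples, ", nrow(x$catalog), " catalog alleles (",
      sum(x$catalog$low_efficiency), " low-efficiency)\n", sep = "")
  rp <- vapply(x$calls, `[[`, numeric(1), "repeatability")
  cat("  mean repeatability:", round(mean(rp, na.rm = TRUE), 1), "%\n")
  invisible(x)
}

#' @export
summary.genotype_calls <- function(object, ...) {
  rp <- vapply(object$calls, `[[`, numeric(1), "repeatability")
  nall <- vapply(object$calls, function(cc) length(cc$alleles), integer(1))
  out <- list(n_samples = length(object$calls),
              n_alleles = nrow(object$catalog),
              n_low_efficiency = sum(object$catalog$low_efficiency),
              mean_repeatability = mean(rp, na.rm = TRUE),
              min_repeatability = suppressWarnings(min(rp, na.rm = TRUE)),
              alleles_per_sample = range(nall),
              classification_counts = object$report)
  class(out) <- "summary.genotype_calls"
  out
}

#' @export
print.summary.genotype_calls <- function(x, ...) {
  cat("Samples:", x$n_samples, "  catalog alleles:", x$n_alleles,
      "(", x$n_low_efficiency, "low-efficiency )\n")
  cat("Repeatability: mean", round(x$mean_repeatability, 1), "%, min",
      round(x$min_repeatability, 1), "%\n")
  cat("Alleles per sample:", x$alleles_per_sample[1], "-",
      x$alleles_per_sample[2], "\n")
  print(x$classification_counts)
  invisible(x)
}

#' Run the full genotyping pipeline from FASTQ
#'
#' Reads one or more FASTQ files, applies the quality filter, demultiplexes
#' by dual MIDs, and calls genotypes. Optionally applies a minimum-read
#' (T1) threshold, excluding samples with an under-sequenced replicate.
#'
#' @param fastq_files character vector of FASTQ paths.
#' @param mid_map MID map data.frame (see \code{\link{demultiplex}}).
#' @param mode "large" or "small" post-processing.
#' @param t1 optional \code{t1_result}; samples with any replicate below
#'   \code{t1$n_min} assigned reads are excluded with a recorded reason.
#' @param ... passed to \code{\link{call_genotypes}} and
#'   \code{\link{demultiplex}} via named arguments
#'   (\code{fwd_primer}, \code{rev_primer}, \code{mids}, \code{min_phred},
#'   \code{min_fraction}, \code{min_individuals}, ...).
#' @return a \code{genotype_calls} object with an added \code{demux} element.
#' @export
run_pipeline <- function(fastq_files, mid_map, mode = c("large", "small"),
                         t1 = NULL, ...) {
  mode <- match.arg(mode)
  dots <- list(...)
  darg <- dots[names(dots) %in%
                 c("fwd_primer", "rev_primer", "mids", "min_phred",
                   "min_fraction")]
  garg <- dots[names(dots) %in%
                 c("min_individuals", "prevalence_threshold", "allele_prefix")]
  reads <- do.call(rbind, lapply(fastq_files, read_fastq))
  dm <- do.call(demultiplex, c(list(reads, mid_map), darg))
  res <- do.call(call_genotypes, c(list(dm$amplicons, mode = mode), garg))
  res$demux <- dm
  if (!is.null(t1)) {
    n_assigned <- vapply(dm$amplicons, `[[`, integer(1), "n_assigned")
    part <- apply_t1(data.frame(
      sample_id = vapply(dm$amplicons, `[[`, character(1), "sample_id"),
      replicate = vapply(dm$amplicons, function(a) as.integer(a$replicate),
                         integer(1)),
      n_assigned = n_assigned, stringsAsFactors = FALSE), t1)
    for (sid in part$excluded$sample_id) {
      if (!is.null(res$calls[[sid]])) {
        res$calls[[sid]]$excluded <- TRUE
        res$calls[[sid]]$exclusion_reason <- part$excluded$reason[
          part$excluded$sample_id == sid][1]
        res$calls[[sid]]$alleles <- character(0)
      }
    }
    res$t1 <- t1
  }
  res
}
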