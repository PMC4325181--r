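#' Group an amplicon's reads into identical-sequence clusters
#'
#' @param reads character vector of trimmed template reads (or an
#'   \code{amplicon_record} / \code{sim_amplicon}).
#' @return data.frame with columns \code{sequence}, \code{count},
#'   \code{frequency}, sorted by count descending, ties broken
#'   lexicographically by sequence.
#' @export
cluster_reads <- function(reads) {
  if (is.list(reads)) reads <- reads$reads
  stopifnot(length(reads) >= 1)
  tab <- table(reads)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  df$frequency <- df$count / length(reads)
  rownames(df) <- NULL
  df
}

# longest common prefix / suffix lengths of q against each parent
lcp_lengths <- function(qc, parent_chars) {
  vapply(parent_chars, function(pc) {
    m <- min(length(qc), length(pc))
    if (m == 0) return(0L)
    d <- which(qc[seq_len(m)] != pc[seq_len(m)])
    if (!length(d)) m else d[1] - 1L
  }, integer(1))
}

#' Test whether a sequence can be a PCR chimera of more frequent sequences
#'
#' A query is chimeric if, at some breakpoint k (1 <= k < length), its first
#' k bases equal a length-k prefix of one more frequent sequence and its
#' remaining bases equal a suffix of a *different* more frequent sequence.
#' Returns every (parent A, parent B, k) join; the query is chimeric iff the
#' set is non-empty. Parents identical to the query are ignored.
#'
#' @param query a single sequence.
#' @param parents character vector of strictly more frequent sequences.
#' @return data.frame with columns \code{parent_a}, \code{parent_b}
#'   (indices into \code{parents}) and \code{breakpoint} k.
#' @export
detect_chimera <- function(query, parents) {
  parents <- parents[parents != query]
  empty <- data.frame(parent_a = integer(0), parent_b = integer(0),
                      breakpoint = integer(0))
  if (!length(parents)) return(empty)
  L <- nchar(query)
  if (L < 2) return(empty)
  qc <- chars(query)
  pc <- lapply(parents, chars)
  lcp <- lcp_lengths(qc, pc)
  lcs <- lcp_lengths(rev(qc), lapply(pc, rev))
  out <- list()
  for (i in seq_along(parents)) {
    hi <- min(lcp[i], L - 1L)
    if (hi < 1L) next
    for (j in seq_along(parents)) {
      if (i == j || parents[i] == parents[j]) next
      lo <- max(1L, L - lcs[j])
      if (lo <= hi) out[[length(out) + 1L]] <-
          data.frame(parent_a = i, parent_b = j, breakpoint = lo:hi)
    }
  }
  if (!length(out)) empty else do.call(rbind, out)
}

# fast boolean version used inside step 1: exists i != j with
# min(lcp_i, L-1) + min(lcs_j, L-1) >= L
is_chimeric <- function(lcp, lcs, L) {
  if (length(lcp) < 2) return(FALSE)
  # caps at L-1 ensure that a_i + b_j >= L already implies both parts >= 1
  a <- pmin(lcp, L - 1L)
  b <- pmin(lcs, L - 1L)
  i1 <- which.max(a)
  j1 <- which.max(b)
  if (i1 != j1) return(a[i1] + b[j1] >= L)
  max(a[i1] + max(b[-i1]), max(a[-i1]) + b[j1]) >= L
}

#' Step 1: label clusters within one amplicon
#'
#' The most frequent cluster (all of them, on ties) is a putative allele;
#' single-read clusters are discarded; every other cluster is labelled
#' \code{chimera} if it can be joined from two distinct more frequent
#' clusters, otherwise by its minimum Levenshtein distance d to any strictly
#' more frequent cluster (\code{diff_1_2bp} for d in 1..2, \code{diff_gt2bp}
#' for d > 2). The chimera check takes precedence over the distance label.
#'
#' @param clusters data.frame from \code{\link{cluster_reads}} (or a raw
#'   read vector / amplicon, which is clustered first).
#' @return the cluster data.frame with added \code{label} and initial
#'   \code{state} ("putative_allele", "discarded" for singletons,
#'   "pending" otherwise).
#' @export
classify_step1 <- function(clusters) {
  if (!is.data.frame(clusters)) clusters <- cluster_reads(clusters)
  n <- nrow(clusters)
  label <- rep(NA_character_, n)
  top <- clusters$count == clusters$count[1]
  label[top] <- "putative_allele"
  label[!top & clusters$count == 1L] <- "singleton_discard"
  todo <- which(is.na(label))
  if (length(todo)) {
    ch <- lapply(clusters$sequence, chars)
    rch <- lapply(ch, rev)
    for (q in todo) {
      stronger <- which(clusters$count > clusters$count[q])
      L <- nchar(clusters$sequence[q])
      lcp <- lcp_lengths(ch[[q]], ch[stronger])
      lcs <- lcp_lengths(rch[[q]], rch[stronger])
      if (is_chimeric(lcp, lcs, L)) {
        label[q] <- "chimera"
      } else {
        d <- min(adist(clusters$sequence[q], clusters$sequence[stronger]))
        label[q] <- if (d <= 2) "diff_1_2bp" else "diff_gt2bp"
      }
    }
  }
  clusters$label <- label
  clusters$state <- ifelse(label == "putative_allele", "putative_allele",
                           ifelse(label == "singleton_discard", "discarded",
                                  "pending"))
  clusters
}

# sequences considered "present" in an amplicon: any non-discarded cluster
present_seqs <- function(cl) cl$sequence[cl$state != "discarded"]

#' Step 2: cross-replicate artefact screening for one sample
#'
#' Clusters labelled chimera or 1-2 bp difference become putative artefacts
#' if their sequence is absent from the sample's replicate amplicon; clusters
#' labelled chimera in both replicates are artefacts; >2 bp clusters unique
#' to a single amplicon in the whole data set are artefacts. Everything else
#' is retained for step 3.
#'
#' @param r1,r2 step-1 labelled cluster data.frames of the two replicates.
#' @param dataset_count named integer: for each sequence, the number of
#'   amplicons data-set-wide containing it as a non-discarded cluster.
#' @return list(r1, r2) with updated \code{state}
#'   ("artefact" / "retained" for previously pending clusters).
#' @export
classify_step2 <- function(r1, r2, dataset_count) {
  screen <- function(a, b) {
    rep_present <- present_seqs(b)
    rep_chimera <- b$sequence[b$label == "chimera" & b$state != "discarded"]
    for (q in which(a$state == "pending")) {
      s <- a$sequence[q]
      lab <- a$label[q]
      art <- FALSE
      if (lab %in% c("chimera", "diff_1_2bp") && !(s %in% rep_present))
        art <- TRUE
      if (lab == "chimera" && s %in% rep_chimera)
        art <- TRUE
      dc <- dataset_count[s]
      if (lab == "diff_gt2bp" && (is.na(dc) || dc <= 1L))
        art <- TRUE
      a$state[q] <- if (art) "artefact" else "retained"
    }
    a
  }
  list(r1 = screen(r1, r2), r2 = screen(r2, r1))
}

#' Step 3: frequency-based classification of retained clusters
#'
#' Retained 1-2 bp clusters (present in both replicates by construction) and
#' retained >2 bp clusters that are present in the replicate become putative
#' alleles in an amplicon iff their intra-amplicon frequency exceeds every
#' entry of that amplicon's putative-artefact list (vacuous pass when the
#' list is empty), and unclassified variants otherwise. Retained >2 bp
#' clusters absent from the replicate are unclassified if the sequence is a
#' putative allele in another individual, artefacts otherwise. Retained
#' chimeras are putative alleles if the sequence is a putative allele in
#' another individual, otherwise unclassified.
#'
#' @param r1,r2 cluster data.frames after step 2.
#' @param sample_id the sample the two amplicons belong to.
#' @param allele_samples named list: sequence -> character vector of
#'   sample_ids in which it is a step-1 putative allele.
#' @return list(r1, r2) with final states
#'   ("allele" / "unclassified" / "artefact").
#' @export
classify_step3 <- function(r1, r2, sample_id, allele_samples) {
  elsewhere <- function(s)
    length(setdiff(allele_samples[[s]] %||% character(0), sample_id)) > 0
  art1 <- r1$frequency[r1$state == "artefact"]
  art2 <- r2$frequency[r2$state == "artefact"]
  max_art <- c(if (length(art1)) max(art1) else 0,
               if (length(art2)) max(art2) else 0)
  finish <- function(a, b, i) {
    rep_present <- present_seqs(b)
    for (q in which(a$state == "retained")) {
      s <- a$sequence[q]
      lab <- a$label[q]
      if (lab == "chimera") {
        a$state[q] <- if (elsewhere(s)) "allele" else "unclassified"
      } else if (lab == "diff_1_2bp" || s %in% rep_present) {
        a$state[q] <- if (a$frequency[q] > max_art[i]) "allele" else
          "unclassified"
      } else {
        a$state[q] <- if (elsewhere(s)) "unclassified" else "artefact"
      }
    }
    a
  }
  list(r1 = finish(r1, r2, 1L), r2 = finish(r2, r1, 2L))
}

#' Repeatability of a sample's two replicate calls
#'
#' Percentage of shared alleles between the two replicate amplicons,
#' 100 * |A intersect B| / |A union B| (Jaccard). With
#' \code{denominator = "mean"} the union is replaced by the mean set size.
#'
#' @param call_r1,call_r2 character vectors of allele names/sequences.
#' @param denominator "union" (default) or "mean".
#' @return percentage in [0, 100]; error if both sets are empty.
#' @export
repeatability <- function(call_r1, call_r2, denominator = c("union", "mean")) {
  denominator <- match.arg(denominator)
  a <- unique(call_r1); b <- unique(call_r2)
  if (!length(a) && !length(b)) stop("both replicate calls are empty")
  shared <- length(intersect(a, b))
  den <- if (denominator == "union") length(union(a, b)) else
    (length(a) + length(b)) / 2
  100 * shared / den
}
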