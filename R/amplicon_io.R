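#' Read a FASTQ file into a plain data frame
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet(format = "fastq")}
#' keeping per-base Phred scores (Sanger +33 encoding) as integer lists.
#'
#' @param path FASTQ file.
#' @return data.frame with columns \code{id}, \code{sequence} and a list
#'   column \code{quality} of integer Phred scores.
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(dss)$qualities)
  data.frame(id = names(dss), sequence = as.character(dss),
             quality = I(lapply(qual, function(q) utf8ToInt(q) - 33L)),
             stringsAsFactors = FALSE)
}

#' Whole-read quality filter
#'
#' A read passes iff the fraction of bases with Phred score strictly greater
#' than \code{min_phred} is strictly greater than \code{min_fraction}
#' (the "Phred > 20 at > 95 percent of bases" rule; both comparisons strict).
#' Relax to non-strict by lowering the thresholds if needed.
#'
#' @param quality integer vector of per-base Phred scores (or a list of such
#'   vectors, in which case a logical vector is returned).
#' @param min_phred Phred threshold (default 20).
#' @param min_fraction required fraction of qualifying bases (default 0.95).
#' @return logical: pass (TRUE) or fail. Empty reads fail.
#' @export
quality_filter <- function(quality, min_phred = 20, min_fraction = 0.95) {
  one <- function(q) {
    if (!length(q)) return(FALSE)
    sum(q > min_phred) / length(q) > min_fraction
  }
  if (is.list(quality)) vapply(quality, one, logical(1)) else one(quality)
}

#' Demultiplex dual-MID amplicon reads
#'
#' A read is assigned iff its leading 10-bp forward MID matches exactly, the
#' forward primer follows (IUPAC-aware exact match), and the read ends with
#' the reverse-complemented reverse primer followed by the
#' reverse-complemented reverse MID (again exact MID, IUPAC-aware primer).
#' Assigned reads are trimmed to the template between the primers. Reads
#' failing the quality filter are counted separately; reads whose MID
#' combination is absent from the map are counted unassigned.
#'
#' @param reads data.frame from \code{\link{read_fastq}} (columns
#'   \code{sequence} and optionally \code{quality}).
#' @param mid_map data.frame with columns \code{pool}, \code{sample_id},
#'   \code{replicate}, \code{fwd_mid}, \code{rev_mid}, \code{amplicon_id};
#'   MID columns may contain MID names (resolved via \code{mids}) or literal
#'   sequences.
#' @param fwd_primer,rev_primer primer sequences (IUPAC codes allowed).
#' @param mids named vector translating MID names to sequences (default
#'   \code{\link{ROCHE_MIDS}}).
#' @param min_phred,min_fraction quality-filter settings; set
#'   \code{min_phred = NULL} to skip filtering (e.g. reads lack qualities).
#' @return object of class \code{demux_result}: list with \code{amplicons}
#'   (named list of \code{amplicon_record}s holding trimmed template reads),
#'   and counts \code{n_raw}, \code{n_filtered}, \code{n_unassigned},
#'   \code{n_assigned}.
#' @export
demultiplex <- function(reads, mid_map, fwd_primer = DG2, rev_primer = GENDG,
                        mids = ROCHE_MIDS, min_phred = 20,
                        min_fraction = 0.95) {
  stopifnot(is.data.frame(reads), is.data.frame(mid_map))
  fseq <- if (all(mid_map$fwd_mid %in% names(mids)))
    unname(mids[mid_map$fwd_mid]) else mid_map$fwd_mid
  rseq <- if (all(mid_map$rev_mid %in% names(mids)))
    unname(mids[mid_map$rev_mid]) else mid_map$rev_mid
  if (anyDuplicated(paste(fseq, rseq)))
    stop("MID map has duplicate (fwd, rev) MID pairs")

  n_raw <- nrow(reads)
  seqs <- reads$sequence
  keep <- rep(TRUE, n_raw)
  if (!is.null(min_phred) && !is.null(reads$quality))
    keep <- quality_filter(reads$quality, min_phred, min_fraction)
  n_filtered <- sum(!keep)

  midlen <- nchar(fseq[1])
  flen <- nchar(fwd_primer)
  rlen <- nchar(rev_primer)
  rc_rev <- revcomp(rev_primer)
  len <- nchar(seqs)

  fwd_mid_obs <- substr(seqs, 1, midlen)
  fwd_pri_obs <- substr(seqs, midlen + 1, midlen + flen)
  rev_mid_obs <- substr(seqs, len - midlen + 1, len)
  rev_pri_obs <- substr(seqs, len - midlen - rlen + 1, len - midlen)

  ok_pri <- grepl(paste0("^", iupac_regex(fwd_primer), "$"), fwd_pri_obs) &
    grepl(paste0("^", iupac_regex(rc_rev), "$"), rev_pri_obs) &
    len > midlen * 2 + flen + rlen

  key_read <- paste(fwd_mid_obs, revcomp(rev_mid_obs))
  key_map <- paste(fseq, rseq)
  idx <- match(key_read, key_map)
  assigned <- keep & ok_pri & !is.na(idx)
  n_unassigned <- sum(keep & !assigned)

  template <- substr(seqs, midlen + flen + 1, len - midlen - rlen)

  amplicons <- list()
  for (a in seq_len(nrow(mid_map))) {
    sel <- which(assigned & idx == a)
    amplicons[[mid_map$amplicon_id[a]]] <- structure(
      list(amplicon_id = mid_map$amplicon_id[a],
           sample_id = mid_map$sample_id[a],
           replicate = mid_map$replicate[a],
           pool = mid_map$pool[a],
           reads = template[sel],
           ids = if (!is.null(reads$id)) reads$id[sel] else NULL,
           n_raw = n_raw, n_assigned = length(sel)),
      class = "amplicon_record")
  }
  structure(list(amplicons = amplicons, n_raw = n_raw,
                 n_filtered = n_filtered, n_unassigned = n_unassigned,
                 n_assigned = sum(assigned)),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat("Demultiplexed", x$n_raw, "reads:", x$n_assigned, "assigned to",
      length(x$amplicons), "amplicons;", x$n_filtered, "quality-filtered;",
      x$n_unassigned, "unassigned\n")
  invisible(x)
}

#' Intra-amplicon frequency of a cluster
#'
#' The proportion of an amplicon's assigned reads belonging to one cluster.
#'
#' @param cluster_count reads in the cluster.
#' @param n_assigned assigned reads in the amplicon (> 0).
#' @return numeric in (0, 1].
#' @export
intra_amplicon_frequency <- function(cluster_count, n_assigned) {
  if (n_assigned <= 0) stop("amplicon has no assigned reads")
  stopifnot(cluster_count >= 1, cluster_count <= n_assigned)
  cluster_count / n_assigned
}
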