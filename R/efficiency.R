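#' Estimate per-allele relative amplification efficiencies
#'
#' Assumes an allele's amplification efficiency is independent of genotype
#' and shared across amplicons, and that each called allele contributes one
#' template copy. Within every amplicon, the expected log read-count ratio
#' of two co-amplified alleles is the difference of their log efficiencies;
#' all within-amplicon pairs (both counts >= 1; zero counts contribute no
#' pair) enter a weighted least-squares fit (amplicons weighted by total
#' reads), and estimates are rescaled so the reference allele has
#' efficiency exactly 1.
#'
#' @param counts long data.frame with columns \code{amplicon_id},
#'   \code{allele}, \code{count}: per-amplicon read counts of called alleles.
#' @param reference reference allele name (efficiency anchored at 1).
#' @return object of class \code{efficiency_table}: data.frame with columns
#'   \code{allele}, \code{efficiency} (NA when an allele shares no amplicon
#'   path with the reference) and \code{support} (amplicons used).
#' @examples
#' counts <- data.frame(amplicon_id = "a1", allele = c("A", "B"),
#'                      count = c(75, 25))
#' estimate_efficiencies(counts, reference = "A")  # B -> 1/3
#' @export
estimate_efficiencies <- function(counts, reference) {
  stopifnot(all(c("amplicon_id", "allele", "count") %in% names(counts)))
  counts <- counts[counts$count >= 1, , drop = FALSE]
  alleles <- sort(unique(counts$allele))
  if (!reference %in% alleles)
    stop("reference allele '", reference, "' has no read counts")
  support <- table(counts$allele)

  # connected components over the co-occurrence graph (union-find)
  parent <- setNames(seq_along(alleles), alleles)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  amps <- split(counts, counts$amplicon_id)
  for (am in amps) {
    if (nrow(am) < 2) next
    r <- find(match(am$allele[1], alleles))
    for (al in am$allele[-1]) parent[find(match(al, alleles))] <- r
  }
  comp_ref <- find(match(reference, alleles))
  connected <- alleles[vapply(seq_along(alleles),
                              function(i) find(i) == comp_ref, logical(1))]

  est <- setNames(rep(NA_real_, length(alleles)), alleles)
  fit_alleles <- connected
  if (length(fit_alleles) == 1) {
    est[reference] <- 1
  } else {
    rows_i <- integer(0); rows_j <- integer(0); y <- numeric(0); w <- numeric(0)
    for (am in amps) {
      am <- am[am$allele %in% fit_alleles, , drop = FALSE]
      m <- nrow(am)
      if (m < 2) next
      tot <- sum(am$count)
      pr <- utils::combn(m, 2)
      rows_i <- c(rows_i, match(am$allele[pr[1, ]], fit_alleles))
      rows_j <- c(rows_j, match(am$allele[pr[2, ]], fit_alleles))
      y <- c(y, log(am$count[pr[1, ]] / am$count[pr[2, ]]))
      w <- c(w, rep(tot, ncol(pr)))
    }
    # design over log-efficiencies, reference column dropped (anchored at 0)
    free <- setdiff(fit_alleles, reference)
    X <- matrix(0, length(y), length(free),
                dimnames = list(NULL, free))
    ii <- fit_alleles[rows_i]; jj <- fit_alleles[rows_j]
    for (r in seq_along(y)) {
      if (ii[r] != reference) X[r, ii[r]] <- 1
      if (jj[r] != reference) X[r, jj[r]] <- -1
    }
    fit <- stats::lm.wfit(X, y, w)
    est[free] <- exp(fit$coefficients)
    est[reference] <- 1
  }

  out <- data.frame(allele = alleles, efficiency = unname(est),
                    support = as.integer(support[alleles]),
                    stringsAsFactors = FALSE)
  structure(out, class = c("efficiency_table", "data.frame"),
            reference = reference)
}

#' @export
print.efficiency_table <- function(x, ...) {
  cat("Relative amplification efficiencies (reference:",
      attr(x, "reference"), "= 1)\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Minimum reads per amplicon for reliable genotyping (modified T1)
#'
#' Worst case: a genotype of \code{k_alleles} alleles in which one allele
#' amplifies at the lowest observed relative efficiency \code{e_min} and the
#' others at 1, so its expected read share is
#' \eqn{p_{min} = e_{min} / (e_{min} + (k-1))}. T1 is the smallest read
#' depth N such that a Binomial(N, p_min) draw yields at least \code{m_min}
#' reads with probability at least \code{coverage}. Applied per replicate:
#' each replicate amplicon must independently reach the threshold.
#'
#' @param k_alleles alleles in the worst-case genotype (>= 1).
#' @param e_min lowest relative amplification efficiency (> 0).
#' @param m_min minimum reads per allele (default 2).
#' @param coverage required probability, in (0, 1) (default 0.999).
#' @return object of class \code{t1_result} with \code{p_min} and the
#'   threshold \code{n_min}.
#' @examples
#' t1_threshold(2, 1, m_min = 1)   # n_min = 10
#' @export
t1_threshold <- function(k_alleles, e_min, m_min = 2, coverage = 0.999) {
  stopifnot(k_alleles >= 1, e_min > 0, m_min >= 1)
  if (coverage <= 0 || coverage >= 1) stop("coverage must lie in (0, 1)")
  p_min <- e_min / (e_min + (k_alleles - 1))
  cov_at <- function(N) pbinom(m_min - 1, N, p_min, lower.tail = FALSE)
  lo <- m_min
  hi <- max(lo, ceiling(m_min / p_min))
  while (cov_at(hi) < coverage) hi <- hi * 2L
  while (lo < hi) {            # first N with coverage reached (monotone in N)
    mid <- (lo + hi) %/% 2
    if (cov_at(mid) >= coverage) hi <- mid else lo <- mid + 1L
  }
  structure(list(k_alleles = k_alleles, e_min = e_min, m_min = m_min,
                 coverage = coverage, p_min = p_min, n_min = as.integer(lo)),
            class = "t1_result")
}

#' @export
print.t1_result <- function(x, ...) {
  cat("T1 minimum read depth:", x$n_min, "reads/amplicon",
      sprintf("(k = %d, e_min = %.3g, m_min = %d, coverage = %.4g, p_min = %.4g)\n",
              x$k_alleles, x$e_min, x$m_min, x$coverage, x$p_min))
  invisible(x)
}

#' Partition samples by the T1 minimum-read threshold
#'
#' A sample is excluded iff either replicate amplicon has strictly fewer
#' assigned reads than \code{t1$n_min}.
#'
#' @param amplicons data.frame with columns \code{sample_id},
#'   \code{replicate}, \code{n_assigned}.
#' @param t1 a \code{t1_result}.
#' @return list with data.frames \code{kept} and \code{excluded} (the
#'   latter with a human-readable \code{reason}).
#' @export
apply_t1 <- function(amplicons, t1) {
  stopifnot(inherits(t1, "t1_result"),
            all(c("sample_id", "replicate", "n_assigned") %in%
                  names(amplicons)))
  low <- amplicons[amplicons$n_assigned < t1$n_min, , drop = FALSE]
  bad <- unique(low$sample_id)
  excluded <- do.call(rbind, lapply(bad, function(sid) {
    rows <- low[low$sample_id == sid, ]
    data.frame(sample_id = sid,
               reason = paste0("replicate ", paste(rows$replicate,
                                                   collapse = ","),
                               " below T1 threshold (",
                               paste(rows$n_assigned, collapse = ","),
                               " < ", t1$n_min, " reads)"),
               stringsAsFactors = FALSE)
  })) %||% data.frame(sample_id = character(0), reason = character(0))
  kept <- amplicons[!amplicons$sample_id %in% bad, , drop = FALSE]
  list(kept = kept, excluded = excluded)
}
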