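#' Five physicochemical z-descriptors for the 20 standard amino acids
#'
#' The extended z-scales of Sandberg et al. (1998, J Med Chem 41:2481-2491):
#' z1 (hydrophobicity), z2 (steric bulk), z3 (polarity), z4 and z5
#' (electronic effects). Used to encode peptide-binding-site sequences for
#' supertype clustering.
#'
#' @return data.frame with rownames = one-letter residue codes and columns
#'   z1..z5.
#' @export
z_scales <- function() {
  m <- matrix(c(
    0.24, -2.32,  0.60, -0.14,  1.30,   # A
    3.52,  2.50, -3.50,  1.99, -0.17,   # R
    3.05,  1.62,  1.04, -1.15,  1.61,   # N
    3.98,  0.93,  1.93, -2.46,  0.75,   # D
    0.84, -1.67,  3.71,  0.18, -2.65,   # C
    1.75,  0.50, -1.44, -1.34,  0.66,   # Q
    3.11,  0.26, -0.11, -3.04, -0.25,   # E
    2.05, -4.06,  0.36, -0.82, -0.38,   # G
    2.47,  1.95,  0.26,  3.90,  0.09,   # H
   -3.89, -1.73, -1.71, -0.84,  0.26,   # I
   -4.28, -1.30, -1.49, -0.72,  0.84,   # L
    2.29,  0.89, -2.49,  1.49,  0.31,   # K
   -2.85, -0.22,  0.47,  1.94, -0.98,   # M
   -4.22,  1.94,  1.06,  0.54, -0.62,   # F
   -1.66,  0.27,  1.84,  0.70,  2.00,   # P
    2.39, -1.07,  1.15, -1.39,  0.67,   # S
    0.75, -2.18, -1.12, -1.46, -0.40,   # T
   -4.36,  3.94,  0.59,  3.44, -1.59,   # W
   -2.54,  2.44,  0.43,  0.04, -1.47,   # Y
   -2.59, -2.64, -1.54, -0.85, -0.02),  # V
    ncol = 5, byrow = TRUE,
    dimnames = list(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                    paste0("z", 1:5)))
  as.data.frame(m)
}

#' Encode protein sequences as z-descriptor rows
#'
#' Restricts each protein to the analysed positions, collapses duplicate
#' restricted sequences, and encodes each unique sequence as the
#' concatenation of the five z-descriptors per position (row length
#' 5 x number of positions).
#'
#' By default, positions at which any sequence carries a gap are dropped
#' (with a message), so alignments with a one-residue insertion remain
#' analysable; \code{strict = TRUE} errors instead, naming the sequence
#' and position.
#'
#' @param proteins named character vector of aligned protein sequences.
#' @param positions 1-based positions to analyse.
#' @param strict error on gaps/unknown residues instead of dropping the
#'   affected positions.
#' @return matrix (unique restricted sequences x 5|positions|) with
#'   attributes \code{membership} (named: protein -> row index) and
#'   \code{positions} (positions analysed).
#' @export
z_descriptor_matrix <- function(proteins, positions, strict = FALSE) {
  stopifnot(length(proteins) >= 1, length(positions) >= 1)
  if (is.null(names(proteins)))
    names(proteins) <- sprintf("prot%02d", seq_along(proteins))
  zs <- as.matrix(z_scales())
  pm <- do.call(rbind, strsplit(proteins, ""))
  if (any(positions < 1 | positions > ncol(pm)))
    stop("positions outside the protein length")
  bad <- !pm[, positions, drop = FALSE] %in% rownames(zs)
  if (any(bad)) {
    badm <- matrix(bad, nrow = nrow(pm))
    if (strict) {
      w <- which(badm, arr.ind = TRUE)[1, ]
      stop("residue '", pm[w[1], positions[w[2]]], "' of sequence '",
           names(proteins)[w[1]], "' at position ", positions[w[2]],
           " has no descriptor entry")
    }
    drop_pos <- positions[apply(badm, 2, any)]
    message("dropping position(s) without descriptors in all sequences: ",
            paste(drop_pos, collapse = ", "))
    positions <- setdiff(positions, drop_pos)
    if (!length(positions)) stop("no analysable positions left")
  }
  restricted <- apply(pm[, positions, drop = FALSE], 1, paste, collapse = "")
  uniq <- unique(restricted)
  rows <- t(vapply(uniq, function(s) {
    as.vector(t(zs[chars(s), , drop = FALSE]))
  }, numeric(5 * length(positions))))
  colnames(rows) <- paste0(rep(paste0("p", positions), each = 5),
                           "_z", rep(1:5, length(positions)))
  rownames(rows) <- paste0("u", seq_along(uniq))
  attr(rows, "membership") <- setNames(match(restricted, uniq),
                                       names(proteins))
  attr(rows, "positions") <- positions
  rows
}

# k-means++ seeding: distinct data points, subsequent centres drawn with
# probability proportional to squared distance to the nearest chosen centre
kmpp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  if (k > 1) {
    for (j in 2:k) {
      d2 <- apply(x, 1, function(r)
        min(colSums((t(x[idx, , drop = FALSE]) - r)^2)))
      d2[idx] <- 0
      if (all(d2 == 0)) {
        idx <- c(idx, sample(setdiff(seq_len(n), idx),
                             min(k - j + 1, n - length(idx))))
        break
      }
      idx <- c(idx, sample.int(n, 1, prob = d2))
    }
  }
  x[unique(idx)[seq_len(min(k, length(unique(idx))))], , drop = FALSE]
}

run_kmeans <- function(x, k) {
  if (k >= nrow(x))
    return(list(cluster = seq_len(nrow(x)), tot.withinss = 0))
  cent <- kmpp_centers(x, k)
  if (nrow(cent) < k) {  # fewer distinct rows than k
    extra <- x[sample.int(nrow(x), k - nrow(cent), replace = TRUE), ,
               drop = FALSE]
    cent <- rbind(cent, extra + stats::rnorm(length(extra), 0, 1e-8))
  }
  for (attempt in 1:5) {
    fit <- tryCatch(kmeans(x, centers = cent, iter.max = 100),
                    error = function(e) NULL)
    if (!is.null(fit)) return(fit)
    cent <- kmpp_centers(x, k)
  }
  kmeans(x, centers = k, iter.max = 100, nstart = 5)
}

#' Scan cluster numbers with k-means and BIC
#'
#' For each k in 1..k_max, runs k-means \code{n_runs} times from distinct
#' k-means++ seedings, computes the Bayesian information criterion
#' BIC = n ln(WSS/n) + k ln(n) for each run (WSS floored at machine epsilon
#' so a perfect fit stays finite), and averages. The selected k minimises
#' the mean BIC (smallest k on ties); assignments come from the best run
#' (lowest WSS) at that k. With maximally separated duplicate-free rows the
#' minimum lands at k = n: every sequence its own supertype.
#'
#' @param x descriptor matrix from \code{\link{z_descriptor_matrix}}.
#' @param k_max largest k (default: number of rows).
#' @param n_runs k-means restarts per k (default 4).
#' @param seed integer seed.
#' @return object of class \code{supertype_model}: chosen \code{k},
#'   \code{bic} data.frame (k, mean_bic), \code{assignments}, inputs.
#' @export
kmeans_bic_scan <- function(x, k_max = nrow(x), n_runs = 4, seed = 1) {
  stopifnot(is.matrix(x), k_max >= 1, k_max <= nrow(x), n_runs >= 1)
  n <- nrow(x)
  if (n == 1 || nrow(unique(x)) == 1) {
    return(structure(list(k = 1L,
                          bic = data.frame(k = 1L, mean_bic = NA_real_),
                          assignments = setNames(rep(1L, n), rownames(x)),
                          n_runs = n_runs, seed = seed),
                     class = "supertype_model"))
  }
  bic_of <- function(wss, k) n * log(max(wss, .Machine$double.eps) / n) +
    k * log(n)
  mean_bic <- numeric(k_max)
  best_fit <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    b <- numeric(n_runs)
    best_wss <- Inf
    for (r in seq_len(n_runs)) {
      set.seed(derive_seed(seed, "kmeans", k * 1000L + r))
      fit <- run_kmeans(x, k)
      wss <- fit$tot.withinss
      b[r] <- bic_of(wss, k)
      if (wss < best_wss) {
        best_wss <- wss
        best_fit[[k]] <- fit
      }
    }
    mean_bic[k] <- mean(b)
  }
  k_hat <- which.min(mean_bic)
  structure(list(k = as.integer(k_hat),
                 bic = data.frame(k = seq_len(k_max), mean_bic = mean_bic),
                 assignments = setNames(best_fit[[k_hat]]$cluster,
                                        rownames(x)),
                 n_runs = n_runs, seed = seed),
            class = "supertype_model")
}

#' @export
print.supertype_model <- function(x, ...) {
  cat("Supertype model:", x$k, "clusters selected from",
      nrow(x$bic), "candidates by mean BIC over", x$n_runs, "runs\n")
  invisible(x)
}

#' Map alleles to supertypes
#'
#' Propagates the fitted cluster assignment back to every input allele,
#' including duplicates collapsed during descriptor encoding.
#'
#' @param model a \code{supertype_model}.
#' @param matrix the descriptor matrix used to fit it (for the membership
#'   attribute).
#' @return data.frame with columns \code{allele}, \code{supertype}.
#' @export
supertype_report <- function(model, matrix) {
  mem <- attr(matrix, "membership")
  if (is.null(mem)) stop("matrix lacks a membership attribute")
  data.frame(allele = names(mem),
             supertype = unname(model$assignments[mem]),
             stringsAsFactors = FALSE)
}
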