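#' @keywords internal
"_PACKAGE"

#' @importFrom stats kmeans pbinom rbinom rmultinom rnbinom rpois runif
#'   setNames wilcox.test cor sd
#' @importFrom utils adist head
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degeneracy codes -> base sets (used for primer matching)
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse-complement a nucleotide string
#'
#' Plain-character reverse complement supporting IUPAC degeneracy codes.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D", "-" = "-")
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1))
}

# Convert an IUPAC primer to a fixed-length regular expression.
iupac_regex <- function(primer) {
  bases <- strsplit(toupper(primer), "")[[1]]
  paste(vapply(bases, function(b) {
    s <- IUPAC[[b]]
    if (is.null(s)) stop("unknown IUPAC code: ", b)
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Does `x` match IUPAC pattern `primer` exactly (same length)?
iupac_match <- function(x, primer) {
  nchar(x) == nchar(primer) &
    grepl(paste0("^", iupac_regex(primer), "$"), x)
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# Derive a named substream seed from a master seed. Keeps all derived seeds
# within 32-bit integer range so they are portable set.seed() inputs.
derive_seed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 7919 + h * 104729 + index * 7) %% 2147483629)
}

# Split a string into a character vector of single bases.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Frame-1 stop codon check on a nucleotide string (length divisible by 3).
has_stop <- function(seq) {
  n <- nchar(seq)
  codons <- substring(seq, seq(1, n - 2, 3), seq(3, n, 3))
  any(codons %in% c("TAA", "TAG", "TGA"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
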