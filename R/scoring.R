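# Scoring schemes for frame-shift-aware DNA-vs-protein alignment.

# residue alphabet used throughout: 20 amino acids + X (unknown) + * (stop)
.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

.NT_ALPHABET <- c("A", "C", "G", "T", "N")

#' Scoring scheme for frame-shift alignment
#'
#' Bundles the residue substitution matrix, affine gap penalties, the
#' per-event frame-shift penalty F, and the Karlin-Altschul constants used
#' to convert raw scores to bit scores.  The default matrix is BLOSUM62
#' over the 20 amino acids plus a stop row taken from the same matrix; all
#' scores involving the unknown residue X are set to -1.
#'
#' @param matrix square integer substitution matrix with dimnames covering
#'   the 20 amino acids plus \code{X} and \code{*}; \code{NULL} for the
#'   BLOSUM62 default.
#' @param gap_open,gap_extend affine gap penalties (positive; a gap of
#'   length k costs \code{gap_open + k * gap_extend}).
#' @param frameshift_penalty penalty F subtracted once per frame-shift
#'   event (default 15, the value set by the long-read alignment mode).
#' @param lambda,K Karlin-Altschul constants for the bit-score formula
#'   \code{(lambda * raw - ln K) / ln 2} (defaults for gapped BLOSUM62).
#' @return an object of class \code{fs_scoring}.
#' @examples
#' sc <- scoring_scheme()
#' sc$frameshift_penalty
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11, gap_extend = 1,
                           frameshift_penalty = 15,
                           lambda = 0.267, K = 0.041) {
  if (is.null(matrix)) matrix <- .default_matrix()
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("substitution matrix must be square")
  if (!all(.AA_ALPHABET %in% rownames(matrix)))
    stop("substitution matrix must cover ", paste(.AA_ALPHABET, collapse = ""))
  matrix <- matrix[.AA_ALPHABET, .AA_ALPHABET]
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (gap_open <= 0 || gap_extend <= 0 || frameshift_penalty <= 0)
    stop("gap and frame-shift penalties must be positive")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend,
                 frameshift_penalty = frameshift_penalty,
                 lambda = lambda, K = K),
            class = "fs_scoring")
}

.default_matrix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    b62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                           envir = environment()), envir = environment())
    m <- matrix(0L, length(.AA_ALPHABET), length(.AA_ALPHABET),
                dimnames = list(.AA_ALPHABET, .AA_ALPHABET))
    keep <- setdiff(.AA_ALPHABET, "X")
    m[keep, keep] <- b62[keep, keep]
    m["X", ] <- -1L
    m[, "X"] <- -1L
    cache <<- m
    m
  }
})

#' @export
print.fs_scoring <- function(x, ...) {
  cat("Frame-shift alignment scoring scheme\n")
  cat("  gap open/extend:", x$gap_open, "/", x$gap_extend, "\n")
  cat("  frame-shift penalty F:", x$frameshift_penalty, "\n")
  cat("  bit-score constants: lambda =", x$lambda, ", K =", x$K, "\n")
  invisible(x)
}

# raw -> bit score
.bit_score <- function(raw, scheme) {
  (scheme$lambda * raw - log(scheme$K)) / log(2)
}

# 0-based residue index into the scoring matrix; errors on unknown residues
.res_code <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(ch, .AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- unique(ch[is.na(idx)])
    stop("unknown residue(s) in protein sequence: ", paste(bad, collapse = " "))
  }
  idx - 1L
}

# 0-based nucleotide codes (A,C,G,T,N); errors on anything else
.nt_code <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(ch, .NT_ALPHABET)
  if (anyNA(idx)) {
    bad <- unique(ch[is.na(idx)])
    stop("illegal nucleotide(s): ", paste(bad, collapse = " "))
  }
  idx - 1L
}

# codon (0-based codes, index b1*25+b2*5+b3) -> 0-based residue index;
# any codon containing N translates to X
.codon_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc_tab <- Biostrings::GENETIC_CODE
    tab <- integer(125)
    xi <- match("X", .AA_ALPHABET) - 1L
    nts <- c("A", "C", "G", "T", "N")
    for (b1 in 0:4) for (b2 in 0:4) for (b3 in 0:4) {
      i <- b1 * 25L + b2 * 5L + b3 + 1L
      if (b1 == 4L || b2 == 4L || b3 == 4L) {
        tab[i] <- xi
      } else {
        aa <- gc_tab[[paste0(nts[b1 + 1], nts[b2 + 1], nts[b3 + 1])]]
        tab[i] <- match(aa, .AA_ALPHABET) - 1L
      }
    }
    cache <<- tab
    tab
  }
})

# translate a DNA string (ACGTN) in frame 0, truncating a partial tail codon
.translate_dna <- function(seq) {
  codes <- .nt_code(seq)
  n_aa <- length(codes) %/% 3L
  if (n_aa == 0L) return("")
  tab <- .codon_table()
  i <- seq_len(n_aa) * 3L
  idx <- codes[i - 2L] * 25L + codes[i - 1L] * 5L + codes[i] + 1L
  paste(.AA_ALPHABET[tab[idx] + 1L], collapse = "")
}

.revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}
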