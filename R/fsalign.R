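# Frame-shift-aware local DNA-vs-protein alignment: user-facing wrapper
# around the dynamic-programming kernel, transcript replay/re-scoring and
# range-culling.

# coerce various sequence containers to list(id=, seq=) with one sequence
.seq1 <- function(x, default_id = "seq") {
  if (inherits(x, "XStringSet")) {
    if (length(x) != 1L) stop("expected exactly one sequence")
    return(list(id = if (is.null(names(x))) default_id else names(x)[1],
                seq = as.character(x[[1]])))
  }
  if (inherits(x, "XString")) return(list(id = default_id, seq = as.character(x)))
  if (is.list(x) && !is.null(x$seq))
    return(list(id = if (is.null(x$id)) default_id else x$id, seq = x$seq))
  if (is.character(x) && length(x) == 1L) {
    id <- if (is.null(names(x))) default_id else names(x)
    return(list(id = id, seq = unname(x)))
  }
  stop("cannot interpret sequence input of class ", paste(class(x), collapse = "/"))
}

.empty_alignments <- function() {
  structure(data.frame(qid = character(), qstart = integer(), qend = integer(),
                       strand = character(), sid = character(),
                       sstart = integer(), send = integer(),
                       raw_score = numeric(), bit_score = numeric(),
                       pident = numeric(), transcript = character(),
                       stringsAsFactors = FALSE),
            class = c("fs_alignments", "data.frame"))
}

#' Frame-shift-aware local DNA-to-protein alignment
#'
#' Aligns a nucleotide query against a protein subject with a dynamic
#' program whose match columns may consume 3 query bases (an ordinary
#' codon), 2 bases (a frame decrease, transcript symbol \code{/}) or 4
#' bases (a frame increase, transcript symbol \verb{\\}); each 2- or 4-base
#' column subtracts the frame-shift penalty F once.  Gaps are affine: a
#' gap in the subject consumes 3 query bases per column (\code{D}), a gap
#' in the query consumes one subject residue per column (\code{I}).
#' Alignment is local (scores floored at zero, traceback from the global
#' maximum).  The 2-base codon is translated with an N padded on its 5'
#' side; codons containing N translate to X.
#'
#' Suboptimal alignments are reported by repeated traceback with the query
#' interval of each reported alignment masked before the next pass.
#'
#' @param query nucleotide sequence (character, \code{DNAString(Set)}, or
#'   \code{list(id=, seq=)}); alphabet ACGTN.
#' @param subject protein sequence in the 20-letter alphabet plus
#'   \code{X} and \code{*}.
#' @param scheme a [scoring_scheme()].
#' @param both_strands also align the reverse complement and report hits
#'   with \code{strand == "-"} in forward-strand query coordinates.
#' @param max_hits maximum number of alignments to report per query.
#' @param min_score minimum raw score for a reported alignment.
#' @return an \code{fs_alignments} data frame (possibly 0 rows) with
#'   columns \code{qid, qstart, qend, strand, sid, sstart, send, raw_score,
#'   bit_score, pident, transcript}.  Query coordinates are 0-based
#'   half-open on the forward strand; subject coordinates 0-based
#'   half-open in residues.  \code{pident} is the percentage of alignment
#'   columns that are codon identities.
#' @examples
#' align_frameshift(c(q = "ATGGCT"), c(p = "MA"))
#' @export
align_frameshift <- function(query, subject, scheme = scoring_scheme(),
                             both_strands = FALSE, max_hits = 1L,
                             min_score = 1) {
  q <- .seq1(query, "query")
  s <- .seq1(subject, "subject")
  if (nchar(s$seq) < 1L) stop("subject must have length >= 1")
  if (nchar(q$seq) < 3L) return(.empty_alignments())
  scodes <- .res_code(s$seq)
  strands <- if (both_strands) c("+", "-") else "+"
  hits <- list()
  for (st in strands) {
    seq_st <- if (st == "+") q$seq else .revcomp(q$seq)
    qcodes <- .nt_code(seq_st)
    n <- length(qcodes)
    mask <- logical(n)
    for (k in seq_len(max_hits)) {
      res <- .fs_align_core(qcodes, scodes, scheme$matrix, .codon_table(),
                            scheme$gap_open, scheme$gap_extend,
                            scheme$frameshift_penalty, mask)
      if (!isTRUE(res$found) || res$score < min_score) break
      tr <- res$transcript
      qs <- res$qstart; qe <- res$qend
      if (st == "-") { fs <- n - qe; fe <- n - qs } else { fs <- qs; fe <- qe }
      ncols <- nchar(tr)
      nid <- sum(strsplit(tr, "", fixed = TRUE)[[1]] == "=")
      hits[[length(hits) + 1L]] <- data.frame(
        qid = q$id, qstart = fs, qend = fe, strand = st, sid = s$id,
        sstart = res$sstart, send = res$send, raw_score = res$score,
        bit_score = .bit_score(res$score, scheme),
        pident = 100 * nid / ncols, transcript = tr,
        stringsAsFactors = FALSE)
      mask[(qs + 1L):qe] <- TRUE
    }
  }
  if (!length(hits)) return(.empty_alignments())
  out <- do.call(rbind, hits)
  out <- out[order(-out$raw_score, out$qstart), , drop = FALSE]
  out <- head(out, max_hits)
  rownames(out) <- NULL
  structure(out, class = c("fs_alignments", "data.frame"))
}

#' @export
print.fs_alignments <- function(x, ...) {
  cat("Frame-shift alignments:", nrow(x), "hit(s)\n")
  if (nrow(x)) {
    show <- x
    if (!is.null(show$transcript))
      show$transcript <- ifelse(nchar(show$transcript) > 40,
                                paste0(substr(show$transcript, 1, 37), "..."),
                                show$transcript)
    print.data.frame(show, ...)
  }
  invisible(x)
}

# per-column query/subject consumption of a transcript character
.col_widths <- function(chars) {
  qw <- c("=" = 3L, "X" = 3L, "/" = 2L, "\\" = 4L, "D" = 3L, "I" = 0L)
  sw <- c("=" = 1L, "X" = 1L, "/" = 1L, "\\" = 1L, "D" = 0L, "I" = 1L)
  bad <- setdiff(unique(chars), names(qw))
  if (length(bad))
    stop("illegal transcript character(s): ", paste(bad, collapse = " "))
  list(q = unname(qw[chars]), s = unname(sw[chars]))
}

#' Frame-shift events of alignments
#'
#' Replays each alignment transcript and reports every frame-shift event
#' with its absolute, forward-strand query offset (the offset of the first
#' base of the shifted codon) and kind (\code{/} = frame decrease, 2-base
#' codon; \verb{\\} = frame increase, 4-base codon).
#'
#' @param alignments an \code{fs_alignments} data frame (or compatible).
#' @return data frame with columns \code{row, qid, query_offset, kind},
#'   sorted by row then query offset.
#' @export
alignment_events <- function(alignments) {
  out <- list()
  for (r in seq_len(nrow(alignments))) {
    a <- alignments[r, ]
    chars <- strsplit(a$transcript, "", fixed = TRUE)[[1]]
    w <- .col_widths(chars)
    pos <- cumsum(c(0L, w$q))[seq_along(chars)]  # offset within aligned region
    ev <- which(chars %in% c("/", "\\"))
    if (!length(ev)) next
    width <- w$q[ev]
    off <- if (a$strand == "+") a$qstart + pos[ev] else a$qend - pos[ev] - width
    out[[length(out) + 1L]] <- data.frame(
      row = r, qid = a$qid, query_offset = off,
      kind = chars[ev], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(row = integer(), qid = character(),
                      query_offset = integer(), kind = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  out <- out[order(out$row, out$query_offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count frame-shift events per alignment
#'
#' @param alignments an \code{fs_alignments} data frame.
#' @return integer vector: number of \code{/} plus \verb{\\} characters in
#'   each transcript.
#' @export
n_frameshifts <- function(alignments) {
  vapply(alignments$transcript, function(tr) {
    sum(strsplit(tr, "", fixed = TRUE)[[1]] %in% c("/", "\\"))
  }, integer(1), USE.NAMES = FALSE)
}

#' Re-score an alignment by replaying its transcript
#'
#' Independent audit of the dynamic program: walks the transcript over the
#' query and subject sequences, summing substitution scores for codon
#' columns, subtracting the frame-shift penalty per \code{/} or \verb{\\}
#' column and affine costs per maximal gap run.  Errors if the transcript
#' is inconsistent with the recorded coordinates.
#'
#' @param alignment one row of an \code{fs_alignments} data frame.
#' @param query,subject the sequences the alignment refers to.
#' @param scheme a [scoring_scheme()].
#' @return the recomputed raw score.
#' @export
rescore <- function(alignment, query, subject, scheme = scoring_scheme()) {
  a <- if (is.data.frame(alignment)) alignment[1, ] else alignment
  q <- .seq1(query, a$qid)
  s <- .seq1(subject, a$sid)
  chars <- strsplit(a$transcript, "", fixed = TRUE)[[1]]
  w <- .col_widths(chars)
  if (sum(w$q) != a$qend - a$qstart)
    stop("transcript consumes ", sum(w$q), " query bases but qend - qstart = ",
         a$qend - a$qstart)
  if (sum(w$s) != a$send - a$sstart)
    stop("transcript consumes ", sum(w$s), " subject residues but send - sstart = ",
         a$send - a$sstart)
  n <- nchar(q$seq)
  if (a$qend > n || a$send > nchar(s$seq) || a$qstart < 0 || a$sstart < 0)
    stop("alignment coordinates outside the given sequences")
  qseq <- if (a$strand == "-") .revcomp(q$seq) else q$seq
  # aligned segment in alignment orientation
  from <- if (a$strand == "-") n - a$qend else a$qstart
  seg <- substr(qseq, from + 1L, from + sum(w$q))
  sres <- strsplit(s$seq, "", fixed = TRUE)[[1]]
  mat <- scheme$matrix
  qpos <- 0L; spos <- a$sstart
  score <- 0
  run <- ""  # current gap run type
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch %in% c("=", "X", "/", "\\")) {
      wk <- w$q[k]
      codon <- substr(seg, qpos + 1L, qpos + wk)
      if (wk == 2L) codon <- paste0("N", codon)
      if (wk == 4L) codon <- substr(codon, 2L, 4L)
      aa <- .translate_dna(codon)
      res <- sres[spos + 1L]
      score <- score + mat[aa, res]
      if (ch == "=" && aa != res) stop("transcript claims identity where none")
      if (ch == "X" && aa == res) stop("transcript claims mismatch at identity")
      if (ch %in% c("/", "\\")) score <- score - scheme$frameshift_penalty
      qpos <- qpos + wk; spos <- spos + 1L
      run <- ""
    } else {
      score <- score - scheme$gap_extend -
        (if (run == ch) 0 else scheme$gap_open)
      run <- ch
      qpos <- qpos + w$q[k]; spos <- spos + w$s[k]
    }
  }
  score
}

#' Range-culling parameters
#'
#' @param cover_fraction minimum fraction of alignment A's query interval a
#'   stronger alignment B must cover for A to be culled (default 0.5).
#' @param score_fraction A is culled only if its score is below this
#'   fraction of B's score (default 0.9).
#' @export
culling_params <- function(cover_fraction = 0.5, score_fraction = 0.9) {
  stopifnot(cover_fraction > 0, cover_fraction <= 1,
            score_fraction > 0, score_fraction <= 1)
  structure(list(cover_fraction = cover_fraction,
                 score_fraction = score_fraction), class = "fs_culling")
}

#' Range-cull a set of alignments of one query
#'
#' Local alignment filtering: an alignment A is dropped only if an
#' already-retained alignment B covers at least \code{cover_fraction} of
#' A's query interval and A's score is less than \code{score_fraction}
#' times B's score.  Alignments are processed in descending raw score
#' (ties: ascending \code{qstart}, then \code{sid}); the retained set is
#' returned in the input row order.
#'
#' @param alignments an \code{fs_alignments} data frame, all rows sharing
#'   one \code{qid}.
#' @param params a [culling_params()].
#' @return the retained subset, input order preserved.
#' @export
range_cull <- function(alignments, params = culling_params()) {
  if (nrow(alignments) <= 1L) return(alignments)
  if (length(unique(alignments$qid)) != 1L)
    stop("range_cull expects alignments of a single query")
  ord <- order(-alignments$raw_score, alignments$qstart, alignments$sid)
  retained <- integer(0)
  for (i in ord) {
    a_len <- alignments$qend[i] - alignments$qstart[i]
    culled <- FALSE
    for (j in retained) {
      ov <- min(alignments$qend[i], alignments$qend[j]) -
        max(alignments$qstart[i], alignments$qstart[j])
      if (ov >= params$cover_fraction * a_len &&
          alignments$raw_score[i] <
            params$score_fraction * alignments$raw_score[j]) {
        culled <- TRUE
        break
      }
    }
    if (!culled) retained <- c(retained, i)
  }
  out <- alignments[sort(retained), , drop = FALSE]
  rownames(out) <- NULL
  out
}
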