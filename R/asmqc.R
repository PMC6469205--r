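# Assembly-verification statistics: frame-shifts per kilobase, the
# concordance score kappa, clone-coverage break-points, repeat masking and
# coverage correlation.

#' Frame-shift events per kilobase of aligned sequence
#'
#' For each query: events = number of \code{/} and \verb{\\} columns over
#' all its alignments; aligned bases = union length of its query
#' intervals; events per kb = 1000 * events / aligned bases.  The cohort
#' mean and sample standard deviation (n - 1) are reported over queries.
#'
#' @param alignments an \code{fs_alignments} data frame (optionally
#'   range-culled first).
#' @return an \code{fs_frameshift_stats} list: \code{per_sequence} data
#'   frame (\code{qid, n_events, aligned_bases, events_per_kb}),
#'   \code{mean} and \code{sd} (NA for a single sequence).
#' @export
frameshift_stats <- function(alignments) {
  if (!nrow(alignments)) stop("no alignments: nothing is aligned")
  nev <- n_frameshifts(alignments)
  per <- lapply(split(seq_len(nrow(alignments)), alignments$qid), function(ix) {
    ab <- interval_union_length(cbind(alignments$qstart[ix],
                                      alignments$qend[ix]))
    data.frame(qid = alignments$qid[ix[1]], n_events = sum(nev[ix]),
               aligned_bases = ab, events_per_kb = 1000 * sum(nev[ix]) / ab,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  structure(list(per_sequence = per,
                 mean = mean(per$events_per_kb),
                 sd = if (nrow(per) >= 2) sd(per$events_per_kb) else NA_real_),
            class = "fs_frameshift_stats")
}

#' @export
print.fs_frameshift_stats <- function(x, ...) {
  cat("Frame-shifts per kb over", nrow(x$per_sequence), "sequence(s): mean",
      format(x$mean, digits = 4), "sd", format(x$sd, digits = 4), "\n")
  invisible(x)
}

#' Concordance score between a bin of contigs and a long-read contig
#'
#' Four components, each in [0, 1], from the best hit of each bin contig
#' on the long-read (LR) contig:
#' \describe{
#'   \item{c1}{mean over bin contigs of best-hit alignment length /
#'     contig length (0 for contigs without a hit, capped at 1);}
#'   \item{c2}{mean sequence identity of those best hits, as a fraction
#'     (contigs without hits excluded; 0 if no contig has a hit);}
#'   \item{c3}{fraction of LR contig positions covered by aligned bin
#'     contigs;}
#'   \item{c4}{fraction of bin contigs with at least one alignment.}
#' }
#' kappa is the mean of the four.
#'
#' @param lr_length length of the LR contig (bases).
#' @param contig_lengths named vector of bin contig lengths.
#' @param hits \code{data.frame(contig, aln_length, pident, lr_start,
#'   lr_end)}: best hit per contig (extra hits per contig are reduced to
#'   the longest, then highest identity).  \code{pident} in percent,
#'   LR coordinates 0-based half-open.
#' @return an \code{fs_concordance} list: \code{c1..c4}, \code{kappa},
#'   \code{n_contigs}, \code{n_aligned}.
#' @export
concordance <- function(lr_length, contig_lengths, hits) {
  if (!length(contig_lengths)) stop("empty bin: no contigs")
  if (is.null(names(contig_lengths)))
    stop("contig_lengths must be named by contig id")
  if (nrow(hits)) {
    unknown <- setdiff(hits$contig, names(contig_lengths))
    if (length(unknown))
      stop("hits reference contigs outside the bin: ",
           paste(unknown, collapse = ", "))
    hits <- hits[order(-hits$aln_length, -hits$pident), , drop = FALSE]
    hits <- hits[!duplicated(hits$contig), , drop = FALSE]
  }
  n <- length(contig_lengths)
  ratio <- setNames(numeric(n), names(contig_lengths))
  if (nrow(hits))
    ratio[hits$contig] <- pmin(1, hits$aln_length / contig_lengths[hits$contig])
  c1 <- mean(ratio)
  c2 <- if (nrow(hits)) mean(hits$pident) / 100 else 0
  c3 <- if (nrow(hits))
    interval_union_length(cbind(hits$lr_start, hits$lr_end)) / lr_length
  else 0
  c4 <- nrow(hits) / n
  structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4,
                 kappa = mean(c(c1, c2, c3, c4)),
                 n_contigs = n, n_aligned = nrow(hits)),
            class = "fs_concordance")
}

#' @export
print.fs_concordance <- function(x, ...) {
  cat(sprintf(
    "Concordance: c1=%.3f c2=%.3f c3=%.3f c4=%.3f  kappa=%.3f (%d/%d contigs aligned)\n",
    x$c1, x$c2, x$c3, x$c4, x$kappa, x$n_aligned, x$n_contigs))
  invisible(x)
}

#' Clone-validity parameters
#'
#' @param max_insert clones must span strictly fewer than this many bases
#'   (outer distance, default 800).
#' @param require_proper_orientation require forward-reverse mates facing
#'   inward.
#' @export
clone_params <- function(max_insert = 800, require_proper_orientation = TRUE) {
  stopifnot(max_insert > 0)
  structure(list(max_insert = max_insert,
                 require_proper_orientation = require_proper_orientation),
            class = "fs_clone_params")
}

# strip a mate suffix (/1, /2) from read names
.mate_base <- function(qname) sub("/[12]$", "", qname)

#' Clone coverage of a contig from paired-read alignments
#'
#' Mates are paired by read name (identical after removing a trailing
#' \code{/1} or \code{/2}).  A pair is a valid clone iff both mates align
#' to the contig, in forward-reverse orientation facing inward (the
#' leftmost-starting mate on \code{+}), and the outer span (rightmost end
#' minus leftmost start) is strictly below \code{max_insert}.  Every valid
#' clone increments coverage over its full outer span.
#'
#' @param pairs alignment data frame with columns \code{qname, strand,
#'   tstart, tend} (e.g. from [read_paf()], optionally with \code{tname});
#'   coordinates 0-based half-open.
#' @param contig_length length of the contig.
#' @param params a [clone_params()].
#' @return an \code{fs_clone_coverage} list: \code{profile} (integer
#'   vector, one entry per contig position), \code{n_pairs},
#'   \code{n_valid} and the valid clone \code{spans}.
#' @export
clone_coverage <- function(pairs, contig_length, params = clone_params()) {
  stopifnot(all(c("qname", "strand", "tstart", "tend") %in% names(pairs)))
  base <- .mate_base(pairs$qname)
  groups <- split(seq_len(nrow(pairs)), base)
  sizes <- lengths(groups)
  if (any(sizes != 2L)) {
    warning(sum(sizes != 2L), " read group(s) without exactly two mates; skipped")
    groups <- groups[sizes == 2L]
  }
  spans <- matrix(integer(0), ncol = 2)
  for (ix in groups) {
    a <- pairs[ix[1], ]; b <- pairs[ix[2], ]
    if (!is.null(pairs$tname) && a$tname != b$tname) next
    left <- if (a$tstart <= b$tstart) a else b
    right <- if (a$tstart <= b$tstart) b else a
    if (params$require_proper_orientation &&
        !(left$strand == "+" && right$strand == "-")) next
    span <- max(a$tend, b$tend) - min(a$tstart, b$tstart)
    if (span >= params$max_insert) next
    spans <- rbind(spans, c(min(a$tstart, b$tstart), max(a$tend, b$tend)))
  }
  profile <- integer(contig_length)
  if (nrow(spans)) {
    cov <- IRanges::coverage(IRanges::IRanges(start = spans[, 1] + 1L,
                                              end = spans[, 2]),
                             width = contig_length)
    profile <- as.integer(cov)
  }
  structure(list(profile = profile, n_pairs = length(groups),
                 n_valid = nrow(spans), spans = spans),
            class = "fs_clone_coverage")
}

#' Find zero-coverage break-points in a coverage profile
#'
#' Maximal runs of zero coverage are potential assembly break-points.
#' Runs touching a contig end are flagged \code{terminal} (clones cannot
#' span past an end, so such runs are expected and reported separately).
#'
#' @param profile integer coverage vector over the whole contig (e.g.
#'   from [clone_coverage()]), or an \code{fs_clone_coverage} object.
#' @param contig_id id used in the output.
#' @return \code{data.frame(contig_id, start, end, terminal)} with
#'   0-based half-open intervals.
#' @export
find_breakpoints <- function(profile, contig_id = "contig") {
  if (inherits(profile, "fs_clone_coverage")) profile <- profile$profile
  r <- rle(profile == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  zero <- which(r$values)
  out <- data.frame(contig_id = rep(contig_id, length(zero)),
                    start = starts[zero], end = ends[zero],
                    terminal = starts[zero] == 0 | ends[zero] == length(profile),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Repeat-masking parameters
#'
#' @param min_alignment_length minimum self-alignment length for a region
#'   to count as repeat (default 500).
#' @export
repeat_params <- function(min_alignment_length = 500) {
  stopifnot(min_alignment_length > 0)
  structure(list(min_alignment_length = min_alignment_length),
            class = "fs_repeat_params")
}

#' Repeat mask and repeat rate from self-alignments
#'
#' Considers PAF rows of a contig aligned to itself, excluding the trivial
#' full-length diagonal hit; every position inside the query or target
#' interval of an alignment of length >= \code{min_alignment_length} is
#' marked repeat.  The repeat rate is the percentage of marked positions.
#'
#' @param paf data frame from [read_paf()]; only rows with
#'   \code{qname == tname} are used, and they must all concern one contig.
#' @param contig_length contig length; defaults to the PAF \code{qlen}.
#' @param params a [repeat_params()].
#' @return list with \code{mask} (\code{data.frame(start, end)}, merged
#'   0-based half-open intervals), \code{masked_bases} and
#'   \code{repeat_rate} (percent).
#' @export
repeat_mask <- function(paf, contig_length = NULL, params = repeat_params()) {
  self <- paf[paf$qname == paf$tname, , drop = FALSE]
  if (nrow(self) && length(unique(self$qname)) > 1L)
    stop("self-alignments of more than one contig; supply one contig at a time")
  if (is.null(contig_length)) {
    if (!nrow(self)) stop("contig length missing and no alignments to take it from")
    contig_length <- self$qlen[1]
  }
  trivial <- self$qstart == self$tstart & self$qend == self$tend
  self <- self[!trivial, , drop = FALSE]
  len <- pmax(self$qend - self$qstart, self$tend - self$tstart)
  self <- self[len >= params$min_alignment_length, , drop = FALSE]
  if (!nrow(self)) {
    return(list(mask = data.frame(start = integer(), end = integer()),
                masked_bases = 0L, repeat_rate = 0))
  }
  iv <- rbind(cbind(self$qstart, self$qend), cbind(self$tstart, self$tend))
  ir <- IRanges::reduce(IRanges::IRanges(start = iv[, 1] + 1L, end = iv[, 2]))
  masked <- sum(IRanges::width(ir))
  list(mask = data.frame(start = IRanges::start(ir) - 1L,
                         end = IRanges::end(ir)),
       masked_bases = as.integer(masked),
       repeat_rate = 100 * masked / contig_length)
}

#' Pearson correlation of paired measurements
#'
#' Sample Pearson correlation coefficient, e.g. of per-bin long-read vs
#' short-read coverage.
#'
#' @param x,y numeric vectors of equal length (n >= 2), or \code{x} a
#'   two-column data frame/matrix with \code{y} missing.
#' @return the correlation coefficient.
#' @export
pearson <- function(x, y = NULL) {
  if (is.null(y)) {
    stopifnot(ncol(x) >= 2)
    y <- x[[2]]; x <- x[[1]]
  }
  if (length(x) != length(y) || length(x) < 2)
    stop("need at least 2 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector: correlation undefined")
  cor(x, y)
}

#' Write intervals as BED
#'
#' @param intervals data frame with \code{start}, \code{end} and
#'   optionally a contig id column (\code{contig_id} or \code{chrom}).
#' @param path output path.
#' @param contig_id fallback contig name.
#' @export
write_bed <- function(intervals, path, contig_id = "contig") {
  chrom <- intervals$contig_id
  if (is.null(chrom)) chrom <- intervals$chrom
  if (is.null(chrom)) chrom <- rep(contig_id, nrow(intervals))
  write.table(data.frame(chrom, intervals$start, intervals$end),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
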