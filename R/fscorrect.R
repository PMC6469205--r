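# Frame-shift correction: greedy selection of non-overlapping alignments,
# event extraction, and N/NN insertion with an old->new coordinate map.
#
# Convention: a frame-decrease event ('/') marks a 2-base codon and gets a
# single 'N' inserted at the first base of the shifted codon (making one
# full codon); a frame-increase event ('\') marks a 4-base codon and gets
# 'NN' (making two full codons).  This keeps the corrected sequence in
# frame downstream of every event.

#' Greedily select a maximal set of non-overlapping alignments
#'
#' Alignments of one query are visited in descending raw score (ties:
#' ascending \code{qstart}, then \code{sid}); each is kept iff its query
#' interval shares no position with any already-kept alignment.  Abutting
#' half-open intervals do not overlap.
#'
#' @param alignments an \code{fs_alignments} data frame, one query.
#' @return the selected subset, sorted by \code{qstart}.
#' @export
select_nonoverlapping <- function(alignments) {
  if (!nrow(alignments)) return(alignments)
  if (length(unique(alignments$qid)) != 1L)
    stop("select_nonoverlapping expects alignments of a single query")
  ord <- order(-alignments$raw_score, alignments$qstart, alignments$sid)
  kept <- integer(0)
  for (i in ord) {
    clash <- any(alignments$qstart[i] < alignments$qend[kept] &
                 alignments$qstart[kept] < alignments$qend[i])
    if (!clash) kept <- c(kept, i)
  }
  out <- alignments[kept[order(alignments$qstart[kept])], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a correction plan from alignments of one query
#'
#' Selects a maximal non-overlapping alignment set, then turns every
#' frame-shift event of the selected alignments into an insertion:
#' \code{/} (frame decrease) inserts one N, \verb{\\} (frame increase)
#' inserts two, at the forward-strand offset of the first base of the
#' shifted codon (minus-strand events are mapped through the strand
#' flip).
#'
#' @param alignments an \code{fs_alignments} data frame, one query.
#' @return an \code{fs_correction_plan}: list with \code{selected}
#'   (alignments) and \code{insertions}
#'   (\code{data.frame(query_offset, n)}, ascending offsets).
#' @export
build_plan <- function(alignments) {
  sel <- select_nonoverlapping(alignments)
  ev <- alignment_events(sel)
  ins <- if (nrow(ev)) {
    data.frame(query_offset = ev$query_offset,
               n = ifelse(ev$kind == "/", 1L, 2L))
  } else {
    data.frame(query_offset = integer(), n = integer())
  }
  ins <- ins[order(ins$query_offset), , drop = FALSE]
  rownames(ins) <- NULL
  structure(list(selected = sel, insertions = ins),
            class = "fs_correction_plan")
}

#' @export
print.fs_correction_plan <- function(x, ...) {
  cat("Correction plan:", nrow(x$selected), "alignment(s),",
      nrow(x$insertions), "insertion(s),",
      sum(x$insertions$n), "N base(s)\n")
  invisible(x)
}

#' Apply a correction plan to a sequence
#'
#' Inserts the planned N runs, working from the highest offset downward so
#' earlier offsets are unaffected, and records a total, strictly monotone
#' map from original to corrected offsets.  Removing the inserted
#' positions restores the original sequence byte-exactly.
#'
#' @param record sequence to correct (character, \code{DNAString(Set)} or
#'   \code{list(id=, seq=)}).
#' @param plan an [build_plan()] result.
#' @param suffix appended to the record id (default none).
#' @return an \code{fs_corrected} list: \code{id}, \code{seq},
#'   \code{coord_map} (integer vector, 0-based original offset + 1 ->
#'   0-based corrected offset), \code{inserted_at} (0-based corrected
#'   offsets of the inserted Ns) and \code{n_inserted}.
#' @examples
#' aln <- align_frameshift(c(r = "ATGGTAAG"), c(p = "MAK"))
#' cor <- apply_corrections(c(r = "ATGGTAAG"), build_plan(aln))
#' cor$seq  # back in frame: "ATGNGTAAG"
#' @export
apply_corrections <- function(record, plan, suffix = "") {
  rec <- .seq1(record)
  n <- nchar(rec$seq)
  ins <- plan$insertions
  if (nrow(ins) && (any(ins$query_offset < 0) || any(ins$query_offset >= n)))
    stop("insertion offset outside sequence of length ", n)
  if (any(duplicated(ins$query_offset)))
    stop("duplicate insertion offsets")
  seq <- rec$seq
  for (r in rev(seq_len(nrow(ins)))) {
    k <- ins$query_offset[r]
    seq <- paste0(substr(seq, 1, k), strrep("N", ins$n[r]),
                  substr(seq, k + 1, n + sum(ins$n) ))
  }
  shift <- rep(0L, n)
  for (r in seq_len(nrow(ins)))
    shift[ins$query_offset[r] + 1L] <- ins$n[r]
  coord_map <- seq_len(n) - 1L + cumsum(shift)
  inserted_at <- setdiff(seq_len(n + sum(ins$n)) - 1L, coord_map)
  structure(list(id = paste0(rec$id, suffix), seq = seq,
                 coord_map = coord_map,
                 inserted_at = as.integer(inserted_at),
                 n_inserted = sum(ins$n)),
            class = "fs_corrected")
}

#' @export
print.fs_corrected <- function(x, ...) {
  cat("Corrected sequence", x$id, ":", nchar(x$seq), "nt (",
      x$n_inserted, "N inserted)\n")
  invisible(x)
}

#' Correct a set of reads from an alignment table
#'
#' Groups alignments by query, builds a correction plan per read and
#' applies it.  Reads without alignments are passed through unchanged
#' unless \code{drop_unaligned}.
#'
#' @param records \code{DNAStringSet} (or named character vector) of the
#'   reads/contigs.
#' @param alignments an \code{fs_alignments} data frame; every \code{qid}
#'   must be present in \code{records}.
#' @param group \code{"per-read"} returns one corrected set;
#'   \code{"per-taxon"} splits it by the taxa in \code{assignments}.
#' @param assignments for \code{per-taxon}: \code{data.frame(qid,
#'   taxon_id)} as produced by [bin_reads()].
#' @param drop_unaligned drop reads with no alignment instead of copying
#'   them unchanged.
#' @param suffix id suffix for corrected records.
#' @return for \code{per-read}, a list with \code{sequences}
#'   (\code{DNAStringSet}) and \code{details} (per-read
#'   \code{fs_corrected} objects for corrected reads); for
#'   \code{per-taxon}, a named list of such lists, one per taxon
#'   (unassigned reads under \code{"unassigned"}).
#' @export
correct_all <- function(records, alignments,
                        group = c("per-read", "per-taxon"),
                        assignments = NULL, drop_unaligned = FALSE,
                        suffix = "") {
  group <- match.arg(group)
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  ids <- names(records)
  missing_ids <- setdiff(unique(alignments$qid), ids)
  if (length(missing_ids))
    stop("alignments reference unknown read(s): ",
         paste(missing_ids, collapse = ", "))
  correct_one_set <- function(sub_ids) {
    details <- list()
    seqs <- character(0)
    for (id in sub_ids) {
      sel <- alignments[alignments$qid == id, , drop = FALSE]
      if (nrow(sel)) {
        cr <- apply_corrections(list(id = id, seq = as.character(records[[id]])),
                                build_plan(sel), suffix = suffix)
        details[[id]] <- cr
        seqs[cr$id] <- cr$seq
      } else if (!drop_unaligned) {
        seqs[paste0(id, suffix)] <- as.character(records[[id]])
      }
    }
    list(sequences = Biostrings::DNAStringSet(seqs), details = details)
  }
  if (group == "per-read") return(correct_one_set(ids))
  if (is.null(assignments))
    stop("per-taxon grouping needs an assignments table (qid, taxon_id)")
  taxon_of <- setNames(as.character(assignments$taxon_id), assignments$qid)
  grp <- taxon_of[ids]
  grp[is.na(grp)] <- "unassigned"
  lapply(split(ids, grp), correct_one_set)
}

#' Write per-read coordinate maps as TSV
#'
#' @param details list of \code{fs_corrected} objects (from
#'   [correct_all()]).
#' @param path output path; columns \code{id, original_offset,
#'   corrected_offset}.
#' @export
write_coord_maps <- function(details, path) {
  rows <- lapply(details, function(d)
    data.frame(id = d$id, original_offset = seq_along(d$coord_map) - 1L,
               corrected_offset = d$coord_map, stringsAsFactors = FALSE))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
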