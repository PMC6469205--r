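# Readers/writers: FASTA, the native alignment TSV, PAF, taxonomy TSV.
# All coordinates are 0-based half-open; conversion to/from external
# conventions happens only here.

.open_text <- function(path) {
  # gzfile() transparently reads both plain and gzip-compressed text
  gzfile(path, open = "rt")
}

# locate the first line containing a character outside `allowed` (for error
# reporting with a line number); returns NA if none found
.first_bad_line <- function(path, allowed) {
  con <- .open_text(path)
  on.exit(close(con))
  ln <- 0L
  repeat {
    x <- readLines(con, n = 1L)
    if (!length(x)) return(NA_integer_)
    ln <- ln + 1L
    if (startsWith(x, ">")) next
    ch <- unique(strsplit(toupper(x), "", fixed = TRUE)[[1]])
    if (length(setdiff(ch, allowed))) return(ln)
  }
}

#' Read a FASTA file
#'
#' Sequences are upper-cased; for nucleotide input, U is mapped to T and
#' only the alphabet ACGTN is accepted (IUPAC ambiguity codes other than N
#' are rejected).  Protein input accepts the 20 amino acids plus X and *.
#'
#' @param path FASTA file (plain or gzip-compressed).
#' @param kind \code{"nucleotide"} or \code{"protein"}.
#' @return a \code{DNAStringSet} or \code{AAStringSet}, in file order.
#' @export
read_fasta <- function(path, kind = c("nucleotide", "protein")) {
  kind <- match.arg(kind)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids)))
    stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(x) <- ids
  seqs <- toupper(as.character(x))
  if (kind == "nucleotide") {
    seqs <- chartr("U", "T", seqs)
    allowed <- .NT_ALPHABET
  } else {
    allowed <- .AA_ALPHABET
  }
  bad <- grepl(paste0("[^", gsub("\\*", "\\\\*", paste(allowed, collapse = "")), "]"),
               seqs)
  if (any(bad)) {
    line <- .first_bad_line(path, c(allowed, if (kind == "nucleotide") "U"))
    stop("illegal ", kind, " character in ", path,
         if (!is.na(line)) paste0(" at line ", line) else "",
         " (record ", ids[which(bad)[1]], ")")
  }
  if (kind == "nucleotide") {
    Biostrings::DNAStringSet(setNames(seqs, ids))
  } else {
    Biostrings::AAStringSet(setNames(seqs, ids))
  }
}

#' Write sequences to FASTA
#'
#' @param x an \code{XStringSet} or named character vector.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.ALN_COLS <- c("qid", "qstart", "qend", "strand", "sid", "sstart", "send",
               "raw_score", "bit_score", "pident", "transcript")

#' Validate alignment rows
#'
#' Checks coordinate sanity and audits each transcript: it must consume
#' exactly \code{qend - qstart} query bases and \code{send - sstart}
#' subject residues under the per-column consumption rules (\code{=},
#' \code{X}: 3 bases / 1 residue; \code{/}: 2/1; \verb{\\}: 4/1;
#' \code{D}: 3/0; \code{I}: 0/1).
#'
#' @param rows alignment data frame.
#' @return the rows, invisibly, with class \code{fs_alignments}.
#' @export
validate_alignments <- function(rows) {
  miss <- setdiff(.ALN_COLS, names(rows))
  if (length(miss)) stop("missing alignment columns: ", paste(miss, collapse = ", "))
  for (r in seq_len(nrow(rows))) {
    a <- rows[r, ]
    if (!a$strand %in% c("+", "-"))
      stop("row ", r, ": strand must be + or -")
    if (a$qend <= a$qstart || a$send <= a$sstart || a$qstart < 0 || a$sstart < 0)
      stop("row ", r, ": invalid coordinates (need 0 <= start < end)")
    if (is.na(a$pident) || a$pident < 0 || a$pident > 100)
      stop("row ", r, ": pident outside [0, 100]")
    chars <- strsplit(a$transcript, "", fixed = TRUE)[[1]]
    w <- tryCatch(.col_widths(chars), error = function(e)
      stop("row ", r, ": ", conditionMessage(e), call. = FALSE))
    if (sum(w$q) != a$qend - a$qstart)
      stop("row ", r, ": transcript consumes ", sum(w$q),
           " query bases, expected ", a$qend - a$qstart)
    if (sum(w$s) != a$send - a$sstart)
      stop("row ", r, ": transcript consumes ", sum(w$s),
           " subject residues, expected ", a$send - a$sstart)
  }
  invisible(structure(as.data.frame(rows),
                      class = c("fs_alignments", "data.frame")))
}

#' Write / read the native alignment TSV
#'
#' Tab-separated, one row per alignment, with a \code{#}-prefixed header
#' line documenting the column order
#' (\code{qid qstart qend strand sid sstart send raw_score bit_score
#' pident transcript}).  Writing validates rows first; reading validates
#' after parsing, so write followed by read is the identity.
#'
#' @param rows an \code{fs_alignments} data frame.
#' @param path file path (read side accepts gzip).
#' @return \code{read_alignment_tsv} returns an \code{fs_alignments} data
#'   frame.
#' @export
write_alignment_tsv <- function(rows, path) {
  validate_alignments(rows)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(.ALN_COLS, collapse = "\t")), con)
  if (nrow(rows)) {
    apply_fmt <- rows[, .ALN_COLS, drop = FALSE]
    write.table(apply_fmt, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_alignment_tsv
#' @export
read_alignment_tsv <- function(path) {
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(.empty_alignments())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != length(.ALN_COLS)))
    stop("alignment TSV line ", which(nfield != length(.ALN_COLS))[1],
         ": expected ", length(.ALN_COLS), " fields")
  m <- do.call(rbind, parts)
  rows <- data.frame(qid = m[, 1], qstart = as.integer(m[, 2]),
                     qend = as.integer(m[, 3]), strand = m[, 4],
                     sid = m[, 5], sstart = as.integer(m[, 6]),
                     send = as.integer(m[, 7]),
                     raw_score = as.numeric(m[, 8]),
                     bit_score = as.numeric(m[, 9]),
                     pident = as.numeric(m[, 10]), transcript = m[, 11],
                     stringsAsFactors = FALSE)
  validate_alignments(rows)
  structure(rows, class = c("fs_alignments", "data.frame"))
}

#' Read a PAF alignment file
#'
#' Parses the 12 standard columns (query name/length/start/end, strand,
#' target name/length/start/end, residue matches, block length, mapping
#' quality); any further columns (e.g. \code{cg:} CIGAR tags) are
#' preserved verbatim in a single \code{tags} column.
#'
#' @param path PAF file (plain or gzip).
#' @return data frame, one row per alignment; 0 rows for an empty file.
#' @export
read_paf <- function(path) {
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  cols <- c("qname", "qlen", "qstart", "qend", "strand",
            "tname", "tlen", "tstart", "tend", "nmatch", "blocklen", "mapq")
  if (!length(lines)) {
    out <- as.data.frame(setNames(rep(list(character(0)), 13),
                                  c(cols, "tags")), stringsAsFactors = FALSE)
    for (nm in c("qlen", "qstart", "qend", "tlen", "tstart", "tend",
                 "nmatch", "blocklen", "mapq"))
      out[[nm]] <- integer(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 12L)
  if (length(short))
    stop("PAF line ", short[1], ": fewer than 12 columns")
  m <- t(vapply(parts, function(p) p[1:12], character(12)))
  tags <- vapply(parts, function(p)
    if (length(p) > 12L) paste(p[-(1:12)], collapse = "\t") else "",
    character(1))
  out <- data.frame(qname = m[, 1], qlen = as.integer(m[, 2]),
                    qstart = as.integer(m[, 3]), qend = as.integer(m[, 4]),
                    strand = m[, 5], tname = m[, 6],
                    tlen = as.integer(m[, 7]), tstart = as.integer(m[, 8]),
                    tend = as.integer(m[, 9]), nmatch = as.integer(m[, 10]),
                    blocklen = as.integer(m[, 11]), mapq = as.integer(m[, 12]),
                    tags = tags, stringsAsFactors = FALSE)
  bad <- which(out$qstart < 0 | out$qstart >= out$qend | out$qend > out$qlen |
               out$tstart < 0 | out$tstart >= out$tend | out$tend > out$tlen)
  if (length(bad))
    stop("PAF line ", bad[1], ": coordinates violate 0 <= start < end <= len")
  out
}

#' Read a taxonomy table
#'
#' Four tab-separated columns: taxon id, parent id, rank, name.  The root
#' is the unique row whose parent equals its own id or is empty.
#'
#' @param path TSV file (plain or gzip); lines starting with \code{#} are
#'   skipped.
#' @return a \code{data.frame(taxon_id, parent_id, rank, name)}.
#' @seealso [taxonomy()] to build the queryable tree.
#' @export
read_taxonomy_table <- function(path) {
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 4L)
  if (length(bad)) stop("taxonomy TSV line ", bad[1], ": expected 4 columns")
  m <- do.call(rbind, lapply(parts, `[`, 1:4))
  data.frame(taxon_id = m[, 1], parent_id = m[, 2], rank = m[, 3],
             name = m[, 4], stringsAsFactors = FALSE)
}
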