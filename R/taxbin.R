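# Interval-union LCA taxonomic binning of long reads, and the genus-level
# Shannon diversity summary.
#
# This is a minimal implementation guided only by the standard binning
# parameters (long-read LCA mode, 51% aligned-base coverage, aligned-base
# read assignment); it does not reproduce any full published long-read
# binning algorithm.

#' Build a taxonomy tree
#'
#' @param table a \code{data.frame(taxon_id, parent_id, rank, name)}, e.g.
#'   from [read_taxonomy_table()].  Exactly one row must be the root
#'   (parent id empty or equal to its own id); parent chains must be
#'   acyclic.
#' @return an object of class \code{fs_taxonomy} with parent/rank/name
#'   lookups, the root id and per-node depth (root depth 0).
#' @export
taxonomy <- function(table) {
  stopifnot(all(c("taxon_id", "parent_id", "rank", "name") %in% names(table)))
  ids <- as.character(table$taxon_id)
  if (anyDuplicated(ids)) stop("duplicate taxon ids")
  parent <- as.character(table$parent_id)
  is_root <- !nzchar(parent) | parent == ids
  if (sum(is_root) != 1L)
    stop("taxonomy must have exactly one root, found ", sum(is_root))
  root <- ids[is_root]
  parent[is_root] <- ids[is_root]
  unknown <- setdiff(parent, ids)
  if (length(unknown))
    stop("parent id(s) not present as taxa: ", paste(unknown, collapse = ", "))
  p <- setNames(parent, ids)
  depth <- setNames(rep(NA_integer_, length(ids)), ids)
  depth[root] <- 0L
  for (id in ids) {
    if (!is.na(depth[[id]])) next
    chain <- character(0)
    cur <- id
    while (is.na(depth[[cur]])) {
      if (cur %in% chain) stop("cycle in taxonomy involving ", cur)
      chain <- c(chain, cur)
      cur <- p[[cur]]
    }
    depth[chain] <- depth[[cur]] + rev(seq_along(chain))
  }
  structure(list(ids = ids, parent = p,
                 rank = setNames(as.character(table$rank), ids),
                 name = setNames(as.character(table$name), ids),
                 root = root, depth = depth),
            class = "fs_taxonomy")
}

#' @export
print.fs_taxonomy <- function(x, ...) {
  cat("Taxonomy:", length(x$ids), "taxa, root", x$root,
      "(max depth", max(x$depth), ")\n")
  invisible(x)
}

# ancestor chain from a node up to and including the root
.ancestors <- function(tax, id) {
  out <- character(0)
  cur <- id
  repeat {
    out <- c(out, cur)
    if (cur == tax$root) return(out)
    cur <- tax$parent[[cur]]
  }
}

#' LCA binning parameters
#'
#' @param coverage_percent percentage of a read's aligned bases a taxon's
#'   subtree must cover to qualify (inclusive; default 51, so a strict
#'   majority of the aligned sequence).
#' @param assignment_mode how reads are weighted in bin summaries; only
#'   \code{"alignedBases"} (sum of aligned bases) is supported.
#' @export
lca_params <- function(coverage_percent = 51,
                       assignment_mode = "alignedBases") {
  stopifnot(coverage_percent > 50, coverage_percent <= 100,
            assignment_mode == "alignedBases")
  structure(list(coverage_percent = coverage_percent,
                 assignment_mode = assignment_mode), class = "fs_lca_params")
}

#' Length of the union of half-open integer intervals
#'
#' @param intervals two-column matrix/data frame of 0-based half-open
#'   \code{(start, end)} pairs, or a list of length-2 vectors.
#' @return number of integer positions covered by the union.
#' @examples
#' interval_union_length(rbind(c(0, 10), c(5, 15)))  # 15
#' @export
interval_union_length <- function(intervals) {
  if (is.list(intervals) && !is.data.frame(intervals))
    intervals <- do.call(rbind, intervals)
  intervals <- as.matrix(intervals)
  if (!nrow(intervals)) return(0L)
  a <- as.numeric(intervals[, 1]); b <- as.numeric(intervals[, 2])
  if (any(a >= b)) stop("intervals must satisfy start < end")
  ir <- IRanges::IRanges(start = a + 1, end = b)
  sum(IRanges::width(IRanges::reduce(ir)))
}

#' Assign one read to a taxon by interval-union LCA
#'
#' Given all alignments of one read, labelled with taxa, computes for each
#' taxonomy node the union length of the query intervals of alignments
#' falling in its subtree, and assigns the read by descending from the
#' root: at each node, among children whose subtree covers at least
#' \code{coverage_percent} of the read's total aligned bases (union over
#' all alignments), descend into the one with the largest covered length
#' (ties: lexicographically smaller id); stop when no child qualifies.
#' In the usual case where qualifying nodes form a chain this is exactly
#' the deepest qualifying taxon; when overlapping alignments make both
#' sibling subtrees qualify, the descent keeps the assignment on the
#' majority branch and makes raising the threshold move assignments
#' towards the root, never sideways.  The root always qualifies, so an
#' assignment exists whenever any base aligns.
#'
#' @param hits \code{data.frame(taxon_id, qstart, qend)}: one row per
#'   alignment of the read (0-based half-open query intervals).
#' @param tax an [taxonomy()] object.
#' @param params an [lca_params()].
#' @return list with \code{taxon_id} (NA if nothing aligned),
#'   \code{total_aligned_bases} and \code{coverage}, a per-taxon table of
#'   covered bases and percentages.
#' @export
lca_assign <- function(hits, tax, params = lca_params()) {
  stopifnot(all(c("taxon_id", "qstart", "qend") %in% names(hits)))
  unknown <- setdiff(unique(hits$taxon_id), tax$ids)
  if (length(unknown))
    stop("taxa not in taxonomy: ", paste(unknown, collapse = ", "))
  empty <- list(taxon_id = NA_character_, total_aligned_bases = 0L,
                coverage = data.frame(taxon_id = character(),
                                      covered_bases = integer(),
                                      percent = numeric(),
                                      stringsAsFactors = FALSE))
  if (!nrow(hits)) return(empty)
  total <- interval_union_length(cbind(hits$qstart, hits$qend))
  if (total == 0L) return(empty)
  # intervals propagate to every ancestor of their alignment's taxon
  node_rows <- list()
  for (r in seq_len(nrow(hits))) {
    for (anc in .ancestors(tax, hits$taxon_id[r]))
      node_rows[[anc]] <- c(node_rows[[anc]], r)
  }
  nodes <- names(node_rows)
  covered <- vapply(nodes, function(id) {
    rows <- node_rows[[id]]
    interval_union_length(cbind(hits$qstart[rows], hits$qend[rows]))
  }, numeric(1))
  pct <- 100 * covered / total
  qual <- setNames(pct >= params$coverage_percent, nodes)
  cur <- tax$root
  repeat {
    kids <- nodes[qual & nodes != cur & tax$parent[nodes] == cur]
    if (!length(kids)) break
    cur <- kids[order(-covered[kids], kids)][1]
  }
  list(taxon_id = cur,
       total_aligned_bases = as.integer(total),
       coverage = data.frame(taxon_id = nodes,
                             covered_bases = as.integer(covered),
                             percent = pct, row.names = NULL,
                             stringsAsFactors = FALSE))
}

#' Bin reads by LCA and summarise per taxon
#'
#' Runs [lca_assign()] for every query in an alignment set and summarises
#' per-taxon read counts and summed aligned bases (aligned-base read
#' assignment mode).
#'
#' @param alignments an \code{fs_alignments} data frame; subject ids are
#'   taken as taxon ids unless \code{ref2tax} maps them.
#' @param tax an [taxonomy()] object.
#' @param params an [lca_params()].
#' @param ref2tax optional named character vector mapping subject ids to
#'   taxon ids.
#' @return \code{data.frame(taxon_id, rank, name, n_reads, aligned_bases)}
#'   with one row per assigned taxon, plus the per-read assignments in
#'   \code{attr(, "assignments")}.
#' @export
bin_reads <- function(alignments, tax, params = lca_params(),
                      ref2tax = NULL) {
  if (!nrow(alignments)) {
    out <- data.frame(taxon_id = character(), rank = character(),
                      name = character(), n_reads = integer(),
                      aligned_bases = integer(), stringsAsFactors = FALSE)
    attr(out, "assignments") <- data.frame(qid = character(),
                                           taxon_id = character(),
                                           aligned_bases = integer(),
                                           stringsAsFactors = FALSE)
    return(out)
  }
  taxon <- if (is.null(ref2tax)) alignments$sid
           else unname(ref2tax[alignments$sid])
  if (anyNA(taxon))
    stop("no taxon mapping for subject id(s): ",
         paste(unique(alignments$sid[is.na(taxon)]), collapse = ", "))
  unknown <- setdiff(unique(taxon), tax$ids)
  if (length(unknown))
    stop("taxa not in taxonomy: ", paste(unknown, collapse = ", "))
  qids <- unique(alignments$qid)
  asg <- lapply(qids, function(q) {
    sel <- alignments$qid == q
    res <- lca_assign(data.frame(taxon_id = taxon[sel],
                                 qstart = alignments$qstart[sel],
                                 qend = alignments$qend[sel],
                                 stringsAsFactors = FALSE), tax, params)
    data.frame(qid = q, taxon_id = res$taxon_id,
               aligned_bases = res$total_aligned_bases,
               stringsAsFactors = FALSE)
  })
  asg <- do.call(rbind, asg)
  assigned <- asg[!is.na(asg$taxon_id), , drop = FALSE]
  tab <- if (nrow(assigned)) {
    agg_n <- tapply(assigned$qid, assigned$taxon_id, length)
    agg_b <- tapply(assigned$aligned_bases, assigned$taxon_id, sum)
    ids <- names(agg_n)
    data.frame(taxon_id = ids, rank = unname(tax$rank[ids]),
               name = unname(tax$name[ids]),
               n_reads = as.integer(agg_n),
               aligned_bases = as.integer(agg_b),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(taxon_id = character(), rank = character(),
               name = character(), n_reads = integer(),
               aligned_bases = integer(), stringsAsFactors = FALSE)
  }
  tab <- tab[order(-tab$aligned_bases, tab$taxon_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "assignments") <- asg
  tab
}

#' Shannon diversity of genus-level bins
#'
#' H = -sum p_i ln p_i over the relative abundances of the bins (natural
#' logarithm), computed with \code{vegan::diversity}.
#'
#' @param counts non-negative numeric vector of per-genus counts (reads,
#'   bases or contigs), at least one positive; zero categories are
#'   ignored.
#' @return the Shannon index.
#' @examples
#' shannon_index(c(g1 = 5, g2 = 5))  # log(2)
#' @export
shannon_index <- function(counts) {
  counts <- unlist(counts)
  if (!is.numeric(counts) || any(counts < 0))
    stop("counts must be non-negative numbers")
  counts <- counts[counts > 0]
  if (!length(counts)) stop("at least one positive count required")
  unname(vegan::diversity(counts, index = "shannon"))
}
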