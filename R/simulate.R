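# Seeded synthetic-data generator: coding references, indel-corrupted long
# reads with ground truth, tiling bins for concordance scoring, and paired
# clone alignments for break-point detection.  All outputs are pure
# functions of their configuration and seed.

#' Simulation configuration
#'
#' @param seed integer RNG seed.
#' @param n_genes number of reference genes.
#' @param gene_length_aa length range (amino acids) from which gene
#'   lengths are drawn uniformly.
#' @param indel_rate per-base probability of a single-base indel
#'   (split evenly between insertions and deletions); in [0, 0.2].
#' @param substitution_rate per-base substitution probability; in [0, 0.2].
#' @param read_length read length range (bases, before errors).
#' @param n_reads number of reads.
#' @return an \code{fs_sim_config} list.
#' @export
sim_config <- function(seed = 1L, n_genes = 5L, gene_length_aa = c(650, 750),
                       indel_rate = 0.01, substitution_rate = 0.01,
                       read_length = c(1500, 2500), n_reads = 200L) {
  stopifnot(indel_rate >= 0, indel_rate <= 0.2,
            substitution_rate >= 0, substitution_rate <= 0.2,
            all(gene_length_aa > 0), all(read_length > 0),
            n_genes >= 1, n_reads >= 0)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 gene_length_aa = as.integer(gene_length_aa),
                 indel_rate = indel_rate,
                 substitution_rate = substitution_rate,
                 read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads)),
            class = "fs_sim_config")
}

# uniform integer draw on [a, b] that is safe when a == b (avoids the
# sample(x, n) scalar expansion)
.runif_int <- function(n, a, b) a + sample.int(b - a + 1L, n, replace = TRUE) - 1L

.SENSE_CODONS <- local({
  nts <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

#' Simulate a coding reference
#'
#' Genes are uniform-random codon sequences starting with ATG and free of
#' in-frame stops; proteins are their exact translations.
#'
#' @param config an [sim_config()].
#' @return list with \code{dna} (\code{DNAStringSet}) and \code{protein}
#'   (\code{AAStringSet}), names \code{gene1..geneN}.
#' @export
simulate_reference <- function(config = sim_config()) {
  set.seed(config$seed)
  dna <- character(config$n_genes)
  lens <- .runif_int(config$n_genes, config$gene_length_aa[1],
                     config$gene_length_aa[2])
  for (g in seq_len(config$n_genes)) {
    codons <- c("ATG", sample(.SENSE_CODONS, lens[g] - 1L, replace = TRUE))
    dna[g] <- paste(codons, collapse = "")
  }
  names(dna) <- paste0("gene", seq_len(config$n_genes))
  prot <- vapply(dna, .translate_dna, character(1))
  list(dna = Biostrings::DNAStringSet(dna),
       protein = Biostrings::AAStringSet(prot))
}

# corrupt one sequence with iid per-base errors; returns seq + event table
.corrupt <- function(seq, indel_rate, substitution_rate) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  nts <- c("A", "C", "G", "T")
  u <- stats::runif(n)
  p_del <- indel_rate / 2
  p_ins <- indel_rate / 2
  out <- character(0)
  ev_pos <- integer(0); ev_type <- character(0)
  for (i in seq_len(n)) {
    if (u[i] < p_del) {
      ev_pos <- c(ev_pos, i - 1L); ev_type <- c(ev_type, "del")
    } else {
      b <- bases[i]
      if (stats::runif(1) < substitution_rate) {
        b <- sample(setdiff(nts, b), 1L)
        ev_pos <- c(ev_pos, i - 1L); ev_type <- c(ev_type, "sub")
      }
      out <- c(out, b)
      if (stats::runif(1) < p_ins) {
        out <- c(out, sample(nts, 1L))
        ev_pos <- c(ev_pos, i - 1L); ev_type <- c(ev_type, "ins")
      }
    }
  }
  list(seq = paste(out, collapse = ""),
       events = data.frame(pos = ev_pos, type = ev_type,
                           stringsAsFactors = FALSE))
}

#' Simulate indel-corrupted long reads with ground truth
#'
#' Reads are drawn from uniform-random intervals and strands of the
#' reference genes, then corrupted with iid per-base substitutions and
#' single-base insertions/deletions at the configured rates (indels split
#' evenly between the two kinds).  Event positions are recorded in the
#' coordinates of the error-free extracted read.
#'
#' @param reference a [simulate_reference()] result.
#' @param config an [sim_config()]; RNG is seeded with
#'   \code{config$seed + 1} so reads are independent of the reference
#'   draw but equally reproducible.
#' @return list with \code{reads} (\code{DNAStringSet}),
#'   \code{info} (per-read: gene, strand, interval, event counts) and
#'   \code{truth} (per-event: read, position, type).
#' @export
simulate_reads <- function(reference, config = sim_config()) {
  set.seed(config$seed + 1L)
  genes <- as.character(reference$dna)
  glen <- nchar(genes)
  if (config$read_length[1] > max(glen))
    stop("read_length exceeds every gene length")
  reads <- character(config$n_reads)
  info <- vector("list", config$n_reads)
  truth <- vector("list", config$n_reads)
  for (r in seq_len(config$n_reads)) {
    repeat {
      g <- sample(length(genes), 1L)
      len <- .runif_int(1L, config$read_length[1], config$read_length[2])
      if (len <= glen[g]) break
    }
    start <- .runif_int(1L, 0L, glen[g] - len)
    frag <- substr(genes[g], start + 1L, start + len)
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") frag <- .revcomp(frag)
    cor <- .corrupt(frag, config$indel_rate, config$substitution_rate)
    id <- sprintf("read%04d", r)
    reads[r] <- cor$seq
    names(reads)[r] <- id
    info[[r]] <- data.frame(read = id, gene = names(genes)[g],
                            strand = strand, start = start,
                            end = start + len,
                            n_ins = sum(cor$events$type == "ins"),
                            n_del = sum(cor$events$type == "del"),
                            n_sub = sum(cor$events$type == "sub"),
                            stringsAsFactors = FALSE)
    truth[[r]] <- if (nrow(cor$events))
      data.frame(read = id, cor$events, stringsAsFactors = FALSE)
    else NULL
  }
  truth <- truth[!vapply(truth, is.null, logical(1))]
  list(reads = Biostrings::DNAStringSet(reads),
       info = do.call(rbind, c(info, list(make.row.names = FALSE))),
       truth = if (length(truth))
         do.call(rbind, c(truth, list(make.row.names = FALSE))) else NULL)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a bin of short-read contigs tiling a long-read contig
#'
#' The related contigs are abutting windows covering the first
#' \code{coverage_fraction} of a random LR contig, with point mutations at
#' rate \code{1 - identity}; optional unrelated contigs are random
#' sequences of the same length.  The expected concordance components are
#' computed analytically from the construction parameters: c1 = 1 for
#' related contigs (their full length aligns), c2 = identity, c3 =
#' coverage_fraction, c4 = fraction of related contigs.  Truth alignments
#' (with realised identities) are emitted for use with [concordance()].
#'
#' @param lr_length LR contig length.
#' @param n_contigs number of related bin contigs.
#' @param identity expected per-base identity of related contigs, in
#'   [0.8, 1].
#' @param coverage_fraction fraction of the LR contig tiled, in (0, 1].
#' @param seed RNG seed.
#' @param n_unrelated additional random contigs with no LR counterpart.
#' @return list with \code{lr}, \code{contigs} (\code{DNAStringSet}s),
#'   \code{bin} (membership table), \code{hits} (truth alignments) and
#'   \code{expected} (analytic c1..c4 and kappa).
#' @export
simulate_tiling_bin <- function(lr_length = 50000, n_contigs = 10,
                                identity = 1.0, coverage_fraction = 1.0,
                                seed = 1L, n_unrelated = 0) {
  stopifnot(identity >= 0.8, identity <= 1,
            coverage_fraction > 0, coverage_fraction <= 1)
  set.seed(seed)
  lr <- .random_dna(lr_length)
  covered <- floor(lr_length * coverage_fraction)
  bounds <- floor(seq(0, covered, length.out = n_contigs + 1))
  contigs <- character(0)
  hits <- list()
  for (k in seq_len(n_contigs)) {
    s <- bounds[k]; e <- bounds[k + 1]
    w <- substr(lr, s + 1, e)
    bases <- strsplit(w, "", fixed = TRUE)[[1]]
    mut <- which(stats::runif(length(bases)) < 1 - identity)
    for (i in mut) bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
    id <- sprintf("sr%03d", k)
    contigs[id] <- paste(bases, collapse = "")
    hits[[k]] <- data.frame(contig = id, aln_length = e - s,
                            pident = 100 * (1 - length(mut) / length(bases)),
                            lr_start = s, lr_end = e,
                            stringsAsFactors = FALSE)
  }
  for (k in seq_len(n_unrelated)) {
    id <- sprintf("srU%03d", k)
    contigs[id] <- .random_dna(max(1L, floor(covered / n_contigs)))
  }
  n_total <- n_contigs + n_unrelated
  exp_c1 <- n_contigs / n_total
  exp_c2 <- identity
  exp_c4 <- n_contigs / n_total
  expected <- list(c1 = exp_c1, c2 = exp_c2, c3 = coverage_fraction,
                   c4 = exp_c4,
                   kappa = mean(c(exp_c1, exp_c2, coverage_fraction, exp_c4)))
  list(lr = Biostrings::DNAStringSet(c(lr_contig = lr)),
       contigs = Biostrings::DNAStringSet(contigs),
       bin = data.frame(contig = names(contigs), bin_id = "bin1",
                        stringsAsFactors = FALSE),
       hits = do.call(rbind, c(hits, list(make.row.names = FALSE))),
       expected = expected)
}

#' Simulate paired clone alignments around an optional coverage gap
#'
#' Clone spans (insert sizes uniform in \code{insert_range}) are placed
#' uniformly on the contig; a span whose uniform draw would cross the
#' configured gap is shifted to abut the nearer gap boundary, emulating
#' the read pile-up observed at a misjoin, so that no clone spans the gap
#' while positions flanking it stay covered.  Mates are emitted as
#' forward-reverse alignments facing inward, named \code{cloneN/1} and
#' \code{cloneN/2}.
#'
#' @param contig_length contig length.
#' @param gap 0-based half-open interval with no clone coverage, or
#'   \code{NULL} for none.
#' @param n_pairs number of clones.
#' @param insert_range inclusive range of insert (outer span) sizes; the
#'   maximum must stay below the clone-validity cut-off to be useful.
#' @param read_length mate length (must be <= min insert / 2... practically
#'   below the minimum insert).
#' @param seed RNG seed.
#' @return data frame of mate alignments (\code{qname, strand, tstart,
#'   tend, tname}), with the true clone spans in \code{attr(, "spans")}.
#' @export
simulate_clone_pairs <- function(contig_length = 10000, gap = c(4000, 4500),
                                 n_pairs = 2000, insert_range = c(300, 799),
                                 read_length = 150, seed = 1L) {
  stopifnot(insert_range[1] <= insert_range[2],
            insert_range[2] < contig_length,
            read_length * 2 <= insert_range[1])
  if (!is.null(gap))
    stopifnot(gap[1] >= insert_range[2], gap[2] + insert_range[2] <= contig_length)
  set.seed(seed)
  ins <- .runif_int(n_pairs, insert_range[1], insert_range[2])
  s <- vapply(ins, function(i) .runif_int(1L, 0L, contig_length - i), integer(1))
  if (!is.null(gap)) {
    e <- s + ins
    cross <- s < gap[2] & e > gap[1]
    mid <- (s + e) / 2
    left <- cross & mid < mean(gap)
    right <- cross & !left
    s[left] <- gap[1] - ins[left]
    s[right] <- gap[2]
  }
  e <- s + ins
  out <- data.frame(
    qname = as.vector(rbind(sprintf("clone%04d/1", seq_len(n_pairs)),
                            sprintf("clone%04d/2", seq_len(n_pairs)))),
    strand = rep(c("+", "-"), n_pairs),
    tstart = as.vector(rbind(s, e - read_length)),
    tend = as.vector(rbind(s + read_length, e)),
    tname = "contig", stringsAsFactors = FALSE)
  attr(out, "spans") <- cbind(start = s, end = e)
  out
}
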