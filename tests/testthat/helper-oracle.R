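# Independent oracle for the frame-shift alignment DP: exhaustive
# enumeration over all monotone local alignments with at most `max_events`
# frame-shift columns.  Alignments are generated as k codon columns
# (widths 3 / 2 / 4 query bases) separated by gap runs (D runs consume 3
# query bases per column, I runs one subject residue per column), placed
# at every feasible query/subject start.  Gap runs are costed
# open + length * extend per maximal run.  End gaps are omitted: they
# strictly lower the score of an otherwise identical alignment, so they
# never change the optimum.

oracle_best_score <- function(qseq, sseq, scheme, max_events = 2) {
  qc <- strsplit(qseq, "", fixed = TRUE)[[1]]
  sc <- strsplit(sseq, "", fixed = TRUE)[[1]]
  n <- length(qc); m <- length(sc)
  GC <- Biostrings::GENETIC_CODE
  aa_of <- function(b) if (any(b == "N")) "X" else GC[[paste(b, collapse = "")]]
  mat <- scheme$matrix
  go <- scheme$gap_open; ge <- scheme$gap_extend
  Fp <- scheme$frameshift_penalty
  widths <- c(3L, 2L, 4L)

  # column score tables: colsc[[w]][qpos + 1, spos] for a column of width w
  # whose query bases start at 0-based offset qpos against subject residue spos
  colsc <- list()
  for (w in c(3L, 2L, 4L)) {
    nq <- n - w + 1L
    if (nq < 1L) { colsc[[w]] <- NULL; next }
    tabw <- matrix(-Inf, nq, m)
    for (qp in seq_len(nq)) {
      cod <- qc[qp:(qp + w - 1L)]
      if (w == 2L) cod <- c("N", cod)
      if (w == 4L) cod <- cod[2:4]
      aa <- aa_of(cod)
      tabw[qp, ] <- mat[aa, sc]
    }
    colsc[[w]] <- tabw
  }

  best <- 0
  for (k in seq_len(min(m, n %/% 2L))) {
    combos <- as.matrix(expand.grid(rep(list(1:3), k)))
    for (ci in seq_len(nrow(combos))) {
      t <- combos[ci, ]
      n_ev <- sum(t != 1L)
      if (n_ev > max_events) next
      w <- widths[t]
      qM <- sum(w)
      if (qM > n) next
      slots <- k - 1L
      dmax_tot <- (n - qM) %/% 3L
      imax_tot <- m - k

      eval_gaps <- function(d, i) {
        qtot <- qM + 3L * sum(d)
        stot <- k + sum(i)
        gapcost <- sum(ifelse(d > 0L, go + d * ge, 0)) +
                   sum(ifelse(i > 0L, go + i * ge, 0))
        base <- -gapcost - Fp * n_ev
        for (qs in 0:(n - qtot)) for (ss in 0:(m - stot)) {
          qp <- qs; sp <- ss
          sco <- base
          for (j in seq_len(k)) {
            if (j > 1L) { qp <- qp + 3L * d[j - 1L]; sp <- sp + i[j - 1L] }
            sco <- sco + colsc[[w[j]]][qp + 1L, sp + 1L]
            qp <- qp + w[j]; sp <- sp + 1L
          }
          if (sco > best) best <<- sco
        }
      }
      enum_slots <- function(slot, d, i) {
        if (slot > slots) { eval_gaps(d, i); return(invisible(NULL)) }
        for (dd in 0:(dmax_tot - sum(d)))
          for (ii in 0:(imax_tot - sum(i)))
            enum_slots(slot + 1L, c(d, dd), c(i, ii))
      }
      enum_slots(1L, integer(0), integer(0))
    }
  }
  best
}

# random test instance generators (alphabet weights keep N and X rare)
random_dna_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
}
random_protein_seq <- function(len) {
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(c(aa20, "X"), len, replace = TRUE,
               prob = c(rep(0.0485, 20), 0.03)), collapse = "")
}

# DP optimum as a bare number (0 when no positive-scoring alignment exists)
dp_best_score <- function(qseq, sseq, scheme) {
  hits <- align_frameshift(c(q = qseq), c(s = sseq), scheme, max_hits = 1L)
  if (nrow(hits)) hits$raw_score[1] else 0
}
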