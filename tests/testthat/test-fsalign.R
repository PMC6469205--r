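# Frame-shift-aware DP alignment: worked examples, oracle equivalence,
# limits, transcript audits, re-scoring and range-culling.

test_that("exact codon alignment scores the BLOSUM62 diagonal with no events", {
  a <- align_frameshift(c(q = "ATGGCT"), c(p = "MA"))
  expect_equal(nrow(a), 1L)
  expect_equal(a$transcript, "==")
  sc <- scoring_scheme()
  expect_equal(a$raw_score, sc$matrix["M", "M"] + sc$matrix["A", "A"])
  expect_equal(n_frameshifts(a), 0L)
  expect_equal(c(a$qstart, a$qend, a$sstart, a$send), c(0, 6, 0, 2))
})

test_that("a single-base deletion is recovered as one frame-shift event when the penalty allows", {
  # query is ATG GCT AAG (MAK) with the C of codon 2 deleted; the 2-base
  # codon column translates to X (N padding), so the shifted chain scores
  # s(M,M) + s(X,A) - F + s(K,K) = 9 - F and beats the best single codon
  # (score 5) only for F < 4
  sc3 <- scoring_scheme(frameshift_penalty = 3)
  a <- align_frameshift(c(r = "ATGGTAAG"), c(p = "MAK"), sc3)
  expect_equal(n_frameshifts(a), 1L)
  expect_equal(a$transcript, "=/=")
  expect_equal(a$raw_score, 9 - 3)
  expect_equal(a$raw_score, oracle_best_score("ATGGTAAG", "MAK", sc3, 1))
  # at the default F = 15 the unshifted sub-alignment wins; oracle agrees
  a15 <- align_frameshift(c(r = "ATGGTAAG"), c(p = "MAK"))
  expect_equal(a15$raw_score, oracle_best_score("ATGGTAAG", "MAK", scoring_scheme()))
  expect_equal(n_frameshifts(a15), 0L)
})

test_that("queries shorter than one codon yield an empty result", {
  a <- align_frameshift(c(q = "AT"), c(p = "MAK"))
  expect_s3_class(a, "fs_alignments")
  expect_equal(nrow(a), 0L)
  expect_error(align_frameshift(c(q = "ATGQCT"), c(p = "MA")), "illegal")
  expect_error(align_frameshift(c(q = "ATGGCT"), c(p = "MB")), "unknown residue")
})

test_that("DP optimum equals exhaustive enumeration on random small instances", {
  set.seed(101)
  sc <- scoring_scheme()
  for (i in 1:120) {
    q <- random_dna_seq(sample(6:12, 1))
    s <- random_protein_seq(sample(2:4, 1))
    expect_equal(dp_best_score(q, s, sc), oracle_best_score(q, s, sc),
                 info = paste(q, s))
  }
})

test_that("optimal score is non-increasing in the frame-shift penalty", {
  set.seed(7)
  for (i in 1:25) {
    q <- random_dna_seq(sample(15:40, 1))
    s <- random_protein_seq(sample(4:10, 1))
    scores <- vapply(c(2, 5, 15, 40), function(F)
      dp_best_score(q, s, scoring_scheme(frameshift_penalty = F)), numeric(1))
    expect_true(all(diff(scores) <= 0), info = q)
  }
})

test_that("for F -> Inf the DP equals the best 3-frame local protein alignment", {
  # independent cross-check against Biostrings::pairwiseAlignment on the
  # three forward-frame translations (no Ns, so translations are clean)
  set.seed(11)
  sc_inf <- scoring_scheme(frameshift_penalty = 1e7)
  full_mat <- sc_inf$matrix  # includes X and * rows for stop codons
  for (i in 1:20) {
    q <- paste(sample(c("A", "C", "G", "T"), sample(45:90, 1), TRUE),
               collapse = "")
    s <- random_protein_seq(sample(8:20, 1))
    if (grepl("X", s)) s <- gsub("X", "L", s)
    frames <- vapply(0:2, function(f) {
      tr <- framefix:::.translate_dna(substr(q, f + 1, nchar(q)))
      if (nchar(tr) == 0) return(0)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(tr), Biostrings::AAString(s),
        type = "local", substitutionMatrix = full_mat,
        gapOpening = 11, gapExtension = 1)
      max(0, Biostrings::score(pa))
    }, numeric(1))
    dp <- dp_best_score(q, s, sc_inf)
    expect_equal(dp, max(frames), info = paste(q, s))
  }
})

test_that("emitted transcripts pass the consumption audit and re-score exactly", {
  set.seed(21)
  cfg <- sim_config(seed = 5, n_genes = 2, gene_length_aa = c(120, 150),
                    read_length = c(200, 320), n_reads = 12,
                    indel_rate = 0.02, substitution_rate = 0.01)
  ref <- simulate_reference(cfg)
  rd <- simulate_reads(ref, cfg)
  for (r in seq_along(rd$reads)) {
    gene <- rd$info$gene[r]
    a <- align_frameshift(rd$reads[r], ref$protein[gene], both_strands = TRUE)
    if (!nrow(a)) next
    expect_silent(validate_alignments(a))
    expect_equal(rescore(a[1, ], rd$reads[r], ref$protein[gene]),
                 a$raw_score[1], info = rd$info$read[r])
  }
})

test_that("rescore rejects transcripts inconsistent with the coordinates", {
  a <- align_frameshift(c(q = "ATGGCT"), c(p = "MA"))
  a$transcript <- "="
  expect_error(rescore(a, c(q = "ATGGCT"), c(p = "MA")), "consumes")
})

test_that("minus-strand hits are reported in forward coordinates with mapped events", {
  cfg <- sim_config(seed = 9, n_genes = 1, gene_length_aa = c(100, 100),
                    read_length = c(300, 300), n_reads = 1,
                    indel_rate = 0, substitution_rate = 0)
  ref <- simulate_reference(cfg)
  fwd <- substr(as.character(ref$dna[[1]]), 31, 210)  # in-frame window
  rev <- framefix:::.revcomp(fwd)
  a <- align_frameshift(c(r = rev), ref$protein[1], both_strands = TRUE)
  expect_equal(a$strand, "-")
  expect_equal(c(a$qstart, a$qend), c(0, nchar(rev)))
  expect_equal(n_frameshifts(a), 0L)
  # plant one deletion: the event must map back to a forward offset
  rev_del <- paste0(substr(rev, 1, 89), substr(rev, 91, nchar(rev)))
  a2 <- align_frameshift(c(r = rev_del), ref$protein[1],
                         scoring_scheme(), both_strands = TRUE)
  ev <- alignment_events(a2)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$query_offset >= 0 && ev$query_offset < nchar(rev_del))
  # replayed events agree with a fresh alignment of the reverse complement
  a3 <- align_frameshift(c(r = framefix:::.revcomp(rev_del)), ref$protein[1])
  expect_equal(n_frameshifts(a3), 1L)
})

test_that("range-culling applies the coverage and score thresholds exactly", {
  p <- culling_params()
  B <- make_aln("q", 0, 100, 100, sid = "B", transcript = strrep("=", 33),
                send = 33)
  # A fully covered, 80 < 0.9 * 100 -> culled
  A1 <- make_aln("q", 0, 100, 80, sid = "A", transcript = strrep("=", 33),
                 send = 33)
  expect_equal(range_cull(rbind(A1, B), p)$sid, "B")
  # A fully covered but 95 >= 90 -> both retained
  A2 <- make_aln("q", 0, 100, 95, sid = "A", transcript = strrep("=", 33),
                 send = 33)
  expect_equal(sort(range_cull(rbind(A2, B), p)$sid), c("A", "B"))
  # only 40% of A covered -> retained regardless of score
  B2 <- make_aln("q", 60, 200, 100, sid = "B")
  A3 <- make_aln("q", 0, 100, 50, sid = "A", transcript = strrep("=", 33),
                 send = 33)
  expect_equal(sort(range_cull(rbind(A3, B2), p)$sid), c("A", "B"))
  # single alignment is always retained
  expect_equal(nrow(range_cull(B, p)), 1L)
})

test_that("range-culling is idempotent and every culled alignment has a retained witness", {
  set.seed(33)
  p <- culling_params()
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    qs <- sample(0:300, n, replace = TRUE)
    rows <- do.call(rbind, lapply(seq_len(n), function(i)
      make_aln("q", qs[i], qs[i] + sample(30:150, 1),
               score = sample(20:120, 1), sid = paste0("s", i))))
    kept <- range_cull(rows, p)
    # subset, idempotent
    expect_true(all(kept$sid %in% rows$sid))
    expect_equal(range_cull(kept, p), kept)
    # witness property
    culled <- rows[!rows$sid %in% kept$sid, , drop = FALSE]
    for (i in seq_len(nrow(culled))) {
      a_len <- culled$qend[i] - culled$qstart[i]
      witness <- vapply(seq_len(nrow(kept)), function(j) {
        ov <- min(culled$qend[i], kept$qend[j]) -
          max(culled$qstart[i], kept$qstart[j])
        ov >= p$cover_fraction * a_len &&
          culled$raw_score[i] < p$score_fraction * kept$raw_score[j]
      }, logical(1))
      expect_true(any(witness))
    }
  }
})

test_that("mixed queries are rejected by range_cull and select_nonoverlapping", {
  rows <- rbind(make_aln("q1"), make_aln("q2"))
  expect_error(range_cull(rows), "single query")
  expect_error(select_nonoverlapping(rows), "single query")
})

test_that("suboptimal hits are disjoint on the query and reported by score", {
  cfg <- sim_config(seed = 13, n_genes = 2, gene_length_aa = c(80, 90),
                    read_length = c(100, 100), n_reads = 1,
                    indel_rate = 0, substitution_rate = 0)
  ref <- simulate_reference(cfg)
  g1 <- as.character(ref$dna[[1]]); g2 <- as.character(ref$dna[[2]])
  # segments in reverse order relative to the subject, so one monotone
  # alignment cannot cover both and two disjoint hits are required
  chim <- paste0(substr(g2, 1, 120), substr(g1, 1, 120))
  prot <- Biostrings::AAStringSet(c(
    j = paste0(substr(as.character(ref$protein[[1]]), 1, 40),
               substr(as.character(ref$protein[[2]]), 1, 40))))
  a <- align_frameshift(c(r = chim), prot, max_hits = 4)
  expect_gte(nrow(a), 2L)
  expect_true(all(diff(a$raw_score) <= 0))
  if (nrow(a) >= 2) {
    ov <- min(a$qend[1], a$qend[2]) - max(a$qstart[1], a$qstart[2])
    expect_lte(ov, 0)
  }
})
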