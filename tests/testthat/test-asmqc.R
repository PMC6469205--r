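# Assembly-verification statistics: frame-shifts/kb, concordance kappa,
# clone coverage and break-points, repeat masking, Pearson correlation.

test_that("frameshift_stats computes per-sequence rates and cohort moments", {
  rows <- rbind(
    # seq A: 3 events over 1500 aligned bases -> 2.0 per kb
    make_aln("A", 0, 700, 50, send = 233,
             transcript = paste0(strrep("=", 100), "\\", strrep("=", 132))),
    make_aln("A", 700, 1500, 40, send = 266,
             transcript = paste0(strrep("=", 120), "\\",
                                 strrep("=", 120), "\\", strrep("=", 24))),
    # seq B: 2 events over 500 aligned bases -> 4.0 per kb
    make_aln("B", 0, 500, 30, send = 166,
             transcript = paste0(strrep("=", 80), "\\\\", strrep("=", 84))))
  validate_alignments(rows)
  st <- frameshift_stats(rows)
  per <- st$per_sequence
  expect_equal(per$events_per_kb[per$qid == "A"], 2.0)
  expect_equal(per$events_per_kb[per$qid == "B"], 4.0)
  expect_equal(st$mean, 3.0)
  expect_equal(st$sd, sd(c(2, 4)))
  expect_equal(st$sd, sqrt(2), tolerance = 1e-12)
})

test_that("frameshift_stats: no events means 0 per kb; doubling events doubles the rate", {
  one <- make_aln("A", 0, 999, 50, send = 333, transcript = strrep("=", 333))
  expect_equal(frameshift_stats(one)$per_sequence$events_per_kb, 0)
  base <- make_aln("A", 0, 500, 30, send = 166,
                   transcript = paste0(strrep("=", 80), "\\\\", strrep("=", 84)))
  doubled <- rbind(base, make_aln("A", 500, 1000, 30, send = 166,
                                  transcript = paste0(strrep("=", 80), "\\\\",
                                                      strrep("=", 84))))
  # same rate over twice the span and events; then same events over the span
  expect_equal(frameshift_stats(doubled)$per_sequence$events_per_kb,
               frameshift_stats(base)$per_sequence$events_per_kb)
  expect_error(frameshift_stats(base[0, ]), "no alignments")
})

test_that("concordance is 1 for a perfect single-contig tiling", {
  k <- concordance(1000, c(sr1 = 1000),
                   data.frame(contig = "sr1", aln_length = 1000,
                              pident = 100, lr_start = 0, lr_end = 1000))
  expect_equal(k$kappa, 1.0)
  expect_equal(c(k$c1, k$c2, k$c3, k$c4), rep(1, 4))
})

test_that("kappa is the mean of the four components", {
  # constructed so c1 = 0.5 (two of four contigs align in full), c2 = 0.9,
  # c3 = 0.8, c4 = 0.5; note c1 <= c4 always, since contigs without a hit
  # contribute 0 to c1
  lens <- c(a = 400, b = 400, c = 100, d = 100)
  hits <- data.frame(contig = c("a", "b"), aln_length = c(400, 400),
                     pident = c(90, 90), lr_start = c(0, 400),
                     lr_end = c(400, 800))
  k <- concordance(1000, lens, hits)
  expect_equal(k$c1, 0.5)
  expect_equal(k$c2, 0.9)
  expect_equal(k$c3, 0.8)
  expect_equal(k$c4, 0.5)
  expect_equal(k$kappa, mean(c(k$c1, k$c2, k$c3, k$c4)))
  # with no alignments at all, every component (c2 by convention) is 0
  k0 <- concordance(1000, lens, hits[0, ])
  expect_equal(k0$kappa, 0)
  expect_error(concordance(1000, numeric(0), hits), "empty bin")
})

test_that("concordance keeps one best hit per contig and stays within [0,1]", {
  lens <- c(a = 100)
  hits <- data.frame(contig = c("a", "a"), aln_length = c(60, 120),
                     pident = c(99, 80), lr_start = c(0, 0),
                     lr_end = c(60, 120))
  k <- concordance(200, lens, hits)
  expect_equal(k$c2, 0.8)   # the longer hit wins
  expect_equal(k$c1, 1)     # ratio capped at 1
  expect_true(all(unlist(k[c("c1", "c2", "c3", "c4", "kappa")]) >= 0 &
                  unlist(k[c("c1", "c2", "c3", "c4", "kappa")]) <= 1))
})

test_that("clone validity requires inward orientation and outer span below the cut-off", {
  mk <- function(name, s1, e1, st1, s2, e2, st2)
    data.frame(qname = paste0(name, c("/1", "/2")), strand = c(st1, st2),
               tstart = c(s1, s2), tend = c(e1, e2), tname = "c",
               stringsAsFactors = FALSE)
  params <- clone_params()
  # proper pair, span 500 -> valid
  ok <- clone_coverage(mk("a", 100, 250, "+", 450, 600, "-"), 1000, params)
  expect_equal(ok$n_valid, 1L)
  expect_equal(sum(ok$profile > 0), 500L)
  # same orientation -> invalid
  same <- clone_coverage(mk("b", 100, 250, "+", 450, 600, "+"), 1000, params)
  expect_equal(same$n_valid, 0L)
  # outward-facing (reverse leftmost) -> invalid
  outw <- clone_coverage(mk("c", 100, 250, "-", 450, 600, "+"), 1000, params)
  expect_equal(outw$n_valid, 0L)
  # outer span exactly 800 -> rejected (strictly below)
  at800 <- clone_coverage(mk("d", 0, 150, "+", 650, 800, "-"), 1000, params)
  expect_equal(at800$n_valid, 0L)
  # span 799 -> accepted
  at799 <- clone_coverage(mk("e", 0, 150, "+", 649, 799, "-"), 1000, params)
  expect_equal(at799$n_valid, 1L)
  # unpaired reads are skipped with a warning
  expect_warning(clone_coverage(mk("f", 0, 150, "+", 649, 799, "-")[1, ],
                                1000, params), "mates")
})

test_that("clone coverage is additive and monotone under clone removal", {
  mk2 <- function(name, s, e)
    data.frame(qname = paste0(name, c("/1", "/2")), strand = c("+", "-"),
               tstart = c(s, e - 100), tend = c(s + 100, e), tname = "c",
               stringsAsFactors = FALSE)
  all3 <- rbind(mk2("a", 0, 500), mk2("b", 200, 700), mk2("c", 400, 900))
  cov3 <- clone_coverage(all3, 1000)$profile
  cov2 <- clone_coverage(rbind(mk2("a", 0, 500), mk2("b", 200, 700)), 1000)$profile
  expect_true(all(cov3 >= cov2))
  expect_equal(sum(cov3), 500 * 3)
})

test_that("find_breakpoints returns maximal zero runs with terminal flags", {
  prof <- rep(1L, 100)
  expect_equal(nrow(find_breakpoints(prof)), 0L)
  prof[41:50] <- 0L
  bp <- find_breakpoints(prof, "ctg")
  expect_equal(bp$start, 40)
  expect_equal(bp$end, 50)
  expect_false(bp$terminal)
  # all-zero profile: one terminal run spanning the contig
  bp0 <- find_breakpoints(rep(0L, 100))
  expect_equal(nrow(bp0), 1L)
  expect_true(bp0$terminal)
  expect_equal(c(bp0$start, bp0$end), c(0, 100))
})

test_that("repeat masking applies the length threshold and masks both intervals", {
  paf0 <- data.frame(qname = "c", qlen = 10000L, qstart = 0L, qend = 10000L,
                     strand = "+", tname = "c", tlen = 10000L, tstart = 0L,
                     tend = 10000L, nmatch = 10000L, blocklen = 10000L,
                     mapq = 60L, tags = "", stringsAsFactors = FALSE)
  # only the trivial self-hit -> 0%
  expect_equal(repeat_mask(paf0)$repeat_rate, 0)
  # two identical 1 kb copies reported as one off-diagonal self-hit -> 20%
  paf1 <- rbind(paf0, within(paf0, {
    qstart <- 1000L; qend <- 2000L; tstart <- 6000L; tend <- 7000L
    nmatch <- 1000L; blocklen <- 1000L
  }))
  rm1 <- repeat_mask(paf1)
  expect_equal(rm1$repeat_rate, 20)
  expect_equal(rm1$masked_bases, 2000L)
  expect_equal(rm1$mask$start, c(1000, 6000))
  # a 499 bp self-hit is below the threshold -> 0%
  paf2 <- rbind(paf0, within(paf0, {
    qstart <- 1000L; qend <- 1499L; tstart <- 6000L; tend <- 6499L
    nmatch <- 499L; blocklen <- 499L
  }))
  expect_equal(repeat_mask(paf2)$repeat_rate, 0)
  # 500 bp exactly qualifies (>= threshold)
  paf3 <- rbind(paf0, within(paf0, {
    qstart <- 1000L; qend <- 1500L; tstart <- 6000L; tend <- 6500L
    nmatch <- 500L; blocklen <- 500L
  }))
  expect_equal(repeat_mask(paf3)$repeat_rate, 10)
})

test_that("pearson is affine-invariant, symmetric, and guards degenerate input", {
  x <- c(1, 3, 4, 8, 9)
  expect_equal(pearson(x, 2 * x + 1), 1.0)
  expect_equal(pearson(x, -x), -1.0)
  y <- c(2, 1, 5, 3, 7)
  expect_equal(pearson(x, y), pearson(y, x))
  expect_equal(pearson(3 * x - 2, 0.5 * y + 4), pearson(x, y))
  expect_error(pearson(x, rep(1, 5)), "constant")
  expect_error(pearson(1, 2), "at least 2")
})
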