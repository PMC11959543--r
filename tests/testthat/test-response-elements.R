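# PWM derivation, scoring, calibration, scanning, and motif-pair
# configuration classification.

test_that("derive_spacer_variant lengths and spacer neutrality", {
  seed <- dr5_seed()
  expect_equal(pwm_length(seed), 17)       # 6 + 5 + 6
  for (k in c(0, 3, 9)) {
    dr <- derive_spacer_variant(seed, k, "direct")
    ir <- derive_spacer_variant(seed, k, "inverted")
    expect_equal(pwm_length(dr), 12 + k)
    expect_equal(pwm_length(ir), 12 + k)
    expect_equal(dr$id, paste0("DR", k))
    expect_equal(ir$id, paste0("IR", k))
    if (k > 0)
      expect_true(all(dr$mat[, 6 + seq_len(k)] == 0.25))
  }
  # half-sites are copied verbatim
  dr3 <- derive_spacer_variant(seed, 3, "direct")
  expect_equal(dr3$mat[, 1:6], seed$mat[, 1:6])
  expect_equal(dr3$mat[, 10:15], seed$mat[, 12:17])

  # IR0: downstream half-site is the reverse complement of the seed's
  ir0 <- derive_spacer_variant(seed, 0, "inverted")
  # seed downstream column 12 (A-rich, consensus A) maps to IR0's last
  # column with the A probability moved to T
  expect_equal(unname(ir0$mat["T", 12]), unname(seed$mat["A", 12]))
  expect_equal(unname(ir0$mat["G", 7]), unname(seed$mat["C", 17]))
  expect_error(derive_spacer_variant(pwm("x", matrix(0.25, 4, 8)), 2),
               "half-site")
})

test_that("score_sequence: identity, consensus, and strand symmetry", {
  uni <- pwm("UNI", matrix(0.25, 4, 6))
  expect_equal(score_sequence(uni, "ACGTACGTACGT")$score, 0)

  seed <- dr5_seed()
  cons <- "AGGTCAAATAAAGGTCA"
  lo <- pwm_logodds(seed)
  expected <- bf_best_score(lo, cons)      # exhaustive oracle
  got <- score_sequence(seed, cons)
  expect_equal(got$score, expected)
  expect_gt(got$score, 0)

  # reverse complement scores identically
  rc <- revcomp(cons)
  expect_equal(score_sequence(seed, rc)$score, got$score)

  # N bases contribute zero: all-N sequence scores 0
  expect_equal(score_sequence(seed, strrep("N", 20))$score, 0)
  expect_error(score_sequence(seed, "ACGT"), "shorter")
})

test_that("calibrate_threshold picks the smallest qualifying score", {
  # the order-statistic rule on a controlled score set via mock sequences:
  # verify on real sequences that the control rate never exceeds the target
  set.seed(5)
  seqs <- rand_seqs(500, 100)
  p <- calibrate_threshold(dr5_seed(), seqs, target_fpr = 0.05)
  rate <- attr(p, "control_rate")
  expect_lte(rate, 0.05)
  expect_gt(rate, 0.02)                    # close to the target, not tiny
  # smallest qualifying score: any lower observed score overshoots
  sc <- best_scores(dr5_seed(), seqs)
  lower <- max(sc[sc < p$threshold])
  expect_gt(mean(sc >= lower), 0.05)

  # fpr 1 admits everything
  p1 <- calibrate_threshold(dr5_seed(), seqs, target_fpr = 1)
  expect_equal(p1$threshold, min(sc))

  expect_error(calibrate_threshold(dr5_seed(), seqs[1:10]), ">= 100")
  expect_error(calibrate_threshold(dr5_seed(), rep(strrep("N", 50), 200)),
               "degenerate")
})

test_that("map_motifs equals the exhaustive oracle and collapses hits", {
  set.seed(6)
  seed <- dr5_seed()
  dr3 <- derive_spacer_variant(seed, 3, "direct")
  genome <- c(chrT = paste0(paste(rand_seqs(1, 950), collapse = ""),
                            "AGGTCAAAAAGGTCA",
                            paste(rand_seqs(1, 1035), collapse = "")))
  dr3$threshold <- 8
  hits <- map_motifs(dr3, genome)
  # the planted consensus is recovered
  expect_true(any(hits$start <= 950 & hits$end >= 965))
  # middle base arithmetic: len 15 -> start + 7
  expect_equal(hits$middle_base, hits$start + 7)

  # oracle: enumerate every window on both strands independently
  lo <- pwm_logodds(dr3)
  seqchar <- genome[["chrT"]]
  w <- 15
  oracle_hits <- logical(nchar(seqchar) - w + 1)
  for (i in seq_along(oracle_hits)) {
    sub <- substr(seqchar, i, i + w - 1)
    oracle_hits[i] <- bf_best_score(lo, sub) >= dr3$threshold
  }
  # every oracle-positive window overlaps an emitted (collapsed) hit
  for (i in which(oracle_hits))
    expect_true(any(hits$start < i - 1 + w & hits$end > i - 1))
  # and every emitted hit is oracle-positive at its window
  expect_true(all(oracle_hits[hits$start + 1]))

  # threshold above any attainable score -> empty
  dr3$threshold <- 1e6
  expect_equal(nrow(map_motifs(dr3, genome)), 0)
})

test_that("strand symmetry: reverse-complemented genome, same prevalences", {
  set.seed(8)
  seed <- dr5_seed()
  seed$threshold <- 6
  genome <- c(c1 = rand_seqs(1, 3000))
  rc <- c(c1 = revcomp(genome[["c1"]]))
  h1 <- map_motifs(seed, genome)
  h2 <- map_motifs(seed, rc)
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sort(h1$score), sort(h2$score))
})

test_that("merge_rare concatenates and sorts", {
  a <- data.frame(chrom = "chr2", start = 10, end = 25, strand = "+",
                  score = 5, pwm_id = "DR1", middle_base = 17)
  b <- data.frame(chrom = c("chr1", "chr2"), start = c(40, 5),
                  end = c(55, 20), strand = "+", score = c(6, 7),
                  pwm_id = "DR5", middle_base = c(47, 12))
  m <- merge_rare(a, b)
  expect_equal(nrow(m), 3)
  expect_equal(m$chrom, c("chr1", "chr2", "chr2"))
  expect_equal(m$start, c(40, 5, 10))
  expect_setequal(m$pwm_id, c("DR1", "DR5"))
  expect_equal(nrow(merge_rare(a[0, ], b)), 2)
})

test_that("motif_prevalence and cooccurrence partition regions", {
  regions <- rs(rep("chr1", 4), c(0, 100, 200, 300) * 10,
                c(0, 100, 200, 300) * 10 + 50)
  hits_r <- data.frame(chrom = "chr1", start = c(10, 1010), end = c(25, 1025),
                       strand = "+", score = 5, pwm_id = "DR5",
                       middle_base = c(17, 1017))
  hits_3 <- data.frame(chrom = "chr1", start = c(12, 2012), end = c(27, 2027),
                       strand = "+", score = 5, pwm_id = "DR3",
                       middle_base = c(19, 2019))
  expect_equal(motif_prevalence(regions, hits_r), 0.5)
  expect_equal(motif_prevalence(regions, hits_r[0, ]), 0)
  expect_error(motif_prevalence(regions[0, ], hits_r), "empty")
  co <- cooccurrence(regions, hits_r, hits_3)
  expect_equal(as.character(co$category),
               c("both", "RARE-only", "DR3-only", "none"))
  expect_equal(sum(co$fractions), 1)
})

test_that("configuration classes follow the overlap bins", {
  mk <- function(start, end, id, score = 5)
    data.frame(chrom = "chr1", start = start, end = end, strand = "+",
               score = score, pwm_id = id,
               middle_base = start + (end - start - 1) %/% 2)
  dr3 <- mk(100, 115, "DR3")
  expect_equal(classify_configuration(dr3, mk(110, 123, "DR1"))$class,
               "partially-overlapping")   # 5 shared bases
  expect_equal(classify_configuration(dr3, mk(110, 123, "DR1"))$overlap_bases,
               5)
  expect_equal(classify_configuration(dr3, mk(300, 317, "DR5"))$class,
               "non-overlapping")
  expect_equal(classify_configuration(dr3, mk(103, 117, "DR2"))$class,
               "largely-overlapping")     # 12 shared bases
  # nearest by middle base; tie broken by higher score
  two <- rbind(mk(80, 95, "DR1", score = 2), mk(120, 135, "DR2", score = 9))
  two$middle_base <- c(100, 114)           # |107-100| = |107-114| = 7
  cfg <- classify_configuration(dr3, two)
  expect_equal(cfg$nearest$pwm_id, "DR2")
  expect_error(classify_configuration(dr3, two[0, ]), "no RARE")
})

test_that("configuration frequencies partition and translate invariantly", {
  set.seed(12)
  seed <- dr5_seed()
  dr3p <- derive_spacer_variant(seed, 3, "direct")
  mkhits <- function(offset) {
    list(dr3 = data.frame(chrom = "chr1", start = 100 + offset,
                          end = 115 + offset, strand = "+", score = 5,
                          pwm_id = "DR3", middle_base = 107 + offset),
         rare = data.frame(chrom = "chr1",
                           start = c(110, 400) + offset,
                           end = c(123, 417) + offset, strand = "+",
                           score = c(5, 6), pwm_id = c("DR1", "DR5"),
                           middle_base = c(116, 408) + offset))
  }
  regions <- rs("chr1", 50, 500)
  h <- mkhits(0)
  f0 <- configuration_frequencies(regions, h$dr3, h$rare)
  expect_equal(sum(f0), 1)
  h2 <- mkhits(10000)
  regions2 <- rs("chr1", 10050, 10500)
  f1 <- configuration_frequencies(regions2, h2$dr3, h2$rare)
  expect_equal(f0, f1)
})

test_that("motif files round-trip", {
  seed <- dr5_seed()
  seed$threshold <- 7.25
  f <- tempfile(fileext = ".motif")
  write_motif(seed, f)
  back <- read_motif(f)
  expect_equal(back$mat, seed$mat, tolerance = 1e-5)
  expect_equal(back$threshold, 7.25)
  expect_equal(back$half_site_len, 6)
  expect_equal(back$spacer_len, 5)
})

test_that("sample_control_regions matches sizes and is reproducible", {
  set.seed(77)
  genome <- c(g1 = rand_seqs(1, 5000), g2 = rand_seqs(1, 5000))
  set.seed(1); c1 <- sample_control_regions(genome, sizes = 200, n = 50)
  set.seed(1); c2 <- sample_control_regions(genome, sizes = 200, n = 50)
  expect_equal(c1$regions$start, c2$regions$start)
  expect_true(all(c1$regions$end - c1$regions$start == 200))
  expect_equal(unname(nchar(c1$sequences)), rep(200, 50))
})
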