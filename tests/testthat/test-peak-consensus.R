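# Consensus peak building and occupancy normalization.

summits_at <- function(pos, chrom = "chr1") {
  region_set(rep(chrom, length(pos)), pos, pos + 1, summit = pos,
             name = sprintf("s%d", seq_along(pos)))
}

test_that("extend_summits produces summit +/- flank regions", {
  x <- extend_summits(summits_at(1000))
  expect_equal(c(x$start, x$end), c(900, 1100))
  expect_equal(x$end - x$start, 200)

  expect_warning(y <- extend_summits(summits_at(50)), "truncated")
  expect_equal(c(y$start, y$end), c(0, 150))

  expect_warning(z <- extend_summits(summits_at(990),
                                     chrom_sizes = c(chr1 = 1000)),
                 "truncated")
  expect_equal(z$end, 1000)

  expect_error(extend_summits(summits_at(100), flank = 0), "positive")
  expect_error(extend_summits(rs("chr1", 0, 10)), "summit")
})

test_that("merge_close_summits applies the pairwise center rule", {
  m <- merge_close_summits(summits_at(c(100, 250)))
  expect_equal(nrow(m), 1)
  expect_equal(m$summit, 175)              # center of 100 and 250

  m2 <- merge_close_summits(summits_at(c(100, 400)))
  expect_equal(m2$summit, c(100, 400))     # distance 300 >= 200: untouched

  # chain: 100+250 -> 175; then 175 vs 400 is 225 apart -> two regions
  m3 <- merge_close_summits(summits_at(c(100, 250, 400)))
  expect_equal(m3$summit, c(175, 400))

  # fractional midpoint rounds down
  m4 <- merge_close_summits(summits_at(c(100, 251)))
  expect_equal(m4$summit, 175)
})

test_that("merge_close_summits is idempotent and leaves no close pair", {
  set.seed(11)
  for (i in 1:10) {
    s <- summits_at(sort(sample.int(5000, 30)) + 200)
    m <- merge_close_summits(s)
    expect_true(all(diff(sort(m$summit)) >= 200))
    m2 <- merge_close_summits(m)
    expect_equal(m2$summit, m$summit)
  }
})

test_that("consensus_two_reps applies both-replicate and fallback rules", {
  r1 <- extend_summits(summits_at(c(1000, 5000, 9000)))
  r2 <- extend_summits(summits_at(1020))   # supports only the first
  narrow2 <- rs("chr1", 4900, 5200)        # narrow-peak support for second
  cons <- consensus_two_reps(r1, r2, NULL, narrow2)
  ov <- function(pos) any(cons$start < pos & cons$end > pos)
  expect_true(ov(1000))                    # in both replicates
  expect_true(ov(5000))                    # fallback via narrow peak
  expect_false(ov(9000))                   # unsupported
  expect_true(any(grepl("narrow", cons$name)))
})

test_that("consensus_min_overlap counts replicate support", {
  reps <- list(extend_summits(summits_at(c(1000, 5000))),
               extend_summits(summits_at(9000)),
               extend_summits(summits_at(c(1010, 9020))))
  c2 <- consensus_min_overlap(reps, 2)
  ov <- function(cons, pos) any(cons$start < pos & cons$end > pos)
  expect_true(ov(c2, 1000))                # reps 1 and 3
  expect_true(ov(c2, 9000))                # reps 2 and 3
  expect_false(ov(c2, 5000))               # single replicate
  c1 <- consensus_min_overlap(reps, 1)
  all_m <- merge_regions(rs_three <- region_set(
    rep("chr1", 5), c(900, 4900, 8900, 910, 8920),
    c(1100, 5100, 9100, 1110, 9120)))
  expect_equal(nrow(c1), nrow(all_m))      # minOverlap 1 = merged union
  expect_error(consensus_min_overlap(reps, 0), ">= 1")
  expect_error(consensus_min_overlap(reps, 4), "exceeds")
})

test_that("normalize_occupancy divides by the per-sample 90th percentile", {
  m <- cbind(s1 = 1:10, s2 = rep(4, 10))
  occ <- normalize_occupancy(m)
  expect_equal(unname(occ$p90["s1"]), 9.1)      # type-7 quantile of 1..10
  expect_equal(unname(occ$normalized[10, "s1"]), 10 / 9.1)
  expect_equal(unname(occ$normalized[, "s2"]), rep(1, 10))

  # invariant to per-sample multiplicative scaling
  occ2 <- normalize_occupancy(sweep(m, 2, c(2, 7), "*"))
  expect_equal(occ2$normalized, occ$normalized)

  expect_error(normalize_occupancy(m[1:5, ]), "at least 10")
  expect_error(normalize_occupancy(matrix(0, 10, 2)), "degenerate")
  expect_error(normalize_occupancy(-m), "negative")
})

test_that("consensus rejects single-replicate noise and keeps true sites", {
  # scaled-down version of the acceptance-scale property
  cfg <- sim_config(seed = 5L, n_chroms = 2L, chrom_length = 2e6,
                    n_a_only = 40L, n_common = 60L, n_b_only = 100L,
                    n_noise_peaks = 60L, n_narrow_fallback = 5L)
  study <- simulate_study(cfg)
  cs <- study$truth$chrom_sizes
  reps <- lapply(study$chip$summits$A, function(s)
    merge_close_summits(extend_summits(s, 100, cs), 200, 100, cs))
  cons <- consensus_two_reps(reps[[1]], reps[[2]],
                             study$chip$narrow$A[[1]],
                             study$chip$narrow$A[[2]])
  raw1 <- study$chip$summits$A[[1]]
  noise1 <- extend_summits(raw1[raw1$name %in%
                                  unlist(study$chip$noise_names$A), ],
                           100, cs)
  a_bound <- study$chip$site_regions[
    study$truth$sites$class != "B-only", ]
  retained_noise <- mean(bf_overlaps(noise1, cons))
  expect_lt(retained_noise, 0.10)
  expect_equal(mean(bf_overlaps(a_bound, cons)), 1)
})
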