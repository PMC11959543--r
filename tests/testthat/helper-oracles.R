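# Independent brute-force oracles and small fixture builders. The oracles
# deliberately avoid the package's interval/scanning code paths.

rs <- function(chrom, start, end, ...) region_set(chrom, start, end, ...)

rand_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 2000,
                         max_len = 120) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  region_set(sample(chroms, n, replace = TRUE), start, start + len,
             name = sprintf("r%03d", seq_len(n)))
}

# O(n^2) pairwise overlap oracle: for each row of a, does any row of b
# share >= 1 bp?
bf_overlaps <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# transitive-closure merge oracle via repeated pairwise unioning
bf_merge <- function(x) {
  df <- data.frame(chrom = x$chrom, start = x$start, end = x$end)
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(df)) {
      j <- i + 1
      while (j <= nrow(df)) {
        if (df$chrom[i] == df$chrom[j] && df$start[i] < df$end[j] &&
            df$end[i] > df$start[j]) {
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          df <- df[-j, , drop = FALSE]
          merged <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  df[order(df$chrom, df$start), , drop = FALSE]
}

# exhaustive PWM window oracle: every window, both strands, plain loops
bf_best_score <- function(mat_logodds, seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  sc_one <- function(s, lo) {
    ch <- strsplit(s, NULL)[[1]]
    w <- ncol(lo)
    best <- -Inf
    for (i in seq_len(length(ch) - w + 1)) {
      tot <- 0
      for (j in seq_len(w)) {
        b <- ch[i + j - 1]
        tot <- tot + if (b %in% rownames(lo)) lo[b, j] else 0
      }
      best <- max(best, tot)
    }
    best
  }
  rc <- paste(rev(comp[strsplit(seq, NULL)[[1]]]), collapse = "")
  max(sc_one(seq, mat_logodds), sc_one(rc, mat_logodds))
}

rand_seqs <- function(n, len, gc = 0.41) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    rawToChar(as.raw(c(65L, 67L, 71L, 84L)[
      sample.int(4L, len, replace = TRUE, prob = probs)])), character(1))
}

toy_pwm <- function(id = "TOY", probs = c(0.91, 0.03, 0.03, 0.03), len = 6) {
  m <- matrix(0.25, 4, len)
  for (j in seq_len(len)) m[, j] <- probs[(seq_len(4) + j) %% 4 + 1]
  pwm(id, sweep(m, 2, colSums(m), "/"))
}

dr5_seed <- function() {
  read_motif(system.file("extdata", "dr5_halfsite_synthetic.motif",
                         package = "nrcobind"))
}

# cache expensive shared fixtures across test files (one R session)
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_study <- function() cached("study", {
  simulate_study(sim_config(seed = 101L))
})

default_consensus <- function() cached("consensus", {
  study <- default_study()
  cs <- study$truth$chrom_sizes
  lapply(c(A = "A", B = "B"), function(f) {
    reps <- lapply(study$chip$summits[[f]], function(s)
      merge_close_summits(extend_summits(s, 100, cs), 200, 100, cs))
    consensus_two_reps(reps[[1]], reps[[2]],
                       study$chip$narrow[[f]][[1]],
                       study$chip$narrow[[f]][[2]])
  })
})
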