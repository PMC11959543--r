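# Direct/inverted-repeat PWM toolkit: spacer-variant and inverted-repeat
# generation from a seed matrix, log2-odds scoring against a uniform
# background, FPR-calibrated score thresholds from random control regions,
# genome scanning, prevalence, co-occurrence, and the overlap-configuration
# classification of co-occurring motifs.

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param id motif identifier (e.g. `"DR3"`, `"IR0"`).
#' @param mat 4 x L numeric matrix (rows A, C, G, T), columns summing to 1.
#' @param half_site_len half-site length in bp.
#' @param spacer_len spacer length in bp; `2 * half_site_len + spacer_len`
#'   must equal `ncol(mat)`.
#' @param orientation `"direct"` or `"inverted"`.
#' @param threshold calibrated minimum log2-odds score, or `NA` if not yet
#'   calibrated.
#' @return an object of class `pwm`.
#' @export
pwm <- function(id, mat, half_site_len = NA_integer_,
                spacer_len = NA_integer_,
                orientation = c("direct", "inverted"), threshold = NA_real_) {
  orientation <- match.arg(orientation)
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM matrix must have 4 rows (A, C, G, T)")
  dimnames(mat) <- list(BASES, NULL)
  if (any(mat < 0)) stop("negative PWM probabilities")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-6)) stop("PWM columns must sum to 1")
  if (!is.na(half_site_len) && !is.na(spacer_len) &&
      2 * half_site_len + spacer_len != ncol(mat))
    stop("2 * half_site_len + spacer_len must equal PWM length")
  structure(list(id = id, mat = mat, half_site_len = half_site_len,
                 spacer_len = spacer_len, orientation = orientation,
                 threshold = threshold),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d bp (%s%s), threshold %s\n", x$id, ncol(x$mat),
              x$orientation,
              if (!is.na(x$spacer_len))
                sprintf(", half-site %d + spacer %d", x$half_site_len,
                        x$spacer_len) else "",
              if (is.na(x$threshold)) "uncalibrated" else
                format(x$threshold, digits = 4)))
  invisible(x)
}

#' PWM length in bp
#' @param x a `pwm`.
#' @return integer length.
#' @export
pwm_length <- function(x) ncol(x$mat)

#' Log2-odds scoring matrix
#'
#' Per-cell pseudocount regularization (`(p + pseudo) / (1 + 4 * pseudo)`)
#' followed by `log2(p / 0.25)` against a uniform background.
#' @param x a `pwm`.
#' @param pseudo per-cell pseudocount (default 0.008).
#' @return 4 x L matrix of log2-odds.
#' @export
pwm_logodds <- function(x, pseudo = 0.008) {
  p <- sweep(x$mat + pseudo, 2, colSums(x$mat + pseudo), "/")
  log2(p / 0.25)
}

revcomp_mat <- function(mat) {
  mat[c("T", "G", "C", "A"), rev(seq_len(ncol(mat))), drop = FALSE]
}

#' Reverse complement of a DNA string
#' @param seq character vector of sequences (ACGTN).
#' @return reverse-complemented sequences.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(seq, NULL), function(ch)
    paste(rev(ch), collapse = ""), character(1)))
}

#' Derive a spacer variant or inverted repeat from a seed PWM
#'
#' Copies the seed's half-site columns, replaces the spacer with
#' `new_spacer` uniform (0.25) columns, and - for inverted variants -
#' reverse-complements the downstream half-site's columns. The derived
#' motif is `DRk` or `IRk` with length `2 * half_site + k`.
#'
#' @param seed a `pwm` with `half_site_len` and `spacer_len` annotated
#'   (e.g. a DR5 seed).
#' @param new_spacer new spacer length, 0-9.
#' @param orientation `"direct"` (DR) or `"inverted"` (IR).
#' @return a new, uncalibrated `pwm`.
#' @export
derive_spacer_variant <- function(seed, new_spacer,
                                  orientation = c("direct", "inverted")) {
  orientation <- match.arg(orientation)
  if (is.na(seed$half_site_len) || is.na(seed$spacer_len))
    stop("seed PWM lacks half-site/spacer annotation")
  h <- seed$half_site_len
  up <- seed$mat[, seq_len(h), drop = FALSE]
  down <- seed$mat[, seed$spacer_len + h + seq_len(h), drop = FALSE]
  if (orientation == "inverted") down <- revcomp_mat(down)
  spacer <- matrix(0.25, 4, new_spacer)
  id <- paste0(if (orientation == "direct") "DR" else "IR", new_spacer)
  pwm(id, cbind(up, spacer, down), half_site_len = h,
      spacer_len = new_spacer, orientation = orientation)
}

# integer encoding: A=1 C=2 G=3 T=4, anything else 0 (scores 0 via padded row)
encode_seq <- function(seq) {
  code <- match(strsplit(seq, NULL)[[1]], BASES)
  code[is.na(code)] <- 0L
  code
}

# all window scores of `lo` (4 x w log2-odds) along encoded sequence
scan_scores <- function(code, lo) {
  w <- ncol(lo); L <- length(code)
  if (L < w) return(numeric(0))
  lo5 <- rbind(0, lo)                    # row 1 = N (score 0)
  acc <- numeric(L - w + 1)
  for (j in seq_len(w))
    acc <- acc + lo5[code[seq.int(j, L - w + j)] + 1L, j]
  acc
}

#' Best PWM score in a sequence
#'
#' Scores every window on both strands (`score = sum log2(p/0.25)`; `N`
#' contributes 0) and returns the best. Ties resolve to the lowest
#' coordinate, `+` strand first.
#'
#' @param x a `pwm`.
#' @param seq a DNA string (ACGTN), at least as long as the PWM.
#' @param pseudo pseudocount for [pwm_logodds()].
#' @return list with `score`, `start` (0-based window start), `strand`.
#' @export
score_sequence <- function(x, seq, pseudo = 0.008) {
  w <- pwm_length(x)
  if (nchar(seq) < w) stop("sequence shorter than PWM")
  code <- encode_seq(toupper(seq))
  lo <- pwm_logodds(x, pseudo)
  plus <- scan_scores(code, lo)
  minus <- scan_scores(code, revcomp_mat(lo))
  bp <- max(plus); bm <- max(minus)
  if (bp >= bm) {
    i <- which.max(plus)
    list(score = bp, start = i - 1L, strand = "+")
  } else {
    i <- which.max(minus)
    list(score = bm, start = i - 1L, strand = "-")
  }
}

#' Best-score profile of many sequences
#' @param x a `pwm`.
#' @param seqs character vector of sequences.
#' @param pseudo pseudocount.
#' @return numeric vector of best scores (both strands).
#' @export
best_scores <- function(x, seqs, pseudo = 0.008) {
  lo <- pwm_logodds(x, pseudo)
  lorc <- revcomp_mat(lo)
  vapply(seqs, function(s) {
    code <- encode_seq(toupper(s))
    max(scan_scores(code, lo), scan_scores(code, lorc))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Sample random size-matched control regions
#'
#' Draws `n` regions uniformly over the allowed chromosomes with sizes
#' resampled (with replacement) from `sizes`; regions with more than 50%
#' `N` bases are rejected and redrawn (up to `100 * n` attempts).
#'
#' @param genome named character vector of chromosome sequences.
#' @param sizes size distribution (bp) to match, e.g. widths of a target
#'   region set.
#' @param n number of control regions (default 5000).
#' @param allowed_chroms optional chromosome names/prefix pattern (as in
#'   [filter_assembly()]).
#' @return list with `regions` (a `region_set`) and `sequences`.
#' @export
sample_control_regions <- function(genome, sizes, n = 5000,
                                   allowed_chroms = NULL) {
  chroms <- names(genome)
  if (!is.null(allowed_chroms)) {
    keep <- if (length(allowed_chroms) == 1L)
      grepl(paste0("^", allowed_chroms), chroms) else chroms %in% allowed_chroms
    chroms <- chroms[keep]
  }
  if (!length(chroms)) stop("no allowed chromosomes")
  lens <- nchar(genome[chroms])
  out_chrom <- character(n); out_start <- numeric(n); out_end <- numeric(n)
  got <- 0L; attempts <- 0L
  while (got < n) {
    attempts <- attempts + 1L
    if (attempts > 100L * n) stop("could not place control regions")
    sz <- sizes[sample.int(length(sizes), 1L)]  # resample, not sample.int!
    chr <- sample(chroms, 1, prob = lens)
    if (lens[chr] < sz) next
    st <- sample.int(lens[chr] - sz + 1L, 1) - 1L
    sq <- substr(genome[chr], st + 1, st + sz)
    if (mean(strsplit(sq, NULL)[[1]] == "N") > 0.5) next
    got <- got + 1L
    out_chrom[got] <- chr; out_start[got] <- st; out_end[got] <- st + sz
  }
  rs <- region_set(out_chrom, out_start, out_end,
                   name = sprintf("control_%d", seq_len(n)), sort = FALSE)
  list(regions = rs, sequences = region_sequences(genome, rs))
}

#' Calibrate a PWM score threshold at a target false-positive rate
#'
#' The threshold is the smallest observed best score `t` such that the
#' fraction of control regions whose best score reaches `t` is at most
#' `target_fpr` ("the score giving 5% positive matches in the control
#' set"); ties resolve toward fewer positives.
#'
#' @param x a `pwm`.
#' @param control_seqs character vector of >= 100 control sequences.
#' @param target_fpr target positive-match rate (default 0.05).
#' @param pseudo pseudocount for scoring.
#' @return the `pwm` with its `threshold` set; the chosen threshold and the
#'   achieved control positive rate are attached as attributes
#'   `control_rate` and `n_control`.
#' @export
calibrate_threshold <- function(x, control_seqs, target_fpr = 0.05,
                                pseudo = 0.008) {
  if (length(control_seqs) < 100) stop("need >= 100 control regions")
  sc <- best_scores(x, control_seqs, pseudo)
  n <- length(sc)
  us <- sort(unique(sc))
  if (length(us) == 1)
    stop("degenerate score distribution: all control scores equal ",
         format(us))
  cnt_ge <- n - c(0, cumsum(tabulate(match(sc, us), length(us))))[
    seq_along(us)]
  ok <- which(cnt_ge / n <= target_fpr)
  thr <- if (length(ok)) us[ok[1]] else us[length(us)] + 1e-8
  x$threshold <- thr
  attr(x, "control_rate") <- mean(sc >= thr)
  attr(x, "n_control") <- n
  x
}

#' Map motif hits genome-wide
#'
#' Emits every window on either strand scoring at or above the PWM's
#' calibrated threshold; overlapping same-strand hits are collapsed to the
#' best-scoring one so that prevalence counts regions, not raw windows.
#' `middle_base = start + floor((len - 1) / 2)` (strand-independent).
#'
#' @param x a calibrated `pwm`.
#' @param genome named character vector of chromosome sequences.
#' @param pseudo pseudocount for scoring.
#' @return data.frame of class `motif_hits`: `chrom`, `start`, `end`,
#'   `strand`, `score`, `pwm_id`, `middle_base`, sorted by
#'   `(chrom, start)`.
#' @export
map_motifs <- function(x, genome, pseudo = 0.008) {
  if (is.na(x$threshold)) stop("PWM threshold not calibrated")
  w <- pwm_length(x)
  lo <- pwm_logodds(x, pseudo)
  lorc <- revcomp_mat(lo)
  rows <- list()
  for (chr in names(genome)) {
    code <- encode_seq(toupper(genome[[chr]]))
    for (strand in c("+", "-")) {
      sc <- scan_scores(code, if (strand == "+") lo else lorc)
      hit <- which(sc >= x$threshold)
      if (!length(hit)) next
      # collapse chains of overlapping same-strand hits, keep best score
      grp <- cumsum(c(TRUE, diff(hit) >= w))
      keep <- vapply(split(hit, grp), function(ii) ii[which.max(sc[ii])],
                     numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chr, start = keep - 1, end = keep - 1 + w, strand = strand,
        score = sc[keep], pwm_id = x$id,
        middle_base = keep - 1 + (w - 1) %/% 2,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               strand = character(), score = numeric(), pwm_id = character(),
               middle_base = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Merge motif hit sets into one putative-element file
#'
#' Concatenates hit sets (retaining each hit's `pwm_id`) and sorts by
#' `(chrom, start)`; positions are not collapsed across motif types. Used
#' to pool DR1, DR2, and DR5 hits into the putative-RARE set.
#' @param ... `motif_hits` data.frames.
#' @return a sorted `motif_hits` data.frame.
#' @export
merge_rare <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

hits_as_rs <- function(hits) {
  region_set(hits$chrom, hits$start, hits$end, name = hits$pwm_id,
             score = hits$score, sort = FALSE)
}

#' Per-region presence of motif hits
#' @param regions a `region_set`.
#' @param hits a `motif_hits` data.frame.
#' @return logical vector: region overlaps (>= 1 bp) at least one hit.
#' @export
regions_with_hit <- function(regions, hits) {
  if (!nrow(hits)) return(logical(nrow(regions)))
  overlap_hits(regions, hits_as_rs(hits))
}

#' Fraction of regions containing a motif
#' @param regions a non-empty `region_set`.
#' @param hits a `motif_hits` data.frame.
#' @return fraction of regions overlapping >= 1 hit.
#' @export
motif_prevalence <- function(regions, hits) {
  if (!nrow(regions)) stop("empty region set")
  mean(regions_with_hit(regions, hits))
}

#' Co-occurrence categories of two motif families
#'
#' Four-way partition of regions by presence of putative-RARE (DR1/2/5)
#' and DR3 hits: `both`, `RARE-only`, `DR3-only`, `none`.
#' @param regions a `region_set`.
#' @param rare_hits,dr3_hits `motif_hits` data.frames.
#' @return list with `category` (factor per region) and `fractions`
#'   (named proportions summing to 1).
#' @export
cooccurrence <- function(regions, rare_hits, dr3_hits) {
  r <- regions_with_hit(regions, rare_hits)
  d <- regions_with_hit(regions, dr3_hits)
  category <- factor(ifelse(r & d, "both",
                     ifelse(r, "RARE-only",
                     ifelse(d, "DR3-only", "none"))),
                     levels = c("both", "RARE-only", "DR3-only", "none"))
  fr <- as.numeric(table(category)) / max(1, length(category))
  names(fr) <- levels(category)
  list(category = category, fractions = fr)
}

#' Classify the spatial configuration of a DR3 and its nearest RARE
#'
#' Chooses the RARE hit (DR1/2/5) whose middle base is closest to the DR3
#' middle base (ties to the higher-scoring RARE), counts the DR3 bases also
#' covered by that RARE, and bins the pair: `>= 7` shared bases = largely
#' overlapping, `1-6` = partially overlapping, `0` = non-overlapping.
#'
#' @param dr3_hit single-row `motif_hits` data.frame (the DR3).
#' @param rare_hits `motif_hits` rows inside the same region (>= 1 row).
#' @return list with `nearest` (the chosen RARE row), `distance` (middle
#'   base difference), `overlap_bases`, `class`.
#' @export
classify_configuration <- function(dr3_hit, rare_hits) {
  if (nrow(rare_hits) == 0) stop("no RARE hits in region")
  if (nrow(dr3_hit) != 1) stop("exactly one DR3 hit expected")
  d <- abs(rare_hits$middle_base - dr3_hit$middle_base)
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[which.max(rare_hits$score[best])]
  nr <- rare_hits[best, , drop = FALSE]
  ov <- max(0, min(dr3_hit$end, nr$end) - max(dr3_hit$start, nr$start))
  cls <- if (ov >= 7) "largely-overlapping" else
    if (ov >= 1) "partially-overlapping" else "non-overlapping"
  list(nearest = nr, distance = nr$middle_base - dr3_hit$middle_base,
       overlap_bases = ov, class = cls)
}

#' Configuration class frequencies over a region set
#'
#' Applies [classify_configuration()] to every region containing both a DR3
#' and a RARE hit (per-region best-scoring DR3 is used) and tabulates the
#' three classes.
#' @param regions a `region_set`.
#' @param dr3_hits,rare_hits `motif_hits` data.frames.
#' @return named proportions over `largely-overlapping`,
#'   `partially-overlapping`, `non-overlapping` (summing to 1), with the
#'   count of both-containing regions as attribute `n`.
#' @export
configuration_frequencies <- function(regions, dr3_hits, rare_hits) {
  lv <- c("largely-overlapping", "partially-overlapping", "non-overlapping")
  cls <- character(0)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    ind3 <- dr3_hits$chrom == r$chrom & dr3_hits$end > r$start &
      dr3_hits$start < r$end
    indr <- rare_hits$chrom == r$chrom & rare_hits$end > r$start &
      rare_hits$start < r$end
    if (!any(ind3) || !any(indr)) next
    d3 <- dr3_hits[ind3, , drop = FALSE]
    d3 <- d3[which.max(d3$score), , drop = FALSE]
    cls <- c(cls, classify_configuration(d3,
                                         rare_hits[indr, , drop = FALSE])$class)
  }
  tab <- table(factor(cls, levels = lv))
  out <- if (length(cls)) as.numeric(tab) / length(cls) else
    rep(NA_real_, 3)
  names(out) <- lv
  attr(out, "n") <- length(cls)
  out
}

#' Read a PWM from a HOMER-style motif file
#'
#' Format: a header line `>consensus<TAB>id<TAB>threshold` followed by one
#' line per position with four tab-separated probabilities (A C G T).
#' Optional header fields 4-5 carry `half_site_len` and `spacer_len`.
#' @param path motif file path.
#' @return a `pwm` (threshold taken from the header; may be `NA`).
#' @export
read_motif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!startsWith(lines[1], ">")) stop("missing motif header in ", path)
  hd <- strsplit(sub("^>", "", lines[1]), "\t")[[1]]
  id <- if (length(hd) >= 2) hd[2] else hd[1]
  thr <- if (length(hd) >= 3) suppressWarnings(as.numeric(hd[3])) else NA_real_
  h <- if (length(hd) >= 4) suppressWarnings(as.integer(hd[4])) else NA_integer_
  sp <- if (length(hd) >= 5) suppressWarnings(as.integer(hd[5])) else
    NA_integer_
  mat <- t(vapply(lines[-1], function(l)
    as.numeric(strsplit(l, "\t")[[1]][1:4]), numeric(4)))
  mat <- sweep(t(mat), 2, colSums(t(mat)), "/")  # renormalize columns
  pwm(id, mat, half_site_len = h, spacer_len = sp,
      threshold = if (is.na(thr)) NA_real_ else thr)
}

#' Write a PWM to a HOMER-style motif file
#' @param x a `pwm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif <- function(x, path) {
  cons <- paste(BASES[apply(x$mat, 2, which.max)], collapse = "")
  hd <- paste0(">", cons, "\t", x$id, "\t",
               if (is.na(x$threshold)) "NA" else format(x$threshold),
               "\t", x$half_site_len, "\t", x$spacer_len)
  body <- apply(x$mat, 2, function(col)
    paste(format(col, digits = 6, trim = TRUE), collapse = "\t"))
  writeLines(c(hd, body), path)
  invisible(path)
}
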