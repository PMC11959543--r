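# Consensus peak building from replicate summit calls, and occupancy
# normalization. Binding regions are summit +/- flank (200 bp by default);
# summits closer than min_dist within one dataset are merged.

#' Extend summits into fixed-width binding regions
#'
#' Each summit becomes `[summit - flank, summit + flank)`, i.e. exactly
#' `2 * flank` bp, truncated (with a warning) at chromosome edges when
#' `chrom_sizes` is supplied.
#'
#' @param summits a `region_set` in which every region has a summit.
#' @param flank half-width in bp (default 100, giving 200-bp regions).
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return a `region_set` of extended regions carrying their summits.
#' @export
extend_summits <- function(summits, flank = 100, chrom_sizes = NULL) {
  if (flank <= 0) stop("flank must be positive")
  if (anyNA(summits$summit)) stop("all regions must have a summit")
  start <- summits$summit - flank
  end <- summits$summit + flank
  trunc_low <- start < 0
  start[trunc_low] <- 0
  trunc_high <- rep(FALSE, length(end))
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[summits$chrom]
    trunc_high <- !is.na(lim) & end > lim
    end[trunc_high] <- lim[trunc_high]
  }
  if (any(trunc_low | trunc_high))
    warning(sum(trunc_low | trunc_high), " region(s) truncated at chromosome edges")
  region_set(summits$chrom, start, end, name = summits$name,
             score = summits$score, summit = summits$summit,
             summit_imputed = summits$summit_imputed,
             genome_id = attr(summits, "genome_id"),
             provenance = attr(summits, "provenance"))
}

#' Merge summits closer than a minimum distance
#'
#' Within one dataset, if two summits are closer than `min_dist` bp the two
#' peaks are merged and the center of the two summits (rounded down when
#' fractional) becomes the new summit; the region is re-derived as the new
#' summit +/- `flank`. Applied iteratively left-to-right per chromosome
#' until no pair violates the rule; the result never contains two summits
#' closer than `min_dist`.
#'
#' @param rs a `region_set` with summits (one dataset).
#' @param min_dist minimum allowed pairwise summit distance (bp).
#' @param flank half-width used to re-derive merged regions.
#' @param chrom_sizes optional chromosome lengths for edge truncation.
#' @return a `region_set` with well-separated summits.
#' @export
merge_close_summits <- function(rs, min_dist = 200, flank = 100,
                                chrom_sizes = NULL) {
  if (anyNA(rs$summit)) stop("all regions must have a summit")
  pieces <- lapply(split(seq_len(nrow(rs)), rs$chrom), function(idx) {
    sub <- rs[idx, ]
    s <- sort(sub$summit)
    repeat {
      if (length(s) < 2) break
      gaps <- diff(s)
      j <- which(gaps < min_dist)
      if (!length(gaps[gaps < min_dist])) break
      j <- j[1]                       # leftmost violating pair
      s[j] <- (s[j] + s[j + 1]) %/% 2 # center, rounded down
      s <- sort(s[-(j + 1)])
    }
    data.frame(chrom = sub$chrom[1], summit = s, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  summits <- region_set(df$chrom, df$summit, df$summit + 1, summit = df$summit,
                        genome_id = attr(rs, "genome_id"))
  suppressWarnings(extend_summits(summits, flank = flank,
                                  chrom_sizes = chrom_sizes))
}

#' Two-replicate consensus with narrow-peak fallback
#'
#' A region is a consensus peak if it was identified in both replicates: an
#' extended summit region of replicate 1 qualifies if it overlaps (>= 1 bp)
#' a replicate-2 summit region, or - fallback - a replicate-2 narrow peak
#' (regions detected without a resolved summit in that replicate); and
#' symmetrically for replicate 2. The consensus set is the merged union of
#' qualifying regions; each envelope's name records which rule admitted its
#' members (`summit` or `narrow`).
#'
#' @param rep1,rep2 extended, self-merged summit `region_set`s.
#' @param rep1_narrow,rep2_narrow narrowPeak `region_set`s for the fallback
#'   check (may be empty).
#' @return a merged consensus `region_set`.
#' @export
consensus_two_reps <- function(rep1, rep2,
                               rep1_narrow = NULL, rep2_narrow = NULL) {
  empty <- region_set()
  if (is.null(rep1_narrow)) rep1_narrow <- empty
  if (is.null(rep2_narrow)) rep2_narrow <- empty
  q1_sum <- overlap_hits(rep1, rep2)
  q1_nar <- overlap_hits(rep1, rep2_narrow)
  q2_sum <- overlap_hits(rep2, rep1)
  q2_nar <- overlap_hits(rep2, rep1_narrow)
  tag <- function(rs, via_summit, via_narrow) {
    keep <- via_summit | via_narrow
    out <- rs[keep, ]
    out$name <- ifelse(via_summit[keep], "summit", "narrow")
    out
  }
  a <- tag(rep1, q1_sum, q1_nar)
  b <- tag(rep2, q2_sum, q2_nar)
  both <- rs_from_df(rbind(as.data.frame(a), as.data.frame(b)),
                     template = rep1, sort = TRUE)
  merge_regions(both)
}

#' Minimum-overlap consensus across replicate sets
#'
#' Builds the merged envelope of all replicate regions and keeps envelopes
#' supported (>= 1 bp overlap) by at least `min_overlap` replicate sets;
#' the DiffBind-style rule used with `minOverlap = 2` (three replicates) or
#' `minOverlap = 3` (pooled multi-sample sets).
#'
#' @param reps list of `region_set`s (one per replicate).
#' @param min_overlap minimum number of supporting replicate sets (>= 1).
#' @return a merged consensus `region_set`.
#' @export
consensus_min_overlap <- function(reps, min_overlap) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  if (min_overlap > length(reps))
    stop("min_overlap exceeds number of replicate sets")
  all_df <- do.call(rbind, lapply(reps, as.data.frame))
  env <- merge_regions(rs_from_df(all_df, template = reps[[1]], sort = TRUE))
  env[support_count(env, reps) >= min_overlap, ]
}

#' Normalize an occupancy table by per-sample 90th percentiles
#'
#' Divides each sample's RPKM column by that sample's 90th percentile over
#' all regions (linear-interpolation quantile, `type = 7`). The returned
#' object records the percentile used per sample.
#'
#' @param rpkm regions x samples non-negative matrix (>= 10 regions).
#' @param samples optional data.frame of sample metadata (e.g. `condition`,
#'   `replicate`), one row per column of `rpkm`.
#' @param p percentile (default 0.9).
#' @return an `occupancy_matrix`: list with `normalized`, `rpkm`, `p90`,
#'   `samples`.
#' @export
normalize_occupancy <- function(rpkm, samples = NULL, p = 0.9) {
  rpkm <- as.matrix(rpkm)
  if (nrow(rpkm) < 10) stop("need at least 10 regions to normalize")
  if (any(rpkm < 0)) stop("negative occupancy values")
  p90 <- apply(rpkm, 2, stats::quantile, probs = p, names = FALSE)
  if (any(p90 <= 0)) stop("degenerate dataset: 90th percentile is zero")
  structure(list(normalized = sweep(rpkm, 2, p90, "/"), rpkm = rpkm,
                 p90 = p90, p = p, samples = samples),
            class = "occupancy_matrix")
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat(sprintf("occupancy_matrix: %d regions x %d samples (P%d-normalized)\n",
              nrow(x$normalized), ncol(x$normalized), round(100 * x$p)))
  invisible(x)
}
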