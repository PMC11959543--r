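# Interval algebra on region_set objects. 0-based half-open intervals are
# converted to IRanges (1-based closed) only inside these helpers.

rs_iranges <- function(rs) {
  IRanges::IRanges(start = rs$start + 1L, end = rs$end)
}

# indices of rows in `a` overlapping any row of `b` by >= 1 bp
overlap_hits <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(logical(nrow(a)))
  hit <- logical(nrow(a))
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == chr)
    ib <- which(b$chrom == chr)
    ov <- IRanges::overlapsAny(rs_iranges(a[ia, , drop = FALSE]),
                               rs_iranges(b[ib, , drop = FALSE]))
    hit[ia] <- ov
  }
  hit
}

#' Count overlapping sets supporting each region
#'
#' For each region in `rs`, the number of region sets in `sets` that overlap
#' it by at least 1 bp.
#' @param rs a `region_set`.
#' @param sets list of `region_set`s.
#' @return integer vector parallel to `rs`.
#' @export
support_count <- function(rs, sets) {
  Reduce(`+`, lapply(sets, function(s) as.integer(overlap_hits(rs, s))),
         integer(nrow(rs)) + 0L)
}

#' Partition two region sets by mutual overlap
#'
#' Splits each of two canonicalized sets into the subset overlapping the
#' other set (by >= 1 bp) and the remainder. A region of `a` spanning several
#' regions of `b` contributes once to `a_overlapping`. Mirrors the two-step
#' intersect workflow used for pairwise cistrome comparisons.
#'
#' @param a,b `region_set` objects.
#' @return list with `a_only`, `a_overlapping`, `b_only`, `b_overlapping`.
#' @export
overlap_partition <- function(a, b) {
  ha <- overlap_hits(a, b)
  hb <- overlap_hits(b, a)
  list(a_only = a[!ha, ], a_overlapping = a[ha, ],
       b_only = b[!hb, ], b_overlapping = b[hb, ])
}

#' Merge overlapping regions into union envelopes
#'
#' Collapses every chain of regions overlapping by >= 1 bp into its union
#' envelope (mergeBed semantics, transitively closed). Output is sorted and
#' non-overlapping; each envelope's `name` lists member region names.
#'
#' @param rs a `region_set`.
#' @return a `region_set` of disjoint envelopes.
#' @export
merge_regions <- function(rs) {
  if (nrow(rs) == 0) return(rs)
  out <- lapply(split(seq_len(nrow(rs)), rs$chrom), function(idx) {
    sub <- rs[idx, ]
    ir <- rs_iranges(sub)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)  # adjacency is not overlap
    memb <- IRanges::findOverlaps(ir, red)
    nm <- vapply(split(sub$name[S4Vectors::queryHits(memb)],
                       S4Vectors::subjectHits(memb)),
                 function(v) paste(stats::na.omit(v), collapse = ","),
                 character(1))
    nm[nm == ""] <- NA_character_
    data.frame(chrom = sub$chrom[1], start = IRanges::start(red) - 1L,
               end = IRanges::end(red), name = nm, score = NA_real_,
               summit = NA_real_, summit_imputed = FALSE,
               stringsAsFactors = FALSE)
  })
  rs_from_df(do.call(rbind, out), template = rs, sort = TRUE)
}

#' Filter a region set by assembly and blacklist
#'
#' Keeps regions on allowed chromosomes (exact names or a regular-expression
#' pattern anchored at the chromosome-name start) and removes any region
#' overlapping the blacklist by >= 1 bp. Matches the convention of keeping
#' only complete-assembly ("NC"-prefixed) sequences while excluding
#' ENCODE-blacklisted artifact regions.
#'
#' @param rs a `region_set`.
#' @param allowed_chroms character vector of chromosome names, or a single
#'   string interpreted as a prefix pattern (e.g. `"NC"`).
#' @param blacklist optional `region_set` of regions to exclude.
#' @return the filtered `region_set` (order preserved).
#' @export
filter_assembly <- function(rs, allowed_chroms, blacklist = NULL) {
  if (length(allowed_chroms) == 0) stop("empty allowed chromosome list")
  keep <- if (length(allowed_chroms) == 1L)
    grepl(paste0("^", allowed_chroms), rs$chrom)
  else rs$chrom %in% allowed_chroms
  out <- rs[keep, ]
  if (!is.null(blacklist) && nrow(blacklist) > 0 && nrow(out) > 0)
    out <- out[!overlap_hits(out, blacklist), ]
  out
}

#' Annotate each region with its nearest gene TSS
#'
#' Distance is measured from the region center to the TSS; the gene with the
#' minimal absolute distance wins, ties broken by lexicographically smaller
#' `gene_id`. The sign follows the gene's strand: negative means the region
#' lies upstream of the TSS.
#'
#' @param rs a `region_set`.
#' @param genes a `gene_model` table (non-empty).
#' @return data.frame with `gene_id` and signed `distance` per region;
#'   regions on chromosomes without genes get `gene_id = "none"` and
#'   `distance = NA`.
#' @export
nearest_feature <- function(rs, genes) {
  if (nrow(genes) == 0) stop("empty gene collection")
  centers <- region_center(rs)
  gene_id <- rep("none", nrow(rs))
  distance <- rep(NA_real_, nrow(rs))
  for (chr in unique(rs$chrom)) {
    gi <- which(genes$chrom == chr)
    if (!length(gi)) next
    g <- genes[gi, , drop = FALSE]
    g <- g[order(g$gene_id), , drop = FALSE]  # tie-break: first minimum wins
    ri <- which(rs$chrom == chr)
    for (i in ri) {
      d <- abs(centers[i] - g$tss)
      j <- which.min(d)
      raw <- centers[i] - g$tss[j]           # + strand: downstream positive
      gene_id[i] <- g$gene_id[j]
      distance[i] <- if (g$strand[j] == "+") raw else -raw
    }
  }
  data.frame(gene_id = gene_id, distance = distance, stringsAsFactors = FALSE)
}
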