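# Classification of two consensus cistromes into exclusive and common
# regions, dominance clusters by normalized-occupancy ratio, and chromatin
# accessibility categories.

#' Symmetric common/exclusive split of two cistromes
#'
#' Treats the two consensus sets equally: every region of `a` overlapping
#' `b` (>= 1 bp) and vice versa is pooled and merged (mergeBed semantics)
#' into common envelopes, which may exceed the uniform 200-bp region width;
#' the remainders are the exclusive sets.
#'
#' @param a,b consensus `region_set`s (factor A and factor B).
#' @return list with `a_only`, `common`, `b_only`.
#' @export
common_set <- function(a, b) {
  part <- overlap_partition(a, b)
  ov <- rbind(as.data.frame(part$a_overlapping),
              as.data.frame(part$b_overlapping))
  common <- if (nrow(ov)) merge_regions(rs_from_df(ov, template = a))
            else a[0, ]
  list(a_only = part$a_only, common = common, b_only = part$b_only)
}

#' Classify common regions into dominance clusters
#'
#' Per common region, the ratio of replicate-mean normalized factor-A signal
#' to factor-B signal decides the cluster: `> hi` A-dominant, `< lo`
#' B-dominant, otherwise similarly occupied (closed middle interval; ratios
#' exactly at a cutoff fall in the middle). Regions with zero B but nonzero
#' A signal get ratio `Inf` (A-dominant); regions with both signals zero are
#' excluded with a warning.
#'
#' @param common `region_set` of common envelopes.
#' @param a_signal,b_signal matrices (regions x replicates) of normalized
#'   signal re-quantified on the common envelopes, rows parallel to `common`.
#' @param hi,lo ratio cutoffs (defaults 1.5 and 0.66).
#' @return list of three `binding_cluster`s: `a_dominant`,
#'   `similarly_occupied`, `b_dominant`; each a list with `label`, `regions`,
#'   `ratio`.
#' @export
classify_dominance <- function(common, a_signal, b_signal,
                               hi = 1.5, lo = 0.66) {
  a_mean <- rowMeans(as.matrix(a_signal))
  b_mean <- rowMeans(as.matrix(b_signal))
  stopifnot(length(a_mean) == nrow(common), length(b_mean) == nrow(common))
  dead <- a_mean == 0 & b_mean == 0
  if (any(dead)) {
    warning(sum(dead), " region(s) with zero signal for both factors excluded")
    common <- common[!dead, ]
    a_mean <- a_mean[!dead]; b_mean <- b_mean[!dead]
  }
  ratio <- ifelse(b_mean == 0, Inf, a_mean / b_mean)
  lab <- ifelse(ratio > hi, "A-dominant",
                ifelse(ratio < lo, "B-dominant", "similarly-occupied"))
  mk <- function(l) {
    sel <- lab == l
    structure(list(label = l, regions = common[sel, ], ratio = ratio[sel]),
              class = "binding_cluster")
  }
  list(a_dominant = mk("A-dominant"),
       similarly_occupied = mk("similarly-occupied"),
       b_dominant = mk("B-dominant"))
}

#' @export
print.binding_cluster <- function(x, ...) {
  cat(sprintf("binding_cluster '%s': %d region(s)\n", x$label,
              nrow(x$regions)))
  invisible(x)
}

#' Chromatin accessibility categories of binding regions
#'
#' Assigns each binding region one of four categories by >= 1 bp overlap
#' with ATAC consensus peak sets from vehicle- and ligand-treated cells:
#' `open-both`, `open-ligand-only`, `open-vehicle-only`, `closed-both`.
#'
#' @param binding a `region_set`.
#' @param atac_vehicle,atac_ligand ATAC consensus `region_set`s.
#' @return list with `category` (factor per region, partitioning the set)
#'   and `fraction_open` (share of regions overlapping either ATAC set).
#' @export
accessibility_categories <- function(binding, atac_vehicle, atac_ligand) {
  v <- overlap_hits(binding, atac_vehicle)
  l <- overlap_hits(binding, atac_ligand)
  category <- factor(ifelse(v & l, "open-both",
                     ifelse(l, "open-ligand-only",
                     ifelse(v, "open-vehicle-only", "closed-both"))),
                     levels = c("open-both", "open-ligand-only",
                                "open-vehicle-only", "closed-both"))
  list(category = category,
       fraction_open = if (nrow(binding)) mean(v | l) else NA_real_)
}

#' Five-number signal summary per cluster
#'
#' Median, quartiles, and Tukey whiskers (last data points within
#' 1.5 x IQR of the quartiles), the box-and-whisker convention.
#'
#' @param values numeric signal values for the regions of one cluster.
#' @return named numeric vector `lower`, `q1`, `median`, `q3`, `upper`,
#'   or an empty vector (with a warning) for an empty cluster.
#' @export
cluster_signal_summary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) {
    warning("empty cluster: no summary")
    return(stats::setNames(numeric(0), character(0)))
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lower <- min(values[values >= q[1] - 1.5 * iqr])
  upper <- max(values[values <= q[3] + 1.5 * iqr])
  c(lower = lower, q1 = q[1], median = q[2], q3 = q[3], upper = upper)
}
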