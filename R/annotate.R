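# Connecting binding clusters to gene sets: nearest-gene annotation,
# TSS-window membership, and observed/expected enrichment.

#' Closest-gene regulation profile per cluster
#'
#' Annotates every region of every cluster with its nearest gene
#' ([nearest_feature()]) and tabulates, per cluster, the proportion of
#' regions whose closest gene carries each regulation label.
#'
#' @param clusters named list of `region_set`s (one per binding cluster).
#' @param genes a `gene_model` table.
#' @param labels named character vector: regulation label per `gene_id`
#'   (genes absent from it count as `"none"`).
#' @return matrix clusters x labels of proportions (rows sum to 1; empty
#'   clusters yield all-`NA` rows with a warning).
#' @export
annotate_closest <- function(clusters, genes, labels) {
  all_labels <- sort(unique(c("none", labels)))
  out <- matrix(NA_real_, nrow = length(clusters), ncol = length(all_labels),
                dimnames = list(names(clusters), all_labels))
  for (cl in names(clusters)) {
    rs <- clusters[[cl]]
    if (!nrow(rs)) { warning("empty cluster: ", cl); next }
    ann <- nearest_feature(rs, genes)
    lab <- unname(labels[ann$gene_id])
    lab[is.na(lab)] <- "none"
    tab <- table(factor(lab, levels = all_labels))
    out[cl, ] <- as.numeric(tab) / sum(tab)
  }
  out
}

#' TSS-window membership of regions
#'
#' A region belongs to a gene's window when its center lies within
#' `[TSS - half_width, TSS + half_width]` on the same chromosome; a region
#' may belong to several genes' windows.
#'
#' @param genes a `gene_model` table (the gene set of interest).
#' @param regions a `region_set` (all clustered regions).
#' @param half_width window half-width in bp (default 25000).
#' @return list per gene (named by `gene_id`) of member region row indices
#'   into `regions`.
#' @export
windows_membership <- function(genes, regions, half_width = 25000) {
  centers <- region_center(regions)
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    sel <- which(regions$chrom == genes$chrom[i] &
                   centers >= genes$tss[i] - half_width &
                   centers <= genes$tss[i] + half_width)
    out[[i]] <- sel
  }
  out
}

#' Assemble the annotation gene sets
#'
#' The five gene sets used for window enrichment and prevalence analyses:
#' the three up-sets (A-only, both, D-only), the downregulated set, and
#' the top-`n_top` non-regulated genes by mean vehicle expression
#' ("non-regulated highly expressed", default 250).
#'
#' @param calls result of [de_gate()].
#' @param norm the normalized expression matrix used for the calls.
#' @param design the [expression_design()].
#' @param n_top size of the non-regulated highly-expressed set.
#' @return named list of gene-id vectors: `A_only_up`, `both_up`,
#'   `D_only_up`, `down`, `nonreg_high`.
#' @export
select_gene_sets <- function(calls, norm, design, n_top = 250) {
  sets <- gene_set_partition(calls)
  nonreg <- calls$gene[calls$label == "none"]
  veh <- rowMeans(as.matrix(norm)[, design$condition == "vehicle",
                                  drop = FALSE])
  nonreg <- nonreg[order(veh[nonreg], decreasing = TRUE)]
  sets$nonreg_high <- utils::head(nonreg, n_top)
  sets
}

#' Observed/expected enrichment of clusters in gene-set windows
#'
#' For each (cluster, gene set) pair: observed = number of that cluster's
#' regions inside the set's TSS windows; expected = total window regions x
#' cluster share of all clustered regions; ratio = observed / expected.
#' A region in several genes' windows of one set is counted once per set.
#'
#' @param cluster_of character vector: cluster label per region of the full
#'   clustered `region_set` (the universe).
#' @param memberships named list (one element per gene set) of
#'   [windows_membership()] results computed against that same universe.
#' @return data.frame with `cluster`, `gene_set`, `observed`, `expected`,
#'   `ratio` (`NA` ratio flagged where expected is 0).
#' @export
enrichment <- function(cluster_of, memberships) {
  clusters <- sort(unique(cluster_of))
  share <- table(factor(cluster_of, levels = clusters)) / length(cluster_of)
  rows <- list()
  for (gs in names(memberships)) {
    members <- sort(unique(unlist(memberships[[gs]])))
    tot <- length(members)
    obs <- table(factor(cluster_of[members], levels = clusters))
    for (cl in clusters) {
      e <- tot * as.numeric(share[cl])
      o <- as.numeric(obs[cl])
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, gene_set = gs, observed = o, expected = e,
        ratio = if (e > 0) o / e else NA_real_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Normalized prevalence of common regions in gene-set windows
#'
#' Per gene set: fraction of window-member regions that belong to the common
#' cluster, i.e. common member count divided by total member count
#' ("peak counts normalized by the total number of peaks in the regions").
#' Optionally restricted to a subset of common regions (e.g. those with
#' significantly induced MED1 signal).
#'
#' @param is_common logical vector per region of the universe.
#' @param memberships named list of [windows_membership()] results.
#' @param restrict optional logical vector per region: additional filter on
#'   the numerator (membership in the restricted common subset).
#' @return named numeric vector of fractions per gene set (`NA`, flagged by
#'   a warning, where a set has no window regions).
#' @export
normalized_prevalence <- function(is_common, memberships, restrict = NULL) {
  num_ok <- if (is.null(restrict)) is_common else is_common & restrict
  out <- vapply(memberships, function(m) {
    members <- sort(unique(unlist(m)))
    if (!length(members)) return(NA_real_)
    sum(num_ok[members]) / length(members)
  }, numeric(1))
  if (anyNA(out)) warning("gene set(s) with zero window regions flagged NA")
  out
}
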