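# Replicate-aware differential occupancy (Welch t-test on log2 normalized
# counts with BH, a documented stand-in for a negative-binomial GLM), MED1
# ligand-responsiveness, and the cooperative MED1 recruitment test.

welch_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
               1)
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[se2 == 0 & m1 == m2] <- 1
  p[se2 == 0 & m1 != m2] <- 0
  p_greater <- stats::pt(t, df, lower.tail = FALSE)
  p_greater[se2 == 0] <- ifelse(m1[se2 == 0] > m2[se2 == 0], 0, 1)
  list(diff = m1 - m2, p = p, p_greater = p_greater, t = t, df = df)
}

#' Differential occupancy between two sample groups
#'
#' Per region, a t-test on `log2(normalized count + 1)` between the two
#' groups, with Benjamini-Hochberg correction across regions. The effect
#' size is the difference of group means on the log2 scale (log2 fold
#' change). Significance flag at `FDR <= fdr`.
#'
#' The default `"moderated"` method shrinks the per-region pooled variance
#' toward a common prior by empirical Bayes (limma's `squeezeVar`), adding
#' the prior degrees of freedom to the residual ones; with 2-3 replicates
#' per group an unmoderated per-region test cannot reach BH-adjusted
#' significance at all (its p-values are floored by 2-4 degrees of
#' freedom), which is why replicate-aware ChIP-seq tools borrow strength
#' across regions. `"welch"` gives the plain per-region Welch test.
#'
#' @param norm regions x samples normalized count matrix.
#' @param groupA,groupB column indices (or logical masks) of the two groups,
#'   each with >= 2 replicates.
#' @param fdr significance threshold on adjusted p-values (default 0.05).
#' @param method `"moderated"` (default) or `"welch"`.
#' @return data.frame with `region`, `log2fc` (A minus B), `p`, `fdr`,
#'   `significant`.
#' @export
differential_occupancy <- function(norm, groupA, groupB, fdr = 0.05,
                                   method = c("moderated", "welch")) {
  method <- match.arg(method)
  norm <- as.matrix(norm)
  x <- log2(norm[, groupA, drop = FALSE] + 1)
  y <- log2(norm[, groupB, drop = FALSE] + 1)
  if (ncol(x) < 2 || ncol(y) < 2) stop("need >= 2 replicates per group")
  if (method == "welch") {
    w <- welch_rows(x, y)
    diff <- w$diff; p <- w$p
  } else {
    n1 <- ncol(x); n2 <- ncol(y)
    diff <- rowMeans(x) - rowMeans(y)
    df_resid <- n1 + n2 - 2
    s2 <- (apply(x, 1, stats::var) * (n1 - 1) +
             apply(y, 1, stats::var) * (n2 - 1)) / df_resid
    sq <- tryCatch(limma::squeezeVar(s2, df = df_resid),
                   error = function(e) list(var.post = s2, df.prior = 0))
    df_prior <- if (is.finite(sq$df.prior)) sq$df.prior else 1e6
    se <- sqrt(sq$var.post * (1 / n1 + 1 / n2))
    t <- ifelse(se > 0, diff / se, 0)
    p <- 2 * stats::pt(abs(t), df_resid + df_prior, lower.tail = FALSE)
    p[se == 0 & diff == 0] <- 1
    p[se == 0 & diff != 0] <- 0
  }
  q <- stats::p.adjust(p, method = "BH")
  data.frame(region = rownames(norm), log2fc = diff, p = p, fdr = q,
             significant = q <= fdr, stringsAsFactors = FALSE)
}

#' Fraction of cluster regions overlapping induced MED1 peaks
#'
#' @param clusters named list of `region_set`s (binding clusters).
#' @param med1_regions `region_set` of MED1 consensus peaks, rows parallel
#'   to `med1_diff`.
#' @param med1_diff result of [differential_occupancy()] for one treatment
#'   contrast (ligand vs vehicle) on the MED1 consensus.
#' @return named numeric vector: per cluster, the fraction of regions
#'   overlapping (>= 1 bp) significantly induced MED1 peaks (positive
#'   log2fc and significant).
#' @export
med1_responsive <- function(clusters, med1_regions, med1_diff) {
  sig <- med1_regions[med1_diff$significant & med1_diff$log2fc > 0, ]
  vapply(clusters, function(rs) {
    if (!nrow(rs)) return(NA_real_)
    mean(overlap_hits(rs, sig))
  }, numeric(1))
}

#' Cooperative MED1 recruitment test
#'
#' Per region of a pooled multi-sample consensus: the more effective single
#' treatment is the one (A or D) with the larger replicate-mean signal; an
#' unpaired Welch t-test (one-sided, testing an increase) compares the
#' combined-treatment replicates against that treatment's replicates. A
#' region is cooperative when the combined/best-single fold change exceeds
#' 1 AND `p <= alpha` (uncorrected, per-region tests; under the null the
#' called fraction is therefore ~`alpha`).
#'
#' @param norm regions x samples normalized signal matrix.
#' @param design an [expression_design()]-style data.frame for the columns.
#' @param alpha per-region significance level (default 0.05).
#' @param fc_min minimum fold change (default 1, i.e. any increase).
#' @return data.frame with `region`, `more_effective`, `fc`, `p`,
#'   `cooperative`.
#' @export
med1_cooperative <- function(norm, design, alpha = 0.05, fc_min = 1) {
  norm <- as.matrix(norm)
  ia <- which(design$condition == "A"); id <- which(design$condition == "D")
  ic <- which(design$condition == "combined")
  if (length(ia) < 2 || length(id) < 2 || length(ic) < 2)
    stop("need >= 2 replicates per treatment")
  ma <- rowMeans(norm[, ia, drop = FALSE])
  md <- rowMeans(norm[, id, drop = FALSE])
  eff <- ifelse(ma >= md, "A", "D")
  if (length(ia) != length(id))
    stop("A and D treatments must have equal replicate counts")
  mc <- rowMeans(norm[, ic, drop = FALSE])
  best_mean <- pmax(ma, md)
  fc <- ifelse(best_mean == 0, ifelse(mc > 0, Inf, 1), mc / best_mean)
  single <- norm[, ia, drop = FALSE]
  single[eff == "D", ] <- norm[eff == "D", id, drop = FALSE]
  w <- welch_rows(norm[, ic, drop = FALSE], single)
  data.frame(region = rownames(norm), more_effective = eff, fc = fc,
             p = w$p_greater,
             cooperative = fc > fc_min & w$p_greater <= alpha,
             stringsAsFactors = FALSE)
}

#' Category composition of cooperative MED1 regions
#'
#' Compares the proportions of binding categories (A-only / common /
#' B-only) among binding regions overlapping cooperative MED1 peaks with
#' the whole-cistrome background proportions.
#'
#' @param categories named list of three `region_set`s: `a_only`, `common`,
#'   `b_only`.
#' @param coop_med1 `region_set` of cooperative MED1 peaks.
#' @return data.frame with one row per category: `category`, `n_total`,
#'   `n_coop`, `prop_background`, `prop_coop` (each proportion column sums
#'   to 1; all-zero with a warning if the cooperative set is empty).
#' @export
cooperative_composition <- function(categories, coop_med1) {
  n_tot <- vapply(categories, nrow, integer(1))
  n_coop <- vapply(categories, function(rs)
    if (nrow(coop_med1)) sum(overlap_hits(rs, coop_med1)) else 0L, integer(1))
  if (sum(n_coop) == 0) warning("empty cooperative MED1 overlap: zero table")
  data.frame(category = names(categories), n_total = n_tot, n_coop = n_coop,
             prop_background = n_tot / sum(n_tot),
             prop_coop = if (sum(n_coop)) n_coop / sum(n_coop) else
               rep(0, length(n_coop)),
             stringsAsFactors = FALSE, row.names = NULL)
}
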