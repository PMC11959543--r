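# RNA-seq differential-expression gate (low-expression filter -> one-way
# ANOVA + BH -> Tukey HSD per ligand-vs-vehicle contrast -> 1.5/0.66 fold
# cutoffs) and the four-step cooperative-upregulation caller for the
# vehicle / ligand A / ligand D / combined x 3-replicate design.

#' Build a 4-condition expression design
#' @param conditions condition labels in sample order.
#' @param replicates replicate index per sample.
#' @return data.frame with `condition` (factor: vehicle, A, D, combined)
#'   and `replicate`.
#' @export
expression_design <- function(conditions = rep(c("vehicle", "A", "D",
                                                 "combined"), each = 3),
                              replicates = rep(1:3, times = 4)) {
  data.frame(condition = factor(conditions,
                                levels = c("vehicle", "A", "D", "combined")),
             replicate = replicates)
}

#' Library-size normalize a count matrix
#'
#' Per-sample scaling to the mean library size (counts-per-million up to a
#' constant), keeping values on the raw-count scale. All downstream labels
#' are invariant to global library scaling.
#' @param counts genes x samples non-negative matrix.
#' @return normalized matrix of the same shape.
#' @export
normalize_libsize <- function(counts) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("sample with zero total counts")
  sweep(counts, 2, lib / mean(lib), "/")
}

cond_means <- function(norm, design) {
  vapply(levels(design$condition), function(cc)
    rowMeans(norm[, design$condition == cc, drop = FALSE]), numeric(nrow(norm)))
}

# vectorized one-way ANOVA + Tukey HSD p-values for selected contrasts
anova_tukey <- function(norm, design) {
  cond <- design$condition
  k <- nlevels(cond); n <- ncol(norm)
  gm <- cond_means(norm, design)
  nn <- as.numeric(table(cond))[match(colnames(gm), levels(cond))]
  grand <- rowMeans(norm)
  ssb <- rowSums(sweep(sweep(gm, 1, grand, "-")^2, 2, nn, "*"))
  sst <- rowSums(sweep(norm, 1, grand, "-")^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1; df2 <- n - k
  mse <- ssw / df2
  f <- ifelse(mse > 0, (ssb / df1) / mse, ifelse(ssb > 0, Inf, 0))
  p_anova <- ifelse(is.finite(f), stats::pf(f, df1, df2, lower.tail = FALSE),
                    0)
  p_anova[f == 0] <- 1
  tukey_p <- function(c1, c2) {
    m1 <- gm[, c1]; m2 <- gm[, c2]
    n1 <- nn[match(c1, colnames(gm))]; n2 <- nn[match(c2, colnames(gm))]
    se <- sqrt(mse / 2 * (1 / n1 + 1 / n2))
    q <- ifelse(se > 0, abs(m1 - m2) / se, ifelse(m1 == m2, 0, Inf))
    p <- rep(1, length(q))
    ok <- is.finite(q)
    p[ok] <- stats::ptukey(q[ok], nmeans = k, df = df2, lower.tail = FALSE)
    p[!ok & m1 != m2] <- 0
    p
  }
  list(means = gm, p_anova = p_anova, mse = mse, tukey_p = tukey_p)
}

#' Differential-expression gate
#'
#' Four sequential steps: (1) drop genes whose mean normalized count is
#' below `min_expr` in every condition; (2) one-way ANOVA across the four
#' conditions with Benjamini-Hochberg adjustment (`padj < alpha`); (3)
#' Tukey HSD post-hoc per ligand-vs-vehicle contrast (`p < 0.05`); (4) fold
#' change vs vehicle (pseudocount 1) `>= fc_up` for up, `<= fc_down` for
#' down. Labels derive from which single-ligand contrasts pass.
#'
#' @param norm genes x samples normalized count matrix (rownames = genes).
#' @param design an [expression_design()] data.frame.
#' @param fc_up,fc_down fold-change cutoffs (defaults 1.5 and 0.66).
#' @param alpha BH-adjusted ANOVA significance level.
#' @param tukey_alpha post-hoc significance level.
#' @param min_expr low-expression filter threshold.
#' @return data.frame (one row per input gene) with per-contrast fold
#'   changes, test results, `up_A`, `up_D`, `up_combined`, `down_A`,
#'   `down_D`, and `label` in `{none, A-only-up, D-only-up, both-up, down}`.
#' @export
de_gate <- function(norm, design, fc_up = 1.5, fc_down = 0.66, alpha = 0.05,
                    tukey_alpha = 0.05, min_expr = 1.0) {
  if (!all(c("vehicle", "A", "D", "combined") %in% design$condition))
    stop("design must contain vehicle, A, D, and combined conditions")
  norm <- as.matrix(norm)
  expressed <- apply(cond_means(norm, design), 1, max) >= min_expr
  res <- data.frame(gene = rownames(norm), expressed = expressed,
                    padj = NA_real_, p_A = NA_real_, p_D = NA_real_,
                    p_combined = NA_real_, fc_A = NA_real_, fc_D = NA_real_,
                    fc_combined = NA_real_, stringsAsFactors = FALSE)
  sub <- norm[expressed, , drop = FALSE]
  if (nrow(sub)) {
    at <- anova_tukey(sub, design)
    padj <- stats::p.adjust(at$p_anova, method = "BH")
    pc <- 1
    fcs <- sweep(at$means[, c("A", "D", "combined"), drop = FALSE] + pc, 1,
                 at$means[, "vehicle"] + pc, "/")
    res$padj[expressed] <- padj
    res$p_A[expressed] <- at$tukey_p("A", "vehicle")
    res$p_D[expressed] <- at$tukey_p("D", "vehicle")
    res$p_combined[expressed] <- at$tukey_p("combined", "vehicle")
    res$fc_A[expressed] <- fcs[, "A"]
    res$fc_D[expressed] <- fcs[, "D"]
    res$fc_combined[expressed] <- fcs[, "combined"]
  }
  gate <- res$expressed & !is.na(res$padj) & res$padj < alpha
  res$up_A <- gate & res$p_A < tukey_alpha & res$fc_A >= fc_up
  res$up_D <- gate & res$p_D < tukey_alpha & res$fc_D >= fc_up
  res$up_combined <- gate & res$p_combined < tukey_alpha &
    res$fc_combined >= fc_up
  res$down_A <- gate & res$p_A < tukey_alpha & res$fc_A <= fc_down
  res$down_D <- gate & res$p_D < tukey_alpha & res$fc_D <= fc_down
  res$label <- ifelse(res$up_A & res$up_D, "both-up",
               ifelse(res$up_A, "A-only-up",
               ifelse(res$up_D, "D-only-up",
               ifelse(res$down_A | res$down_D, "down", "none"))))
  res[is.na(res$label), "label"] <- "none"
  res
}

#' Cooperative-upregulation caller
#'
#' For every gene upregulated by at least one single ligand: (1) the more
#' effective single ligand is the one with the larger replicate-mean
#' normalized expression; (2) a Welch t-test (one-sided, testing an
#' increase) compares the combined-treatment replicates against that
#' ligand's replicates (`p <= alpha`); (3) the ratio
#' of combined to more-effective-single mean must reach `ratio_cut` (a zero
#' single-ligand mean gives ratio `Inf` but the t-test must still pass);
#' (4) the protein-coding subset is flagged from gene biotypes.
#'
#' @param norm genes x samples normalized count matrix.
#' @param design an [expression_design()] data.frame.
#' @param calls result of [de_gate()] on the same matrix.
#' @param biotypes named character vector of gene biotypes (by gene id).
#' @param ratio_cut cooperativity ratio cutoff (inclusive; default 1.5).
#' @param alpha t-test significance level (default 0.05).
#' @return data.frame per up-regulated gene: `gene`, `more_effective`
#'   (`"A"` or `"D"`), `ratio`, `p`, `cooperative`, `protein_coding`.
#' @export
cooperative_caller <- function(norm, design, calls, biotypes = NULL,
                               ratio_cut = 1.5, alpha = 0.05) {
  norm <- as.matrix(norm)
  up <- calls$up_A | calls$up_D
  genes <- calls$gene[up]
  ia <- design$condition == "A"; id <- design$condition == "D"
  ic <- design$condition == "combined"
  if (sum(ic) < 2 || sum(ia) < 2 || sum(id) < 2)
    stop("need >= 2 replicates per condition for the t-test")
  out <- lapply(genes, function(g) {
    x <- norm[g, ]
    ma <- mean(x[ia]); md <- mean(x[id])
    eff <- if (ma >= md) "A" else "D"
    single <- if (eff == "A") x[ia] else x[id]
    comb <- x[ic]
    ratio <- if (mean(single) == 0) Inf else mean(comb) / mean(single)
    p <- tryCatch(stats::t.test(comb, single,
                                alternative = "greater")$p.value,
                  error = function(e) 1)
    data.frame(gene = g, more_effective = eff, ratio = ratio, p = p,
               cooperative = is.finite(p) && p <= alpha && ratio >= ratio_cut,
               stringsAsFactors = FALSE)
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(), more_effective = character(),
               ratio = numeric(), p = numeric(), cooperative = logical(),
               stringsAsFactors = FALSE)
  res$protein_coding <- if (is.null(biotypes)) NA else
    unname(biotypes[res$gene] == "protein_coding")
  res
}

#' Fold-change table for the four contrasts
#'
#' Replicate-mean fold changes (with pseudocount) for A/vehicle, D/vehicle,
#' combined/vehicle, and combined over the more effective single ligand.
#' @param norm genes x samples normalized counts.
#' @param design an [expression_design()] data.frame.
#' @param pseudocount added to all means before ratios (default 1).
#' @return data.frame with one row per gene.
#' @export
fold_change_table <- function(norm, design, pseudocount = 1) {
  gm <- cond_means(as.matrix(norm), design)
  best <- pmax(gm[, "A"], gm[, "D"])
  data.frame(gene = rownames(norm),
             fc_A = (gm[, "A"] + pseudocount) / (gm[, "vehicle"] + pseudocount),
             fc_D = (gm[, "D"] + pseudocount) / (gm[, "vehicle"] + pseudocount),
             fc_combined = (gm[, "combined"] + pseudocount) /
               (gm[, "vehicle"] + pseudocount),
             fc_combined_vs_best = (gm[, "combined"] + pseudocount) /
               (best + pseudocount),
             stringsAsFactors = FALSE)
}

#' Partition regulated genes into gene sets
#'
#' @param calls result of [de_gate()].
#' @return list of character vectors: `A_only_up`, `both_up`, `D_only_up`
#'   (disjoint; union = all upregulated genes), and `down`.
#' @export
gene_set_partition <- function(calls) {
  list(A_only_up = calls$gene[calls$label == "A-only-up"],
       both_up = calls$gene[calls$label == "both-up"],
       D_only_up = calls$gene[calls$label == "D-only-up"],
       down = calls$gene[calls$down_A | calls$down_D])
}
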