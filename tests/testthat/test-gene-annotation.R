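# Nearest-gene profiles, TSS windows, observed/expected enrichment.

test_that("annotate_closest tabulates closest-gene regulation labels", {
  genes <- gene_model(c("g1", "g2", "g3", "g4"), chrom = "chr1",
                      strand = "+", tss = c(1000, 5000, 9000, 13000))
  labels <- c(g1 = "none", g2 = "none", g3 = "A-only", g4 = "both")
  cl <- list(clu = rs(rep("chr1", 4), c(901, 4901, 8901, 12901),
                      c(1100, 5100, 9100, 13100)))
  tab <- annotate_closest(cl, genes, labels)
  expect_equal(tab["clu", "none"], 0.5)
  expect_equal(tab["clu", "A-only"], 0.25)
  expect_equal(tab["clu", "both"], 0.25)
  expect_equal(sum(tab["clu", ]), 1)
  expect_warning(annotate_closest(list(e = rs("chr1", 1, 2)[0, ]),
                                  genes, labels), "empty")
})

test_that("windows_membership uses region centers and the closed window", {
  genes <- gene_model("g1", chrom = "chr1", strand = "+", tss = 100000)
  regions <- rs(rep("chr1", 3),
                c(100000 + 24999 - 99, 100000 + 25001 - 99, 100000 - 80099),
                c(100000 + 24999 + 100, 100000 + 25001 + 100,
                  100000 - 79900))
  m <- windows_membership(genes, regions)
  centers <- region_center(regions)       # note: region_set sorts by start
  in_idx <- which(centers == 100000 + 24999)
  expect_equal(m$g1, in_idx)              # 24999 in, 25001 and far out

  # a region may belong to two genes' windows
  g2 <- gene_model(c("gA", "gB"), chrom = "chr1", strand = "+",
                   tss = c(100000, 110000))
  m2 <- windows_membership(g2, regions[in_idx, ])
  expect_equal(lengths(m2), c(gA = 1L, gB = 1L))
})

test_that("enrichment computes observed/expected per cluster", {
  # 100 regions, cluster X has 20; a gene set's windows hold 10 regions,
  # 4 from X -> expected 2, ratio 2
  cluster_of <- rep(c("X", "Y"), c(20, 80))
  memberships <- list(setA = list(g1 = c(1:4, 21:26)))
  e <- enrichment(cluster_of, memberships)
  ex <- e[e$cluster == "X", ]
  expect_equal(ex$observed, 4)
  expect_equal(ex$expected, 2)
  expect_equal(ex$ratio, 2)
  # observed sums to the window total; count-weighted mean ratio is 1
  expect_equal(sum(e$observed), 10)
  expect_equal(sum(e$observed) / sum(e$expected), 1)
  w <- e$expected / sum(e$expected)
  expect_equal(sum(w * e$ratio), 1)

  # proportional membership -> all ratios 1
  e2 <- enrichment(cluster_of, list(s = list(g = c(1:2, 21:28))))
  expect_equal(e2$ratio, c(1, 1))
})

test_that("normalized_prevalence divides common members by all members", {
  is_common <- rep(c(TRUE, FALSE), c(4, 6))
  m <- list(set1 = list(g = 1:10), set2 = list(g = 1:4))
  expect_equal(unname(normalized_prevalence(is_common, m)), c(0.4, 1.0))
  # restriction to an empty significant subset gives 0
  expect_equal(unname(normalized_prevalence(is_common, m,
                                            restrict = rep(FALSE, 10))),
               c(0, 0))
  expect_warning(
    out <- normalized_prevalence(is_common, list(empty = list())),
    "zero window")
  expect_true(is.na(out[["empty"]]))
})

test_that("select_gene_sets adds the top-N non-regulated set", {
  study <- default_study()
  norm <- normalize_libsize(study$expr$counts)
  calls <- de_gate(norm, study$expr$design)
  sets <- select_gene_sets(calls, norm, study$expr$design, n_top = 50)
  expect_length(sets$nonreg_high, 50)
  expect_true(all(calls$label[match(sets$nonreg_high, calls$gene)] ==
                    "none"))
  # they really are the highest-expressed non-regulated genes in vehicle
  veh <- rowMeans(norm[, study$expr$design$condition == "vehicle"])
  other_nonreg <- setdiff(calls$gene[calls$label == "none"],
                          sets$nonreg_high)
  expect_gte(min(veh[sets$nonreg_high]), max(veh[other_nonreg]))
})

test_that("planted regulated genes enrich their matching clusters", {
  study <- default_study()
  truth <- study$truth
  sites <- study$chip$site_regions
  genes <- study$expr$genes
  labels <- stats::setNames(truth$genes$label, truth$genes$gene_id)
  clusters <- list(
    a_only = sites[truth$sites$class == "A-only", ],
    common = sites[startsWith(truth$sites$class, "common"), ],
    b_only = sites[truth$sites$class == "B-only", ])
  tab <- annotate_closest(clusters, genes, labels)
  # A-only cluster regions sit closer to A-only genes than B-only ones do
  expect_gt(tab["a_only", "A-only"], tab["b_only", "A-only"])
  expect_gt(tab["b_only", "D-only"], tab["a_only", "D-only"])

  # enrichment of the A-only cluster in A-only up-gene windows
  cluster_of <- ifelse(truth$sites$class == "A-only", "a_only",
                       ifelse(truth$sites$class == "B-only", "b_only",
                              "common"))
  gsets <- split(genes, labels[genes$gene_id])
  mem <- lapply(gsets[c("A-only", "D-only")], windows_membership,
                regions = sites)
  e <- enrichment(cluster_of, mem)
  expect_gt(e$ratio[e$cluster == "a_only" & e$gene_set == "A-only"], 1)
  expect_gt(e$ratio[e$cluster == "b_only" & e$gene_set == "D-only"], 1)
})
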