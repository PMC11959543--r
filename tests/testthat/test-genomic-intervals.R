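# Core interval data model, algebra, and file dialects.

test_that("region_set enforces its invariants", {
  expect_error(region_set("chr1", 100, 100), "strictly greater")
  expect_error(region_set("chr1", 100, 300, summit = 300), "summit")
  x <- region_set(c("chr2", "chr1"), c(5, 10), c(50, 20))
  expect_equal(x$chrom, c("chr1", "chr2"))  # canonical sort
  dup <- region_set(c("chr1", "chr1"), c(5, 5), c(50, 50), sort = FALSE)
  expect_equal(nrow(canonicalize(dup)), 1)
})

test_that("read_regions handles the three dialects", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t300", bed)
  x <- read_regions(bed, "bed")
  expect_equal(unname(as.numeric(x[1, c("start", "end")])), c(100, 300))
  expect_true(is.na(x$summit[1]))

  np <- tempfile(fileext = ".narrowPeak")
  writeLines(c(
    "chr1\t100\t300\tpk1\t100\t.\t5.0\t4.0\t3.0\t50",
    "chr1\t500\t700\tpk2\t100\t.\t5.0\t4.0\t3.0\t-1"), np)
  y <- read_regions(np, "narrowpeak")
  expect_equal(y$summit, c(150, 600))      # offset 50; -1 -> midpoint
  # the documented midpoint rule: [100,300) imputes 200
  np2 <- tempfile()
  writeLines("chr1\t100\t300\tpk\t0\t.\t1\t1\t1\t-1", np2)
  expect_equal(read_regions(np2, "narrowpeak")$summit, 200)
  expect_equal(y$summit_imputed, c(FALSE, TRUE))

  sb <- tempfile(fileext = ".bed")
  writeLines("chr1\t250\t251\ts1\t12", sb)
  z <- read_regions(sb, "summit_bed")
  expect_equal(z$summit, 250)
})

test_that("malformed lines error with the line number", {
  bad <- tempfile()
  writeLines(c("chr1\t1\t10", "chr1\t20"), bad)
  expect_error(read_regions(bad, "bed"), "line 2")
  bad2 <- tempfile()
  writeLines("chr1\t30\t10", bad2)
  expect_error(read_regions(bad2, "bed"), "line 1")
})

test_that("BED round-trip is byte-identical for canonical records", {
  x <- region_set(c("chr1", "chr1", "chr2"), c(10, 500, 3),
                  c(200, 900, 44), name = c("a", "b", "c"),
                  score = c(1, 2, 3))
  f1 <- tempfile(); f2 <- tempfile()
  write_bed(x, f1)
  write_bed(read_regions(f1, "bed"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("filter_assembly removes disallowed chromosomes and blacklist", {
  x <- rs(c("NC_1", "NC_2", "NW_001"), c(100, 100, 100), c(300, 300, 300))
  expect_equal(nrow(filter_assembly(x, "NC")), 2)
  bl <- rs("NC_1", 299, 400)
  out <- filter_assembly(x, "NC", bl)
  expect_equal(out$chrom, "NC_2")          # 1 bp overlap removes NC_1
  expect_equal(nrow(filter_assembly(x, "N", region_set())), 3)
  expect_error(filter_assembly(x, character(0)), "empty")
})

test_that("overlap_partition matches its examples and conserves regions", {
  a <- rs("chr1", 0, 200); b <- rs("chr1", 100, 300)
  p <- overlap_partition(a, b)
  expect_equal(nrow(p$a_overlapping), 1)
  expect_equal(nrow(p$a_only), 0)

  a2 <- rs("chr1", 0, 100); b2 <- rs("chr2", 0, 100)
  p2 <- overlap_partition(a2, b2)
  expect_equal(nrow(p2$a_only), 1)
  expect_equal(nrow(p2$b_only), 1)

  # one a-region spanning two b-regions counts once in a, twice in b
  a3 <- rs("chr1", 0, 500)
  b3 <- rs(c("chr1", "chr1"), c(10, 300), c(50, 400))
  p3 <- overlap_partition(a3, b3)
  expect_equal(nrow(p3$a_overlapping), 1)
  expect_equal(nrow(p3$b_overlapping), 2)
})

test_that("overlap_partition and merge_regions agree with brute force", {
  set.seed(7)
  for (rep in 1:20) {
    a <- rand_regions(sample(3:50, 1))
    b <- rand_regions(sample(3:50, 1))
    p <- overlap_partition(a, b)
    expect_equal(nrow(p$a_only) + nrow(p$a_overlapping), nrow(a))
    bf <- bf_overlaps(a, b)
    expect_setequal(p$a_overlapping$name, a$name[bf])
    expect_setequal(p$b_overlapping$name, b$name[bf_overlaps(b, a)])

    m <- merge_regions(a)
    ref <- bf_merge(a)
    expect_equal(m$start, ref$start)
    expect_equal(m$end, ref$end)
    expect_equal(m$chrom, ref$chrom)
  }
})

test_that("merge_regions collapses chains and is idempotent", {
  x <- rs(c("chr1", "chr1"), c(0, 150), c(200, 350))
  m <- merge_regions(x)
  expect_equal(c(m$start, m$end), c(0, 350))
  chain <- rs(rep("chr1", 3), c(0, 150, 320), c(200, 350, 500),
              name = c("a", "b", "c"))
  m2 <- merge_regions(chain)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$name, "a,b,c")           # provenance of members
  disj <- rs(c("chr1", "chr1"), c(0, 500), c(100, 600))
  expect_equal(nrow(merge_regions(disj)), 2)
  expect_equal(as.data.frame(merge_regions(m2))[c("start", "end")],
               as.data.frame(m2)[c("start", "end")])
})

test_that("nearest_feature follows the distance and tie conventions", {
  g <- gene_model(c("gA", "gB"), chrom = "chr1", strand = c("+", "+"),
                  tss = c(1300, 99000))
  r <- rs("chr1", 901, 1100)               # center = 901 + (199-1)/2 = 1000
  ann <- nearest_feature(r, g)
  expect_equal(ann$gene_id, "gA")
  expect_equal(ann$distance, -300)         # upstream of + strand TSS

  r0 <- rs("chr1", 1201, 1400)             # center 1300, on the TSS
  expect_equal(nearest_feature(r0, g)$distance, 0)

  # minus strand flips the sign
  gm <- gene_model("gC", chrom = "chr1", strand = "-", tss = 1300)
  expect_equal(nearest_feature(r, gm)$distance, 300)

  # equidistant TSSs: lexicographically smaller gene_id wins
  g2 <- gene_model(c("gZ", "gM"), chrom = "chr1", strand = "+",
                   tss = c(900, 1100))
  expect_equal(nearest_feature(rs("chr1", 901, 1100), g2)$gene_id, "gM")

  # chromosome without genes
  ann2 <- nearest_feature(rs("chrX", 0, 100), g)
  expect_equal(ann2$gene_id, "none")
  expect_true(is.na(ann2$distance))
  expect_error(nearest_feature(r, g[0, ]), "empty")
})

test_that("GTF genes round-trip with strand-aware TSS", {
  g <- gene_model(c("g1", "g2"), chrom = "chrS1", strand = c("+", "-"),
                  tss = c(5000, 9000), biotype = c("protein_coding", "lncRNA"))
  f <- tempfile(fileext = ".gtf")
  write_gtf(g, f)
  back <- read_gtf_genes(f)
  expect_equal(back$tss, g$tss)
  expect_equal(back$strand, g$strand)
  expect_equal(back$biotype, g$biotype)
})
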