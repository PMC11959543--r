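# Report bookkeeping and the standardized cistrome-pair / end-to-end
# workflows that tie the stages together.

#' Category fractions of a two-cistrome comparison
#'
#' The bookkeeping used in every pair report: given the exclusive and
#' common region counts, the share of each category in the merged cistrome
#' and the share of the common set within each input cistrome.
#'
#' @param n_a_only,n_common,n_b_only region counts (common = merged common
#'   envelopes; the input-cistrome sizes are `n_a_only + n_common` etc.,
#'   ignoring envelope mergers, unless explicit sizes are given).
#' @param n_a,n_b optional explicit input cistrome sizes.
#' @return named list of percentages: `pct_a_only`, `pct_common`,
#'   `pct_b_only` (of the merged set, summing to 100), `pct_common_of_a`,
#'   `pct_common_of_b`.
#' @export
overlap_fractions <- function(n_a_only, n_common, n_b_only,
                              n_a = n_a_only + n_common,
                              n_b = n_b_only + n_common) {
  tot <- n_a_only + n_common + n_b_only
  list(pct_a_only = 100 * n_a_only / tot,
       pct_common = 100 * n_common / tot,
       pct_b_only = 100 * n_b_only / tot,
       pct_common_of_a = 100 * n_common / n_a,
       pct_common_of_b = 100 * n_common / n_b)
}

#' Dominance-cluster size bookkeeping
#'
#' @param n_a_dominant,n_similar,n_b_dominant cluster sizes.
#' @return list with the three counts, their `total` (which must equal the
#'   common-set size), and percentage shares.
#' @export
dominance_totals <- function(n_a_dominant, n_similar, n_b_dominant) {
  total <- n_a_dominant + n_similar + n_b_dominant
  list(n_a_dominant = n_a_dominant, n_similar = n_similar,
       n_b_dominant = n_b_dominant, total = total,
       pct = 100 * c(a_dominant = n_a_dominant, similar = n_similar,
                     b_dominant = n_b_dominant) / total)
}

#' Percentage of a cluster with a property
#'
#' @param n_with count of regions with the property (e.g. containing both
#'   motif types).
#' @param n_total cluster size.
#' @return percentage `100 * n_with / n_total`.
#' @export
cluster_percentage <- function(n_with, n_total) 100 * n_with / n_total

#' Prevalence ratio between two cistromes
#'
#' @param prevalence_a,prevalence_b motif prevalences (fractions or
#'   percentages, consistently).
#' @return `prevalence_a / prevalence_b`.
#' @export
prevalence_ratio <- function(prevalence_a, prevalence_b)
  prevalence_a / prevalence_b

#' Standardized cistrome-pair analysis
#'
#' The re-analysis workflow applied to any two consensus cistromes:
#' cistrome sizes, symmetric common/exclusive split with overlap
#' fractions, and - when a genome and calibrated PWMs are supplied -
#' per-cistrome motif prevalences and common-set co-occurrence.
#'
#' @param a,b consensus `region_set`s.
#' @param genome optional named character vector of chromosome sequences.
#' @param pwm_a,pwm_b optional calibrated `pwm`s (factor A's and factor
#'   B's motifs).
#' @return list (JSON-serializable) with `sizes`, `counts`, `fractions`,
#'   and optionally `prevalence` and `cooccurrence` (`NA`-flagged when the
#'   common set is empty).
#' @export
run_pair_analysis <- function(a, b, genome = NULL, pwm_a = NULL,
                              pwm_b = NULL) {
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty input cistrome")
  cs <- common_set(a, b)
  counts <- list(a_only = nrow(cs$a_only), common = nrow(cs$common),
                 b_only = nrow(cs$b_only))
  out <- list(sizes = list(a = nrow(a), b = nrow(b)),
              counts = counts,
              fractions = overlap_fractions(counts$a_only, counts$common,
                                            counts$b_only,
                                            n_a = nrow(a), n_b = nrow(b)))
  if (!is.null(genome) && !is.null(pwm_a) && !is.null(pwm_b)) {
    hits_a <- map_motifs(pwm_a, genome)
    hits_b <- map_motifs(pwm_b, genome)
    out$prevalence <- list(
      a_motif_in_a = motif_prevalence(a, hits_a),
      a_motif_in_b = motif_prevalence(b, hits_a),
      b_motif_in_a = motif_prevalence(a, hits_b),
      b_motif_in_b = motif_prevalence(b, hits_b))
    out$cooccurrence <- if (nrow(cs$common) == 0)
      list(flag = "common set empty", fractions = NA) else
      list(fractions = as.list(cooccurrence(cs$common, hits_a,
                                            hits_b)$fractions))
  }
  out
}

#' Run the complete workflow on a synthetic study
#'
#' Simulate -> consensus -> classify -> annotate -> DE/cooperative ->
#' MED1 -> ATAC -> motifs, writing every intermediate plus a manifest of
#' outputs (with parameters, seed, and content hashes) to `out_dir`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param with_genome also simulate sequence and run the motif stage
#'   (slower for large genomes).
#' @return the manifest list, invisibly; files are written under
#'   `out_dir`.
#' @export
end_to_end <- function(cfg = sim_config(), out_dir = tempfile("nrcobind_"),
                       with_genome = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  pwms <- NULL
  seed_pwm <- read_motif(system.file("extdata",
                                     "dr5_halfsite_synthetic.motif",
                                     package = "nrcobind"))
  if (with_genome) {
    dr3 <- derive_spacer_variant(seed_pwm, 3, "direct")
    pwms <- list(DR5 = seed_pwm, DR3 = dr3)
  }
  study <- stage("simulate", simulate_study(cfg, pwms = pwms))
  truth <- study$truth

  # consensus per factor
  cons <- stage("consensus", lapply(c(A = "A", B = "B"), function(f) {
    reps <- lapply(study$chip$summits[[f]], function(s)
      merge_close_summits(extend_summits(s, flank = cfg$flank,
                                         chrom_sizes = truth$chrom_sizes),
                          flank = cfg$flank,
                          chrom_sizes = truth$chrom_sizes))
    consensus_two_reps(reps[[1]], reps[[2]],
                       study$chip$narrow[[f]][[1]],
                       study$chip$narrow[[f]][[2]])
  }))
  write_bed(cons$A, file.path(out_dir, "consensus_A.bed"))
  write_bed(cons$B, file.path(out_dir, "consensus_B.bed"))

  # classification
  cls <- stage("classify", {
    cs <- common_set(cons$A, cons$B)
    idx <- match_sites(cs$common, study$chip$site_regions)
    occ_a <- normalize_occupancy(study$chip$counts$A)
    occ_b <- normalize_occupancy(study$chip$counts$B)
    keep <- !is.na(idx)
    dom <- classify_dominance(
      cs$common[keep, ],
      occ_a$normalized[idx[keep], c("ligand_r1", "ligand_r2")],
      occ_b$normalized[idx[keep], c("ligand_r1", "ligand_r2")])
    list(cs = cs, dom = dom)
  })
  for (nm in names(cls$dom))
    write_bed(cls$dom[[nm]]$regions,
              file.path(out_dir, paste0("cluster_", nm, ".bed")))

  # expression + cooperative genes
  expr <- study$expr
  de <- stage("de", {
    norm <- normalize_libsize(expr$counts)
    calls <- de_gate(norm, expr$design)
    coop <- cooperative_caller(norm, expr$design, calls, expr$biotypes)
    list(calls = calls, coop = coop)
  })
  utils::write.table(de$calls, file.path(out_dir, "de_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(de$coop, file.path(out_dir, "cooperative_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # MED1 cooperative + composition
  med1 <- stage("med1", {
    mc <- med1_cooperative(study$med1_atac$med1_counts,
                           study$med1_atac$med1_design)
    comp <- cooperative_composition(
      list(a_only = cls$cs$a_only, common = cls$cs$common,
           b_only = cls$cs$b_only),
      study$med1_atac$med1_regions[mc$cooperative, ])
    list(calls = mc, composition = comp)
  })
  utils::write.table(med1$composition,
                     file.path(out_dir, "med1_composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # accessibility
  atac <- stage("atac", accessibility_categories(
    cls$cs$common, study$med1_atac$atac_vehicle,
    study$med1_atac$atac_ligand))

  manifest <- list(
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "motif_plan")],
    outputs = lapply(list.files(out_dir, full.names = TRUE), function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))),
    summary = list(
      consensus_sizes = lapply(cons, nrow),
      category_counts = lapply(cls$cs, nrow),
      dominance = lapply(cls$dom, function(d) nrow(d$regions)),
      n_cooperative_genes = sum(de$coop$cooperative),
      n_cooperative_med1 = sum(med1$calls$cooperative),
      common_fraction_open = atac$fraction_open))
  if (with_genome) {
    motifs <- stage("motifs", {
      ctrl <- sample_control_regions(study$genome,
                                     sizes = rep(200, 50), n = 500)
      p5 <- calibrate_threshold(pwms$DR5, ctrl$sequences)
      p3 <- calibrate_threshold(pwms$DR3, ctrl$sequences)
      list(prev_a = motif_prevalence(cons$A, map_motifs(p5, study$genome)),
           prev_b = motif_prevalence(cons$B, map_motifs(p3, study$genome)))
    })
    manifest$summary$motif_prevalence <- motifs
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# map common envelopes back to true-site rows by >= 1 bp overlap (first hit)
match_sites <- function(envelopes, site_regions) {
  idx <- rep(NA_integer_, nrow(envelopes))
  for (chr in unique(envelopes$chrom)) {
    ei <- which(envelopes$chrom == chr)
    si <- which(site_regions$chrom == chr)
    if (!length(si)) next
    ov <- IRanges::findOverlaps(rs_iranges(envelopes[ei, ]),
                                rs_iranges(site_regions[si, ]),
                                select = "first")
    idx[ei] <- si[ov]
  }
  idx
}
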