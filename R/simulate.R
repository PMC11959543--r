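# Synthetic-study generator: a genome with planted motifs, two-factor
# replicate ChIP peak sets with a controlled common/exclusive overlap
# structure and occupancy-ratio classes, negative-binomial expression
# counts with additive and cooperative ligand effects, MED1-like occupancy
# with cooperative regions, and ATAC peak sets whose openness tracks the
# binding category. Every artifact has known ground-truth labels.
#
# Determinism: one RNG substream per artifact, derived from the master seed
# and the artifact name, so adding an artifact never perturbs the others.

substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults encode the emulated study: ~1500 binding regions split
#' 14%/21%/65% into A-only / common / B-only with the common set divided
#' into A-dominant / similarly-occupied / B-dominant in the observed
#' 1343:1571:637 proportions; 2000 genes with up-set sizes scaled from
#' 537/91/158; four conditions x three replicates.
#'
#' @param seed master seed (integer).
#' @param n_chroms,chrom_length synthetic chromosome count and length (bp).
#' @param gc_content genome GC fraction, in (0,1).
#' @param n_a_only,n_common,n_b_only binding-site counts per category.
#' @param dominance_props proportions of the common set that are
#'   A-dominant / similarly-occupied / B-dominant.
#' @param ratio_class_means true A:B normalized-occupancy ratio per
#'   dominance class.
#' @param ratio_jitter_sd lognormal sd of per-region ratio around its class
#'   mean (0 = exact class ratios).
#' @param occupancy_base mean ligand-condition count at a bound site.
#' @param background_occupancy mean count for the unbound factor at an
#'   exclusive site.
#' @param ligand_effect multiplicative ligand-vs-vehicle occupancy effect.
#' @param chip_dispersion,med1_dispersion,atac_dispersion NB dispersions
#'   (variance = mu + dispersion * mu^2) for count artifacts.
#' @param summit_jitter_sd Gaussian sd (bp) of replicate summit positions.
#' @param n_noise_peaks single-replicate noise peaks per factor and
#'   replicate.
#' @param n_narrow_fallback true sites per factor whose replicate-2 support
#'   is a narrow peak without a summit (exercises the consensus fallback).
#' @param flank summit half-width (binding regions are `2 * flank` bp).
#' @param n_genes,n_up_a,n_up_both,n_up_d,n_down expression design sizes.
#' @param n_coop_both,n_coop_a,n_coop_d cooperative genes drawn from the
#'   both-up / A-only-up / D-only-up sets.
#' @param expr_base_meanlog,expr_base_sdlog lognormal baseline expression.
#' @param expr_fc_up,expr_fc_down single-ligand fold effects.
#' @param coop_multiplier combined mean = multiplier x max(single means)
#'   for cooperative genes (> 1.5).
#' @param expr_dispersion RNA-seq NB dispersion.
#' @param frac_protein_coding fraction of protein-coding biotypes.
#' @param med1_base,med1_fc_responsive,med1_coop_fc MED1 signal parameters.
#' @param p_med1_coop_common,p_med1_coop_exclusive probability that a
#'   common / exclusive site has cooperative MED1 recruitment.
#' @param atac_open_common,atac_open_exclusive probability a site is open.
#' @param atac_mean_common,atac_mean_exclusive mean ATAC signal when open.
#' @param motif_plan named integer vector: planted motif count per PWM id
#'   (resolved against PWMs passed to [simulate_genome()]).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 4L, chrom_length = 5e6, gc_content = 0.41,
                       n_a_only = 210L, n_common = 315L, n_b_only = 975L,
                       dominance_props = c(a_dominant = 1343, similar = 1571,
                                           b_dominant = 637) / 3551,
                       ratio_class_means = c(a_dominant = 2.5, similar = 1,
                                             b_dominant = 0.4),
                       ratio_jitter_sd = 0.1,
                       occupancy_base = 50, background_occupancy = 2,
                       ligand_effect = 3,
                       chip_dispersion = 0.05, med1_dispersion = 0.05,
                       atac_dispersion = 0.05,
                       summit_jitter_sd = 10, n_noise_peaks = 150L,
                       n_narrow_fallback = 20L, flank = 100L,
                       n_genes = 2000L, n_up_a = 150L, n_up_both = 30L,
                       n_up_d = 50L, n_down = 80L,
                       n_coop_both = 25L, n_coop_a = 9L, n_coop_d = 6L,
                       expr_base_meanlog = log(100), expr_base_sdlog = 0.8,
                       expr_fc_up = 3, expr_fc_down = 0.4,
                       coop_multiplier = 2.0, expr_dispersion = 0.01,
                       frac_protein_coding = 0.85,
                       med1_base = 50, med1_fc_responsive = 2.5,
                       med1_coop_fc = 1.8,
                       p_med1_coop_common = 0.3,
                       p_med1_coop_exclusive = 0.05,
                       atac_open_common = 0.85, atac_open_exclusive = 0.5,
                       atac_mean_common = 30, atac_mean_exclusive = 15,
                       motif_plan = c(DR3 = 40, DR5 = 40)) {
  cfg <- as.list(environment())
  stopifnot(cfg$gc_content > 0, cfg$gc_content < 1,
            cfg$coop_multiplier > 1,
            all(unlist(cfg[grep("^n_", names(cfg))]) >= 0))
  class(cfg) <- "sim_config"
  cfg
}

rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

chrom_names <- function(cfg) sprintf("chrS%d", seq_len(cfg$n_chroms))

#' Simulate ground-truth binding sites and gene labels
#'
#' Places non-overlapping binding sites on the synthetic chromosomes,
#' assigns each a category and dominance class with a true A:B occupancy
#' ratio, assigns gene regulation labels and cooperative flags, places
#' regulated genes' TSSs within +/-20 kb of category-matched sites, and
#' assigns per-site MED1 behavior and ATAC openness.
#'
#' @param cfg a [sim_config()].
#' @return list of class `ground_truth` with `sites` (data.frame: chrom,
#'   start, end, center, site_id, class, ratio, med1, atac_open), `genes`
#'   (data.frame: gene_id, label, cooperative, biotype, chrom, strand,
#'   tss), and `chrom_sizes`.
#' @export
simulate_truth <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "truth"))
  n_sites <- cfg$n_a_only + cfg$n_common + cfg$n_b_only
  chroms <- chrom_names(cfg)
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)
  # slot placement guarantees non-overlap and wide spacing
  total <- cfg$n_chroms * cfg$chrom_length
  slot <- floor(total / n_sites)
  margin <- 1000
  if (slot < 2 * margin + 2 * cfg$flank)
    stop("site demand exceeds genome capacity")
  idx <- sample(seq_len(n_sites))  # shuffle class assignment over slots
  pos_global <- (seq_len(n_sites) - 1) * slot + margin +
    floor(stats::runif(n_sites) * (slot - 2 * margin))
  chrom_of <- chroms[pmin(cfg$n_chroms,
                          1 + pos_global %/% cfg$chrom_length)]
  center <- pos_global %% cfg$chrom_length
  # keep regions inside chromosomes
  center <- pmin(pmax(center, cfg$flank + 1), cfg$chrom_length - cfg$flank - 1)
  n_dom <- round(cfg$n_common * cfg$dominance_props / sum(cfg$dominance_props))
  n_dom[1] <- cfg$n_common - sum(n_dom[-1])
  class <- c(rep("A-only", cfg$n_a_only),
             rep(c("common-A-dominant", "common-similar", "common-B-dominant"),
                 times = n_dom),
             rep("B-only", cfg$n_b_only))[order(idx)]
  ratio_mean <- c(`A-only` = NA, `common-A-dominant` =
                    unname(cfg$ratio_class_means["a_dominant"]),
                  `common-similar` = unname(cfg$ratio_class_means["similar"]),
                  `common-B-dominant` =
                    unname(cfg$ratio_class_means["b_dominant"]),
                  `B-only` = NA)[class]
  ratio <- ratio_mean * exp(stats::rnorm(n_sites, 0, cfg$ratio_jitter_sd))
  # clamp jittered ratios inside their class interval so truth stays truth
  ratio[class == "common-A-dominant"] <-
    pmax(ratio[class == "common-A-dominant"], 1.6)
  ratio[class == "common-similar"] <-
    pmin(pmax(ratio[class == "common-similar"], 0.7), 1.45)
  ratio[class == "common-B-dominant"] <-
    pmin(ratio[class == "common-B-dominant"], 0.62)
  is_common <- startsWith(class, "common")
  med1 <- ifelse(stats::runif(n_sites) <
                   ifelse(is_common, cfg$p_med1_coop_common,
                          cfg$p_med1_coop_exclusive),
                 "cooperative",
                 sample(c("unresponsive", "A-responsive", "D-responsive"),
                        n_sites, replace = TRUE, prob = c(0.6, 0.25, 0.15)))
  atac_open <- stats::runif(n_sites) <
    ifelse(is_common, cfg$atac_open_common, cfg$atac_open_exclusive)
  sites <- data.frame(chrom = chrom_of, start = center - cfg$flank,
                      end = center + cfg$flank, center = center,
                      site_id = sprintf("site_%04d", seq_len(n_sites)),
                      class = class, ratio = ratio, med1 = med1,
                      atac_open = atac_open, stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$start), ]
  rownames(sites) <- NULL

  # gene labels; cooperative genes come from designated up-sets
  lab <- rep("none", cfg$n_genes)
  stopifnot(cfg$n_up_a + cfg$n_up_both + cfg$n_up_d + cfg$n_down <=
              cfg$n_genes)
  lab[seq_len(cfg$n_up_a)] <- "A-only"
  lab[cfg$n_up_a + seq_len(cfg$n_up_both)] <- "both"
  lab[cfg$n_up_a + cfg$n_up_both + seq_len(cfg$n_up_d)] <- "D-only"
  lab[cfg$n_up_a + cfg$n_up_both + cfg$n_up_d + seq_len(cfg$n_down)] <- "down"
  coop <- rep(FALSE, cfg$n_genes)
  coop[sample(which(lab == "both"), min(cfg$n_coop_both, sum(lab == "both")))] <-
    TRUE
  coop[sample(which(lab == "A-only"), min(cfg$n_coop_a, sum(lab == "A-only")))] <-
    TRUE
  coop[sample(which(lab == "D-only"), min(cfg$n_coop_d, sum(lab == "D-only")))] <-
    TRUE
  biotype <- ifelse(stats::runif(cfg$n_genes) < cfg$frac_protein_coding,
                    "protein_coding", "lncRNA")
  # place regulated genes near category-matched sites, others at random
  site_pool <- function(classes) which(sites$class %in% classes)
  pools <- list(`A-only` = site_pool(c("A-only", "common-A-dominant")),
                `both` = site_pool(c("common-similar", "common-A-dominant",
                                     "common-B-dominant")),
                `D-only` = site_pool(c("B-only", "common-B-dominant")),
                `down` = seq_len(nrow(sites)),
                `none` = seq_len(nrow(sites)))
  chrom_g <- character(cfg$n_genes); tss <- numeric(cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    if (lab[i] %in% c("A-only", "both", "D-only")) {
      s <- sample(pools[[lab[i]]], 1)
      chrom_g[i] <- sites$chrom[s]
      tss[i] <- sites$center[s] + round(stats::runif(1, -20000, 20000))
    } else {
      chrom_g[i] <- sample(chroms, 1)
      tss[i] <- sample.int(cfg$chrom_length - 2000, 1) + 1000
    }
  }
  tss <- pmin(pmax(tss, 100), cfg$chrom_length - 100)
  genes <- data.frame(gene_id = sprintf("gene_%04d", seq_len(cfg$n_genes)),
                      label = lab, cooperative = coop, biotype = biotype,
                      chrom = chrom_g,
                      strand = sample(c("+", "-"), cfg$n_genes, TRUE),
                      tss = tss, stringsAsFactors = FALSE)
  structure(list(sites = sites, genes = genes, chrom_sizes = chrom_sizes),
            class = "ground_truth")
}

#' Simulate a genome with planted motifs
#'
#' I.i.d. bases at the configured GC content; motif instances are sampled
#' per column from their PWMs and written over the background at
#' non-overlapping uniform positions. Deterministic given the seed.
#'
#' @param cfg a [sim_config()].
#' @param pwms named list of `pwm` objects referenced by `cfg$motif_plan`
#'   (ids absent from the plan are ignored); may be empty.
#' @return list with `genome` (named character vector) and `planted`
#'   (a `region_set` of planted motif coordinates named by PWM id).
#' @export
simulate_genome <- function(cfg, pwms = list()) {
  set.seed(substream_seed(cfg$seed, "genome"))
  gc <- cfg$gc_content
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)  # A C G T
  raw_codes <- c(65L, 67L, 71L, 84L)
  genome <- stats::setNames(vapply(seq_len(cfg$n_chroms), function(i) {
    codes <- sample.int(4L, cfg$chrom_length, replace = TRUE, prob = probs)
    rawToChar(as.raw(raw_codes[codes]))
  }, character(1)), chrom_names(cfg))
  plan <- cfg$motif_plan
  plan <- plan[plan > 0]
  planted <- region_set()
  if (length(plan)) {
    missing <- setdiff(names(plan), names(pwms))
    if (length(missing))
      stop("motif plan references unknown PWM(s): ",
           paste(missing, collapse = ", "))
    total_demand <- sum(plan * vapply(pwms[names(plan)], pwm_length,
                                      numeric(1))) * 20
    if (total_demand > cfg$n_chroms * cfg$chrom_length)
      stop("motif demand exceeds genome capacity")
    occupied <- list()
    rows <- list()
    for (id in names(plan)) {
      p <- pwms[[id]]
      w <- pwm_length(p)
      placed <- 0L; guard <- 0L
      while (placed < plan[[id]]) {
        guard <- guard + 1L
        if (guard > 1000L * plan[[id]]) stop("could not place motifs")
        chr <- sample(names(genome), 1)
        st <- sample.int(cfg$chrom_length - w, 1)  # 1-based
        key <- occupied[[chr]]
        if (!is.null(key) && any(st < key[, 2] + w & st + w > key[, 1]))
          next
        occupied[[chr]] <- rbind(key, c(st, st + w))
        inst <- paste(apply(p$mat, 2, function(col)
          sample(BASES, 1, prob = col)), collapse = "")
        substr(genome[[chr]], st, st + w - 1) <- inst
        placed <- placed + 1L
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chr, start = st - 1, end = st - 1 + w, name = id,
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    planted <- region_set(df$chrom, df$start, df$end, name = df$name)
  }
  list(genome = genome, planted = planted)
}

#' Simulate replicate ChIP-seq peak sets and occupancy counts
#'
#' True sites emit a summit in both replicates (Gaussian jitter around the
#' site center); noise peaks appear in exactly one replicate; a small
#' designated subset of true sites lacks a replicate-2 summit but carries a
#' replicate-2 narrow peak (the consensus fallback case). Per-site counts
#' are negative binomial with means encoding the class A:B ratio, and the
#' ligand-vs-vehicle effect is multiplicative.
#'
#' @param cfg a [sim_config()].
#' @param truth a [simulate_truth()] result.
#' @param noiseless if `TRUE`, summits have no jitter and counts equal
#'   their means exactly (for exact-recovery checks).
#' @return list with per-factor replicate summit sets (`summits$A` etc.,
#'   1-bp `region_set`s), narrow-peak sets (`narrow`), per-site count
#'   matrices over `site_regions` (columns vehicle_r1, vehicle_r2,
#'   ligand_r1, ligand_r2), the `site_regions` `region_set`, and
#'   bookkeeping of noise peak ids (`noise_names`).
#' @export
simulate_chipseq <- function(cfg, truth, noiseless = FALSE) {
  set.seed(substream_seed(cfg$seed, "chipseq"))
  sites <- truth$sites
  n <- nrow(sites)
  jitter_sd <- if (noiseless) 0 else cfg$summit_jitter_sd
  bound <- list(A = sites$class %in% c("A-only", "common-A-dominant",
                                       "common-similar", "common-B-dominant"),
                B = sites$class %in% c("B-only", "common-A-dominant",
                                       "common-similar", "common-B-dominant"))
  # per-factor means on the A:B ratio scale (geometric split of the ratio)
  r <- ifelse(is.na(sites$ratio), 1, sites$ratio)
  mean_A <- ifelse(bound$A, cfg$occupancy_base * sqrt(r),
                   cfg$background_occupancy)
  mean_B <- ifelse(bound$B, cfg$occupancy_base / sqrt(r),
                   cfg$background_occupancy)
  mk_counts <- function(mu) {
    veh <- mu / cfg$ligand_effect
    m <- cbind(vehicle_r1 = veh, vehicle_r2 = veh,
               ligand_r1 = mu, ligand_r2 = mu)
    if (!noiseless)
      m[] <- rnb(length(m), as.numeric(m), cfg$chip_dispersion)
    rownames(m) <- sites$site_id
    m
  }
  counts <- list(A = mk_counts(mean_A), B = mk_counts(mean_B))
  site_regions <- region_set(sites$chrom, sites$start, sites$end,
                             name = sites$site_id,
                             summit = sites$center, sort = FALSE)
  fallback <- list(A = sample(which(bound$A), min(cfg$n_narrow_fallback,
                                                  sum(bound$A))),
                   B = sample(which(bound$B), min(cfg$n_narrow_fallback,
                                                  sum(bound$B))))
  mk_rep <- function(fac, rep_i) {
    sel <- which(bound[[fac]])
    if (rep_i == 2) sel <- setdiff(sel, fallback[[fac]])
    s <- round(sites$center[sel] + stats::rnorm(length(sel), 0, jitter_sd))
    s <- pmin(pmax(s, 1), truth$chrom_sizes[sites$chrom[sel]] - 2)
    noise_n <- if (noiseless) 0L else cfg$n_noise_peaks
    noise_chr <- character(0); noise_pos <- numeric(0)
    if (noise_n > 0) {
      noise_chr <- sample(names(truth$chrom_sizes), noise_n, replace = TRUE)
      noise_pos <- vapply(noise_chr, function(ch)
        sample.int(truth$chrom_sizes[[ch]] - 400L, 1) + 200, numeric(1))
    }
    nm <- c(sites$site_id[sel],
            sprintf("noise_%s_rep%d_%03d", fac, rep_i,
                    seq_len(noise_n)))
    region_set(c(sites$chrom[sel], noise_chr), c(s, noise_pos),
               c(s, noise_pos) + 1, name = nm,
               summit = c(s, noise_pos))
  }
  mk_narrow <- function(fac, rep_i) {
    sel <- which(bound[[fac]])  # narrow peaks cover all bound sites
    region_set(sites$chrom[sel], pmax(0, sites$center[sel] - 150),
               sites$center[sel] + 150, name = sites$site_id[sel])
  }
  summits <- list(A = list(mk_rep("A", 1), mk_rep("A", 2)),
                  B = list(mk_rep("B", 1), mk_rep("B", 2)))
  narrow <- list(A = list(mk_narrow("A", 1), mk_narrow("A", 2)),
                 B = list(mk_narrow("B", 1), mk_narrow("B", 2)))
  noise_names <- lapply(summits, function(reps)
    lapply(reps, function(rs) rs$name[startsWith(rs$name, "noise_")]))
  list(summits = summits, narrow = narrow, counts = counts,
       site_regions = site_regions, noise_names = noise_names)
}

#' Simulate the four-condition expression experiment
#'
#' Negative-binomial counts for `n_genes` x 12 samples. Non-regulated
#' genes have equal means in all conditions; up-regulated genes get the
#' single-ligand fold effect in their ligand(s) with the combined mean
#' equal to the larger single-ligand mean (additive-saturation model)
#' unless the gene is cooperative, in which case the combined mean is
#' `coop_multiplier x max(single means)`.
#'
#' @param cfg a [sim_config()].
#' @param truth a [simulate_truth()] result.
#' @return list with `counts` (genes x 12), `design`
#'   ([expression_design()]), `genes` (a `gene_model`), `biotypes` (named
#'   vector), and `true_means` (genes x 4 condition means).
#' @export
simulate_expression <- function(cfg, truth) {
  set.seed(substream_seed(cfg$seed, "expression"))
  g <- truth$genes
  base <- stats::rlnorm(nrow(g), cfg$expr_base_meanlog, cfg$expr_base_sdlog)
  fa <- ifelse(g$label %in% c("A-only", "both"), cfg$expr_fc_up, 1)
  fd <- ifelse(g$label %in% c("D-only", "both"), cfg$expr_fc_up, 1)
  down_lig <- ifelse(g$label == "down",
                     sample(c("A", "D"), nrow(g), replace = TRUE), "")
  fa[down_lig == "A"] <- cfg$expr_fc_down
  fd[down_lig == "D"] <- cfg$expr_fc_down
  m_veh <- base
  m_a <- base * fa
  m_d <- base * fd
  m_comb <- pmax(m_a, m_d)
  m_comb[g$label == "down"] <- pmin(m_a, m_d)[g$label == "down"]
  m_comb[g$cooperative] <- cfg$coop_multiplier *
    pmax(m_a, m_d)[g$cooperative]
  mu <- cbind(m_veh, m_veh, m_veh, m_a, m_a, m_a, m_d, m_d, m_d,
              m_comb, m_comb, m_comb)
  counts <- matrix(rnb(length(mu), as.numeric(mu), cfg$expr_dispersion),
                   nrow = nrow(g),
                   dimnames = list(g$gene_id,
                                   paste0(rep(c("vehicle", "A", "D",
                                                "combined"), each = 3),
                                          "_r", rep(1:3, 4))))
  list(counts = counts, design = expression_design(),
       genes = gene_model(g$gene_id, g$gene_id, g$chrom, g$strand, g$tss,
                          g$biotype),
       biotypes = stats::setNames(g$biotype, g$gene_id),
       true_means = cbind(vehicle = m_veh, A = m_a, D = m_d,
                          combined = m_comb))
}

#' Simulate MED1 occupancy and ATAC accessibility
#'
#' MED1: per-site means over vehicle / A / D / combined follow the site's
#' true MED1 behavior; cooperative sites have combined mean
#' `med1_coop_fc x max(single means)`. ATAC: open sites draw peaks (in
#' both replicates) and higher signal for common than exclusive sites.
#'
#' @param cfg a [sim_config()].
#' @param truth a [simulate_truth()] result.
#' @param noiseless exact means instead of NB draws.
#' @return list with `med1_counts` (sites x 12), `med1_design`,
#'   `med1_regions`, `atac_vehicle`, `atac_ligand` (peak `region_set`s),
#'   and `atac_signal` (per-site vehicle-condition mean signal).
#' @export
simulate_med1_atac <- function(cfg, truth, noiseless = FALSE) {
  set.seed(substream_seed(cfg$seed, "med1_atac"))
  sites <- truth$sites
  n <- nrow(sites)
  base <- cfg$med1_base
  m_veh <- rep(base, n)
  m_a <- ifelse(sites$med1 %in% c("A-responsive", "cooperative"),
                base * cfg$med1_fc_responsive, base)
  m_d <- ifelse(sites$med1 %in% c("D-responsive", "cooperative"),
                base * cfg$med1_fc_responsive, base)
  m_comb <- pmax(m_a, m_d)
  m_comb[sites$med1 == "cooperative"] <-
    cfg$med1_coop_fc * pmax(m_a, m_d)[sites$med1 == "cooperative"]
  mu <- cbind(m_veh, m_veh, m_veh, m_a, m_a, m_a, m_d, m_d, m_d,
              m_comb, m_comb, m_comb)
  med1 <- if (noiseless) mu else
    matrix(rnb(length(mu), as.numeric(mu), cfg$med1_dispersion), nrow = n)
  dimnames(med1) <- list(sites$site_id,
                         paste0(rep(c("vehicle", "A", "D", "combined"),
                                    each = 3), "_r", rep(1:3, 4)))
  med1_regions <- region_set(sites$chrom, sites$start, sites$end,
                             name = sites$site_id, sort = FALSE)
  is_common <- startsWith(sites$class, "common")
  atac_mu <- ifelse(is_common, cfg$atac_mean_common,
                    cfg$atac_mean_exclusive)
  open <- sites$atac_open
  atac_sig <- ifelse(open,
                     if (noiseless) atac_mu else
                       rnb(n, atac_mu, cfg$atac_dispersion),
                     if (noiseless) rep(1, n) else
                       rnb(n, 1, cfg$atac_dispersion))
  mk_atac <- function(which_open) {
    sel <- which(which_open)
    region_set(sites$chrom[sel], pmax(0, sites$center[sel] - 200),
               sites$center[sel] + 200, name = sites$site_id[sel])
  }
  # ligand condition opens a few extra sites; vehicle = baseline openness
  extra <- !open & stats::runif(n) < 0.05
  list(med1_counts = med1, med1_design = expression_design(),
       med1_regions = med1_regions,
       atac_vehicle = mk_atac(open),
       atac_ligand = mk_atac(open | extra),
       atac_signal = stats::setNames(as.numeric(atac_sig), sites$site_id))
}

#' Simulate the complete synthetic study
#'
#' @param cfg a [sim_config()].
#' @param pwms optional named PWM list for genome motif planting; when
#'   `NULL`, no genome sequence is generated (coordinate-only study).
#' @param noiseless exact-mean, jitter-free variant.
#' @return list with `cfg`, `truth`, `chip`, `expr`, `med1_atac`, and
#'   (when `pwms` is given) `genome` and `planted`.
#' @export
simulate_study <- function(cfg = sim_config(), pwms = NULL,
                           noiseless = FALSE) {
  truth <- simulate_truth(cfg)
  out <- list(cfg = cfg, truth = truth,
              chip = simulate_chipseq(cfg, truth, noiseless = noiseless),
              expr = simulate_expression(cfg, truth),
              med1_atac = simulate_med1_atac(cfg, truth,
                                             noiseless = noiseless))
  if (!is.null(pwms)) {
    gen <- simulate_genome(cfg, pwms)
    out$genome <- gen$genome
    out$planted <- gen$planted
  }
  out
}
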