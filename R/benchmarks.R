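## Standard synthetic benchmark scenarios with recoverable ground truth.
## These fix the "stated world" used by the calibration checks: exchangeable
## Balding-Nichols populations for the scan, and looped pedigrees with
## gene-dropped genomes for the inbreeding recovery checks.

#' Exchangeable-population panel for scan calibration
#'
#' Builds a map whose every 1-Mb window holds exactly `snps_per_window`
#' SNPs, so that after the >= 4-SNP filter the scan retains exactly
#' `n_chrom * windows_per_chrom` windows per group, and simulates
#' `n_groups` exchangeable populations at the same divergence. With
#' continuous d_i means the 99th-percentile rule then flags exactly 1% of
#' windows per group.
#'
#' @param n_groups exchangeable populations (default 8).
#' @param n_chrom chromosomes (default 25).
#' @param windows_per_chrom 1-Mb windows per chromosome (default 100).
#' @param snps_per_window SNPs per window (default 5).
#' @param n_per_group individuals per population (default 30).
#' @param divergence_F shared Balding-Nichols divergence (default 0.05).
#' @param seed integer seed.
#' @return As [simulate_panel()], plus `n_windows` (the retained-window
#'   count the map implies).
#' @export
calibration_scan_panel <- function(n_groups = 8, n_chrom = 25,
                                   windows_per_chrom = 100,
                                   snps_per_window = 5, n_per_group = 30,
                                   divergence_F = 0.05, seed) {
  offs <- round(seq(0.1, 0.9, length.out = snps_per_window) * 1e6)
  pos <- as.vector(outer(offs, (seq_len(windows_per_chrom) - 1) * 1e6, "+"))
  m <- windows_per_chrom * snps_per_window
  map <- snp_map(paste0("c", rep(seq_len(n_chrom), each = m), "_",
                        rep(seq_len(m), n_chrom)),
                 rep(seq_len(n_chrom), each = m), rep(pos, n_chrom))
  out <- simulate_panel(map,
                        data.frame(label = paste0("G", seq_len(n_groups)),
                                   divergence_F = divergence_F,
                                   n = n_per_group),
                        seed = seed)
  out$n_windows <- n_chrom * windows_per_chrom
  out
}

#' Plant a selective frequency shift in one window
#'
#' Displaces one population's allele frequencies at every SNP of one 1-Mb
#' window by `shift` away from the ancestral frequency (replacing that
#' population's drift there) and redraws its genotypes at those SNPs.
#' Emulates strong recent directional selection private to one population.
#'
#' @param panel output of [calibration_scan_panel()].
#' @param population label of the shifted population.
#' @param chrom,window target window (window index is 0-based, as in
#'   [window_scan()]).
#' @param shift frequency displacement (default 0.3).
#' @return The panel with modified genotypes; `$planted` records the target.
#' @export
plant_frequency_shift <- function(panel, population, chrom, window,
                                  shift = 0.3) {
  map <- panel$geno$map
  target <- which(map$chrom == chrom & map$pos_bp > window * 1e6 &
                    map$pos_bp <= (window + 1) * 1e6)
  a <- panel$truth$ancestral[target]
  f2 <- ifelse(a < 0.5, a + shift, a - shift)
  rows <- which(panel$pops == population)
  panel$geno$calls[rows, target] <-
    matrix(rbinom(length(rows) * length(target), 2,
                  rep(f2, each = length(rows))),
           length(rows))
  panel$planted <- list(population = population, chrom = chrom,
                        window = window, shift = shift, snps = target)
  panel
}

#' Looped-pedigree cohort with gene-dropped genomes
#'
#' A mixed cohort spanning the inbreeding range of a managed livestock
#' population: outbred matings (F = 0), half-sib loops (F = 0.125),
#' full-sib loops (F = 0.25) and two-generation full-sib loops
#' (F = 0.375), gene-dropped over an evenly spaced map so every
#' individual's true autozygous tracts are known.
#'
#' @param n_outbred,n_half_sib,n_full_sib,n_deep study-generation
#'   individuals per mating class (defaults 74/50/50/26: a 200-animal
#'   cohort).
#' @param n_chrom,snps_per_chrom,spacing_bp map geometry (defaults:
#'   10 chromosomes x 1100 SNPs at 90 kb, a 50k-density genome scaled to
#'   one third).
#' @param seed integer seed.
#' @return A list: `geno` (study individuals only), `pedigree`, `truth`
#'   (tracts, per-SNP autozygous fraction and F_PED for the study set).
#' @export
inbreeding_cohort <- function(n_outbred = 74, n_half_sib = 50,
                              n_full_sib = 50, n_deep = 26,
                              n_chrom = 10, snps_per_chrom = 1100,
                              spacing_bp = 90000, seed) {
  set.seed(seed)
  ped <- rbind(
    sim_pedigree(n_outbred, 1, "random", seed = seed + 1, prefix = "R"),
    sim_pedigree(n_full_sib, 2, "full_sib_loop", seed = seed + 2,
                 prefix = "FS"),
    sim_pedigree(3 * n_half_sib / 2, 2, "half_sib_loop", seed = seed + 3,
                 prefix = "HS"),
    sim_pedigree(n_deep, 3, "full_sib_loop", seed = seed + 4,
                 prefix = "FD"))
  study <- c(grep("^R_G1_", ped$id, value = TRUE),
             grep("^FS_G2_", ped$id, value = TRUE),
             grep("^HS_G2_", ped$id, value = TRUE),
             grep("^FD_G3_", ped$id, value = TRUE))
  map <- sim_map(n_chrom, snps_per_chrom, spacing_bp)
  gd <- gene_drop(ped, map, runif(nrow(map), 0.1, 0.9), seed = seed + 5)
  list(geno = subset_geno(gd$geno, ind = study),
       pedigree = ped,
       truth = list(
         tracts = gd$truth$tracts[gd$truth$tracts$id %in% study, ],
         autozygous_fraction = gd$truth$autozygous_fraction[study],
         f_ped = gd$truth$f_ped[study]))
}
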