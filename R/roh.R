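## Runs-of-homozygosity detection (exact maximal-run search, not a sliding
## window heuristic) and the genomic inbreeding coefficients built on it.

#' ROH detection parameters
#'
#' Defaults reproduce a 50k-density cattle analysis: at least 50 SNPs and
#' 1 Mb per run, density at least 1 SNP per 100 kb, no gap above 1800 kb,
#' no heterozygote and at most two missing genotypes per run.
#'
#' @param min_snps minimum SNPs in a run (default 50).
#' @param min_length_kb minimum span in kb (default 1000).
#' @param min_density_kb_per_snp maximum kb per SNP across the run
#'   (default 100).
#' @param max_gap_kb maximum gap between adjacent SNPs in kb (default 1800).
#' @param max_missing maximum missing genotypes in a run (default 2).
#' @param max_het maximum heterozygous genotypes in a run (default 0).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_snps = 50, min_length_kb = 1000,
                       min_density_kb_per_snp = 100, max_gap_kb = 1800,
                       max_missing = 2, max_het = 0) {
  stopifnot(min_snps >= 1, min_length_kb > 0, min_density_kb_per_snp > 0,
            max_gap_kb > 0, max_missing >= 0, max_het >= 0)
  structure(list(min_snps = min_snps, min_length_kb = min_length_kb,
                 min_density_kb_per_snp = min_density_kb_per_snp,
                 max_gap_kb = max_gap_kb, max_missing = max_missing,
                 max_het = max_het), class = "roh_params")
}

#' Minimum run length by the false-positive bound
#'
#' Smallest number of consecutive homozygous SNPs `l` such that the expected
#' number of chance runs across the whole dataset stays below `alpha`:
#' `l = ceil( ln(alpha / (n_snps * n_individuals)) / ln(1 - mean_het) )`.
#'
#' @param n_snps SNPs in the panel.
#' @param n_individuals individuals scanned.
#' @param mean_het mean observed heterozygosity, strictly in (0, 1).
#' @param alpha familywise false-positive bound (default 0.05).
#' @return Integer minimum run length.
#' @export
lencz_min_snps <- function(n_snps, n_individuals, mean_het, alpha = 0.05) {
  if (mean_het <= 0 || mean_het >= 1) stop("mean_het must be in (0, 1)")
  as.integer(ceiling(log(alpha / (n_snps * n_individuals)) /
                       log(1 - mean_het)))
}

#' Detect runs of homozygosity on one chromosome of one individual
#'
#' Reports all maximal runs of consecutive SNPs that satisfy every
#' constraint in `params` simultaneously: heterozygote and missing counts
#' within bounds, every adjacent gap at most `max_gap_kb`, at least
#' `min_snps` SNPs spanning at least `min_length_kb`, and overall density of
#' at most `min_density_kb_per_snp` kb per SNP. Maximal means no reported
#' run is a proper sub-run of another qualifying run; overlapping qualifying
#' runs separated by a disqualifying SNP are reported separately.
#'
#' @param calls genotype vector (0/1/2, `NA` missing) for one chromosome.
#' @param positions strictly increasing base-pair positions.
#' @param params a [roh_params()].
#' @return data.frame(start_idx, end_idx, start_bp, end_bp, n_snps,
#'   length_kb); zero rows when no run qualifies.
#' @export
detect_roh <- function(calls, positions, params = roh_params()) {
  n <- length(calls)
  stopifnot(length(positions) == n)
  if (n > 1 && any(diff(positions) <= 0)) stop("positions must be sorted")
  empty <- data.frame(start_idx = integer(0), end_idx = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), length_kb = numeric(0))
  if (n < params$min_snps) return(empty)

  het <- cumsum(c(0L, !is.na(calls) & calls == 1L))
  mis <- cumsum(c(0L, is.na(calls)))
  gap_ok <- c(diff(positions) <= params$max_gap_kb * 1000, FALSE)
  count <- function(cs, i, j) cs[j + 1L] - cs[i]

  # hereditary constraints (het, missing, gaps) survive in any sub-run, so
  # two pointers give, for each start i, the furthest feasible end e(i)
  e <- integer(n)
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j < n && gap_ok[j] &&
           count(het, i, j + 1L) <= params$max_het &&
           count(mis, i, j + 1L) <= params$max_missing) j <- j + 1L
    # j may overshoot on het/missing when advancing from a previous start
    while (j > i && (count(het, i, j) > params$max_het ||
                     count(mis, i, j) > params$max_missing)) j <- j - 1L
    e[i] <- j
  }

  qualifies <- function(i, j) {
    nn <- j - i + 1L
    if (nn < params$min_snps) return(FALSE)
    span_kb <- (positions[j] - positions[i]) / 1000
    span_kb >= params$min_length_kb &&
      span_kb / nn <= params$min_density_kb_per_snp
  }

  # candidate per start: the largest qualifying end (smaller ends would be
  # proper sub-runs); then drop candidates contained in an earlier one
  cand_start <- integer(0); cand_end <- integer(0)
  best_end <- 0L
  for (i in seq_len(n)) {
    jmax <- e[i]
    if (jmax - i + 1L < params$min_snps) next
    if (jmax <= best_end) next # contained in an earlier candidate
    for (j in seq(jmax, max(i + params$min_snps - 1L, i), by = -1L)) {
      if (j <= best_end) break
      if (qualifies(i, j)) {
        cand_start <- c(cand_start, i)
        cand_end <- c(cand_end, j)
        best_end <- j
        break
      }
    }
  }
  if (!length(cand_start)) return(empty)
  cand_start <- as.integer(cand_start)
  cand_end <- as.integer(cand_end)
  data.frame(start_idx = cand_start, end_idx = cand_end,
             start_bp = positions[cand_start], end_bp = positions[cand_end],
             n_snps = cand_end - cand_start + 1L,
             length_kb = (positions[cand_end] - positions[cand_start]) / 1000)
}

#' Detect ROH for every individual across the genome
#'
#' @param gm a [geno_matrix()].
#' @param params a [roh_params()].
#' @return data.frame(id, chrom, start_bp, end_bp, n_snps, length_kb).
#' @export
detect_roh_all <- function(gm, params = roh_params()) {
  map <- gm$map
  chrom_idx <- split(seq_len(nrow(map)), map$chrom)
  out <- list()
  for (id in individuals(gm)) {
    g <- gm$calls[id, ]
    for (ch in names(chrom_idx)) {
      i <- chrom_idx[[ch]]
      seg <- detect_roh(g[i], map$pos_bp[i], params)
      if (nrow(seg))
        out[[length(out) + 1L]] <-
          data.frame(id = id, chrom = as.integer(ch),
                     start_bp = seg$start_bp, end_bp = seg$end_bp,
                     n_snps = seg$n_snps, length_kb = seg$length_kb,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(id = character(0), chrom = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), length_kb = numeric(0)))
  do.call(rbind, out)
}

#' Autosomal genome length spanned by SNP positions
#'
#' `L_AUTO`: the sum over chromosomes of (last SNP position - first SNP
#' position), in kb — the denominator of F_ROH.
#'
#' @param map a [snp_map()].
#' @return Length in kb.
#' @export
l_auto_kb <- function(map) {
  sum(vapply(split(map$pos_bp, map$chrom),
             function(p) (max(p) - min(p)) / 1000, 0))
}

#' Genomic inbreeding from ROH
#'
#' `F_ROH = sum(L_ROH) / L_AUTO` over one individual's segments, optionally
#' restricted to segments strictly longer than `min_segment_kb` (e.g.
#' 5000 kb for the long-ROH variant).
#'
#' @param segments data.frame with a `length_kb` column (one individual).
#' @param genome_length_kb `L_AUTO` in kb (see [l_auto_kb()]).
#' @param min_segment_kb only segments with `length_kb > min_segment_kb`
#'   count (default 0).
#' @return F_ROH in `[0, 1]`.
#' @export
f_roh <- function(segments, genome_length_kb, min_segment_kb = 0) {
  if (genome_length_kb <= 0) stop("genome length must be positive")
  if (is.null(segments) || nrow(segments) == 0) return(0)
  sum(segments$length_kb[segments$length_kb > min_segment_kb]) /
    genome_length_kb
}

#' Excess-homozygosity inbreeding coefficient
#'
#' `(observed hom - expected hom) / (non-missing - expected hom)`; may be
#' negative for individuals less homozygous than expected.
#'
#' @param n_obs_hom observed homozygous loci.
#' @param n_exp_hom expected homozygous loci.
#' @param n_nonmissing non-missing loci.
#' @return F_HOM.
#' @export
f_hom <- function(n_obs_hom, n_exp_hom, n_nonmissing) {
  den <- n_nonmissing - n_exp_hom
  if (den <= 0) stop("non-positive denominator")
  (n_obs_hom - n_exp_hom) / den
}

#' Expected homozygous-locus count for one individual
#'
#' Sum over the individual's non-missing SNPs of
#' `1 - 2 p q * 2n / (2n - 1)` where `p` is the allele frequency and `n` the
#' number of non-missing individuals at the SNP in the frequency basis (the
#' merged sample by default) — the small-sample-corrected expected
#' homozygosity. SNPs observed in fewer than two individuals are excluded
#' with a warning.
#'
#' @param gm a [geno_matrix()] (the frequency basis).
#' @param individual individual id.
#' @return Expected count of homozygous loci.
#' @export
expected_hom <- function(gm, individual) {
  g <- gm$calls[individual, ]
  n_obs <- colSums(!is.na(gm$calls))
  p <- colSums(gm$calls, na.rm = TRUE) / (2 * n_obs)
  use <- !is.na(g)
  thin <- use & n_obs < 2
  if (any(thin)) {
    warning(sum(thin), " SNP(s) with fewer than 2 observations excluded")
    use <- use & !thin
  }
  q <- 1 - p
  sum(1 - 2 * p[use] * q[use] * (2 * n_obs[use]) / (2 * n_obs[use] - 1))
}

#' Per-individual inbreeding table
#'
#' Computes F_HOM, F_ROH and F_ROH(>5 Mb) for every individual of a panel,
#' and merges pedigree-based F_PED and PCI_5G when a pedigree is given.
#'
#' @param gm a [geno_matrix()].
#' @param segments output of [detect_roh_all()].
#' @param pedigree optional data.frame(id, sire, dam).
#' @param long_kb threshold for the long-ROH coefficient (default 5000,
#'   strictly greater).
#' @return data.frame(id, f_hom, f_roh, f_roh_gt5mb[, f_ped, pci_5g]).
#' @export
inbreeding_table <- function(gm, segments, pedigree = NULL, long_kb = 5000) {
  la <- l_auto_kb(gm$map)
  ids <- individuals(gm)
  n_obs <- colSums(!is.na(gm$calls))
  p <- colSums(gm$calls, na.rm = TRUE) / (2 * n_obs)
  exp_hom_snp <- 1 - 2 * p * (1 - p) * (2 * n_obs) / (2 * n_obs - 1)
  out <- data.frame(id = ids, f_hom = NA_real_, f_roh = NA_real_,
                    f_roh_gt5mb = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    g <- gm$calls[ids[k], ]
    use <- !is.na(g) & n_obs >= 2
    out$f_hom[k] <- f_hom(sum(g[use] != 1L), sum(exp_hom_snp[use]), sum(use))
    seg <- segments[segments$id == ids[k], , drop = FALSE]
    out$f_roh[k] <- f_roh(seg, la)
    out$f_roh_gt5mb[k] <- f_roh(seg, la, min_segment_kb = long_kb)
  }
  if (!is.null(pedigree)) {
    fp <- pedigree_inbreeding(pedigree)
    pc <- pci_5g(pedigree)
    out$f_ped <- unname(fp[out$id])
    out$pci_5g <- unname(pc[out$id])
  }
  out
}

#' Per-population ROH summary
#'
#' Counts of individuals with/without ROH, segment totals and means, a
#' length-class histogram (1-5, 5-10, 10-15, 15-20, 20-25, 25-30, >= 30 Mb)
#' and per-chromosome counts.
#'
#' @param segments output of [detect_roh_all()].
#' @param pops population assignment (named by id; must cover all ids that
#'   were scanned).
#' @return A list: `per_population` data.frame, `length_classes` matrix
#'   (population x class) and `per_chromosome` matrix (population x chrom).
#' @export
roh_summaries <- function(segments, pops) {
  labs <- unique(pops)
  breaks <- c(1, 5, 10, 15, 20, 25, 30, Inf) * 1000 # kb
  class_names <- c("1-5", "5-10", "10-15", "15-20", "20-25", "25-30", ">=30")
  lc <- matrix(0L, length(labs), length(class_names),
               dimnames = list(labs, class_names))
  pc <- matrix(0L, length(labs), N_AUTOSOMES,
               dimnames = list(labs, as.character(seq_len(N_AUTOSOMES))))
  rows <- list()
  for (lab in labs) {
    ids <- names(pops)[pops == lab]
    seg <- segments[segments$id %in% ids, , drop = FALSE]
    with_roh <- unique(seg$id)
    per_ind_n <- table(factor(seg$id, levels = ids))
    per_ind_kb <- tapply(seg$length_kb, factor(seg$id, levels = ids),
                         sum, default = 0)
    has <- ids %in% with_roh
    rows[[lab]] <- data.frame(
      population = lab,
      n_without_roh = sum(!has),
      n_with_roh = sum(has),
      total_roh = nrow(seg),
      mean_n_roh = mean(per_ind_n),
      min_n_roh = min(per_ind_n), max_n_roh = max(per_ind_n),
      mean_total_mb = mean(per_ind_kb) / 1000,
      min_total_mb = min(per_ind_kb) / 1000,
      max_total_mb = max(per_ind_kb) / 1000,
      stringsAsFactors = FALSE)
    if (nrow(seg)) {
      cls <- cut(seg$length_kb, breaks, right = FALSE, labels = class_names)
      lc[lab, ] <- as.integer(table(cls))
      tb <- table(factor(seg$chrom, levels = seq_len(N_AUTOSOMES)))
      pc[lab, ] <- as.integer(tb)
    }
  }
  list(per_population = do.call(rbind, rows), length_classes = lc,
       per_chromosome = pc)
}

#' Per-SNP ROH incidence within populations
#'
#' For every SNP and population, the fraction of individuals with a segment
#' covering the SNP position (closed interval), with a flag for fractions at
#' or above `threshold`.
#'
#' @param segments output of [detect_roh_all()].
#' @param map a [snp_map()].
#' @param pops population assignment.
#' @param threshold flagging fraction (default 0.25, inclusive).
#' @return data.frame(snp_id, chrom, pos_bp, population, fraction, flagged).
#' @export
roh_incidence <- function(segments, map, pops, threshold = 0.25) {
  labs <- unique(pops)
  out <- list()
  for (lab in labs) {
    ids <- names(pops)[pops == lab]
    seg <- segments[segments$id %in% ids, , drop = FALSE]
    cover <- numeric(nrow(map))
    if (nrow(seg)) {
      for (ch in unique(seg$chrom)) {
        snp_i <- which(map$chrom == ch)
        sc <- seg[seg$chrom == ch, , drop = FALSE]
        cnt <- numeric(length(snp_i))
        for (id in unique(sc$id)) {
          si <- sc[sc$id == id, , drop = FALSE]
          hit <- rep(FALSE, length(snp_i))
          for (r in seq_len(nrow(si)))
            hit <- hit | (map$pos_bp[snp_i] >= si$start_bp[r] &
                            map$pos_bp[snp_i] <= si$end_bp[r])
          cnt <- cnt + hit
        }
        cover[snp_i] <- cnt
      }
    }
    frac <- cover / length(ids)
    out[[lab]] <- data.frame(snp_id = map$snp_id, chrom = map$chrom,
                             pos_bp = map$pos_bp, population = lab,
                             fraction = frac,
                             flagged = frac >= threshold,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Compare pedigree and genomic inbreeding
#'
#' Pearson correlation and ordinary least-squares fit of a genomic
#' coefficient on F_PED, across all individuals or only those with pedigree
#' completeness `pci_5g >= pci_min`.
#'
#' @param records output of [inbreeding_table()] including `f_ped`.
#' @param genomic which genomic column to compare (default "f_roh").
#' @param pci_min optional completeness filter.
#' @return Named vector: r, slope, intercept, r_squared, n.
#' @export
compare_inbreeding <- function(records, genomic = "f_roh", pci_min = NULL) {
  x <- records
  if (!is.null(pci_min)) x <- x[x$pci_5g >= pci_min, , drop = FALSE]
  x <- x[is.finite(x$f_ped) & is.finite(x[[genomic]]), , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 records after filtering")
  if (sd(x$f_ped) == 0 || sd(x[[genomic]]) == 0)
    stop("zero variance in inbreeding values")
  fit <- lm(x[[genomic]] ~ x$f_ped)
  r <- cor(x$f_ped, x[[genomic]])
  c(r = r, slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared, n = nrow(x))
}
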