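## PLINK text-dialect input/output and the three-stage quality control:
## call rate on the merged sample, then per-population MAF and exact HWE.

#' Read PLINK text-dialect PED/MAP files
#'
#' The MAP file has four whitespace-separated columns (chromosome, SNP id,
#' genetic position in cM, base-pair position); the PED file has six metadata
#' columns (family, individual, sire, dam, sex, phenotype) followed by two
#' allele columns per SNP, with `"0"` encoding a missing allele. Records on
#' non-autosomal chromosome codes (outside 1--29) are skipped with a warning.
#' A genotype with exactly one missing allele is treated as entirely missing.
#'
#' Allele coding is assigned per SNP on the merged sample: `allele_a` is the
#' major and `allele_b` the minor allele by frequency, ties broken
#' lexicographically, and calls count copies of `allele_b`.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return A list with elements `geno` (a [geno_matrix()]), `map` (its
#'   [snp_map()]) and `pops` (named character vector: the PED family column
#'   as population assignment).
#' @export
read_plink_text <- function(ped_path, map_path) {
  map_raw <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                        col.names = c("chrom", "snp_id", "cm", "pos_bp"),
                        colClasses = c("character", "character",
                                       "character", "integer"))
  chrom <- suppressWarnings(as.integer(map_raw$chrom))
  auto <- !is.na(chrom) & chrom >= 1L & chrom <= N_AUTOSOMES
  if (any(!auto)) {
    warning(sum(!auto), " SNP(s) on non-autosomal chromosome codes skipped: ",
            paste(unique(map_raw$chrom[!auto]), collapse = ", "))
  }
  n_all <- nrow(map_raw)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n_ind <- length(lines)
  expected_fields <- 6L + 2L * n_all

  fam <- character(n_ind)
  iid <- character(n_ind)
  a1 <- matrix("0", n_ind, n_all)
  a2 <- matrix("0", n_ind, n_all)
  for (i in seq_len(n_ind)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != expected_fields)
      stop("PED parse error at line ", i, ": expected ", expected_fields,
           " fields, found ", length(f))
    fam[i] <- f[1]
    iid[i] <- f[2]
    al <- f[-(1:6)]
    a1[i, ] <- al[seq(1L, by = 2L, length.out = n_all)]
    a2[i, ] <- al[seq(2L, by = 2L, length.out = n_all)]
  }
  if (anyDuplicated(iid))
    iid <- paste(fam, iid, sep = "_")

  keep <- which(auto)
  n_snp <- length(keep)
  calls <- matrix(NA_integer_, n_ind, n_snp)
  allele_a <- character(n_snp)
  allele_b <- character(n_snp)
  for (k in seq_len(n_snp)) {
    j <- keep[k]
    x1 <- a1[, j]; x2 <- a2[, j]
    ok <- x1 != "0" & x2 != "0" # half-missing -> whole call missing
    als <- c(x1[ok], x2[ok])
    tab <- sort(table(als), decreasing = TRUE)
    if (length(tab) == 0L) {
      allele_a[k] <- "A"; allele_b[k] <- "B"
      next
    }
    labs <- names(tab)
    if (length(tab) > 2L)
      stop("SNP ", map_raw$snp_id[j], " has more than two alleles: ",
           paste(labs, collapse = ", "))
    # major/minor by count; ties broken lexicographically (smaller = major)
    if (length(tab) == 1L) {
      allele_a[k] <- labs[1]
      allele_b[k] <- if (labs[1] == "B") "b" else "B" # placeholder minor
    } else {
      if (tab[1] == tab[2]) labs <- sort(labs)
      allele_a[k] <- labs[1]; allele_b[k] <- labs[2]
    }
    calls[ok, k] <- (x1[ok] == allele_b[k]) + (x2[ok] == allele_b[k])
    calls[!ok, k] <- NA_integer_
  }

  map <- snp_map(map_raw$snp_id[keep], chrom[keep], map_raw$pos_bp[keep],
                 allele_a, allele_b)
  calls_named <- calls
  rownames(calls_named) <- iid
  gm <- geno_matrix(calls_named, map)
  pops <- setNames(fam, iid)
  list(geno = gm, map = map, pops = pops)
}

#' Write PLINK text-dialect PED/MAP files
#'
#' Inverse of [read_plink_text()]: missing calls become `"0 0"`, genotype 0
#' is `allele_a allele_a`, 1 is `allele_a allele_b`, 2 is
#' `allele_b allele_b`. The family column carries the population label.
#'
#' @param gm a [geno_matrix()].
#' @param pops named character vector individual id -> population label.
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_plink_text <- function(gm, pops, ped_path, map_path) {
  map <- gm$map
  write.table(data.frame(map$chrom, map$snp_id, 0, map$pos_bp),
              map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ids <- individuals(gm)
  pops <- check_pops(gm, pops)
  con <- file(ped_path, "w")
  on.exit(close(con))
  n_snp <- ncol(gm$calls)
  for (i in seq_along(ids)) {
    g <- gm$calls[i, ]
    h1 <- ifelse(is.na(g), "0", ifelse(g == 2L, map$allele_b, map$allele_a))
    h2 <- ifelse(is.na(g), "0", ifelse(g >= 1L, map$allele_b, map$allele_a))
    writeLines(paste(c(pops[i], ids[i], "0", "0", "0", "-9",
                       as.vector(rbind(h1, h2))), collapse = " "), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Intersect SNP panels
#'
#' Returns the SNPs present, by id and with identical chromosome and
#' position, in every input map — the shared panel of several genotyping
#' arrays. Order follows the first map. The same id at conflicting
#' coordinates is a hard error.
#'
#' @param maps a list of [snp_map()] objects (>= 1).
#' @return A `snp_map` with the common SNPs.
#' @export
intersect_panels <- function(maps) {
  stopifnot(length(maps) >= 1L)
  base <- maps[[1]]
  keep <- rep(TRUE, nrow(base))
  conflicts <- character(0)
  for (m in maps[-1]) {
    idx <- match(base$snp_id, m$snp_id)
    present <- !is.na(idx)
    same <- present & base$chrom == m$chrom[idx] &
      base$pos_bp == m$pos_bp[idx]
    conflicts <- c(conflicts, base$snp_id[present & !same])
    keep <- keep & present & (same | !present)
  }
  if (length(conflicts))
    stop("conflicting positions for shared SNP ids: ",
         paste(unique(conflicts), collapse = ", "))
  out <- base[keep, , drop = FALSE]
  class(out) <- c("snp_map", "data.frame")
  out
}

#' Call-rate SNP filter
#'
#' Keeps a SNP if its missing-call fraction is at most `max_missing_rate`
#' (PLINK `--geno` semantics: rates strictly above the bound are removed).
#'
#' @param gm a [geno_matrix()].
#' @param max_missing_rate maximum allowed missing fraction (default 0.1).
#' @return Logical vector over SNPs, `TRUE` = kept.
#' @export
filter_call_rate <- function(gm, max_missing_rate = 0.1) {
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1)
  colMeans(is.na(gm$calls)) <= max_missing_rate
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test on the heterozygote count given the
#' observed allele counts: the p-value is the sum of probabilities of all
#' heterozygote configurations whose conditional probability does not exceed
#' that of the observed one. No mid-p adjustment.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom major, het, hom minor).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("no genotype data")
  n_b <- 2 * n_bb + n_ab # minor allele count (or either; test is symmetric)
  probs <- hwe_het_probs(n, min(n_b, 2 * n - n_b))
  obs_p <- probs[as.character(n_ab)]
  if (is.na(obs_p)) stop("heterozygote count incompatible with allele counts")
  sum(probs[probs <= obs_p * (1 + 1e-12)])
}

## Conditional distribution of the heterozygote count given n individuals and
## n_rare copies of the rarer allele; named by attainable het counts.
hwe_het_probs <- function(n, n_rare) {
  if (n_rare == 0) return(setNames(1, "0"))
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # log P(het) = const + log[ n! / (n_aa! n_ab! n_bb!) * 2^n_ab ]
  n_bb <- (n_rare - hets) / 2
  n_aa <- n - hets - n_bb
  lp <- hets * log(2) - lfactorial(n_aa) - lfactorial(hets) - lfactorial(n_bb)
  p <- exp(lp - max(lp))
  setNames(p / sum(p), as.character(hets))
}

#' Per-population MAF and HWE filter
#'
#' Applies the second QC stage: a SNP stays in the shared panel only if,
#' within every population, its minor-allele frequency over non-missing
#' alleles is at least `maf_min` and the exact HWE p-value is at least
#' `hwe_alpha`. A population with no data at a SNP drops that SNP.
#'
#' @param gm a [geno_matrix()].
#' @param pops population assignment (named character vector).
#' @param maf_min minimum within-population minor allele frequency
#'   (default 0.01, i.e. "lower than 1 percent" removed).
#' @param hwe_alpha HWE exact-test significance bound (default 1e-4).
#' @return A list: `keep` (logical over SNPs) and `report` (a `data.frame`
#'   with one row per SNP: snp_id, status, and for dropped SNPs the first
#'   failing population and reason).
#' @export
per_population_filter <- function(gm, pops, maf_min = 0.01,
                                  hwe_alpha = 1e-4) {
  pops <- check_pops(gm, pops)
  labels <- unique(pops)
  n_snp <- ncol(gm$calls)
  keep <- rep(TRUE, n_snp)
  reason <- rep(NA_character_, n_snp)
  where <- rep(NA_character_, n_snp)
  for (lab in labels) {
    sub <- gm$calls[pops == lab, , drop = FALSE]
    active <- which(keep)
    if (!length(active)) break
    for (j in active) {
      g <- sub[, j]
      g <- g[!is.na(g)]
      if (!length(g)) {
        keep[j] <- FALSE; where[j] <- lab; reason[j] <- "no data in population"
        next
      }
      n_bb <- sum(g == 2L); n_ab <- sum(g == 1L); n_aa <- sum(g == 0L)
      p_b <- (2 * n_bb + n_ab) / (2 * length(g))
      maf <- min(p_b, 1 - p_b)
      if (maf < maf_min) {
        keep[j] <- FALSE; where[j] <- lab; reason[j] <- "maf"
        next
      }
      if (hwe_exact_test(n_aa, n_ab, n_bb) < hwe_alpha) {
        keep[j] <- FALSE; where[j] <- lab; reason[j] <- "hwe"
      }
    }
  }
  report <- data.frame(snp_id = gm$map$snp_id,
                       status = ifelse(keep, "kept", "dropped"),
                       population = where, reason = reason,
                       stringsAsFactors = FALSE)
  list(keep = keep, report = report)
}

#' Run the full three-stage quality control
#'
#' Stage 1 drops SNPs with missing rate above `geno`; stage 2 applies the
#' per-population MAF/HWE filter to the survivors. Stages are
#' order-sensitive and the final panel is the intersection of both.
#'
#' @param gm a [geno_matrix()].
#' @param pops population assignment.
#' @param geno maximum missing rate (default 0.1).
#' @param maf minimum per-population MAF (default 0.01).
#' @param hwe HWE alpha (default 1e-4).
#' @return A list: `geno` (filtered [geno_matrix()]), `qc_report` (per-SNP
#'   fate table with stage), and `counts` (n_input, n_after_callrate,
#'   n_after_per_population).
#' @export
run_qc <- function(gm, pops, geno = 0.1, maf = 0.01, hwe = 1e-4) {
  keep1 <- filter_call_rate(gm, geno)
  gm1 <- subset_geno(gm, snp = which(keep1))
  pp <- per_population_filter(gm1, pops, maf_min = maf, hwe_alpha = hwe)
  fate <- data.frame(snp_id = gm$map$snp_id,
                     stage = ifelse(keep1, "per_population", "call_rate"),
                     status = "dropped", reason = NA_character_,
                     stringsAsFactors = FALSE)
  fate$reason[!keep1] <- "call_rate"
  idx <- match(gm1$map$snp_id, fate$snp_id)
  fate$status[idx] <- pp$report$status
  fate$reason[idx[!pp$keep]] <-
    paste0(pp$report$reason[!pp$keep], " (", pp$report$population[!pp$keep], ")")
  fate$stage[fate$status == "kept"] <- "final"
  list(geno = subset_geno(gm1, snp = which(pp$keep)),
       qc_report = fate,
       counts = c(n_input = ncol(gm$calls),
                  n_after_callrate = sum(keep1),
                  n_after_per_population = sum(pp$keep)))
}
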