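## Windowed d_i selection-signature scan: per-SNP pairwise Weir-Cockerham
## F_ST, standardization per population pair, the d_i sum over pairs,
## 1-Mb window averaging, and empirical-percentile significance calling.

#' Per-SNP pairwise Weir-Cockerham F_ST
#'
#' The single-SNP estimate `a / (a + b + c)` for one pair of populations.
#' SNPs where the total variance is zero (e.g. monomorphic in both
#' populations) are undefined and returned as `NA`, not zero; negative
#' estimates are retained.
#'
#' @param gm a [geno_matrix()].
#' @param pops population assignment.
#' @param pop_a,pop_b population labels.
#' @return Numeric vector over SNPs (`NA` = undefined).
#' @export
per_snp_pairwise_fst <- function(gm, pops, pop_a, pop_b) {
  pops <- check_pops(gm, pops)
  stopifnot(sum(pops == pop_a) >= 2, sum(pops == pop_b) >= 2)
  wc <- wc_components(gm$calls[pops == pop_a, , drop = FALSE],
                      gm$calls[pops == pop_b, , drop = FALSE])
  fst <- wc$a / wc$total
  fst[wc$undefined] <- NA
  fst
}

#' Mean and SD of a per-SNP F_ST vector
#'
#' The moments entering the d_i standardization, computed over the SNPs
#' where the pairwise estimate is defined (denominator n - 1 for the SD).
#'
#' @param fst_snp per-SNP F_ST vector (`NA` = undefined).
#' @param pair optional label pair for bookkeeping.
#' @return List of class `fst_pair_stats`: `fst_snp`, `mean`, `sd`, `pair`.
#' @export
fst_pair_stats <- function(fst_snp, pair = NULL) {
  ok <- !is.na(fst_snp)
  structure(list(fst_snp = fst_snp, mean = mean(fst_snp[ok]),
                 sd = sd(fst_snp[ok]), pair = pair),
            class = "fst_pair_stats")
}

#' Standardize a per-SNP F_ST vector
#'
#' `(F_ST - mean) / sd` using the pair's own moments; defined exactly where
#' the input is defined. A degenerate pair (zero SD) is an error.
#'
#' @param stats an [fst_pair_stats()].
#' @return Numeric z vector over SNPs.
#' @export
standardize_pair <- function(stats) {
  if (!is.finite(stats$sd) || stats$sd == 0)
    stop("degenerate population pair: sd of F_ST is zero")
  (stats$fst_snp - stats$mean) / stats$sd
}

#' d_i track for one population
#'
#' Per SNP, the sum over all other populations `j` of the standardized
#' pairwise F_ST involving population `i`; pairs undefined at a SNP
#' contribute nothing there. A SNP with no defined pair is `NA`.
#'
#' @param z_list list of standardized z vectors, one per pair involving the
#'   focal population.
#' @return Numeric d_i vector over SNPs.
#' @export
di_track <- function(z_list) {
  stopifnot(length(z_list) >= 1)
  zm <- do.call(cbind, z_list)
  di <- rowSums(zm, na.rm = TRUE)
  di[rowSums(!is.na(zm)) == 0] <- NA
  di
}

#' Average d_i in non-overlapping 1-Mb windows
#'
#' A SNP at base-pair position p on chromosome c belongs to window
#' `floor((p - 1) / (window_mb * 1e6))` of c, which spans
#' `[w * 1e6 + 1, (w + 1) * 1e6]`. Windows with fewer than `min_snps` SNPs
#' carrying a defined d_i are discarded; empty windows are never emitted.
#'
#' @param di per-SNP d_i vector.
#' @param map a [snp_map()] aligned with `di`.
#' @param window_mb window width in Mb (default 1).
#' @param min_snps minimum defined-d_i SNPs to retain a window (default 4).
#' @return data.frame(chrom, window, start_bp, end_bp, n_snps, mean_di).
#' @export
window_scan <- function(di, map, window_mb = 1, min_snps = 4) {
  stopifnot(length(di) == nrow(map))
  w_bp <- window_mb * 1e6
  ok <- !is.na(di)
  win <- floor((map$pos_bp[ok] - 1) / w_bp)
  key <- paste(map$chrom[ok], win, sep = ":")
  n <- tapply(di[ok], key, length)
  m <- tapply(di[ok], key, mean)
  keep <- n >= min_snps
  if (!any(keep))
    return(data.frame(chrom = integer(0), window = integer(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), mean_di = numeric(0)))
  parts <- strsplit(names(n)[keep], ":", fixed = TRUE)
  chrom <- as.integer(vapply(parts, `[`, "", 1))
  wdx <- as.numeric(vapply(parts, `[`, "", 2))
  out <- data.frame(chrom = chrom, window = wdx,
                    start_bp = wdx * w_bp + 1, end_bp = (wdx + 1) * w_bp,
                    n_snps = as.integer(n[keep]),
                    mean_di = as.numeric(m[keep]))
  out[order(out$chrom, out$window), , drop = FALSE]
}

#' Flag windows above the empirical percentile
#'
#' Nearest-rank convention: the threshold is the `ceil(q * W)`-th smallest
#' of the `W` retained window means; a window is significant if its mean is
#' strictly greater than the threshold. With 2,500 tie-free windows and the
#' 99th percentile this flags exactly 25.
#'
#' @param windows output of [window_scan()].
#' @param percentile percentile in (0, 100) (default 99).
#' @return `windows` with logical column `significant` added; attribute
#'   `threshold` carries the cutoff.
#' @export
call_significant <- function(windows, percentile = 99) {
  stopifnot(nrow(windows) >= 1, percentile > 0, percentile < 100)
  s <- sort(windows$mean_di)
  thr <- s[ceiling(percentile / 100 * length(s))]
  windows$significant <- windows$mean_di > thr
  attr(windows, "threshold") <- thr
  windows
}

#' Classify flagged windows as private or shared
#'
#' @param flagged named list (population -> data.frame with `chrom`,
#'   `window`, `significant`) as returned by [call_significant()].
#' @return A list: `windows` (data.frame chrom, window, populations
#'   (comma-joined), n_populations, private) and `counts`
#'   (`c(private = ..., shared = ..., total = ...)`).
#' @export
classify_windows <- function(flagged) {
  keys <- list()
  for (pop in names(flagged)) {
    f <- flagged[[pop]]
    f <- f[f$significant, , drop = FALSE]
    if (!nrow(f)) next
    k <- paste(f$chrom, f$window, sep = ":")
    for (kk in k) keys[[kk]] <- c(keys[[kk]], pop)
  }
  if (!length(keys))
    return(list(windows = data.frame(chrom = integer(0), window = integer(0),
                                     populations = character(0),
                                     n_populations = integer(0),
                                     private = logical(0)),
                counts = c(private = 0L, shared = 0L, total = 0L)))
  parts <- strsplit(names(keys), ":", fixed = TRUE)
  out <- data.frame(chrom = as.integer(vapply(parts, `[`, "", 1)),
                    window = as.numeric(vapply(parts, `[`, "", 2)),
                    populations = vapply(keys, paste, "", collapse = ","),
                    n_populations = lengths(keys),
                    private = lengths(keys) == 1L,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$window), , drop = FALSE]
  rownames(out) <- NULL
  list(windows = out,
       counts = c(private = sum(out$private),
                  shared = sum(!out$private),
                  total = nrow(out)))
}

#' Full d_i selection scan across populations
#'
#' Runs the whole chain: per-SNP pairwise F_ST for every population pair,
#' per-pair standardization, d_i per population, 1-Mb window averaging,
#' percentile calling per population, and private/shared classification.
#'
#' @param gm a [geno_matrix()].
#' @param pops population assignment (pool populations first with
#'   [pool_populations()] if desired).
#' @param window_mb window width (default 1).
#' @param min_snps minimum defined-d_i SNPs per retained window (default 4).
#' @param percentile significance percentile (default 99).
#' @return A list: `windows` (named list per population, each with
#'   `significant` flags), `classification` (see [classify_windows()]),
#'   `pair_stats` (mean/sd per pair), `di` (named list of per-SNP tracks).
#' @export
selection_scan <- function(gm, pops, window_mb = 1, min_snps = 4,
                           percentile = 99) {
  pops <- check_pops(gm, pops)
  labs <- unique(pops)
  stopifnot(length(labs) >= 2)
  z <- list(); pair_stats <- list()
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (i >= j) next
    key <- paste(labs[i], labs[j], sep = "|")
    st <- fst_pair_stats(per_snp_pairwise_fst(gm, pops, labs[i], labs[j]),
                         pair = c(labs[i], labs[j]))
    pair_stats[[key]] <- st
    z[[key]] <- standardize_pair(st)
  }
  di <- list(); windows <- list()
  for (lab in labs) {
    involves <- vapply(pair_stats, function(s) lab %in% s$pair, TRUE)
    zl <- z[names(pair_stats)[involves]]
    di[[lab]] <- di_track(zl)
    windows[[lab]] <- call_significant(
      window_scan(di[[lab]], gm$map, window_mb, min_snps), percentile)
  }
  list(windows = windows, classification = classify_windows(windows),
       pair_stats = pair_stats, di = di)
}
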