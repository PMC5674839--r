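## Population-structure statistics: observed heterozygosity, IBS distance,
## method-of-moments IBD sharing, classical (Torgerson) MDS, and
## Weir-Cockerham F_ST with a SNP-resampling bootstrap.

#' Observed heterozygosity of one individual
#'
#' `1 - (observed homozygous loci / non-missing loci)`, i.e. the fraction of
#' non-missing calls that are heterozygous.
#'
#' @param calls integer vector of genotype calls (0/1/2, `NA` missing).
#' @return Fraction in `[0, 1]`.
#' @export
observed_heterozygosity <- function(calls) {
  g <- calls[!is.na(calls)]
  if (!length(g)) stop("all calls missing")
  1 - sum(g != 1L) / length(g)
}

#' Pairwise identity-by-state distance matrix
#'
#' Distance between two individuals is `1 - mean(IBS)/2` over jointly
#' non-missing SNPs, where IBS sharing is 0, 1 or 2 alleles. This is the
#' dissimilarity PLINK clusters on for its MDS plot.
#'
#' @param gm a [geno_matrix()].
#' @return A symmetric matrix with zero diagonal, labelled by individual id.
#' @export
ibs_distance <- function(gm) {
  calls <- gm$calls
  n <- nrow(calls)
  if (n < 2) stop("need at least 2 individuals")
  d <- matrix(0, n, n, dimnames = list(rownames(calls), rownames(calls)))
  for (i in seq_len(n - 1)) {
    gi <- calls[i, ]
    for (j in (i + 1):n) {
      gj <- calls[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      if (!any(ok))
        stop("no jointly non-missing SNPs for pair ",
             rownames(calls)[i], " / ", rownames(calls)[j])
      d[i, j] <- d[j, i] <- mean(abs(gi[ok] - gj[ok])) / 2
    }
  }
  d
}

## Per-SNP expected IBS-state probabilities given IBD state, with the
## small-sample corrections of the PLINK --genome method-of-moments
## estimator. p: frequency of the counted allele; n_obs: non-missing
## individuals at the SNP in the frequency basis sample.
ibd_expectations <- function(p, n_obs) {
  q <- 1 - p
  S <- 2 * n_obs
  X <- p * S
  Y <- q * S
  cs2 <- (S / (S - 1)) * (S / (S - 2))
  cs3 <- cs2 * (S / (S - 3))
  x1 <- (X - 1) / X; x2 <- (X - 2) / X; x3 <- (X - 3) / X
  y1 <- (Y - 1) / Y; y2 <- (Y - 2) / Y; y3 <- (Y - 3) / Y
  list(
    e00 = 2 * p^2 * q^2 * x1 * y1 * cs3,
    e10 = 4 * p^3 * q * x1 * x2 * cs3 + 4 * p * q^3 * y1 * y2 * cs3,
    e20 = p^4 * x1 * x2 * x3 * cs3 + q^4 * y1 * y2 * y3 * cs3 +
      4 * p^2 * q^2 * x1 * y1 * cs3,
    e11 = 2 * p^2 * q * x1 * cs2 + 2 * p * q^2 * y1 * cs2,
    e21 = p^3 * x1 * x2 * cs2 + q^3 * y1 * y2 * cs2 +
      p^2 * q * x1 * cs2 + p * q^2 * y1 * cs2)
}

#' Method-of-moments IBD sharing for all pairs
#'
#' PLINK-style `--genome` estimates: per pair, observed counts of IBS states
#' 0/1/2 over jointly non-missing SNPs are equated with their expectations
#' given IBD state (computed from allele frequencies of the merged sample
#' with small-sample bias corrections) and solved for (Z0, Z1, Z2), which
#' are then constrained to the probability simplex. `pi_hat = Z1/2 + Z2`.
#'
#' @param gm a [geno_matrix()]. Frequencies are computed from this merged
#'   sample, mirroring an analysis run on all populations together.
#' @return data.frame(id1, id2, Z0, Z1, Z2, pi_hat).
#' @export
ibd_moments <- function(gm) {
  calls <- gm$calls
  n <- nrow(calls)
  n_obs <- colSums(!is.na(calls))
  p <- colSums(calls, na.rm = TRUE) / (2 * n_obs)
  usable <- n_obs >= 2 & p > 0 & p < 1 & (2 * n_obs) >= 4
  if (!any(usable)) stop("no polymorphic SNPs: IBD expectations undefined")
  e <- ibd_expectations(p[usable], n_obs[usable])
  calls_u <- calls[, usable, drop = FALSE]

  out <- vector("list", n * (n - 1) / 2)
  k <- 0
  for (i in seq_len(n - 1)) {
    gi <- calls_u[i, ]
    for (j in (i + 1):n) {
      gj <- calls_u[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      ibs <- 2L - abs(gi[ok] - gj[ok])
      N0 <- sum(ibs == 0L); N1 <- sum(ibs == 1L); N2 <- sum(ibs == 2L)
      E00 <- sum(e$e00[ok]); E10 <- sum(e$e10[ok]); E20 <- sum(e$e20[ok])
      E11 <- sum(e$e11[ok]); E21 <- sum(e$e21[ok]); E22 <- sum(ok)
      z0 <- N0 / E00
      z1 <- (N1 - z0 * E10) / E11
      z2 <- (N2 - z0 * E20 - z1 * E21) / E22
      z <- pmin(pmax(c(z0, z1, z2), 0), 1)
      z <- z / sum(z)
      k <- k + 1
      out[[k]] <- data.frame(id1 = rownames(calls)[i],
                             id2 = rownames(calls)[j],
                             Z0 = z[1], Z1 = z[2], Z2 = z[3],
                             pi_hat = z[2] / 2 + z[3],
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared-distance matrix, takes the leading
#' eigenpairs with non-negative eigenvalues, and returns
#' `eigenvector * sqrt(eigenvalue)` coordinates ordered by decreasing
#' eigenvalue. If fewer than `n_dims` non-negative eigenvalues exist the
#' trailing dimensions are zero, with a warning.
#'
#' @param dist symmetric dissimilarity matrix with zero diagonal.
#' @param n_dims number of output dimensions (default 2).
#' @return Matrix (individuals x n_dims) of coordinates.
#' @export
classical_mds <- function(dist, n_dims = 2) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  stopifnot(n_dims < n)
  if (max(abs(dist - t(dist))) > 1e-12) stop("distance matrix not symmetric")
  d2 <- dist^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- eg$values > 1e-12 * max(abs(eg$values), 1e-300)
  k <- min(n_dims, sum(pos))
  coords <- matrix(0, n, n_dims)
  if (k > 0)
    coords[, seq_len(k)] <- eg$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(eg$values[seq_len(k)]), k)
  if (k < n_dims)
    warning("only ", k, " non-negative eigenvalue(s); trailing dimensions 0")
  rownames(coords) <- rownames(dist)
  colnames(coords) <- paste0("C", seq_len(n_dims))
  coords
}

## Weir-Cockerham (1984) variance components for one pair of populations,
## vectorized over SNPs. Returns per-SNP a (between-population) and the
## total a+b+c; a SNP is undefined when the total is zero.
wc_components <- function(calls_a, calls_b) {
  n1 <- colSums(!is.na(calls_a)); n2 <- colSums(!is.na(calls_b))
  p1 <- colSums(calls_a, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(calls_b, na.rm = TRUE) / (2 * n2)
  h1 <- colMeans(calls_a == 1L, na.rm = TRUE)
  h2 <- colMeans(calls_b == 1L, na.rm = TRUE)
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  ok <- n1 >= 1 & n2 >= 1 & nbar > 1 & nc > 0
  a[!ok] <- NA; b[!ok] <- NA; c_[!ok] <- NA
  tot <- a + b + c_
  undef <- !ok | abs(tot) < 1e-300
  list(a = a, total = tot, undefined = undef)
}

#' Multi-SNP Weir-Cockerham pairwise F_ST
#'
#' The ratio-of-sums estimator `sum(a) / sum(a + b + c)` of the
#' Weir-Cockerham variance components over all SNPs with defined components.
#' May be slightly negative for undifferentiated populations.
#'
#' @param gm a [geno_matrix()].
#' @param pops population assignment.
#' @param pop_a,pop_b the two population labels.
#' @return A single F_ST estimate.
#' @export
pairwise_fst <- function(gm, pops, pop_a, pop_b) {
  pops <- check_pops(gm, pops)
  stopifnot(sum(pops == pop_a) >= 2, sum(pops == pop_b) >= 2)
  wc <- wc_components(gm$calls[pops == pop_a, , drop = FALSE],
                      gm$calls[pops == pop_b, , drop = FALSE])
  ok <- !wc$undefined
  if (!any(ok)) stop("no SNP with defined variance components")
  sum(wc$a[ok]) / sum(wc$total[ok])
}

#' Bootstrap confidence interval for pairwise F_ST
#'
#' Percentile interval from `n_boot` resamples of SNP columns with
#' replacement, recomputing the ratio-of-sums estimate on each resample.
#' Under degenerate resampling the interval is widened to contain the point
#' estimate.
#'
#' @inheritParams pairwise_fst
#' @param n_boot bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return Named vector `c(fst, ci_low, ci_high)`.
#' @export
bootstrap_fst_ci <- function(gm, pops, pop_a, pop_b, n_boot = 1000,
                             level = 0.95, seed = NULL) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  pops <- check_pops(gm, pops)
  wc <- wc_components(gm$calls[pops == pop_a, , drop = FALSE],
                      gm$calls[pops == pop_b, , drop = FALSE])
  ok <- which(!wc$undefined)
  if (!length(ok)) stop("no SNP with defined variance components")
  a <- wc$a[ok]; tot <- wc$total[ok]
  point <- sum(a) / sum(tot)
  m <- length(ok)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(m, m, replace = TRUE)
    sum(a[idx]) / sum(tot[idx])
  }, 0)
  alpha <- (1 - level) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
  ci[1] <- min(ci[1], point)
  ci[2] <- max(ci[2], point)
  c(fst = point, ci_low = ci[1], ci_high = ci[2])
}

#' Pairwise F_ST matrix over all populations
#'
#' @param gm a [geno_matrix()].
#' @param pops population assignment.
#' @param clamp_negative clamp negative estimates to 0 (default `TRUE`;
#'   appropriate when the matrix feeds a tree or ordination).
#' @return Symmetric matrix of F_ST values, zero diagonal.
#' @export
fst_matrix <- function(gm, pops, clamp_negative = TRUE) {
  pops <- check_pops(gm, pops)
  labs <- unique(pops)
  k <- length(labs)
  m <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    v <- pairwise_fst(gm, pops, labs[i], labs[j])
    if (clamp_negative) v <- max(v, 0)
    m[i, j] <- m[j, i] <- v
  }
  m
}

#' Per-population summary of heterozygosity and genomic relationship
#'
#' Mean and SD of observed heterozygosity per population, and of the
#' method-of-moments `pi_hat` over within-population pairs (frequencies from
#' the merged sample).
#'
#' @param gm a [geno_matrix()].
#' @param pops population assignment.
#' @param relationships optional precomputed output of [ibd_moments()].
#' @return data.frame, one row per population in input order.
#' @export
diversity_summary <- function(gm, pops, relationships = NULL) {
  pops <- check_pops(gm, pops)
  if (is.null(relationships)) relationships <- ibd_moments(gm)
  het <- apply(gm$calls, 1, observed_heterozygosity)
  rel_pop1 <- pops[relationships$id1]
  rel_pop2 <- pops[relationships$id2]
  labs <- unique(pops)
  do.call(rbind, lapply(labs, function(lab) {
    h <- het[pops == lab]
    ph <- relationships$pi_hat[rel_pop1 == lab & rel_pop2 == lab]
    data.frame(population = lab, n = sum(pops == lab),
               mean_relationship = if (length(ph)) mean(ph) else NA_real_,
               sd_relationship = if (length(ph) > 1) sd(ph) else NA_real_,
               mean_het = mean(h), sd_het = sd(h),
               stringsAsFactors = FALSE)
  }))
}
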