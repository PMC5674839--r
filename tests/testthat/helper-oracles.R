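# Independent oracles used across tests. These deliberately use the most
# literal formulation available (full enumeration, double loops, closed
# forms) and share no code with the implementation.

# O(n^2) ROH enumerator: tests every (i, j) sub-run against all constraints
# and keeps the maximal qualifiers.
brute_roh <- function(calls, positions, params) {
  n <- length(calls)
  het <- cumsum(c(0L, !is.na(calls) & calls == 1L))
  mis <- cumsum(c(0L, is.na(calls)))
  gap_bad <- c(diff(positions) > params$max_gap_kb * 1000, FALSE)
  bad_after <- cumsum(c(0L, gap_bad))
  quals <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      nn <- j - i + 1L
      if (nn < params$min_snps) next
      if (het[j + 1L] - het[i] > params$max_het) break
      if (mis[j + 1L] - mis[i] > params$max_missing) break
      if (j > i && bad_after[j] - bad_after[i] > 0) break
      sp <- (positions[j] - positions[i]) / 1000
      if (sp >= params$min_length_kb &&
          sp / nn <= params$min_density_kb_per_snp)
        quals[[length(quals) + 1L]] <- c(i, j)
    }
  }
  if (!length(quals)) return(matrix(0L, 0, 2))
  q <- do.call(rbind, quals)
  keep <- vapply(seq_len(nrow(q)), function(a) {
    !any(q[, 1] <= q[a, 1] & q[, 2] >= q[a, 2] &
           (q[, 1] != q[a, 1] | q[, 2] != q[a, 2]))
  }, TRUE)
  q[keep, , drop = FALSE]
}

# canonical attribute-free 2-column matrix for run comparisons
seg_matrix <- function(start, end)
  matrix(as.integer(c(start, end)), ncol = 2)

# genotype vector with homozygous stretches broken by hets/missing, for
# exercising the ROH detector
random_roh_calls <- function(n, p_het = 0.08, p_mis = 0.03) {
  sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
         prob = c((1 - p_het - p_mis) / 2, p_het,
                  (1 - p_het - p_mis) / 2, p_mis))
}

# scalar Weir & Cockerham (1984) two-population single-SNP estimator,
# transcribed independently from genotype counts
wc_fst_scalar <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  r <- 2
  n_i <- c(length(g1), length(g2))
  p_i <- c(sum(g1) / (2 * n_i[1]), sum(g2) / (2 * n_i[2]))
  h_i <- c(mean(g1 == 1), mean(g2 == 1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (abs(a + b + cc) < 1e-300) return(NA_real_)
  a / (a + b + cc)
}

# single-locus gene-dropping estimate of the autozygosity probability, an
# independent Monte-Carlo oracle for Wright's F
drop_f_estimate <- function(ped, individual, n_drops = 20000) {
  ped$sire[ped$sire %in% c("0", "")] <- NA
  ped$dam[ped$dam %in% c("0", "")] <- NA
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  hits <- 0L
  for (rep in seq_len(n_drops)) {
    h1 <- integer(n); h2 <- integer(n)
    lab <- 0L
    for (k in seq_len(n)) {
      if (is.na(ped$sire[k])) {
        h1[k] <- lab + 1L; h2[k] <- lab + 2L; lab <- lab + 2L
      } else {
        s <- idx[[ped$sire[k]]]; d <- idx[[ped$dam[k]]]
        h1[k] <- if (runif(1) < 0.5) h1[s] else h2[s]
        h2[k] <- if (runif(1) < 0.5) h1[d] else h2[d]
      }
    }
    t <- idx[[individual]]
    if (h1[t] == h2[t]) hits <- hits + 1L
  }
  hits / n_drops
}

# small multi-population panel used by several structure tests
make_test_panel <- function(seed = 42, k = 3, n = 20, n_snp = 400,
                            divergence = 0.08) {
  map <- sim_map(2, n_snp / 2, 90000)
  simulate_panel(map, data.frame(label = paste0("POP", seq_len(k)),
                                 divergence_F = divergence, n = n),
                 seed = seed)
}
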