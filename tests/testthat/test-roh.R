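test_that("false-positive run-length bound reproduces the arithmetic", {
  # published-scale inputs: 27,612 SNPs x 9,214 individuals, het 0.37
  expect_equal(lencz_min_snps(27612, 9214, 0.37, 0.05), 49L)
  # exact fixed point: alpha/(ns*ni) = (1 - het)^l at integer l
  het <- 0.5; l <- 20
  alpha <- (1 - het)^l * 1000 * 10
  expect_equal(lencz_min_snps(1000, 10, het, alpha), l)
  # monotone in heterozygosity
  res <- vapply(seq(0.1, 0.9, by = 0.1),
                function(h) lencz_min_snps(5000, 100, h), 1L)
  expect_true(all(diff(res) <= 0))
  expect_error(lencz_min_snps(100, 10, 0), "mean_het")
})

test_that("detect_roh handles the textbook cases", {
  params <- roh_params()
  # heterozygote every 25 SNPs: no 50-SNP het-free stretch
  calls <- rep(c(rep(0L, 24), 1L), 12)
  pos <- seq_len(length(calls)) * 50000
  expect_equal(nrow(detect_roh(calls, pos, params)), 0)
  # 60 homozygous SNPs, 50 kb apart: one segment covering all
  seg <- detect_roh(rep(2L, 60), seq_len(60) * 50000, params)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_idx, 1L)
  expect_equal(seg$end_idx, 60L)
  expect_equal(seg$length_kb, 2950)
  expect_error(detect_roh(rep(0L, 60), rev(seq_len(60)) * 1000, params),
               "sorted")
})

test_that("detect_roh equals the O(n^2) enumerator on crafted inputs", {
  params <- roh_params(min_snps = 20, min_length_kb = 500,
                       min_density_kb_per_snp = 100, max_gap_kb = 600,
                       max_missing = 3, max_het = 1)
  set.seed(79)
  for (rep in 1:60) {
    n <- 300
    pos <- sort(sample.int(3e7, n))
    calls <- random_roh_calls(n)
    mine <- detect_roh(calls, pos, params)
    oracle <- brute_roh(calls, pos, params)
    expect_identical(seg_matrix(mine$start_idx, mine$end_idx),
                     seg_matrix(oracle[, 1], oracle[, 2]))
  }
})

test_that("relaxing any constraint never shrinks the covered genome", {
  # monotonicity holds for the union of covered base pairs; the summed
  # span can drop when two overlapping maximal runs merge into one, so
  # coverage is the right monotone functional
  covered_bp <- function(seg) {
    if (!nrow(seg)) return(0)
    s <- seg[order(seg$start_bp), ]
    tot <- 0; cur_s <- s$start_bp[1]; cur_e <- s$end_bp[1]
    for (k in seq_len(nrow(s))[-1]) {
      if (s$start_bp[k] > cur_e) {
        tot <- tot + cur_e - cur_s
        cur_s <- s$start_bp[k]; cur_e <- s$end_bp[k]
      } else cur_e <- max(cur_e, s$end_bp[k])
    }
    tot + cur_e - cur_s
  }
  set.seed(83)
  base <- roh_params(min_snps = 25, min_length_kb = 800,
                     min_density_kb_per_snp = 80, max_gap_kb = 400,
                     max_missing = 1, max_het = 0)
  relaxed <- list(
    roh_params(20, 800, 80, 400, 1, 0),
    roh_params(25, 500, 80, 400, 1, 0),
    roh_params(25, 800, 120, 400, 1, 0),
    roh_params(25, 800, 80, 700, 1, 0),
    roh_params(25, 800, 80, 400, 3, 0),
    roh_params(25, 800, 80, 400, 1, 1))
  for (rep in 1:20) {
    n <- 400
    pos <- sort(sample.int(3e7, n))
    calls <- random_roh_calls(n, p_het = 0.05)
    len0 <- covered_bp(detect_roh(calls, pos, base))
    for (p in relaxed)
      expect_gte(covered_bp(detect_roh(calls, pos, p)), len0)
  }
})

test_that("F_ROH arithmetic reproduces the published population means", {
  l_auto <- 2497129 # kb spanned by SNP positions on the 29 autosomes
  seg <- function(kb) data.frame(length_kb = kb)
  expect_equal(round(f_roh(seg(226400), l_auto), 3), 0.091) # BS
  expect_equal(round(f_roh(seg(66200), l_auto), 3), 0.027)  # ER
  expect_equal(round(f_roh(seg(184600), l_auto), 3), 0.074) # BV
  expect_equal(f_roh(seg(numeric(0)), l_auto), 0)
  expect_equal(f_roh(NULL, l_auto), 0)
  # long-ROH variant uses a strict > threshold
  s <- seg(c(4000, 5000, 6000))
  expect_equal(f_roh(s, 10000, min_segment_kb = 5000), 0.6)
  expect_error(f_roh(s, 0), "positive")
})

test_that("F_HOM follows its defining ratio", {
  expect_equal(f_hom(80, 80, 100), 0)
  expect_equal(f_hom(100, 80, 100), 1)
  expect_equal(f_hom(90, 80, 100), 0.5)
  expect_lt(f_hom(70, 80, 100), 0)
  expect_error(f_hom(5, 10, 10), "denominator")
})

test_that("expected homozygosity equals the per-SNP loop oracle", {
  set.seed(89)
  sim <- make_test_panel(seed = 89, k = 1, n = 25, n_snp = 50)
  calls <- sim$geno$calls
  calls[sample(length(calls), 100)] <- NA
  gm <- geno_matrix(calls, sim$geno$map)
  eh <- expected_hom(gm, "POP1_3")
  oracle <- 0
  for (j in seq_len(ncol(calls))) {
    if (is.na(calls["POP1_3", j])) next
    g <- calls[, j][!is.na(calls[, j])]
    n <- length(g); p <- sum(g) / (2 * n)
    oracle <- oracle + 1 - 2 * p * (1 - p) * 2 * n / (2 * n - 1)
  }
  expect_equal(eh, oracle)
  # monomorphic panel: expected hom = number of non-missing calls
  gm0 <- geno_matrix(matrix(0L, 5, 10), sim_map(1, 10))
  expect_equal(expected_hom(gm0, "ind1"), 10)
})

test_that("ROH summaries bin lengths and count carriers correctly", {
  pops <- setNames(rep(c("A", "B"), each = 3), paste0("i", 1:6))
  seg <- data.frame(id = c("i1", "i1", "i2", "i4"),
                    chrom = c(1L, 2L, 1L, 3L),
                    start_bp = 1, end_bp = 2,
                    n_snps = 50,
                    length_kb = c(1200, 7200, 31000, 16000))
  s <- roh_summaries(seg, pops)
  expect_equal(s$per_population$n_without_roh, c(1, 2))
  expect_equal(s$per_population$total_roh, c(3, 1))
  expect_equal(unname(s$length_classes["A", c("1-5", "5-10", ">=30")]),
               c(1L, 1L, 1L))
  expect_equal(unname(s$length_classes["B", "15-20"]), 1L)
  expect_equal(unname(s$per_chromosome["A", "1"]), 2L)
  # population with no segments: all-zero row
  none <- roh_summaries(seg[0, ], pops)
  expect_equal(none$per_population$total_roh, c(0, 0))
  expect_equal(none$per_population$n_without_roh, c(3, 3))
})

test_that("per-SNP ROH incidence equals an interval-stabbing oracle", {
  map <- sim_map(2, 30, 100000)
  pops <- setNames(rep("A", 20), paste0("i", 1:20))
  set.seed(97)
  segs <- do.call(rbind, lapply(1:20, function(k) {
    if (runif(1) < 0.3) return(NULL)
    st <- sample(map$pos_bp, 1)
    data.frame(id = paste0("i", k), chrom = sample(1:2, 1),
               start_bp = st, end_bp = st + 500000, n_snps = 5,
               length_kb = 500)
  }))
  inc <- roh_incidence(segs, map, pops, threshold = 0.25)
  for (r in sample(nrow(inc), 20)) {
    hit <- sum(vapply(unique(segs$id), function(id) {
      s <- segs[segs$id == id & segs$chrom == inc$chrom[r], , drop = FALSE]
      any(s$start_bp <= inc$pos_bp[r] & s$end_bp >= inc$pos_bp[r])
    }, TRUE))
    expect_equal(inc$fraction[r], hit / 20)
    expect_equal(inc$flagged[r], hit / 20 >= 0.25)
  }
  # no segments -> all zero
  inc0 <- roh_incidence(segs[0, ], map, pops)
  expect_true(all(inc0$fraction == 0))
})

test_that("gene-dropped tracts are recovered with high sensitivity", {
  set.seed(101)
  ped <- rbind(sim_pedigree(20, 2, "full_sib_loop", seed = 102,
                            prefix = "FS"),
               sim_pedigree(15, 2, "half_sib_loop", seed = 103,
                            prefix = "HS"))
  map <- sim_map(4, 600, 90000)
  gd <- gene_drop(ped, map, runif(nrow(map), 0.15, 0.85), seed = 104)
  study <- c(grep("FS_G2_", ped$id, value = TRUE),
             grep("HS_G2_", ped$id, value = TRUE))
  gm <- subset_geno(gd$geno, ind = study)
  seg <- detect_roh_all(gm)
  tr <- gd$truth$tracts
  tr <- tr[tr$id %in% study &
             (tr$end_bp - tr$start_bp) > 5e6 & tr$n_snps >= 50, ]
  expect_gt(nrow(tr), 10)
  covered <- vapply(seq_len(nrow(tr)), function(k) {
    s <- seg[seg$id == tr$id[k] & seg$chrom == tr$chrom[k], , drop = FALSE]
    if (!nrow(s)) return(0)
    ov <- pmax(0, pmin(s$end_bp, tr$end_bp[k]) -
                 pmax(s$start_bp, tr$start_bp[k]))
    sum(ov) / (tr$end_bp[k] - tr$start_bp[k])
  }, 0)
  expect_gte(mean(covered >= 0.8), 0.95)
  # per-individual: f_roh_gt5mb <= f_roh always
  inb <- inbreeding_table(gm, seg)
  expect_true(all(inb$f_roh_gt5mb <= inb$f_roh + 1e-12))
})
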