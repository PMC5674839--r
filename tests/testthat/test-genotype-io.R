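test_that("PED/MAP parsing codes calls as minor-allele counts", {
  td <- withr::local_tempdir()
  writeLines(c("1 snp1 0 1000", "1 snp2 0 2000"), file.path(td, "t.map"))
  writeLines(c("FAM1 i1 0 0 0 -9 A A A G",
               "FAM1 i2 0 0 0 -9 A G G G",
               "FAM2 i3 0 0 0 -9 A A G G"),
             file.path(td, "t.ped"))
  x <- read_plink_text(file.path(td, "t.ped"), file.path(td, "t.map"))
  # snp1: alleles A(5) G(1) -> minor G; snp2: A(2) G(4) -> minor A
  expect_equal(unname(x$geno$calls[, 1]), c(0L, 1L, 0L))
  expect_equal(unname(x$geno$calls[, 2]), c(1L, 0L, 0L))
  expect_equal(x$map$allele_b, c("G", "A"))
  expect_equal(unname(x$pops), c("FAM1", "FAM1", "FAM2"))
})

test_that("half-missing genotypes, ragged rows and odd chromosomes", {
  td <- withr::local_tempdir()
  writeLines(c("1 snp1 0 1000", "30 snpX 0 500", "1 snp2 0 2000"),
             file.path(td, "t.map"))
  writeLines(c("F a 0 0 0 -9 A 0 C C G G",
               "F b 0 0 0 -9 A A C C G T"),
             file.path(td, "t.ped"))
  expect_warning(x <- read_plink_text(file.path(td, "t.ped"),
                                      file.path(td, "t.map")),
                 "non-autosomal")
  expect_equal(nrow(x$map), 2L) # snpX skipped
  expect_true(is.na(x$geno$calls[1, 1])) # one "0" allele -> whole call NA
  writeLines(c("F a 0 0 0 -9 A A"), file.path(td, "bad.ped"))
  expect_error(suppressWarnings(read_plink_text(file.path(td, "bad.ped"),
                                                file.path(td, "t.map"))),
               "line 1")
})

test_that("write + re-read round trip is the identity on files", {
  set.seed(7)
  sim <- make_test_panel(seed = 7, k = 2, n = 10, n_snp = 50)
  calls <- sim$geno$calls
  calls[sample(length(calls), 30)] <- NA
  gm <- geno_matrix(calls, sim$geno$map)
  td <- withr::local_tempdir()
  p1 <- file.path(td, "a.ped"); m1 <- file.path(td, "a.map")
  write_plink_text(gm, sim$pops, p1, m1)
  r1 <- read_plink_text(p1, m1)
  p2 <- file.path(td, "b.ped"); m2 <- file.path(td, "b.map")
  write_plink_text(r1$geno, r1$pops, p2, m2)
  r2 <- read_plink_text(p2, m2)
  expect_identical(r2$geno$calls, r1$geno$calls)
  expect_identical(r2$map, r1$map)
  expect_identical(r2$pops, r1$pops)
  # genotype content preserved from the original up to allele relabelling
  expect_identical(is.na(r1$geno$calls), is.na(gm$calls))
  expect_identical(r1$geno$calls == 1L, gm$calls == 1L)
})

test_that("missing calls are written as 0 0 and empty panels are valid", {
  map <- snp_map("s1", 1L, 100L, "A", "G")
  gm <- geno_matrix(matrix(NA_integer_, 1, 1, dimnames = list("x", NULL)),
                    map)
  td <- withr::local_tempdir()
  write_plink_text(gm, c(x = "P"), file.path(td, "m.ped"),
                   file.path(td, "m.map"))
  expect_match(readLines(file.path(td, "m.ped")), "0 0$")
  gm0 <- geno_matrix(matrix(integer(0), 0, 1), map)
  write_plink_text(gm0, character(0), file.path(td, "e.ped"),
                   file.path(td, "e.map"))
  expect_length(readLines(file.path(td, "e.ped")), 0)
  expect_length(readLines(file.path(td, "e.map")), 1)
})

test_that("intersect_panels equals brute-force set intersection", {
  m <- function(ids, pos) snp_map(ids, rep(1L, length(ids)), pos)
  a <- m(c("a", "b", "c"), c(10, 20, 30))
  b <- m(c("b", "c", "d"), c(20, 30, 40))
  expect_equal(intersect_panels(list(a))$snp_id, a$snp_id)
  expect_equal(intersect_panels(list(a, b))$snp_id, c("b", "c"))
  set.seed(1)
  maps <- lapply(1:4, function(i) {
    ids <- sort(sample(100, 60))
    m(paste0("s", ids), ids * 1000)
  })
  common <- Reduce(intersect, lapply(maps, `[[`, "snp_id"))
  expect_setequal(intersect_panels(maps)$snp_id, common)
  # conflicting coordinates are a hard error
  conflict <- m(c("b", "c"), c(21, 30))
  expect_error(intersect_panels(list(a, conflict)), "conflicting")
})

test_that("call-rate filter equals a per-SNP loop oracle", {
  set.seed(3)
  sim <- make_test_panel(seed = 3, k = 1, n = 20, n_snp = 200,
                         divergence = 0)
  calls <- sim$geno$calls
  calls[sample(length(calls), 500)] <- NA
  gm <- geno_matrix(calls, sim$geno$map)
  keep <- filter_call_rate(gm, 0.1)
  oracle <- vapply(seq_len(ncol(calls)),
                   function(j) sum(is.na(calls[, j])) / nrow(calls) <= 0.1,
                   TRUE)
  expect_identical(unname(keep), oracle)
  # boundary: exactly at the threshold is kept
  calls2 <- matrix(c(rep(0L, 18), NA, NA), 20, 1)
  expect_true(filter_call_rate(geno_matrix(calls2, sim$geno$map[1, ]), 0.1))
})

test_that("HWE exact test matches enumeration and is label-symmetric", {
  expect_equal(hwe_exact_test(10, 0, 0), 1.0)
  # brute-force enumeration for (3,1,3): 7 copies of rarer allele over
  # 7 individuals -> het counts {1,3,5,7}
  hets <- c(1, 3, 5, 7)
  probs <- vapply(hets, function(h) {
    nbb <- (7 - h) / 2; naa <- 7 - h - nbb
    # P(het = h | allele counts) proportional to 2^h / (naa! h! nbb!)
    exp(h * log(2) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb))
  }, 0)
  probs <- probs / sum(probs)
  expected <- sum(probs[probs <= probs[1] + 1e-15])
  expect_equal(hwe_exact_test(3, 1, 3), expected, tolerance = 1e-12)
  for (cfg in list(c(5, 2, 1), c(12, 7, 3), c(0, 4, 9))) {
    expect_equal(hwe_exact_test(cfg[1], cfg[2], cfg[3]),
                 hwe_exact_test(cfg[3], cfg[2], cfg[1]))
  }
  expect_error(hwe_exact_test(0, 0, 0), "no genotype data")
})

test_that("HWE conditional probabilities sum to 1 for totals <= 200", {
  for (n in c(5, 37, 100)) {
    for (nr in c(1, 2, n %/% 2, n)) {
      p <- herdscan:::hwe_het_probs(n, nr)
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
})

test_that("per-population filter equals a literal double-loop oracle", {
  set.seed(9)
  map <- sim_map(2, 250, 90000)
  sim <- simulate_panel(map, data.frame(label = c("A", "B", "C"),
                                        divergence_F = c(0.02, 0.1, 0.2),
                                        n = 15), seed = 9)
  calls <- sim$geno$calls
  calls[sample(length(calls), 800)] <- NA
  gm <- geno_matrix(calls, map)
  res <- per_population_filter(gm, sim$pops, maf_min = 0.05,
                               hwe_alpha = 0.01)
  oracle <- rep(TRUE, ncol(calls))
  for (j in seq_len(ncol(calls))) {
    for (lab in c("A", "B", "C")) {
      g <- calls[sim$pops == lab, j]
      g <- g[!is.na(g)]
      if (!length(g)) { oracle[j] <- FALSE; break }
      p <- sum(g) / (2 * length(g))
      if (min(p, 1 - p) < 0.05) { oracle[j] <- FALSE; break }
      if (hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2)) < 0.01) {
        oracle[j] <- FALSE; break
      }
    }
  }
  expect_identical(unname(res$keep), oracle)
  expect_true(all(res$report$status[res$keep] == "kept"))
  expect_true(all(!is.na(res$report$reason[!res$keep])))
})

test_that("QC stages are ordered and the final set is a subset of both", {
  set.seed(5)
  sim <- make_test_panel(seed = 5, k = 2, n = 20, n_snp = 300)
  calls <- sim$geno$calls
  calls[sample(length(calls), 900)] <- NA
  gm <- geno_matrix(calls, sim$geno$map)
  qc <- run_qc(gm, sim$pops, geno = 0.1, maf = 0.05, hwe = 0.001)
  expect_true(qc$counts["n_after_callrate"] <= qc$counts["n_input"])
  expect_true(qc$counts["n_after_per_population"] <=
                qc$counts["n_after_callrate"])
  expect_equal(sort(table(qc$qc_report$status))[["kept"]],
               unname(qc$counts["n_after_per_population"]))
  kept1 <- gm$map$snp_id[filter_call_rate(gm, 0.1)]
  expect_true(all(qc$geno$map$snp_id %in% kept1))
  expect_equal(nrow(qc$qc_report), ncol(gm$calls)) # every SNP exactly once
})
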