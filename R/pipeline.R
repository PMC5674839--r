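## One-config orchestration of the full chain:
## qc -> structure -> roh/inbreeding -> selection scan, with deterministic
## per-stage seeds, TSV outputs and a JSON run manifest.

default_config <- function() {
  list(
    stages = list(qc = TRUE, structure = TRUE, roh = TRUE,
                  inbreed = TRUE, scan = TRUE),
    qc = list(geno = 0.1, maf = 0.01, hwe = 1e-4),
    structure = list(mds_dims = 2, n_boot = 1000),
    roh = list(min_snps = 50, min_length_kb = 1000,
               min_density_kb_per_snp = 100, max_gap_kb = 1800,
               max_missing = 2, max_het = 0, long_kb = 5000,
               incidence_threshold = 0.25),
    scan = list(window_mb = 1, min_snps = 4, percentile = 99,
                pool = NULL),
    seed = 1L)
}

merge_config <- function(user, base = default_config()) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && k %in% names(base) && is.list(base[[k]]))
      base[[k]] <- merge_config(user[[k]], base[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages run in fixed order qc, structure, roh, inbreed, scan; each stage
#' can be toggled in `config$stages`. Every stochastic stage receives a
#' seed derived deterministically from `config$seed`, so identical
#' config + inputs reproduce identical outputs. A JSON manifest records
#' parameters, seeds, input checksums and the row counts of every output.
#'
#' @param ped,map_file,pops_file paths: PLINK text PED/MAP and a two-column
#'   TSV (id, population). The PED family column is used when `pops_file`
#'   is `NULL`.
#' @param pedigree_file optional three-column TSV (id, sire, dam).
#' @param out_dir output directory (created).
#' @param config nested list of stage parameters; defaults are the
#'   settings of a 50k-density cattle analysis (geno 0.1, maf 0.01,
#'   hwe 1e-4, 50-SNP/1-Mb/100-kb/1800-kb ROH rules, 1-Mb windows, >= 4
#'   SNPs, 99th percentile). Partial lists are merged over the defaults.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(ped, map_file, pops_file = NULL,
                         pedigree_file = NULL, out_dir, config = list()) {
  cfg <- merge_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, inputs = list(), outputs = list())
  for (f in c(ped = ped, map = map_file, pops = pops_file,
              pedigree = pedigree_file))
    manifest$inputs[[f]] <- unname(tools::md5sum(f))

  dat <- read_plink_text(ped, map_file)
  gm <- dat$geno
  pops <- dat$pops
  if (!is.null(pops_file)) {
    pt <- read.table(pops_file, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    pops <- setNames(pt[[2]], pt[[1]])
  }
  pedigree <- NULL
  if (!is.null(pedigree_file))
    pedigree <- read.table(pedigree_file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("id", "sire", "dam"),
                           na.strings = c("NA", "0"))

  note <- function(name, df) {
    manifest$outputs[[name]] <<- nrow(df)
    write_tsv(df, file.path(out_dir, name))
  }

  if (isTRUE(cfg$stages$qc)) {
    qc <- run_qc(gm, pops, geno = cfg$qc$geno, maf = cfg$qc$maf,
                 hwe = cfg$qc$hwe)
    gm <- qc$geno
    note("qc_report.tsv", qc$qc_report)
    manifest$qc_counts <- as.list(qc$counts)
  }

  rel <- NULL
  if (isTRUE(cfg$stages$structure)) {
    rel <- ibd_moments(gm)
    note("relationships.tsv", rel)
    mds <- classical_mds(ibs_distance(gm), cfg$structure$mds_dims)
    note("mds.tsv", data.frame(id = rownames(mds), pop = pops[rownames(mds)],
                               mds, stringsAsFactors = FALSE))
    labs <- unique(pops)
    fst_rows <- list()
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (i >= j) next
      ci <- bootstrap_fst_ci(gm, pops, labs[i], labs[j],
                             n_boot = cfg$structure$n_boot,
                             seed = cfg$seed + 1000L * i + j)
      fst_rows[[length(fst_rows) + 1L]] <-
        data.frame(pop_a = labs[i], pop_b = labs[j], fst = ci["fst"],
                   ci_low = ci["ci_low"], ci_high = ci["ci_high"])
    }
    note("fst_pairs.tsv", do.call(rbind, fst_rows))
    if (length(labs) >= 3) {
      tree <- neighbor_joining(fst_matrix(gm, pops))
      write_newick(tree, file.path(out_dir, "nj_tree.nwk"))
      manifest$outputs[["nj_tree.nwk"]] <- length(tree$tip.label)
    }
  }

  segments <- NULL
  if (isTRUE(cfg$stages$roh)) {
    params <- roh_params(min_snps = cfg$roh$min_snps,
                         min_length_kb = cfg$roh$min_length_kb,
                         min_density_kb_per_snp = cfg$roh$min_density_kb_per_snp,
                         max_gap_kb = cfg$roh$max_gap_kb,
                         max_missing = cfg$roh$max_missing,
                         max_het = cfg$roh$max_het)
    segments <- detect_roh_all(gm, params)
    note("roh_segments.tsv", segments)
    summ <- roh_summaries(segments, pops)
    note("roh_summary.tsv", summ$per_population)
    inc <- roh_incidence(segments, gm$map, pops,
                         threshold = cfg$roh$incidence_threshold)
    note("roh_incidence.tsv", inc[inc$flagged, , drop = FALSE])
  }

  if (isTRUE(cfg$stages$inbreed)) {
    if (is.null(segments))
      stop("inbreed stage requires the roh stage (toggled off)")
    inb <- inbreeding_table(gm, segments, pedigree,
                            long_kb = cfg$roh$long_kb)
    inb$pop <- unname(pops[inb$id])
    note("inbreeding.tsv", inb)
    if (!is.null(pedigree)) {
      cmp <- rbind(
        data.frame(comparison = "f_ped~f_roh",
                   t(compare_inbreeding(inb, "f_roh"))),
        data.frame(comparison = "f_ped~f_hom",
                   t(compare_inbreeding(inb, "f_hom"))))
      note("inbreeding_comparison.tsv", cmp)
    }
  }

  if (isTRUE(cfg$stages$scan)) {
    spops <- pops
    if (!is.null(cfg$scan$pool))
      spops <- pool_populations(spops, cfg$scan$pool)
    scan <- selection_scan(gm, spops, window_mb = cfg$scan$window_mb,
                           min_snps = cfg$scan$min_snps,
                           percentile = cfg$scan$percentile)
    wtab <- do.call(rbind, lapply(names(scan$windows), function(lab) {
      w <- scan$windows[[lab]]
      w$population <- lab
      w
    }))
    note("scan_windows.tsv", wtab)
    note("scan_classification.tsv", scan$classification$windows)
    manifest$scan_counts <- as.list(scan$classification$counts)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Summary tables across pipeline outputs
#'
#' Per-population means and SDs of heterozygosity, genomic relationship,
#' ROH counts and lengths and all inbreeding coefficients — the structure
#' of a standard multi-population diversity report.
#'
#' @param gm a [geno_matrix()] (post-QC).
#' @param pops population assignment.
#' @param segments output of [detect_roh_all()].
#' @param inbreeding output of [inbreeding_table()].
#' @param relationships optional output of [ibd_moments()].
#' @return A list of data.frames: `diversity`, `roh`, `inbreeding`.
#' @export
summarize_tables <- function(gm, pops, segments, inbreeding,
                             relationships = NULL) {
  pops <- check_pops(gm, pops)
  div <- diversity_summary(gm, pops, relationships)
  roh <- roh_summaries(segments, pops)$per_population
  labs <- unique(pops)
  stat <- function(x) if (length(x)) c(mean(x), if (length(x) > 1) sd(x)
                                       else 0) else c(NA, NA)
  inb <- do.call(rbind, lapply(labs, function(lab) {
    x <- inbreeding[pops[inbreeding$id] == lab, , drop = FALSE]
    row <- data.frame(population = lab, n = nrow(x))
    for (col in intersect(c("pci_5g", "f_ped", "f_hom", "f_roh",
                            "f_roh_gt5mb"), names(x))) {
      s <- stat(x[[col]][is.finite(x[[col]])])
      row[[paste0("mean_", col)]] <- s[1]
      row[[paste0("sd_", col)]] <- s[2]
    }
    row
  }))
  list(diversity = div, roh = roh, inbreeding = inb)
}
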