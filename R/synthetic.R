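## Synthetic multi-population genotype panels and pedigrees with known truth:
## Balding-Nichols allele-frequency divergence, gene-dropping down a pedigree
## with Haldane recombination, and founder-allele labelling so that true
## autozygous tracts are observable, not inferred.

#' Build an evenly spaced SNP map
#'
#' Lays `n_snps_per_chrom` SNPs per chromosome at constant spacing, emulating
#' a medium-density array (the default spacing of 90 kb matches a 50k-class
#' bovine panel).
#'
#' @param n_chromosomes number of autosomes (default 29).
#' @param n_snps_per_chrom SNPs per chromosome.
#' @param spacing_bp distance between adjacent SNPs (default 90000).
#' @param start_bp position of the first SNP (default `spacing_bp`).
#' @return A [snp_map()].
#' @export
sim_map <- function(n_chromosomes = 29, n_snps_per_chrom = 100,
                    spacing_bp = 90000, start_bp = spacing_bp) {
  pos <- start_bp + spacing_bp * (seq_len(n_snps_per_chrom) - 1L)
  snp_map(snp_id = paste0("chr", rep(seq_len(n_chromosomes),
                                     each = n_snps_per_chrom),
                          "_snp", rep(seq_len(n_snps_per_chrom),
                                      n_chromosomes)),
          chrom = rep(seq_len(n_chromosomes), each = n_snps_per_chrom),
          pos_bp = rep(pos, n_chromosomes))
}

#' Balding-Nichols population allele frequencies
#'
#' Draws ancestral frequencies from Uniform(0.05, 0.95) (bounded away from
#' fixation so post-QC SNP loss stays small) and, for divergence `F > 0`,
#' population frequencies from Beta(p(1-F)/F, (1-p)(1-F)/F). `F` is the
#' drift-level F_ST of the population relative to the ancestral pool.
#'
#' @param n_snps number of SNPs.
#' @param divergence_F drift parameter in `[0, 1)`.
#' @param seed optional integer seed.
#' @param ancestral optional vector of ancestral frequencies to reuse across
#'   populations; drawn if `NULL`.
#' @return A list with `ancestral` and `pop` frequency vectors.
#' @export
balding_nichols_freqs <- function(n_snps, divergence_F, seed = NULL,
                                  ancestral = NULL) {
  if (divergence_F < 0 || divergence_F >= 1)
    stop("divergence_F must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ancestral)) ancestral <- runif(n_snps, 0.05, 0.95)
  if (divergence_F == 0) {
    pop <- ancestral
  } else {
    k <- (1 - divergence_F) / divergence_F
    pop <- rbeta(n_snps, ancestral * k, (1 - ancestral) * k)
  }
  list(ancestral = ancestral, pop = pop)
}

#' Simulate a multi-population genotype panel
#'
#' Each population's allele frequencies are drawn by [balding_nichols_freqs()]
#' around one shared ancestral frequency vector; genotypes are then sampled
#' in Hardy-Weinberg proportions within populations.
#'
#' @param map a [snp_map()].
#' @param populations data.frame with columns `label`, `divergence_F`, `n`.
#' @param seed integer seed (mandatory: runs must be reproducible).
#' @param ancestral optional ancestral frequency vector.
#' @return A list: `geno` ([geno_matrix()]), `pops` (named assignment),
#'   `truth` (list with `ancestral` and `population_freqs`, a matrix
#'   populations x SNPs).
#' @export
simulate_panel <- function(map, populations, seed, ancestral = NULL) {
  set.seed(seed)
  n_snp <- nrow(map)
  if (is.null(ancestral)) ancestral <- runif(n_snp, 0.05, 0.95)
  calls <- NULL; ids <- character(0); pop_vec <- character(0)
  freqs <- matrix(NA_real_, nrow(populations), n_snp,
                  dimnames = list(populations$label, map$snp_id))
  for (i in seq_len(nrow(populations))) {
    bn <- balding_nichols_freqs(n_snp, populations$divergence_F[i],
                                ancestral = ancestral)
    freqs[i, ] <- bn$pop
    n <- populations$n[i]
    g <- matrix(rbinom(n * n_snp, 2, rep(bn$pop, each = n)), n, n_snp)
    calls <- rbind(calls, g)
    ids <- c(ids, paste0(populations$label[i], "_", seq_len(n)))
    pop_vec <- c(pop_vec, rep(populations$label[i], n))
  }
  rownames(calls) <- ids
  list(geno = geno_matrix(calls, map),
       pops = setNames(pop_vec, ids),
       truth = list(ancestral = ancestral, population_freqs = freqs))
}

#' Simulate a pedigree with controllable inbreeding loops
#'
#' Builds repeated family units `n_generations` deep. Under `"random"`
#' mating the whole previous generation is paired at random (near-zero
#' inbreeding at shallow depth). `"full_sib_loop"` units start from two
#' founders and mate two full sibs of the latest litter in every subsequent
#' generation (first looped offspring: F = 0.25, deepening thereafter).
#' `"half_sib_loop"` units start from one sire and two dams, mate the two
#' half-sib offspring (F = 0.125), then continue with full-sib loops.
#'
#' @param n_founders founder count: even for "random"/"full_sib_loop",
#'   a multiple of 3 for "half_sib_loop".
#' @param n_generations generations below the founders (>= 1).
#' @param scheme one of "random", "full_sib_loop", "half_sib_loop".
#' @param litter offspring per mating pair (default 2).
#' @param seed integer seed.
#' @param prefix id prefix.
#' @return data.frame(id, sire, dam) with `NA` for unknown founder parents;
#'   parents precede offspring.
#' @export
sim_pedigree <- function(n_founders, n_generations,
                         scheme = c("random", "full_sib_loop",
                                    "half_sib_loop"),
                         litter = 2, seed = NULL, prefix = "P") {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  counter <- 0L
  new_id <- function(g) {
    counter <<- counter + 1L
    paste0(prefix, "_G", g, "_", counter)
  }
  add <- function(id, sire, dam) {
    rows[[length(rows) + 1L]] <<- data.frame(id = id, sire = sire, dam = dam,
                                             stringsAsFactors = FALSE)
  }
  mate <- function(s, d, g) {
    kids <- vapply(seq_len(litter), function(i) new_id(g), "")
    for (k in kids) add(k, s, d)
    kids
  }
  if (scheme == "random") {
    if (n_founders %% 2 != 0) stop("n_founders must be even")
    gen <- vapply(seq_len(n_founders), function(i) new_id(0), "")
    for (f in gen) add(f, NA_character_, NA_character_)
    for (g in seq_len(n_generations)) {
      pool <- sample(gen)
      gen <- character(0)
      k <- 1
      while (k + 1 <= length(pool)) {
        gen <- c(gen, mate(pool[k], pool[k + 1], g))
        k <- k + 2
      }
    }
  } else if (scheme == "full_sib_loop") {
    if (n_founders %% 2 != 0) stop("n_founders must be even")
    for (u in seq_len(n_founders / 2)) {
      s <- new_id(0); d <- new_id(0)
      add(s, NA_character_, NA_character_)
      add(d, NA_character_, NA_character_)
      lit <- c(s, d)
      for (g in seq_len(n_generations)) lit <- mate(lit[1], lit[2], g)
    }
  } else { # half_sib_loop
    if (n_founders %% 3 != 0) stop("n_founders must be a multiple of 3")
    for (u in seq_len(n_founders / 3)) {
      s <- new_id(0); d1 <- new_id(0); d2 <- new_id(0)
      for (f in c(s, d1, d2)) add(f, NA_character_, NA_character_)
      c1 <- mate(s, d1, 1)[1]
      c2 <- mate(s, d2, 1)[1]
      lit <- c(c1, c2)
      for (g in seq_len(max(0, n_generations - 1)) + 1)
        lit <- mate(lit[1], lit[2], g)
    }
  }
  do.call(rbind, rows)
}

## topological order of a pedigree; error on cycles
pedigree_order <- function(ped) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire]) # NA = unknown or out-of-pedigree parent
  di <- unname(idx[ped$dam])
  placed <- rep(FALSE, n)
  order_out <- integer(0)
  repeat {
    ready <- !placed & (is.na(si) | placed[pmax(si, 1L)] & !is.na(si)) &
      (is.na(di) | placed[pmax(di, 1L)] & !is.na(di))
    if (!any(ready)) break
    order_out <- c(order_out, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed))
    stop("pedigree contains a cycle involving: ",
         paste(ped$id[!placed], collapse = ", "))
  order_out
}

#' Gene-drop genotypes down a pedigree
#'
#' Founders receive two haplotypes drawn per SNP from `founder_freqs`; each
#' transmitted gamete is a recombination mosaic of the parent's two
#' haplotypes under a Haldane model (crossover count Poisson with mean
#' `recomb_rate` cM/Mb x length / 100, positions uniform, no interference).
#' Every founder haplotype carries a unique label, so tracts where an
#' individual's two haplotypes descend from the same founder haplotype — the
#' truly autozygous tracts — are reported exactly.
#'
#' Individuals must have both parents known or both unknown (unknowns are
#' founders). Parents must precede offspring; the pedigree must be acyclic.
#'
#' @param pedigree data.frame(id, sire, dam); `NA` or `"0"` = unknown.
#' @param map a [snp_map()].
#' @param founder_freqs frequency of the counted allele per SNP: a vector, or
#'   a matrix with one row per founder population plus a `founder_pop` vector.
#' @param recomb_rate cM per Mb (default 1).
#' @param seed integer seed.
#' @param founder_pop optional named vector founder id -> row of
#'   `founder_freqs`.
#' @return A list: `geno` ([geno_matrix()]), `truth` with `tracts`
#'   (data.frame id, chrom, start_bp, end_bp over SNP spans),
#'   `autozygous_fraction` (per-SNP fraction of the genome IBD, per
#'   individual) and `f_ped` (Wright's coefficient from the same pedigree).
#' @export
gene_drop <- function(pedigree, map, founder_freqs, recomb_rate = 1,
                      seed = NULL, founder_pop = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ped <- pedigree
  ped$sire[ped$sire %in% c("0", "")] <- NA
  ped$dam[ped$dam %in% c("0", "")] <- NA
  one_parent <- xor(is.na(ped$sire), is.na(ped$dam))
  if (any(one_parent))
    stop("individuals with exactly one known parent: ",
         paste(ped$id[one_parent], collapse = ", "))
  absent <- setdiff(c(ped$sire, ped$dam), c(ped$id, NA))
  if (length(absent))
    stop("parents not present in pedigree: ", paste(absent, collapse = ", "))
  ord <- pedigree_order(ped)
  ped <- ped[ord, , drop = FALSE]

  n_ind <- nrow(ped)
  n_snp <- nrow(map)
  founder <- is.na(ped$sire)
  n_f <- sum(founder)
  # founder haplotype alleles: one row per founder haplotype
  if (is.matrix(founder_freqs)) {
    if (is.null(founder_pop)) stop("founder_pop required with a freq matrix")
    fp <- founder_pop[ped$id[founder]]
    fr <- founder_freqs[fp, , drop = FALSE]
  } else {
    fr <- matrix(rep(founder_freqs, each = n_f), n_f, n_snp)
  }
  hap_alleles <- matrix(0L, 2L * n_f, n_snp)
  for (k in seq_len(n_f)) {
    hap_alleles[2L * k - 1L, ] <- rbinom(n_snp, 1L, fr[k, ])
    hap_alleles[2L * k, ] <- rbinom(n_snp, 1L, fr[k, ])
  }

  chrom_idx <- split(seq_len(n_snp), map$chrom)
  chrom_pos <- lapply(chrom_idx, function(i) map$pos_bp[i])
  chrom_len <- vapply(chrom_pos, function(p) max(p) - min(p) + 1, 0)

  anc1 <- matrix(NA_integer_, n_ind, n_snp)
  anc2 <- matrix(NA_integer_, n_ind, n_snp)
  rownames(anc1) <- rownames(anc2) <- ped$id
  f_counter <- 0L
  row_of <- setNames(seq_len(n_ind), ped$id)

  meiosis <- function(h1, h2) {
    out <- integer(n_snp)
    for (c in seq_along(chrom_idx)) {
      i <- chrom_idx[[c]]
      pos <- chrom_pos[[c]]
      n_x <- rpois(1, recomb_rate * chrom_len[c] / 1e6 / 100)
      phase <- sample(0:1, 1)
      if (n_x > 0) {
        xo <- sort(runif(n_x, min(pos), max(pos)))
        phase <- (phase + findInterval(pos, xo)) %% 2
      }
      out[i] <- ifelse(phase == 0, h1[i], h2[i])
    }
    out
  }

  for (r in seq_len(n_ind)) {
    if (founder[r]) {
      f_counter <- f_counter + 1L
      anc1[r, ] <- 2L * f_counter - 1L
      anc2[r, ] <- 2L * f_counter
    } else {
      s <- row_of[ped$sire[r]]; d <- row_of[ped$dam[r]]
      anc1[r, ] <- meiosis(anc1[s, ], anc2[s, ])
      anc2[r, ] <- meiosis(anc1[d, ], anc2[d, ])
    }
  }

  take <- cbind(as.vector(anc1), rep(seq_len(n_snp), each = n_ind))
  calls <- matrix(hap_alleles[take], n_ind, n_snp) +
    matrix(hap_alleles[cbind(as.vector(anc2),
                             rep(seq_len(n_snp), each = n_ind))], n_ind, n_snp)
  rownames(calls) <- ped$id

  auto <- anc1 == anc2
  tracts <- autozygous_tracts(auto, map, chrom_idx)
  list(geno = geno_matrix(calls, map),
       truth = list(tracts = tracts,
                    autozygous_fraction = rowMeans(auto),
                    f_ped = pedigree_inbreeding(ped)))
}

## runs of TRUE in the autozygosity indicator, reported as SNP-position spans
autozygous_tracts <- function(auto, map, chrom_idx) {
  out <- list()
  for (r in seq_len(nrow(auto))) {
    for (c in seq_along(chrom_idx)) {
      i <- chrom_idx[[c]]
      x <- auto[r, i]
      if (!any(x)) next
      rl <- rle(x)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      w <- which(rl$values)
      if (!length(w)) next
      out[[length(out) + 1L]] <- data.frame(
        id = rownames(auto)[r],
        chrom = map$chrom[i[1]],
        start_bp = map$pos_bp[i[starts[w]]],
        end_bp = map$pos_bp[i[ends[w]]],
        n_snps = rl$lengths[w],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(id = character(0), chrom = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0)))
  do.call(rbind, out)
}

#' Cross two populations of an existing panel
#'
#' Draws each offspring by sampling one gamete from a random individual of
#' each parent population (per SNP: a homozygote transmits its allele, a
#' heterozygote transmits either with probability 1/2). Emulates an F1
#' crossbred population.
#'
#' @param gm parent [geno_matrix()].
#' @param pops population assignment for `gm`.
#' @param label label for the offspring.
#' @param parent_a,parent_b labels of the two parent populations.
#' @param n_offspring number of crossbred individuals; 0 returns an empty
#'   matrix.
#' @param seed integer seed.
#' @return A list: `geno` (a [geno_matrix()] of only the offspring) and
#'   `pops` for them.
#' @export
make_cross <- function(gm, pops, label, parent_a, parent_b, n_offspring,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- check_pops(gm, pops)
  for (p in c(parent_a, parent_b))
    if (!p %in% pops) stop("unknown parent population: ", p)
  n_snp <- ncol(gm$calls)
  ia <- which(pops == parent_a); ib <- which(pops == parent_b)
  calls <- matrix(NA_integer_, n_offspring, n_snp)
  gamete <- function(g) {
    out <- g / 2L
    het <- which(!is.na(g) & g == 1L)
    out[het] <- rbinom(length(het), 1L, 0.5)
    as.integer(round(out))
  }
  for (k in seq_len(n_offspring)) {
    calls[k, ] <- gamete(gm$calls[sample(ia, 1), ]) +
      gamete(gm$calls[sample(ib, 1), ])
  }
  if (n_offspring > 0)
    rownames(calls) <- paste0(label, "_", seq_len(n_offspring))
  list(geno = geno_matrix(calls, gm$map),
       pops = setNames(rep(label, n_offspring), rownames(calls)))
}
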