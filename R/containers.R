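## Core containers: a SNP map, a coded genotype matrix, and a population
## assignment. Kept as light S3 wrappers around base structures so that
## data.frame/matrix idioms keep working.

N_AUTOSOMES <- 29L

#' Construct a SNP map
#'
#' A SNP map holds the marker coordinates of a panel: one row per SNP with a
#' unique identifier, an autosome index (1--29, the bovine autosomes), a
#' 1-based physical position and the two allele labels. Allele `a` is the
#' major allele, allele `b` the minor allele whose copies the genotype matrix
#' counts.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chrom integer autosome index in `1:29`.
#' @param pos_bp integer base-pair position (>= 1); positions must be strictly
#'   increasing within a chromosome.
#' @param allele_a,allele_b single-character allele labels (major, minor).
#' @return A `data.frame` of class `snp_map` with the five columns above.
#' @examples
#' snp_map(c("s1", "s2"), c(1L, 1L), c(1000L, 2000L), c("A", "C"), c("G", "T"))
#' @export
snp_map <- function(snp_id, chrom, pos_bp,
                    allele_a = rep("A", length(snp_id)),
                    allele_b = rep("B", length(snp_id))) {
  m <- data.frame(snp_id = as.character(snp_id),
                  chrom = as.integer(chrom),
                  pos_bp = as.integer(pos_bp),
                  allele_a = as.character(allele_a),
                  allele_b = as.character(allele_b),
                  stringsAsFactors = FALSE)
  class(m) <- c("snp_map", "data.frame")
  validate_snp_map(m)
}

validate_snp_map <- function(m) {
  stopifnot(is.data.frame(m),
            all(c("snp_id", "chrom", "pos_bp") %in% names(m)))
  if (anyDuplicated(m$snp_id))
    stop("duplicated snp_id: ", paste(unique(m$snp_id[duplicated(m$snp_id)]),
                                      collapse = ", "))
  if (any(m$chrom < 1L | m$chrom > N_AUTOSOMES))
    stop("chrom outside 1..", N_AUTOSOMES)
  if (any(m$pos_bp < 1L)) stop("pos_bp must be >= 1")
  for (ch in unique(m$chrom)) {
    p <- m$pos_bp[m$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  m
}

#' Construct a genotype matrix
#'
#' Genotypes are coded as the number of copies of the minor allele
#' (`allele_b` in the map): 0, 1 or 2, with `NA` for missing calls. Rows are
#' individuals, columns SNPs; column order follows the map.
#'
#' @param calls integer matrix (individuals x SNPs) with values in
#'   `{0, 1, 2, NA}`; rownames are individual ids.
#' @param map a [snp_map()] with one row per column of `calls`.
#' @return A list of class `geno_matrix` with elements `calls` and `map`.
#' @export
geno_matrix <- function(calls, map) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(map))
    stop("calls has ", ncol(calls), " columns but map has ", nrow(map), " SNPs")
  bad <- calls[!is.na(calls)]
  if (length(bad) && any(bad < 0L | bad > 2L))
    stop("non-missing calls must be 0, 1 or 2")
  if (is.null(rownames(calls)) && nrow(calls) > 0)
    rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  colnames(calls) <- map$snp_id
  structure(list(calls = calls, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$calls), "individuals x", ncol(x$calls), "SNPs on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  cat("missing rate:", format(mean(is.na(x$calls)), digits = 3), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

individuals <- function(gm) rownames(gm$calls)

#' Subset a genotype matrix
#'
#' @param gm a [geno_matrix()].
#' @param ind individual selector (indices, logical, or ids); default all.
#' @param snp SNP selector (indices, logical, or snp ids); default all.
#' @return A `geno_matrix` restricted to the selection.
#' @export
subset_geno <- function(gm, ind = NULL, snp = NULL) {
  calls <- gm$calls
  map <- gm$map
  if (!is.null(ind)) {
    if (is.character(ind)) ind <- match(ind, rownames(calls))
    calls <- calls[ind, , drop = FALSE]
  }
  if (!is.null(snp)) {
    if (is.character(snp)) snp <- match(snp, map$snp_id)
    calls <- calls[, snp, drop = FALSE]
    map <- map[snp, , drop = FALSE]
    class(map) <- c("snp_map", "data.frame")
  }
  geno_matrix(calls, map)
}

## population assignment: named character vector individual id -> label
check_pops <- function(gm, pops) {
  ids <- individuals(gm)
  if (!length(ids)) return(setNames(character(0), character(0)))
  if (is.null(names(pops))) stop("population assignment must be named by id")
  miss <- setdiff(ids, names(pops))
  if (length(miss))
    stop("individuals without population label: ",
         paste(utils::head(miss, 5), collapse = ", "))
  pops[ids]
}

#' Pool populations under a single label
#'
#' Relabels the listed populations with one shared label, e.g. to analyse two
#' small closely related populations as a single group in the selection scan.
#'
#' @param pops named character vector mapping individual id to population.
#' @param members character vector of labels to merge.
#' @param label replacement label (default the members joined with "/").
#' @return The relabelled assignment vector.
#' @export
pool_populations <- function(pops, members,
                             label = paste(members, collapse = "/")) {
  pops[pops %in% members] <- label
  pops
}
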