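## Pedigree-based inbreeding: Wright's coefficient via the additive
## (numerator) relationship recursion, and the five-generation pedigree
## completeness index.

#' Pedigree inbreeding coefficients
#'
#' Wright's F for every individual: the kinship between its parents, computed
#' by the tabular (numerator-relationship) recursion. Founders and
#' individuals with an unknown parent get F = 0; unknown-parent individuals
#' are treated as founders. The pedigree must be acyclic (a cycle is an
#' error naming the individuals involved).
#'
#' @param pedigree data.frame(id, sire, dam); `NA` or `"0"` = unknown.
#' @return Named numeric vector of inbreeding coefficients.
#' @export
pedigree_inbreeding <- function(pedigree) {
  ped <- pedigree
  ped$sire[ped$sire %in% c("0", "")] <- NA
  ped$dam[ped$dam %in% c("0", "")] <- NA
  ped$sire[!ped$sire %in% ped$id] <- NA
  ped$dam[!ped$dam %in% ped$id] <- NA
  ord <- pedigree_order(ped)
  ped <- ped[ord, , drop = FALSE]
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])

  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      aj <- numeric(i - 1L)
      if (!is.na(s)) aj <- aj + 0.5 * A[j, s]
      if (!is.na(d)) aj <- aj + 0.5 * A[j, d]
      A[j, i] <- A[i, j] <- aj
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  f <- diag(A) - 1
  names(f) <- ped$id
  f[pedigree$id]
}

#' Pedigree completeness index over d generations
#'
#' The fraction of the `sum(2^k, k = 1..depth)` ancestor slots (62 for five
#' generations) occupied by known individuals; a slot is unknown as soon as
#' any link on its path is missing.
#'
#' @param pedigree data.frame(id, sire, dam).
#' @param individual id(s) to evaluate; default all.
#' @param depth number of ancestral generations (default 5).
#' @return Named numeric vector of completeness indices in `[0, 1]`.
#' @export
pci_5g <- function(pedigree, individual = pedigree$id, depth = 5) {
  stopifnot(depth >= 1)
  ped <- pedigree
  ped$sire[ped$sire %in% c("0", "")] <- NA
  ped$dam[ped$dam %in% c("0", "")] <- NA
  sire_of <- setNames(ped$sire, ped$id)
  dam_of <- setNames(ped$dam, ped$id)
  known_slots <- function(id, d) {
    if (d == 0 || is.na(id) || !(id %in% names(sire_of))) return(0)
    s <- sire_of[[id]]; dm <- dam_of[[id]]
    total <- 0
    if (!is.na(s)) total <- total + 1 + known_slots(s, d - 1)
    if (!is.na(dm)) total <- total + 1 + known_slots(dm, d - 1)
    total
  }
  n_slots <- sum(2^(seq_len(depth)))
  setNames(vapply(individual, function(i) known_slots(i, depth) / n_slots,
                  0), individual)
}
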