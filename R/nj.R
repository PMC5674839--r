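## Saitou-Nei neighbor joining with a deterministic tie-break and
## non-negative branch lengths. Returns an ape "phylo" object so the tree
## can be written as Newick and plotted with the usual tools.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomeration on the Q criterion
#' `Q(i,j) = (m - 2) d(i,j) - r_i - r_j`. Ties in Q are broken by the
#' lexicographically smallest label pair (each cluster is labelled by its
#' smallest member tip). A negative branch length is clamped to zero and the
#' signed deficit transferred to its sister branch, preserving the path
#' length between the joined nodes; sister branches are clamped at zero as
#' well. Exact on additive distances.
#'
#' @param dist symmetric distance matrix with labelled rows/columns (>= 2).
#' @return An object of class `phylo` (unrooted; for 3+ taxa all internal
#'   nodes have degree 3).
#' @export
neighbor_joining <- function(dist) {
  d <- as.matrix(dist)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix not symmetric")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(d)))
  n <- length(labs)
  stopifnot(n >= 2)

  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  next_internal <- n + 1L

  if (n == 2) {
    edges <- rbind(c(3L, 1L), c(3L, 2L))
    lens <- c(d[1, 2] / 2, d[1, 2] / 2)
    return(new_phylo(edges, lens, labs, 1L))
  }

  node_id <- seq_len(n)          # phylo node number of each active cluster
  clab <- labs                   # smallest-tip label of each cluster
  active <- rep(TRUE, n)
  D <- d

  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }

  while (sum(active) > 3) {
    idx <- which(active)
    m <- length(idx)
    r <- rowSums(D[idx, idx])
    Q <- (m - 2) * D[idx, idx] - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      p <- sort(c(clab[idx[ij[1]]], clab[idx[ij[2]]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- idx[pick[1]]; j <- idx[pick[2]]
    ri <- r[pick[1]]; rj <- r[pick[2]]
    li <- D[i, j] / 2 + (ri - rj) / (2 * (m - 2))
    lj <- D[i, j] - li
    ll <- clamp_pair(li, lj)

    u <- next_internal; next_internal <- next_internal + 1L
    edges <- rbind(edges, c(u, node_id[i]), c(u, node_id[j]))
    lens <- c(lens, ll[1], ll[2])

    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D[i, ] <- newd; D[, i] <- newd; D[i, i] <- 0
    node_id[i] <- u
    clab[i] <- min(clab[i], clab[j])
    active[j] <- FALSE
  }

  idx <- which(active)
  if (length(idx) == 3) {
    a <- idx[1]; b <- idx[2]; c_ <- idx[3]
    v <- next_internal; next_internal <- next_internal + 1L
    la <- (D[a, b] + D[a, c_] - D[b, c_]) / 2
    lb <- (D[a, b] + D[b, c_] - D[a, c_]) / 2
    lc <- (D[a, c_] + D[b, c_] - D[a, b]) / 2
    edges <- rbind(edges, c(v, node_id[a]), c(v, node_id[b]),
                   c(v, node_id[c_]))
    lens <- c(lens, max(la, 0), max(lb, 0), max(lc, 0))
  } else { # two clusters left (possible when n == 3 never reaches here)
    a <- idx[1]; b <- idx[2]
    v <- next_internal; next_internal <- next_internal + 1L
    edges <- rbind(edges, c(v, node_id[a]), c(v, node_id[b]))
    lens <- c(lens, D[a, b] / 2, D[a, b] / 2)
  }
  new_phylo(edges, lens, labs, next_internal - 1L - n)
}

new_phylo <- function(edges, lens, tip_labels, n_internal) {
  n <- length(tip_labels)
  # internal nodes were created leaves-up; ape wants the root at n + 1,
  # so reverse the internal numbering (the last node created is the root)
  remap <- function(x)
    ifelse(x > n, n + 1L + (n + n_internal - as.integer(x)), as.integer(x))
  tr <- list(edge = cbind(remap(edges[, 1]), remap(edges[, 2])),
             edge.length = lens, tip.label = tip_labels,
             Nnode = as.integer(n_internal))
  class(tr) <- "phylo"
  # round-trip through Newick to normalise edge ordering for ape
  ape::read.tree(text = ape::write.tree(tr))
}

#' Write a tree to a Newick file
#'
#' @param tree a `phylo` object (e.g. from [neighbor_joining()]).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
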