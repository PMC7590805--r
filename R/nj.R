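#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou–Nei agglomeration. At each step the pair minimizing
#' \deqn{Q(i,j) = (r-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)}
#' (with `r` clusters remaining) is joined; branch lengths use the standard
#' split formula, with negative estimates clamped to zero. Ties in the Q
#' minimization are broken deterministically in favour of the pair with the
#' lowest (row, column) index in the current label ordering, so repeated
#' runs are bit-identical. The three final clusters are joined at a
#' trifurcating root, giving the usual unrooted topology.
#'
#' On an additive (tree-realizable) metric the generating topology and
#' branch lengths are recovered exactly.
#'
#' @param d Symmetric non-negative matrix with zero diagonal (or a `dist`),
#'   at least 3 labels; dimnames are used as leaf labels.
#' @return An unrooted `ape` `"phylo"` tree whose leaf set equals the input
#'   labels.
#' @export
#' @examples
#' d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighbor_joining(d)   # star with branches 1, 2, 3
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) abort("need at least 3 labels for neighbor joining.")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) abort("distance matrix must be symmetric.")
  if (any(d < 0)) abort("distance matrix must be non-negative.")
  if (any(abs(diag(d)) > 1e-12)) abort("distance matrix must have a zero diagonal.")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  # each active cluster is carried as a partial Newick string; placeholder
  # leaf names sidestep reserved characters until the tree is assembled
  rep_str <- paste0("L", seq_len(n))
  fmt <- function(len) formatC(max(len, 0), format = "g", digits = 15)

  while (nrow(d) > 3) {
    r <- nrow(d)
    tot <- rowSums(d)
    q <- (r - 2) * d - outer(tot, tot, `+`)
    diag(q) <- Inf
    hits <- which(q == min(q), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    li <- 0.5 * d[i, j] + (tot[i] - tot[j]) / (2 * (r - 2))
    lj <- 0.5 * d[i, j] + (tot[j] - tot[i]) / (2 * (r - 2))
    new_str <- paste0("(", rep_str[i], ":", fmt(li), ",",
                      rep_str[j], ":", fmt(lj), ")")
    d_new <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], d_new[keep]),
               c(d_new[keep], 0))
    rep_str <- c(rep_str[keep], new_str)
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- paste0("(", rep_str[1], ":", fmt(la), ",",
                rep_str[2], ":", fmt(lb), ",",
                rep_str[3], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = txt)
  tree$tip.label <- labels[as.integer(sub("^L", "", tree$tip.label))]
  tree
}
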