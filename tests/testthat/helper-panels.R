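# in-code fixtures and independent oracles shared across test files

make_manifest <- function(marker_ids, favorable = "B") {
  tibble::tibble(marker_id = marker_ids,
                 gene = paste0("gene_", marker_ids),
                 favorable_allele = rep(favorable, length.out = length(marker_ids)),
                 trait_class = "yield")
}

make_metadata <- function(n, zone = "I", group = "CL", decade = NA_integer_) {
  tibble::tibble(accession_id = sprintf("acc%03d", seq_len(n)),
                 zone = rep(zone, length.out = n),
                 group = rep(group, length.out = n),
                 decade = rep(as.integer(decade), length.out = n))
}

# panel from a per-group list of call vectors, one locus per list entry:
# calls[[marker]] is a character vector over all accessions
make_panel <- function(calls, metadata, favorable = "B") {
  mk <- names(calls)
  df <- tibble::as_tibble(c(list(accession_id = metadata$accession_id), calls))
  geno_panel(df, metadata, make_manifest(mk, favorable))
}

# two-group one-zone panel with exact allele counts per group:
# counts is a list(marker = list(cl = c(nAA, nAB, nBB), mcc = ...))
panel_from_counts <- function(counts, n_cl = NULL, n_mcc = NULL) {
  expand <- function(ct) rep(c("AA", "AB", "BB"), ct)
  cl_n <- length(expand(counts[[1]]$cl))
  mcc_n <- length(expand(counts[[1]]$mcc))
  meta <- dplyr::bind_rows(make_metadata(cl_n, group = "CL"),
                           make_metadata(mcc_n, group = "MCC"))
  meta$accession_id <- sprintf("acc%03d", seq_len(nrow(meta)))
  calls <- lapply(counts, function(ct) c(expand(ct$cl), expand(ct$mcc)))
  make_panel(calls, meta)
}

# reorder accessions and markers of a panel (for invariance checks)
shuffle_panel <- function(panel, seed = 1) {
  withr::with_seed(seed, {
    man <- manifest(panel)
    perm_r <- sample(nrow(panel))
    perm_c <- sample(nrow(man))
    calls <- tibble::as_tibble(panel)[c("accession_id", man$marker_id[perm_c])]
    calls <- calls[perm_r, ]
    meta <- tibble::as_tibble(panel)[perm_r, setdiff(names(panel), man$marker_id)]
    geno_panel(calls, meta, man[perm_c, ])
  })
}

# brute-force mean pairwise allele difference (oracle for corrected pi):
# n_b B-alleles among n copies, all C(n, 2) pairs enumerated
pi_pairwise_oracle <- function(n_b, n) {
  alleles <- rep(c(1, 0), c(n_b, n - n_b))
  pairs <- utils::combn(n, 2)
  mean(abs(alleles[pairs[1, ]] - alleles[pairs[2, ]]))
}

# --- neighbor-joining oracles ------------------------------------------------

random_additive_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  tr
}

# pair x edge incidence matrix of a tree (which edges lie on each tip path)
edge_design <- function(tree) {
  n <- length(tree$tip.label)
  pairs <- t(utils::combn(n, 2))
  x <- matrix(0, nrow(pairs), nrow(tree$edge))
  for (r in seq_len(nrow(pairs))) {
    np <- ape::nodepath(tree, pairs[r, 1], pairs[r, 2])
    for (k in seq_len(length(np) - 1)) {
      e <- which((tree$edge[, 1] == np[k] & tree$edge[, 2] == np[k + 1]) |
                   (tree$edge[, 1] == np[k + 1] & tree$edge[, 2] == np[k]))
      x[r, e] <- 1
    }
  }
  list(x = x, pairs = pairs)
}

# least-squares branch-length fit of a fixed topology to a distance matrix;
# returns the residual sum of squares
ls_topology_ss <- function(topology, d) {
  des <- edge_design(topology)
  labs <- topology$tip.label
  dv <- d[cbind(labs[des$pairs[, 1]], labs[des$pairs[, 2]])]
  b <- qr.solve(des$x, dv)
  sum((des$x %*% b - dv)^2)
}

same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}
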