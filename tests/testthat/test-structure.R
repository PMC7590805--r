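test_that("three-taxon neighbor joining has the closed-form star solution", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("neighbor joining validates its input", {
  d <- matrix(c(0, 1, 1, 0), 2)
  expect_error(neighbor_joining(d), "at least 3")
  d3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3)
  expect_error(neighbor_joining(d3), "symmetric")
  d3 <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3)
  expect_error(neighbor_joining(d3), "non-negative")
})

test_that("neighbor joining recovers additive trees exactly", {
  withr::with_seed(21, {
    for (i in 1:30) {
      n <- sample(4:12, 1)
      tr <- random_additive_tree(n)
      d <- ape::cophenetic.phylo(tr)
      nj <- neighbor_joining(d)
      expect_setequal(nj$tip.label, tr$tip.label)
      expect_true(same_topology(nj, tr))
      # additivity: path distances of the reconstruction equal the input
      expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
                   tolerance = 1e-8)
    }
  })
})

test_that("neighbor joining agrees with the exhaustive least-squares topology fit", {
  withr::with_seed(33, {
    for (i in 1:8) {
      tr <- random_additive_tree(5)
      d <- ape::cophenetic.phylo(tr)
      nj <- neighbor_joining(d)
      cand <- phangorn::allTrees(5, rooted = FALSE, tip.label = tr$tip.label)
      ss <- vapply(cand, ls_topology_ss, numeric(1), d = d)
      best <- cand[[which.min(ss)]]
      expect_lt(min(ss), 1e-12)
      expect_true(same_topology(nj, best))
    }
  })
})

test_that("neighbor joining matches the reference implementation on noisy matrices", {
  withr::with_seed(7, {
    for (i in 1:10) {
      tr <- random_additive_tree(8)
      d <- ape::cophenetic.phylo(tr)
      noise <- matrix(runif(64, 0, 0.02), 8)
      d <- d + noise + t(noise)
      diag(d) <- 0
      expect_true(same_topology(neighbor_joining(d), ape::nj(d)))
    }
  })
})

test_that("accession distances use dosage/2 frequency vectors with pairwise locus exclusion", {
  panel <- make_panel(list(M1 = c("AA", "AB", "BB")), make_metadata(3))
  d <- accession_dist(panel)
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 3), rownames(d)))
  expect_equal(round(d["acc001", "acc002"], 4), 0.3466)  # AA vs AB
  # missing entries drop the locus only for pairs involving that accession
  p2 <- make_panel(list(M1 = c("AA", "AB", "BB"), M2 = c("AA", NA, "AA")),
                   make_metadata(3))
  d2 <- accession_dist(p2)
  expect_equal(d2["acc001", "acc002"], d["acc001", "acc002"])
  expect_error(accession_dist(make_panel(list(M1 = c("AA", NA, "BB")),
                                         make_metadata(3))),
               "no defined locus")
})

test_that("pca has fixed sign convention, identical rows for identical accessions", {
  panel <- make_panel(list(M1 = c("AA", "AA", "BB", "BB"),
                           M2 = c("AB", "AB", "AA", "BB"),
                           M3 = c("AA", "AA", "BB", "AB")),
                      make_metadata(4, group = c("CL", "CL", "MCC", "MCC")))
  p <- panel_pca(panel, k = 2)
  sc <- tidy(p)
  expect_equal(sc$PC1[1], sc$PC1[2])
  expect_equal(sc$PC2[1], sc$PC2[2])
  ev <- glance(p)$explained_variance_fraction
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(sum(ev), 1 + 1e-12)
  expect_equal(sum(ev), 1)
  # monomorphic-only panel is an error
  mono <- make_panel(list(M1 = rep("AA", 4)), make_metadata(4))
  expect_error(panel_pca(mono), "monomorphic")
})

test_that("pca scores are invariant to accession ordering and separate simulated groups", {
  sim <- simulate_panel(sim_config(seed = 4, n_zones = 1, n_cl = 30,
                                   n_mcc = 30, n_loci = 40, fst = 0.3))
  p1 <- tidy(panel_pca(sim$panel))
  p2 <- tidy(panel_pca(shuffle_panel(sim$panel, seed = 8)))
  merged <- dplyr::inner_join(p1, p2, by = "accession_id")
  expect_equal(merged$PC1.x, merged$PC1.y, tolerance = 1e-8)
  # PC1 separates CL from MCC: silhouette-style check on the group means
  cl <- p1$PC1[p1$group == "CL"]; mcc <- p1$PC1[p1$group == "MCC"]
  gap <- abs(mean(cl) - mean(mcc))
  spread <- (stats::sd(cl) + stats::sd(mcc)) / 2
  expect_gt(gap, spread)
})

test_that("total variance is conserved across the eigendecomposition", {
  sim <- simulate_panel(sim_config(seed = 10, n_zones = 2, n_loci = 15))
  z <- dosage_matrix(sim$panel)
  mu <- colMeans(z, na.rm = TRUE)
  idx <- which(is.na(z), arr.ind = TRUE)
  z[idx] <- mu[idx[, 2]]
  z <- z[, apply(z, 2, stats::var) > 0, drop = FALSE]
  z <- scale(z, center = TRUE, scale = FALSE)
  total <- sum(apply(z, 2, stats::var))
  p <- panel_pca(sim$panel, k = 2)
  expect_equal(p$total_variance, total, tolerance = 1e-10)
})

test_that("zone-level distance matrices feed trees whose leaves are the zones", {
  sim <- simulate_panel(sim_config(seed = 12, n_zones = 5, n_loci = 30))
  cl <- suppressWarnings(filter_panel(sim$panel, group = "CL"))
  d <- group_dist(cl, by = "zone")
  expect_equal(dim(d), c(5L, 5L))
  expect_equal(d, t(d))
  tr <- neighbor_joining(d)
  expect_setequal(tr$tip.label, rownames(d))
})
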