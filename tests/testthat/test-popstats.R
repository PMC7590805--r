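test_that("allele and carrier frequencies follow diploid counting", {
  # 10 AA + 10 BB + 2 AB over 22 diploids -> p_B = 22/44 = 0.5
  panel <- make_panel(
    list(M1 = rep(c("AA", "BB", "AB"), c(10, 10, 2)),
         M2 = rep("AA", 22)),
    make_metadata(22))
  fr <- allele_freqs(panel, by = "group")
  expect_equal(fr$p[fr$marker_id == "M1"], 0.5)
  expect_equal(fr$n_alleles[fr$marker_id == "M1"], 44L)
  # fixed locus: all AA -> p_B = 0; carrier of favorable A = 1
  panel_a <- make_panel(list(M2 = rep("AA", 22)), make_metadata(22),
                        favorable = "A")
  fr_a <- allele_freqs(panel_a)
  expect_equal(fr_a$p, 0)
  expect_equal(fr_a$carrier_freq, 1)
  # 11 of 22 accessions carrying the favorable allele -> 0.50
  panel_c <- make_panel(list(M3 = rep(c("BB", "AA"), c(11, 11))),
                        make_metadata(22, group = "MCC"))
  expect_equal(allele_freqs(panel_c)$carrier_freq, 0.5)
})

test_that("under-called loci are flagged undefined, not dropped", {
  panel <- make_panel(list(M1 = c("AA", "BB", NA, NA, NA, NA),
                           M2 = rep("AB", 6)),
                      make_metadata(6))
  fr <- allele_freqs(panel, min_calls = 5)
  expect_equal(nrow(fr), 2L)
  expect_false(fr$defined[fr$marker_id == "M1"])
  expect_true(is.na(fr$p[fr$marker_id == "M1"]))
  expect_true(fr$defined[fr$marker_id == "M2"])
})

test_that("site_pi matches closed forms and the pairwise-difference oracle", {
  expect_equal(site_pi(0), 0)
  expect_equal(site_pi(0.09), 0.1638)
  expect_equal(round(site_pi(0.09), 2), 0.16)
  expect_equal(site_pi(0.5, 44, corrected = TRUE), 44 / 43 * 0.5)
  expect_equal(site_pi(0.5, 44, corrected = TRUE),
               pi_pairwise_oracle(22, 44))
  # oracle agreement across sample sizes and counts
  withr::with_seed(11, {
    for (rep in 1:25) {
      n <- 2 * sample(2:30, 1)        # even allele counts (diploid)
      n_b <- sample(0:n, 1)
      expect_equal(site_pi(n_b / n, n, corrected = TRUE),
                   pi_pairwise_oracle(n_b, n))
    }
  })
  expect_error(site_pi(0.5, 1, corrected = TRUE), "n_alleles")
  expect_error(site_pi(1.2), "0, 1")
})

test_that("diversity averages defined loci and is frequency-invariant", {
  # known frequencies {0.1, 0.5} -> per-locus pi {0.18, 0.5}, mean 0.34
  panel <- make_panel(
    list(M1 = rep(c("BB", "AA"), c(1, 9)),       # p = 0.1
         M2 = rep(c("BB", "AA"), c(5, 5))),      # p = 0.5
    make_metadata(10))
  d <- diversity(panel)
  expect_equal(sort(d$per_locus$pi), c(0.18, 0.5))
  expect_equal(d$summary$mean_pi, 0.34)
  # duplicating every accession leaves uncorrected pi unchanged
  doubled <- make_panel(
    list(M1 = rep(rep(c("BB", "AA"), c(1, 9)), 2),
         M2 = rep(rep(c("BB", "AA"), c(5, 5)), 2)),
    make_metadata(20))
  expect_equal(glance(diversity(doubled))$mean_pi, 0.34)
  # all loci fixed -> mean 0
  fixed <- make_panel(list(M1 = rep("AA", 6), M2 = rep("BB", 6)),
                      make_metadata(6))
  expect_equal(glance(diversity(fixed))$mean_pi, 0)
})

test_that("gst reproduces hand-computed Hs/Ht/Fst and the fixed-difference case", {
  # p1 = 0.2, p2 = 0.8 -> Hs = 0.32, Ht = 0.5, fst = 0.36
  panel <- panel_from_counts(list(
    M1 = list(cl = c(4, 0, 1), mcc = c(1, 0, 4)),   # p 0.2 vs 0.8
    M2 = list(cl = c(5, 0, 0), mcc = c(0, 0, 5))    # fixed A vs fixed B
  ))
  g <- gst(panel)
  pl <- tidy(g)
  expect_equal(pl$hs[pl$marker_id == "M1"], 0.32)
  expect_equal(pl$ht[pl$marker_id == "M1"], 0.5)
  expect_equal(pl$fst[pl$marker_id == "M1"], 0.36)
  expect_equal(pl$fst[pl$marker_id == "M2"], 1)
  expect_equal(pl$hs[pl$marker_id == "M2"], 0)
  # identical frequencies -> multilocus fst = 0
  null <- panel_from_counts(list(
    M1 = list(cl = c(3, 0, 2), mcc = c(3, 0, 2)),
    M2 = list(cl = c(1, 2, 2), mcc = c(1, 2, 2))
  ))
  expect_equal(gst(null)$fst, 0)
})

test_that("gene-flow identities hold and match the printed pair", {
  expect_equal(nm_from_fst(0.5), 0.25)
  expect_equal(round(nm_from_fst(0.0439), 2), 5.44)
  x <- seq(0.01, 0.99, by = 0.014)
  expect_equal(fst_from_nm(nm_from_fst(x)), x)
  expect_true(all(abs(nm_from_fst(x) * 4 * x + x - 1) < 1e-12))
  expect_warning(expect_true(is.na(nm_from_fst(0))), "undefined")
  expect_warning(expect_true(is.na(nm_from_fst(1))), "undefined")
})

test_that("nei distance matches hand computation, symmetry and identity cases", {
  same <- nei_distance(c(0.2, 0.7), c(0.2, 0.7))
  expect_equal(same$identity, 1)
  expect_equal(same$distance, 0)
  # x = (1, 0), y = (0.5, 0.5): I = 0.5 / sqrt(0.5), D = 0.3466
  one <- nei_distance(1, 0.5)
  expect_equal(one$identity, 1 / sqrt(2), tolerance = 1e-10)
  expect_equal(round(one$distance, 4), 0.3466)
  withr::with_seed(5, {
    for (i in 1:10) {
      px <- runif(8); py <- runif(8)
      expect_equal(nei_distance(px, py)$distance,
                   nei_distance(py, px)$distance)
      expect_gte(nei_distance(px, py)$distance, 0)
    }
  })
  expect_error(nei_distance(c(0.1, 0.2), 0.1), "length")
  # fully opposite fixation -> infinite distance flag
  expect_equal(nei_distance(1, 0)$distance, Inf)
})

test_that("statistics are invariant to accession and marker ordering", {
  sim <- simulate_panel(sim_config(seed = 9, n_zones = 2, n_loci = 10))
  shuf <- shuffle_panel(sim$panel, seed = 2)
  d1 <- glance(diversity(sim$panel, by = c("zone", "group")))
  d2 <- glance(diversity(shuf, by = c("zone", "group")))
  expect_equal(d1, d2)
  expect_equal(gst(sim$panel)$fst, gst(shuf)$fst)
  pl1 <- dplyr::arrange(tidy(gst(sim$panel)), marker_id)
  pl2 <- dplyr::arrange(tidy(gst(shuf)), marker_id)
  expect_equal(pl1, pl2)
})
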