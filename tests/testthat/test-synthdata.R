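test_that("simulation is bitwise reproducible from its seed", {
  cfg <- sim_config(seed = 99, n_zones = 3, n_loci = 15)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(tibble::as_tibble(s1$panel), tibble::as_tibble(s2$panel))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$sweeps, s2$sweeps)
  s3 <- simulate_panel(sim_config(seed = 100, n_zones = 3, n_loci = 15))
  expect_false(identical(tibble::as_tibble(s1$panel),
                         tibble::as_tibble(s3$panel)))
})

test_that("config validation rejects degenerate parameters", {
  expect_error(sim_config(fst = 0), "fst")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(n_cl = 0), "positive")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(p0 = c(2, 0.5), n_loci = 2), "p0")
})

test_that("vanishing F pins stratum frequencies to the ancestral value", {
  cfg <- sim_config(seed = 41, fst = 1e-6, n_loci = 100, n_zones = 2)
  sim <- simulate_panel(cfg)
  dev <- abs(sim$truth$p_latent - sim$truth$p0)
  expect_gt(mean(dev < 0.01), 0.99)
})

test_that("genotype draws are consistent with latent frequencies", {
  # large stratum, no missingness: sample allele frequency tracks truth
  sim <- simulate_panel(sim_config(seed = 55, n_zones = 1, n_cl = 500,
                                   n_mcc = 500, n_loci = 60,
                                   missing_rate = 0))
  fr <- allele_freqs(sim$panel, by = c("zone", "group"))
  tr <- dplyr::inner_join(fr, sim$truth,
                          by = c("zone", "group", "marker_id"))
  se <- sqrt(tr$p_latent * (1 - tr$p_latent) / tr$n_alleles)
  expect_gt(mean(abs(tr$p - tr$p_latent) <= 4 * pmax(se, 1e-3)), 0.95)
  # residual heterozygosity near its configured rate
  z <- dosage_matrix(sim$panel)
  p <- tr$p_latent[match(colnames(z), tr$marker_id)]
  expected_het <- mean(0.02 * 2 * p * (1 - p))
  expect_equal(mean(z == 1L, na.rm = TRUE), expected_het, tolerance = 0.35)
})

test_that("injected selection shifts only the targeted cell and registers it", {
  cfg <- sim_config(seed = 61, n_zones = 2, n_loci = 10, fst = 0.1)
  base <- simulate_panel(cfg)
  shifted <- inject_selection(base, zone = "II", locus = "M03", delta = 0.5)
  expect_equal(shifted$sweeps,
               tibble::tibble(zone = "II", marker_id = "M03", delta = 0.5))
  # latent truth clipped into [0, 1]
  p_old <- base$truth$p_latent[base$truth$zone == "II" &
                                 base$truth$group == "MCC" &
                                 base$truth$marker_id == "M03"]
  p_new <- shifted$truth$p_latent[shifted$truth$zone == "II" &
                                    shifted$truth$group == "MCC" &
                                    shifted$truth$marker_id == "M03"]
  expect_equal(p_new, min(p_old + 0.5, 1))
  # untouched cells identical
  others <- setdiff(marker_ids(base$panel), "M03")
  expect_identical(tibble::as_tibble(base$panel)[others],
                   tibble::as_tibble(shifted$panel)[others])
  untouched <- base$panel$zone != "II" | base$panel$group != "MCC"
  expect_identical(base$panel$M03[untouched], shifted$panel$M03[untouched])
  # no-op and error cases
  expect_identical(inject_selection(base, "II", "M03", 0), base)
  expect_error(inject_selection(base, "II", "M99", 0.2), "unknown locus")
  expect_error(inject_selection(base, "IX", "M03", 0.2), "unknown zone")
  # clipping at the latent level: large shift fixes the stratum
  fixed <- inject_selection(base, "I", "M01", 2)
  expect_equal(fixed$truth$p_latent[fixed$truth$zone == "I" &
                                      fixed$truth$group == "MCC" &
                                      fixed$truth$marker_id == "M01"], 1)
})

test_that("null panels carry no group effect and re-simulate identically", {
  cfg <- sim_config(seed = 77, n_zones = 4, n_loci = 30)
  np <- null_panel(cfg)
  tr <- tidyr::pivot_wider(np$truth, names_from = "group",
                           values_from = "p_latent")
  expect_equal(tr$CL, tr$MCC)
  expect_identical(tibble::as_tibble(null_panel(cfg)$panel),
                   tibble::as_tibble(np$panel))
  # observed CL-vs-MCC gst within sampling noise of zero, per zone
  fst_zones <- vapply(c("I", "II", "III", "IV"), function(z) {
    gst(suppressWarnings(filter_panel(np$panel, zone = z)))$fst
  }, numeric(1))
  expect_lt(mean(fst_zones), 0.05)
})

test_that("injected sweeps raise expected Fst above background (one-sided contrast)", {
  contrast <- vapply(1:40, function(seed) {
    sel <- tibble::tibble(zone = "I", locus = 1, delta = 0.7)
    sim <- simulate_panel(sim_config(seed = seed, n_zones = 1, n_loci = 20,
                                     fst = 0.05, selection = sel))
    sc <- scan_zone(sim$panel, "I")
    inj <- sc$marker_id == "M01"
    c(inj = sc$fst[inj], bg = mean(sc$fst[!inj], na.rm = TRUE))
  }, numeric(2))
  expect_gt(mean(contrast["inj", ], na.rm = TRUE),
            mean(contrast["bg", ]) + 0.1)
})

test_that("the simulated file dialect round-trips through the readers", {
  sim <- simulate_panel(sim_config(seed = 83, n_zones = 2, n_loci = 6))
  dir <- withr::local_tempdir()
  paths <- write_sim(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_genotypes(paths[["genotypes"]], paths[["metadata"]],
                         paths[["manifest"]])
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(sim$panel))
})
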