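#' Configuration for the Balding-Nichols panel simulator
#'
#' The simulator emulates the stratified KASP panel the analyses target:
#' ten agro-ecological zones, each contributing a landrace (CL) and a
#' modern-cultivar (MCC) stratum of inbred-like diploids typed at ~52
#' biallelic loci. Per locus an ancestral B-allele frequency \eqn{p_0} is
#' drawn (Beta by default), and every zone x group stratum receives a
#' latent frequency from the Balding-Nichols distribution
#' \deqn{p \sim \mathrm{Beta}\!\left(p_0 \tfrac{1-F}{F},\;
#'       (1-p_0) \tfrac{1-F}{F}\right),}
#' so that the expected differentiation between strata equals `F`.
#' Selection is injected by shifting the MCC latent frequency of chosen
#' (zone, locus) cells by `delta` (clipped to \[0, 1\]).
#'
#' Defaults mirror the study design: 22 CL + 22 MCC per zone with one
#' short zone (IX: 20 MCC), 52 loci, `fst = 0.13`, residual heterozygosity
#' and missingness 2% each, MCC release decades uniform over 1950–2000.
#'
#' @param n_zones Number of zones (default 10, labelled I..X).
#' @param n_cl,n_mcc Accessions per zone and group; scalars or vectors of
#'   length `n_zones`. Default 22 and 22 with zone IX reduced to 20 MCC.
#' @param n_loci Number of markers (default 52).
#' @param fst Balding-Nichols `F` in (0, 1); default 0.13.
#' @param p0 Ancestral frequencies: `NULL` to draw from
#'   `Beta(p0_shape[1], p0_shape[2])`, or a fixed numeric vector of length
#'   `n_loci`.
#' @param p0_shape Beta shape parameters for the ancestral draw; default
#'   `c(0.5, 0.5)` (U-shaped, uneven frequencies).
#' @param selection Injected sweeps: a data frame with columns `zone`,
#'   `locus` (marker index or id) and `delta`, or `NULL`.
#' @param missing_rate,het_rate Missing-call rate and residual
#'   heterozygosity in \[0, 1); defaults 0.02. Heterozygote probability is
#'   `het_rate * 2p(1-p)` with the remainder redistributed to the
#'   homozygotes in proportion to allele frequency (inbreeding-style), so
#'   allele frequencies are preserved.
#' @param decades Candidate MCC release-decade start years (sampled
#'   uniformly); default `seq(1950, 2000, 10)`.
#' @param hierarchical If `TRUE`, draw a zone pool around `p0` first
#'   (at differentiation `fst`) and then the two group frequencies around
#'   the zone pool (at `fst_within`), giving zone-level gene-flow
#'   structure.
#' @param fst_within Within-zone group differentiation for the
#'   hierarchical mode (default 0.02).
#' @param seed Integer RNG seed; the panel is fully reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_zones = 10, n_cl = 22, n_mcc = NULL, n_loci = 52,
                       fst = 0.13, p0 = NULL, p0_shape = c(0.5, 0.5),
                       selection = NULL, missing_rate = 0.02, het_rate = 0.02,
                       decades = seq(1950, 2000, 10), hierarchical = FALSE,
                       fst_within = 0.02, seed = 1L) {
  if (is.null(n_mcc)) {
    n_mcc <- rep(22L, n_zones)
    if (n_zones >= 9) n_mcc[9] <- 20L   # zone IX is the short stratum
  }
  n_cl <- rep(as.integer(n_cl), length.out = n_zones)
  n_mcc <- rep(as.integer(n_mcc), length.out = n_zones)
  if (any(c(n_cl, n_mcc) <= 0) || n_loci <= 0) abort("counts must be positive.")
  if (fst <= 0 || fst >= 1) abort("fst must lie in (0, 1).")
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate must lie in [0, 1).")
  if (het_rate < 0 || het_rate >= 1) abort("het_rate must lie in [0, 1).")
  if (!is.null(p0)) {
    p0 <- rep(p0, length.out = n_loci)
    if (any(p0 < 0 | p0 > 1)) abort("fixed p0 must lie in [0, 1].")
  }
  if (!is.null(selection)) {
    selection <- as_tibble(selection)
    stopifnot(all(c("zone", "locus", "delta") %in% names(selection)))
  }
  structure(list(n_zones = as.integer(n_zones), n_cl = n_cl, n_mcc = n_mcc,
                 n_loci = as.integer(n_loci), fst = fst, p0 = p0,
                 p0_shape = p0_shape, selection = selection,
                 missing_rate = missing_rate, het_rate = het_rate,
                 decades = as.integer(decades),
                 hierarchical = hierarchical, fst_within = fst_within,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Accession metadata for the study sampling design
#'
#' Builds the metadata table implied by the stated design: `n_cl` CL and
#' `n_mcc` MCC accessions per zone (defaults 22 + 22, zone IX 22 + 20,
#' totalling 438), with MCC release decades assigned cyclically over the
#' candidate decades (deterministic).
#'
#' @inheritParams sim_config
#' @return Metadata tibble (`accession_id`, `zone`, `group`, `decade`,
#'   `growth_habit`).
#' @export
panel_design <- function(n_zones = 10, n_cl = 22, n_mcc = NULL,
                         decades = seq(1950, 2000, 10)) {
  cfg <- sim_config(n_zones = n_zones, n_cl = n_cl, n_mcc = n_mcc,
                    decades = decades)
  zones <- .zone_levels(cfg$n_zones)
  rows <- purrr::map2(seq_len(cfg$n_zones), zones, function(zi, z) {
    tibble(
      zone = z,
      group = rep(c("CL", "MCC"), c(cfg$n_cl[zi], cfg$n_mcc[zi])),
      within = c(seq_len(cfg$n_cl[zi]), seq_len(cfg$n_mcc[zi]))
    )
  }) |> bind_rows()
  rows |>
    mutate(accession_id = sprintf("%s_%s_%02d", .data$group, .data$zone,
                                  .data$within),
           decade = ifelse(.data$group == "MCC",
                           cfg$decades[(.data$within - 1L) %% length(cfg$decades) + 1L],
                           NA_integer_),
           growth_habit = NA_character_) |>
    select(all_of(c("accession_id", "zone", "group", "decade", "growth_habit")))
}

#' Simulate a stratified KASP panel with known truth
#'
#' Draws a full panel under the Balding-Nichols model of [sim_config()]:
#' ancestral frequencies, latent stratum frequencies, injected selection
#' shifts, inbred-like diploid genotypes and missing calls. The latent
#' frequencies and the sweep registry are returned alongside the panel so
#' every downstream statistic can be checked against truth.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `sim_panel`: list with `panel` (a `geno_tbl`),
#'   `truth` (tibble `zone`, `group`, `marker_id`, `p0`, `p_latent`),
#'   `sweeps` (registry tibble `zone`, `marker_id`, `delta`) and `config`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_panel_impl(cfg, null_groups = FALSE))
}

#' Simulate a null panel (no CL/MCC differentiation)
#'
#' As [simulate_panel()], but CL and MCC within each zone share the same
#' latent frequency, so the expected CL-vs-MCC Gst is zero in every zone —
#' the calibration input for the sweep-scan false-positive rate.
#'
#' @inheritParams simulate_panel
#' @return A `sim_panel` (see [simulate_panel()]).
#' @export
null_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_panel_impl(cfg, null_groups = TRUE))
}

simulate_panel_impl <- function(cfg, null_groups = FALSE) {
  zones <- .zone_levels(cfg$n_zones)
  mk <- sprintf("M%02d", seq_len(cfg$n_loci))
  p0 <- cfg$p0 %||% rbeta(cfg$n_loci, cfg$p0_shape[1], cfg$p0_shape[2])
  p0 <- pmin(pmax(p0, 1e-4), 1 - 1e-4)   # Beta parameters must be positive

  bn_draw <- function(center, f) {
    a <- center * (1 - f) / f
    b <- (1 - center) * (1 - f) / f
    rbeta(length(center), a, b)
  }
  # latent frequency per stratum (zone x group) x locus
  latent <- array(NA_real_, c(cfg$n_zones, 2, cfg$n_loci),
                  dimnames = list(zones, .group_levels, mk))
  for (zi in seq_len(cfg$n_zones)) {
    if (cfg$hierarchical) {
      pool <- pmin(pmax(bn_draw(p0, cfg$fst), 1e-4), 1 - 1e-4)
      latent[zi, "CL", ] <- bn_draw(pool, cfg$fst_within)
      latent[zi, "MCC", ] <- if (null_groups) latent[zi, "CL", ] else
        bn_draw(pool, cfg$fst_within)
    } else {
      latent[zi, "CL", ] <- bn_draw(p0, cfg$fst)
      latent[zi, "MCC", ] <- if (null_groups) latent[zi, "CL", ] else
        bn_draw(p0, cfg$fst)
    }
  }

  sweeps <- tibble(zone = character(), marker_id = character(),
                   delta = numeric())
  if (!is.null(cfg$selection)) {
    for (r in seq_len(nrow(cfg$selection))) {
      z <- as.character(cfg$selection$zone[r])
      loc <- cfg$selection$locus[r]
      id <- if (is.numeric(loc)) mk[loc] else as.character(loc)
      if (!z %in% zones) abort(paste0("unknown zone in selection: ", z))
      if (!id %in% mk) abort(paste0("unknown locus in selection: ", loc))
      d <- cfg$selection$delta[r]
      latent[z, "MCC", id] <- min(max(latent[z, "MCC", id] + d, 0), 1)
      sweeps <- bind_rows(sweeps, tibble(zone = z, marker_id = id, delta = d))
    }
  }

  metadata <- panel_design(cfg$n_zones, cfg$n_cl, cfg$n_mcc, cfg$decades)
  n_acc <- nrow(metadata)
  zi <- match(metadata$zone, zones)
  gi <- match(metadata$group, .group_levels)
  pm <- matrix(latent[cbind(rep(zi, cfg$n_loci), rep(gi, cfg$n_loci),
                            rep(seq_len(cfg$n_loci), each = n_acc))],
               nrow = n_acc)
  calls <- draw_genotypes(pm, cfg$het_rate)
  if (cfg$missing_rate > 0) {
    calls[runif(length(calls)) < cfg$missing_rate] <- NA
  }
  colnames(calls) <- mk
  calls_df <- dplyr::bind_cols(tibble(accession_id = metadata$accession_id),
                               as_tibble(calls))
  manifest <- default_manifest(mk)
  truth <- tidyr::expand_grid(zone = zones, group = .group_levels,
                              marker_id = mk) |>
    mutate(p0 = p0[match(.data$marker_id, mk)],
           p_latent = latent[cbind(.data$zone, .data$group, .data$marker_id)])
  structure(list(panel = geno_panel(calls_df, metadata, manifest),
                 truth = truth, sweeps = sweeps, config = cfg),
            class = "sim_panel")
}

# inbred-like diploid draw: P(AB) = het_rate * 2p(1-p), remainder of the
# Hardy-Weinberg heterozygosity redistributed to the homozygotes in
# proportion to allele frequency, so E[dosage]/2 = p exactly
draw_genotypes <- function(p, het_rate) {
  f <- 1 - het_rate                     # inbreeding coefficient
  u <- runif(length(p))
  p_bb <- p^2 + f * p * (1 - p)
  p_ab <- (1 - f) * 2 * p * (1 - p)
  code <- (u < p_bb) + (u < p_bb + p_ab)   # 2 = BB, 1 = AB, 0 = AA
  matrix(c("AA", "AB", "BB")[code + 1L], nrow = nrow(p))
}

default_manifest <- function(marker_ids) {
  tibble(marker_id = marker_ids,
         gene = sub("^M", "gene", marker_ids),
         favorable_allele = "B",
         trait_class = .trait_levels[(seq_along(marker_ids) - 1L) %%
                                       length(.trait_levels) + 1L])
}

#' Inject a selection shift into an existing simulated panel
#'
#' Shifts the MCC latent frequency at one (zone, locus) cell by `delta`
#' (clipped to \[0, 1\]) and redraws the genotype calls of the affected
#' accessions only, using an RNG stream derived from the panel seed and the
#' cell coordinates, so the operation is reproducible and leaves every
#' other cell untouched. `delta = 0` returns the panel unchanged.
#'
#' @param sim A `sim_panel` from [simulate_panel()].
#' @param zone Zone label.
#' @param locus Marker id or index.
#' @param delta Frequency shift.
#' @return The modified `sim_panel` (registry updated).
#' @export
inject_selection <- function(sim, zone, locus, delta) {
  stopifnot(inherits(sim, "sim_panel"))
  mk <- marker_ids(sim$panel)
  id <- if (is.numeric(locus)) mk[locus] else as.character(locus)
  if (is.na(id) || !id %in% mk) abort(paste0("unknown locus: ", locus))
  zones <- levels(sim$panel$zone)
  if (!zone %in% as.character(unique(sim$panel$zone))) {
    abort(paste0("unknown zone: ", zone))
  }
  if (delta == 0) return(sim)
  row <- sim$truth$zone == zone & sim$truth$group == "MCC" &
    sim$truth$marker_id == id
  p_new <- min(max(sim$truth$p_latent[row] + delta, 0), 1)
  sim$truth$p_latent[row] <- p_new
  cells <- which(sim$panel$zone == zone & sim$panel$group == "MCC")
  seed <- (sim$config$seed + 7919L * match(id, mk) +
             104729L * match(zone, zones)) %% .Machine$integer.max
  cfg <- sim$config
  new_calls <- withr::with_seed(seed, {
    calls <- draw_genotypes(matrix(p_new, length(cells), 1), cfg$het_rate)
    calls[runif(length(calls)) < cfg$missing_rate] <- NA
    calls
  })
  sim$panel[[id]][cells] <- new_calls[, 1]
  sim$sweeps <- bind_rows(sim$sweeps,
                          tibble(zone = zone, marker_id = id, delta = delta))
  sim
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("Simulated KASP panel: ", nrow(x$panel), " accessions x ",
      x$config$n_loci, " loci (F = ", x$config$fst, ", seed ",
      x$config$seed, ")\n", sep = "")
  if (nrow(x$sweeps)) {
    cat("injected sweeps:\n")
    print(x$sweeps, n = Inf)
  }
  invisible(x)
}

#' Write a simulated panel (and its truth) to disk
#'
#' Emits the three panel files via [write_panel()] plus `truth.tsv` (latent
#' frequencies) and `sweeps.tsv` (injected-sweep registry).
#'
#' @param sim A `sim_panel`.
#' @param dir Output directory.
#' @return Invisibly, the named vector of paths written.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_panel"))
  paths <- write_panel(sim$panel, dir)
  truth_path <- file.path(dir, "truth.tsv")
  sweeps_path <- file.path(dir, "sweeps.tsv")
  readr::write_tsv(sim$truth, truth_path, progress = FALSE)
  readr::write_tsv(sim$sweeps, sweeps_path, progress = FALSE)
  invisible(c(paths, truth = truth_path, sweeps = sweeps_path))
}
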