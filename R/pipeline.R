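#' Configuration for a full pipeline run
#'
#' Exactly one of `genotype_path`/`metadata_path`/`manifest_path` (the
#' three input files) or `simulate` (a [sim_config()]) must be given.
#'
#' @param genotype_path,metadata_path,manifest_path Input files, see
#'   [read_genotypes()].
#' @param simulate A [sim_config()] to generate the panel instead of
#'   reading files.
#' @param out_dir Output directory for all result tables.
#' @param q Sweep-scan quantile in (0, 1), default 0.95.
#' @param counting Signal counting mode, see [scan_all()].
#' @param corrected Small-sample-corrected diversity? Default `FALSE`.
#' @param weights Gst group weighting, `"equal"` or `"size"`.
#' @param min_calls Minimum calls per (group, locus), default 5.
#' @param seed Seed echoed into the log (the simulator carries its own).
#' @return A `run_config` list.
#' @export
run_config <- function(genotype_path = NULL, metadata_path = NULL,
                       manifest_path = NULL, simulate = NULL,
                       out_dir = "kaspdiv_out", q = 0.95,
                       counting = "per_statistic", corrected = FALSE,
                       weights = "equal", min_calls = 5, seed = 1L) {
  has_files <- !is.null(genotype_path)
  if (has_files == !is.null(simulate)) {
    abort("supply exactly one of input paths or a simulate config.")
  }
  if (has_files && (is.null(metadata_path) || is.null(manifest_path))) {
    abort("all three input paths are required.")
  }
  if (q <= 0 || q >= 1) abort("q must lie in (0, 1).")
  structure(list(genotype_path = genotype_path, metadata_path = metadata_path,
                 manifest_path = manifest_path, simulate = simulate,
                 out_dir = out_dir, q = q, counting = counting,
                 corrected = corrected, weights = weights,
                 min_calls = min_calls, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments; a `simulate:` block holds
#' [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$simulate)) vals$simulate <- do.call(sim_config, vals$simulate)
  do.call(run_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load or simulate the panel; CL-vs-MCC PCA and global
#' Gst/gene flow; decade differentiation grid; zone-level trees (per group)
#' and per-group PCA; zone-wise diversity (pi and pi-ratio); zone-wise
#' CL-vs-MCC Gst/Nm; pairwise-zone grids for CL and MCC; sweep scans
#' (per-zone and pooled); allele survey with fixed/rare counts. Every
#' result is written as TSV (trees as Newick) into `out_dir`, and a
#' one-line-per-stage log records sizes and headline statistics.
#'
#' @param cfg A [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @return A `run_report`: list with `files` (tibble of stage, path,
#'   exists), `counts` (headline numbers) and `config`.
#' @export
run_full <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  files <- list()
  logline <- function(...) writeLines(paste0(...), log_con)
  emit <- function(stage, name, df) {
    path <- file.path(cfg$out_dir, name)
    readr::write_tsv(df, path, na = "NA", progress = FALSE)
    files[[length(files) + 1]] <<- tibble(stage = stage, path = path)
    path
  }
  stage <- "load"
  report <- tryCatch({
    # -- load / simulate ----------------------------------------------------
    panel <- if (!is.null(cfg$simulate)) {
      sim <- simulate_panel(cfg$simulate)
      emit("load", "truth.tsv", sim$truth)
      if (nrow(sim$sweeps)) emit("load", "sweeps_injected.tsv", sim$sweeps)
      sim$panel
    } else {
      read_genotypes(cfg$genotype_path, cfg$metadata_path, cfg$manifest_path)
    }
    logline("load: ", nrow(panel), " accessions x ", length(marker_ids(panel)),
            " markers")

    # -- global structure ---------------------------------------------------
    stage <- "pca_global"
    pca <- panel_pca(panel, k = 2)
    emit(stage, "pca_scores.tsv", pca$scores)
    emit(stage, "pca_explained.tsv", glance(pca))
    logline(stage, ": PC1 ", sprintf("%.1f%%", 100 * pca$explained[1]))

    stage <- "fst_global"
    g <- gst(panel, by = "group", weights = cfg$weights,
             min_calls = cfg$min_calls)
    emit(stage, "global_fst_per_locus.tsv", tidy(g))
    emit(stage, "global_fst.tsv", glance(g))
    logline(stage, ": multilocus Fst ", sprintf("%.4f", g$fst),
            ", Nm ", sprintf("%.4f", g$nm))

    # -- decade grid --------------------------------------------------------
    stage <- "decade_grid"
    has_decades <- any(!is.na(panel$decade))
    if (has_decades) {
      dg <- pair_grid(panel, axis = "decade", weights = cfg$weights,
                      min_calls = cfg$min_calls)
      emit(stage, "decade_grid.tsv", tidy(dg))
      logline(stage, ": ", length(dg$labels), " strata")
    } else {
      logline(stage, ": skipped (no decade metadata)")
    }

    # -- zone trees and per-group PCA --------------------------------------
    stage <- "zone_trees"
    for (grp in intersect(.group_levels, as.character(unique(panel$group)))) {
      sub <- suppressWarnings(filter_panel(panel, group = grp))
      if (length(unique(sub$zone)) >= 3) {
        tr <- neighbor_joining(group_dist(sub, by = "zone",
                                          min_calls = cfg$min_calls))
        path <- file.path(cfg$out_dir, paste0("zone_tree_", grp, ".nwk"))
        write_newick(tr, path)
        files[[length(files) + 1]] <- tibble(stage = stage, path = path)
        sp <- panel_pca(sub, k = 2)
        emit(stage, paste0("pca_scores_", grp, ".tsv"), sp$scores)
      }
    }
    logline(stage, ": done")

    # -- zone-wise diversity ------------------------------------------------
    stage <- "diversity"
    dv <- diversity(panel, by = c("zone", "group"),
                    min_calls = cfg$min_calls, corrected = cfg$corrected)
    emit(stage, "diversity_per_locus.tsv", tidy(dv))
    emit(stage, "diversity_summary.tsv", glance(dv))
    logline(stage, ": mean pi range ",
            sprintf("%.3f-%.3f", min(dv$summary$mean_pi),
                    max(dv$summary$mean_pi)))

    # -- zone-wise CL-vs-MCC Fst/Nm ----------------------------------------
    stage <- "zone_fst"
    zones <- as.character(sort(unique(panel$zone)))
    zone_fst <- purrr::map_dfr(zones, function(z) {
      sub <- suppressWarnings(filter_panel(panel, zone = z))
      if (length(unique(sub$group)) < 2) return(tibble())
      gg <- gst(sub, by = "group", weights = cfg$weights,
                min_calls = cfg$min_calls)
      mutate(glance(gg), zone = z, .before = 1)
    })
    emit(stage, "zone_fst.tsv", zone_fst)
    logline(stage, ": ", nrow(zone_fst), " zones")

    # -- pairwise-zone grids ------------------------------------------------
    stage <- "zone_grids"
    for (grp in intersect(.group_levels, as.character(unique(panel$group)))) {
      pg <- pair_grid(panel, axis = "zone", group = grp,
                      weights = cfg$weights, min_calls = cfg$min_calls)
      emit(stage, paste0("zone_grid_", grp, ".tsv"), tidy(pg))
      emit(stage, paste0("zone_grid_", grp, "_fst_matrix.tsv"),
           as_tibble(cbind(tibble(stratum = pg$labels),
                           as.data.frame(pg$fst))))
    }
    logline(stage, ": done")

    # -- sweep scans --------------------------------------------------------
    stage <- "scan"
    sc <- scan_all(panel, q = cfg$q, min_calls = cfg$min_calls,
                   counting = cfg$counting)
    emit(stage, "scan_per_zone.tsv", sc$scans)
    emit(stage, "scan_thresholds.tsv", sc$thresholds)
    emit(stage, "scan_signals.tsv", tidy(sc))
    emit(stage, "scan_summary.tsv", glance(sc))
    gsc <- global_scan(panel, q = cfg$q, min_calls = cfg$min_calls)
    emit(stage, "scan_global.tsv", as_tibble(gsc))
    logline(stage, ": ", sc$total_signals, " signals across ",
            sc$distinct_markers, " markers")

    # -- allele survey ------------------------------------------------------
    stage <- "survey"
    sv <- survey(panel, min_calls = cfg$min_calls)
    emit(stage, "survey.tsv", sv)
    emit(stage, "variant_classes.tsv", classify_variants(sv))
    logline(stage, ": ", nrow(sv), " rows")

    list(panel = panel, scan = sc, global_fst = g)
  }, error = function(e) {
    logline("ERROR in stage ", stage, ": ", conditionMessage(e))
    abort(paste0("pipeline failed in stage `", stage, "`: ",
                 conditionMessage(e)))
  })

  files <- bind_rows(files)
  files$exists <- file.exists(files$path)
  cfg_echo <- cfg
  cfg_echo$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate)
  yaml::write_yaml(unclass(cfg_echo), file.path(cfg$out_dir, "config_echo.yaml"))
  structure(list(files = files,
                 counts = list(
                   n_accessions = nrow(report$panel),
                   n_markers = length(marker_ids(report$panel)),
                   global_fst = report$global_fst$fst,
                   global_nm = report$global_fst$nm,
                   total_signals = report$scan$total_signals,
                   distinct_markers = report$scan$distinct_markers),
                 config = cfg),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("kaspdiv pipeline run: ", x$counts$n_accessions, " accessions x ",
      x$counts$n_markers, " markers\n",
      "  global Fst ", sprintf("%.4f", x$counts$global_fst),
      ", Nm ", sprintf("%.4f", x$counts$global_nm), "\n",
      "  sweep signals: ", x$counts$total_signals, " (",
      x$counts$distinct_markers, " markers)\n",
      "  ", nrow(x$files), " files in ", x$config$out_dir, "\n", sep = "")
  invisible(x)
}
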