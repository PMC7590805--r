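#' Empirical nearest-rank quantile threshold
#'
#' The threshold used for the top-5% sweep scans: the \eqn{\lceil qL
#' \rceil}-th order statistic of the `L` finite values. Everywhere in the
#' package, values are flagged only when *strictly greater* than the
#' threshold, so with distinct values at most \eqn{L - \lceil qL \rceil}
#' can be flagged and with all values equal nothing is.
#'
#' @param values Numeric; non-finite entries are ignored (at least 2 finite
#'   values required).
#' @param q Quantile in (0, 1), default 0.95.
#' @param type `"nearest_rank"` (default, deterministic) or
#'   `"interpolated"` (type-7 [stats::quantile()]).
#' @return The threshold (scalar).
#' @export
#' @examples
#' empirical_threshold(1:20)          # 19; only 20 exceeds strictly
empirical_threshold <- function(values, q = 0.95,
                                type = c("nearest_rank", "interpolated")) {
  type <- match.arg(type)
  v <- values[is.finite(values)]
  if (length(v) < 2) abort("need at least 2 finite values for a threshold.")
  if (q <= 0 || q >= 1) abort("q must lie in (0, 1).")
  if (type == "nearest_rank") {
    unname(sort(v)[ceiling(q * length(v))])
  } else {
    unname(quantile(v, q, type = 7))
  }
}

#' Selective-sweep scan of one zone (CL vs MCC)
#'
#' Per marker within the zone: the per-locus Nei Gst between CL and MCC and
#' the diversity ratio \eqn{\pi_{CL}/\pi_{MCC}} (uncorrected \eqn{\pi}).
#' Each statistic is thresholded independently at its empirical top-`1-q`
#' level ([empirical_threshold()] over the finite defined values); a value
#' strictly exceeding its threshold is a selection signal. Infinite
#' \eqn{\pi}-ratios (diversity wiped out in MCC) never enter threshold
#' estimation but do count as signals, since they exceed any finite
#' threshold.
#'
#' @param panel A `geno_tbl`.
#' @param zone Zone label (Roman numeral); `NULL` scans the pooled panel.
#' @param q Signal quantile, default 0.95 (top 5%).
#' @param min_calls Minimum non-missing accessions per (group, locus).
#' @param type Threshold type, see [empirical_threshold()].
#' @return A `zone_scan` tibble: `marker_id`, `fst`, `pi_cl`, `pi_mcc`,
#'   `pi_ratio`, `ratio_flag`, `fst_signal`, `pi_signal`; attributes
#'   `thresholds` (named numeric `fst`, `pi_ratio`), `zone`, `q`.
#' @export
scan_zone <- function(panel, zone, q = 0.95, min_calls = 5,
                      type = "nearest_rank") {
  sub <- if (is.null(zone)) panel else
    suppressWarnings(filter_panel(panel, zone = zone))
  n_by_group <- table(factor(sub$group, levels = .group_levels))
  if (any(n_by_group == 0)) {
    abort(paste0("zone ", zone %||% "(pooled)",
                 " lacks accessions in group(s): ",
                 paste(names(n_by_group)[n_by_group == 0], collapse = ", ")))
  }
  fm <- freq_matrix(sub, by = "group", min_calls = min_calls)
  labs <- fm$strata$group
  g <- gst_from_freqs(fm$p[match("CL", labs), ], fm$p[match("MCC", labs), ])
  pr <- pi_ratio(sub, min_calls = min_calls)

  # degenerate panels can leave a statistic with <2 finite values; the
  # threshold is then undefined and nothing can be flagged for it
  thr_of <- function(v) {
    if (sum(is.finite(v)) < 2) NA_real_ else
      empirical_threshold(v, q = q, type = type)
  }
  thr_fst <- thr_of(g$per_locus$fst)
  thr_pi <- thr_of(pr$pi_ratio)
  out <- tibble(
    marker_id = colnames(fm$p),
    fst = g$per_locus$fst,
    pi_cl = pr$pi_num,
    pi_mcc = pr$pi_den,
    pi_ratio = pr$pi_ratio,
    ratio_flag = pr$ratio_flag,
    fst_signal = !is.na(thr_fst) & !is.na(g$per_locus$fst) &
      g$per_locus$fst > thr_fst,
    pi_signal = !is.na(thr_pi) & !is.na(pr$pi_ratio) & pr$pi_ratio > thr_pi
  )
  structure(out, thresholds = c(fst = thr_fst, pi_ratio = thr_pi),
            zone = if (is.null(zone)) NA_character_ else zone, q = q,
            class = c("zone_scan", class(tibble())))
}

#' Pooled CL-vs-MCC sweep scan ignoring zones
#'
#' Identical computation to [scan_zone()] on the whole panel (pooled CL
#' against pooled MCC), with thresholds recomputed on the pooled
#' statistics.
#'
#' @inheritParams scan_zone
#' @return A `zone_scan` tibble (see [scan_zone()]) with `zone = NA`.
#' @export
global_scan <- function(panel, q = 0.95, min_calls = 5, type = "nearest_rank") {
  scan_zone(panel, zone = NULL, q = q, min_calls = min_calls, type = type)
}

#' Zone-wise sweep scan over the whole panel
#'
#' Runs [scan_zone()] for every zone present and aggregates the signals.
#' Under the default `counting = "per_statistic"` each (zone, marker,
#' statistic) exceedance is one signal — a marker exceeding both the Fst
#' and the \eqn{\pi}-ratio thresholds in a zone contributes two;
#' `"per_marker"` collapses the two statistics.
#'
#' @inheritParams scan_zone
#' @param counting `"per_statistic"` (default) or `"per_marker"`.
#' @return Object of class `scan_summary`: list with `scans` (bound
#'   `zone_scan` rows with a `zone` column), `thresholds` (per-zone tibble),
#'   `signals` (tibble `zone`, `marker_id`, `statistic`, `value`),
#'   `per_zone_counts`, `total_signals`, `distinct_markers`, `q`,
#'   `counting`. `tidy()` returns the signal table, `glance()` the per-zone
#'   counts.
#' @export
scan_all <- function(panel, q = 0.95, min_calls = 5,
                     counting = c("per_statistic", "per_marker"),
                     type = "nearest_rank") {
  counting <- match.arg(counting)
  zones <- as.character(sort(unique(panel$zone)))
  pieces <- lapply(zones, function(z) {
    sc <- scan_zone(panel, z, q = q, min_calls = min_calls, type = type)
    list(scan = mutate(as_tibble(sc), zone = z, .before = 1),
         thr = tibble(zone = z,
                      fst_threshold = attr(sc, "thresholds")[["fst"]],
                      pi_ratio_threshold = attr(sc, "thresholds")[["pi_ratio"]]))
  })
  scans <- bind_rows(lapply(pieces, `[[`, "scan"))
  thresholds <- bind_rows(lapply(pieces, `[[`, "thr"))
  sig_fst <- scans |> filter(.data$fst_signal) |>
    mutate(statistic = "fst", value = .data$fst)
  sig_pi <- scans |> filter(.data$pi_signal) |>
    mutate(statistic = "pi_ratio", value = .data$pi_ratio)
  signals <- bind_rows(sig_fst, sig_pi) |>
    select(all_of(c("zone", "marker_id", "statistic", "value"))) |>
    arrange(.data$zone, .data$marker_id, .data$statistic)
  counted <- if (counting == "per_marker") {
    distinct(signals, .data$zone, .data$marker_id)
  } else {
    signals
  }
  per_zone <- counted |> dplyr::count(.data$zone, name = "n_signals") |>
    tidyr::complete(zone = zones, fill = list(n_signals = 0L))
  structure(list(scans = scans, thresholds = thresholds, signals = signals,
                 per_zone_counts = per_zone,
                 total_signals = nrow(counted),
                 distinct_markers = dplyr::n_distinct(signals$marker_id),
                 q = q, counting = counting),
            class = "scan_summary")
}

#' @export
print.scan_summary <- function(x, ...) {
  cat("Zone-wise sweep scan (top ", round(100 * (1 - x$q)), "%, ",
      x$counting, " counting)\n",
      "  total signals: ", x$total_signals,
      " across ", x$distinct_markers, " distinct markers\n", sep = "")
  print(x$per_zone_counts, n = Inf)
  invisible(x)
}

#' @rdname scan_all
#' @param x A `scan_summary`.
#' @param ... Unused.
#' @export
tidy.scan_summary <- function(x, ...) x$signals

#' @rdname scan_all
#' @export
glance.scan_summary <- function(x, ...) {
  mutate(x$per_zone_counts,
         total_signals = x$total_signals,
         distinct_markers = x$distinct_markers)
}

#' @rdname scan_all
#' @param object A `scan_summary`.
#' @export
autoplot.scan_summary <- function(object, ...) {
  df <- object$scans |>
    tidyr::pivot_longer(all_of(c("fst", "pi_ratio")),
                        names_to = "statistic", values_to = "value") |>
    filter(is.finite(.data$value))
  thr <- object$thresholds |>
    tidyr::pivot_longer(-"zone", names_to = "statistic",
                        values_to = "threshold") |>
    mutate(statistic = sub("_threshold$", "", .data$statistic))
  ggplot2::ggplot(df, ggplot2::aes(.data$marker_id, .data$value)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_grid(statistic ~ zone, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "marker", y = NULL)
}
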