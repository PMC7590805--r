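#' Allele survey per zone and group
#'
#' One row per (zone, group, marker): favorable-allele carrier frequency,
#' B-allele frequency and sample size, via [allele_freqs()]. Rows are
#' exhaustive over zones x groups present in the panel x markers; empty or
#' under-called strata are flagged (`defined = FALSE`), never dropped.
#'
#' @inheritParams allele_freqs
#' @return A tibble with `zone`, `group`, `marker_id`, `gene`,
#'   `favorable_allele`, `carrier_freq`, `p`, `carrier_a`, `carrier_b`,
#'   `n_calls`, `n_missing`, `defined`.
#' @export
survey <- function(panel, min_calls = 5) {
  allele_freqs(panel, by = c("zone", "group"), min_calls = min_calls,
               complete = TRUE) |>
    select(all_of(c("zone", "group", "marker_id", "gene", "favorable_allele",
                    "carrier_freq", "p", "carrier_a", "carrier_b",
                    "n_calls", "n_missing", "defined")))
}

#' Fixed-variant and rare-allele counts per stratum
#'
#' Classifies marker alleles within each stratum of a frequency table by
#' carrier frequency (the fraction of accessions carrying the allele, the
#' unit in which the source analyses report percentages):
#' * a marker is a **fixed variant** when its majority allele is carried by
#'   at least `fixed_cut` of the accessions (inclusive bound, default 0.95);
#' * an allele is **rare** when carried by strictly fewer than `rare_cut`
#'   (default 0.05).
#' Each marker contributes two classifiable alleles, so `n_total` is twice
#' the number of defined markers (a fixed marker's minor allele is
#' typically also rare, and both classifications are reported).
#'
#' @param freqs A frequency table from [survey()] or [allele_freqs()]
#'   containing `carrier_a`, `carrier_b`, `defined` and grouping columns.
#' @param fixed_cut Inclusive fixation bound (default 0.95).
#' @param rare_cut Strict rarity bound (default 0.05).
#' @param by Grouping columns of `freqs`; defaults to those of
#'   `c("zone", "group", "decade")` present.
#' @return Tibble per stratum: `n_fixed`, `n_rare`, `n_total` (classifiable
#'   alleles = 2 x defined markers), `n_markers_defined`.
#' @export
classify_variants <- function(freqs, fixed_cut = 0.95, rare_cut = 0.05,
                              by = intersect(c("zone", "group", "decade"),
                                             names(freqs))) {
  stopifnot(all(c("carrier_a", "carrier_b", "defined") %in% names(freqs)))
  freqs |>
    group_by(across(all_of(by))) |>
    summarise(
      n_fixed = sum(.data$defined &
                      pmax(.data$carrier_a, .data$carrier_b) >= fixed_cut),
      n_rare = sum(.data$defined & .data$carrier_a < rare_cut) +
               sum(.data$defined & .data$carrier_b < rare_cut),
      n_markers_defined = sum(.data$defined),
      n_total = 2L * sum(.data$defined),
      .groups = "drop")
}

#' Pairwise differentiation grid between zones or decade strata
#'
#' All pairwise multilocus Nei Gst values (and the derived island-model
#' gene flow) between the strata of an axis:
#' * `axis = "zone"`: the ten agro-ecological zones, optionally restricted
#'   to one group (`group = "CL"` or `"MCC"`), as in zone-by-zone heat
#'   maps;
#' * `axis = "decade"`: the CL pool plus one stratum per MCC release
#'   decade, the breeding-era comparison grid.
#'
#' @param panel A `geno_tbl`.
#' @param axis `"zone"` or `"decade"`.
#' @param group Optional group restriction for the zone axis.
#' @param weights,min_calls Passed to the Gst computation, see [gst()].
#' @return Object of class `pair_grid`: list with `labels`, symmetric
#'   matrices `fst` (zero diagonal) and `nm` (`NA` diagonal: gene flow is
#'   undefined for a stratum against itself), `axis`, `group`. `tidy()`
#'   returns the long pair table; `autoplot()` a heat-map.
#' @export
pair_grid <- function(panel, axis = c("zone", "decade"), group = NULL,
                      weights = "equal", min_calls = 5) {
  axis <- match.arg(axis)
  if (axis == "zone") {
    sub <- if (is.null(group)) panel else
      suppressWarnings(filter_panel(panel, group = group))
    if (nrow(sub) == 0L) abort("no accessions left after group restriction.")
    strata_of <- as.character(sub$zone)
  } else {
    sub <- panel
    strata_of <- ifelse(sub$group == "CL", "CL",
                        ifelse(is.na(sub$decade), NA, paste0(sub$decade, "s")))
    if (anyNA(strata_of)) {
      abort("MCC accessions without a decade cannot enter the decade grid.")
    }
  }
  counts <- table(strata_of)
  if (any(counts == 0)) abort(paste0("empty stratum: ",
                                     paste(names(counts)[counts == 0], collapse = ", ")))
  labels <- if (axis == "zone") {
    intersect(.zone_levels(), names(counts))
  } else {
    c(intersect("CL", names(counts)), sort(setdiff(names(counts), "CL")))
  }
  fm <- freq_matrix_by_vector(sub, strata_of, min_calls = min_calls)
  k <- length(labels)
  fst <- matrix(0, k, k, dimnames = list(labels, labels))
  nm <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      g <- gst_from_freqs(fm$p[labels[a], ], fm$p[labels[b], ],
                          n1 = fm$n[labels[a], ], n2 = fm$n[labels[b], ],
                          weights = weights)
      fst[a, b] <- fst[b, a] <- g$fst
      nm[a, b] <- nm[b, a] <- suppressWarnings(nm_from_fst(g$fst))
    }
  }
  structure(list(labels = labels, fst = fst, nm = nm,
                 axis = axis, group = group),
            class = "pair_grid")
}

# frequency matrix keyed by an arbitrary stratum vector
freq_matrix_by_vector <- function(panel, strata, min_calls = 5) {
  z <- dosage_matrix(panel)
  g <- factor(strata)
  scored <- !is.na(z)
  nc <- rowsum(scored * 1L, g)
  nb <- rowsum(ifelse(scored, z, 0L), g)
  p <- ifelse(nc >= min_calls, nb / (2 * nc), NA_real_)
  list(p = p, n = 2L * nc)
}

#' @export
print.pair_grid <- function(x, ...) {
  cat("Pairwise Gst grid over ", x$axis, " strata",
      if (!is.null(x$group)) paste0(" (", x$group, " only)"), ":\n", sep = "")
  print(round(x$fst, 3))
  invisible(x)
}

#' @rdname pair_grid
#' @param x A `pair_grid`.
#' @param ... Unused.
#' @export
tidy.pair_grid <- function(x, ...) {
  pairs <- which(upper.tri(x$fst), arr.ind = TRUE)
  tibble(stratum_1 = x$labels[pairs[, 1]],
         stratum_2 = x$labels[pairs[, 2]],
         fst = x$fst[pairs],
         nm = x$nm[pairs])
}

#' @rdname pair_grid
#' @param object A `pair_grid`.
#' @param statistic `"fst"` or `"nm"`.
#' @export
autoplot.pair_grid <- function(object, statistic = c("fst", "nm"), ...) {
  statistic <- match.arg(statistic)
  m <- object[[statistic]]
  df <- tibble(stratum_1 = factor(rep(object$labels, times = length(object$labels)),
                                  levels = object$labels),
               stratum_2 = factor(rep(object$labels, each = length(object$labels)),
                                  levels = rev(object$labels)),
               value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$stratum_1, .data$stratum_2,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = statistic) +
    ggplot2::theme_minimal()
}
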