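#' Nei's Gst (Fst) between two groups, with island-model gene flow
#'
#' Per locus, with group B-allele frequencies \eqn{p_1, p_2}:
#' \eqn{H_S} = weighted mean of the within-group gene diversities
#' \eqn{2p_i(1-p_i)}, \eqn{\bar p} = the same weighted mean of frequencies,
#' \eqn{H_T = 2\bar p(1-\bar p)}, and \eqn{F_{ST} = (H_T - H_S)/H_T}
#' where \eqn{H_T > 0} (undefined otherwise). Groups are equally weighted by
#' default (`weights = "equal"`, the legacy-tool convention); `"size"`
#' weights by scored allele copies. The multilocus value is the
#' ratio-of-sums \eqn{\sum(H_T - H_S)/\sum H_T} over loci defined in both
#' groups and polymorphic in the pool; the mean of per-locus values is also
#' reported. Gene flow is \eqn{N_m = (1 - F_{ST})/(4 F_{ST})} from the
#' multilocus value.
#'
#' @param panel A `geno_tbl` containing both groups.
#' @param by Metadata column whose levels define the two groups (default
#'   `"group"`).
#' @param levels Length-2 character: which two levels of `by` to compare;
#'   default the two levels present (error if not exactly two).
#' @param weights `"equal"` or `"size"`.
#' @param min_calls Minimum non-missing accessions per (group, locus).
#' @return Object of class `gst_result`: list with `per_locus` (tibble
#'   `marker_id`, `p1`, `p2`, `hs`, `ht`, `fst`, `defined`), `fst`
#'   (multilocus ratio-of-sums), `fst_mean` (mean of per-locus values),
#'   `nm`, `group_pair`, `n_loci_used`. `tidy()` returns the per-locus
#'   table; `glance()` a one-row summary.
#' @export
gst <- function(panel, by = "group", levels = NULL, weights = c("equal", "size"),
                min_calls = 5) {
  weights <- match.arg(weights)
  fm <- freq_matrix(panel, by = by, min_calls = min_calls)
  labs <- do.call(paste, c(fm$strata, sep = "\r"))
  if (is.null(levels)) {
    if (length(labs) != 2L) {
      abort("panel has more (or fewer) than two groups; supply `levels`.")
    }
    levels <- labs
  }
  if (!all(levels %in% labs)) abort("requested group level(s) absent from panel.")
  i <- match(levels, labs)
  res <- gst_from_freqs(fm$p[i[1], ], fm$p[i[2], ],
                        n1 = fm$n_alleles[i[1], ], n2 = fm$n_alleles[i[2], ],
                        weights = weights)
  res$per_locus <- dplyr::bind_cols(tibble(marker_id = colnames(fm$p)),
                                    res$per_locus)
  structure(c(res, list(group_pair = levels, weights = weights)),
            class = "gst_result")
}

# workhorse shared by gst(), pair_grid() and the sweep scans;
# p1/p2 may contain NA (undefined loci), n1/n2 are scored allele copies
gst_from_freqs <- function(p1, p2, n1 = NULL, n2 = NULL, weights = "equal") {
  p1 <- unname(p1); p2 <- unname(p2)
  if (weights == "size") {
    if (is.null(n1) || is.null(n2)) abort("size weights need allele counts.")
    w1 <- n1 / (n1 + n2)
  } else {
    w1 <- rep(0.5, length(p1))
  }
  w2 <- 1 - w1
  hs <- w1 * 2 * p1 * (1 - p1) + w2 * 2 * p2 * (1 - p2)
  pbar <- w1 * p1 + w2 * p2
  ht <- 2 * pbar * (1 - pbar)
  defined <- !is.na(p1) & !is.na(p2) & ht > 0
  fst <- ifelse(defined, (ht - hs) / ht, NA_real_)
  multilocus <- if (any(defined)) {
    sum(ht[defined] - hs[defined]) / sum(ht[defined])
  } else {
    abort("no locus is defined in both groups.")
  }
  list(per_locus = tibble(p1 = p1, p2 = p2, hs = hs, ht = ht,
                          fst = fst, defined = defined),
       fst = multilocus,
       fst_mean = mean(fst[defined]),
       nm = suppressWarnings(nm_from_fst(multilocus)),
       n_loci_used = sum(defined))
}

#' @export
print.gst_result <- function(x, ...) {
  cat("Nei Gst between ", paste(x$group_pair, collapse = " and "),
      " (", x$n_loci_used, " loci, ", x$weights, " weights)\n",
      "  multilocus Fst = ", signif(x$fst, 4),
      "  (mean of per-locus = ", signif(x$fst_mean, 4), ")\n",
      "  gene flow Nm   = ", signif(x$nm, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname gst
#' @param x A `gst_result`.
#' @param ... Unused.
#' @export
tidy.gst_result <- function(x, ...) x$per_locus

#' @rdname gst
#' @export
glance.gst_result <- function(x, ...) {
  tibble(group_1 = x$group_pair[1], group_2 = x$group_pair[2],
         fst = x$fst, fst_mean = x$fst_mean, nm = x$nm,
         n_loci_used = x$n_loci_used)
}

#' Multilocus Gst across all strata of a partition
#'
#' The k-group generalization of [gst()]: per locus, \eqn{H_S} is the
#' unweighted mean of the stratum gene diversities, \eqn{H_T} the gene
#' diversity of the mean frequency, combined across loci by ratio-of-sums.
#' With strata drawn from a Balding-Nichols distribution at parameter `F`,
#' this statistic converges to `F` as the number of strata grows (up to a
#' \eqn{(1 - 1/k)} factor), so it is the package's estimator for recovering
#' the simulator's differentiation parameter.
#'
#' @param panel A `geno_tbl`.
#' @param by Metadata columns defining the strata; default
#'   `c("zone", "group")`.
#' @param min_calls Minimum non-missing accessions per (stratum, locus).
#' @return One-row tibble with `fst` (multilocus Gst), `n_strata`,
#'   `n_loci_used`.
#' @export
gst_strata <- function(panel, by = c("zone", "group"), min_calls = 5) {
  fm <- freq_matrix(panel, by = by, min_calls = min_calls)
  p <- fm$p
  k <- nrow(p)
  if (k < 2) abort("need at least 2 strata.")
  defined_n <- colSums(!is.na(p))
  hs <- colMeans(2 * p * (1 - p), na.rm = TRUE)
  pbar <- colMeans(p, na.rm = TRUE)
  ht <- 2 * pbar * (1 - pbar)
  ok <- defined_n == k & ht > 0
  if (!any(ok)) abort("no locus is defined in all strata.")
  tibble(fst = sum(ht[ok] - hs[ok]) / sum(ht[ok]),
         n_strata = k, n_loci_used = sum(ok))
}

#' Island-model gene flow from Fst, and back
#'
#' Wright's island-model relation \eqn{N_m = (1 - F_{ST})/(4 F_{ST})}.
#' Outside the open interval (0, 1) the quantity is undefined and `NA` is
#' returned with a warning (e.g. on the diagonal of a pairwise grid).
#'
#' @param fst Fixation index (vectorized).
#' @return Effective migrant number(s) `Nm`.
#' @export
#' @examples
#' nm_from_fst(0.5)      # 0.25
#' nm_from_fst(0.0439)   # ~5.44
nm_from_fst <- function(fst) {
  bad <- !is.na(fst) & (fst <= 0 | fst >= 1)
  if (any(bad)) warn("Nm undefined for Fst outside (0, 1); returning NA.")
  out <- ifelse(is.na(fst) | bad, NA_real_, (1 - fst) / (4 * fst))
  out
}

#' @rdname nm_from_fst
#' @param nm Effective migrant number (vectorized), `> 0`.
#' @export
fst_from_nm <- function(nm) {
  bad <- !is.na(nm) & nm <= 0
  if (any(bad)) warn("Fst undefined for Nm <= 0; returning NA.")
  ifelse(is.na(nm) | bad, NA_real_, 1 / (4 * nm + 1))
}
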