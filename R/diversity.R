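#' Per-site nucleotide diversity from an allele frequency
#'
#' For a biallelic site with B-allele frequency `p`, the uncorrected value
#' is Nei's gene diversity \eqn{\pi = 2p(1-p)} (the package default, matching
#' the legacy population-genetics tools this analysis reproduces). With
#' `corrected = TRUE` the unbiased small-sample version
#' \eqn{\pi = \frac{n}{n-1} 2p(1-p)} is returned, which equals the average
#' pairwise difference over all \eqn{\binom{n}{2}} pairs of sampled allele
#' copies.
#'
#' @param p B-allele frequency (vectorized), in `[0, 1]`.
#' @param n_alleles Number of scored allele copies; required (and `>= 2`)
#'   when `corrected = TRUE`.
#' @param corrected Apply the `n/(n-1)` correction? Default `FALSE`.
#' @return Numeric vector of diversity values in `[0, 1]`.
#' @export
#' @examples
#' site_pi(0.09)                       # 0.1638
#' site_pi(0.5, n_alleles = 44, corrected = TRUE)
site_pi <- function(p, n_alleles = NULL, corrected = FALSE) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p must lie in [0, 1].")
  pi0 <- 2 * p * (1 - p)
  if (!corrected) return(pi0)
  if (is.null(n_alleles)) abort("n_alleles is required when corrected = TRUE.")
  if (any(n_alleles < 2, na.rm = TRUE)) {
    abort("n_alleles must be >= 2 for the corrected estimator.")
  }
  n_alleles / (n_alleles - 1) * pi0
}

#' Nucleotide diversity of panel groups
#'
#' Applies [site_pi()] to the group allele frequencies of every marker and
#' averages over the loci where the frequency is defined (at least
#' `min_calls` non-missing accessions).
#'
#' @inheritParams allele_freqs
#' @param corrected Use the small-sample-corrected estimator? Default
#'   `FALSE` (see [site_pi()]).
#' @return An object of class `div_result`: list with `per_locus` (tibble of
#'   the `by` columns, `marker_id`, `pi`, `defined`) and `summary` (tibble
#'   with `mean_pi` and `n_loci_used` per group). `tidy()` returns the
#'   per-locus table, `glance()` the summary.
#' @export
diversity <- function(panel, by = "group", min_calls = 5, corrected = FALSE) {
  fr <- allele_freqs(panel, by = by, min_calls = min_calls)
  pi <- rep(NA_real_, nrow(fr))
  ok <- fr$defined
  pi[ok] <- site_pi(fr$p[ok], fr$n_alleles[ok], corrected = corrected)
  per_locus <- dplyr::bind_cols(fr[c(by, "marker_id")],
                                tibble(pi = pi, defined = ok))
  if (!any(ok)) abort("no locus has a defined frequency in any group.")
  summary <- per_locus |>
    group_by(across(all_of(by))) |>
    summarise(mean_pi = mean(.data$pi[.data$defined]),
              n_loci_used = sum(.data$defined), .groups = "drop")
  structure(list(per_locus = per_locus, summary = summary,
                 by = by, corrected = corrected, min_calls = min_calls),
            class = "div_result")
}

#' @export
print.div_result <- function(x, ...) {
  cat("Nucleotide diversity (", if (x$corrected) "corrected" else "uncorrected",
      " pi), by ", paste(x$by, collapse = " x "), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname diversity
#' @param x A `div_result`.
#' @param ... Unused.
#' @export
tidy.div_result <- function(x, ...) x$per_locus

#' @rdname diversity
#' @export
glance.div_result <- function(x, ...) x$summary

#' Per-marker diversity ratio between two groups
#'
#' The \eqn{\pi}-ratio \eqn{\pi_{CL}/\pi_{MCC}} per marker: values below 1
#' indicate diversity gain in the second group at that locus, large values
#' indicate diversity loss (a selective-sweep signature). Degenerate cases
#' are flagged: `0/0` is undefined (`NA`, flag `"zero_zero"`), `x/0` with
#' `x > 0` is `Inf` (flag `"infinite"`); loci undefined in either group get
#' flag `"undefined"`.
#'
#' @param panel A `geno_tbl`.
#' @param numerator,denominator Group labels (levels of `group`), defaults
#'   `"CL"` and `"MCC"`.
#' @inheritParams diversity
#' @return Tibble with `marker_id`, `pi_num`, `pi_den`, `pi_ratio`,
#'   `ratio_flag`.
#' @export
pi_ratio <- function(panel, numerator = "CL", denominator = "MCC",
                     min_calls = 5, corrected = FALSE) {
  d <- diversity(panel, by = "group", min_calls = min_calls,
                 corrected = corrected)$per_locus
  num <- d[d$group == numerator, ]
  den <- d[d$group == denominator, ]
  stopifnot(identical(num$marker_id, den$marker_id))
  ratio <- num$pi / den$pi
  flag <- dplyr::case_when(
    !num$defined | !den$defined ~ "undefined",
    den$pi == 0 & num$pi == 0 ~ "zero_zero",
    den$pi == 0 ~ "infinite",
    TRUE ~ "ok"
  )
  ratio[flag %in% c("undefined", "zero_zero")] <- NA_real_
  ratio[flag == "infinite"] <- Inf
  tibble(marker_id = num$marker_id, pi_num = num$pi, pi_den = den$pi,
         pi_ratio = ratio, ratio_flag = flag)
}
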