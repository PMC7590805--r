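#' Principal component analysis of the dosage-encoded panel
#'
#' Encodes calls as B-allele dosage (0/1/2), imputes missing entries with
#' the locus mean, mean-centers columns (no variance scaling) and projects
#' onto the top-`k` eigenvectors of the covariance matrix. The sign of each
#' component is fixed by making its largest-magnitude loading positive, so
#' scores are reproducible across accession orderings.
#'
#' @param panel A `geno_tbl` with at least 2 accessions and at least one
#'   polymorphic marker.
#' @param k Number of components to keep (default 2, clipped to the rank).
#' @return Object of class `panel_pca`: list with `scores` (tibble of the
#'   accession metadata plus `PC1..PCk`), `explained` (variance fractions,
#'   all components), `loadings` (markers x k), `k`. `tidy()` returns the
#'   score table; `glance()` the explained-variance fractions; `autoplot()`
#'   a PC1-PC2 scatter.
#' @export
panel_pca <- function(panel, k = 2) {
  stopifnot(inherits(panel, "geno_tbl"))
  if (nrow(panel) < 2) abort("need at least 2 accessions for PCA.")
  z <- dosage_matrix(panel)
  mu <- colMeans(z, na.rm = TRUE)
  idx <- which(is.na(z), arr.ind = TRUE)
  if (nrow(idx)) z[idx] <- mu[idx[, 2]]
  keep <- apply(z, 2, function(col) stats::var(col) > 0)
  if (!any(keep)) abort("all loci are monomorphic; PCA undefined.")
  z <- z[, keep, drop = FALSE]
  fit <- prcomp(z, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(fit$rotation))
  flip <- vapply(seq_len(k), function(j) {
    lo <- fit$rotation[, j]
    sign(lo[which.max(abs(lo))])
  }, numeric(1))
  scores <- sweep(fit$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  loadings <- sweep(fit$rotation[, seq_len(k), drop = FALSE], 2, flip, `*`)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  out <- dplyr::bind_cols(as_tibble(panel)[meta_cols],
                          as_tibble(scores))
  structure(list(scores = out, explained = explained,
                 loadings = loadings, k = k,
                 total_variance = sum(fit$sdev^2)),
            class = "panel_pca")
}

#' @export
print.panel_pca <- function(x, ...) {
  cat("PCA of dosage matrix: ", nrow(x$scores), " accessions, ",
      x$k, " components kept\n", sep = "")
  cat("explained variance: ",
      paste0(sprintf("PC%d %.1f%%", seq_len(x$k),
                     100 * x$explained[seq_len(x$k)]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname panel_pca
#' @param x A `panel_pca`.
#' @param ... Unused.
#' @export
tidy.panel_pca <- function(x, ...) x$scores

#' @rdname panel_pca
#' @export
glance.panel_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$explained)),
         explained_variance_fraction = x$explained)
}

#' @rdname panel_pca
#' @param object A `panel_pca`.
#' @param colour Metadata column mapped to point colour (default `"group"`).
#' @export
autoplot.panel_pca <- function(object, colour = "group", ...) {
  stopifnot(object$k >= 2)
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               colour = .data[[colour]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])) +
    ggplot2::theme_minimal()
}
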