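#' Nei (1972) genetic identity and distance
#'
#' For two taxa with per-locus biallelic frequency vectors (here summarised
#' by the B-allele frequency, so allele frequencies are `(1 - p, p)`):
#' \deqn{J_{xy} = \overline{\sum_a x_a y_a}, \quad
#'       I = J_{xy} / \sqrt{J_x J_y}, \quad D = -\ln I,}
#' with the bar averaging over loci defined in both taxa. `D = 0` iff the
#' frequency vectors agree at every shared locus; `I = 0` (possible only
#' with fixed opposite alleles at every locus) is reported as `D = Inf`.
#'
#' @param px,py Numeric vectors of B-allele frequencies on the same locus
#'   set; `NA` entries are excluded pairwise.
#' @return One-row tibble with `identity` (I) and `distance` (D).
#' @export
#' @examples
#' nei_distance(1, 0.5)   # I = 0.7071, D = 0.3466
nei_distance <- function(px, py) {
  if (length(px) != length(py)) abort("frequency vectors differ in length (locus sets differ).")
  ok <- !is.na(px) & !is.na(py)
  if (!any(ok)) abort("no shared defined locus between the two taxa.")
  x <- px[ok]; y <- py[ok]
  jxy <- mean(x * y + (1 - x) * (1 - y))
  jx <- mean(x^2 + (1 - x)^2)
  jy <- mean(y^2 + (1 - y)^2)
  i <- min(jxy / sqrt(jx * jy), 1)
  tibble(identity = i, distance = if (i > 0) -log(i) else Inf)
}

#' Pairwise Nei distance matrix between accessions
#'
#' Each accession's per-locus "frequency" vector is its B-allele dosage / 2
#' (0, 0.5 or 1), the standard device for individual-level Nei distances on
#' inbred panels. Loci missing in either member of a pair are excluded
#' pairwise; a pair sharing no scored locus is an error.
#'
#' @param panel A `geno_tbl` with at least 3 accessions.
#' @return Symmetric numeric matrix with zero diagonal, dimnames =
#'   accession ids.
#' @export
accession_dist <- function(panel) {
  stopifnot(inherits(panel, "geno_tbl"))
  if (nrow(panel) < 3) abort("need at least 3 accessions for a distance matrix.")
  p <- dosage_matrix(panel) / 2
  nei_dist_matrix(p)
}

#' Pairwise Nei distance matrix between strata frequency vectors
#'
#' Computes group-level allele frequencies per stratum (e.g. one frequency
#' vector per agro-ecological zone) and returns the pairwise Nei distance
#' matrix between strata — the input for zone-level neighbor-joining trees.
#'
#' @inheritParams allele_freqs
#' @return Symmetric numeric matrix with zero diagonal, dimnames = stratum
#'   labels (levels of `by` joined by `"/"` when several columns).
#' @export
group_dist <- function(panel, by = "zone", min_calls = 5) {
  fm <- freq_matrix(panel, by = by, min_calls = min_calls)
  p <- fm$p
  rownames(p) <- do.call(paste, c(fm$strata, sep = "/"))
  nei_dist_matrix(p)
}

# vectorized pairwise Nei distance over rows of a frequency matrix
# (NA entries excluded pairwise)
nei_dist_matrix <- function(p) {
  m <- !is.na(p)
  x <- ifelse(m, p, 0)
  y <- 1 - x
  y[!m] <- 0
  shared <- m %*% t(m)
  if (any(shared[upper.tri(shared)] == 0)) {
    abort("some pair of rows shares no defined locus.")
  }
  sxy <- x %*% t(x) + y %*% t(y)
  q <- (x^2 + y^2) * m
  jx_pair <- q %*% t(m)          # sum of self-products over shared loci
  jxy <- sxy / shared
  jx <- jx_pair / shared
  i_mat <- pmin(jxy / sqrt(jx * t(jx)), 1)
  d <- -log(i_mat)
  d[i_mat == 0] <- Inf
  diag(d) <- 0
  d[d < 0] <- 0                   # guard tiny negative rounding
  dimnames(d) <- list(rownames(p), rownames(p))
  d
}
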