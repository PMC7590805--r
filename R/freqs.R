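#' Per-group allele and carrier frequencies
#'
#' For each group of the chosen stratification and each marker, counts allele
#' copies under ordinary diploid counting (a heterozygote contributes one
#' copy of each allele) and reports:
#' \describe{
#'   \item{p}{frequency of the B allele among scored copies;}
#'   \item{carrier_freq}{fraction of non-missing accessions carrying at
#'     least one copy of the manifest's favorable allele;}
#'   \item{carrier_a, carrier_b}{the same carrier fraction for each allele
#'     orientation (used by the fixed/rare classification);}
#'   \item{n_alleles}{scored allele copies (2 per non-missing diploid);}
#'   \item{n_missing}{accessions without a call.}
#' }
#' Markers with fewer than `min_calls` non-missing accessions in a group are
#' retained with `defined = FALSE` and `NA` frequencies — flagged, never
#' silently dropped.
#'
#' @param panel A `geno_tbl`.
#' @param by Metadata columns defining the grouping partition; default
#'   `"group"` (CL vs MCC). Any subset of `c("zone", "group", "decade")`.
#' @param min_calls Minimum non-missing accessions per (group, marker) for
#'   frequencies to be defined (default 5).
#' @param complete If `TRUE`, include rows for empty strata (all
#'   combinations of the `by` levels present in the panel).
#' @return A tibble with the `by` columns, `marker_id`, `gene`,
#'   `favorable_allele`, `p`, `carrier_freq`, `carrier_a`, `carrier_b`,
#'   `n_alleles`, `n_missing`, `n_calls`, `defined`.
#' @export
allele_freqs <- function(panel, by = "group", min_calls = 5, complete = FALSE) {
  stopifnot(inherits(panel, "geno_tbl"))
  bad <- setdiff(by, setdiff(meta_cols, "accession_id"))
  if (length(bad)) abort(paste0("unknown grouping column(s): ",
                                paste(bad, collapse = ", ")))
  if (nrow(panel) == 0L) abort("panel has no accessions.")

  key_df <- as_tibble(panel)[by]
  key_df[] <- lapply(key_df, as.character)
  g <- interaction(key_df, drop = !complete, sep = "\r", lex.order = TRUE)
  if (anyNA(g)) abort("grouping columns contain NA for some accessions (not a partition).")

  z <- dosage_matrix(panel)
  scored <- !is.na(z)
  z0 <- ifelse(scored, z, 0L)
  n_calls <- rowsum_by(scored * 1L, g)            # groups x markers
  n_b <- rowsum_by(z0, g)
  has_b <- rowsum_by((z >= 1L & scored) * 1L, g)
  has_a <- rowsum_by((z <= 1L & scored) * 1L, g)

  man <- manifest(panel)
  n_grp <- nrow(n_calls)
  keys <- do.call(rbind, strsplit(rownames(n_calls), "\r", fixed = TRUE))
  key_tbl <- as_tibble(setNames(as.data.frame(keys, stringsAsFactors = FALSE), by))

  out <- tidyr::expand_grid(key_tbl, marker_id = man$marker_id)
  idx <- cbind(rep(seq_len(n_grp), each = nrow(man)),
               rep(seq_len(nrow(man)), times = n_grp))
  nc <- n_calls[idx]
  p <- ifelse(nc > 0, n_b[idx] / (2 * nc), NA_real_)
  ca <- ifelse(nc > 0, has_a[idx] / nc, NA_real_)
  cb <- ifelse(nc > 0, has_b[idx] / nc, NA_real_)
  fav <- man$favorable_allele[idx[, 2]]
  group_sizes <- as.integer(table(g)[rownames(n_calls)])

  out <- mutate(out,
    gene = man$gene[idx[, 2]],
    favorable_allele = fav,
    p = p,
    carrier_freq = ifelse(fav == "B", cb, ca),
    carrier_a = ca,
    carrier_b = cb,
    n_calls = as.integer(nc),
    n_alleles = 2L * as.integer(nc),
    n_missing = group_sizes[idx[, 1]] - as.integer(nc),
    defined = nc >= min_calls
  )
  out$p[!out$defined] <- NA_real_
  out$carrier_freq[!out$defined] <- NA_real_
  out$carrier_a[!out$defined] <- NA_real_
  out$carrier_b[!out$defined] <- NA_real_
  out
}

# rowsum with stable (factor-level) row order, keeping empty groups
rowsum_by <- function(x, g) {
  res <- rowsum(x, g)                       # drops empty levels
  lev <- levels(g)
  out <- matrix(0L, nrow = length(lev), ncol = ncol(x),
                dimnames = list(lev, colnames(x)))
  out[rownames(res), ] <- res
  out
}

#' Frequency matrix of strata x markers
#'
#' Convenience pivot of [allele_freqs()]: B-allele frequencies as a matrix
#' with one row per stratum, `NA` where undefined.
#'
#' @inheritParams allele_freqs
#' @return List with `p` (matrix), `n_alleles` (matrix of scored copies) and
#'   `strata` (tibble of the key columns, rows aligned with the matrices).
#' @export
freq_matrix <- function(panel, by = "group", min_calls = 5, complete = FALSE) {
  fr <- allele_freqs(panel, by = by, min_calls = min_calls, complete = complete)
  key <- do.call(paste, c(fr[by], sep = "\r"))
  strata_keys <- unique(key)
  mk <- marker_ids(panel)
  p <- matrix(NA_real_, length(strata_keys), length(mk),
              dimnames = list(strata_keys, mk))
  n <- matrix(0L, length(strata_keys), length(mk),
              dimnames = list(strata_keys, mk))
  p[cbind(match(key, strata_keys), match(fr$marker_id, mk))] <- fr$p
  n[cbind(match(key, strata_keys), match(fr$marker_id, mk))] <- fr$n_alleles
  strata <- dplyr::distinct(fr[by])
  list(p = p, n_alleles = n, strata = strata)
}
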