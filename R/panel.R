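#' Assemble a genotype panel from calls, accession metadata and a marker manifest
#'
#' A genotype panel (`geno_tbl`) is the single container behind every
#' statistic in the package: one row per accession, the metadata columns
#' `accession_id`, `zone`, `group`, `decade`, `growth_habit`, and one column
#' per marker holding normalized diploid calls `"AA"`, `"BB"`, `"AB"` or `NA`
#' (missing). The marker manifest travels with the panel as an attribute and
#' is consulted wherever a favorable-allele orientation is needed.
#'
#' @param calls A data frame with column `accession_id` and one column per
#'   marker; call tokens are normalized via the dialect table (see
#'   [kasp_dialect()]).
#' @param metadata A data frame with columns `accession_id`, `zone` (Roman
#'   numeral I..X), `group` (`"CL"` or `"MCC"`), and optionally `decade`
#'   (release decade start year, MCC only) and `growth_habit`
#'   (`"winter"`/`"spring"`).
#' @param manifest A data frame with columns `marker_id`, `gene`,
#'   `favorable_allele` (`"A"` or `"B"`) and `trait_class` (one of
#'   `r paste0('"', .trait_levels, '"', collapse = ", ")`).
#' @param dialect Named character vector mapping raw call tokens to
#'   normalized calls; defaults to [kasp_dialect()].
#'
#' @return A `geno_tbl` tibble (accessions x markers) with the manifest
#'   attached as attribute `"manifest"`.
#' @export
#' @examples
#' man <- tibble::tibble(marker_id = c("M1", "M2"), gene = c("g1", "g2"),
#'                       favorable_allele = "B", trait_class = "yield")
#' met <- tibble::tibble(accession_id = c("a1", "a2"), zone = "I",
#'                       group = c("CL", "MCC"))
#' calls <- tibble::tibble(accession_id = c("a1", "a2"),
#'                         M1 = c("AA", "BB"), M2 = c("H", "-"))
#' geno_panel(calls, met, man)
geno_panel <- function(calls, metadata, manifest, dialect = kasp_dialect()) {
  manifest <- validate_manifest(manifest)
  metadata <- validate_metadata(metadata)
  calls <- as_tibble(calls)
  if (!"accession_id" %in% names(calls)) {
    abort("`calls` must have an `accession_id` column.")
  }
  if (anyDuplicated(calls$accession_id)) {
    abort("duplicate accession ids in `calls`.")
  }

  missing_meta <- setdiff(calls$accession_id, metadata$accession_id)
  if (length(missing_meta)) {
    abort(paste0("accessions absent from metadata: ",
                 paste(head(missing_meta, 5), collapse = ", ")))
  }
  unknown_markers <- setdiff(setdiff(names(calls), "accession_id"),
                             manifest$marker_id)
  if (length(unknown_markers)) {
    abort(paste0("markers absent from manifest: ",
                 paste(head(unknown_markers, 5), collapse = ", ")))
  }
  absent_markers <- setdiff(manifest$marker_id, names(calls))
  if (length(absent_markers)) {
    abort(paste0("manifest markers absent from calls: ",
                 paste(head(absent_markers, 5), collapse = ", ")))
  }
  extra_meta <- setdiff(metadata$accession_id, calls$accession_id)
  if (length(extra_meta)) {
    abort(paste0("metadata accessions absent from calls: ",
                 paste(head(extra_meta, 5), collapse = ", ")))
  }

  mk <- manifest$marker_id
  norm <- purrr::imap(calls[mk], function(col, id) {
    normalize_calls(as.character(col), dialect, marker = id,
                    accession = calls$accession_id)
  })
  out <- dplyr::bind_cols(
    metadata[match(calls$accession_id, metadata$accession_id), ],
    tibble::new_tibble(norm, nrow = nrow(calls))
  )
  new_geno_tbl(out, manifest)
}

new_geno_tbl <- function(df, manifest) {
  structure(as_tibble(df),
            manifest = manifest,
            class = c("geno_tbl", class(tibble())))
}

#' Marker manifest of a panel
#' @param panel A `geno_tbl`.
#' @return The manifest tibble (`marker_id`, `gene`, `favorable_allele`,
#'   `trait_class`).
#' @export
manifest <- function(panel) {
  stopifnot(inherits(panel, "geno_tbl"))
  attr(panel, "manifest")
}

#' Marker ids of a panel
#' @inheritParams manifest
#' @return Character vector of marker ids, in panel column order.
#' @export
marker_ids <- function(panel) manifest(panel)$marker_id

meta_cols <- c("accession_id", "zone", "group", "decade", "growth_habit")

validate_manifest <- function(manifest) {
  manifest <- as_tibble(manifest)
  need <- c("marker_id", "gene", "favorable_allele", "trait_class")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) abort(paste0("manifest lacks columns: ",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(manifest$marker_id)) abort("duplicate marker ids in manifest.")
  if (!all(manifest$favorable_allele %in% c("A", "B"))) {
    abort("favorable_allele must be \"A\" or \"B\".")
  }
  if (!all(manifest$trait_class %in% .trait_levels)) {
    abort(paste0("trait_class must be one of: ",
                 paste(.trait_levels, collapse = ", ")))
  }
  manifest[need]
}

validate_metadata <- function(metadata) {
  metadata <- as_tibble(metadata)
  need <- c("accession_id", "zone", "group")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) abort(paste0("metadata lacks columns: ",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(metadata$accession_id)) abort("duplicate accession ids in metadata.")
  bad_zone <- setdiff(unique(as.character(metadata$zone)), .zone_levels())
  if (length(bad_zone)) {
    abort(paste0("illegal zone label(s): ", paste(bad_zone, collapse = ", "),
                 " (zones are Roman numerals I..X)"))
  }
  bad_grp <- setdiff(unique(as.character(metadata$group)), .group_levels)
  if (length(bad_grp)) {
    abort(paste0("illegal group label(s): ", paste(bad_grp, collapse = ", ")))
  }
  if (!"decade" %in% names(metadata)) metadata$decade <- NA_integer_
  metadata$decade <- as.integer(metadata$decade)
  if (any(!is.na(metadata$decade) & metadata$group != "MCC")) {
    abort("decade may only be set for MCC accessions.")
  }
  if (!"growth_habit" %in% names(metadata)) metadata$growth_habit <- NA_character_
  metadata$growth_habit <- as.character(metadata$growth_habit)
  bad_habit <- setdiff(stats::na.omit(unique(metadata$growth_habit)), .habit_levels)
  if (length(bad_habit)) {
    abort(paste0("illegal growth_habit: ", paste(bad_habit, collapse = ", ")))
  }
  metadata$zone <- factor(as.character(metadata$zone), levels = .zone_levels())
  metadata$group <- factor(as.character(metadata$group), levels = .group_levels)
  metadata[c(need, "decade", "growth_habit")]
}

#' Token dialect for KASP genotype calls
#'
#' Raw genotype files encode calls in several conventions; this table maps
#' every accepted token to the normalized call set `AA`/`BB`/`AB`/missing.
#' Single-letter tokens mean homozygous (the inbred-line convention) and
#' `"H"` means heterozygous.
#'
#' @return Named character vector, `names` = accepted tokens, values in
#'   `c("AA", "BB", "AB", NA)`.
#' @export
kasp_dialect <- function() {
  setNames(
    c("AA", "BB", "AB", "AB", "AA", "BB", "AB",
      NA, NA, NA, NA),
    c("AA", "BB", "AB", "BA", "A", "B", "H",
      "NA", "-", "", "."))
}

normalize_calls <- function(x, dialect, marker, accession) {
  x[is.na(x)] <- "NA"
  hit <- match(x, names(dialect))
  if (anyNA(hit)) {
    i <- which(is.na(hit))[1]
    abort(paste0("unknown call token \"", x[i], "\" at accession ",
                 accession[i], ", marker ", marker))
  }
  unname(dialect[hit])
}

#' @export
print.geno_tbl <- function(x, ...) {
  m <- manifest(x)
  cat("<geno_tbl> ", nrow(x), " accessions x ", nrow(m), " markers\n", sep = "")
  NextMethod()
}

#' Restrict a panel to a zone, group and/or release decade
#'
#' The marker list is unchanged; an empty selection is returned as an empty
#' panel with a warning (not an error), so that survey code can report
#' vacuous strata explicitly.
#'
#' @param panel A `geno_tbl`.
#' @param zone,group,decade Optional filters; `zone` a Roman numeral I..X,
#'   `group` `"CL"`/`"MCC"`, `decade` a release-decade start year.
#' @return The filtered `geno_tbl`.
#' @export
filter_panel <- function(panel, zone = NULL, group = NULL, decade = NULL) {
  stopifnot(inherits(panel, "geno_tbl"))
  keep <- rep(TRUE, nrow(panel))
  if (!is.null(zone)) {
    if (!all(zone %in% .zone_levels())) {
      abort(paste0("illegal zone label: ", paste(setdiff(zone, .zone_levels()),
                                                 collapse = ", ")))
    }
    keep <- keep & panel$zone %in% zone
  }
  if (!is.null(group)) {
    if (!all(group %in% .group_levels)) {
      abort(paste0("illegal group label: ",
                   paste(setdiff(group, .group_levels), collapse = ", ")))
    }
    keep <- keep & panel$group %in% group
  }
  if (!is.null(decade)) {
    keep <- keep & !is.na(panel$decade) & panel$decade %in% decade
  }
  out <- new_geno_tbl(panel[keep, , drop = FALSE], manifest(panel))
  if (nrow(out) == 0L) warn("selection is empty; returning an empty panel.")
  out
}

#' B-allele dosage matrix of a panel
#'
#' Encodes each call as the count of B alleles: `AA` = 0, `AB` = 1,
#' `BB` = 2, missing = `NA`. This encoding feeds the PCA and the
#' accession-level Nei distances.
#'
#' @inheritParams manifest
#' @return Integer matrix, accessions x markers, dimnames set.
#' @export
dosage_matrix <- function(panel) {
  mk <- marker_ids(panel)
  calls <- unlist(lapply(as_tibble(panel)[mk], as.character),
                  use.names = FALSE)
  z <- match(calls, c("AA", "AB", "BB")) - 1L
  matrix(z, nrow = nrow(panel), ncol = length(mk),
         dimnames = list(panel$accession_id, mk))
}
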