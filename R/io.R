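#' Read a genotype panel from delimited text files
#'
#' Expects three delimited files (TSV or CSV, sniffed from the extension or
#' `delim`): a genotype matrix whose first column is `accession_id` and whose
#' remaining columns are marker ids; an accession metadata table
#' (`accession_id`, `zone`, `group`, optional `decade`, `growth_habit`); and
#' a marker manifest (`marker_id`, `gene`, `favorable_allele`,
#' `trait_class`). Call tokens are normalized through the dialect table;
#' unknown tokens, unknown ids and duplicate ids are errors, never silently
#' dropped.
#'
#' @param genotype_path,metadata_path,manifest_path File paths.
#' @param dialect Token dialect, see [kasp_dialect()].
#' @param delim Field delimiter; `NULL` (default) infers `","` for `.csv`,
#'   otherwise tab.
#' @return A [geno_panel()] object.
#' @export
read_genotypes <- function(genotype_path, metadata_path, manifest_path,
                           dialect = kasp_dialect(), delim = NULL) {
  calls <- read_table_file(genotype_path, delim, col_types = readr::cols(
    .default = readr::col_character()))
  metadata <- read_table_file(metadata_path, delim, na = c("NA", ""))
  manifest <- read_table_file(manifest_path, delim, na = c("NA", ""))
  geno_panel(calls, metadata, manifest, dialect = dialect)
}

read_table_file <- function(path, delim = NULL, col_types = NULL,
                            na = character()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, col_types = col_types,
                    na = na, show_col_types = FALSE, progress = FALSE)
}

#' Write a genotype panel to delimited text files
#'
#' Emits the same three-file dialect [read_genotypes()] reads, so
#' write-then-read round-trips losslessly. Missing calls are written as
#' `"NA"`.
#'
#' @param panel A `geno_tbl`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `"panel"`.
#' @return Invisibly, a named character vector of the three paths written.
#' @export
write_panel <- function(panel, dir, prefix = "panel") {
  stopifnot(inherits(panel, "geno_tbl"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, paste0(prefix, "_genotypes.tsv")),
    metadata = file.path(dir, paste0(prefix, "_metadata.tsv")),
    manifest = file.path(dir, paste0(prefix, "_manifest.tsv"))
  )
  calls <- panel[c("accession_id", marker_ids(panel))]
  calls[is.na(calls)] <- "NA"
  readr::write_tsv(calls, paths[["genotypes"]], progress = FALSE)
  meta <- as_tibble(panel)[meta_cols]
  meta$zone <- as.character(meta$zone)
  meta$group <- as.character(meta$group)
  readr::write_tsv(meta, paths[["metadata"]], na = "NA", progress = FALSE)
  readr::write_tsv(manifest(panel), paths[["manifest"]], progress = FALSE)
  invisible(paths)
}

#' Write a phylogenetic tree as Newick text
#'
#' Serializes an `ape` `"phylo"` tree with branch lengths at fixed 6-decimal
#' precision. Leaf labels containing Newick-reserved characters
#' (`(){},:;[]`, quotes or whitespace) are single-quoted with internal
#' quotes doubled, per the Newick dialect rules.
#'
#' @param tree An object of class `"phylo"`.
#' @param path Output file path.
#' @param digits Decimals for branch lengths (default 6).
#' @return Invisibly, the Newick string written.
#' @export
write_newick <- function(tree, path, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  txt <- paste0(newick_string(tree, digits = digits), ";")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(txt, con)
  invisible(txt)
}

newick_string <- function(tree, digits = 6) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(len) {
    if (is.null(len) || is.na(len)) "" else
      paste0(":", formatC(len, format = "f", digits = digits))
  }
  rec <- function(node, edge_i) {
    len <- if (is.na(edge_i)) NA else tree$edge.length[edge_i]
    if (node <= n_tip) {
      return(paste0(quote_label(tree$tip.label[node]), fmt(len)))
    }
    sub <- vapply(kids[[as.character(node)]], function(e) {
      rec(tree$edge[e, 2], e)
    }, character(1))
    paste0("(", paste(sub, collapse = ","), ")", fmt(len))
  }
  rec(root, NA)
}

quote_label <- function(x) {
  if (grepl("[](){},:;'\"\\[[:space:]]", x)) {
    paste0("'", gsub("'", "''", x), "'")
  } else {
    x
  }
}
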