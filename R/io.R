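#' Read and write paired expression cohorts
#'
#' The expression file is a TSV with a header row of sample ids and gene
#' symbols in the first column; the pairing file is a 3-column TSV
#' (`patient_id`, `tumor_sample`, `normal_sample`).  Tab separator, UTF-8,
#' '.' decimal, no quoting; the header cell above the gene column is
#' ignored.  `write_expression()` emits the same dialect with shortest
#' round-trippable number formatting, so write -> read is the identity.
#'
#' @param path Expression TSV path.
#' @param pairs_path Pairing TSV path.
#' @param cohort_id Cohort id; defaults to the expression file name without
#'   extension.
#'
#' @return [read_expression()] returns a [paired_cohort()];
#'   `write_expression()` invisibly returns the paths.
#' @export
read_expression <- function(path, pairs_path, cohort_id = NULL) {
  df <- read_matrix_tsv(path)
  if (ncol(df) < 2) abort_format(sprintf("%s: expected gene column plus samples", path))
  genes <- as.character(df[[1]])
  vals <- df[-1]
  not_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(not_num) > 0) {
    abort_format(sprintf("%s: non-numeric expression column(s): %s",
                         path, paste(not_num, collapse = ", ")))
  }
  expr <- as.matrix(vals)
  storage.mode(expr) <- "double"
  rownames(expr) <- genes
  pairs <- readr::read_tsv(pairs_path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  paired_cohort(expr, pairs,
                cohort_id %||% tools::file_path_sans_ext(basename(path)))
}

#' @rdname read_expression
#' @param cohort A [paired_cohort()] to serialise.
#' @export
write_expression <- function(cohort, path, pairs_path) {
  tab <- matrix_to_tsv_tibble(cohort$expr)
  write_atomic(path, function(p) readr::write_tsv(tab, p, progress = FALSE))
  write_atomic(pairs_path,
               function(p) readr::write_tsv(cohort$pairs, p, progress = FALSE))
  invisible(c(path, pairs_path))
}

#' Read and write gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members.  Duplicate members within a line are collapsed.
#'
#' @param path GMT file path.
#' @param kind Set kind tag attached to every set read: `"category"`,
#'   `"tissue"` or `"pathway"`.
#' @return [read_gmt()] returns a [gene_catalog()] fragment.
#' @export
read_gmt <- function(path, kind = "category") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(lines != ""), 0))]  # drop trailing blanks
  if (length(lines) == 0) return(gene_catalog(kind = kind))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort_format(sprintf("%s: line %d has %d field(s); GMT requires at least 3",
                         path, short[1], lengths(fields)[short[1]]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  gene_catalog(sets, kind = kind)
}

#' @rdname read_gmt
#' @param catalog A [gene_catalog()]; its set kind is written into the GMT
#'   description field.
#' @param sets Optional subset of set names to write (default all).
#' @export
write_gmt <- function(catalog, path, sets = NULL) {
  sets <- sets %||% names(catalog$sets)
  lines <- vapply(sets, function(s) {
    paste(c(s, unname(catalog$set_kind[s]), catalog$sets[[s]]), collapse = "\t")
  }, character(1))
  write_atomic(path, function(p) writeLines(lines, p))
  invisible(path)
}

#' Read and write a PPI network as a two-column edge list
#'
#' Self-loops are dropped with a warning and duplicate / reversed edges
#' collapsed (see [ppi_network()]).  The format is SIF-compatible TSV, two
#' gene symbols per line, no header.
#'
#' @param path Edge-list path.
#' @return [read_network()] returns a [ppi_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[lines != ""]
  if (length(lines) == 0) return(ppi_network())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad) > 0) {
    abort_format(sprintf("%s: line %d has %d field(s); expected 2",
                         path, bad[1], lengths(fields)[bad[1]]))
  }
  m <- do.call(rbind, fields)
  ppi_network(data.frame(from = m[, 1], to = m[, 2]))
}

#' @rdname read_network
#' @param network A [ppi_network()].
#' @export
write_network <- function(network, path) {
  lines <- paste(network$edges$from, network$edges$to, sep = "\t")
  write_atomic(path, function(p) writeLines(lines, p))
  invisible(path)
}

#' Read and write the tissue-set to cohort mapping
#'
#' Two-column TSV with header `set_name`, `cohort_id`.
#'
#' @param path File path.
#' @return [read_tissue_map()] returns a named character vector
#'   (set name -> cohort id).
#' @export
read_tissue_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = "cc")
  if (!all(c("set_name", "cohort_id") %in% names(df))) {
    abort_format(sprintf("%s: expected columns set_name, cohort_id", path))
  }
  setNames(df$cohort_id, df$set_name)
}

#' @rdname read_tissue_map
#' @param map Named character vector, tissue set name -> cohort id.
#' @export
write_tissue_map <- function(map, path) {
  df <- tibble(set_name = names(map), cohort_id = unname(map))
  write_atomic(path, function(p) readr::write_tsv(df, p, progress = FALSE))
  invisible(path)
}

#' Read and write gene-level molecular matrices (CNV / methylation)
#'
#' Same TSV dialect as expression matrices: gene symbols in the first
#' column, tumor sample (patient) ids in the header.
#'
#' @param path TSV path.
#' @param assay `"cnv"` or `"methylation"`.
#' @return [read_molecular()] returns a [molecular_matrix()].
#' @export
read_molecular <- function(path, assay = c("cnv", "methylation")) {
  assay <- match.arg(assay)
  df <- read_matrix_tsv(path)
  vals <- as.matrix(df[-1])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(df[[1]])
  molecular_matrix(vals, assay)
}

#' @rdname read_molecular
#' @param mat A [molecular_matrix()].
#' @export
write_molecular <- function(mat, path) {
  tab <- matrix_to_tsv_tibble(mat$values)
  write_atomic(path, function(p) readr::write_tsv(tab, p, progress = FALSE))
  invisible(path)
}

# base strtod parsing: correctly rounded, so full-precision values survive
read_matrix_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

# values formatted with 17 significant digits so write -> read is bit-exact
matrix_to_tsv_tibble <- function(m) {
  cols <- lapply(seq_len(ncol(m)), function(j) sprintf("%.17g", m[, j]))
  names(cols) <- colnames(m)
  dplyr::bind_cols(tibble(gene = rownames(m)), as_tibble(cols))
}
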