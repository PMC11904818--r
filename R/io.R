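#' Read a 10x-style count directory (matrix.mtx + features.tsv + barcodes.tsv)
#'
#' Accepts plain or gzipped files. On-disk MatrixMarket orientation is
#' normalized to observations x genes using the features/barcodes lengths;
#' 10x exports genes x barcodes, but either orientation is accepted.
#'
#' @param dir_path directory holding `matrix.mtx(.gz)`, `features.tsv(.gz)`
#'   (columns: gene id, gene name), `barcodes.tsv(.gz)`
#' @param obs_kind `"nucleus"` or `"spot"`
#' @param sample_id sample label to attach
#' @return a [count_matrix()]
#' @export
read_counts_10x <- function(dir_path, obs_kind = c("nucleus", "spot"),
                            sample_id = basename(dir_path)) {
  obs_kind <- match.arg(obs_kind)
  find1 <- function(base) {
    for (f in file.path(dir_path, c(base, paste0(base, ".gz"))))
      if (file.exists(f)) return(f)
    stopf("missing %s(.gz) in %s", base, dir_path)
  }
  mtx_path <- find1("matrix.mtx")
  feat <- utils::read.table(find1("features.tsv"), sep = "\t",
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
  bc <- utils::read.table(find1("barcodes.tsv"), sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")[[1]]
  m <- tryCatch(Matrix::readMM(mtx_path),
                error = function(e) stopf("failed to parse %s: %s",
                                          mtx_path, conditionMessage(e)))
  gene_ids <- feat[[1]]
  gene_names <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
  if (nrow(m) == length(gene_ids) && ncol(m) == length(bc)) {
    m <- Matrix::t(m)                       # genes x obs on disk -> obs x genes
  } else if (nrow(m) == length(bc) && ncol(m) == length(gene_ids)) {
    # already obs x genes
  } else {
    stopf("matrix dimensions %dx%d match neither %d features x %d barcodes nor its transpose",
          nrow(m), ncol(m), length(gene_ids), length(bc))
  }
  if (anyDuplicated(bc)) stopf("duplicate barcodes in %s", dir_path)
  count_matrix(m, bc, gene_ids, gene_names, obs_kind = obs_kind,
               sample_id = sample_id)
}

#' Write a count matrix as a 10x-style directory
#'
#' Emits `matrix.mtx` (genes x observations, the 10x convention),
#' `features.tsv` and `barcodes.tsv`, uncompressed, deterministically.
#'
#' @param m a [count_matrix()]
#' @param dir_path output directory (created if needed)
#' @return `dir_path`, invisibly
#' @export
write_counts_10x <- function(m, dir_path) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(m$counts), file.path(dir_path, "matrix.mtx"))
  utils::write.table(data.frame(m$gene_ids, m$gene_names),
                     file.path(dir_path, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  writeLines(m$obs_ids, file.path(dir_path, "barcodes.tsv"))
  invisible(dir_path)
}

#' Read a Visium tissue-positions table
#'
#' Accepts both dialects: with a header line
#' (`barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres`)
#' and headerless (older Space Ranger exports). Array coordinates must be
#' integers; `in_tissue` must be 0/1.
#'
#' @param csv_path path to a 6-column CSV
#' @param sample_id sample label to attach
#' @return a [spot_geometry()]
#' @export
read_tissue_positions <- function(csv_path, sample_id = "sample1") {
  first <- readLines(csv_path, n = 1L)
  has_header <- grepl("barcode", strsplit(first, ",")[[1]][1], ignore.case = TRUE)
  df <- utils::read.csv(csv_path, header = has_header,
                        stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) != 6) stopf("tissue positions file must have 6 columns, found %d", ncol(df))
  names(df) <- c("barcode", "in_tissue", "array_row", "array_col",
                 "pxl_row", "pxl_col")
  num <- function(x, col, integral = FALSE) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stopf("non-numeric value in column %s", col)
    if (integral && any(abs(v - round(v)) > 0))
      stopf("non-integer value in column %s", col)
    v
  }
  spot_geometry(df$barcode,
                num(df$in_tissue, "in_tissue", TRUE),
                num(df$array_row, "array_row", TRUE),
                num(df$array_col, "array_col", TRUE),
                num(df$pxl_row, "pxl_row"),
                num(df$pxl_col, "pxl_col"),
                sample_id = sample_id)
}

#' Write a tissue-positions CSV (headered dialect)
#' @param geom a [spot_geometry()]
#' @param csv_path output path
#' @return `csv_path`, invisibly
#' @export
write_tissue_positions <- function(geom, csv_path) {
  df <- as.data.frame(geom)
  names(df) <- c("barcode", "in_tissue", "array_row", "array_col",
                 "pxl_row_in_fullres", "pxl_col_in_fullres")
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then member genes, tab-separated.
#' Members are deduplicated (set semantics); duplicate set names are an
#' error.
#'
#' @param path GMT file path
#' @return named list of character vectors; descriptions kept as the
#'   `"descriptions"` attribute
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) stopf("malformed GMT line(s): need at least name + description")
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stopf("duplicate gene-set names: %s", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(vapply(parts, `[[`, "", 2L), nm)
  sets
}

#' Write gene sets as GMT
#' @param sets named list of character vectors
#' @param path output path
#' @param descriptions optional named descriptions (defaults to set names)
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("sets must have unique names")
  desc <- descriptions %||% stats::setNames(names(sets), names(sets))
  writeLines(vapply(names(sets), function(n)
    paste(c(n, desc[[n]] %||% n, sets[[n]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Write a records table as a deterministic TSV
#'
#' Fixed column order (as supplied), rows sorted by the first column(s)
#' given in `key` so identical records always give identical bytes.
#'
#' @param records a data.frame
#' @param path output path
#' @param key column name(s) to sort rows by (default: first column)
#' @return `path`, invisibly
#' @export
write_records <- function(records, path, key = names(records)[1]) {
  stopifnot(is.data.frame(records))
  if (nrow(records) > 0) {
    ord <- do.call(order, c(unname(records[key]), list(method = "radix")))
    records <- records[ord, , drop = FALSE]
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_records()]
#' @param path input path
#' @return a data.frame
#' @export
read_records <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                    comment.char = "")
}

#' Read a subcellular-location table (TSV: gene_id, location)
#'
#' Locations for one gene may be pipe-separated. Duplicate gene ids are an
#' error.
#'
#' @param path TSV path with a header line
#' @return data.frame with columns `gene_id`, `location`
#' @export
read_location_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (!all(c("gene_id", "location") %in% names(df)))
    stopf("location table needs columns gene_id and location")
  if (anyDuplicated(df$gene_id)) stopf("duplicate gene_id in location table")
  df
}
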