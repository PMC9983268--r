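#' Read an SRT dataset from standard on-disk formats
#'
#' Supports a sparse Matrix Market count matrix (with sidecar one-ID-per-line
#' gene and location files) or a dense TSV/CSV matrix with a header row and
#' gene identifiers in the first column. Dense matrices are accepted in either
#' orientation: the loader matches matrix dimensions (and, where available,
#' identifiers) against the coordinate table and transposes when the matrix is
#' locations-by-genes; square matrices whose identifiers do not resolve the
#' orientation are rejected as ambiguous.
#'
#' @param count_path Path to the count matrix (`.mtx`, `.tsv` or `.csv`).
#' @param coord_path Path to the coordinate table (CSV/TSV with columns
#'   `location_id`, `x`, `y`; `location_id` is synthesised when missing).
#' @param domain_path Optional path to a domain table (columns `location_id`,
#'   `domain`).
#' @param format One of `"auto"`, `"mtx"`, `"tsv"`, `"csv"`. `"auto"` infers
#'   from the file extension.
#' @param gene_path,location_path Sidecar ID files for MTX input; default to
#'   `<prefix>_genes.txt` / `<prefix>_locations.txt` next to the matrix.
#' @return An [srt_data] object.
#' @export
read_srt <- function(count_path, coord_path, domain_path = NULL,
                     format = c("auto", "mtx", "tsv", "csv"),
                     gene_path = NULL, location_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(count_path)),
                     mtx = "mtx", tsv = "tsv", txt = "tsv", csv = "csv",
                     abort(sprintf("cannot infer format from '%s'", count_path)))
  }
  for (p in c(count_path, coord_path, domain_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  coords <- read_table_auto(coord_path)
  if (!all(c("x", "y") %in% names(coords))) {
    abort("coordinate table must contain columns `x` and `y`")
  }
  if (!"location_id" %in% names(coords)) {
    coords$location_id <- sprintf("loc_%04d", seq_len(nrow(coords)))
  }
  n_loc <- nrow(coords)

  if (format == "mtx") {
    prefix <- sub("_counts\\.mtx$|\\.mtx$", "", count_path)
    gene_path <- gene_path %||% paste0(prefix, "_genes.txt")
    location_path <- location_path %||% paste0(prefix, "_locations.txt")
    m <- as.matrix(Matrix::readMM(count_path))
    if (file.exists(gene_path)) rownames(m) <- readLines(gene_path)
    if (file.exists(location_path)) colnames(m) <- readLines(location_path)
  } else {
    tab <- read_table_auto(count_path, delim = if (format == "csv") "," else "\t")
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- as.character(tab[[1]])
  }

  m <- resolve_orientation(m, coords$location_id, n_loc)
  if (any(is.na(m)) || any(m != round(m)) || any(m < 0)) {
    abort("count matrix must contain non-negative integers")
  }
  if (!is.null(colnames(m)) && all(colnames(m) %in% coords$location_id)) {
    coords <- coords[match(colnames(m), coords$location_id), ]
  } else {
    colnames(m) <- coords$location_id
  }

  domains <- NULL
  if (!is.null(domain_path)) {
    dt <- read_table_auto(domain_path)
    if (!all(c("location_id", "domain") %in% names(dt))) {
      abort("domain table must contain columns `location_id` and `domain`")
    }
    idx <- match(coords$location_id, as.character(dt$location_id))
    if (anyNA(idx)) abort("domain table is missing labels for some locations")
    domains <- as.character(dt$domain)[idx]
  }
  srt_data(m, coords, domains)
}

read_table_auto <- function(path, delim = NULL) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

resolve_orientation <- function(m, loc_ids, n_loc) {
  by_col <- ncol(m) == n_loc
  by_row <- nrow(m) == n_loc
  if (!by_col && !by_row) {
    abort(sprintf(
      "count matrix is %d x %d but the coordinate table has %d locations",
      nrow(m), ncol(m), n_loc
    ))
  }
  if (by_col && by_row) {
    col_match <- !is.null(colnames(m)) && all(colnames(m) %in% loc_ids)
    row_match <- !is.null(rownames(m)) && all(rownames(m) %in% loc_ids)
    if (row_match && !col_match) return(t(m))
    if (col_match && !row_match) return(m)
    abort("square count matrix: orientation is ambiguous; identifiers do not resolve it")
  }
  if (by_row && !by_col) t(m) else m
}

#' Write an SRT dataset to disk
#'
#' Emits `<prefix>_counts.<ext>` plus `<prefix>_coords.csv` and, when domain
#' labels are present, `<prefix>_domains.csv`. MTX output additionally writes
#' `<prefix>_genes.txt` and `<prefix>_locations.txt` sidecar ID files.
#' [read_srt()] on the emitted files reproduces the object exactly.
#'
#' @param data An [srt_data] object.
#' @param out_prefix Output path prefix.
#' @param format `"mtx"` (sparse Matrix Market) or `"tsv"` (dense).
#' @return Invisibly, the character vector of files written.
#' @export
write_srt <- function(data, out_prefix, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(data, "srt_data"))
  if (nrow(data$counts) == 0) abort("empty gene set: nothing to write")
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) abort(sprintf("directory does not exist: %s", dir))
  files <- character()
  if (format == "mtx") {
    f <- paste0(out_prefix, "_counts.mtx")
    Matrix::writeMM(Matrix::Matrix(data$counts, sparse = TRUE), f)
    writeLines(gene_ids(data), paste0(out_prefix, "_genes.txt"))
    writeLines(location_ids(data), paste0(out_prefix, "_locations.txt"))
    files <- c(f, paste0(out_prefix, c("_genes.txt", "_locations.txt")))
  } else {
    f <- paste0(out_prefix, "_counts.tsv")
    tab <- tibble::as_tibble(data$counts, .name_repair = "minimal")
    tab <- dplyr::bind_cols(tibble::tibble(gene_id = gene_ids(data)), tab)
    readr::write_tsv(tab, f)
    files <- f
  }
  fc <- paste0(out_prefix, "_coords.csv")
  readr::write_csv(data$coords, fc)
  files <- c(files, fc)
  if (!is.null(data$domains)) {
    fd <- paste0(out_prefix, "_domains.csv")
    readr::write_csv(tibble::tibble(location_id = location_ids(data),
                                    domain = data$domains), fd)
    files <- c(files, fd)
  }
  invisible(files)
}
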