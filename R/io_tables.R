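#' Feature tables
#'
#' A feature table is a sparse non-negative count matrix with features as
#' rows and samples as columns (the dense-TSV convention: one feature per
#' row, a header row of sample ids). It is stored as a `Matrix::dgCMatrix`
#' with unique dimnames; explicit zeros are always dropped, so stored
#' entries are exactly the non-zero cells.
#'
#' @param x a matrix or Matrix with rownames = feature ids and colnames =
#'   sample ids.
#' @return a validated `dgCMatrix`.
#' @export
as_feature_table <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x * 1.0, sparse = TRUE)
  m <- methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  m <- Matrix::drop0(m)
  validate_feature_table(m)
  m
}

validate_feature_table <- function(m) {
  ids <- dimnames(m)
  if (is.null(ids) || is.null(ids[[1L]]) || is.null(ids[[2L]]))
    stop("feature table needs feature rownames and sample colnames")
  check_ids(ids[[1L]], "feature")
  check_ids(ids[[2L]], "sample")
  if (any(m@x < 0)) stop("feature table contains negative values")
  invisible(m)
}

check_ids <- function(ids, what) {
  if (any(!nzchar(ids))) stop("empty ", what, " id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, " id(s): ",
         paste(utils::head(dup, 5L), collapse = ", "))
  invisible(ids)
}

#' Read a feature table
#'
#' Dense TSV (default): features as rows, samples as columns, first row the
#' sample-id header, first column the feature ids. `orient = "samples"`
#' transposes on read for tables stored the other way around. JSON BIOM
#' files are read through the biomformat package when `format = "biom"`.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"biom"`.
#' @param orient for TSV: `"features"` (rows are features, the canonical
#'   orientation) or `"samples"` (rows are samples; transposed on read).
#' @return a feature table (`dgCMatrix`, features x samples).
#' @export
read_table <- function(path, format = c("tsv", "biom"),
                       orient = c("features", "samples")) {
  format <- match.arg(format)
  orient <- match.arg(orient)
  if (format == "biom") return(read_table_biom(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("table needs a header row and at least one row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  body <- cells[-1L]
  body_width <- lengths(body)[1L]
  # the header's corner cell (feature-id column name) is optional
  sample_ids <- if (length(header) == body_width) header[-1L] else header
  if (any(lengths(body) != length(sample_ids) + 1L))
    stop("ragged TSV: row(s) ",
         paste(utils::head(which(lengths(body) != length(sample_ids) + 1L), 5L),
               collapse = ", "),
         " do not have ", length(sample_ids) + 1L, " fields")
  feature_ids <- vapply(body, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1L]), numeric(length(sample_ids))))
  if (anyNA(vals)) stop("non-numeric cell in table body")
  m <- matrix(as.numeric(vals), nrow = length(feature_ids),
              ncol = length(sample_ids), byrow = TRUE,
              dimnames = list(feature_ids, sample_ids))
  if (orient == "samples") m <- t(m)
  as_feature_table(m)
}

read_table_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("format = \"biom\" needs the biomformat package")
  first <- readChar(path, 8L, useBytes = TRUE)
  if (grepl("^HDF", first))
    stop("HDF5 BIOM is not supported; convert to JSON BIOM first")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")   # observations x samples
  as_feature_table(m)
}

#' Write a feature table
#'
#' @param table a feature table (features x samples).
#' @param path output file.
#' @param format `"tsv"` (dense, features as rows) or `"biom"` (JSON BIOM
#'   via biomformat).
#' @export
write_table <- function(table, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("format = \"biom\" needs the biomformat package")
    b <- biomformat::make_biom(as.matrix(table))
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  dense <- as.matrix(table)
  header <- paste(c("#FeatureID", colnames(dense)), collapse = "\t")
  rows <- paste(rownames(dense),
                apply(dense, 1L, function(r)
                  paste(format_length(r), collapse = "\t")),
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Metadata tables
#'
#' A metadata table maps identifiers (samples or features) to typed
#' columns. Each column is either numeric — every non-missing cell parses
#' as a real — or categorical. Missing cells are `NA`. The object is a
#' `data.frame` with the ids as row names and a `types` attribute, one of
#' `"numeric"`/`"categorical"` per column.
#'
#' @param ids character identifiers (unique, non-empty).
#' @param columns named list of equal-length vectors.
#' @return a `metadata_table`.
#' @export
metadata_table <- function(ids, columns) {
  check_ids(ids, "metadata")
  stopifnot(is.list(columns), length(names(columns)) == length(columns))
  columns <- lapply(columns, function(col) {
    if (is.numeric(col)) return(as.numeric(col))
    as.character(col)
  })
  types <- vapply(columns, function(col)
    if (is.numeric(col)) "numeric" else "categorical", character(1))
  df <- data.frame(columns, row.names = ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  structure(df, types = types, class = c("metadata_table", "data.frame"))
}

#' @export
print.metadata_table <- function(x, ...) {
  cat("<metadata_table> ", nrow(x), " ids x ", ncol(x), " columns (",
      paste(paste0(names(x), ":", attr(x, "types")), collapse = ", "),
      ")\n", sep = "")
  NextMethod()
}

md_types <- function(md) attr(md, "types")

md_column <- function(md, field, type = NULL) {
  if (!field %in% names(md))
    stop("metadata has no column '", field, "'")
  if (!is.null(type) && md_types(md)[[field]] != type)
    stop("column '", field, "' is ", md_types(md)[[field]],
         ", need ", type)
  stats::setNames(md[[field]], rownames(md))
}

MISSING_TOKENS <- c("", "NA")

#' Read a metadata TSV
#'
#' First column is the identifier; every other column is typed numeric if
#' all of its non-missing cells parse as reals, categorical otherwise.
#' Empty cells and `NA` are missing. Re-reading a written metadata table
#' infers the same types (inference is idempotent).
#'
#' @param path TSV file, first row a header.
#' @return a [metadata_table].
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  if (ncol(df) < 1L) stop("metadata needs at least the identifier column")
  ids <- df[[1L]]
  check_ids(ids, "metadata")
  cols <- lapply(df[-1L], function(col) {
    col[col %in% MISSING_TOKENS] <- NA_character_
    num <- suppressWarnings(as.numeric(col))
    if (all(is.na(num) == is.na(col))) num else col
  })
  metadata_table(ids, cols)
}

#' @rdname read_metadata
#' @param md a [metadata_table]; `id_name` the header of the id column.
#' @export
write_metadata <- function(md, path, id_name = "#ID") {
  out <- lapply(md, function(col) {
    s <- if (is.numeric(col)) format_length(col) else as.character(col)
    s[is.na(col)] <- ""
    s
  })
  lines <- do.call(paste, c(list(rownames(md)), out, sep = "\t"))
  writeLines(c(paste(c(id_name, names(md)), collapse = "\t"), lines), path)
  invisible(path)
}

#' Read ordination results
#'
#' Parses the sectioned plain-text ordination format (as written by
#' scikit-bio's `OrdinationResults`): an `Eigvals` block, a `Proportion
#' explained` block, a `Site` block of per-sample coordinates and an
#' optional `Species` block of per-feature (biplot) coordinates. Empty
#' `Biplot` / `Site constraints` blocks are tolerated; any other section
#' name is an error, as is any axis-count disagreement between sections.
#'
#' @param path file to read.
#' @return an `ordination` object: list with `sample_ids`, `sample_coords`
#'   (samples x axes matrix), `proportion_explained`, `eigvals`, and
#'   optionally `feature_ids` / `feature_coords`.
#' @export
read_ordination <- function(path) {
  lines <- readLines(path, warn = FALSE)
  known <- c("Eigvals", "Proportion explained", "Species", "Site",
             "Biplot", "Site constraints")
  sections <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    head_fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    name <- head_fields[1L]
    if (!name %in% known)
      stop("unknown ordination section '", name, "'")
    dims <- suppressWarnings(as.integer(head_fields[-1L]))
    if (anyNA(dims)) stop("bad dimensions in section header '", lines[i], "'")
    # Eigvals / Proportion explained declare an axis count and carry one row
    n_rows <- if (name %in% c("Eigvals", "Proportion explained"))
      as.integer(dims[1L] > 0L)
    else if (length(dims) >= 1L) dims[1L] else 0L
    body <- character(0)
    i <- i + 1L
    while (i <= length(lines) && nzchar(trimws(lines[i]))) {
      body <- c(body, lines[i])
      i <- i + 1L
    }
    if (length(body) != n_rows)
      stop("section '", name, "' declares ", n_rows, " rows but has ",
           length(body))
    sections[[name]] <- list(dims = dims, body = body)
  }
  need <- c("Eigvals", "Proportion explained", "Site")
  miss <- setdiff(need, names(sections))
  if (length(miss))
    stop("ordination file lacks section(s): ", paste(miss, collapse = ", "))

  vector_section <- function(name) {
    sec <- sections[[name]]
    if (sec$dims[1L] == 0L) return(numeric(0))
    as.numeric(strsplit(sec$body[1L], "\t", fixed = TRUE)[[1L]])
  }
  # Eigvals / Proportion explained: "<name>\t<k>" then one row of k values
  eig_sec <- sections[["Eigvals"]]
  k <- eig_sec$dims[1L]
  eigvals <- as.numeric(strsplit(eig_sec$body[1L], "\t", fixed = TRUE)[[1L]])
  if (length(eigvals) != k) stop("Eigvals row has wrong length")
  pe_sec <- sections[["Proportion explained"]]
  prop <- as.numeric(strsplit(pe_sec$body[1L], "\t", fixed = TRUE)[[1L]])
  if (pe_sec$dims[1L] != k || length(prop) != k)
    stop("Proportion explained has ", pe_sec$dims[1L],
         " axes, Eigvals has ", k)
  if (any(prop < 0 | prop > 1))
    stop("proportion explained must lie in [0, 1]")

  coord_section <- function(name) {
    sec <- sections[[name]]
    if (is.null(sec)) return(NULL)
    if (length(sec$dims) != 2L)
      stop("section '", name, "' header needs rows and columns")
    if (sec$dims[1L] == 0L) return(NULL)
    if (sec$dims[2L] != k)
      stop("section '", name, "' has ", sec$dims[2L], " axes, Eigvals has ", k)
    fields <- strsplit(sec$body, "\t", fixed = TRUE)
    if (any(lengths(fields) != k + 1L))
      stop("section '", name, "' has a row of the wrong width")
    ids <- vapply(fields, `[[`, character(1), 1L)
    check_ids(ids, name)
    coords <- t(vapply(fields, function(f) as.numeric(f[-1L]), numeric(k)))
    rownames(coords) <- ids
    coords
  }
  site <- coord_section("Site")
  if (is.null(site)) stop("Site section is empty")
  species <- coord_section("Species")
  for (nm in c("Biplot", "Site constraints")) {
    sec <- sections[[nm]]
    if (!is.null(sec) && length(sec$body) > 0L)
      stop("section '", nm, "' is not supported (only empty placeholders)")
  }
  structure(list(sample_ids = rownames(site), sample_coords = site,
                 proportion_explained = prop, eigvals = eigvals,
                 feature_ids = if (!is.null(species)) rownames(species),
                 feature_coords = species),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("<ordination> ", length(x$sample_ids), " samples x ",
      length(x$proportion_explained), " axes",
      if (!is.null(x$feature_coords))
        paste0(", ", nrow(x$feature_coords), " biplot features") else "",
      "\n", sep = "")
  invisible(x)
}

#' @rdname read_ordination
#' @param ord an `ordination`; `path` the output file.
#' @export
write_ordination <- function(ord, path) {
  k <- length(ord$proportion_explained)
  row_of <- function(v) paste(format_length(v), collapse = "\t")
  coord_rows <- function(coords)
    paste(rownames(coords),
          apply(coords, 1L, row_of), sep = "\t")
  out <- c(paste0("Eigvals\t", k), row_of(ord$eigvals), "",
           paste0("Proportion explained\t", k),
           row_of(ord$proportion_explained), "")
  if (!is.null(ord$feature_coords))
    out <- c(out, paste0("Species\t", nrow(ord$feature_coords), "\t", k),
             coord_rows(ord$feature_coords), "")
  else out <- c(out, "Species\t0\t0", "")
  out <- c(out, paste0("Site\t", nrow(ord$sample_coords), "\t", k),
           coord_rows(ord$sample_coords), "",
           "Biplot\t0\t0", "", "Site constraints\t0\t0")
  writeLines(out, path)
  invisible(path)
}
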