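# Reading, validation and writing of the tab-delimited inputs and outputs.
# All files are TSV (UTF-8) with a header row and a leading ID column.

# Markers treated as missing in metadata files (case-insensitive).
.na_markers <- c("", "na", "nan")

#' Validate a distance matrix
#'
#' Checks squareness, unique ids, symmetry (within `tol`, then exact
#' symmetrization by averaging with the transpose), a zero diagonal, and
#' finite nonnegative entries.
#'
#' @param m Square numeric matrix with identical row and column names.
#' @param tol Maximum tolerated absolute asymmetry (and diagonal deviation)
#'   before the matrix is rejected. Default `1e-8`, enough to absorb
#'   floating-point round-trip noise while rejecting genuine errors.
#' @return The validated matrix: exactly symmetric, zero diagonal.
#' @export
validate_distance_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("distance matrix must be a numeric matrix", call. = FALSE)
  }
  if (nrow(m) != ncol(m)) {
    stop("distance matrix is not square", call. = FALSE)
  }
  ids <- rownames(m)
  if (is.null(ids) || is.null(colnames(m))) {
    stop("distance matrix must have row and column names", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate ID in distance matrix: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (!setequal(ids, colnames(m))) {
    stop("row and column ID sets differ", call. = FALSE)
  }
  m <- m[, ids, drop = FALSE]  # align columns to row order
  if (any(!is.finite(m))) {
    stop("distance matrix contains non-finite entries", call. = FALSE)
  }
  if (any(m < 0)) {
    stop("distance matrix contains negative entries", call. = FALSE)
  }
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop("distance matrix is not symmetric (max asymmetry ",
         format(asym), ")", call. = FALSE)
  }
  m <- (m + t(m)) / 2
  if (max(abs(diag(m))) > tol) {
    stop("distance matrix diagonal is not zero", call. = FALSE)
  }
  diag(m) <- 0
  m
}

#' Read a labeled distance matrix from a TSV file
#'
#' The file must be tab-delimited with a header row and a leading ID column;
#' row and column ID sets must be identical (order may differ; rows are
#' aligned to the column order of the header). The matrix is validated with
#' [validate_distance_matrix()].
#'
#' @param path Path to the TSV file.
#' @param tol Asymmetry tolerance, see [validate_distance_matrix()].
#' @return A validated numeric distance matrix with ids as dimnames.
#' @export
read_distance_matrix <- function(path, tol = 1e-8) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids_row <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids_row
  if (!setequal(ids_row, colnames(m))) {
    stop("row and column ID sets differ in ", path, call. = FALSE)
  }
  # align rows to the header (column) order
  m <- m[colnames(m), , drop = FALSE]
  validate_distance_matrix(m, tol = tol)
}

#' Write a distance matrix to a TSV file
#'
#' Inverse of [read_distance_matrix()]: full double precision is written so
#' that a read/write round trip reproduces the matrix exactly.
#'
#' @param m Validated distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  out <- cbind(ID = rownames(m),
               apply(m, 2, function(x) sprintf("%.17g", x)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bray-Curtis dissimilarities from an abundance table
#'
#' Computes BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i) between all sample
#' pairs of a nonnegative abundance table (samples in rows), delegating to
#' [vegan::vegdist()].
#'
#' @param table Numeric matrix or data frame of nonnegative counts or
#'   relative abundances, samples in rows, features in columns. Row names
#'   are the sample ids (defaults to `S1..Sn`).
#' @return A validated distance matrix over samples, entries in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  x <- as.matrix(table)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("abundance table has non-finite entries", call. = FALSE)
  if (any(x < 0)) stop("abundance table has negative entries", call. = FALSE)
  zero <- rowSums(x) == 0
  if (any(zero)) {
    stop("sample(s) with all-zero abundances: ",
         paste(rownames(x)[zero], collapse = ", "),
         " (Bray-Curtis undefined)", call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  validate_distance_matrix(d)
}

#' Read a metadata table keyed by sample ids
#'
#' Columns are auto-typed: numeric when every non-missing value parses as a
#' number, categorical (character) otherwise; `type_overrides` forces a kind
#' per column. Missing markers are the empty string, "NA" and "NaN"
#' (case-insensitive). Rows are reordered to match `ids`; ids absent from the
#' file become all-missing rows (with a warning); file rows whose id is not
#' in `ids` are dropped with a warning.
#'
#' @param path Path to a TSV file with a header row and a leading ID column.
#' @param ids Character vector of ids (typically the distance-matrix ids).
#' @param type_overrides Optional named character vector mapping column names
#'   to "numeric" or "categorical".
#' @return A tibble with first column `id` (in the order of `ids`) and one
#'   column per metadata variable.
#' @export
read_metadata <- function(path, ids, type_overrides = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE,
                   na.strings = NULL)
  file_ids <- as.character(df[[1]])
  if (anyDuplicated(file_ids)) {
    stop("duplicate ID in metadata file", call. = FALSE)
  }
  keep <- file_ids %in% ids
  if (!any(keep)) stop("no metadata ids overlap the distance-matrix ids", call. = FALSE)
  if (any(!keep)) {
    warning(sum(!keep), " metadata row(s) with unknown ids dropped: ",
            paste(head(file_ids[!keep], 5), collapse = ", "), call. = FALSE)
  }
  df <- df[keep, , drop = FALSE]
  file_ids <- file_ids[keep]
  vars <- df[, -1, drop = FALSE]
  vars[] <- lapply(vars, function(x) {
    x[tolower(trimws(x)) %in% .na_markers] <- NA_character_
    x
  })
  typed <- lapply(names(vars), function(nm) {
    x <- vars[[nm]]
    kind <- if (!is.null(type_overrides) && nm %in% names(type_overrides)) {
      match.arg(type_overrides[[nm]], c("numeric", "categorical"))
    } else {
      num <- suppressWarnings(as.numeric(x[!is.na(x)]))
      if (length(num) > 0 && !anyNA(num)) "numeric" else "categorical"
    }
    if (kind == "numeric") suppressWarnings(as.numeric(x)) else x
  })
  names(typed) <- names(vars)
  out <- tibble::tibble(id = file_ids, !!!typed)
  missing_ids <- setdiff(ids, file_ids)
  if (length(missing_ids) > 0) {
    warning(length(missing_ids), " id(s) absent from metadata file; ",
            "filled with missing values", call. = FALSE)
  }
  out <- dplyr::left_join(tibble::tibble(id = ids), out, by = "id")
  out
}
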