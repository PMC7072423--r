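#' Ligand-by-target binding-affinity matrix
#'
#' The canonical container for a multi-target docking screen: an L x T grid
#' of binding affinities in signed kcal/mol (negative = favorable), with
#' ligands as rows and targets as columns. Missing cells (pairs never
#' docked) are `NA` and are treated downstream as non-passing.
#'
#' @param values Numeric matrix with unique, non-empty row names (ligand
#'   ids) and column names (target ids). Non-missing cells must be finite.
#' @param metadata Optional named list of opaque annotations (e.g. target
#'   PDB ids, compound registry ids), stored as-is.
#' @return An object of class `affinity_matrix`: a list with elements
#'   `values` (the numeric matrix) and `metadata`.
#' @examples
#' m <- affinity_matrix(matrix(c(-7, -5, -6.5, -8), nrow = 2, byrow = TRUE,
#'   dimnames = list(c("A", "B"), c("X", "Y"))))
#' ligands(m)
#' @seealso [read_affinity_matrix()], [affinity_from_records()],
#'   [triphala_matrix()]
#' @export
affinity_matrix <- function(values, metadata = list()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  lig <- rownames(values)
  tgt <- colnames(values)
  if (is.null(lig) || is.null(tgt))
    stop("`values` must carry ligand row names and target column names",
         call. = FALSE)
  check_axis_ids(lig, "ligand")
  check_axis_ids(tgt, "target")
  bad <- !is.na(values) & !is.finite(values)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite affinity at ligand '%s', target '%s'",
                 lig[i[1]], tgt[i[2]]), call. = FALSE)
  }
  structure(list(values = values, metadata = metadata),
            class = "affinity_matrix")
}

check_axis_ids <- function(ids, axis) {
  if (anyNA(ids) || any(!nzchar(trimws(ids))))
    stop(sprintf("empty %s id", axis), call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate %s id: '%s'", axis, dup[1]), call. = FALSE)
}

#' @export
print.affinity_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("affinity_matrix: %d ligands x %d targets (%d missing cells)\n",
              nrow(v), ncol(v), sum(is.na(v))))
  nn <- v[!is.na(v)]
  if (length(nn))
    cat(sprintf("  affinity range: %.1f to %.1f kcal/mol\n",
                min(nn), max(nn)))
  invisible(x)
}

#' @export
dim.affinity_matrix <- function(x) dim(x$values)

#' @export
as.matrix.affinity_matrix <- function(x, ...) x$values

#' @rdname affinity_matrix
#' @param x An `affinity_matrix`.
#' @export
ligands <- function(x) rownames(x$values)

#' @rdname affinity_matrix
#' @export
targets <- function(x) colnames(x$values)

#' Matrix file dialect
#'
#' Delimited affinity-matrix files come in two sign conventions and two
#' orientations. `signed` files carry affinities as-is (negative =
#' favorable); `magnitude` files carry the unsigned magnitudes of negative
#' affinities, which are negated at ingest. Orientation says which axis is
#' on the rows of the file; internally ligands are always rows.
#'
#' @param sign `"signed"` or `"magnitude"`.
#' @param orientation `"ligands-as-rows"` or `"targets-as-rows"`.
#' @return A `matrix_dialect` object.
#' @export
matrix_dialect <- function(sign = c("signed", "magnitude"),
                           orientation = c("ligands-as-rows",
                                           "targets-as-rows")) {
  structure(list(sign = match.arg(sign),
                 orientation = match.arg(orientation)),
            class = "matrix_dialect")
}

split_fields <- function(line, sep) strsplit(line, sep, fixed = TRUE)[[1]]

#' Read a delimited affinity matrix
#'
#' Reads a ligand x target affinity table from a UTF-8 delimited text file.
#' The first row is a header of ids for the column axis; the first column
#' holds the ids of the row axis. The dialect is given explicitly, never
#' sniffed. The returned matrix is in canonical form: ligands as rows,
#' signed kcal/mol (magnitude cells are negated). Ids are whitespace-trimmed
#' with case preserved.
#'
#' @param path Path to the file.
#' @param dialect A [matrix_dialect()].
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @param missing Cell content marking a missing value, besides `"NA"`.
#'   Default is the empty cell.
#' @return An [affinity_matrix()].
#' @export
read_affinity_matrix <- function(path, dialect = matrix_dialect(),
                                 sep = ",", missing = "") {
  stopifnot(inherits(dialect, "matrix_dialect"))
  if (!file.exists(path))
    stop(sprintf("no such file: '%s'", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) < 2L)
    stop(sprintf("'%s': need a header row and at least one data row", path),
         call. = FALSE)
  header <- trimws(split_fields(lines[1], sep))
  col_ids <- header[-1]
  n_col <- length(col_ids)
  row_ids <- character(length(lines) - 1L)
  vals <- matrix(NA_real_, nrow = length(lines) - 1L, ncol = n_col)
  for (r in seq_along(row_ids)) {
    # append one sep so strsplit cannot drop a trailing missing cell
    fields <- trimws(split_fields(paste0(lines[r + 1L], sep), sep))
    if (length(fields) != n_col + 1L)
      stop(sprintf("'%s': ragged row %d (%d fields, expected %d)",
                   path, r + 1L, length(fields), n_col + 1L), call. = FALSE)
    row_ids[r] <- fields[1]
    for (k in seq_len(n_col)) {
      cell <- fields[k + 1L]
      if (identical(cell, missing) || identical(cell, "NA")) next
      num <- suppressWarnings(as.numeric(cell))
      if (is.na(num))
        stop(sprintf("'%s': non-numeric cell '%s' at row %d, column %d",
                     path, cell, r + 1L, k + 1L), call. = FALSE)
      vals[r, k] <- num
    }
  }
  rows_are_ligands <- dialect$orientation == "ligands-as-rows"
  check_axis_ids(row_ids, if (rows_are_ligands) "ligand" else "target")
  check_axis_ids(col_ids, if (rows_are_ligands) "target" else "ligand")
  dimnames(vals) <- list(row_ids, col_ids)
  if (!rows_are_ligands) vals <- t(vals)
  if (dialect$sign == "magnitude") vals <- -vals
  affinity_matrix(vals)
}

#' Write a delimited affinity matrix
#'
#' Inverse of [read_affinity_matrix()]: a file written in a dialect and
#' re-read with the same dialect yields a cell-for-cell identical matrix
#' (for `magnitude`, provided every affinity is favorable, since magnitudes
#' drop signs).
#'
#' @inheritParams read_affinity_matrix
#' @param x An [affinity_matrix()].
#' @export
write_affinity_matrix <- function(x, path, dialect = matrix_dialect(),
                                  sep = ",", missing = "") {
  stopifnot(inherits(x, "affinity_matrix"), inherits(dialect, "matrix_dialect"))
  vals <- x$values
  if (dialect$sign == "magnitude") vals <- abs(vals)
  rows_are_ligands <- dialect$orientation == "ligands-as-rows"
  if (!rows_are_ligands) vals <- t(vals)
  corner <- if (rows_are_ligands) "ligand" else "target"
  fmt <- function(v) ifelse(is.na(v), missing,
                            vapply(v, format, "", digits = 15))
  lines <- c(paste(c(corner, colnames(vals)), collapse = sep),
             vapply(seq_len(nrow(vals)), function(r)
               paste(c(rownames(vals)[r], fmt(vals[r, ])), collapse = sep),
               ""))
  writeLines(lines, path, useBytes = TRUE)
  invisible(NULL)
}

#' Assemble an affinity matrix from per-pair records
#'
#' Bridges parsed docking outputs to the matrix form. Axes are the union of
#' observed ids in first-seen order. Duplicate (ligand, target) pairs
#' collapse to the most negative (best-pose) affinity; pairs never observed
#' are missing.
#'
#' @param records Data frame with columns `ligand_id`, `target_id`,
#'   `affinity` (signed kcal/mol) and optionally `source`.
#' @return An [affinity_matrix()].
#' @examples
#' recs <- data.frame(ligand_id = c("A", "A"), target_id = c("X", "X"),
#'                    affinity = c(-7, -6.2))
#' as.matrix(affinity_from_records(recs))  # keeps -7
#' @export
affinity_from_records <- function(records) {
  need <- c("ligand_id", "target_id", "affinity")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("`records` must have columns ligand_id, target_id, affinity",
         call. = FALSE)
  if (nrow(records) == 0L)
    stop("`records` is empty", call. = FALSE)
  lig_id <- trimws(as.character(records$ligand_id))
  tgt_id <- trimws(as.character(records$target_id))
  aff <- as.numeric(records$affinity)
  if (any(!nzchar(lig_id)) || any(!nzchar(tgt_id)))
    stop("empty ligand or target id in records", call. = FALSE)
  if (any(!is.finite(aff)))
    stop("non-finite affinity in records", call. = FALSE)
  lig <- unique(lig_id)
  tgt <- unique(tgt_id)
  vals <- matrix(NA_real_, length(lig), length(tgt),
                 dimnames = list(lig, tgt))
  for (i in seq_along(aff)) {
    r <- lig_id[i]; k <- tgt_id[i]
    cur <- vals[r, k]
    if (is.na(cur) || aff[i] < cur) vals[r, k] <- aff[i]
  }
  affinity_matrix(vals)
}
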