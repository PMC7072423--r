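#' Parse a Vina docked PDBQT file
#'
#' Extracts the per-mode result lines (`REMARK VINA RESULT: affinity
#' rmsd_lb rmsd_ub`) from a multi-model docked PDBQT file, one row per
#' docked pose in file order.
#'
#' @param path Path to a docked PDBQT file.
#' @return Data frame with columns `mode`, `affinity` (kcal/mol),
#'   `rmsd_lb`, `rmsd_ub`.
#' @seealso [parse_vina_log()], [best_affinity()]
#' @export
parse_docked_pdbqt <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such file: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hits <- grep("REMARK VINA RESULT:", lines, fixed = TRUE)
  if (!length(hits))
    stop(sprintf("'%s': no Vina result remark found in any model", path),
         call. = FALSE)
  poses <- lapply(seq_along(hits), function(i) {
    ln <- hits[i]
    rest <- sub(".*REMARK VINA RESULT:", "", lines[ln])
    nums <- suppressWarnings(as.numeric(strsplit(trimws(rest), "[[:space:]]+")[[1]]))
    if (length(nums) < 1L || anyNA(nums))
      stop(sprintf("'%s': malformed result remark at line %d", path, ln),
           call. = FALSE)
    data.frame(mode = i, affinity = nums[1],
               rmsd_lb = if (length(nums) >= 2) nums[2] else NA_real_,
               rmsd_ub = if (length(nums) >= 3) nums[3] else NA_real_)
  })
  do.call(rbind, poses)
}

#' Parse a Vina console log
#'
#' Reads the results table Vina prints to stdout (columns: mode, affinity,
#' RMSD l.b., RMSD u.b.) into one pose per row. A table truncated mid-way
#' yields the rows parsed so far, with a warning.
#'
#' @param text Character vector of log lines, or a single string with
#'   embedded newlines.
#' @return Data frame as in [parse_docked_pdbqt()].
#' @export
parse_vina_log <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  hdr <- grep("^\\s*mode\\s*\\|", lines)
  if (!length(hdr))
    stop("no Vina results table header ('mode | affinity ...') found",
         call. = FALSE)
  start <- hdr[1]
  body <- lines[-seq_len(start)]
  # skip the unit line and the ----+---- rule
  body <- body[!grepl("^\\s*\\|", body) & !grepl("^[-+\\s]*-{3,}", body)]
  poses <- list()
  truncated <- FALSE
  for (ln in body) {
    if (!nzchar(trimws(ln))) break
    nums <- suppressWarnings(
      as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]]))
    if (length(nums) < 2L || anyNA(nums[1:2])) {
      if (grepl("^\\s*[0-9]", ln)) truncated <- TRUE
      break
    }
    if (length(nums) < 4L) truncated <- TRUE
    poses[[length(poses) + 1L]] <- data.frame(
      mode = as.integer(nums[1]), affinity = nums[2],
      rmsd_lb = if (length(nums) >= 3) nums[3] else NA_real_,
      rmsd_ub = if (length(nums) >= 4) nums[4] else NA_real_)
    if (truncated) break
  }
  if (truncated)
    warning("Vina results table truncated; returning poses parsed so far",
            call. = FALSE)
  if (!length(poses))
    return(data.frame(mode = integer(), affinity = double(),
                      rmsd_lb = double(), rmsd_ub = double()))
  do.call(rbind, poses)
}

#' Best-pose affinity
#'
#' The single affinity reported for a ligand-target pair is that of the
#' best docked pose, i.e. the minimum (most negative) over all modes.
#'
#' @param poses Data frame of poses as returned by [parse_docked_pdbqt()]
#'   or [parse_vina_log()].
#' @return The most negative affinity, kcal/mol.
#' @export
best_affinity <- function(poses) {
  if (!is.data.frame(poses) || !"affinity" %in% names(poses))
    stop("`poses` must be a data frame with an `affinity` column",
         call. = FALSE)
  if (nrow(poses) == 0L)
    stop("no poses: cannot take a best affinity", call. = FALSE)
  min(poses$affinity)
}

#' Collect a batch of docked PDBQT files into affinity records
#'
#' Walks a directory of docked PDBQT files whose names encode the ligand
#' and target of each pair, and emits one record per file carrying the
#' best-pose affinity. Vina outputs do not embed receptor identity, so the
#' filename template is the source of pair identity.
#'
#' @param root Directory to scan (non-recursive).
#' @param pattern Filename template with `{ligand}` and `{target}`
#'   placeholders, e.g. the default `"{ligand}__{target}.pdbqt"`.
#' @return Data frame of records (`ligand_id`, `target_id`, `affinity`,
#'   `source`) suitable for [affinity_from_records()]. Files not matching
#'   the template, and files that fail to parse, are skipped with a
#'   warning.
#' @export
collect_vina_batch <- function(root, pattern = "{ligand}__{target}.pdbqt") {
  if (!dir.exists(root))
    stop(sprintf("no such directory: '%s'", root), call. = FALSE)
  tpl <- sub("{ligand}", "\001", pattern, fixed = TRUE)
  tpl <- sub("{target}", "\002", tpl, fixed = TRUE)
  tpl <- gsub("([][{}()+*^$|\\\\?.#-])", "\\\\\\1", tpl)
  tpl <- sub("\001", "(?<ligand>.+?)", tpl, fixed = TRUE)
  tpl <- sub("\002", "(?<target>.+)", tpl, fixed = TRUE)
  rx <- paste0("^", tpl, "$")
  files <- sort(list.files(root))
  m <- regexpr(rx, files, perl = TRUE)
  matched <- which(m > 0L)
  if (!length(matched))
    stop(sprintf("no files in '%s' match template '%s'", root, pattern),
         call. = FALSE)
  skipped <- setdiff(seq_along(files), matched)
  for (i in skipped)
    warning(sprintf("skipping '%s': does not match template", files[i]),
            call. = FALSE)
  recs <- list()
  for (i in matched) {
    st <- attr(m, "capture.start")[i, ]
    len <- attr(m, "capture.length")[i, ]
    lig <- substr(files[i], st["ligand"], st["ligand"] + len["ligand"] - 1L)
    tgt <- substr(files[i], st["target"], st["target"] + len["target"] - 1L)
    aff <- tryCatch(best_affinity(parse_docked_pdbqt(file.path(root, files[i]))),
                    error = function(e) {
                      warning(sprintf("skipping '%s': %s", files[i],
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    if (is.null(aff)) next
    recs[[length(recs) + 1L]] <- data.frame(
      ligand_id = lig, target_id = tgt, affinity = aff,
      source = files[i])
  }
  if (!length(recs))
    stop(sprintf("no parsable docked files in '%s'", root), call. = FALSE)
  do.call(rbind, recs)
}
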