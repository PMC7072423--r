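#' Simulate a screening affinity matrix
#'
#' Generates a ligand x target matrix with the statistical shape of a real
#' multi-target docking screen: most cells are favorable binders drawn
#' uniformly from `favorable_range`, a `nonbinder_fraction` of cells are
#' weak non-binders drawn from `nonbinder_range` (above the usual -6
#' kcal/mol pass filter), and selected targets can have a planted champion
#' ligand forced strictly below every other cell in its column by at least
#' 0.5 kcal/mol. One integer seed fully determines the matrix; the caller's
#' random-number state is left untouched.
#'
#' In a column with a planted champion, the other cells are drawn from
#' `[low + 1, high]` so a champion slot strictly 0.5 kcal/mol below the
#' column minimum always exists inside the favorable range; a favorable
#' range of width 1 or less cannot host a plant and errors.
#'
#' @param n_ligands,n_targets Matrix dimensions, positive integers.
#' @param favorable_range Length-2 `c(low, high)`, kcal/mol, `low <= high
#'   <= 0`. Default `c(-20.4, -6)`, the spread seen in real screens of
#'   polyphenol-sized ligands.
#' @param nonbinder_fraction Fraction of cells drawn from
#'   `nonbinder_range`, in `[0, 1]`. Default `0.1`.
#' @param nonbinder_range Length-2 `c(low, high)` with `high >= low > -6`:
#'   non-binders must sit above the conventional pass filter. Default
#'   `c(-5.9, -3)`.
#' @param planted_champions Optional named integer vector: names are target
#'   indices, values are the ligand index forced to be that target's best
#'   binder. `NULL` for none.
#' @param seed Integer seed.
#' @return An [affinity_matrix()] with ligands `L1..Ln` and targets
#'   `T1..Tm`.
#' @examples
#' m <- simulate_affinity_matrix(3, 4, seed = 42)
#' @export
simulate_affinity_matrix <- function(n_ligands, n_targets,
                                     favorable_range = c(-20.4, -6),
                                     nonbinder_fraction = 0.1,
                                     nonbinder_range = c(-5.9, -3),
                                     planted_champions = NULL,
                                     seed) {
  stopifnot(n_ligands >= 1, n_targets >= 1)
  if (length(favorable_range) != 2L || favorable_range[1] > favorable_range[2] ||
      favorable_range[2] > 0)
    stop("`favorable_range` must be c(low, high) with low <= high <= 0",
         call. = FALSE)
  if (nonbinder_fraction < 0 || nonbinder_fraction > 1)
    stop("`nonbinder_fraction` must be in [0, 1]", call. = FALSE)
  if (length(nonbinder_range) != 2L || nonbinder_range[1] > nonbinder_range[2] ||
      nonbinder_range[1] <= -6)
    stop("`nonbinder_range` must be c(low, high) with high >= low > -6",
         call. = FALSE)
  champs <- integer(0)
  if (!is.null(planted_champions)) {
    champs <- as.integer(planted_champions)
    names(champs) <- names(planted_champions)
    ti <- as.integer(names(champs))
    if (anyNA(ti) || anyNA(champs) || any(ti < 1 | ti > n_targets) ||
        any(champs < 1 | champs > n_ligands))
      stop("`planted_champions` indices out of range", call. = FALSE)
    if (anyDuplicated(ti))
      stop("duplicate target in `planted_champions`", call. = FALSE)
    if (diff(favorable_range) <= 1)
      stop("favorable_range too narrow to plant a champion", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    lo <- favorable_range[1]; hi <- favorable_range[2]
    vals <- matrix(stats::runif(n_ligands * n_targets, lo, hi),
                   n_ligands, n_targets)
    n_nb <- round(nonbinder_fraction * length(vals))
    if (n_nb > 0) {
      nb <- sample.int(length(vals), n_nb)
      vals[nb] <- stats::runif(n_nb, nonbinder_range[1], nonbinder_range[2])
    }
    for (k in seq_along(champs)) {
      t <- as.integer(names(champs))[k]
      l <- champs[[k]]
      others <- setdiff(seq_len(n_ligands), l)
      if (length(others)) {
        # redraw favorable cells in this column clear of the champion slot
        fav <- others[vals[others, t] <= hi]
        vals[fav, t] <- stats::runif(length(fav), lo + 1, hi)
        m <- min(vals[others, t])
      } else m <- hi + 0.5
      if (m - 0.5 <= lo)
        stop("favorable_range too narrow to plant a champion", call. = FALSE)
      vals[l, t] <- stats::runif(1, lo, m - 0.5)
    }
    dimnames(vals) <- list(paste0("L", seq_len(n_ligands)),
                           paste0("T", seq_len(n_targets)))
    affinity_matrix(vals)
  })
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "mtscreen")
  if (!nzchar(p)) stop(sprintf("fixture '%s' not found", file), call. = FALSE)
  p
}

#' Machine-readable errata for the packaged Triphala matrices
#'
#' The packaged screening matrices are shipped exactly as published,
#' including three internally inconsistent cells; this manifest documents
#' the corrections the `*_errata` fixture variants apply (and nothing
#' else). Values are canonical signed kcal/mol.
#'
#' @return A list with elements `angiogenesis` and `inflammation`, each a
#'   data frame of corrections (`ligand`, `target`, `as_printed`,
#'   `corrected`, `note`).
#' @export
triphala_errata <- function() {
  j <- jsonlite::read_json(fixture_path("triphala_errata.json"),
                           simplifyVector = TRUE)
  list(angiogenesis = j$angiogenesis, inflammation = j$inflammation)
}

#' Packaged Triphala churna screening matrices
#'
#' Two published screens of the 15 principal phytochemicals of Triphala
#' churna: `angiogenesis` (27 targets of the VEGF/VEGFR2 signaling
#' pathway, signed kcal/mol) and `inflammation` (COX-2 and 5-LOX, published
#' as unsigned magnitudes of negative affinities and negated at ingest).
#' The `*_as_printed` variants reproduce every published cell verbatim --
#' including two angiogenesis cells printed without a minus sign and one
#' inflammation cell inconsistent with its compound's published efficacy.
#' The `*_errata` variants apply only the corrections listed by
#' [triphala_errata()].
#'
#' @param name One of `"angiogenesis_as_printed"`, `"angiogenesis_errata"`,
#'   `"inflammation_as_printed"`, `"inflammation_errata"`.
#' @return An [affinity_matrix()]; `metadata` carries the compound PubChem
#'   CIDs, the target PDB ids, the variant name, and any applied errata.
#' @examples
#' m <- triphala_matrix("inflammation_as_printed")
#' dim(m)  # 15 ligands x 2 targets
#' @export
triphala_matrix <- function(name = c("angiogenesis_as_printed",
                                     "angiogenesis_errata",
                                     "inflammation_as_printed",
                                     "inflammation_errata")) {
  name <- match.arg(name)
  panel <- sub("_(as_printed|errata)$", "", name)
  dialect <- matrix_dialect(
    sign = if (panel == "inflammation") "magnitude" else "signed",
    orientation = "targets-as-rows")
  m <- read_affinity_matrix(
    fixture_path(sprintf("triphala_%s_as_printed.csv", panel)), dialect)
  applied <- NULL
  if (grepl("_errata$", name)) {
    applied <- triphala_errata()[[panel]]
    for (i in seq_len(nrow(applied)))
      m$values[applied$ligand[i], applied$target[i]] <- applied$corrected[i]
  }
  comp <- utils::read.csv(fixture_path("triphala_compounds.csv"),
                          check.names = FALSE)
  tgt <- utils::read.csv(fixture_path("triphala_targets.csv"),
                         check.names = FALSE)
  m$metadata <- list(
    variant = name,
    pubchem_cid = stats::setNames(as.character(comp$pubchem_cid), comp$ligand),
    pdb_id = stats::setNames(tgt$pdb_id, tgt$target)[targets(m)],
    errata_applied = applied)
  m
}
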