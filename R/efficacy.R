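#' Pass-filter threshold policy
#'
#' Weak docked poses are discarded before any prediction-efficacy sum: an
#' affinity contributes only if it passes the cutoff. The default policy is
#' a cutoff of -6.0 kcal/mol, inclusive (an affinity of exactly -6.0
#' passes). Inclusivity is a flag because published screens are not always
#' consistent about the boundary. Cutoffs above zero are rejected: an
#' unfavorable "pass" would break the monotonicity of efficacy in the
#' cutoff.
#'
#' @param cutoff Threshold in signed kcal/mol, `<= 0`. Default `-6`.
#' @param inclusive If `TRUE` (default) an affinity equal to the cutoff
#'   passes; if `FALSE` it must be strictly more negative.
#' @return A `threshold_policy` object.
#' @export
threshold_policy <- function(cutoff = -6, inclusive = TRUE) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff))
    stop("`cutoff` must be a single finite number", call. = FALSE)
  if (cutoff > 0)
    stop("`cutoff` must be <= 0 kcal/mol", call. = FALSE)
  structure(list(cutoff = as.numeric(cutoff), inclusive = isTRUE(inclusive)),
            class = "threshold_policy")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat(sprintf("threshold_policy: affinity %s %.3g kcal/mol passes\n",
              if (x$inclusive) "<=" else "<", x$cutoff))
  invisible(x)
}

#' Does an affinity pass the filter?
#'
#' Vectorized over `affinity`. Missing values (`NA`) never pass.
#'
#' @param affinity Numeric vector of affinities, kcal/mol; `NA` allowed.
#' @param policy A [threshold_policy()].
#' @return Logical vector.
#' @export
passes <- function(affinity, policy = threshold_policy()) {
  stopifnot(inherits(policy, "threshold_policy"))
  ok <- if (policy$inclusive) affinity <= policy$cutoff
        else affinity < policy$cutoff
  ok & !is.na(affinity)
}

#' Per-compound prediction efficacy
#'
#' The prediction efficacy (PE) of a compound is the sum of its binding
#' affinities over all targets whose affinity passes the filter. A compound
#' with no passing target has PE exactly 0 (the empty sum); more negative
#' PE means the compound is predicted to engage the target panel more
#' strongly.
#'
#' @param x An [affinity_matrix()].
#' @param ligand_id Ligand to score; must be present in `x`.
#' @param policy A [threshold_policy()].
#' @return A list with `ligand_id`, `pe` (kcal/mol) and `n_contributing`
#'   (number of passing targets).
#' @examples
#' m <- triphala_matrix("inflammation_errata")
#' compound_pe(m, "punicalagin")  # pe -33.8 over COX-2 and 5-LOX
#' @export
compound_pe <- function(x, ligand_id, policy = threshold_policy()) {
  stopifnot(inherits(x, "affinity_matrix"))
  if (!ligand_id %in% ligands(x))
    stop(sprintf("unknown ligand: '%s'", ligand_id), call. = FALSE)
  row <- x$values[ligand_id, ]
  keep <- passes(row, policy)
  list(ligand_id = ligand_id,
       pe = sum(row[keep]),
       n_contributing = sum(keep))
}

#' Prediction efficacy of every compound, ranked
#'
#' Scores every ligand with [compound_pe()] and ranks them by ascending PE
#' (most negative = rank 1). Ties break lexicographically by ligand id.
#'
#' @inheritParams compound_pe
#' @return Data frame with one row per ligand, sorted by rank: columns
#'   `rank`, `ligand_id`, `pe`, `n_contributing`.
#' @export
all_compound_pe <- function(x, policy = threshold_policy()) {
  stopifnot(inherits(x, "affinity_matrix"))
  lig <- ligands(x)
  if (!length(lig)) stop("matrix has no ligands", call. = FALSE)
  pe <- vapply(lig, function(l) compound_pe(x, l, policy)$pe, 0)
  n <- vapply(lig, function(l) compound_pe(x, l, policy)$n_contributing, 0L)
  ord <- order(pe, lig, method = "radix")
  data.frame(rank = seq_along(lig),
             ligand_id = lig[ord],
             pe = unname(pe[ord]),
             n_contributing = unname(n[ord]),
             row.names = NULL)
}

#' Best passing binder for each target
#'
#' For each target, the champion is the ligand with the most negative
#' passing affinity; ties break by ligand order in the matrix. Targets with
#' no passing ligand get `NA`.
#'
#' @inheritParams compound_pe
#' @return Data frame with columns `target_id`, `ligand_id`, `affinity`
#'   (the latter two `NA` where nothing passes), in target order.
#' @export
per_target_best <- function(x, policy = threshold_policy()) {
  stopifnot(inherits(x, "affinity_matrix"))
  tgt <- targets(x)
  lig <- ligands(x)
  best <- lapply(tgt, function(t) {
    col <- x$values[, t]
    col[!passes(col, policy)] <- NA_real_
    if (all(is.na(col)))
      return(data.frame(target_id = t, ligand_id = NA_character_,
                        affinity = NA_real_))
    i <- which.min(col)  # first index wins ties: ligand input order
    data.frame(target_id = t, ligand_id = lig[i], affinity = col[[i]])
  })
  out <- do.call(rbind, best)
  row.names(out) <- NULL
  out
}

#' Formulation-level prediction efficacy
#'
#' The PE of a multi-compound formulation. In the default
#' `"best-per-target"` mode it is the sum over targets of the best (most
#' negative) passing affinity among all compounds -- the formulation is
#' credited with its strongest binder at each target. The alternative
#' `"sum-of-compound-pe"` mode instead sums every compound's PE, counting a
#' target once per passing compound.
#'
#' @inheritParams compound_pe
#' @param mode `"best-per-target"` (default) or `"sum-of-compound-pe"`.
#' @return A list with `pe` (kcal/mol), `mode`, and `per_target_best` (the
#'   [per_target_best()] table; `NULL` in sum mode).
#' @export
formulation_pe <- function(x, policy = threshold_policy(),
                           mode = c("best-per-target", "sum-of-compound-pe")) {
  stopifnot(inherits(x, "affinity_matrix"))
  mode <- match.arg(mode)
  if (mode == "best-per-target") {
    champ <- per_target_best(x, policy)
    list(pe = sum(champ$affinity, na.rm = TRUE), mode = mode,
         per_target_best = champ)
  } else {
    tab <- all_compound_pe(x, policy)
    list(pe = sum(tab$pe), mode = mode, per_target_best = NULL)
  }
}

#' Compound PE across a set of cutoffs
#'
#' Sensitivity analysis of the pass filter: evaluates every compound's PE
#' at each cutoff. Cutoffs must be `<= 0`.
#'
#' @inheritParams compound_pe
#' @param cutoffs Numeric vector of cutoffs, kcal/mol, all `<= 0`.
#' @param inclusive Boundary rule applied at every cutoff.
#' @return Data frame with columns `cutoff`, `ligand_id`, `pe`,
#'   `n_contributing`, sorted by cutoff then ligand id.
#' @export
threshold_sweep <- function(x, cutoffs, inclusive = TRUE) {
  stopifnot(inherits(x, "affinity_matrix"))
  if (!length(cutoffs) || any(!is.finite(cutoffs)))
    stop("`cutoffs` must be finite numbers", call. = FALSE)
  if (any(cutoffs > 0))
    stop("`cutoffs` must all be <= 0 kcal/mol", call. = FALSE)
  lig <- ligands(x)
  out <- lapply(sort(cutoffs), function(cf) {
    pol <- threshold_policy(cf, inclusive)
    res <- lapply(sort(lig, method = "radix"), function(l) {
      ce <- compound_pe(x, l, pol)
      data.frame(cutoff = cf, ligand_id = l, pe = ce$pe,
                 n_contributing = ce$n_contributing)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  row.names(out) <- NULL
  out
}

#' Round half away from zero
#'
#' Display rounding used in PE reports (so -32.05 prints as -32.1, not the
#' banker's -32.0). Comparison and storage always use full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a ranked compound-PE report
#'
#' Delimited report with one row per compound, PE displayed to one decimal
#' (half away from zero), plus an optional formulation summary line.
#'
#' @inheritParams compound_pe
#' @param path Output file path.
#' @param registry_ids Optional named character vector mapping ligand id to
#'   a registry id (e.g. PubChem CID) for an extra column.
#' @param formulation If `TRUE`, append a final summary row with the
#'   best-per-target formulation PE.
#' @param sep Field delimiter.
#' @return Invisibly, the report data frame (full precision).
#' @export
write_pe_report <- function(x, path, policy = threshold_policy(),
                            registry_ids = NULL, formulation = TRUE,
                            sep = "\t") {
  tab <- all_compound_pe(x, policy)
  reg <- if (is.null(registry_ids)) rep("", nrow(tab))
         else ifelse(is.na(registry_ids[tab$ligand_id]), "",
                     registry_ids[tab$ligand_id])
  lines <- c(paste(c("rank", "ligand_id", "registry_id", "pe_kcal_mol",
                     "n_contributing"), collapse = sep),
             vapply(seq_len(nrow(tab)), function(i)
               paste(c(tab$rank[i], tab$ligand_id[i], reg[i],
                       format(round_half_away(tab$pe[i]), nsmall = 0),
                       tab$n_contributing[i]), collapse = sep), ""))
  if (formulation) {
    f <- formulation_pe(x, policy)
    lines <- c(lines, paste(c("", "formulation", "",
                              format(round_half_away(f$pe), nsmall = 0), ""),
                            collapse = sep))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(tab)
}
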