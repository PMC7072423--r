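#' Build the drug-target network
#'
#' The drug-target network (DTN) is the bipartite graph whose edges are the
#' ligand-target pairs passing the affinity filter; edge weight is the
#' signed affinity, and for each target the edge to its best binder is
#' flagged as the champion edge. All ligands and targets appear as nodes
#' even when isolated, so the network's degree table is comparable across
#' policies.
#'
#' @param x An [affinity_matrix()].
#' @param policy A [threshold_policy()].
#' @return A `drug_target_network`: a list with `compounds`, `targets`
#'   (node id vectors), `edges` (data frame `ligand_id`, `target_id`,
#'   `affinity`, `champion`), and the `policy` used.
#' @examples
#' net <- build_dtn(triphala_matrix("inflammation_errata"))
#' nrow(net$edges)  # 29 passing interactions
#' @export
build_dtn <- function(x, policy = threshold_policy()) {
  stopifnot(inherits(x, "affinity_matrix"))
  vals <- x$values
  pass <- passes(vals, policy)
  idx <- which(pass, arr.ind = TRUE)
  champ <- per_target_best(x, policy)
  edges <- data.frame(ligand_id = ligands(x)[idx[, 1]],
                      target_id = targets(x)[idx[, 2]],
                      affinity = vals[pass],
                      stringsAsFactors = FALSE)
  # deterministic edge order: target panel order, then ligand order
  if (nrow(edges)) {
    edges <- edges[order(match(edges$target_id, targets(x)),
                         match(edges$ligand_id, ligands(x))), ]
    key <- paste(edges$ligand_id, edges$target_id, sep = "\r")
    ckey <- paste(champ$ligand_id, champ$target_id, sep = "\r")
    edges$champion <- key %in% ckey[!is.na(champ$ligand_id)]
  } else {
    edges$champion <- logical(0)
  }
  row.names(edges) <- NULL
  structure(list(compounds = ligands(x), targets = targets(x),
                 edges = edges, policy = policy),
            class = "drug_target_network")
}

#' @export
print.drug_target_network <- function(x, ...) {
  cat(sprintf("drug_target_network: %d compounds, %d targets, %d edges (%d champion)\n",
              length(x$compounds), length(x$targets), nrow(x$edges),
              sum(x$edges$champion)))
  invisible(x)
}

#' Node degrees of a drug-target network
#'
#' A compound's degree is the number of targets it hits (equal to its
#' `n_contributing` under the same policy); a target's degree is the number
#' of compounds passing on it. Isolated nodes have degree 0.
#'
#' @param network A [build_dtn()] result.
#' @return Data frame with columns `node_id`, `kind` (`"compound"` or
#'   `"target"`), `degree`.
#' @export
degree_metrics <- function(network) {
  stopifnot(inherits(network, "drug_target_network"))
  e <- network$edges
  cd <- vapply(network$compounds, function(l) sum(e$ligand_id == l), 0L)
  td <- vapply(network$targets, function(t) sum(e$target_id == t), 0L)
  data.frame(node_id = c(network$compounds, network$targets),
             kind = rep(c("compound", "target"),
                        c(length(network$compounds), length(network$targets))),
             degree = c(cd, td), row.names = NULL)
}

#' Convert a drug-target network to an igraph object
#'
#' Nodes carry a `kind` attribute (`compound`/`target`); edges carry
#' `affinity` (or its absolute value) and the `champion` flag. If a name is
#' used both as a compound and as a target, nodes are disambiguated with
#' `compound:`/`target:` prefixes.
#'
#' @param network A [build_dtn()] result.
#' @param abs_weights If `TRUE`, edge `weight` is `abs(affinity)` for
#'   viewers that require positive weights; the signed `affinity` attribute
#'   is kept either way.
#' @return An [igraph::graph] object.
#' @export
dtn_igraph <- function(network, abs_weights = FALSE) {
  stopifnot(inherits(network, "drug_target_network"))
  clash <- length(intersect(network$compounds, network$targets)) > 0L
  cid <- if (clash) paste0("compound:", network$compounds) else network$compounds
  tid <- if (clash) paste0("target:", network$targets) else network$targets
  verts <- data.frame(name = c(cid, tid),
                      kind = rep(c("compound", "target"),
                                 c(length(cid), length(tid))))
  e <- network$edges
  el <- data.frame(
    from = if (clash) paste0("compound:", e$ligand_id) else e$ligand_id,
    to = if (clash) paste0("target:", e$target_id) else e$target_id,
    affinity = e$affinity,
    weight = if (abs_weights) abs(e$affinity) else e$affinity,
    champion = e$champion)
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = verts)
}

#' Export a drug-target network
#'
#' Writes the network as SIF (`ligand binds target`, tab-separated) or
#' GraphML (via igraph, with node kind and edge affinity/champion
#' attributes), re-importable by Cytoscape and similar viewers.
#'
#' @inheritParams dtn_igraph
#' @param path Output file path.
#' @param format `"sif"` or `"graphml"`.
#' @export
export_dtn <- function(network, path, format = c("sif", "graphml"),
                       abs_weights = FALSE) {
  stopifnot(inherits(network, "drug_target_network"))
  format <- match.arg(format)
  if (format == "sif") {
    e <- network$edges
    clash <- length(intersect(network$compounds, network$targets)) > 0L
    lig <- if (clash) paste0("compound:", e$ligand_id) else e$ligand_id
    tgt <- if (clash) paste0("target:", e$target_id) else e$target_id
    writeLines(paste(lig, "binds", tgt, sep = "\t"), path, useBytes = TRUE)
  } else {
    igraph::write_graph(dtn_igraph(network, abs_weights), path,
                        format = "graphml")
  }
  invisible(NULL)
}
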