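# Brute-force reference implementations, written independently of the
# package internals: explicit loops over a plain numeric matrix. Used to
# cross-check compound_pe / formulation_pe / per_target_best on small
# random matrices.

oracle_pass <- function(v, cutoff, inclusive) {
  if (is.na(v)) return(FALSE)
  if (inclusive) v <= cutoff else v < cutoff
}

oracle_compound_pe <- function(vals, ligand, cutoff = -6, inclusive = TRUE) {
  total <- 0
  n <- 0L
  for (t in colnames(vals)) {
    v <- vals[ligand, t]
    if (oracle_pass(v, cutoff, inclusive)) {
      total <- total + v
      n <- n + 1L
    }
  }
  list(pe = total, n = n)
}

oracle_per_target_best <- function(vals, cutoff = -6, inclusive = TRUE) {
  out <- list()
  for (t in colnames(vals)) {
    best_l <- NA_character_
    best_v <- NA_real_
    for (l in rownames(vals)) {
      v <- vals[l, t]
      if (oracle_pass(v, cutoff, inclusive) &&
          (is.na(best_v) || v < best_v)) {
        best_l <- l
        best_v <- v
      }
    }
    out[[t]] <- list(ligand = best_l, affinity = best_v)
  }
  out
}

oracle_formulation_pe <- function(vals, cutoff = -6, inclusive = TRUE) {
  total <- 0
  for (b in oracle_per_target_best(vals, cutoff, inclusive))
    if (!is.na(b$affinity)) total <- total + b$affinity
  total
}

# Random test matrix: mix of favorable, weak and missing cells.
random_test_matrix <- function(n_lig, n_tgt, seed, missing_frac = 0.1) {
  withr::with_seed(seed, {
    vals <- matrix(round(runif(n_lig * n_tgt, -15, -2), 1), n_lig, n_tgt,
                   dimnames = list(paste0("lig", seq_len(n_lig)),
                                   paste0("tgt", seq_len(n_tgt))))
    if (missing_frac > 0) {
      k <- round(missing_frac * length(vals))
      if (k > 0) vals[sample.int(length(vals), k)] <- NA_real_
    }
    vals
  })
}
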