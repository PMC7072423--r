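# Builders for Vina-style output fixtures, constructed in code.

vina_pdbqt_text <- function(affinities,
                            rmsd_lb = rep(0, length(affinities)),
                            rmsd_ub = rep(0, length(affinities))) {
  unlist(lapply(seq_along(affinities), function(i) c(
    sprintf("MODEL %d", i),
    sprintf("REMARK VINA RESULT:    %6.1f    %6.3f    %6.3f",
            affinities[i], rmsd_lb[i], rmsd_ub[i]),
    "REMARK  9 active torsions:",
    "ROOT",
    sprintf("ATOM      1  C   LIG A   1       0.000   0.000   %.3f  1.00  0.00     0.000 C",
            i * 1.0),
    "ENDROOT",
    "TORSDOF 0",
    "ENDMDL")))
}

vina_log_text <- function(affinities,
                          rmsd_lb = rep(0, length(affinities)),
                          rmsd_ub = rep(0, length(affinities)),
                          truncate_last = FALSE) {
  rows <- vapply(seq_along(affinities), function(i)
    sprintf("%4d %12.1f %10.3f %10.3f", i, affinities[i],
            rmsd_lb[i], rmsd_ub[i]), "")
  if (truncate_last && length(rows))
    rows[length(rows)] <- sub("\\s+[0-9.]+$", "", rows[length(rows)])
  c("Detected 4 CPUs",
    "Performing search ... done.",
    "mode |   affinity | dist from best mode",
    "     | (kcal/mol) | rmsd l.b.| rmsd u.b.",
    "-----+------------+----------+----------",
    rows)
}

write_vina_batch <- function(dir, pairs) {
  # pairs: data frame ligand, target, list-column affs
  for (i in seq_len(nrow(pairs))) {
    writeLines(vina_pdbqt_text(pairs$affs[[i]]),
               file.path(dir, sprintf("%s__%s.pdbqt",
                                      pairs$ligand[i], pairs$target[i])))
  }
}
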