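test_that("the pass filter honors the boundary, inclusivity, and missingness", {
  expect_true(passes(-6.0, threshold_policy(-6, inclusive = TRUE)))
  expect_false(passes(-6.0, threshold_policy(-6, inclusive = FALSE)))
  expect_false(passes(-5.9, threshold_policy(-6)))
  expect_true(passes(-6.1, threshold_policy(-6)))
  expect_false(passes(NA_real_, threshold_policy(-6)))
  expect_false(passes(6.4, threshold_policy(-6)))  # unfavorable never passes
  expect_equal(passes(c(-7, NA, -5), threshold_policy(-6)),
               c(TRUE, FALSE, FALSE))
  expect_error(threshold_policy(1), "<= 0")
})

test_that("compound PE reproduces the published inflammation efficacies", {
  m <- triphala_matrix("inflammation_as_printed")
  pun <- compound_pe(m, "punicalagin")
  expect_equal(pun$pe, -33.8)
  expect_equal(pun$n_contributing, 2L)
  tri <- compound_pe(m, "triacontanoic acid")
  expect_equal(tri$pe, -6.7)  # the -4.2 COX-2 cell fails the filter
  expect_equal(tri$n_contributing, 1L)
  expect_error(compound_pe(m, "nosuch"), "unknown ligand: 'nosuch'")
})

test_that("compound PE reproduces the reconstructible angiogenesis efficacies", {
  a <- triphala_matrix("angiogenesis_as_printed")
  expect_equal(compound_pe(a, "dehydroshikimic acid")$pe, -66.6)
  expect_equal(compound_pe(a, "triacontanoic acid")$pe, -39)
  expect_equal(compound_pe(a, "triacontanoic acid")$n_contributing, 6L)
  # negating the two sign-typo cells recovers shikimic acid's published PE
  expect_equal(compound_pe(triphala_matrix("angiogenesis_errata"),
                           "shikimic acid")$pe, -59.4)
})

test_that("a compound with no passing target has PE exactly zero", {
  v <- matrix(c(-5, -4, -7, -8), 2, 2, byrow = TRUE,
              dimnames = list(c("weak", "strong"), c("X", "Y")))
  m <- affinity_matrix(v)
  ce <- compound_pe(m, "weak")
  expect_identical(ce$pe, 0)
  expect_identical(ce$n_contributing, 0L)
})

test_that("ranking is by ascending PE with lexicographic tie-break", {
  a <- triphala_matrix("angiogenesis_as_printed")
  tab <- all_compound_pe(a)
  expect_identical(tab$ligand_id[1:5],
                   c("punicalagin", "chebulagic acid", "isoterchebulin",
                     "chebulinic acid", "corilagin"))
  expect_identical(all_compound_pe(triphala_matrix("inflammation_as_printed"))$ligand_id[1],
                   "punicalagin")

  v <- matrix(c(-7, -8, -7, -8), 2, 2, byrow = TRUE,
              dimnames = list(c("zeta", "alpha"), c("X", "Y")))
  tied <- all_compound_pe(affinity_matrix(v))
  expect_equal(tied$pe, c(-15, -15))
  expect_identical(tied$ligand_id, c("alpha", "zeta"))
  expect_identical(tied$rank, 1:2)
})

test_that("formulation PE follows its mode on hand-enumerable matrices", {
  v <- matrix(c(-7, -5, -6.5, -8), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("X", "Y")))
  m <- affinity_matrix(v)
  f <- formulation_pe(m)
  expect_equal(f$pe, -15)  # targets contribute -7 (A on X) and -8 (B on Y)
  expect_identical(f$per_target_best$ligand_id, c("A", "B"))

  fsum <- formulation_pe(m, mode = "sum-of-compound-pe")
  expect_equal(fsum$pe, compound_pe(m, "A")$pe + compound_pe(m, "B")$pe)
  expect_error(formulation_pe(m, mode = "bogus"))

  single <- affinity_matrix(v["A", , drop = FALSE])
  expect_equal(formulation_pe(single)$pe, compound_pe(single, "A")$pe)

  nothing <- affinity_matrix(matrix(c(-5, -4), 1, 2,
                                    dimnames = list("A", c("X", "Y"))))
  fn <- formulation_pe(nothing)
  expect_identical(fn$pe, 0)
  expect_true(all(is.na(fn$per_target_best$ligand_id)))
})

test_that("per-target champions are the most negative passing binders", {
  a <- triphala_matrix("angiogenesis_as_printed")
  best <- per_target_best(a)
  expect_identical(best$ligand_id[best$target_id == "RAF 1"], "chebulagic acid")
  expect_equal(best$affinity[best$target_id == "RAF 1"], -20.4)
  expect_identical(best$ligand_id[best$target_id == "beta-catenin"],
                   "chebulagic acid")
  # exact -18.4 tie on GSK 3beta resolves to the earlier ligand column
  expect_identical(best$ligand_id[best$target_id == "GSK 3beta"], "punicalagin")

  none <- affinity_matrix(matrix(-5, 2, 1, dimnames = list(c("A", "B"), "X")))
  expect_true(is.na(per_target_best(none)$ligand_id))
})

test_that("threshold sweeps are monotone and expose boundary cells", {
  a <- triphala_matrix("angiogenesis_as_printed")
  sw <- threshold_sweep(a, c(-6, -100))
  expect_true(all(sw$pe[sw$cutoff == -100] == 0))
  loose <- threshold_sweep(a, -0.001)
  strict <- threshold_sweep(a, -6)
  expect_true(all(loose$pe <= strict$pe))

  # gallic acid has exactly one cell at the -6.0 boundary
  g_in <- compound_pe(a, "gallic acid", threshold_policy(-6, TRUE))
  g_ex <- compound_pe(a, "gallic acid", threshold_policy(-6, FALSE))
  expect_equal(g_in$pe - g_ex$pe, -6)
  expect_equal(g_in$n_contributing - g_ex$n_contributing, 1L)
  expect_equal(g_ex$pe, -72.3)

  expect_error(threshold_sweep(a, c(-6, 1)), "<= 0")
})

test_that("PE values and champions match the brute-force oracle", {
  for (seed in 1:25) {
    dims <- withr::with_seed(seed * 1000L, sample(1:6, 2, replace = TRUE))
    vals <- random_test_matrix(dims[1], dims[2], seed)
    m <- affinity_matrix(vals)
    cutoff <- c(-6, -8, -4.5)[seed %% 3 + 1]
    inclusive <- seed %% 2 == 0
    pol <- threshold_policy(cutoff, inclusive)
    for (l in rownames(vals)) {
      got <- compound_pe(m, l, pol)
      want <- oracle_compound_pe(vals, l, cutoff, inclusive)
      expect_equal(got$pe, want$pe)
      expect_equal(got$n_contributing, want$n)
    }
    expect_equal(formulation_pe(m, pol)$pe,
                 oracle_formulation_pe(vals, cutoff, inclusive))
    got_best <- per_target_best(m, pol)
    want_best <- oracle_per_target_best(vals, cutoff, inclusive)
    for (t in colnames(vals)) {
      expect_identical(got_best$ligand_id[got_best$target_id == t],
                       want_best[[t]]$ligand)
    }
  }
})

test_that("permuting rows or columns changes no PE and no champion", {
  vals <- random_test_matrix(6, 5, seed = 7)
  m <- affinity_matrix(vals)
  base_pe <- all_compound_pe(m)
  base_best <- per_target_best(m)
  for (seed in 1:5) {
    perm <- withr::with_seed(seed, vals[sample.int(nrow(vals)),
                                        sample.int(ncol(vals))])
    mp <- affinity_matrix(perm)
    pe_p <- all_compound_pe(mp)
    expect_equal(pe_p[order(pe_p$ligand_id), c("ligand_id", "pe")],
                 base_pe[order(base_pe$ligand_id), c("ligand_id", "pe")],
                 ignore_attr = TRUE)
    bp <- per_target_best(mp)
    expect_equal(bp[order(bp$target_id), ],
                 base_best[order(base_best$target_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("display rounding is half away from zero at one decimal", {
  expect_equal(round_half_away(-32.05), -32.1)
  expect_equal(round_half_away(-6.74), -6.7)
  expect_equal(round_half_away(12.45), 12.5)
  expect_equal(round_half_away(-424.84), -424.8)
})

test_that("PE reports carry rank, registry id and formulation line", {
  m <- triphala_matrix("inflammation_errata")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pe_report(m, f, registry_ids = m$metadata$pubchem_cid)
  lines <- readLines(f)
  expect_length(lines, 17L)  # header + 15 compounds + formulation
  expect_match(lines[2], "^1\tpunicalagin\t44584733\t-33.8\t2$")
  expect_match(lines[17], "formulation\t\t-33.8")
})
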