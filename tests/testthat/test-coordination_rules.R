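test_that("donor classification matches the oxygen-centred taxonomy", {
  d <- classify_donors(fx_abeta())
  counts <- table(d$donor_class)
  expect_identical(unname(counts[["CARBOXYLATE_O"]]), 12L) # 6 Asp/Glu x 2
  expect_identical(unname(counts[["IMIDAZOLE_N"]]), 6L)    # His6/13/14 x 2
  expect_identical(unname(counts[["PHENOL_O"]]), 1L)       # Tyr10
  expect_identical(unname(counts[["CARBONYL_O"]]), 42L)
  expect_identical(unname(counts[["NTERM_N"]]), 1L)
  expect_true(all(d$requires_deprotonation == (d$donor_class == "PHENOL_O")))
  # deterministic ordering by (residue, atom name)
  expect_false(is.unsorted(d$resno))

  ala3 <- classify_donors(new_model_from_atoms(build_peptide(rep("ALA", 3))))
  expect_identical(sort(unique(ala3$donor_class)),
                   c("CARBONYL_O", "NTERM_N"))
  expect_identical(nrow(ala3), 4L) # 3 carbonyls + 1 N-terminal amine
})

test_that("motif admissibility enforces the cluster-model rules", {
  m <- ligand_motif(C = 4L, W = 1L, A = 1L) # the 4CWA motif
  expect_true(motif_is_admissible(m))
  expect_identical(m$coordination_number, 6L)

  poor <- ligand_motif(C = 1L, W = 5L)
  v <- motif_is_admissible(poor)
  expect_false(as.logical(v))
  expect_match(attr(v, "reason"), "carboxylate")

  allb <- ligand_motif(C = 4L, denticity = rep("B", 4L)) # CN 8
  expect_false(as.logical(motif_is_admissible(allb)))
  expect_match(attr(motif_is_admissible(allb), "reason"), "coordination")

  expect_error(ligand_motif(C = -1L), "non-negative")
})

test_that("complex charge bookkeeping reproduces printed charges", {
  # hexaaqua reference: no ligands displaced
  expect_identical(complex_charge(reaction_spec()), 3L)
  # four acetates + neutral W, A: 3 - 4 = -1
  m4cwa <- ligand_motif(C = 4L, W = 1L, A = 1L)
  expect_identical(complex_charge(reaction_spec_for_motif(m4cwa)), -1L)
  # three acetates: neutral complex
  m3cwha <- ligand_motif(C = 3L, W = 1L, H = 1L, A = 1L)
  expect_identical(complex_charge(reaction_spec_for_motif(m3cwha)), 0L)
  expect_true(all(charges_match_reference()))
  # waters displaced equals the number of non-water ligands
  spec <- reaction_spec_for_motif(m4cwa)
  expect_identical(spec$waters_displaced, spec$m + spec$n)
})

test_that("the packaged cluster-model table matches its contract", {
  tab <- load_reference_table()
  expect_identical(nrow(tab), 14L)
  expect_identical(tab$dH298[tab$model == "4CWA"], -126.1)
  expect_identical(tab$dE[tab$model == "4C" & tab$carb == "2M2B"], -108.6)
  expect_true(all(tab$dE < 0) && all(tab$dH298 < 0))
  # every packaged motif is admissible under the rules it was built with
  for (i in seq_len(nrow(tab))) {
    motif <- alsite:::motif_from_label(tab$model[i], tab$carb[i])
    expect_true(motif_is_admissible(motif), label = tab$model[i])
    expect_identical(length(motif$denticity), unname(motif$counts[["C"]]))
  }
})

test_that("enthalpy ranking orders motifs most stable first", {
  tab <- load_reference_table()
  ranked <- rank_by_enthalpy(tab)
  expect_identical(ranked$model[1L], "4CWA")
  expect_identical(ranked$model[2L], "4CWH")
  expect_setequal(paste(ranked$model, ranked$carb)[1:4],
                  c("4CWA 4M", "4CWH 4M", "4CW 3M1B", "4CW 4M"))
  # a permutation: nothing lost or duplicated
  expect_setequal(paste(ranked$model, ranked$carb),
                  paste(tab$model, tab$carb))
  expect_false(is.unsorted(ranked$dH298))
  one <- rank_by_enthalpy(tab[3L, , drop = FALSE])
  expect_identical(one$model, tab$model[3L])
})

test_that("final-complex reference records carry the printed descriptors", {
  rec <- load_complex_reference()
  expect_identical(nrow(rec), 13L)
  expect_identical(rec$shell_residues[[which(rec$label == "Compl3")]],
                   c(3L, 7L, 9L, 11L))
  i9 <- which(rec$label == "Compl9")
  expect_true(rec$has_water[i9])
  expect_identical(rec$shell_residues[[i9]], c(7L, 11L))
  expect_identical(min(rec$dE_aq, na.rm = TRUE), -172.9)
  expect_identical(sum(!is.na(rec$dE_aq)), 5L)
})

test_that("relative interaction energies are anchored at the most stable complex", {
  rec <- delta_delta_e(load_complex_reference())
  expect_identical(rec$relative_dE[rec$label == "Compl1"], 0)
  expect_equal(rec$relative_dE[rec$label == "Compl5"], 14.3)
  expect_true(max(rec$relative_dE, na.rm = TRUE) < 15)
  expect_true(all(rec$relative_dE >= 0, na.rm = TRUE))
  # invariant to input order
  shuffled <- load_complex_reference()[c(7:13, 1:6), ]
  rec2 <- delta_delta_e(shuffled)
  expect_equal(rec2$relative_dE[rec2$label == "Compl5"], 14.3)
})
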