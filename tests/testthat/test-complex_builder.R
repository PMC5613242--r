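donor_row <- function(resno, resname, atom, class, pos) {
  data.frame(resno = resno, resname = resname, atom = atom,
             donor_class = class, is_sidechain = TRUE,
             requires_deprotonation = FALSE, formal_charge = 0L,
             x = pos[1L], y = pos[2L], z = pos[3L])
}

test_that("carboxylate denticity follows the two-oxygen rule", {
  metal <- c(0, 0, 0)
  both <- rbind(
    donor_row(1L, "ASP", "OD1", "CARBOXYLATE_O", c(1.9, 0, 0)),
    donor_row(1L, "ASP", "OD2", "CARBOXYLATE_O", c(0, 1.9, 0)))
  asg <- assign_denticity(metal, both)
  expect_identical(unique(asg$shell$denticity), "B")
  expect_identical(asg$coordination_number, 2L)

  mono <- rbind(
    donor_row(1L, "ASP", "OD1", "CARBOXYLATE_O", c(1.9, 0, 0)),
    donor_row(1L, "ASP", "OD2", "CARBOXYLATE_O", c(3.4, 0, 1.5)))
  asg <- assign_denticity(metal, mono)
  expect_identical(asg$shell$denticity, "M")
  expect_identical(asg$shell$atom, "OD1")
  expect_identical(asg$coordination_number, 1L)

  # relabelling is idempotent
  again <- assign_denticity(metal, mono)
  expect_identical(asg$shell, again$shell)
})

test_that("a Compl1-like shell reaches coordination number six", {
  # Glu3 monodentate, Asp7 monodentate, Glu11 bidentate, plus the
  # backbone carbonyls of Glu3 and Glu11
  metal <- c(0, 0, 0)
  v <- 1.9 * octahedron_vertices()
  donors <- rbind(
    donor_row(3L, "GLU", "OE2", "CARBOXYLATE_O", v[1L, ] * 0.953), # 1.81
    donor_row(3L, "GLU", "OE1", "CARBOXYLATE_O", c(3.4, 1, 0)),
    donor_row(7L, "ASP", "OD2", "CARBOXYLATE_O", v[2L, ]),
    donor_row(7L, "ASP", "OD1", "CARBOXYLATE_O", c(-3.4, 1, 0)),
    donor_row(11L, "GLU", "OE1", "CARBOXYLATE_O", v[3L, ]),
    donor_row(11L, "GLU", "OE2", "CARBOXYLATE_O", v[4L, ] * 1.058), # 2.01
    donor_row(3L, "GLU", "O", "CARBONYL_O", v[5L, ]),
    donor_row(11L, "GLU", "O", "CARBONYL_O", v[6L, ] * 1.058))
  asg <- assign_denticity(metal, donors)
  expect_identical(asg$coordination_number, 6L)
  expect_identical(asg$shell$denticity[asg$shell$resno == 11L &
                                         asg$shell$donor_class ==
                                           "CARBOXYLATE_O"],
                   c("B", "B"))
  expect_identical(sum(asg$shell$denticity == "M"), 2L)
  # the shortest shell distance is a carboxylate oxygen
  expect_identical(asg$shell$donor_class[1L], "CARBOXYLATE_O")
})

test_that("water completion fills exactly the vacant octahedron vertices", {
  # six planted peptide oxygens: nothing to add
  fx6 <- fx_plant6m()
  asg6 <- assign_denticity(c(0, 0, 0), fx6$donors)
  cx6 <- alsite:::new_complex_model(fx6$model, c(0, 0, 0),
                                    first_shell = asg6)
  cx6 <- complete_with_waters(cx6)
  expect_identical(nrow(cx6$waters), 0L)

  # three monodentate donors: three waters at the vacant vertices
  three <- build_planted_model(plant_spec(
    site = c(0, 0, 0),
    donors = list(list(restype = "GLU", vertex = 1L, denticity = "M"),
                  list(restype = "ASP", vertex = 3L, denticity = "M"),
                  list(restype = "GLU", vertex = 5L, denticity = "M")),
    spacers = 1L))
  asg3 <- assign_denticity(c(0, 0, 0), classify_donors(three$model))
  cx3 <- alsite:::new_complex_model(three$model, c(0, 0, 0),
                                    first_shell = asg3)
  cx3 <- complete_with_waters(cx3)
  expect_identical(nrow(cx3$waters), 3L)
  wd <- sqrt(rowSums(sweep(cx3$waters, 2L, cx3$metal_pos)^2))
  expect_true(all(abs(wd - 1.95) <= 0.01))
  # water-donor angles sit near the octahedral ideals
  sx <- as.matrix(three$model$atoms[
    paste(three$model$atoms$resno, three$model$atoms$atom) %in%
      paste(asg3$shell$resno, asg3$shell$atom), c("x", "y", "z")])
  for (i in seq_len(nrow(cx3$waters))) {
    for (j in seq_len(nrow(sx))) {
      ang <- acos(sum(cx3$waters[i, ] * sx[j, ]) /
                    (sqrt(sum(cx3$waters[i, ]^2)) * sqrt(sum(sx[j, ]^2)))) *
        180 / pi
      expect_lte(min(abs(ang - 90), abs(ang - 180)), 20)
    }
  }
})

test_that("five shell oxygens leave room for exactly one water", {
  five <- build_planted_model(plant_spec(
    site = c(0, 0, 0),
    donors = lapply(1:5, function(v) {
      list(restype = if (v %% 2L) "GLU" else "ASP", vertex = v,
           denticity = "M")
    }),
    spacers = 1L))
  asg <- assign_denticity(c(0, 0, 0), classify_donors(five$model))
  expect_identical(asg$coordination_number, 5L)
  cx <- complete_with_waters(alsite:::new_complex_model(
    five$model, c(0, 0, 0), first_shell = asg))
  expect_identical(nrow(cx$waters), 1L)
})

test_that("first-shell summaries are complete, sorted and bounded", {
  fx <- fx_plant6()
  asg <- assign_denticity(c(0, 0, 0), fx$donors)
  cx <- complete_with_waters(alsite:::new_complex_model(
    fx$model, c(0, 0, 0), first_shell = asg))
  fs <- first_shell_summary(cx)
  expect_identical(nrow(fs$shell), nrow(asg$shell) + fs$n_waters)
  expect_identical(fs$coordination_number, nrow(fs$shell))
  expect_false(is.unsorted(fs$shell$distance_A))
  # ideal planted shell distances bracket the refined-complex range
  pep <- fs$shell[fs$shell$resname != "HOH", ]
  expect_true(all(pep$distance_A >= 1.8 & pep$distance_A <= 2.1))

  # no donors in reach: coordination comes entirely from water
  empty <- assign_denticity(c(200, 200, 200), fx$donors)
  cx0 <- complete_with_waters(alsite:::new_complex_model(
    fx$model, c(200, 200, 200), first_shell = empty))
  fs0 <- first_shell_summary(cx0)
  expect_identical(fs0$coordination_number, fs0$n_waters)
  expect_identical(nrow(cx0$waters), 6L)
})

test_that("built complexes from GA survivors approach hexacoordination", {
  fx <- fx_plant6()
  p <- moga_params(population = 60L, generations = 30L, seed = 4L)
  surv <- filter_solutions(evolve(fx$site, fx$model, fx$donors, p), p)
  cx <- build_complex(surv[[1L]], fx$site, fx$model, fx$donors, p)
  fs <- first_shell_summary(cx)
  # a vertex stays empty when a just-out-of-shell donor blocks its water,
  # mirroring the occasional pentacoordinate refined complex
  expect_gte(fs$coordination_number, 5L)
  expect_lte(fs$coordination_number, 6L)
  expect_true(all(fs$shell$distance_A <= p$coordination_cutoff))
  path <- withr::local_tempfile(fileext = ".csv")
  write_shell_csv(fs, path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), nrow(fs$shell))
  expect_named(back, c("residue", "atom", "distance_A", "denticity"))
})
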