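single_atom_model <- function(pos = c(0, 0, 0)) {
  new_model_from_atoms(data.frame(
    serial = 1L, atom = "CA", resname = "GLY", resno = 1L, element = "C",
    is_backbone = TRUE, x = pos[1L], y = pos[2L], z = pos[3L]))
}

test_that("the scan lattice covers the padded bounding box", {
  m <- single_atom_model()
  g <- build_grid(m, grid_params(spacing = 1, padding = 1))
  expect_identical(nrow(g), 27L) # 3 x 3 x 3
  expect_identical(nrow(build_grid(m, grid_params(spacing = 1, padding = 0))),
                   1L)
  two <- new_model_from_atoms(data.frame(
    serial = 1:2, atom = "CA", resname = "GLY", resno = 1:2, element = "C",
    is_backbone = TRUE, x = c(0, 5), y = 0, z = 0))
  g2 <- build_grid(two, grid_params(spacing = 1, padding = 0))
  expect_identical(nrow(g2), 6L) # 6 x 1 x 1
  # lexicographic (x, y, z) ordering
  g3 <- build_grid(m, grid_params(spacing = 1, padding = 1))
  expect_false(is.unsorted(g3[, 1L]))
  expect_error(grid_params(spacing = 0), "spacing")
})

test_that("residues_near uses C-alpha references sorted by distance", {
  fx <- fx_plant4()
  ca <- alsite:::calpha_xyz(fx$model)
  hit <- residues_near(ca[1L, ], fx$model, 0.1)
  expect_identical(hit$resno, as.integer(rownames(ca))[1L])
  expect_identical(nrow(residues_near(c(500, 500, 500), fx$model, 5)), 0L)
  carbs <- residues_near(c(1, 2, 3), fx$model, 7)
  carbs <- carbs[carbs$resname %in% c("ASP", "GLU"), ]
  expect_setequal(carbs$resno, fx$truth$shell$resno)
  expect_false(is.unsorted(residues_near(c(1, 2, 3), fx$model, 10)$ca_dist))
})

test_that("planted octahedral cages are detected near the planted point", {
  fx <- fx_plant4()
  sites <- detect_sites(fx$model, fx$donors)
  expect_gte(length(sites), 1L)
  errs <- vapply(sites, function(s) sqrt(sum((s$centroid - c(1, 2, 3))^2)),
                 numeric(1L))
  expect_lte(min(errs), 1 * sqrt(3)) # within lattice discretization
  best <- sites[[which.min(errs)]]
  expect_gte(nrow(best$supporters), 3L)
  expect_gte(sum(best$supporters$resname %in% c("ASP", "GLU")), 2L)
})

test_that("models without suitable donors yield no sites", {
  pa <- fx_polyala()
  expect_length(detect_sites(pa, classify_donors(pa)), 0L)
  # two carboxylates alone fail the three-donor-residue rule
  two <- build_planted_model(plant_spec(
    site = c(0, 0, 0),
    donors = list(list(restype = "GLU", vertex = 1L, denticity = "M"),
                  list(restype = "ASP", vertex = 3L, denticity = "M")),
    spacers = 1L))
  expect_length(detect_sites(two$model, classify_donors(two$model)), 0L)
})

test_that("tightening the grid rule never admits more points", {
  fx <- fx_plant4()
  pts <- build_grid(fx$model, grid_params())
  n_pass <- function(p) sum(alsite:::grid_points_pass(pts, fx$model,
                                                      fx$donors, p))
  base <- n_pass(grid_params())
  expect_lte(n_pass(grid_params(calpha_radius = 5.5)), base)
  expect_lte(n_pass(grid_params(min_donor_residues = 4L)), base)
  expect_lte(n_pass(grid_params(min_carboxylate_residues = 3L)), base)
})

test_that("the vectorized grid rule equals a brute-force double loop", {
  fx <- fx_plant4()
  params <- grid_params()
  pts <- build_grid(fx$model, params)
  set.seed(7)
  pts <- pts[sample.int(nrow(pts), 400L), , drop = FALSE]
  fast <- alsite:::grid_points_pass(pts, fx$model, fx$donors, params)
  # independent oracle: per point, loop over residues and atoms
  ca <- alsite:::calpha_xyz(fx$model)
  xyz <- alsite:::model_xyz(fx$model)
  sd_classes <- c("CARBOXYLATE_O", "IMIDAZOLE_N", "NTERM_N")
  slow <- vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    ok_res <- integer(0)
    for (rn in unique(fx$donors$resno)) {
      sub <- fx$donors[fx$donors$resno == rn & fx$donors$is_sidechain &
                         fx$donors$donor_class %in% sd_classes, , drop = FALSE]
      if (!nrow(sub)) next
      ca_d <- sqrt(sum((ca[as.character(rn), ] - p)^2))
      atom_d <- min(sqrt((sub$x - p[1L])^2 + (sub$y - p[2L])^2 +
                           (sub$z - p[3L])^2))
      if (ca_d <= params$calpha_radius && atom_d <= params$donor_atom_radius) {
        ok_res <- c(ok_res, rn)
      }
    }
    rn_names <- fx$donors$resname[match(ok_res, fx$donors$resno)]
    ad <- sqrt(rowSums(sweep(xyz, 2L, p)^2))
    floors <- ifelse(fx$model$atoms$element %in% c("N", "O"),
                     params$donor_floor, params$clash_floor)
    length(ok_res) >= params$min_donor_residues &&
      sum(rn_names %in% c("ASP", "GLU")) >= params$min_carboxylate_residues &&
      all(ad >= floors)
  }, logical(1L))
  expect_identical(fast, slow)
})

test_that("site detection is equivariant under rigid motion", {
  fx <- fx_plant4()
  set.seed(11)
  R <- alsite:::random_rotation()
  shift <- c(3.3, -7.1, 12.9)
  moved <- fx$model
  xyz <- alsite:::model_xyz(moved) %*% t(R)
  xyz <- sweep(xyz, 2L, shift, FUN = "+")
  moved$atoms$x <- xyz[, 1L]; moved$atoms$y <- xyz[, 2L]
  moved$atoms$z <- xyz[, 3L]
  sites0 <- detect_sites(fx$model, fx$donors)
  sites1 <- detect_sites(moved, classify_donors(moved))
  expect_gte(length(sites1), 1L)
  # every original site has a transformed counterpart; exact counts can
  # differ because the lattice is re-discretized in the new frame
  for (s0 in sites0) {
    mapped <- as.numeric(R %*% s0$centroid) + shift
    d <- vapply(sites1, function(s) sqrt(sum((s$centroid - mapped)^2)),
                numeric(1L))
    expect_lte(min(d), sqrt(3) * 1.0)
    near <- sites1[[which.min(d)]]
    expect_setequal(near$supporters$resno, s0$supporters$resno)
  }
})

test_that("site tables are deterministic and complete", {
  fx <- fx_plant4()
  sites <- detect_sites(fx$model, fx$donors)
  tab <- site_table(sites)
  expect_identical(nrow(tab), length(sites))
  expect_identical(nrow(site_table(list())), 0L)
  expect_named(site_table(list()),
               c("model_id", "x", "y", "z", "n_points", "supporters"))
})
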