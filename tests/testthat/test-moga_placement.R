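test_that("chi re-posing is an exact, periodic rotation of the distal atoms", {
  res <- build_peptide("GLU")
  expect_identical(n_chi("GLU"), 3L)
  expect_identical(n_chi("ASP"), 2L)
  expect_identical(n_chi("HIS"), 2L)
  expect_identical(n_chi("TYR"), 2L)

  # identity: measured chi reproduces the input coordinates
  same <- apply_chi(res, measure_chi(res))
  expect_lt(max(abs(as.matrix(same[, c("x", "y", "z")]) -
                      as.matrix(res[, c("x", "y", "z")]))), 1e-6)
  # periodicity
  shifted <- apply_chi(res, measure_chi(res) + c(360, -360, 720))
  expect_lt(max(abs(as.matrix(shifted[, c("x", "y", "z")]) -
                      as.matrix(res[, c("x", "y", "z")]))), 1e-6)
  # arity contract
  expect_error(apply_chi(res, c(10, 20)), "3 chi")
  # target angles are hit exactly and bonded geometry survives
  posed <- apply_chi(res, c(-63, 87, 12))
  expect_equal(measure_chi(posed), c(-63, 87, 12), tolerance = 1e-9)
  d0 <- as.matrix(stats::dist(res[, c("x", "y", "z")]))
  d1 <- as.matrix(stats::dist(posed[, c("x", "y", "z")]))
  bb <- res$atom %in% c("N", "CA", "CB")
  expect_lt(max(abs(d1[bb, bb] - d0[bb, bb])), 1e-9)
})

test_that("a chi1 flip matches an independent rotation-matrix oracle", {
  res <- build_peptide("ASP")
  chi <- measure_chi(res)
  flipped <- apply_chi(res, chi + c(180, 0))
  # oracle: Rodrigues rotation written out directly in the test
  rot180 <- function(p, a, b) {
    u <- (b - a) / sqrt(sum((b - a)^2))
    v <- p - a
    # R(180) v = 2 u (u.v) - v
    2 * u * sum(u * v) - v + a
  }
  ca <- as.numeric(res[res$atom == "CA", c("x", "y", "z")])
  cb <- as.numeric(res[res$atom == "CB", c("x", "y", "z")])
  for (nm in c("CG", "OD1", "OD2")) {
    p0 <- as.numeric(res[res$atom == nm, c("x", "y", "z")])
    p1 <- as.numeric(flipped[flipped$atom == nm, c("x", "y", "z")])
    expect_lt(sqrt(sum((p1 - rot180(p0, ca, cb))^2)), 1e-9)
  }
})

test_that("sphere overlap volumes match the analytic limits and a Monte-Carlo oracle", {
  r <- 1.7
  expect_identical(sphere_overlap_volume(r, r, 3.4), 0)
  expect_identical(sphere_overlap_volume(r, r, 4.0), 0)
  expect_equal(sphere_overlap_volume(r, r, 0), (4 / 3) * pi * r^3,
               tolerance = 1e-12)
  # Monte-Carlo oracle: sample inside sphere 1, count hits in sphere 2
  mc_overlap <- function(r1, r2, d, n = 2e5) {
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2)) * (stats::runif(n)^(1 / 3) * r1)
    inside <- (u[, 1L] - d)^2 + u[, 2L]^2 + u[, 3L]^2 <= r2^2
    mean(inside) * (4 / 3) * pi * r1^3
  }
  set.seed(99)
  v <- sphere_overlap_volume(r, r, r)
  expect_equal(v, mc_overlap(r, r, r), tolerance = 0.03)
  # engulfed case
  expect_equal(sphere_overlap_volume(0.6, 1.7, 0.5),
               (4 / 3) * pi * 0.6^3, tolerance = 1e-12)
})

test_that("clash volume sums pairwise overlaps and honours exclusions", {
  probe <- rbind(c(0, 0, 0))
  ctx <- rbind(c(1.7, 0, 0), c(10, 0, 0))
  v <- clash_volume(probe, ctx, "C", c("C", "C"))
  expect_equal(v, sphere_overlap_volume(1.7, 1.7, 1.7), tolerance = 1e-12)
  v0 <- clash_volume(probe, ctx, "C", c("C", "C"),
                     exclude = cbind(1L, 1L))
  expect_identical(v0, 0)
  expect_error(clash_volume(probe, ctx, "XX", c("C", "C")), "radius")
})

test_that("octahedral deviation is zero for ideal subsets and matches enumeration", {
  metal <- c(0, 0, 0)
  expect_identical(octahedral_deviation(metal, 1.9 * octahedron_vertices()),
                   0)
  two <- rbind(c(2, 0, 0), c(0, 2, 0)) # 90 degrees
  expect_identical(octahedral_deviation(metal, two), 0)
  # three donors with pairwise angles 80, 80, 120: deviations -10, -10, 30
  a <- pi / 180
  u1 <- c(1, 0, 0)
  u2 <- c(cos(80 * a), sin(80 * a), 0)
  y3 <- (cos(120 * a) - cos(80 * a)^2) / sin(80 * a)
  u3 <- c(cos(80 * a), y3, sqrt(1 - cos(80 * a)^2 - y3^2))
  dev <- octahedral_deviation(metal, 2 * rbind(u1, u2, u3))
  expect_equal(dev, sqrt((100 + 100 + 900) / 3), tolerance = 1e-6)
  expect_error(octahedral_deviation(metal, rbind(u1)), "at least 2")
})

test_that("octahedral deviation is invariant under rigid motion", {
  set.seed(5)
  donors <- matrix(stats::rnorm(15), 5L, 3L) + 3
  metal <- c(0.5, -0.2, 1)
  base <- octahedral_deviation(metal, donors)
  for (i in 1:5) {
    R <- alsite:::random_rotation()
    t <- stats::rnorm(3, sd = 10)
    moved <- sweep(donors %*% t(R), 2L, t, FUN = "+")
    expect_equal(octahedral_deviation(as.numeric(R %*% metal) + t, moved),
                 base, tolerance = 1e-9)
  }
})

test_that("the ground-truth pose of an ideal O6 cage scores near-perfect", {
  fx <- fx_plant6m()
  params <- moga_params()
  chi0 <- unlist(lapply(unique(fx$truth$shell$resno), function(rn) {
    measure_chi(fx$model$atoms[fx$model$atoms$resno == rn, ])
  }))
  genome <- c(c(0, 0, 0) - fx$site$centroid, chi0)
  obj <- evaluate(genome, fx$site, fx$model, fx$donors, params)
  expect_identical(unname(obj["clash"]), 0)
  expect_lte(obj["donor_score"], 0.3)
  expect_lte(obj["octa_dev"], 5)
  expect_identical(unname(obj["n_donors"]), 6)
})

test_that("pathological poses are penalized", {
  fx <- fx_plant6m()
  params <- moga_params()
  # a metal placed on top of a spacer heavy atom must register clash
  spacer <- fx$model$atoms[fx$model$atoms$resname == "ALA", ]
  fake <- fx$site
  clashes <- vapply(seq_len(nrow(spacer)), function(i) {
    fake$centroid <- as.numeric(spacer[i, c("x", "y", "z")])
    genome <- c(0, 0, 0, rep(0, 15L))
    evaluate(genome, fake, fx$model, fx$donors, params)[["clash"]]
  }, numeric(1L))
  expect_gt(max(clashes), 0)
  # no donors in reach: the shortfall penalty floor applies
  far <- fx$site
  far$centroid <- c(500, 500, 500)
  genome <- c(0, 0, 0, rep(0, 15L))
  obj <- evaluate(genome, far, fx$model, fx$donors, params)
  expect_gte(obj["donor_score"], params$shortfall_lambda * params$min_donors)
  expect_identical(unname(obj["n_donors"]), 0)
})

test_that("non-dominated sorting matches an exhaustive oracle", {
  oracle_ranks <- function(obj) {
    n <- nrow(obj)
    dominates <- function(i, j) {
      all(obj[i, ] <= obj[j, ]) && any(obj[i, ] < obj[j, ])
    }
    rank <- rep(NA_integer_, n)
    r <- 0L
    while (anyNA(rank)) {
      pool <- which(is.na(rank))
      front <- pool[vapply(pool, function(j) {
        !any(vapply(pool, function(i) i != j && dominates(i, j), logical(1L)))
      }, logical(1L))]
      rank[front] <- r
      r <- r + 1L
    }
    rank
  }
  set.seed(31)
  for (n in c(10L, 60L)) {
    obj <- cbind(stats::rnorm(n), stats::rnorm(n),
                 sample(c(0, 1, 2), n, replace = TRUE)) # ties included
    expect_identical(alsite:::pareto_ranks(obj), oracle_ranks(obj))
  }
})

test_that("evolution is seeded-deterministic and returns the population", {
  fx <- fx_plant4()
  p <- moga_params_small(seed = 7L)
  s1 <- evolve(fx$site, fx$model, fx$donors, p)
  s2 <- evolve(fx$site, fx$model, fx$donors, p)
  expect_identical(lapply(s1, `[[`, "genome"), lapply(s2, `[[`, "genome"))
  expect_length(s1, p$population)
  tiny <- evolve(fx$site, fx$model, fx$donors,
                 moga_params(population = 4L, generations = 1L, seed = 1L))
  expect_length(tiny, 4L)
  # rank-0 solutions are non-dominated within the returned population
  obj <- t(vapply(s1, function(s) unlist(s$objectives), numeric(3L)))
  r0 <- which(vapply(s1, `[[`, integer(1L), "pareto_rank") == 0L)
  for (i in r0) {
    dominated <- vapply(seq_len(nrow(obj)), function(j) {
      all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ])
    }, logical(1L))
    expect_false(any(dominated))
  }
})

test_that("survivor filters enforce the clash and donor-count thresholds", {
  mk <- function(clash, ndon, score = 1) {
    structure(list(genome = numeric(4L),
                   objectives = list(clash_volume = clash,
                                     donor_score = score,
                                     octa_deviation = 10),
                   n_donors = ndon, pareto_rank = 0L, crowding = Inf,
                   metal_pos = c(0, 0, 0)), class = "moga_solution")
  }
  p <- moga_params()
  expect_warning(
    kept <- filter_solutions(list(mk(0, 3L), mk(31000, 5L), mk(0, 2L),
                                  mk(100, 4L, score = 0.1)), p),
    "30 nm")
  expect_length(kept, 2L)
  # ordered by (rank, donor_score)
  expect_identical(kept[[1L]]$objectives$donor_score, 0.1)
  quiet <- filter_solutions(list(mk(0, 3L), mk(2, 4L)), p)
  expect_length(quiet, 2L)
})

test_that("the GA recovers a planted site from the apo ensemble", {
  fx <- fx_plant6()
  p <- moga_params(population = 100L, generations = 50L, seed = 2L)
  surv <- filter_solutions(evolve(fx$site, fx$model, fx$donors, p), p)
  expect_gte(length(surv), 1L)
  expect_lte(recovered_error(surv, c(0, 0, 0)), 1.0)
  expect_gte(surv[[1L]]$n_donors, 3L)
  # survivors all satisfy the shell condition they were filtered on
  expect_true(all(vapply(surv, `[[`, integer(1L), "n_donors") >= 3L))
})
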