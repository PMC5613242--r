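# Synthetic peptide fixtures with planted, ground-truth octahedral
# Al(III) sites.  Donor residues are built from the internal-coordinate
# templates and rigidly posed so their donor atoms sit on ideal
# octahedron vertices 1.90 A from the chosen site; spacer residues form
# extended segments routed away from the site.  These fixtures emulate
# the pre-organized apo conformations the pipeline screens for; they are
# not covalently continuous chains and make no claim of Ramachandran
# realism.

PLANT_BOND <- 1.90 # A, ideal Al-O/N distance used for planting

#' Specify a planted octahedral site
#'
#' @param site Numeric 3-vector, the ground-truth metal position (A).
#' @param donors List of donor plans, each `list(restype =, vertex =,
#'   denticity =)`: `restype` one of ASP/GLU/HIS/TYR, `vertex` an
#'   octahedron vertex index 1..6 (a length-2 vector for a bidentate
#'   carboxylate), `denticity` "M" or "B" (carboxylates only).
#' @param spacers Number of Ala spacer residues inserted between
#'   consecutive donors (scalar or vector of length `length(donors)-1`).
#' @param chi_noise_sigma,backbone_noise_sigma,n_models,seed Ensemble
#'   perturbation settings consumed by [build_planted_ensemble()].
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(site = c(0, 0, 0), donors, spacers = 1L,
                       chi_noise_sigma = 0, backbone_noise_sigma = 0,
                       n_models = 1L, seed = 1L) {
  stopifnot(length(site) == 3L, length(donors) >= 1L)
  types <- vapply(donors, `[[`, character(1L), "restype")
  if (!all(types %in% c("ASP", "GLU", "HIS", "TYR"))) {
    stop("donor residues must be ASP, GLU, HIS or TYR")
  }
  ncarb <- sum(types %in% c("ASP", "GLU"))
  if (ncarb < 2L) stop("a plant needs at least two carboxylate donors")
  verts <- unlist(lapply(donors, `[[`, "vertex"))
  if (anyDuplicated(verts) || any(!verts %in% 1:6)) {
    stop("octahedron vertex indices must be distinct values in 1..6")
  }
  for (d in donors) {
    if (length(d$vertex) == 2L &&
        ceiling(d$vertex[1L] / 2) == ceiling(d$vertex[2L] / 2)) {
      stop("a bidentate carboxylate needs two adjacent (90 degree) ",
           "octahedron vertices, not an opposite pair")
    }
  }
  structure(list(site = as.numeric(site), donors = donors,
                 spacers = spacers, chi_noise_sigma = chi_noise_sigma,
                 backbone_noise_sigma = backbone_noise_sigma,
                 n_models = as.integer(n_models), seed = as.integer(seed)),
            class = "plant_spec")
}

# rotation taking unit vector a onto unit vector b
align_rotation <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- cross3(a, b)
  s <- vnorm(v)
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular axis
    perp <- if (abs(a[1L]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
    return(rotation_about_axis(perp, 180))
  }
  rotation_about_axis(v, rad2deg(atan2(s, c_)))
}

# orthonormal frame from primary direction x and secondary hint y
make_frame <- function(x, yhint) {
  x <- unitv(x)
  y <- yhint - sum(yhint * x) * x
  y <- unitv(y)
  cbind(x, y, cross3(x, y))
}

donor_anchor <- function(restype, res, denticity) {
  # returns list(target_atoms, local anchor geometry) in residue coords
  xyz <- function(n) as.numeric(res_xyz(res, n))
  if (restype %in% c("ASP", "GLU")) {
    nm <- if (restype == "ASP") c("CG", "OD1", "OD2") else c("CD", "OE1", "OE2")
    C <- xyz(nm[1L]); O1 <- xyz(nm[2L]); O2 <- xyz(nm[3L])
    if (denticity == "M") {
      list(kind = "mono", donor = nm[2L], point = O1, dir = unitv(C - O1))
    } else {
      list(kind = "bi", donor = nm[2:3], O1 = O1, O2 = O2, C = C,
           mid = (O1 + O2) / 2)
    }
  } else if (restype == "HIS") {
    ring <- c("CG", "ND1", "CD2", "CE1", "NE2")
    centroid <- colMeans(res_xyz(res, ring))
    NE2 <- xyz("NE2")
    list(kind = "mono", donor = "NE2", point = NE2,
         dir = unitv(centroid - NE2))
  } else if (restype == "TYR") {
    OH <- xyz("OH"); CZ <- xyz("CZ")
    list(kind = "mono", donor = "OH", point = OH, dir = unitv(CZ - OH))
  } else stop("unsupported donor residue ", restype)
}

transform_res <- function(res, R, shift) {
  xyz <- as.matrix(res[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2L, shift, FUN = "+")
  res$x <- xyz[, 1L]; res$y <- xyz[, 2L]; res$z <- xyz[, 3L]
  res
}

min_interdist <- function(xyz_a, xyz_b) {
  if (!nrow(xyz_a) || !nrow(xyz_b)) return(Inf)
  d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
    2 * tcrossprod(xyz_a, xyz_b)
  sqrt(max(0, min(d2)))
}

#' Build a single peptide model with a planted octahedral site
#'
#' @param spec A [plant_spec()].
#' @return List with `model` (a `peptide_model`) and `truth` (a
#'   `plant_truth`: ground-truth `metal_pos` and the expected `shell`
#'   table of donor atoms with their built distances).
#' @export
build_planted_model <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  site <- spec$site
  V <- octahedron_vertices()
  placed <- list() # residue data frames, donor or spacer, in build order
  placed_xyz <- matrix(numeric(0), 0L, 3L)
  truth_rows <- list()

  pose_donor <- function(plan) {
    rt <- plan$restype
    dent <- if (is.null(plan$denticity)) "M" else plan$denticity
    res <- build_peptide(rt)
    anchor <- donor_anchor(rt, res, dent)
    if (anchor$kind == "mono") {
      u <- V[plan$vertex[1L], ]
      P <- site + PLANT_BOND * u
      R0 <- align_rotation(anchor$dir, u)
      best <- NULL; best_score <- -Inf
      for (roll in seq(0, 345, by = 15)) {
        R <- rotation_about_axis(u, roll) %*% R0
        cand <- transform_res(res, R, P - as.numeric(R %*% anchor$point))
        cxyz <- as.matrix(cand[, c("x", "y", "z")])
        dsite <- sqrt(rowSums(sweep(cxyz, 2L, site)^2))
        dsite <- dsite[cand$atom != anchor$donor]
        score <- min(min(dsite), min_interdist(cxyz, placed_xyz))
        if (score > best_score) { best_score <- score; best <- cand }
      }
      best
    } else {
      va <- V[plan$vertex[1L], ]; vb <- V[plan$vertex[2L], ]
      umid <- unitv(va + vb)
      oo <- vnorm(anchor$O2 - anchor$O1)
      if (oo / 2 >= PLANT_BOND) stop("carboxylate bite too wide to plant")
      dmid <- sqrt(PLANT_BOND^2 - (oo / 2)^2)
      Ftarget <- make_frame(umid, vb - va)
      Flocal <- make_frame(anchor$C - anchor$mid, anchor$O2 - anchor$O1)
      R <- Ftarget %*% t(Flocal)
      M <- site + dmid * umid
      # carboxylate C sits on the far side of the O-O midpoint
      shift <- M - as.numeric(R %*% anchor$mid)
      transform_res(res, R, shift)
    }
  }

  donor_res <- list()
  for (k in seq_along(spec$donors)) {
    plan <- spec$donors[[k]]
    cand <- pose_donor(plan)
    donor_res[[k]] <- cand
    placed_xyz <- rbind(placed_xyz, as.matrix(cand[, c("x", "y", "z")]))
    anchor_names <- if (plan$restype == "ASP") c("OD1", "OD2")
      else if (plan$restype == "GLU") c("OE1", "OE2")
      else if (plan$restype == "HIS") "NE2" else "OH"
    dent <- if (is.null(plan$denticity)) "M" else plan$denticity
    shell_atoms <- if (dent == "B") anchor_names else anchor_names[1L]
    for (a in shell_atoms) {
      p <- as.numeric(res_xyz(cand, a))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        restype = plan$restype, atom = a, denticity = dent,
        distance = vnorm(p - site), stringsAsFactors = FALSE)
    }
  }

  # spacer segments: extended Ala runs routed radially away from the site
  nd <- length(spec$donors)
  spacers <- rep_len(spec$spacers, max(1L, nd - 1L))
  segments <- list()
  if (nd > 1L) {
    for (g in seq_len(nd - 1L)) {
      ns <- spacers[g]
      if (ns < 1L) { segments[[g]] <- NULL; next }
      seg <- build_peptide(rep("ALA", ns))
      sxyz <- as.matrix(seg[, c("x", "y", "z")])
      sxyz <- sweep(sxyz, 2L, colMeans(sxyz))
      ca_a <- colMeans(as.matrix(donor_res[[g]][, c("x", "y", "z")]))
      ca_b <- colMeans(as.matrix(donor_res[[g + 1L]][, c("x", "y", "z")]))
      mid <- (ca_a + ca_b) / 2
      away <- mid - site
      if (vnorm(away) < 1e-6) away <- c(0, 0, 1)
      away <- unitv(away)
      ok <- FALSE
      for (push in seq(8, 20, by = 1)) {
        centre <- site + push * away
        cand <- sweep(sxyz, 2L, centre, FUN = "+")
        if (min_interdist(cand, placed_xyz) >= 2.4 &&
            min(sqrt(rowSums(sweep(cand, 2L, site)^2))) >= 4) {
          seg$x <- cand[, 1L]; seg$y <- cand[, 2L]; seg$z <- cand[, 3L]
          placed_xyz <- rbind(placed_xyz, cand)
          segments[[g]] <- seg
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not route spacer segment ", g,
                    " without steric overlap")
    }
  }

  # assemble: donor 1, spacers 1, donor 2, ...
  pieces <- list(donor_res[[1L]])
  if (nd > 1L) {
    for (g in seq_len(nd - 1L)) {
      if (!is.null(segments[g][[1L]])) pieces <- c(pieces, segments[g])
      pieces <- c(pieces, donor_res[g + 1L])
    }
  }
  resno <- 0L
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    old <- unique(p$resno)
    p$resno <- resno + match(p$resno, old)
    p$piece <- i
    resno <- resno + length(old)
    pieces[[i]] <- p
  }
  atoms <- do.call(rbind, pieces)
  piece_id <- atoms$piece
  atoms$piece <- NULL
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  model <- new_peptide_model(atoms, model_id = 1L)

  # audit: inter-residue heavy-atom separation (no covalent bonds exist
  # between the rigidly placed pieces, so 2.4 A is required throughout)
  xyz <- model_xyz(model)
  rg <- model$atoms$resno
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  # peptide-bonded neighbours exist only within a contiguous spacer piece
  bonded <- outer(piece_id, piece_id, "==") & abs(outer(rg, rg, "-")) <= 1L
  inter <- outer(rg, rg, "!=") & upper.tri(d2) & !bonded
  if (any(d2[inter] < 2.4^2 - 1e-9)) {
    bad <- which(inter & d2 < 2.4^2, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "planted model has steric overlap: %s%d:%s - %s%d:%s at %.2f A",
      model$atoms$resname[bad[1L]], rg[bad[1L]], model$atoms$atom[bad[1L]],
      model$atoms$resname[bad[2L]], rg[bad[2L]], model$atoms$atom[bad[2L]],
      sqrt(d2[bad[1L], bad[2L]])))
  }
  # rebuild truth with final residue numbers
  truth <- do.call(rbind, truth_rows)
  donor_resnos <- vapply(seq_len(nd), function(k) {
    unique(pieces[[which(vapply(pieces, function(p)
      isTRUE(all.equal(p$x[1L], donor_res[[k]]$x[1L])), logical(1L)))[1L]]]$resno)
  }, integer(1L))
  truth$resno <- rep(donor_resnos, times = vapply(seq_len(nd), function(k) {
    dent <- if (is.null(spec$donors[[k]]$denticity)) "M"
      else spec$donors[[k]]$denticity
    if (dent == "B") 2L else 1L
  }, integer(1L)))
  if (any(abs(truth$distance - PLANT_BOND) > 0.05)) {
    stop("internal error: planted shell distances off by more than 0.05 A")
  }
  list(model = model,
       truth = structure(list(metal_pos = site,
                              shell = truth[, c("resno", "restype", "atom",
                                                "denticity", "distance")]),
                         class = "plant_truth"))
}

#' Perturb a model into a synthetic conformational ensemble
#'
#' Each copy receives Gaussian chi-angle noise on every rotatable side
#' chain and a small rigid-body jitter applied per 3-residue segment
#' (translation sd `backbone_sigma` A; rotation about the segment
#' centroid with angular sd of 10 degrees per A of `backbone_sigma`).
#' Rigid segmenting avoids unphysical bond stretching within residues.
#'
#' @param model A `peptide_model`.
#' @param n_models Number of copies (>= 1).
#' @param chi_sigma Chi-angle noise sd, degrees.
#' @param backbone_sigma Segment jitter sd, Angstrom.
#' @param seed Integer RNG seed; the result is reproducible.
#' @return A `peptide_ensemble` of `n_models` perturbed copies.
#' @export
perturb_ensemble <- function(model, n_models, chi_sigma = 0,
                             backbone_sigma = 0, seed = 1L) {
  stopifnot(n_models >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  resnos <- residue_indices(model)
  segs <- split(resnos, ceiling(seq_along(resnos) / 3))
  models <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    atoms <- model$atoms
    if (backbone_sigma > 0) {
      for (sg in segs) {
        sel <- atoms$resno %in% sg
        xyz <- as.matrix(atoms[sel, c("x", "y", "z")])
        centroid <- colMeans(xyz)
        axis <- stats::rnorm(3)
        ang <- stats::rnorm(1L, sd = 10 * backbone_sigma)
        shift <- stats::rnorm(3L, sd = backbone_sigma)
        xyz <- rotate_points(xyz, centroid, axis, ang)
        xyz <- sweep(xyz, 2L, shift, FUN = "+")
        atoms[sel, c("x", "y", "z")] <- xyz
      }
    }
    if (chi_sigma > 0) {
      for (rn in resnos) {
        sel <- atoms$resno == rn
        res <- atoms[sel, , drop = FALSE]
        k <- n_chi(res$resname[1L])
        if (k == 0L) next
        chi <- measure_chi(res) + stats::rnorm(k, sd = chi_sigma)
        atoms[sel, ] <- apply_chi(res, chi)
      }
    }
    models[[m]] <- new_peptide_model(atoms, model_id = m)
  }
  new_ensemble(models, source_id = sprintf("perturbed(seed=%d)", seed))
}

#' Convenience: planted model expanded into a perturbed ensemble
#'
#' @param spec A [plant_spec()]; its noise, `n_models` and `seed` fields
#'   drive [perturb_ensemble()].
#' @return List with `ensemble` and `truth`.
#' @export
build_planted_ensemble <- function(spec) {
  built <- build_planted_model(spec)
  ens <- perturb_ensemble(built$model, spec$n_models,
                          chi_sigma = spec$chi_noise_sigma,
                          backbone_sigma = spec$backbone_noise_sigma,
                          seed = spec$seed)
  list(ensemble = ens, truth = built$truth)
}

#' The canonical amyloid-beta 1-42 sequence
#' @return Single 42-character string.
#' @export
abeta42_sequence <- function() {
  "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"
}

#' Extended-chain model of the amyloid-beta 1-42 peptide
#'
#' Builds the 42-mer in an extended conformation (phi/psi about
#' -140/+135 degrees) from the internal-coordinate templates, side
#' chains at extended chi angles.  Used for donor-census worked examples
#' and as a sequence reference; it is not an experimental conformer.
#'
#' @return A `peptide_model`.
#' @export
abeta_extended_model <- function() {
  one <- strsplit(abeta42_sequence(), "")[[1L]]
  seq3 <- unname(aa_one_to_three()[one])
  atoms <- build_peptide(seq3, phi = -140, psi = 135)
  new_peptide_model(atoms, model_id = 1L)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
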