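# Grid protocol: scan each conformer for loci that could host an
# octahedral Al(III).  A regular lattice covers the model's bounding box;
# a lattice point passes when enough distinct donor-bearing residues have
# their C-alpha within reach (C-alpha, not donor-atom, referencing keeps
# the screen permissive toward side chains the genetic algorithm will
# re-pose later), enough of them are carboxylate residues, and the point
# is not buried inside the van der Waals core of the peptide.  Passing
# points are merged by single-linkage clustering into candidate sites.

#' Grid-protocol parameters
#'
#' @param spacing Lattice spacing, A (default 1.0, so no site can fall
#'   farther than ~0.9 A from a lattice point).
#' @param padding Bounding-box expansion, A (default 4.0).
#' @param calpha_radius C-alpha capture radius, A (default 7.0: a Glu
#'   C-alpha-to-carboxylate-O reach of about 4.9 A plus a 2 A metal-oxygen
#'   bond plus slack).
#' @param min_donor_residues Minimum distinct residues bearing side-chain
#'   donor classes (default 3).
#' @param min_carboxylate_residues Minimum Asp/Glu among them (default 2).
#' @param merge_radius Single-linkage merge distance, A (default 3.0:
#'   the clash floor around a donor cage can carve the passing region
#'   into pockets separated by one rejected lattice plane, which a
#'   2 A radius fails to bridge).
#' @param clash_floor Minimum distance from non-donor heavy atoms
#'   (C, S), A (default 1.5), rejecting points buried in the peptide
#'   core.  N/O atoms are held to the smaller `donor_floor`: a viable
#'   metal point is necessarily within bonding range of oxygens.
#' @param donor_floor Minimum distance from N/O atoms, A (default 0.9:
#'   an Al-O bond of ~1.9 minus the worst-case lattice offset).
#' @param count_phenol Count Tyr phenol toward the donor-residue rule?
#'   Default `FALSE` (phenol coordination requires deprotonation).
#' @param donor_atom_radius Capture radius, A, for the pre-organization
#'   condition: a supporting residue must also have a side-chain donor
#'   atom within this distance of the grid point (default 3.5: the
#'   2.5 A coordination shell plus the worst-case lattice offset).  Set
#'   `use_donor_atoms = FALSE` for the permissive C-alpha-only rule.
#' @param use_donor_atoms Apply the donor-atom condition? Default `TRUE`;
#'   without it the intersection of C-alpha balls is too diffuse to
#'   localize a site to within the genetic algorithm's offset bound.
#' @return A `grid_params` list.
#' @export
grid_params <- function(spacing = 1.0, padding = 4.0, calpha_radius = 7.0,
                        min_donor_residues = 3L,
                        min_carboxylate_residues = 2L,
                        merge_radius = 3.0, clash_floor = 1.5,
                        count_phenol = FALSE, donor_atom_radius = 3.5,
                        use_donor_atoms = TRUE, donor_floor = 0.9) {
  stopifnot(spacing > 0, padding >= 0, calpha_radius > 0,
            min_donor_residues >= 1L, min_carboxylate_residues >= 0L,
            merge_radius > 0, clash_floor >= 0, donor_atom_radius > 0,
            donor_floor >= 0)
  if (spacing > merge_radius) {
    stop("spacing must not exceed merge_radius (adjacent lattice points ",
         "must be mergeable)")
  }
  structure(list(spacing = spacing, padding = padding,
                 calpha_radius = calpha_radius,
                 min_donor_residues = as.integer(min_donor_residues),
                 min_carboxylate_residues = as.integer(min_carboxylate_residues),
                 merge_radius = merge_radius, clash_floor = clash_floor,
                 count_phenol = count_phenol,
                 donor_atom_radius = donor_atom_radius,
                 use_donor_atoms = use_donor_atoms,
                 donor_floor = donor_floor),
            class = "grid_params")
}

#' Build the scan lattice for a model
#'
#' Axis-aligned lattice covering the heavy-atom bounding box expanded by
#' `padding`, ordered lexicographically by (x, y, z).
#'
#' @param model A `peptide_model`.
#' @param params A [grid_params()].
#' @return Matrix (n x 3) of lattice points.
#' @export
build_grid <- function(model, params = grid_params()) {
  stopifnot(inherits(params, "grid_params"))
  xyz <- model_xyz(model)
  lo <- apply(xyz, 2L, min) - params$padding
  hi <- apply(xyz, 2L, max) + params$padding
  ax <- lapply(1:3, function(k) {
    n <- floor((hi[k] - lo[k]) / params$spacing + 1e-9)
    lo[k] + params$spacing * (0:n)
  })
  g <- expand.grid(z = ax[[3L]], y = ax[[2L]], x = ax[[1L]],
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[, c("x", "y", "z")])
}

#' Residues whose C-alpha lies within a radius of a point
#'
#' @param point Numeric 3-vector.
#' @param model A `peptide_model`.
#' @param radius Capture radius, A.
#' @return Data frame (`resno`, `resname`, `ca_dist`) sorted by distance,
#'   ties by residue index.
#' @export
residues_near <- function(point, model, radius) {
  stopifnot(radius > 0)
  ca <- calpha_xyz(model)
  d <- sqrt(rowSums(sweep(ca, 2L, point)^2))
  keep <- which(d <= radius)
  resno <- as.integer(rownames(ca))[keep]
  out <- data.frame(resno = resno,
                    resname = residue_names(model)[match(resno, residue_indices(model))],
                    ca_dist = d[keep])
  out <- out[order(out$ca_dist, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# logical vector over grid points: passes the donor/carboxylate/clash rule
grid_points_pass <- function(points, model, donors, params) {
  np <- nrow(points)
  if (np == 0L) return(logical(0))
  classes <- sidechain_donor_classes()
  if (!params$count_phenol) classes <- setdiff(classes, "PHENOL_O")
  dres <- unique(donors$resno[donors$is_sidechain &
                                donors$donor_class %in% classes])
  if (length(dres) < params$min_donor_residues) return(rep(FALSE, np))
  rn <- residue_names(model)
  ri <- residue_indices(model)
  carb <- dres[rn[match(dres, ri)] %in% c("ASP", "GLU")]
  ca <- calpha_xyz(model)
  ca_d <- ca[match(as.character(dres), rownames(ca)), , drop = FALSE]
  # distances grid x donor-CA
  d2 <- outer(rowSums(points^2), rowSums(ca_d^2), "+") -
    2 * tcrossprod(points, ca_d)
  within <- d2 <= params$calpha_radius^2
  if (params$use_donor_atoms) {
    # pre-organization: the residue's donor atom itself must be in reach
    datoms <- donors[donors$is_sidechain & donors$donor_class %in% classes, ,
                     drop = FALSE]
    dxyz <- as.matrix(datoms[, c("x", "y", "z")])
    dd2 <- outer(rowSums(points^2), rowSums(dxyz^2), "+") -
      2 * tcrossprod(points, dxyz)
    near_atom <- dd2 <= params$donor_atom_radius^2
    atom_res_ok <- vapply(seq_along(dres), function(j) {
      cols <- which(datoms$resno == dres[j])
      if (!length(cols)) return(rep(FALSE, np))
      rowSums(near_atom[, cols, drop = FALSE]) > 0L
    }, logical(np))
    within <- within & matrix(atom_res_ok, nrow = np)
  }
  n_donor <- rowSums(within)
  n_carb <- rowSums(within[, dres %in% carb, drop = FALSE])
  pass <- n_donor >= params$min_donor_residues &
    n_carb >= params$min_carboxylate_residues
  if (any(pass)) {
    xyz <- model_xyz(model)
    is_no_atom <- toupper(model$atoms$element) %in% c("N", "O")
    floors2 <- ifelse(is_no_atom, params$donor_floor, params$clash_floor)^2
    p <- points[pass, , drop = FALSE]
    d2a <- outer(rowSums(p^2), rowSums(xyz^2), "+") - 2 * tcrossprod(p, xyz)
    ok <- apply(sweep(d2a, 2L, floors2, ">="), 1L, all)
    pass[pass] <- ok
  }
  pass
}

#' Detect candidate pre-organized metal sites in one conformer
#'
#' Applies the grid rule to every lattice point and merges passing
#' points into sites by single-linkage clustering at `merge_radius`.
#' Each site's centroid is the mean of its member points; its supporting
#' residues are those satisfying the rule at the member point closest to
#' the centroid, with distances reported from the centroid.
#'
#' @param model A `peptide_model`.
#' @param donors Donor table from [classify_donors()] for the same model.
#' @param params A [grid_params()].
#' @return List of `grid_site` objects (possibly empty), each with
#'   `centroid`, `model_id`, `supporters` (data frame of residue index,
#'   donor classes, C-alpha distance) and `n_points`.
#' @export
detect_sites <- function(model, donors, params = grid_params()) {
  points <- build_grid(model, params)
  pass <- grid_points_pass(points, model, donors, params)
  if (!any(pass)) return(list())
  pts <- points[pass, , drop = FALSE]
  if (nrow(pts) == 1L) {
    cl <- 1L
  } else {
    cl <- stats::cutree(stats::hclust(stats::dist(pts), method = "single"),
                        h = params$merge_radius)
  }
  classes <- sidechain_donor_classes()
  if (!params$count_phenol) classes <- setdiff(classes, "PHENOL_O")
  sites <- lapply(sort(unique(cl)), function(k) {
    member <- pts[cl == k, , drop = FALSE]
    centroid <- colMeans(member)
    medoid <- member[which.min(rowSums(sweep(member, 2L, centroid)^2)), ]
    near <- residues_near(medoid, model, params$calpha_radius)
    sup <- donors[donors$resno %in% near$resno & donors$is_sidechain &
                    donors$donor_class %in% classes, , drop = FALSE]
    if (params$use_donor_atoms && nrow(sup)) {
      dd <- sqrt(rowSums(sweep(as.matrix(sup[, c("x", "y", "z")]),
                               2L, medoid)^2))
      ok_res <- unique(sup$resno[dd <= params$donor_atom_radius])
      sup <- sup[sup$resno %in% ok_res, , drop = FALSE]
    }
    supporters <- do.call(rbind, lapply(split(sup, sup$resno), function(s) {
      data.frame(resno = s$resno[1L], resname = s$resname[1L],
                 classes = paste(sort(unique(s$donor_class)), collapse = "+"),
                 ca_dist = NA_real_)
    }))
    ca <- calpha_xyz(model)
    supporters$ca_dist <-
      sqrt(rowSums(sweep(ca[match(as.character(supporters$resno),
                                  rownames(ca)), , drop = FALSE],
                         2L, centroid)^2))
    supporters <- supporters[order(supporters$resno), , drop = FALSE]
    rownames(supporters) <- NULL
    structure(list(centroid = centroid, model_id = model$model_id,
                   supporters = supporters, n_points = nrow(member)),
              class = "grid_site")
  })
  ord <- order(vapply(sites, function(s) s$centroid[1L], numeric(1L)),
               vapply(sites, function(s) s$centroid[2L], numeric(1L)),
               vapply(sites, function(s) s$centroid[3L], numeric(1L)))
  sites[ord]
}

#' @export
print.grid_site <- function(x, ...) {
  cat(sprintf("<grid_site> model %d centroid (%.2f, %.2f, %.2f), %d point(s), supporters: %s\n",
              x$model_id, x$centroid[1L], x$centroid[2L], x$centroid[3L],
              x$n_points,
              paste0(x$supporters$resname, x$supporters$resno, collapse = ", ")))
  invisible(x)
}

#' Tabulate detected sites
#'
#' @param sites List of `grid_site` objects.
#' @return Data frame with one row per site (model_id, centroid x/y/z,
#'   n_points, semicolon-joined supporter descriptors), ordered by
#'   (model_id, centroid).
#' @export
site_table <- function(sites) {
  if (!length(sites)) {
    return(data.frame(model_id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), n_points = integer(0),
                      supporters = character(0)))
  }
  df <- do.call(rbind, lapply(sites, function(s) {
    data.frame(model_id = s$model_id, x = s$centroid[1L], y = s$centroid[2L],
               z = s$centroid[3L], n_points = s$n_points,
               supporters = paste(sprintf("%d:%s:%.2f", s$supporters$resno,
                                          s$supporters$classes,
                                          s$supporters$ca_dist),
                                  collapse = ";"))
  }))
  df <- df[order(df$model_id, df$x, df$y, df$z), , drop = FALSE]
  rownames(df) <- NULL
  df
}
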