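# Internal-coordinate peptide construction and side-chain chi machinery.
#
# Side-chain geometry beyond CB comes from the packaged template table
# (inst/extdata/residue_templates.csv): one row per atom giving its parent
# chain (p1 bonded, p2, p3), bond length, bond angle and a torsion that is
# either a fixed value or a chi token ("chi1", "chi2+180", ...).  Backbone
# atoms (N, CA, C, O) and CB are placed by the chain builder itself with
# standard peptide geometry.

.alsite_env <- new.env(parent = emptyenv())

backbone_names <- function() c("N", "CA", "C", "O")

aa_three_to_one <- function() {
  c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
    GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
    MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
    TYR = "Y", VAL = "V")
}

aa_one_to_three <- function() {
  m <- aa_three_to_one()
  stats::setNames(names(m), unname(m))
}

residue_templates <- function() {
  if (is.null(.alsite_env$templates)) {
    path <- system.file("extdata", "residue_templates.csv", package = "alsite")
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df <- df[!is.na(df$atom) & nzchar(df$atom), , drop = FALSE]
    .alsite_env$templates <- split(df, df$restype)
  }
  .alsite_env$templates
}

has_template <- function(restype) {
  restype %in% c("ALA", "GLY", names(residue_templates()))
}

# parse a torsion field: returns list(chi = integer or NA, offset = numeric)
parse_torsion <- function(x) {
  m <- regmatches(x, regexec("^chi([0-9])([+-][0-9.]+)?$", x))[[1L]]
  if (length(m)) {
    list(chi = as.integer(m[2L]),
         offset = if (nzchar(m[3L])) as.numeric(m[3L]) else 0)
  } else {
    list(chi = NA_integer_, offset = as.numeric(x))
  }
}

#' Side-chain chi-angle definitions for a residue type
#'
#' Returns, for each rotatable chi angle of the residue type, the four
#' atom names defining the dihedral and the set of atoms that move when
#' it rotates (all template atoms downstream of the axis).
#'
#' @param restype Three-letter residue code (e.g. "ASP").
#' @return A list with one element per chi angle, each a list with
#'   `atoms` (length-4 dihedral definition, proximal to distal) and
#'   `moving` (character vector of atom names displaced by the rotation),
#'   or an empty list for residues without rotatable side chains.
#' @export
chi_definitions <- function(restype) {
  if (restype %in% c("ALA", "GLY")) return(list())
  tpl <- residue_templates()[[restype]]
  if (is.null(tpl)) stop("no side-chain template for residue type ", restype)
  tors <- lapply(tpl$torsion, parse_torsion)
  chis <- vapply(tors, function(t) t$chi, integer(1L))
  kmax <- suppressWarnings(max(chis, na.rm = TRUE))
  if (!is.finite(kmax)) return(list())
  # descendants of an atom within the side-chain tree (children via p1)
  descendants <- function(a) {
    out <- character(0)
    kids <- tpl$atom[tpl$p1 == a]
    for (k in kids) out <- c(out, k, descendants(k))
    out
  }
  defs <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    i <- which(chis == k & vapply(tors, function(t) t$offset == 0, logical(1L)))[1L]
    if (is.na(i)) i <- which(chis == k)[1L]
    row <- tpl[i, ]
    defs[[k]] <- list(
      atoms = c(row$p3, row$p2, row$p1, row$atom),
      axis = c(row$p2, row$p1),
      moving = c(descendants(row$p1))
    )
  }
  defs
}

#' Number of rotatable chi angles for a residue type
#' @param restype Three-letter residue code.
#' @return Integer count (0 for Gly/Ala).
#' @export
n_chi <- function(restype) length(chi_definitions(restype))

# --- residue-level coordinate helpers -------------------------------------

res_xyz <- function(res, names) {
  i <- match(names, res$atom)
  if (anyNA(i)) stop("residue ", res$resname[1L], res$resno[1L],
                     " lacks atom(s): ", paste(names[is.na(i)], collapse = ", "))
  as.matrix(res[i, c("x", "y", "z"), drop = FALSE])
}

#' Measure the side-chain chi angles of a residue
#'
#' @param residue Data frame of one residue's atoms (columns `atom`,
#'   `resname`, `x`, `y`, `z`).
#' @return Numeric vector of chi angles in degrees (possibly length 0).
#' @export
measure_chi <- function(residue) {
  defs <- chi_definitions(residue$resname[1L])
  vapply(defs, function(d) {
    p <- res_xyz(residue, d$atoms)
    dihedral_angle(p[1L, ], p[2L, ], p[3L, ], p[4L, ])
  }, numeric(1L))
}

#' Re-pose a residue's side chain at given chi angles
#'
#' Rotates the atoms distal to each chi bond axis, proximal to distal, so
#' that the measured dihedrals equal `chi`.  Backbone atoms, bond lengths
#' and bond angles are untouched.
#'
#' @param residue Data frame of one residue's atoms.
#' @param chi Numeric vector of target chi angles in degrees; its length
#'   must equal [n_chi()] of the residue type.
#' @return The residue data frame with updated coordinates.
#' @export
apply_chi <- function(residue, chi) {
  defs <- chi_definitions(residue$resname[1L])
  if (length(chi) != length(defs)) {
    stop("residue ", residue$resname[1L], " has ", length(defs),
         " chi angle(s), got ", length(chi))
  }
  if (!length(defs)) return(residue)
  xyz <- as.matrix(residue[, c("x", "y", "z")])
  rownames(xyz) <- residue$atom
  for (k in seq_along(defs)) {
    d <- defs[[k]]
    cur <- dihedral_angle(xyz[d$atoms[1L], ], xyz[d$atoms[2L], ],
                          xyz[d$atoms[3L], ], xyz[d$atoms[4L], ])
    delta <- wrap_angle(chi[k] - cur)
    if (abs(delta) < 1e-12) next
    mov <- intersect(d$moving, rownames(xyz))
    origin <- xyz[d$axis[2L], ]
    axis <- xyz[d$axis[1L], ] - origin
    xyz[mov, ] <- rotate_points(xyz[mov, , drop = FALSE], origin, axis, delta)
  }
  residue$x <- xyz[, 1L]; residue$y <- xyz[, 2L]; residue$z <- xyz[, 3L]
  residue
}

element_of <- function(atom_name) {
  # first alphabetic character block; peptide heavy atoms are single-letter
  # elements except when a name starts with a digit (none in our templates)
  substr(gsub("[^A-Z]", "", toupper(atom_name)), 1L, 1L)
}

# Build a linear peptide from 3-letter codes with given backbone torsions.
# phi/psi may be scalars (recycled) or per-residue vectors; chi is a list
# of per-residue chi vectors (NULL entries = default extended angles).
build_peptide <- function(seq3, phi = -140, psi = 135, omega = 180,
                          chi = NULL) {
  nres <- length(seq3)
  stopifnot(nres >= 1L)
  bad <- seq3[!vapply(seq3, has_template, logical(1L))]
  if (length(bad)) stop("no residue template for: ", paste(unique(bad), collapse = ", "))
  phi <- rep_len(phi, nres); psi <- rep_len(psi, nres)
  omega <- rep_len(omega, nres)
  tpls <- residue_templates()
  rows <- list()
  prev <- NULL # list(N, CA, C)
  for (i in seq_len(nres)) {
    rt <- seq3[i]
    if (is.null(prev)) {
      N <- c(0, 0, 0)
      CA <- c(1.458, 0, 0)
      C <- place_atom_nerf(CA, N, c(0, 1, 0), 1.525, 111.2, phi[i] + 60)
      # phi of residue 1 is undefined (no preceding C); orientation arbitrary
    } else {
      N <- place_atom_nerf(prev$C, prev$CA, prev$N, 1.329, 116.2, psi[i - 1L])
      CA <- place_atom_nerf(N, prev$C, prev$CA, 1.458, 121.7, omega[i])
      C <- place_atom_nerf(CA, N, prev$C, 1.525, 111.2, phi[i])
    }
    O <- place_atom_nerf(C, CA, N, 1.231, 120.5, psi[i] + 180)
    coords <- rbind(N = N, CA = CA, C = C, O = O)
    if (rt != "GLY") {
      CB <- place_atom_nerf(CA, C, N, 1.530, 110.4, -122.6)
      coords <- rbind(coords, CB = CB)
      tpl <- tpls[[rt]]
      if (!is.null(tpl)) {
        for (j in seq_len(nrow(tpl))) {
          row <- tpl[j, ]
          tor <- parse_torsion(row$torsion)
          tval <- if (is.na(tor$chi)) tor$offset else wrap_angle(180 + tor$offset)
          pos <- place_atom_nerf(coords[row$p1, ], coords[row$p2, ],
                                 coords[row$p3, ], row$bond, row$angle, tval)
          coords <- rbind(coords, pos)
          rownames(coords)[nrow(coords)] <- row$atom
        }
      }
    }
    rows[[i]] <- data.frame(
      atom = rownames(coords), resname = rt, resno = i,
      x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
      stringsAsFactors = FALSE, row.names = NULL
    )
    prev <- list(N = N, CA = CA, C = C)
  }
  atoms <- do.call(rbind, rows)
  atoms$element <- element_of(atoms$atom)
  atoms$is_backbone <- atoms$atom %in% backbone_names()
  atoms$serial <- seq_len(nrow(atoms))
  if (!is.null(chi)) {
    for (i in seq_len(nres)) {
      if (is.null(chi[[i]])) next
      sel <- atoms$resno == i
      atoms[sel, ] <- apply_chi(atoms[sel, , drop = FALSE], chi[[i]])
    }
  }
  atoms[, c("serial", "atom", "resname", "resno", "element",
            "is_backbone", "x", "y", "z")]
}
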