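# Donor taxonomy and coordination bookkeeping for hard-acid Al(III).
#
# Six donor classes mirror the ligand building blocks used for the
# quantum cluster models: C carboxylate (Asp/Glu), T phenol (Tyr),
# A backbone carbonyl, W water, H imidazole (His), N N-terminal amine.
# Ser/Thr hydroxyls are deliberately not donors.  Tyr phenol is kept in
# the taxonomy but flagged as requiring deprotonation; the site scan and
# the genetic algorithm exclude it from coordination counts by default.

donor_classes <- function() {
  c("CARBOXYLATE_O", "PHENOL_O", "CARBONYL_O", "WATER_O",
    "IMIDAZOLE_N", "NTERM_N")
}

sidechain_donor_classes <- function() {
  c("CARBOXYLATE_O", "IMIDAZOLE_N", "PHENOL_O", "NTERM_N")
}

#' Classify the metal-donor atoms of a peptide model
#'
#' Every Asp/Glu contributes its two carboxylate oxygens, every residue
#' its backbone carbonyl oxygen, Tyr its phenol oxygen (flagged as
#' requiring deprotonation), His both imidazole nitrogens and residue 1
#' its N-terminal amine nitrogen.
#'
#' @param model A `peptide_model`.
#' @return Data frame ordered by (residue index, atom name) with columns
#'   `resno`, `resname`, `atom`, `donor_class`, `is_sidechain`,
#'   `requires_deprotonation`, `formal_charge`, `x`, `y`, `z`.
#' @export
classify_donors <- function(model) {
  a <- model$atoms
  first_res <- min(a$resno)
  rows <- list()
  add <- function(sel, class, sidechain, deprot = FALSE, charge = 0L) {
    if (!any(sel)) return()
    d <- a[sel, c("resno", "resname", "atom", "x", "y", "z"), drop = FALSE]
    d$donor_class <- class
    d$is_sidechain <- sidechain
    d$requires_deprotonation <- deprot
    d$formal_charge <- charge
    rows[[length(rows) + 1L]] <<- d
  }
  add(a$resname %in% c("ASP") & a$atom %in% c("OD1", "OD2"),
      "CARBOXYLATE_O", TRUE, charge = -1L)
  add(a$resname %in% c("GLU") & a$atom %in% c("OE1", "OE2"),
      "CARBOXYLATE_O", TRUE, charge = -1L)
  add(a$resname == "TYR" & a$atom == "OH", "PHENOL_O", TRUE,
      deprot = TRUE, charge = -1L)
  add(a$atom == "O" & a$is_backbone, "CARBONYL_O", FALSE)
  add(a$resname == "HIS" & a$atom %in% c("ND1", "NE2"), "IMIDAZOLE_N", TRUE)
  add(a$resno == first_res & a$atom == "N", "NTERM_N", TRUE)
  if (!length(rows)) {
    return(data.frame(resno = integer(0), resname = character(0),
                      atom = character(0), donor_class = character(0),
                      is_sidechain = logical(0),
                      requires_deprotonation = logical(0),
                      formal_charge = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$resno, out$atom), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("resno", "resname", "atom", "donor_class", "is_sidechain",
          "requires_deprotonation", "formal_charge", "x", "y", "z")]
}

#' Construct a first-shell ligand motif
#'
#' @param C,T,A,W,H,N Counts of carboxylate, phenol, carbonyl, water,
#'   imidazole and N-terminal ligands.
#' @param denticity Character vector of length `C` with entries "M"
#'   (monodentate) or "B" (bidentate); a bidentate carboxylate counts
#'   twice toward the coordination number.
#' @return A `ligand_motif` list with the counts, denticity and derived
#'   `coordination_number`.
#' @export
ligand_motif <- function(C = 0L, T = 0L, A = 0L, W = 0L, H = 0L, N = 0L,
                         denticity = rep("M", C)) {
  counts <- c(C = C, T = T, A = A, W = W, H = H, N = N)
  if (any(counts < 0)) stop("ligand counts must be non-negative")
  if (length(denticity) != C) stop("need one denticity entry per carboxylate")
  if (!all(denticity %in% c("M", "B"))) stop("denticity entries must be 'M' or 'B'")
  cn <- sum(denticity == "M") + 2L * sum(denticity == "B") +
    sum(counts[c("T", "A", "W", "H", "N")])
  structure(list(counts = counts, denticity = denticity,
                 coordination_number = as.integer(cn)),
            class = "ligand_motif")
}

#' Is a ligand motif admissible under the cluster-model rules?
#'
#' Admissible motifs have at least two carboxylate groups, at least two
#' non-water ligands, and a coordination number of 4, 5 or 6.
#'
#' @param motif A `ligand_motif`.
#' @return Logical scalar with attribute `reason` explaining a rejection
#'   (or "ok").
#' @export
motif_is_admissible <- function(motif) {
  stopifnot(inherits(motif, "ligand_motif"))
  k <- motif$counts
  non_water <- sum(k) - k[["W"]]
  reason <- "ok"
  ok <- TRUE
  if (k[["C"]] < 2L) {
    ok <- FALSE; reason <- "fewer than two carboxylate groups"
  } else if (non_water < 2L) {
    ok <- FALSE; reason <- "fewer than two non-water ligands"
  } else if (!(motif$coordination_number %in% 4:6)) {
    ok <- FALSE
    reason <- sprintf("coordination number %d outside {4,5,6}",
                      motif$coordination_number)
  }
  structure(ok, reason = reason)
}

#' Complexation-reaction stoichiometry and charge bookkeeping
#'
#' Describes the displacement reaction in which `m` ligands that are
#' already ionized in solution (total charge `p`) and `n` ligands that
#' ionize upon complexation (total in-complex charge `q`) replace
#' `m + n` waters of the hexaaqua Al(III) reference.
#'
#' @param m,n Ligand counts (non-negative integers).
#' @param p,q Total charges of the two ligand sets.
#' @return A `reaction_spec` list; `waters_displaced` is always `m + n`.
#' @export
reaction_spec <- function(m = 0L, n = 0L, p = 0L, q = 0L) {
  stopifnot(m >= 0, n >= 0)
  structure(list(m = as.integer(m), n = as.integer(n),
                 p = as.integer(p), q = as.integer(q),
                 waters_displaced = as.integer(m + n)),
            class = "reaction_spec")
}

#' Reaction stoichiometry implied by a ligand motif
#'
#' Carboxylates are anionic in solution (non-ionized upon complexation,
#' -1 each); phenols are neutral in solution and deprotonate upon
#' complexation (-1 each in the complex); carbonyl, imidazole and
#' N-terminal ligands are neutral; water ligands remain part of the aqua
#' shell and displace nothing.
#'
#' @param motif A `ligand_motif`.
#' @return A `reaction_spec`.
#' @export
reaction_spec_for_motif <- function(motif) {
  stopifnot(inherits(motif, "ligand_motif"))
  k <- motif$counts
  reaction_spec(m = k[["C"]] + k[["A"]] + k[["H"]] + k[["N"]],
                n = k[["T"]],
                p = -k[["C"]],
                q = -k[["T"]])
}

#' Total charge of an Al(III) complex
#'
#' The Al(III) cation charge plus the solution charge of the
#' non-ionizing ligands plus the in-complex charge of the ionizing ones.
#'
#' @param spec A `reaction_spec`.
#' @return Integer complex charge `3 + p + q`.
#' @export
complex_charge <- function(spec) {
  stopifnot(inherits(spec, "reaction_spec"))
  3L + spec$p + spec$q
}

# parse a reference-table motif label like "4CWA" / "3C2WH" into counts,
# combined with the carboxylate pattern field ("3M1B" etc.)
motif_from_label <- function(label, carb) {
  toks <- regmatches(label, gregexpr("([0-9]*)([CTAWHN])", label))[[1L]]
  counts <- c(C = 0L, T = 0L, A = 0L, W = 0L, H = 0L, N = 0L)
  for (t in toks) {
    m <- regexec("([0-9]*)([CTAWHN])", t)[[1L]]
    parts <- regmatches(t, list(m))[[1L]]
    k <- if (nzchar(parts[2L])) as.integer(parts[2L]) else 1L
    counts[parts[3L]] <- counts[parts[3L]] + k
  }
  dent <- character(0)
  for (t in regmatches(carb, gregexpr("[0-9]+[MB]", carb))[[1L]]) {
    k <- as.integer(sub("[MB]", "", t))
    dent <- c(dent, rep(sub("[0-9]+", "", t), k))
  }
  ligand_motif(C = counts[["C"]], T = counts[["T"]], A = counts[["A"]],
               W = counts[["W"]], H = counts[["H"]], N = counts[["N"]],
               denticity = dent)
}
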