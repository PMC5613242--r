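# From a surviving GA solution to a chemically annotated complex model:
# carboxylate denticity assignment, exact octahedron fitting, water
# completion to the target coordination number and first-shell summary.

new_complex_model <- function(peptide, metal_pos, waters = NULL,
                              first_shell = NULL, cutoff = 2.5) {
  stopifnot(inherits(peptide, "peptide_model"), length(metal_pos) == 3L)
  if (inherits(first_shell, "shell_assignment") &&
      nrow(first_shell$shell) &&
      any(first_shell$shell$distance_A > cutoff + 1e-6)) {
    stop("first-shell distances exceed the coordination cutoff")
  }
  structure(list(peptide = peptide, metal_pos = as.numeric(metal_pos),
                 metal_element = "AL",
                 waters = if (is.null(waters)) matrix(numeric(0), 0L, 3L)
                          else rbind(waters),
                 first_shell = first_shell, cutoff = cutoff),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  ns <- if (is.null(x$first_shell)) 0L else nrow(x$first_shell)
  cat(sprintf("<complex_model> Al at (%.2f, %.2f, %.2f): %d peptide donor(s), %d water(s)\n",
              x$metal_pos[1L], x$metal_pos[2L], x$metal_pos[3L], ns,
              nrow(x$waters)))
  invisible(x)
}

#' Assign carboxylate denticity for a posed first shell
#'
#' Every Asp/Glu with at least one carboxylate oxygen within `cutoff` of
#' the metal is labelled B (bidentate) if both oxygens are within the
#' cutoff and M (monodentate) otherwise; non-carboxylate donors within
#' the cutoff are listed individually with denticity "-".  Relabelling
#' an already-assigned shell is idempotent.
#'
#' @param metal Numeric 3-vector, metal position.
#' @param donors Donor table from [classify_donors()] on the posed model.
#' @param cutoff First-shell capture radius, A (default 2.5).
#' @param include_phenol Count Tyr phenol oxygens? Default `FALSE`.
#' @return A `shell_assignment`: list with `shell` (data frame resno,
#'   resname, atom, donor_class, distance_A, denticity, sorted by
#'   distance) and `coordination_number` (a B carboxylate contributes 2).
#' @export
assign_denticity <- function(metal, donors, cutoff = 2.5,
                             include_phenol = FALSE) {
  stopifnot(cutoff > 0)
  d <- donors
  if (!include_phenol) d <- d[d$donor_class != "PHENOL_O", , drop = FALSE]
  dist <- sqrt((d$x - metal[1L])^2 + (d$y - metal[2L])^2 +
                 (d$z - metal[3L])^2)
  d$distance_A <- dist
  within <- d[dist <= cutoff, , drop = FALSE]
  rows <- list()
  for (rn in unique(within$resno)) {
    sub <- within[within$resno == rn, , drop = FALSE]
    carb <- sub[sub$donor_class == "CARBOXYLATE_O", , drop = FALSE]
    if (nrow(carb)) {
      dent <- if (nrow(carb) == 2L) "B" else "M"
      carb$denticity <- dent
      rows[[length(rows) + 1L]] <- carb
    }
    oth <- sub[sub$donor_class != "CARBOXYLATE_O", , drop = FALSE]
    if (nrow(oth)) {
      oth$denticity <- "-"
      rows[[length(rows) + 1L]] <- oth
    }
  }
  shell <- if (length(rows)) {
    out <- do.call(rbind, rows)
    out <- out[order(out$distance_A, out$resno, out$atom), , drop = FALSE]
    rownames(out) <- NULL
    out[, c("resno", "resname", "atom", "donor_class", "distance_A",
            "denticity")]
  } else {
    data.frame(resno = integer(0), resname = character(0),
               atom = character(0), donor_class = character(0),
               distance_A = numeric(0), denticity = character(0))
  }
  structure(list(shell = shell, coordination_number = nrow(shell),
                 cutoff = cutoff),
            class = "shell_assignment")
}

# all ordered arrangements of k items out of 1..6 (k <= 6)
vertex_arrangements <- function(k) {
  perm_rec <- function(avail, k) {
    if (k == 0L) return(list(integer(0)))
    out <- list()
    for (i in seq_along(avail)) {
      for (rest in perm_rec(avail[-i], k - 1L)) {
        out[[length(out) + 1L]] <- c(avail[i], rest)
      }
    }
    out
  }
  perm_rec(1:6, k)
}

# best rotation of the ideal octahedron onto unit shell directions:
# exhaustive assignment over ordered vertex subsets + Kabsch fit each
fit_octahedron <- function(directions) {
  k <- nrow(directions)
  stopifnot(k >= 1L, k <= 6L)
  V <- octahedron_vertices()
  best <- NULL
  best_rss <- Inf
  for (asg in vertex_arrangements(k)) {
    P <- V[asg, , drop = FALSE]
    R <- kabsch_rotation(P, directions)
    rss <- sum((directions - P %*% t(R))^2)
    if (rss < best_rss - 1e-12) {
      best_rss <- rss
      best <- list(assignment = asg, rotation = R, rss = rss)
    }
  }
  best$vacant <- setdiff(1:6, best$assignment)
  best
}

#' Complete a complex to the target coordination number with waters
#'
#' Fits the ideal octahedron to the existing shell directions
#' (exhaustive vertex assignment, one Kabsch rotation per assignment --
#' exact for up to six donors), then places a water oxygen at each
#' vacant vertex at `bond` from the metal.  A vertex is skipped when its
#' water would overlap peptide atoms outside the coordination set.
#' Peptide donors are never removed; a shell already at or above the
#' target is returned unchanged (with a warning if above).
#'
#' @param complex A `complex_model` whose `first_shell` is assigned.
#' @param target_cn Target coordination number (default 6).
#' @param bond Al-water bond length, A (default 1.95, the midpoint of
#'   the 1.81-2.01 A range of refined first-shell distances).
#' @return The `complex_model` with `waters` filled in.
#' @export
complete_with_waters <- function(complex, target_cn = 6L, bond = 1.95) {
  stopifnot(inherits(complex, "complex_model"))
  shell <- complex$first_shell$shell
  cn <- nrow(shell)
  if (cn >= target_cn) {
    if (cn > target_cn) {
      warning("coordination number ", cn, " already exceeds target ",
              target_cn, "; no waters added")
    }
    complex$waters <- matrix(numeric(0), 0L, 3L)
    return(complex)
  }
  metal <- complex$metal_pos
  atoms <- complex$peptide$atoms
  if (cn == 0L) {
    # nothing to orient against: any octahedron orientation serves
    fit <- list(rotation = diag(3), vacant = 1:6)
    V <- octahedron_vertices()
    waters <- lapply(seq_len(target_cn), function(v) {
      metal + bond * as.numeric(V[v, , drop = FALSE])
    })
    complex$waters <- do.call(rbind, waters)
    return(complex)
  }
  sxyz <- t(vapply(seq_len(cn), function(i) {
    as.numeric(res_xyz(atoms[atoms$resno == shell$resno[i], , drop = FALSE],
                       shell$atom[i]))
  }, numeric(3L)))
  dirs <- sweep(sxyz, 2L, metal)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  fit <- fit_octahedron(dirs)
  V <- octahedron_vertices()
  # clash context: peptide atoms outside the coordination set (shell
  # atoms and their bonded parents, e.g. the carboxylate carbon, are
  # part of the metal's bonded framework)
  coord_key <- unlist(lapply(seq_len(cn), function(i) {
    rn <- shell$resno[i]
    res <- atoms[atoms$resno == rn, , drop = FALSE]
    g <- residue_graph_dist(res$resname[1L], res$atom)
    near <- res$atom[g[match(shell$atom[i], res$atom), ] <= 2]
    paste(rn, near)
  }))
  ctx_keep <- !(paste(atoms$resno, atoms$atom) %in% coord_key)
  ctx_xyz <- as.matrix(atoms[ctx_keep, c("x", "y", "z")])
  ctx_el <- atoms$element[ctx_keep]
  waters <- list()
  for (v in fit$vacant) {
    if (length(waters) + cn >= target_cn) break
    w <- metal + bond * as.numeric(V[v, , drop = FALSE] %*% t(fit$rotation))
    if (clash_volume(w, ctx_xyz, "O", ctx_el) > 0) next
    waters[[length(waters) + 1L]] <- w
  }
  complex$waters <- if (length(waters)) do.call(rbind, waters)
                    else matrix(numeric(0), 0L, 3L)
  complex
}

#' Summarize the first coordination shell of a complex
#'
#' @param complex A `complex_model`.
#' @return List with `shell` (one row per shell atom and per water:
#'   residue, resname, atom, distance_A to 2 decimals, denticity, sorted
#'   by distance), `coordination_number` (peptide donors + waters) and
#'   `n_waters`.
#' @export
first_shell_summary <- function(complex) {
  stopifnot(inherits(complex, "complex_model"))
  shell <- complex$first_shell$shell
  rows <- data.frame(residue = shell$resno, resname = shell$resname,
                     atom = shell$atom,
                     distance_A = round(shell$distance_A, 2L),
                     denticity = shell$denticity,
                     stringsAsFactors = FALSE)
  if (nrow(complex$waters)) {
    wd <- sqrt(rowSums(sweep(complex$waters, 2L, complex$metal_pos)^2))
    rows <- rbind(rows, data.frame(residue = NA_integer_, resname = "HOH",
                                   atom = "O", distance_A = round(wd, 2L),
                                   denticity = "-"))
  }
  rows <- rows[order(rows$distance_A, rows$residue), , drop = FALSE]
  rownames(rows) <- NULL
  list(shell = rows,
       coordination_number = nrow(rows),
       n_waters = nrow(complex$waters))
}

#' Build a water-completed complex model from a GA solution
#'
#' Re-poses the side chains, assigns denticity at the solution's metal
#' position and completes the shell to the target coordination number
#' with explicit waters.
#'
#' @param solution A `moga_solution` surviving [filter_solutions()].
#' @param site The `grid_site` it was evolved at.
#' @param model The source `peptide_model`.
#' @param donors Donor table from [classify_donors()] on `model`.
#' @param params The [moga_params()] used.
#' @param target_cn,water_bond Passed to [complete_with_waters()].
#' @return A `complex_model`.
#' @export
build_complex <- function(solution, site, model, donors,
                          params = moga_params(), target_cn = 6L,
                          water_bond = 1.95) {
  posed <- pose_solution(solution, site, model, donors, params)
  pd <- classify_donors(posed$model)
  assignment <- assign_denticity(posed$metal_pos, pd,
                                 cutoff = params$coordination_cutoff)
  cx <- new_complex_model(posed$model, posed$metal_pos,
                          first_shell = assignment,
                          cutoff = params$coordination_cutoff)
  complete_with_waters(cx, target_cn = target_cn, bond = water_bond)
}
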