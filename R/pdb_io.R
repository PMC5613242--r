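# Multi-model PDB ingestion and the hierarchical structure data model.
#
# A `peptide_model` is a list(model_id, atoms, hetero) where `atoms` is a
# data frame with one row per heavy atom (serial, atom, resname, resno,
# element, is_backbone, x, y, z) and `hetero` holds HETATM records kept
# under the ingestion policy (the Al cation and, on request, waters).
# A `peptide_ensemble` is a list(source_id, models).
#
# Ingestion policy: hydrogens are stripped, only altloc ' '/'A' is kept,
# only the first chain is read (multi-chain files warn), residue numbering
# is taken from the file (1-based amyloid-beta convention).

new_peptide_model <- function(atoms, model_id = 1L, hetero = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  if (is.unsorted(atoms$resno)) stop("residue indices must be non-decreasing")
  structure(list(model_id = as.integer(model_id), atoms = atoms,
                 hetero = hetero), class = "peptide_model")
}

new_ensemble <- function(models, source_id = "") {
  stopifnot(length(models) >= 1L)
  seqs <- vapply(models, function(m) paste(residue_names(m), collapse = "-"),
                 character(1L))
  if (length(unique(seqs)) != 1L) {
    stop("ensemble-consistency error: models do not share an identical ",
         "residue sequence")
  }
  structure(list(source_id = source_id, models = models),
            class = "peptide_ensemble")
}

#' @export
print.peptide_model <- function(x, ...) {
  cat("<peptide_model> model", x$model_id, ":",
      length(unique(x$atoms$resno)), "residues,",
      nrow(x$atoms), "heavy atoms\n")
  invisible(x)
}

#' @export
print.peptide_ensemble <- function(x, ...) {
  cat("<peptide_ensemble>", if (nzchar(x$source_id)) x$source_id else "",
      length(x$models), "model(s),",
      length(unique(x$models[[1L]]$atoms$resno)), "residues\n")
  invisible(x)
}

# one resname per residue, in residue order
residue_names <- function(model) {
  a <- model$atoms
  a$resname[!duplicated(a$resno)]
}

residue_indices <- function(model) unique(model$atoms$resno)

get_residue <- function(model, resno) {
  model$atoms[model$atoms$resno == resno, , drop = FALSE]
}

model_xyz <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

calpha_xyz <- function(model) {
  ca <- model$atoms[model$atoms$atom == "CA", , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resno
  m
}

parse_pdb_float <- function(txt, field, lineno) {
  v <- suppressWarnings(as.numeric(txt))
  if (anyNA(v) || any(!is.finite(v))) {
    stop("malformed ATOM record at line ", lineno, ": bad ", field,
         " field '", trimws(txt), "'")
  }
  v
}

#' Read a (multi-model) PDB file into a peptide ensemble
#'
#' Parses MODEL/ENDMDL blocks (a file without MODEL records yields a
#' single model with id 1).  Hydrogens are stripped, alternate locations
#' other than ' '/'A' are dropped, and only the first chain is read (a
#' warning is raised for multi-chain files).  HETATM records are kept on
#' each model's `hetero` table: the Al cation always, waters (residue
#' HOH) only when `keep_waters = TRUE`.
#'
#' @param path Path to a PDB file.
#' @param keep_waters Keep HETATM water oxygens? Default `FALSE`.
#' @return A `peptide_ensemble` with one `peptide_model` per MODEL block.
#' @export
read_pdb_ensemble <- function(path, keep_waters = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  model_no <- 0L
  in_model <- FALSE
  models <- list()
  cur <- list(); cur_het <- list()
  flush_model <- function(cur, cur_het, id) {
    if (!length(cur)) return(NULL)
    atoms <- do.call(rbind, cur)
    chains <- unique(atoms$chain)
    if (length(chains) > 1L) {
      warning("multiple chains found; keeping only chain '", chains[1L], "'")
      atoms <- atoms[atoms$chain == chains[1L], , drop = FALSE]
    }
    keep <- atoms$element != "H" & atoms$altloc %in% c(" ", "", "A")
    atoms <- atoms[keep, , drop = FALSE]
    for (rn in unique(atoms$resno)) {
      an <- atoms$atom[atoms$resno == rn]
      if (anyDuplicated(an)) {
        stop("duplicate atom name(s) in residue ", rn, ": ",
             paste(unique(an[duplicated(an)]), collapse = ", "))
      }
    }
    het <- if (length(cur_het)) do.call(rbind, cur_het) else NULL
    atoms$is_backbone <- atoms$atom %in% backbone_names()
    atoms$serial <- seq_len(nrow(atoms))
    new_peptide_model(atoms[, c("serial", "atom", "resname", "resno",
                                "element", "is_backbone", "x", "y", "z")],
                      model_id = id, hetero = het)
  }
  parse_line <- function(ln, i) {
    if (nchar(ln) < 54L) {
      stop("malformed ATOM record at line ", i, ": line too short")
    }
    name <- trimws(substr(ln, 13L, 16L))
    el <- trimws(substr(ln, 77L, 78L))
    if (!nzchar(el)) el <- element_of(name)
    data.frame(
      atom = name,
      altloc = substr(ln, 17L, 17L),
      resname = trimws(substr(ln, 18L, 20L)),
      chain = substr(ln, 22L, 22L),
      resno = as.integer(parse_pdb_float(substr(ln, 23L, 26L), "resSeq", i)),
      element = toupper(el),
      x = parse_pdb_float(substr(ln, 31L, 38L), "x", i),
      y = parse_pdb_float(substr(ln, 39L, 46L), "y", i),
      z = parse_pdb_float(substr(ln, 47L, 54L), "z", i),
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      in_model <- TRUE
      cur <- list(); cur_het <- list()
    } else if (r == "ENDMDL") {
      model_no <- model_no + 1L
      m <- flush_model(cur, cur_het, model_no)
      if (!is.null(m)) models[[length(models) + 1L]] <- m
      cur <- list(); cur_het <- list()
      in_model <- FALSE
    } else if (r == "ATOM  ") {
      cur[[length(cur) + 1L]] <- parse_line(lines[i], i)
    } else if (r == "HETATM") {
      h <- parse_line(lines[i], i)
      if (h$element == "H") next
      if (h$resname == "HOH" && !keep_waters) next
      cur_het[[length(cur_het) + 1L]] <- h
    }
  }
  if (length(cur)) { # implicit single model (no MODEL/ENDMDL records)
    m <- flush_model(cur, cur_het, model_no + 1L)
    if (!is.null(m)) models[[length(models) + 1L]] <- m
  }
  if (!length(models)) stop("no ATOM records found in ", path)
  new_ensemble(models, source_id = basename(path))
}

fmt_pdb_atom <- function(record, serial, name, resname, chain, resno,
                         x, y, z, element) {
  # atom names shorter than 4 characters start in column 14
  name_f <- if (nchar(name) >= 4L) substr(name, 1L, 4L) else
    sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_f, resname, chain, resno, x, y, z,
          1.00, 0.00, element)
}

model_pdb_lines <- function(model, serial0 = 0L) {
  a <- model$atoms
  vapply(seq_len(nrow(a)), function(i) {
    fmt_pdb_atom("ATOM", serial0 + i, a$atom[i], a$resname[i], "A",
                 a$resno[i], a$x[i], a$y[i], a$z[i], a$element[i])
  }, character(1L))
}

#' Write a peptide ensemble as a multi-model PDB file
#'
#' @param ensemble A `peptide_ensemble`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in ensemble$models) {
    writeLines(sprintf("MODEL     %4d", m$model_id), con)
    writeLines(model_pdb_lines(m), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write an Al(III)-peptide complex model as a single-model PDB file
#'
#' Emits the peptide ATOM records followed by one HETATM AL record for
#' the cation (residue name AL) and one HETATM oxygen per completing
#' water (residue name HOH).  The file round-trips through
#' [read_pdb_ensemble()] with coordinates equal to three decimals.
#'
#' @param complex A `complex_model` (see [build_complex()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_complex_pdb <- function(complex, path) {
  stopifnot(inherits(complex, "complex_model"))
  lines <- model_pdb_lines(complex$peptide)
  n <- nrow(complex$peptide$atoms)
  resmax <- max(complex$peptide$atoms$resno)
  mp <- complex$metal_pos
  lines <- c(lines, "TER",
             fmt_pdb_atom("HETATM", n + 1L, "AL", "AL", "A", resmax + 1L,
                          mp[1L], mp[2L], mp[3L], "AL"))
  if (!is.null(complex$waters) && nrow(rbind(complex$waters)) > 0L) {
    w <- rbind(complex$waters)
    for (i in seq_len(nrow(w))) {
      lines <- c(lines,
                 fmt_pdb_atom("HETATM", n + 1L + i, "O", "HOH", "A",
                              resmax + 1L + i, w[i, 1L], w[i, 2L], w[i, 3L], "O"))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' One-letter sequence of a peptide model
#'
#' @param model A `peptide_model`.
#' @return Single string, one character per residue (standard 3-to-1
#'   mapping).  Nonstandard residue names raise an error naming them.
#' @export
sequence_of <- function(model) {
  rn <- residue_names(model)
  map <- aa_three_to_one()
  one <- map[rn]
  if (anyNA(one)) {
    stop("unknown residue name(s): ", paste(unique(rn[is.na(one)]), collapse = ", "))
  }
  paste(one, collapse = "")
}

#' Export first-shell descriptors to CSV
#'
#' @param summary A first-shell summary (see [first_shell_summary()]).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_shell_csv <- function(summary, path) {
  df <- summary$shell[, c("residue", "atom", "distance_A", "denticity")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
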