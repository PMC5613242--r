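# End-to-end orchestration: scan -> evolve -> filter -> build, with a
# machine-readable run manifest.  The configuration is a flat key=value
# file; every key maps to a documented grid_params()/moga_params() field
# or a pipeline-level setting.

#' Read a flat key-value run configuration
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored.  Keys prefixed `grid.` and `moga.` set [grid_params()] and
#' [moga_params()] fields; pipeline keys are `pdb`, `out_dir`, `seed`,
#' `keep_top` (survivors built per site, default 3), `target_cn` and
#' `water_bond`.
#'
#' @param path Path to the configuration file.
#' @return Named list of character values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1L)) != 3L]
  if (length(bad)) stop("malformed config line(s): ", paste(bad, collapse = "; "))
  stats::setNames(lapply(kv, function(m) trimws(m[3L])),
                  vapply(kv, function(m) trimws(m[2L]), character(1L)))
}

config_params <- function(config, prefix, constructor) {
  keys <- grep(paste0("^", prefix, "\\."), names(config), value = TRUE)
  args <- lapply(config[keys], function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else identical(tolower(v), "true")
  })
  names(args) <- sub(paste0("^", prefix, "\\."), "", keys)
  unknown <- setdiff(names(args), names(formals(constructor)))
  if (length(unknown)) {
    stop("unknown ", prefix, " config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(constructor, args)
}

#' Run the full site-detection and model-building pipeline
#'
#' Reads the multi-model PDB named in the configuration, scans every
#' conformer for candidate sites, evolves the genetic algorithm at each
#' site (with a per-site seed derived deterministically from the run
#' seed), filters survivors, builds water-completed complex models for
#' the `keep_top` best survivors per site, and writes all stage outputs
#' (`sites.csv`, `solutions.csv`, `shells.csv`, one PDB per complex,
#' `manifest.json`) into the output directory.
#'
#' @param config Path to a key-value configuration file, or an
#'   equivalent named list.
#' @return A `run_manifest` list (invisibly written to manifest.json):
#'   configuration snapshot, input checksum, seed, per-stage counts and
#'   timestamps.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  for (key in c("pdb", "out_dir", "seed")) {
    if (is.null(config[[key]])) stop("config is missing required key: ", key)
  }
  t_start <- Sys.time()
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  keep_top <- if (is.null(config$keep_top)) 3L else as.integer(config$keep_top)
  target_cn <- if (is.null(config$target_cn)) 6L else as.integer(config$target_cn)
  water_bond <- if (is.null(config$water_bond)) 1.95 else as.numeric(config$water_bond)
  gp <- config_params(config, "grid", grid_params)
  mp_base <- config_params(config, "moga", moga_params)

  ens <- read_pdb_ensemble(config$pdb)
  all_sites <- list()
  all_solutions <- list()
  complexes <- list()
  shell_rows <- list()
  n_solutions <- 0L
  n_survivors <- 0L
  for (m in ens$models) {
    donors <- classify_donors(m)
    sites <- detect_sites(m, donors, gp)
    all_sites <- c(all_sites, sites)
    for (si in seq_along(sites)) {
      site <- sites[[si]]
      mp <- mp_base
      # per-site deterministic seed, kept within 32-bit range
      mp$seed <- (seed + 131L * m$model_id + 17L * si) %% 2147483647L
      sols <- evolve(site, m, donors, mp)
      n_solutions <- n_solutions + length(sols)
      surv <- filter_solutions(sols, mp)
      n_survivors <- n_survivors + length(surv)
      for (j in seq_len(min(keep_top, length(surv)))) {
        cx <- build_complex(surv[[j]], site, m, donors, mp,
                            target_cn = target_cn, water_bond = water_bond)
        tag <- sprintf("m%d_s%d_r%d", m$model_id, si, j)
        complexes[[tag]] <- cx
        fs <- first_shell_summary(cx)
        sh <- fs$shell
        sh$complex <- tag
        shell_rows[[tag]] <- sh
      }
      all_solutions[[length(all_solutions) + 1L]] <- data.frame(
        model_id = m$model_id, site_id = si,
        rank = vapply(sols, `[[`, integer(1L), "pareto_rank"),
        clash_A3 = vapply(sols, function(s) s$objectives$clash_volume, numeric(1L)),
        clash_nm3 = vapply(sols, function(s) s$objectives$clash_volume, numeric(1L)) / 1000,
        donor_score = vapply(sols, function(s) s$objectives$donor_score, numeric(1L)),
        octa_dev_deg = vapply(sols, function(s) s$objectives$octa_deviation, numeric(1L)),
        n_donors_2p5 = vapply(sols, `[[`, integer(1L), "n_donors"),
        x = vapply(sols, function(s) s$metal_pos[1L], numeric(1L)),
        y = vapply(sols, function(s) s$metal_pos[2L], numeric(1L)),
        z = vapply(sols, function(s) s$metal_pos[3L], numeric(1L)),
        chi = vapply(sols, function(s)
          as.character(jsonlite::toJSON(unname(s$genome[-(1:3)]), digits = NA)),
          character(1L)),
        passed_filter = vapply(sols, function(s) {
          s$objectives$clash_volume <= mp$clash_max &&
            s$n_donors >= mp$min_donors
        }, logical(1L)))
    }
  }
  utils::write.csv(site_table(all_sites), file.path(out_dir, "sites.csv"),
                   row.names = FALSE)
  sol_df <- if (length(all_solutions)) do.call(rbind, all_solutions) else
    data.frame()
  utils::write.csv(sol_df, file.path(out_dir, "solutions.csv"),
                   row.names = FALSE)
  for (tag in names(complexes)) {
    write_complex_pdb(complexes[[tag]],
                      file.path(out_dir, paste0("complex_", tag, ".pdb")))
  }
  shells <- if (length(shell_rows)) do.call(rbind, shell_rows) else
    data.frame()
  utils::write.csv(shells, file.path(out_dir, "shells.csv"),
                   row.names = FALSE)
  manifest <- list(
    tool = "alsite",
    version = as.character(utils::packageVersion("alsite")),
    config = lapply(config, as.character),
    input = list(pdb = config$pdb,
                 md5 = unname(tools::md5sum(config$pdb))),
    seed = seed,
    counts = list(models_read = length(ens$models),
                  sites_found = length(all_sites),
                  solutions_generated = n_solutions,
                  survivors = n_survivors,
                  complexes_written = length(complexes)),
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$counts$models_read, "model(s),",
      x$counts$sites_found, "site(s),", x$counts$solutions_generated,
      "solution(s),", x$counts$survivors, "survivor(s),",
      x$counts$complexes_written, "complex(es) written\n")
  invisible(x)
}

#' Print the packaged cluster-model table ranked by enthalpy
#'
#' @param file Connection or path passed to [write()] (default stdout).
#' @return Invisibly, the ranked data frame.
#' @export
rank_motifs_cmd <- function(file = stdout()) {
  ranked <- rank_by_enthalpy(load_reference_table())
  cells <- vapply(seq_len(nrow(ranked)), function(i) {
    paste(vapply(ranked[i, ], as.character, character(1L)), collapse = "\t")
  }, character(1L))
  writeLines(c(paste(names(ranked), collapse = "\t"), cells), file)
  invisible(ranked)
}
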