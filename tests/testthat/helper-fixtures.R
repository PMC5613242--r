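# Shared fixtures, built once per test session.

.fx_cache <- new.env(parent = emptyenv())

fx_cached <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

# planted site with 3 donor residues / 4 shell oxygens (one bidentate)
fx_plant4 <- function() {
  fx_cached("plant4", function() {
    spec <- plant_spec(
      site = c(1, 2, 3),
      donors = list(
        list(restype = "GLU", vertex = 1L, denticity = "M"),
        list(restype = "ASP", vertex = 3L, denticity = "M"),
        list(restype = "GLU", vertex = c(5L, 4L), denticity = "B")),
      spacers = 2L)
    built <- build_planted_model(spec)
    built$donors <- classify_donors(built$model)
    built$site <- detect_sites(built$model, built$donors)[[1L]]
    built
  })
}

# fully pre-organized octahedral O6 cage: three bidentate carboxylates
# spanning all six vertices (their simultaneous chelation point is unique)
fx_plant6 <- function() {
  fx_cached("plant6", function() {
    spec <- plant_spec(
      site = c(0, 0, 0),
      donors = list(
        list(restype = "GLU", vertex = c(1L, 3L), denticity = "B"),
        list(restype = "ASP", vertex = c(2L, 5L), denticity = "B"),
        list(restype = "GLU", vertex = c(4L, 6L), denticity = "B")),
      spacers = 2L)
    built <- build_planted_model(spec)
    built$spec <- spec
    built$donors <- classify_donors(built$model)
    built$site <- detect_sites(built$model, built$donors)[[1L]]
    built
  })
}

# six monodentate carboxylates, one per octahedron vertex (ideal shell)
fx_plant6m <- function() {
  fx_cached("plant6m", function() {
    spec <- plant_spec(
      site = c(0, 0, 0),
      donors = lapply(1:6, function(v) {
        list(restype = if (v %% 2L) "GLU" else "ASP", vertex = v,
             denticity = "M")
      }),
      spacers = 1L)
    built <- build_planted_model(spec)
    built$donors <- classify_donors(built$model)
    built$site <- detect_sites(built$model, built$donors)[[1L]]
    built
  })
}

fx_polyala <- function(n = 5L) {
  new_model_from_atoms(build_peptide(rep("ALA", n)))
}

# small helper: peptide_model from a raw atom table
new_model_from_atoms <- function(atoms, model_id = 1L) {
  alsite:::new_peptide_model(atoms, model_id = model_id)
}

fx_abeta <- function() fx_cached("abeta", abeta_extended_model)

moga_params_small <- function(seed = 1L, ...) {
  moga_params(population = 20L, generations = 5L, seed = seed, ...)
}

# metal error of the top-ordered survivor against a planted truth
recovered_error <- function(survivors, truth_pos) {
  if (!length(survivors)) return(Inf)
  sqrt(sum((survivors[[1L]]$metal_pos - truth_pos)^2))
}
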