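# shared fixtures; expensive simulations are computed once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# simulate -> normalize -> fit -> call, the standard front half of the
# pipeline
call_pipeline <- function(specs, n, seed, model = ipd_model(),
                          weights = NULL) {
  quiet({
    sim <- simulate_sample(specs, n, model, weights = weights, seed = seed)
    norm <- normalize_ipd(sim$molecules)
    mix <- fit_mixture(norm, subsample = 200000L)
    tracks <- call_sample(sim$molecules, mix, normalized = norm)
  })
  list(sim = sim, norm = norm, mix = mix, tracks = tracks)
}

spec_regular <- function(id, nrl, n_nucleosomes = 7L, ...) {
  fibre_spec(id, "regular", nrl = nrl, n_nucleosomes = n_nucleosomes,
             flank5 = 5L, flank3 = 5L, ...)
}

# the in vitro 601-array benchmark: 1000 molecules, full pipeline to dyads
array_benchmark <- function() cached("array_benchmark", {
  pl <- call_pipeline(spec_601_array(), 1000L, seed = 1L)
  dyads <- quiet(call_dyads(smooth_tracks(pl$tracks, window = 5L)))
  truth <- pl$sim$truth$dyads[match(dyads$molecule_id,
                                    pl$sim$truth$molecule_id)]
  errors <- unlist(purrr::map2(dyads$dyads, truth, function(cd, td) {
    if (!length(cd)) return(NULL)
    abs(cd - td[vapply(cd, function(x) which.min(abs(td - x)), integer(1))])
  }))
  c(pl, list(dyads = dyads, errors = errors))
})

# two planted regular patterns (NRL 172 vs 193) through autocorrelograms
planted_two_patterns <- function() cached("planted_two", {
  pl <- call_pipeline(list(spec_regular("NRL172", 172L),
                           spec_regular("NRL193", 193L)),
                      500L, seed = 11L)
  acgs <- quiet(autocorrelograms(pl$tracks, smooth_window = 33L))
  m <- quiet(build_matrix(acgs))
  c(pl, list(acgs = acgs, matrix = m))
})

# four planted patterns: one irregular + three regular
planted_four_patterns <- function() cached("planted_four", {
  pl <- call_pipeline(list(
    fibre_spec("IRS", "irregular", n_nucleosomes = 8L,
               flank5 = 5L, flank3 = 5L),
    spec_regular("NRL172", 172L), spec_regular("NRL187", 187L),
    spec_regular("NRL193", 193L)
  ), 800L, seed = 13L)
  acgs <- quiet(autocorrelograms(pl$tracks, smooth_window = 33L))
  m <- quiet(build_matrix(acgs))
  c(pl, list(acgs = acgs, matrix = m))
})

pattern_of <- function(ids, labels) {
  labels$pattern_id[match(ids, labels$molecule_id)]
}

# bare track tibble from explicit prob vectors
track_tbl <- function(probs, ids = sprintf("m%03d", seq_along(probs)),
                      ref_start = 0L, strand = "+") {
  tibble::tibble(
    molecule_id = ids, ref_name = ids,
    ref_start = ref_start,
    ref_end = ref_start + lengths(probs),
    strand = strand, prob = probs
  )
}
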