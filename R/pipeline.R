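#' Validate a pipeline run configuration
#'
#' The configuration is a named list (typically read from YAML) with one
#' section per stage. Unknown keys are rejected and every stochastic stage
#' must carry an explicit seed.
#'
#' @param config A named list or a path to a YAML file.
#' @return The validated configuration list (with defaults filled in).
#' @export
read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  assert_that(is.list(config), "config must be a list or a YAML path")
  allowed <- list(
    simulate = c("n_molecules", "seed", "patterns", "ipd_model"),
    call = c("min_obs", "per_molecule", "subsample", "seed"),
    footprint = c("mode", "dyad_window", "min_separation", "edge_margin",
                  "smooth_window", "lag_range", "prominence", "max_len"),
    cluster = c("k_neighbors", "resolution", "seed", "min_len",
                "min_molecules", "small_cluster"),
    enrich = c("categories", "fdr_threshold")
  )
  unknown_sections <- setdiff(names(config), names(allowed))
  assert_that(length(unknown_sections) == 0,
              paste("unknown config section(s):",
                    paste(unknown_sections, collapse = ", ")))
  for (s in names(config)) {
    bad <- setdiff(names(config[[s]]), allowed[[s]])
    assert_that(length(bad) == 0,
                paste0("unknown key(s) in section '", s, "': ",
                       paste(bad, collapse = ", ")))
  }
  for (s in c("simulate", "call", "cluster")) {
    if (!is.null(config[[s]])) {
      assert_that(!is.null(config[[s]]$seed) || s == "call",
                  paste0("config section '", s, "' is missing its seed"))
    }
  }
  config
}

pattern_from_config <- function(p) {
  args <- p[setdiff(names(p), "weight")]
  do.call(fibre_spec, args)
}

#' Run the full pipeline: simulate, call, footprint, cluster
#'
#' Orchestrates the stages on a simulated sample and writes every artifact
#' plus a machine-readable manifest (package version, parameters, seeds,
#' file digests) to `out_dir`. Stages are plain package functions and can
#' be re-run individually.
#'
#' @param config Configuration list or YAML path (see [read_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)

  sim_cfg <- config$simulate
  assert_that(!is.null(sim_cfg), "config needs a 'simulate' section")
  specs <- purrr::map(sim_cfg$patterns, pattern_from_config)
  weights <- purrr::map_dbl(sim_cfg$patterns, ~ .x$weight %||% NA_real_)
  if (anyNA(weights)) weights <- rep(1 / length(specs), length(specs))
  model <- do.call(ipd_model, as.list(sim_cfg$ipd_model %||% list()))
  sim <- simulate_sample(specs, sim_cfg$n_molecules, model,
                         weights = weights, seed = sim_cfg$seed)
  write_kinetics(sim$molecules, pth("kinetics.tsv"))
  truth_bed <- tibble::tibble(
    chrom = rep(sim$truth$molecule_id, lengths(sim$truth$dyads)),
    start = unlist(sim$truth$dyads),
    end = unlist(sim$truth$dyads) + 1L,
    name = rep(sim$truth$pattern_id, lengths(sim$truth$dyads)),
    score = 0, strand = "+"
  )
  write_bed(truth_bed, pth("truth_dyads.bed"))
  readr::write_tsv(sim$labels, pth("pattern_labels.tsv"), progress = FALSE)
  yaml::write_yaml(config, pth("config_echo.yaml"))

  call_cfg <- config$call %||% list()
  normalized <- normalize_ipd(sim$molecules,
                              min_obs = call_cfg$min_obs %||% 20L)
  mix <- fit_mixture(normalized, subsample = call_cfg$subsample %||% 200000L,
                     seed = call_cfg$seed %||% 1L)
  write_mixture(mix, pth("model.json"))
  tracks <- call_sample(sim$molecules, mix, normalized = normalized,
                        per_molecule = isTRUE(call_cfg$per_molecule))
  write_tracks(tracks, pth("tracks.tsv"))

  fp_cfg <- config$footprint %||% list()
  mode <- fp_cfg$mode %||% "invivo"
  sm <- fp_cfg$smooth_window %||% if (mode == "invitro") 5L else 33L
  dy <- call_dyads(smooth_tracks(tracks, window = if (mode == "invitro") 5L else 33L),
                   window = fp_cfg$dyad_window %||% 133L,
                   min_separation = fp_cfg$min_separation %||% 147L,
                   edge_margin = fp_cfg$edge_margin %||% 73L)
  write_dyads(dy, sim$molecules, pth("dyads.bed"))
  acgs <- autocorrelograms(tracks, smooth_window = sm,
                           max_len = fp_cfg$max_len %||% 1000L)
  nrl <- find_nrl_peak(acgs,
                       lag_range = fp_cfg$lag_range %||% c(120L, 350L),
                       prominence = fp_cfg$prominence %||% 0.03)
  nrl_out <- dplyr::left_join(nrl,
                              dy[, c("molecule_id", "averaged_nrl")],
                              by = "molecule_id")
  readr::write_csv(nrl_out, pth("nrl.csv"), progress = FALSE)
  acg_mat <- tibble::tibble(
    molecule_id = acgs$molecule_id,
    acg = purrr::map_chr(acgs$acg, fmt_num_field, digits = 6L)
  )
  readr::write_tsv(acg_mat, pth("acg.tsv"), progress = FALSE)

  results <- list(sim = sim, model = mix, tracks = tracks, dyads = dy,
                  acgs = acgs, nrl = nrl)

  cl_cfg <- config$cluster
  if (!is.null(cl_cfg)) {
    m <- build_matrix(acgs, min_len = cl_cfg$min_len %||% 500L,
                      min_molecules = cl_cfg$min_molecules %||% 50L)
    assignment <- leiden_cluster(
      m, k_neighbors = cl_cfg$k_neighbors %||% 15L,
      resolution = cl_cfg$resolution %||% 1,
      seed = cl_cfg$seed,
      small_cluster = cl_cfg$small_cluster %||% 100L
    )
    summary <- summarize_clusters(assignment, nrl_calls = nrl,
                                  tracks = tracks, acgs = acgs)
    readr::write_csv(assignment, pth("clusters.csv"), progress = FALSE)
    readr::write_csv(
      dplyr::select(summary, -dplyr::any_of(c("profile", "mean_acg"))),
      pth("cluster_summary.csv"), progress = FALSE
    )
    results$assignment <- assignment
    results$cluster_summary <- summary

    en_cfg <- config$enrich
    if (!is.null(en_cfg)) {
      categories <- if (identical(en_cfg$categories, "pattern")) {
        dplyr::rename(sim$labels, category = "pattern_id")
      } else {
        readr::read_csv(en_cfg$categories, show_col_types = FALSE)
      }
      enr <- enrichment_scan(assignment, categories,
                             fdr_threshold = en_cfg$fdr_threshold %||% 0.1)
      readr::write_csv(enr, pth("enrichment.csv"), progress = FALSE)
      results$enrichment <- enr
    }
  }

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "samosa",
    version = as.character(utils::packageVersion("samosa")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config,
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs)))
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}
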