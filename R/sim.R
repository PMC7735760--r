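#' Describe a synthetic chromatin fibre pattern
#'
#' A fibre spec captures the geometry and methylation behaviour of one
#' oligonucleosome pattern: either a regular array with a fixed nucleosome
#' repeat length (NRL) or an irregular fibre whose linker lengths are drawn
#' from a broad sampler. Accessible (linker) A/T bases are methylated with
#' probability `linker_meth_prob`; nucleosome-protected A/T bases with
#' probability `occluded_meth_prob`.
#'
#' @param pattern_id Label for the pattern (used in truth tables).
#' @param pattern_type `"regular"` or `"irregular"`.
#' @param nrl Nucleosome repeat length in bp (regular patterns only); must
#'   exceed `footprint`.
#' @param n_nucleosomes Number of nucleosomes per molecule (>= 1).
#' @param footprint Nucleosome-protected width in bp (default 147).
#' @param dyad_jitter_sd Gaussian jitter (bp) applied to each dyad position.
#' @param linker_meth_prob,occluded_meth_prob Per-A/T methylation
#'   probabilities outside / inside nucleosome footprints, in \[0, 1\].
#' @param flank5,flank3 Nucleosome-free DNA (bp) at the molecule ends.
#' @param linker_mean,linker_floor,linker_max Irregular-linker sampler:
#'   linker ~ `linker_floor` + Geometric with mean `linker_mean - linker_floor`,
#'   truncated at `linker_max` (see [sample_linkers()]).
#' @param seq_mode `"random"` (uniform bases) or `"array"` (a fixed
#'   pattern-specific repeat unit of length `nrl` tiled along the molecule,
#'   mimicking tandem positioning-sequence arrays).
#' @return A `fibre_spec` object (a named list).
#' @export
fibre_spec <- function(pattern_id,
                       pattern_type = c("regular", "irregular"),
                       nrl = NULL,
                       n_nucleosomes = 1L,
                       footprint = 147L,
                       dyad_jitter_sd = 2,
                       linker_meth_prob = 0.9,
                       occluded_meth_prob = 0.05,
                       flank5 = 0L,
                       flank3 = 0L,
                       linker_mean = 40,
                       linker_floor = 5,
                       linker_max = 250,
                       seq_mode = c("random", "array")) {
  pattern_type <- match.arg(pattern_type)
  seq_mode <- match.arg(seq_mode)
  assert_that(is.character(pattern_id) && length(pattern_id) == 1L,
              "pattern_id must be a single label")
  assert_that(n_nucleosomes >= 1, "n_nucleosomes must be >= 1")
  assert_that(footprint >= 1, "footprint must be positive")
  for (p in c(linker_meth_prob, occluded_meth_prob)) {
    assert_that(p >= 0 && p <= 1, "methylation probabilities must lie in [0, 1]")
  }
  assert_that(dyad_jitter_sd >= 0, "dyad_jitter_sd must be >= 0")
  assert_that(flank5 >= 0 && flank3 >= 0, "flanks must be >= 0")
  if (pattern_type == "regular") {
    assert_that(!is.null(nrl), "regular specs need an nrl")
    assert_that(nrl > footprint,
                "geometry cannot fit nucleosomes: nrl must exceed footprint")
  }
  structure(
    list(pattern_id = pattern_id, pattern_type = pattern_type,
         nrl = if (is.null(nrl)) NA_integer_ else as.integer(nrl),
         n_nucleosomes = as.integer(n_nucleosomes),
         footprint = as.integer(footprint),
         dyad_jitter_sd = dyad_jitter_sd,
         linker_meth_prob = linker_meth_prob,
         occluded_meth_prob = occluded_meth_prob,
         flank5 = as.integer(flank5), flank3 = as.integer(flank3),
         linker_mean = linker_mean, linker_floor = linker_floor,
         linker_max = linker_max, seq_mode = seq_mode),
    class = "fibre_spec"
  )
}

#' @export
print.fibre_spec <- function(x, ...) {
  cat(sprintf("<fibre_spec '%s': %s, %d nucleosomes%s, footprint %d bp>\n",
              x$pattern_id, x$pattern_type, x$n_nucleosomes,
              if (x$pattern_type == "regular") sprintf(", NRL %d bp", x$nrl) else "",
              x$footprint))
  invisible(x)
}

#' The in vitro nonanucleosomal positioning-sequence array design
#'
#' Nine tandem nucleosomes on a strong positioning sequence at a 193-bp
#' repeat (147-bp core + ~46-bp linker), preceded by ~450 bp of
#' nucleosome-free DNA and followed by the trailing linker.
#'
#' @param dyad_jitter_sd Dyad jitter in bp (default 2).
#' @param ... Further arguments passed to [fibre_spec()].
#' @return A `fibre_spec`.
#' @export
spec_601_array <- function(dyad_jitter_sd = 2, ...) {
  fibre_spec("601x9", "regular", nrl = 193L, n_nucleosomes = 9L,
             footprint = 147L, dyad_jitter_sd = dyad_jitter_sd,
             flank5 = 450L, flank3 = 46L, seq_mode = "array", ...)
}

#' Kinetics emission model for synthetic molecules
#'
#' Interpulse durations (IPD) are drawn log-normally: `log(IPD)` is Normal
#' with mean `meth_logmean` at methylated A/T bases and `unmeth_logmean`
#' elsewhere. The defaults give a ~3x median IPD fold-change at methylated
#' adenines with overlapping distributions. An optional zero-mean per-8-mer
#' (2 bp 5', 5 bp 3') offset on the log scale emulates sequence-context bias.
#'
#' @param unmeth_logmean,unmeth_logsd Log-IPD parameters of unmethylated
#'   positions (natural-log scale).
#' @param meth_logmean,meth_logsd Log-IPD parameters of methylated A/T.
#' @param context_effect_sd SD of the per-context additive log offset
#'   (0 disables the effect).
#' @param missing_rate Fraction of A/T positions with no IPD observation.
#' @param n5,n3 Context window: bases 5' and 3' of the template base.
#' @param context_seed Seed for the fixed per-context offset table.
#' @return An `ipd_model` object.
#' @export
ipd_model <- function(unmeth_logmean = 0, unmeth_logsd = 0.5,
                      meth_logmean = 1.1, meth_logsd = 0.5,
                      context_effect_sd = 0, missing_rate = 0.05,
                      n5 = 2L, n3 = 5L, context_seed = 99L) {
  assert_that(meth_logmean > unmeth_logmean,
              "meth_logmean must exceed unmeth_logmean")
  assert_that(unmeth_logsd > 0 && meth_logsd > 0, "log-sds must be positive")
  assert_that(missing_rate >= 0 && missing_rate <= 1,
              "missing_rate must lie in [0, 1]")
  offsets <- NULL
  if (context_effect_sd > 0) {
    k <- n5 + 1L + n3
    offsets <- withr::with_seed(as.integer(context_seed),
                                rnorm(4L^k, 0, context_effect_sd))
    offsets <- offsets - mean(offsets)
  }
  structure(
    list(unmeth_logmean = unmeth_logmean, unmeth_logsd = unmeth_logsd,
         meth_logmean = meth_logmean, meth_logsd = meth_logsd,
         context_effect_sd = context_effect_sd, missing_rate = missing_rate,
         n5 = as.integer(n5), n3 = as.integer(n3),
         context_offsets = offsets),
    class = "ipd_model"
  )
}

#' Draw irregular-fibre linker lengths
#'
#' Linker length = `floor` + Geometric (mean `mean - floor`), truncated at
#' `max`: a broad right-skewed distribution with no dominant periodicity.
#'
#' @param n Number of linkers.
#' @param mean,floor,max Sampler parameters in bp.
#' @return Integer vector of linker lengths.
#' @export
sample_linkers <- function(n, mean = 40, floor = 5, max = 250) {
  assert_that(mean > floor, "linker mean must exceed the floor")
  p <- 1 / (mean - floor + 1)
  pmin(floor + stats::rgeom(n, p), max)
}

#' Plan nucleosome dyad positions for one molecule
#'
#' Regular patterns place dyads at `flank5 + footprint/2 + k * nrl` with
#' Gaussian jitter; irregular patterns place nucleosomes sequentially with
#' linkers drawn by [sample_linkers()]. Adjacent dyads are always kept at
#' least one footprint apart. Positions are 0-based molecule coordinates.
#'
#' @param spec A [fibre_spec()].
#' @param seed Optional integer seed (NULL uses the current RNG state).
#' @return Integer vector of strictly increasing dyad positions, with the
#'   total molecule length in attribute `"molecule_length"`.
#' @export
plan_nucleosomes <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "fibre_spec"))
  with_seed_if(seed, {
    fp <- spec$footprint
    half <- fp %/% 2L
    n <- spec$n_nucleosomes
    if (spec$pattern_type == "regular") {
      len <- spec$flank5 + (n - 1L) * spec$nrl + fp + spec$flank3
      base <- spec$flank5 + half + (seq_len(n) - 1L) * spec$nrl
      jit <- if (spec$dyad_jitter_sd > 0) round(rnorm(n, 0, spec$dyad_jitter_sd)) else 0
      d <- as.integer(base + jit)
    } else {
      linkers <- sample_linkers(n - 1L, spec$linker_mean, spec$linker_floor,
                                spec$linker_max)
      d <- as.integer(spec$flank5 + half +
                        cumsum(c(0L, linkers + fp)))
      len <- spec$flank5 + n * fp + sum(linkers) + spec$flank3
    }
    # keep dyads inside the molecule and >= footprint apart
    d[1] <- max(d[1], half)
    if (n > 1L) for (k in 2:n) d[k] <- max(d[k], d[k - 1L] + fp)
    lim <- len - 1L - half
    if (d[n] > lim) {
      d[n] <- lim
      if (n > 1L) for (k in (n - 1L):1L) d[k] <- min(d[k], d[k + 1L] - fp)
    }
    if (d[1] < half || is.unsorted(d, strictly = TRUE) ||
        (n > 1L && any(diff(d) < fp))) {
      stop("geometry cannot fit ", n, " nucleosomes in ", len, " bp",
           call. = FALSE)
    }
    structure(as.integer(d), molecule_length = as.integer(len))
  })
}

# deterministic repeat unit for "array" sequence mode, shared by all
# molecules of a pattern
array_unit <- function(spec) {
  unit_len <- if (is.na(spec$nrl)) 193L else spec$nrl
  s <- (sum(utf8ToInt(spec$pattern_id)) * 7919L + unit_len) %% .Machine$integer.max
  withr::with_seed(s, sample(c("A", "C", "G", "T"), unit_len, replace = TRUE))
}

context_index <- function(codes, n5, n3) {
  # base-4 index of the (n5+1+n3)-mer around each position; NA where the
  # window is truncated or contains N
  L <- length(codes)
  k <- n5 + 1L + n3
  idx <- rep(0, L)
  pow <- 1
  for (j in seq(-n5, n3)) {
    shifted <- rep(NA_integer_, L)
    src <- seq_len(L) + j
    ok <- src >= 1L & src <= L
    shifted[ok] <- codes[src[ok]]
    idx <- idx + shifted * pow
    pow <- pow * 4
  }
  idx + 1L
}

#' Emit one synthetic molecule with per-base IPDs
#'
#' Generates the base string, assigns methylation to A/T bases (probability
#' `linker_meth_prob` outside every nucleosome footprint, `occluded_meth_prob`
#' inside), and draws IPDs from the emission model. A fraction
#' `missing_rate` of A/T observations is masked.
#'
#' @param dyads Dyad positions from [plan_nucleosomes()].
#' @param spec The [fibre_spec()] used to plan them.
#' @param model An [ipd_model()].
#' @param molecule_id Identifier for the molecule.
#' @param seed Optional integer seed.
#' @return A list with `molecule` (one-row tibble in the kinetics-table
#'   layout) and `truth` (one-row tibble with true dyads and the per-base
#'   methylation mask).
#' @export
emit_molecule <- function(dyads, spec, model = ipd_model(),
                          molecule_id = "mol1", seed = NULL) {
  stopifnot(inherits(spec, "fibre_spec"), inherits(model, "ipd_model"))
  L <- attr(dyads, "molecule_length")
  assert_that(!is.null(L), "dyads must come from plan_nucleosomes()")
  with_seed_if(seed, {
    if (spec$seq_mode == "array") {
      unit <- array_unit(spec)
      bases <- rep(unit, length.out = L)
    } else {
      bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    }
    half <- spec$footprint %/% 2L
    protected <- rep(FALSE, L)
    for (d in dyads) {
      lo <- max(0L, d - half); hi <- min(L - 1L, d + half)
      protected[(lo + 1L):(hi + 1L)] <- TRUE
    }
    is_at <- bases %in% c("A", "T")
    p_meth <- ifelse(protected, spec$occluded_meth_prob, spec$linker_meth_prob)
    meth <- is_at & runif(L) < p_meth
    meanlog <- ifelse(meth, model$meth_logmean, model$unmeth_logmean)
    sdlog <- ifelse(meth, model$meth_logsd, model$unmeth_logsd)
    if (!is.null(model$context_offsets)) {
      codes <- match(bases, c("A", "C", "G", "T")) - 1L
      ci <- context_index(codes, model$n5, model$n3)
      off <- model$context_offsets[ci]
      meanlog <- meanlog + ifelse(is.na(off), 0, off)
    }
    ipd <- rlnorm(L, meanlog, sdlog)
    if (model$missing_rate > 0) {
      ipd[is_at & runif(L) < model$missing_rate] <- NA_real_
    }
    molecule <- tibble::tibble(
      molecule_id = molecule_id, ref_name = molecule_id,
      ref_start = 0L, ref_end = as.integer(L), strand = "+",
      bases = paste(bases, collapse = ""), ipd = list(ipd)
    )
    truth <- tibble::tibble(
      molecule_id = molecule_id, pattern_id = spec$pattern_id,
      length = as.integer(L),
      dyads = list(as.integer(dyads)), meth = list(meth)
    )
    list(molecule = molecule, truth = truth)
  })
}

#' Simulate a sample of fibres from a mixture of patterns
#'
#' Draws each molecule's pattern from the mixture weights (multinomial),
#' plans nucleosome positions and emits kinetics. All randomness derives
#' from `seed`.
#'
#' @param mixture A list of [fibre_spec()] objects, or a tibble with
#'   list-column `spec` and column `weight`.
#' @param n_molecules Number of molecules to simulate.
#' @param model An [ipd_model()].
#' @param weights Mixture weights (recycled to equal if missing); must sum
#'   to 1.
#' @param seed Integer seed (required: the sample is fully reproducible).
#' @return A list of tibbles: `molecules` (kinetics layout), `truth`
#'   (per-molecule dyads + methylation mask), `labels`
#'   (molecule_id, pattern_id).
#' @export
simulate_sample <- function(mixture, n_molecules, model = ipd_model(),
                            weights = NULL, seed = 1L) {
  if (inherits(mixture, "fibre_spec")) mixture <- list(mixture)
  if (is.data.frame(mixture)) {
    weights <- mixture$weight
    mixture <- mixture$spec
  }
  assert_that(length(mixture) >= 1, "mixture must contain at least one spec")
  if (is.null(weights)) weights <- rep(1 / length(mixture), length(mixture))
  assert_that(abs(sum(weights) - 1) < 1e-8, "mixture weights must sum to 1")
  assert_that(n_molecules >= 1, "n_molecules must be >= 1")
  withr::with_seed(as.integer(seed), {
    which_pattern <- sample.int(length(mixture), n_molecules, replace = TRUE,
                                prob = weights)
    ids <- sprintf("mol%06d", seq_len(n_molecules))
    out <- purrr::map(seq_len(n_molecules), function(i) {
      sp <- mixture[[which_pattern[i]]]
      emit_molecule(plan_nucleosomes(sp), sp, model, molecule_id = ids[i])
    })
    molecules <- dplyr::bind_rows(purrr::map(out, "molecule"))
    truth <- dplyr::bind_rows(purrr::map(out, "truth"))
    list(molecules = molecules, truth = truth,
         labels = dplyr::select(truth, "molecule_id", "pattern_id"))
  })
}

#' Simulate an MNase digestion ladder for one molecule
#'
#' Cuts are placed in linkers (linker midpoint plus Gaussian jitter, clamped
#' so no cut falls inside a nucleosome footprint); each internal linker is
#' cut independently with probability `cut_prob`, so fragment lengths
#' concentrate near integer multiples of the repeat length for regular
#' fibres.
#'
#' @param dyads Dyad positions from [plan_nucleosomes()].
#' @param spec The corresponding [fibre_spec()].
#' @param cut_jitter_sd SD (bp) of the cut-position jitter.
#' @param cut_prob Probability that a given linker is cut.
#' @param seed Optional integer seed.
#' @return Tibble of fragments: `start`, `end` (0-based half-open), `length`.
#' @export
simulate_mnase_fragments <- function(dyads, spec, cut_jitter_sd = 5,
                                     cut_prob = 0.5, seed = NULL) {
  stopifnot(inherits(spec, "fibre_spec"))
  L <- attr(dyads, "molecule_length")
  assert_that(!is.null(L), "dyads must come from plan_nucleosomes()")
  assert_that(length(dyads) >= 1, "need at least one nucleosome")
  with_seed_if(seed, {
    half <- spec$footprint %/% 2L
    cuts <- integer(0)
    n <- length(dyads)
    if (n > 1L) {
      for (j in seq_len(n - 1L)) {
        lo <- dyads[j] + half + 1L
        hi <- dyads[j + 1L] - half - 1L
        if (lo > hi || runif(1) >= cut_prob) next
        site <- round((lo + hi) / 2 + rnorm(1, 0, cut_jitter_sd))
        cuts <- c(cuts, as.integer(min(max(site, lo), hi)))
      }
    }
    b <- sort(unique(c(0L, cuts, as.integer(L))))
    tibble::tibble(start = head(b, -1L), end = tail(b, -1L),
                   length = tail(b, -1L) - head(b, -1L))
  })
}
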