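#' Assign molecules to genomic features
#'
#' A molecule hits a feature when its alignment interval overlaps the
#' feature expanded by `max_dist` on both sides (closed expansion: a gap of
#' exactly `max_dist` still counts). Molecules may hit several features and
#' all hits are kept, with the molecule's alignment start/end offsets from
#' the feature midpoint and both strands recorded.
#'
#' @param molecules Molecules (or tracks) tibble with `ref_name`,
#'   `ref_start`, `ref_end`, `strand`.
#' @param features Feature tibble from [read_bed()].
#' @param max_dist Expansion distance in bp (default 1000).
#' @return Tibble of hits: molecule columns plus `feature_chrom`,
#'   `feature_start`, `feature_end`, `feature_name`, `feature_strand`,
#'   `offset_start`, `offset_end` (alignment ends relative to the feature
#'   midpoint, feature-strand oriented).
#' @export
assign_molecules <- function(molecules, features, max_dist = 1000L) {
  missing_contigs <- setdiff(unique(features$chrom), unique(molecules$ref_name))
  if (length(missing_contigs)) {
    warning("skipping features on contig(s) absent from molecules: ",
            paste(missing_contigs, collapse = ", "))
    features <- features[!features$chrom %in% missing_contigs, ]
  }
  if (nrow(features) == 0 || nrow(molecules) == 0) {
    return(empty_hits(molecules))
  }
  mg <- GenomicRanges::GRanges(
    molecules$ref_name,
    IRanges::IRanges(molecules$ref_start + 1L, molecules$ref_end)
  )
  fg <- GenomicRanges::GRanges(
    features$chrom, IRanges::IRanges(features$start + 1L, features$end)
  )
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(mg, fg, maxgap = as.integer(max_dist))
  )
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  mid <- (features$start + features$end) %/% 2L
  flip <- features$strand[si] == "-"
  os <- molecules$ref_start[qi] - mid[si]
  oe <- molecules$ref_end[qi] - mid[si]
  tibble::tibble(
    molecule_id = molecules$molecule_id[qi],
    ref_start = molecules$ref_start[qi],
    ref_end = molecules$ref_end[qi],
    strand = molecules$strand[qi],
    feature_chrom = features$chrom[si],
    feature_start = features$start[si],
    feature_end = features$end[si],
    feature_name = features$name[si],
    feature_strand = features$strand[si],
    offset_start = ifelse(flip, -oe, os),
    offset_end = ifelse(flip, -os, oe)
  )
}

empty_hits <- function(molecules) {
  tibble::tibble(
    molecule_id = character(0), ref_start = integer(0), ref_end = integer(0),
    strand = character(0), feature_chrom = character(0),
    feature_start = integer(0), feature_end = integer(0),
    feature_name = character(0), feature_strand = character(0),
    offset_start = integer(0), offset_end = integer(0)
  )
}

#' Extract strand-aware modification windows around motifs
#'
#' For each motif, takes the posterior track of every molecule fully
#' covering a `2 * flank`-bp window centred on the motif midpoint
#' (`floor((start + end) / 2)`; window `[mid - flank, mid + flank)`).
#' Rows are extracted in reference orientation and reversed for
#' minus-strand motifs, so window column 1 is always the motif's 5' side.
#'
#' @param tracks Track tibble from [call_sample()] (carries placement).
#' @param motifs Motif tibble ([read_bed()], BED6; `name` is the category,
#'   e.g. the TF or "control").
#' @param flank Half-window in bp (default 250: a 500-bp window).
#' @return Tibble: `molecule_id`, `category`, `chrom`, `motif_mid`,
#'   `motif_strand`, list-column `window` (length `2 * flank`). Molecules
#'   not fully covering a window are excluded;
#'   `attr(, "n_excluded")` counts them.
#' @export
motif_windows <- function(tracks, motifs, flank = 250L) {
  hits <- assign_molecules(tracks, motifs, max_dist = 0L)
  mid_all <- (motifs$start + motifs$end) %/% 2L
  key <- paste(motifs$chrom, motifs$start, motifs$end, motifs$name)
  hk <- paste(hits$feature_chrom, hits$feature_start, hits$feature_end,
              hits$feature_name)
  hits$motif_mid <- mid_all[match(hk, key)]
  covers <- hits$ref_start <= hits$motif_mid - flank &
    hits$ref_end >= hits$motif_mid + flank
  n_excl <- sum(!covers)
  hits <- hits[covers, ]
  if (nrow(hits) == 0) {
    warning("no molecules fully cover a motif window")
    out <- tibble::tibble(molecule_id = character(0), category = character(0),
                          chrom = character(0), motif_mid = integer(0),
                          motif_strand = character(0), window = list())
    attr(out, "n_excluded") <- n_excl
    return(out)
  }
  pr <- tracks$prob[match(hits$molecule_id, tracks$molecule_id)]
  win <- purrr::pmap(
    list(pr, hits$ref_start, hits$ref_end, hits$strand,
         hits$motif_mid, hits$feature_strand),
    function(p, rs, re, mol_strand, mid, mot_strand) {
      r <- if (mol_strand == "-") rev(p) else p   # reference orientation
      idx <- (mid - flank - rs + 1L):(mid + flank - rs)
      w <- r[idx]
      if (mot_strand == "-") rev(w) else w
    }
  )
  out <- tibble::tibble(
    molecule_id = hits$molecule_id,
    category = hits$feature_name,
    chrom = hits$feature_chrom,
    motif_mid = hits$motif_mid,
    motif_strand = hits$feature_strand,
    window = win
  )
  attr(out, "n_excluded") <- n_excl
  out
}

#' MNase/fragment-end cut profile around motifs
#'
#' Both alignment ends of every molecule hitting a motif (within
#' `halfwidth`) contribute one count at their offset from the motif
#' midpoint, flipped for minus-strand motifs. Counts are also reported per
#' molecule sequenced.
#'
#' @param molecules Molecules (or tracks) tibble with placement columns.
#' @param motifs Motif tibble (BED6).
#' @param halfwidth Profile half-width in bp (default 1000).
#' @return Tibble: `offset` (-halfwidth..halfwidth), `count`,
#'   `per_molecule` (count / number of molecules supplied).
#' @export
cut_profile <- function(molecules, motifs, halfwidth = 1000L) {
  hits <- assign_molecules(molecules, motifs, max_dist = halfwidth)
  offsets <- c(hits$offset_start, hits$offset_end)
  offsets <- offsets[abs(offsets) <= halfwidth]
  grid <- seq(-halfwidth, halfwidth)
  counts <- tabulate(match(offsets, grid), nbins = length(grid))
  tibble::tibble(offset = grid, count = counts,
                 per_molecule = counts / max(nrow(molecules), 1L))
}

#' Cluster single-molecule states at motifs
#'
#' Smooths the 500-bp motif-window posteriors (33-bp missing-aware rolling
#' mean), imputes residual missing values by the row mean, and reuses
#' [leiden_cluster()] on the resulting matrix to discover single-molecule
#' accessibility states (e.g. occluded vs accessible-centre), including
#' control molecules.
#'
#' @param windows Window tibble from [motif_windows()].
#' @param k_neighbors,resolution,seed,small_cluster See [leiden_cluster()].
#' @param smooth_window Odd smoothing width (default 33).
#' @return List: `assignment` (as [leiden_cluster()], with `category`
#'   joined back) and `profiles` (per-cluster mean window profile tibble).
#' @export
state_cluster <- function(windows, k_neighbors = 15L, resolution = 1,
                          seed = 1L, smooth_window = 33L,
                          small_cluster = 100L) {
  assert_that(nrow(windows) >= 50, "need at least 50 window rows")
  w <- purrr::map(windows$window, rolling_mean_nan, window = smooth_window)
  m <- do.call(rbind, w)
  rownames(m) <- make.unique(windows$molecule_id)
  rmn <- rowMeans(m, na.rm = TRUE)
  ok <- is.finite(rmn)
  m <- m[ok, , drop = FALSE]
  na_idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(na_idx)) m[na_idx] <- rowMeans(m, na.rm = TRUE)[na_idx[, 1]]
  assignment <- leiden_cluster(m, k_neighbors = k_neighbors,
                               resolution = resolution, seed = seed,
                               small_cluster = small_cluster)
  assignment$category <- windows$category[ok]
  assignment$molecule_id <- windows$molecule_id[ok]
  profiles <- assignment |>
    dplyr::mutate(row = seq_len(nrow(assignment))) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      profile = list(colMeans(m[.data$row, , drop = FALSE], na.rm = TRUE)),
      .groups = "drop"
    )
  list(assignment = assignment, profiles = profiles)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional (hypergeometric) two-sided p-value by the probability-mass
#' rule: the sum of probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table. The odds
#' ratio is the sample odds ratio `a*d / (b*c)` (infinite when `b*c = 0`
#' and `a*d > 0`; undefined when a margin is empty).
#'
#' @param a,b,c,d Cell counts: (in cluster & in category), (in cluster &
#'   not), (not in cluster & in category), (neither). Vectorized.
#' @return Tibble: `a,b,c,d`, `odds_ratio`, `p_value`.
#' @export
fisher_test <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0))
  n <- length(a)
  p <- numeric(n)
  or <- numeric(n)
  for (i in seq_len(n)) {
    ai <- a[i]; bi <- b[i]; ci <- c[i]; di <- d[i]
    m1 <- ai + bi; m2 <- ci + di; k <- ai + ci
    if (m1 == 0 || m2 == 0 || k == 0 || (bi + di) == 0) {
      p[i] <- 1
      or[i] <- NA_real_
      next
    }
    supp <- max(0, k - m2):min(k, m1)
    pr <- dhyper(supp, m1, m2, k)
    pobs <- dhyper(ai, m1, m2, k)
    p[i] <- min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
    or[i] <- if (bi * ci == 0) {
      if (ai * di == 0) NA_real_ else Inf
    } else ai * di / (bi * ci)
  }
  tibble::tibble(a = a, b = b, c = c, d = d, odds_ratio = or, p_value = p)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05..0.95 (step
#' 0.05) with a cubic-spline smoother evaluated at the largest lambda
#' (clipped to (0, 1\]), then computes
#' `q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j)`. With fewer
#' than 20 p-values pi0 is fixed at 1, reducing to Benjamini-Hochberg.
#'
#' @param p P-values in \[0, 1\].
#' @param lambda Grid for pi0 estimation.
#' @param pi0 Optional fixed pi0 override (e.g. 1 for plain BH).
#' @return Numeric vector of q-values, monotone in `p`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 20) {
      message("fewer than 20 p-values: pi0 fixed at 1 (Benjamini-Hochberg)")
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  o <- order(p, decreasing = TRUE)
  r <- rank(p, ties.method = "max")
  q <- pi0 * m * p / r
  q[o] <- cummin(q[o])
  pmin(q, 1)
}

#' GC-matched control regions
#'
#' Samples control intervals from a candidate universe so that the control
#' GC histogram matches the target GC histogram bin for bin (default
#' 2.5%-GC bins), without replacement; under-populated bins borrow from the
#' nearest neighbouring bins with a message. A transparent stand-in for
#' model-based matched-region selection (repeat content is not matched).
#'
#' @param candidates Candidate feature tibble (BED-like).
#' @param targets Target feature tibble.
#' @param genome A named character vector of chromosome sequences or a
#'   `Biostrings::DNAStringSet`.
#' @param bin_width GC-fraction bin width (default 0.025).
#' @param seed Integer seed.
#' @return Tibble of control features (same layout as `candidates`).
#' @export
matched_controls <- function(candidates, targets, genome, bin_width = 0.025,
                             seed = 1L) {
  gc_tar <- gc_content(targets, genome)
  gc_can <- gc_content(candidates, genome)
  bin <- function(g) pmin(floor(g / bin_width), floor(1 / bin_width) - 1L)
  tb <- bin(gc_tar)
  cb <- bin(gc_can)
  withr::with_seed(as.integer(seed), {
    need <- table(tb)
    taken <- logical(nrow(candidates))
    picked <- integer(0)
    for (b in as.integer(names(need))) {
      want <- need[[as.character(b)]]
      pool <- which(cb == b & !taken)
      if (length(pool) < want) {
        message("GC bin ", b, " under-populated; borrowing from nearest bins")
        extra <- order(abs(cb - b) + ifelse(taken, Inf, 0))
        extra <- setdiff(extra, pool)
        pool <- c(pool, extra[seq_len(want - length(pool))])
      }
      sel <- if (length(pool) == want) pool else sample(pool, want)
      taken[sel] <- TRUE
      picked <- c(picked, sel)
    }
    candidates[sort(picked), ]
  })
}

gc_content <- function(features, genome) {
  if (is.character(genome)) {
    seqs <- genome
    vapply(seq_len(nrow(features)), function(i) {
      s <- substr(seqs[[features$chrom[i]]], features$start[i] + 1L,
                  features$end[i])
      v <- strsplit(s, "")[[1]]
      mean(v %in% c("G", "C", "g", "c"))
    }, numeric(1))
  } else {
    v <- Biostrings::Views(
      genome[features$chrom],
      start = features$start + 1L, end = features$end
    )
    # Views over a DNAStringSet: one view per feature on its own sequence
    freq <- Biostrings::letterFrequency(
      Biostrings::DNAStringSet(v), c("G", "C")
    )
    rowSums(freq) / (features$end - features$start)
  }
}

#' Cluster-by-category enrichment scan
#'
#' One two-sided Fisher's exact test per (cluster, category) pair against
#' the background of all labeled molecules, with Storey q-values across the
#' whole scan. Molecules carrying several categories are counted once per
#' category.
#'
#' @param assignment Tibble `molecule_id`, `cluster` (from
#'   [leiden_cluster()]).
#' @param categories Tibble `molecule_id`, `category` (one row per label;
#'   molecules may appear under several categories).
#' @param fdr_threshold Significance threshold on q (default 0.1).
#' @return Tibble: `cluster`, `category`, `a,b,c,d`, `odds_ratio`,
#'   `p_value`, `q_value`, `significant`.
#' @export
enrichment_scan <- function(assignment, categories, fdr_threshold = 0.1) {
  lab <- dplyr::inner_join(assignment[, c("molecule_id", "cluster")],
                           categories, by = "molecule_id")
  assert_that(nrow(lab) > 0, "no labeled molecules shared with the assignment")
  universe <- unique(lab$molecule_id)
  cl_of <- assignment$cluster[match(universe, assignment$molecule_id)]
  grid <- tidyr::expand_grid(cluster = sort(unique(lab$cluster)),
                             category = sort(unique(lab$category)))
  cells <- purrr::pmap(grid, function(cluster, category) {
    in_cat <- universe %in% lab$molecule_id[lab$category == category]
    in_cl <- cl_of == cluster
    c(a = sum(in_cl & in_cat), b = sum(in_cl & !in_cat),
      c = sum(!in_cl & in_cat), d = sum(!in_cl & !in_cat))
  })
  cm <- do.call(rbind, cells)
  ft <- fisher_test(cm[, "a"], cm[, "b"], cm[, "c"], cm[, "d"])
  out <- dplyr::bind_cols(grid, ft)
  out$q_value <- storey_qvalues(out$p_value)
  out$significant <- out$q_value < fdr_threshold
  out
}
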