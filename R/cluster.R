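#' Assemble the fibre autocorrelogram matrix
#'
#' Builds the molecules-by-lags matrix used for oligonucleosome-pattern
#' clustering. Molecules shorter than `min_len` are excluded (and counted);
#' autocorrelograms are truncated to the lag range guaranteed to exist for
#' every included molecule (`floor(min_len / 2)` lags, 250 by default).
#' Residual missing lags are imputed by the row mean.
#'
#' @param acgs Autocorrelogram tibble from [autocorrelograms()].
#' @param min_len Minimum molecule length in bp (default 500).
#' @param min_molecules Minimum number of eligible molecules (default 50).
#' @return A numeric matrix with rownames = molecule ids and
#'   `attr(, "n_excluded")` recording the short-molecule count.
#' @export
build_matrix <- function(acgs, min_len = 500L, min_molecules = 50L) {
  n_lags <- min_len %/% 2L
  keep <- acgs$length >= min_len
  n_excl <- sum(!keep)
  if (n_excl > 0) message(n_excl, " molecule(s) below ", min_len, " bp excluded")
  acgs <- acgs[keep, ]
  if (nrow(acgs) < min_molecules) {
    stop("too few molecules for graph clustering (", nrow(acgs), " < ",
         min_molecules, ")", call. = FALSE)
  }
  m <- t(vapply(acgs$acg, function(v) v[seq_len(n_lags)], numeric(n_lags)))
  rownames(m) <- acgs$molecule_id
  # impute residual missing lags with the row mean
  na_idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(na_idx)) {
    rm_ <- rowMeans(m, na.rm = TRUE)
    m[na_idx] <- rm_[na_idx[, 1]]
  }
  attr(m, "n_excluded") <- n_excl
  m
}

#' Leiden clustering of fibre representations
#'
#' Builds a k-nearest-neighbour graph (Euclidean) over the rows of the
#' matrix and partitions it with Leiden community detection under the
#' modularity objective. Clusters are relabeled in decreasing size order
#' (cluster 1 is the largest); clusters smaller than `small_cluster`
#' molecules are flagged rather than merged.
#'
#' @param m Numeric matrix (rows = molecules), e.g. from [build_matrix()].
#' @param k_neighbors Neighbours per molecule in the kNN graph (default 15).
#' @param resolution Leiden resolution parameter (default 1).
#' @param seed Integer seed (partitioning is seeded and reproducible).
#' @param small_cluster Flag clusters smaller than this (default 100).
#' @return Tibble: `molecule_id`, `cluster` (contiguous integers, largest
#'   first), `small_cluster` flag; clustering parameters in
#'   `attr(, "parameters")`.
#' @export
leiden_cluster <- function(m, k_neighbors = 15L, resolution = 1,
                           seed = 1L, small_cluster = 100L) {
  n <- nrow(m)
  assert_that(k_neighbors < n, "k_neighbors must be smaller than the number of molecules")
  assert_that(all(is.finite(m)), "matrix must be finite (impute first)")
  d <- as.matrix(stats::dist(m))
  if (max(d) == 0) {     # all rows identical: one community by definition
    out <- tibble::tibble(molecule_id = rownames(m), cluster = 1L,
                          small_cluster = n < small_cluster)
    attr(out, "parameters") <- list(k_neighbors = k_neighbors,
                                    resolution = resolution, seed = seed)
    return(out)
  }
  diag(d) <- Inf
  nbr <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))
  edges <- cbind(rep(seq_len(n), each = k_neighbors), as.vector(t(nbr)))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  memb <- withr::with_seed(as.integer(seed), {
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution, n_iterations = 5L
    ))
  })
  # contiguous labels, largest cluster first
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  cl <- unname(relabel[as.character(memb)])
  out <- tibble::tibble(
    molecule_id = rownames(m),
    cluster = as.integer(cl),
    small_cluster = as.integer(table(cl)[as.character(cl)]) < small_cluster
  )
  attr(out, "parameters") <- list(k_neighbors = k_neighbors,
                                  resolution = resolution, seed = seed)
  out
}

#' Per-cluster oligonucleosome summaries
#'
#' For each cluster: size and size fraction, median and MAD of the
#' single-molecule NRL estimates, the fraction of molecules where no
#' autocorrelogram peak was found, the mean modification profile over the
#' 5' `profile_len` bp (missing-aware column means), and the mean
#' autocorrelogram.
#'
#' @param assignment Tibble from [leiden_cluster()].
#' @param nrl_calls Optional tibble from [find_nrl_peak()].
#' @param tracks Optional track tibble for modification profiles.
#' @param acgs Optional autocorrelogram tibble for mean autocorrelograms.
#' @param profile_len Profile length in bp (default 1000).
#' @return Tibble, one row per cluster, with list-columns `profile` and
#'   `mean_acg` when the corresponding inputs are supplied.
#' @export
summarize_clusters <- function(assignment, nrl_calls = NULL, tracks = NULL,
                               acgs = NULL, profile_len = 1000L) {
  out <- assignment |>
    dplyr::count(.data$cluster, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::arrange(.data$cluster)
  if (!is.null(nrl_calls)) {
    nr <- dplyr::inner_join(assignment, nrl_calls, by = "molecule_id") |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(
        median_nrl = median(.data$nrl_lag[.data$peak_found]),
        nrl_mad = mad(.data$nrl_lag[.data$peak_found]),
        frac_no_peak = mean(!.data$peak_found),
        .groups = "drop"
      )
    out <- dplyr::left_join(out, nr, by = "cluster")
  }
  if (!is.null(tracks)) {
    pr <- dplyr::inner_join(assignment, tracks, by = "molecule_id") |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(
        profile = list(mean_profile(.data$prob, profile_len)),
        .groups = "drop"
      )
    out <- dplyr::left_join(out, pr, by = "cluster")
  }
  if (!is.null(acgs)) {
    ac <- dplyr::inner_join(assignment, acgs, by = "molecule_id") |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(
        mean_acg = list(mean_profile(.data$acg, max(lengths(.data$acg)))),
        .groups = "drop"
      )
    out <- dplyr::left_join(out, ac, by = "cluster")
  }
  out
}

# missing-aware column mean over ragged per-molecule vectors, padded /
# truncated to len
mean_profile <- function(vectors, len) {
  acc <- numeric(len)
  cnt <- numeric(len)
  for (v in vectors) {
    k <- min(length(v), len)
    if (k == 0) next
    vv <- v[seq_len(k)]
    ok <- !is.na(vv)
    acc[seq_len(k)][ok] <- acc[seq_len(k)][ok] + vv[ok]
    cnt[seq_len(k)][ok] <- cnt[seq_len(k)][ok] + 1
  }
  ifelse(cnt > 0, acc / cnt, NA_real_)
}

#' Choose a Leiden resolution by the small-cluster criterion
#'
#' Scans candidate resolutions from high to low and returns the partition
#' from the first (largest) resolution whose clusters all reach
#' `small_cluster` molecules — the same criterion used when tuning by hand
#' to avoid many very small clusters. Falls back to the smallest candidate
#' if none qualifies.
#'
#' @param m Matrix as for [leiden_cluster()].
#' @param resolutions Candidate resolutions, scanned in decreasing order.
#' @param k_neighbors,seed,small_cluster See [leiden_cluster()].
#' @return The chosen [leiden_cluster()] assignment (its `parameters`
#'   attribute records the selected resolution).
#' @export
tune_resolution <- function(m, resolutions = c(1, 0.8, 0.6, 0.4, 0.25, 0.1),
                            k_neighbors = 15L, seed = 1L,
                            small_cluster = 100L) {
  resolutions <- sort(resolutions, decreasing = TRUE)
  last <- NULL
  for (r in resolutions) {
    last <- leiden_cluster(m, k_neighbors = k_neighbors, resolution = r,
                           seed = seed, small_cluster = small_cluster)
    if (!any(last$small_cluster)) return(last)
  }
  message("all candidate resolutions leave small clusters; using the smallest")
  last
}
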