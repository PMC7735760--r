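#' Missing-aware centered rolling mean
#'
#' Centered mean over the available (non-missing) values in an odd window;
#' positions where fewer than `min_count` values are observed are missing.
#' Output length equals input length.
#'
#' @param x Numeric vector (NA = missing).
#' @param window Odd positive integer window width.
#' @param min_count Minimum observed values per window (default 1).
#' @return Numeric vector of the same length as `x`.
#' @export
rolling_mean_nan <- function(x, window, min_count = 1L) {
  assert_that(window >= 1 && window %% 2 == 1, "window must be an odd positive integer")
  L <- length(x)
  if (window > L) {
    warning("window longer than track; returning all-missing")
    return(rep(NA_real_, L))
  }
  h <- (window - 1L) %/% 2L
  obs <- !is.na(x)
  v <- ifelse(obs, x, 0)
  cs <- c(0, cumsum(v))
  cn <- c(0L, cumsum(obs))
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  s <- cs[hi + 1L] - cs[lo]
  n <- cn[hi + 1L] - cn[lo]
  out <- ifelse(n >= min_count & n > 0, s / n, NA_real_)
  out
}

#' Smooth modification tracks
#'
#' Applies the missing-aware rolling mean to each molecule's posterior
#' track: 5 bp for in vitro dyad calling, 33 bp for in vivo
#' autocorrelogram work.
#'
#' @param tracks Track tibble from [call_sample()].
#' @param window Odd smoothing window in bp.
#' @param min_count Minimum observations per window.
#' @return The track tibble with `prob` smoothed.
#' @export
smooth_tracks <- function(tracks, window = 33L, min_count = 1L) {
  dplyr::mutate(tracks,
                prob = purrr::map(.data$prob, rolling_mean_nan,
                                  window = window, min_count = min_count))
}

# local minima of a numeric vector, plateaus collapsed to their leftmost
# index; NAs break the sequence
local_minima <- function(s) {
  ok <- which(!is.na(s))
  if (length(ok) < 3) return(integer(0))
  mins <- integer(0)
  r <- rle(s[ok])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  if (nr >= 3) {
    for (j in 2:(nr - 1L)) {
      if (r$values[j] < r$values[j - 1L] && r$values[j] < r$values[j + 1L]) {
        mins <- c(mins, ok[starts[j]])   # leftmost index of the plateau
      }
    }
  }
  mins
}

#' Call nucleosome dyads on a modification track
#'
#' Takes a wide (default 133 bp) rolling mean across each molecule's track
#' and calls local minima as dyads: candidate minima are accepted greedily
#' in increasing order of smoothed value (deepest first, leftmost on ties)
#' subject to a minimum pairwise separation (default 147 bp, one
#' nucleosome footprint). Minima within `edge_margin` of either molecule
#' end are excluded. Positions are 0-based molecule coordinates.
#'
#' Valleys shallower than `min_depth` (depth = drop from the lower of the
#' two flanking barriers to the valley bottom) or whose bottom sits above
#' `max_level` are discarded, which suppresses noise minima in long
#' nucleosome-free stretches. Accepted
#' valleys are localized by half-depth centring: the dyad is the midpoint
#' of the interval where the smoothed track stays below
#' `bottom + 0.5 * depth`, which is much more stable than the raw argmin
#' on flat-bottomed valleys (the `window`-bp mean is nearly constant while
#' the window sits inside a footprint).
#'
#' @param tracks Track tibble (typically 5-bp pre-smoothed for in vitro
#'   arrays; see [smooth_tracks()]).
#' @param window Rolling-mean width for the dyad valley detector (odd).
#' @param min_separation Minimum distance between called dyads in bp.
#' @param edge_margin Exclusion zone at molecule ends in bp (half a
#'   footprint by default).
#' @param min_depth Minimum valley depth in posterior units (default 0.05).
#' @param max_level Maximum smoothed posterior at the valley bottom
#'   (default 0.5): at a true dyad the `window`-bp mean lies inside the
#'   147-bp footprint, so the window must be on balance protected; noise
#'   dips in accessible DNA sit well above this and are rejected.
#' @param refine Use half-depth valley centring (default TRUE); FALSE
#'   reports the raw local minimum.
#' @return Tibble: `molecule_id`, `n_dyads`, list-columns `dyads` and
#'   `pairwise_nrls`, and `averaged_nrl` (`(last - first)/(n - 1)`; NA with
#'   fewer than 2 dyads).
#' @export
call_dyads <- function(tracks, window = 133L, min_separation = 147L,
                       edge_margin = 73L, min_depth = 0.05, max_level = 0.5,
                       refine = TRUE) {
  res <- purrr::map(tracks$prob, function(p) {
    L <- length(p)
    if (L < window) return(integer(0))
    # quantize so exact plateaus survive cumsum floating-point dust
    s <- round(rolling_mean_nan(p, window), 9L)
    cand <- local_minima(s)
    pos0 <- cand - 1L
    keep <- pos0 >= edge_margin & pos0 <= (L - 1L - edge_margin)
    cand <- cand[keep]
    if (!length(cand)) return(integer(0))
    depth <- vapply(cand, valley_depth, numeric(1), s = s)
    cand <- cand[depth >= min_depth & s[cand] <= max_level]
    if (!length(cand)) return(integer(0))
    cand <- cand[order(s[cand], cand)]   # deepest first, leftmost tie-break
    accepted <- integer(0)
    for (i in cand) {
      if (!length(accepted) || all(abs(i - accepted) >= min_separation)) {
        accepted <- c(accepted, i)
      }
    }
    if (refine) accepted <- vapply(accepted, valley_center, numeric(1), s = s)
    sort(round(accepted)) - 1L
  })
  nrl <- purrr::map(res, nrl_from_dyads)
  tibble::tibble(
    molecule_id = tracks$molecule_id,
    n_dyads = lengths(res),
    dyads = res,
    pairwise_nrls = purrr::map(nrl, "pairwise"),
    averaged_nrl = purrr::map_dbl(nrl, "averaged")
  )
}

# local geometry of the valley at index i: its bottom plateau [pl, pr] and
# the lower of the two flanking barrier tops. The climb stops at any point
# at or below the bottom (the next, deeper valley) or after `bound` steps,
# so a shallower neighbouring valley cannot contribute its far wall.
valley_local <- function(i, s, bound = 147L) {
  v <- s[i]
  L <- length(s)
  pl <- i
  while (pl > 1L && !is.na(s[pl - 1L]) && s[pl - 1L] == v) pl <- pl - 1L
  pr <- i
  while (pr < L && !is.na(s[pr + 1L]) && s[pr + 1L] == v) pr <- pr + 1L
  climb <- function(from, step) {
    top <- v
    j <- from
    steps <- 0L
    while (j >= 1L && j <= L && steps < bound && !is.na(s[j]) && s[j] > v) {
      top <- max(top, s[j])
      j <- j + step
      steps <- steps + 1L
    }
    top
  }
  list(v = v, pl = pl, pr = pr,
       top = min(climb(pl - 1L, -1L), climb(pr + 1L, 1L)))
}

# depth of the valley below the lower of its local flanking barriers
valley_depth <- function(i, s, bound = 147L) {
  loc <- valley_local(i, s, bound)
  loc$top - loc$v
}

# half-depth centring: midpoint of the interval where s stays below
# bottom + depth / 2 (bounded by the local barriers by construction)
valley_center <- function(i, s, bound = 147L) {
  loc <- valley_local(i, s, bound)
  thr <- loc$v + (loc$top - loc$v) / 2
  if (thr <= loc$v) return((loc$pl + loc$pr) / 2)
  l <- loc$pl
  while (l > 1L && !is.na(s[l - 1L]) && s[l - 1L] < thr) l <- l - 1L
  r <- loc$pr
  while (r < length(s) && !is.na(s[r + 1L]) && s[r + 1L] < thr) r <- r + 1L
  (l + r) / 2
}

#' Nucleosome repeat lengths from a dyad call set
#'
#' Pairwise NRLs are the successive differences between adjacent dyads; the
#' averaged single-molecule NRL is `(last - first) / (n - 1)`. Both are
#' missing with fewer than two dyads.
#'
#' @param dyads Integer vector of strictly increasing dyad positions.
#' @return List with `pairwise` (integer vector) and `averaged` (scalar).
#' @export
nrl_from_dyads <- function(dyads) {
  if (length(dyads) < 2) {
    return(list(pairwise = integer(0), averaged = NA_real_))
  }
  list(pairwise = diff(dyads),
       averaged = (dyads[length(dyads)] - dyads[1]) / (length(dyads) - 1))
}

#' Single-molecule autocorrelogram
#'
#' Pearson correlation between the track and its lagged copy for lags
#' `0 .. floor(L/2) - 1`, using only positions where both copies are
#' observed (regions with unequal compared lengths are ignored), so the
#' result has exactly half the input length. Lags with fewer than `min_n`
#' overlapping observations are missing.
#'
#' @param x Numeric vector (a smoothed modification track; NA = missing).
#' @param min_n Minimum overlapping observations per lag (default 10).
#' @return List with `values` (length `floor(L/2)`) and `n_used`.
#' @export
autocorrelogram <- function(x, min_n = 10L) {
  L <- length(x)
  assert_that(L >= 4, "track too short for an autocorrelogram")
  obs <- x[!is.na(x)]
  if (length(obs) == 0 || stats::var(obs) == 0) {
    stop("constant track: autocorrelogram undefined", call. = FALSE)
  }
  .acf_nan(as.numeric(x), L %/% 2L, as.integer(min_n))
}

#' Autocorrelograms for a set of tracks
#'
#' Smooths each molecule's posterior track (33-bp rolling mean by default),
#' optionally truncates to the first `max_len` bp, and computes the
#' single-molecule autocorrelogram. Molecules whose smoothed track is
#' constant or too short are dropped with a message.
#'
#' @param tracks Track tibble from [call_sample()].
#' @param smooth_window Odd rolling-mean width (NULL to skip smoothing).
#' @param max_len Use at most the first `max_len` bp of each molecule
#'   (default 1000, matching the clustering representation).
#' @param min_n Minimum overlap per lag.
#' @return Tibble: `molecule_id`, `length` (track length used), list-columns
#'   `acg` and `n_used`.
#' @export
autocorrelograms <- function(tracks, smooth_window = 33L, max_len = 1000L,
                             min_n = 10L) {
  res <- purrr::map(tracks$prob, function(p) {
    if (length(p) > max_len) p <- p[seq_len(max_len)]
    if (!is.null(smooth_window)) p <- rolling_mean_nan(p, smooth_window)
    if (length(p) < 4) return(NULL)
    obs <- p[!is.na(p)]
    if (length(obs) == 0 || stats::var(obs) == 0) return(NULL)
    c(autocorrelogram_raw(p, min_n), list(length = length(p)))
  })
  keep <- !purrr::map_lgl(res, is.null)
  if (any(!keep)) message(sum(!keep), " constant/short molecule(s) dropped")
  tibble::tibble(
    molecule_id = tracks$molecule_id[keep],
    length = purrr::map_int(res[keep], "length"),
    acg = purrr::map(res[keep], "values"),
    n_used = purrr::map(res[keep], "n_used")
  )
}

autocorrelogram_raw <- function(x, min_n = 10L) {
  .acf_nan(as.numeric(x), length(x) %/% 2L, as.integer(min_n))
}

#' Find the NRL peak in a single-molecule autocorrelogram
#'
#' Scans the autocorrelogram for the first (smallest-lag) local maximum
#' within `lag_range` whose prominence (height above the higher of the two
#' flanking key minima) exceeds `prominence`. Molecules without such a peak
#' get `peak_found = FALSE`, never an error; the fraction of such
#' peak-missing molecules is itself informative (irregular fibres fail more
#' often).
#'
#' @param acgs Autocorrelogram tibble from [autocorrelograms()], or a bare
#'   numeric vector.
#' @param lag_range Inclusive lag search range in bp (default c(120, 350)).
#' @param prominence Minimum peak prominence (default 0.03).
#' @return Tibble: `molecule_id`, `nrl_lag` (bp, NA when no peak),
#'   `peak_found`.
#' @export
find_nrl_peak <- function(acgs, lag_range = c(120L, 350L), prominence = 0.03) {
  if (is.numeric(acgs)) {
    acgs <- tibble::tibble(molecule_id = "track", acg = list(acgs))
  }
  hits <- purrr::map_int(acgs$acg, peak_scan,
                         lag_range = lag_range, prominence = prominence)
  tibble::tibble(
    molecule_id = acgs$molecule_id,
    nrl_lag = ifelse(hits < 0L, NA_integer_, hits),
    peak_found = hits >= 0L
  )
}

peak_scan <- function(v, lag_range, prominence) {
  L <- length(v)
  if (L < 3) return(-1L)
  for (i in 2:(L - 1L)) {
    lag <- i - 1L            # values are indexed by lag 0..L-1
    if (lag < lag_range[1]) next
    if (lag > lag_range[2]) break
    vi <- v[i]
    if (is.na(vi)) next
    lft <- v[i - 1L]; rgt <- v[i + 1L]
    if (is.na(lft) || is.na(rgt)) next
    if (!(vi > lft && vi >= rgt)) next
    # prominence: walk out until a higher point (or the end), track minima
    jmin <- vi
    j <- i - 1L
    while (j >= 1L && !is.na(v[j]) && v[j] <= vi) {
      jmin <- min(jmin, v[j]); j <- j - 1L
    }
    left_base <- jmin
    kmin <- vi
    k <- i + 1L
    while (k <= L && !is.na(v[k]) && v[k] <= vi) {
      kmin <- min(kmin, v[k]); k <- k + 1L
    }
    right_base <- kmin
    if (vi - max(left_base, right_base) >= prominence) return(lag)
  }
  -1L
}
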