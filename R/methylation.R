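#' Normalize per-base IPDs within each molecule
#'
#' Raw IPDs are transformed as `log2(ipd + pseudocount)` and robustly
#' z-scored within each molecule (median / scaled MAD), removing
#' per-molecule polymerase-speed effects. Interpulse durations are
#' modelled as log-normal within each methylation class, so the mixture is
#' fit on the log scale; the small pseudocount only guards zero IPDs. By default the centre and scale are estimated
#' from the molecule's observed G/C positions: G/C bases cannot carry the
#' m6dA mark, so this baseline preserves genuine between-molecule (and
#' between-sample) methylation-level differences that an A/T-based centre
#' would cancel. With `reference_bases = "AT"` the statistics are computed
#' over the scored A/T positions instead. Normalized values are reported
#' at observed A/T positions; all others are `NA`. Molecules with fewer
#' than `min_obs` observed scored positions, too few reference
#' observations, or no usable spread are flagged and excluded by
#' downstream fitting.
#'
#' @param molecules Molecules tibble ([read_kinetics()] layout).
#' @param min_obs Minimum observed A/T IPD count per molecule (default 20).
#' @param bases_scored `"AT"` (default: both strands' adenine signal) or
#'   `"T"` to score template thymines only.
#' @param reference_bases `"GC"` (default) to estimate the per-molecule
#'   baseline from G/C positions, or `"AT"` to use the scored positions
#'   themselves (falls back to the scored positions when fewer than
#'   `min_obs` reference observations exist).
#' @param pseudocount Offset added to IPDs before taking log2 (default
#'   0.01, small against typical IPDs of order 1).
#' @return Tibble: `molecule_id`, list-column `z`, `n_obs`, `flagged`.
#' @export
normalize_ipd <- function(molecules, min_obs = 20L, bases_scored = c("AT", "T"),
                          reference_bases = c("GC", "AT"),
                          pseudocount = 0.01) {
  bases_scored <- match.arg(bases_scored)
  reference_bases <- match.arg(reference_bases)
  keep <- if (bases_scored == "AT") c("A", "T") else "T"
  res <- purrr::map2(molecules$bases, molecules$ipd, function(b, ipd) {
    bb <- strsplit(b, "", fixed = TRUE)[[1]]
    at <- bb %in% keep
    z <- rep(NA_real_, length(bb))
    obs <- at & !is.na(ipd)
    n <- sum(obs)
    if (n < min_obs) return(list(z = z, n = n, flagged = TRUE))
    ref <- obs
    if (reference_bases == "GC") {
      gc <- bb %in% c("G", "C") & !is.na(ipd)
      if (sum(gc) >= min_obs) ref <- gc
    }
    lg_ref <- log2(ipd[ref] + pseudocount)
    ctr <- median(lg_ref)
    scale <- mad(lg_ref, center = ctr)   # 1.4826 * raw MAD
    if (scale == 0) scale <- sd(lg_ref)
    if (is.na(scale) || scale == 0) return(list(z = z, n = n, flagged = TRUE))
    z[obs] <- (log2(ipd[obs] + pseudocount) - ctr) / scale
    list(z = z, n = n, flagged = FALSE)
  })
  out <- tibble::tibble(
    molecule_id = molecules$molecule_id,
    z = purrr::map(res, "z"),
    n_obs = purrr::map_int(res, "n"),
    flagged = purrr::map_lgl(res, "flagged")
  )
  if (any(out$flagged)) {
    message(sum(out$flagged), " molecule(s) flagged low-information")
  }
  out
}

#' Fit a two-component Gaussian mixture to normalized IPDs
#'
#' Expectation-maximization on values pooled across molecules. Component 1
#' is the methylated (higher-mean) component, enforced by relabeling.
#' Initialization is deterministic (quantile-based), the log-likelihood is
#' non-decreasing over iterations, variances are floored at `var_floor`,
#' and a fit whose smaller component weight drops below `min_weight` is
#' flagged as effectively single-component.
#'
#' @param z Numeric vector of pooled normalized IPDs (NAs dropped), or a
#'   normalized-track tibble from [normalize_ipd()] (unflagged molecules
#'   pooled).
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the change in mean log-likelihood
#'   (per observation) between iterations.
#' @param min_n Minimum number of finite values required (default 1000).
#' @param var_floor Variance floor (default 1e-3).
#' @param min_weight Below this weight the fit is flagged degenerate.
#' @param seed Seed (the fit is deterministic; kept for interface stability
#'   with subsampling workflows).
#' @param subsample Optional cap on the number of pooled values used
#'   (seeded subsample) to bound fitting cost; NULL uses all values.
#' @return A `samosa_mixture` object with fields `w0, w1, mu0, mu1, sd0,
#'   sd1`, the log-likelihood trace, and convergence flags. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
fit_mixture <- function(z, max_iter = 200L, tol = 1e-6, min_n = 1000L,
                        var_floor = 1e-3, min_weight = 0.02, seed = 1L,
                        subsample = NULL) {
  if (is.data.frame(z)) {
    z <- unlist(z$z[!z$flagged], use.names = FALSE)
  }
  x <- z[is.finite(z)]
  assert_that(length(x) >= min_n,
              sprintf("need >= %d finite values to fit the mixture", min_n))
  if (!is.null(subsample) && length(x) > subsample) {
    x <- with_seed_if(seed, sample(x, subsample))
  }
  # deterministic quantile init: lower/upper quartiles as component means
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  mu <- c(q[1], q[2])
  if (mu[1] == mu[2]) mu <- mu + c(-0.5, 0.5)
  s2 <- rep(max(stats::var(x) / 2, var_floor), 2)
  w <- c(0.5, 0.5)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iters <- 0L
  if (max_iter > 0) {
    for (it in seq_len(max_iter)) {
      l0 <- log(w[1]) + dnorm(x, mu[1], sqrt(s2[1]), log = TRUE)
      l1 <- log(w[2]) + dnorm(x, mu[2], sqrt(s2[2]), log = TRUE)
      m <- pmax(l0, l1)
      lse <- m + log(exp(l0 - m) + exp(l1 - m))
      ll <- sum(lse)
      ll_trace <- c(ll_trace, ll)
      r1 <- exp(l1 - lse)
      n1 <- sum(r1); n0 <- length(x) - n1
      w <- c(n0, n1) / length(x)
      mu <- c(sum((1 - r1) * x) / n0, sum(r1 * x) / n1)
      s2 <- c(sum((1 - r1) * (x - mu[1])^2) / n0,
              sum(r1 * (x - mu[2])^2) / n1)
      if (any(s2 < var_floor)) {
        warning("variance floor applied to a mixture component")
        s2 <- pmax(s2, var_floor)
      }
      iters <- it
      if (is.finite(ll_old) && abs(ll - ll_old) / length(x) < tol) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
  }
  if (mu[1] > mu[2]) {    # relabel: component 1 = methylated = higher mean
    mu <- rev(mu); s2 <- rev(s2); w <- rev(w)
  }
  degenerate <- min(w) < min_weight
  if (degenerate) message("mixture fit is near single-component (min weight ",
                          signif(min(w), 3), ")")
  structure(
    list(w0 = w[1], w1 = w[2], mu0 = mu[1], mu1 = mu[2],
         sd0 = sqrt(s2[1]), sd1 = sqrt(s2[2]),
         loglik = ll_trace, n = length(x), iterations = iters,
         converged = converged, degenerate = degenerate),
    class = "samosa_mixture"
  )
}

#' @export
print.samosa_mixture <- function(x, ...) {
  cat(sprintf(paste0(
    "<samosa_mixture: unmethylated N(%.3f, %.3f) w=%.3f | ",
    "methylated N(%.3f, %.3f) w=%.3f; n=%d, %d EM iterations%s>\n"),
    x$mu0, x$sd0, x$w0, x$mu1, x$sd1, x$w1, x$n, x$iterations,
    if (x$converged) ", converged" else ""))
  invisible(x)
}

#' @export
tidy.samosa_mixture <- function(x, ...) {
  tibble::tibble(
    component = c("unmethylated", "methylated"),
    weight = c(x$w0, x$w1), mean = c(x$mu0, x$mu1), sd = c(x$sd0, x$sd1)
  )
}

#' @export
glance.samosa_mixture <- function(x, ...) {
  tibble::tibble(
    n = x$n, iterations = x$iterations,
    logLik = if (length(x$loglik)) tail(x$loglik, 1) else NA_real_,
    converged = x$converged, degenerate = x$degenerate
  )
}

#' Serialize / restore a mixture model as JSON
#'
#' @param model A `samosa_mixture`.
#' @param path JSON file path.
#' @return `write_mixture()` returns `path` invisibly; `read_mixture()` the
#'   model.
#' @export
write_mixture <- function(model, path) {
  jsonlite::write_json(
    model[c("w0", "w1", "mu0", "mu1", "sd0", "sd1")],
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_mixture
#' @export
read_mixture <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(w0 = m$w0, w1 = m$w1, mu0 = m$mu0, mu1 = m$mu1,
         sd0 = m$sd0, sd1 = m$sd1, loglik = numeric(0),
         n = NA_integer_, iterations = NA_integer_,
         converged = NA, degenerate = NA),
    class = "samosa_mixture"
  )
}

#' Posterior probability of methylation given a normalized IPD
#'
#' `p = w1 phi(z; mu1, sd1) / (w0 phi(z; mu0, sd0) + w1 phi(z; mu1, sd1))`,
#' computed on the log scale so extreme values do not underflow; where both
#' densities underflow entirely the nearest-mean rule applies.
#'
#' @param model A `samosa_mixture`.
#' @param z Numeric vector of normalized IPDs (NA propagated).
#' @return Posterior probabilities in \[0, 1\].
#' @export
posterior_prob <- function(model, z) {
  stopifnot(inherits(model, "samosa_mixture"))
  l0 <- log(model$w0) + dnorm(z, model$mu0, model$sd0, log = TRUE)
  l1 <- log(model$w1) + dnorm(z, model$mu1, model$sd1, log = TRUE)
  p <- 1 / (1 + exp(l0 - l1))
  und <- is.finite(z) & !is.finite(l0 - l1)   # both components underflow
  if (any(und)) {
    p[und] <- as.numeric(abs(z[und] - model$mu1) < abs(z[und] - model$mu0))
  }
  p
}

#' Call per-molecule modification tracks
#'
#' Normalizes each molecule and converts its A/T IPDs into posterior
#' methylation probabilities under the fitted mixture. Flagged
#' (low-information) molecules are dropped with a message. The returned
#' track tibble carries the molecules' reference placement so downstream
#' feature-centric operations need no extra join.
#'
#' @param molecules Molecules tibble.
#' @param model A `samosa_mixture` from [fit_mixture()].
#' @param normalized Optional precomputed output of [normalize_ipd()].
#' @param per_molecule If TRUE, refit the mixture within each molecule
#'   (needs many observed A/T positions per molecule); default uses the
#'   single sample-level model.
#' @param ... Passed to [normalize_ipd()].
#' @return Track tibble: `molecule_id`, placement columns, list-column
#'   `prob` (NA at non-A/T and unobserved positions).
#' @export
call_sample <- function(molecules, model, normalized = NULL,
                        per_molecule = FALSE, ...) {
  if (is.null(normalized)) normalized <- normalize_ipd(molecules, ...)
  df <- dplyr::inner_join(
    molecules[, c("molecule_id", "ref_name", "ref_start", "ref_end", "strand")],
    normalized, by = "molecule_id"
  )
  dropped <- sum(df$flagged)
  if (dropped > 0) message(dropped, " flagged molecule(s) excluded from calling")
  df <- df[!df$flagged, ]
  prob <- purrr::map(df$z, function(z) {
    m <- model
    if (per_molecule) {
      zz <- z[is.finite(z)]
      if (length(zz) >= 200) {
        m <- fit_mixture(zz, min_n = 200L)
      }
    }
    posterior_prob(m, z)
  })
  tibble::tibble(
    molecule_id = df$molecule_id, ref_name = df$ref_name,
    ref_start = df$ref_start, ref_end = df$ref_end, strand = df$strand,
    prob = prob
  )
}

#' Sequence-context profile of normalized IPDs
#'
#' Bins observed A/T positions by their k-mer context (`n5` bases 5' and
#' `n3` bases 3' of the template base) and summarizes the normalized IPD in
#' each context. Contexts truncated at molecule ends are skipped. Rows are
#' sorted by mean normalized IPD.
#'
#' @param molecules Molecules tibble.
#' @param n5,n3 Context window half-widths (defaults 2 and 5: an 8-mer).
#' @param normalized Optional precomputed [normalize_ipd()] output.
#' @param breaks Histogram breaks for the per-context z histograms.
#' @return Tibble: `context`, `n`, `mean_z`, list-column `hist` (counts on
#'   `breaks`), sorted by `mean_z`.
#' @export
context_profile <- function(molecules, n5 = 2L, n3 = 5L, normalized = NULL,
                            breaks = seq(-6, 6, by = 0.25)) {
  if (is.null(normalized)) normalized <- normalize_ipd(molecules)
  df <- dplyr::inner_join(molecules[, c("molecule_id", "bases")],
                          normalized[!normalized$flagged, ],
                          by = "molecule_id")
  pieces <- purrr::map2(df$bases, df$z, function(b, z) {
    L <- nchar(b)
    idx <- which(!is.na(z))
    idx <- idx[idx > n5 & idx <= L - n3]
    if (!length(idx)) return(NULL)
    ctx <- stringr::str_sub(rep(b, length(idx)), idx - n5, idx + n3)
    tibble::tibble(context = ctx, z = z[idx])
  })
  all <- dplyr::bind_rows(pieces)
  if (nrow(all) == 0) {
    return(tibble::tibble(context = character(0), n = integer(0),
                          mean_z = numeric(0), hist = list()))
  }
  zc <- pmin(pmax(all$z, min(breaks)), max(breaks))
  out <- all |>
    dplyr::mutate(z_clamped = zc) |>
    dplyr::group_by(.data$context) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_z = mean(.data$z),
      hist = list(graphics::hist(.data$z_clamped, breaks = breaks,
                                 plot = FALSE)$counts),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mean_z)
  out
}
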