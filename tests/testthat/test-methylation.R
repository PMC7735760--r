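test_that("normalization matches the hand-computed robust z", {
  mol <- tibble::tibble(
    molecule_id = "m", ref_name = "m", ref_start = 0L, ref_end = 6L,
    strand = "+", bases = "AAAAAA", ipd = list(c(1, 1, 1, 3, 3, 3))
  )
  # log2(ipd + 1) = {1,1,1,2,2,2}: median 1.5, scaled MAD 0.5 * 1.4826
  norm <- normalize_ipd(mol, min_obs = 5L, reference_bases = "AT",
                        pseudocount = 1)
  expect_false(norm$flagged)
  expect_equal(norm$z[[1]], rep(c(-1, 1), each = 3) * 0.5 / (0.5 * 1.4826),
               tolerance = 1e-12)
  expect_equal(sum(norm$z[[1]]), 0)
})

test_that("G/C-referenced normalization preserves methylation level", {
  gc_ipd <- withr::with_seed(1L, rlnorm(200, 0, 0.5))
  mk <- function(id, a_ipd) tibble::tibble(
    molecule_id = id, ref_name = id, ref_start = 0L, ref_end = 400L,
    strand = "+",
    bases = paste(rep(c("A", "G"), 200), collapse = ""),
    ipd = list(as.vector(rbind(a_ipd, gc_ipd)))
  )
  hot <- mk("hot", withr::with_seed(2L, rlnorm(200, 1.1, 0.5)))
  cold <- mk("cold", withr::with_seed(3L, rlnorm(200, 0, 0.5)))
  norm <- normalize_ipd(dplyr::bind_rows(hot, cold))
  mean_z <- purrr::map_dbl(norm$z, mean, na.rm = TRUE)
  expect_gt(mean_z[1], mean_z[2] + 1)     # methylated molecule stands out
  expect_lt(abs(mean_z[2]), 0.5)          # unmethylated sits at baseline
})

test_that("degenerate and low-information molecules are flagged", {
  const <- tibble::tibble(
    molecule_id = "c", ref_name = "c", ref_start = 0L, ref_end = 100L,
    strand = "+", bases = paste(rep(c("A", "C"), 50), collapse = ""),
    ipd = list(rep(2, 100))
  )
  expect_true(suppressMessages(normalize_ipd(const))$flagged)

  few <- tibble::tibble(
    molecule_id = "f", ref_name = "f", ref_start = 0L, ref_end = 4L,
    strand = "+", bases = "ACGT", ipd = list(c(1, 2, 3, 4))
  )
  expect_true(suppressMessages(normalize_ipd(few))$flagged)
})

test_that("EM recovers planted mixture parameters and is monotone", {
  z <- withr::with_seed(100L, c(rnorm(25000, 0, 1), rnorm(25000, 3, 1)))
  fit <- fit_mixture(z)
  expect_lt(abs(fit$mu0 - 0), 0.05)
  expect_lt(abs(fit$mu1 - 3), 0.05)
  expect_lt(abs(fit$w0 - 0.5), 0.02)
  expect_lt(abs(fit$w1 - 0.5), 0.02)
  expect_lt(abs(fit$sd0 - 1), 0.05)
  expect_lt(abs(fit$sd1 - 1), 0.05)
  # log-likelihood never decreases across EM iterations
  expect_true(all(diff(fit$loglik) > -1e-6))
  expect_true(fit$converged)

  td <- tidy(fit)
  expect_equal(td$component, c("unmethylated", "methylated"))
  expect_equal(glance(fit)$n, 50000L)
})

test_that("EM respects iteration bounds and flags single-component data", {
  z <- withr::with_seed(101L, rnorm(5000))
  init <- fit_mixture(z, max_iter = 0L, tol = 0)
  expect_equal(init$iterations, 0L)
  expect_equal(c(init$w0, init$w1), c(0.5, 0.5))

  fit <- suppressMessages(suppressWarnings(fit_mixture(z)))
  # one true component: the fitted two-component mixture collapses onto the
  # single generating density (components overlap rather than separate)
  grid <- seq(-3, 3, by = 0.1)
  f_mix <- fit$w0 * dnorm(grid, fit$mu0, fit$sd0) +
    fit$w1 * dnorm(grid, fit$mu1, fit$sd1)
  expect_lt(max(abs(f_mix - dnorm(grid))), 0.03)
  p <- posterior_prob(fit, quantile(z, c(0.1, 0.5, 0.9)))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("posteriors follow the two-component Bayes rule", {
  m <- structure(list(w0 = 0.5, w1 = 0.5, mu0 = 0, mu1 = 2, sd0 = 1, sd1 = 1),
                 class = "samosa_mixture")
  expect_equal(posterior_prob(m, 1), 0.5)          # midpoint symmetry
  expect_equal(posterior_prob(m, 50), 1)           # limits
  expect_equal(posterior_prob(m, -50), 0)
  expect_true(is.na(posterior_prob(m, NA_real_)))

  m2 <- structure(list(w0 = 0.8, w1 = 0.2, mu0 = 0, mu1 = 2, sd0 = 1, sd1 = 1),
                  class = "samosa_mixture")
  z <- c(-1, 0.3, 1, 1.7, 4)
  direct <- 0.2 * dnorm(z, 2, 1) / (0.8 * dnorm(z, 0, 1) + 0.2 * dnorm(z, 2, 1))
  expect_equal(posterior_prob(m2, z), direct, tolerance = 1e-12)
})

test_that("sample-level posteriors separate methylated, chromatin and naked controls", {
  mk <- function(id, linker, occluded) {
    fibre_spec(id, "regular", nrl = 193L, n_nucleosomes = 9L,
               flank5 = 450L, flank3 = 46L, seq_mode = "array",
               linker_meth_prob = linker, occluded_meth_prob = occluded)
  }
  chrom <- call_pipeline(spec_601_array(), 80L, seed = 3L)
  meth <- quiet(simulate_sample(mk("meth", 0.95, 0.95), 80L, seed = 4L))
  unmeth <- quiet(simulate_sample(mk("unmeth", 0, 0), 80L, seed = 5L))
  mean_post <- function(mols) {
    tr <- quiet(call_sample(mols, chrom$mix))
    mean(purrr::map_dbl(tr$prob, mean, na.rm = TRUE))
  }
  p_meth <- mean_post(meth$molecules)
  p_chrom <- mean(purrr::map_dbl(chrom$tracks$prob, mean, na.rm = TRUE))
  p_unmeth <- mean_post(unmeth$molecules)
  expect_gt(p_meth, 0.7)
  expect_gt(p_meth, p_chrom + 0.15)
  expect_gt(p_chrom, p_unmeth + 0.15)
  expect_lt(p_unmeth, 0.25)

  expect_equal(nrow(quiet(call_sample(chrom$sim$molecules[0, ], chrom$mix))), 0L)
})

test_that("posteriors are roughly calibrated near the decision boundary", {
  pl <- call_pipeline(spec_601_array(), 100L, seed = 23L)
  truth <- pl$sim$truth
  meth <- truth$meth[match(pl$tracks$molecule_id, truth$molecule_id)]
  p <- unlist(pl$tracks$prob)
  m <- unlist(meth)
  band <- !is.na(p) & p >= 0.45 & p <= 0.55
  expect_gte(sum(band), 2000L)
  frac <- mean(m[band])
  expect_gte(frac, 0.35)
  expect_lte(frac, 0.65)
})

test_that("context profiles bin by k-mer and recover injected context effects", {
  mol <- tibble::tibble(
    molecule_id = "m", ref_name = "m", ref_start = 0L, ref_end = 10L,
    strand = "+", bases = "AAAAAAAAAA", ipd = list(rep(1, 10))
  )
  normed <- tibble::tibble(molecule_id = "m", z = list(rep(1.5, 10)),
                           n_obs = 10L, flagged = FALSE)
  prof <- context_profile(mol, normalized = normed)
  expect_equal(nrow(prof), 1L)                       # one 8-mer context
  expect_equal(prof$context, "AAAAAAAA")
  expect_equal(prof$n, 3L)                           # ends truncated
  expect_equal(prof$mean_z, 1.5)

  prof1 <- context_profile(mol, n5 = 0L, n3 = 0L, normalized = normed)
  expect_equal(prof1$context, "A")

  # injected per-context offsets are recovered in rank order (4-mer
  # contexts keep dozens of observations per context at this scale)
  model <- ipd_model(context_effect_sd = 0.4, missing_rate = 0,
                     n5 = 1L, n3 = 2L)
  naked <- fibre_spec("nk", "irregular", n_nucleosomes = 1L, footprint = 147L,
                      flank5 = 400L, flank3 = 400L, occluded_meth_prob = 0,
                      linker_meth_prob = 0)
  sim <- quiet(simulate_sample(naked, 150L, model = model, seed = 31L))
  prof2 <- quiet(context_profile(sim$molecules, n5 = 1L, n3 = 2L))
  codes <- function(ctx) {
    v <- match(strsplit(ctx, "")[[1]], c("A", "C", "G", "T")) - 1L
    sum(v * 4^(seq_along(v) - 1L)) + 1L
  }
  injected <- model$context_offsets[vapply(prof2$context,
                                           function(x) as.integer(codes(x)),
                                           integer(1))]
  keep <- prof2$n >= 20
  rc <- stats::cor(injected[keep], prof2$mean_z[keep], method = "spearman")
  expect_gt(rc, 0.9)
  # rows come out sorted by mean normalized IPD
  expect_true(!is.unsorted(prof2$mean_z))
})
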