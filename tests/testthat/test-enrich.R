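mols_tbl <- function(starts, ends, chrom = "chr1", strand = "+",
                     ids = sprintf("z%03d", seq_along(starts))) {
  tibble::tibble(molecule_id = ids, ref_name = chrom,
                 ref_start = as.integer(starts), ref_end = as.integer(ends),
                 strand = strand)
}

feat_tbl <- function(starts, ends, chrom = "chr1", name = "f", strand = ".") {
  tibble::tibble(chrom = chrom, start = as.integer(starts),
                 end = as.integer(ends), name = name, score = 0,
                 strand = strand)
}

test_that("molecule-to-feature assignment uses a closed 1-kb expansion", {
  mol <- mols_tbl(1000L, 2000L)
  expect_equal(nrow(assign_molecules(mol, feat_tbl(2500L, 2600L))), 1L)
  expect_equal(nrow(assign_molecules(mol, feat_tbl(3000L, 3100L))), 1L)  # gap 1000
  expect_equal(nrow(assign_molecules(mol, feat_tbl(3001L, 3100L))), 0L)  # gap 1001
  expect_warning(assign_molecules(mol, feat_tbl(10L, 20L, chrom = "chrX")),
                 "absent")
})

test_that("assignment agrees with the all-pairs overlap oracle", {
  withr::with_seed(61L, {
    mol <- mols_tbl(
      starts <- sample(0:50000, 300),
      starts + sample(200:2000, 300, replace = TRUE),
      chrom = sample(c("chr1", "chr2", "chr3"), 300, replace = TRUE)
    )
    fs <- sample(0:50000, 120)
    feats <- feat_tbl(fs, fs + sample(50:500, 120, replace = TRUE),
                      chrom = sample(c("chr1", "chr2"), 120, replace = TRUE),
                      name = sprintf("f%03d", seq_len(120)))
  })
  hits <- suppressWarnings(assign_molecules(mol, feats, max_dist = 1000L))
  oracle <- overlap_oracle(mol, feats, 1000L)
  got <- sort(paste(hits$molecule_id, hits$feature_name))
  want <- sort(paste(mol$molecule_id[oracle[, 1]],
                     feats$name[oracle[, 2]]))
  expect_equal(got, want)
})

test_that("motif windows are strand-aware mirrors with coverage filtering", {
  p <- seq(0, 1, length.out = 800)
  tr <- track_tbl(list(p), ids = "m1", ref_start = 0L)
  tr$ref_name <- "chr1"
  plus <- feat_tbl(395L, 405L, name = "TF", strand = "+")
  minus <- feat_tbl(395L, 405L, name = "TF", strand = "-")
  wp <- motif_windows(tr, plus)
  wm <- motif_windows(tr, minus)
  expect_length(wp$window[[1]], 500L)
  expect_equal(wm$window[[1]], rev(wp$window[[1]]))

  # a minus-strand *molecule* is first flipped into reference orientation
  trm <- tr; trm$strand <- "-"
  wpm <- motif_windows(trm, plus)
  expect_equal(wpm$window[[1]], rev(wp$window[[1]]))

  # motifs too close to the molecule edge are excluded and counted
  edge <- feat_tbl(195L, 205L, name = "TF", strand = "+")
  tr_short <- track_tbl(list(p[1:400]), ids = "m2", ref_start = 0L)
  tr_short$ref_name <- "chr1"
  we <- suppressWarnings(motif_windows(tr_short, edge))
  expect_equal(nrow(we), 0L)
  expect_equal(attr(we, "n_excluded"), 1L)
})

test_that("a planted accessible motif centre shows up in window means", {
  withr::with_seed(71L, {
    n <- 60L
    tracks <- track_tbl(purrr::map(seq_len(n), function(i) {
      v <- runif(700, 0, 0.3)
      v[301:400] <- runif(100, 0.7, 1)      # accessible centre at 300-400
      v
    }), ref_start = 0L)
    tracks$ref_name <- "chr1"
  })
  motif <- feat_tbl(348L, 352L, name = "TF", strand = "+")
  w <- motif_windows(tracks, motif)
  m <- do.call(rbind, w$window)
  cm <- colMeans(m)
  expect_gt(mean(cm[200:300]), mean(cm[1:100]) + 0.3)
  expect_equal(which.max(rolling_mean_nan(cm, 51L)) - 1L, 250L,
               tolerance = 10)
})

test_that("cut profiles count both fragment ends, strand-flipped", {
  mol <- mols_tbl(0L, 500L)
  prof <- cut_profile(mol, feat_tbl(245L, 255L, strand = "+"))
  expect_equal(prof$offset[prof$count > 0], c(-250L, 250L))
  expect_equal(sum(prof$count), 2L)
  expect_equal(max(prof$per_molecule), 1)

  asym <- mols_tbl(0L, 300L)
  pp <- cut_profile(asym, feat_tbl(245L, 255L, strand = "+"))
  pm <- cut_profile(asym, feat_tbl(245L, 255L, strand = "-"))
  expect_equal(pp$offset[pp$count > 0], c(-250L, 50L))
  expect_equal(pm$offset[pm$count > 0], c(-50L, 250L))

  none <- cut_profile(mols_tbl(9000L, 9100L), feat_tbl(245L, 255L))
  expect_true(all(none$count == 0L))
})

test_that("state clustering separates occluded from accessible windows", {
  withr::with_seed(81L, {
    acc <- purrr::map(1:120, function(i) {
      v <- runif(500, 0, 0.35)
      v[176:325] <- runif(150, 0.6, 1)
      v
    })
    occ <- purrr::map(1:120, function(i) runif(500, 0, 0.35))
  })
  windows <- tibble::tibble(
    molecule_id = sprintf("w%03d", 1:240),
    category = rep(c("TF", "control"), each = 120),
    chrom = "chr1", motif_mid = 1000L, motif_strand = "+",
    window = c(acc, occ)
  )
  st <- quiet(state_cluster(windows, resolution = 0.25, seed = 2L))
  truth <- rep(1:2, each = 120)
  expect_gte(ari(st$assignment$cluster, truth), 0.8)

  # control-only input: no cluster with an accessible centre profile
  ctrl <- windows[121:240, ]
  stc <- quiet(state_cluster(ctrl, resolution = 0.25, seed = 2L))
  centre <- purrr::map_dbl(stc$profiles$profile, ~ mean(.x[176:325]))
  expect_true(all(centre < 0.5))

  # identical windows collapse to a single state
  same <- windows
  same$window <- rep(list(rep(0.2, 500)), 240)
  sts <- quiet(state_cluster(same, seed = 2L))
  expect_equal(unique(sts$assignment$cluster), 1L)
})

test_that("Fisher tests match symmetry, enumeration and stats::fisher.test", {
  even <- fisher_test(10, 10, 10, 10)
  expect_equal(even$odds_ratio, 1)
  expect_equal(even$p_value, 1)

  sk <- fisher_test(8, 2, 2, 8)
  expect_equal(sk$odds_ratio, 16)
  expect_equal(sk$p_value, fisher_oracle(8, 2, 2, 8))
  expect_equal(sk$p_value, stats::fisher.test(matrix(c(8, 2, 2, 8), 2))$p.value)

  sep <- fisher_test(5, 0, 0, 5)
  expect_equal(sep$odds_ratio, Inf)
  expect_equal(sep$p_value, 2 / choose(10, 5))

  empty <- fisher_test(0, 0, 3, 4)
  expect_equal(empty$p_value, 1)
  expect_true(is.na(empty$odds_ratio))

  # random tables against both independent routes
  withr::with_seed(17L, {
    tb <- matrix(rpois(4 * 200, 6), ncol = 4)
  })
  got <- fisher_test(tb[, 1], tb[, 2], tb[, 3], tb[, 4])
  for (i in seq_len(nrow(tb))) {
    expect_equal(got$p_value[i], fisher_oracle(tb[i, 1], tb[i, 2],
                                               tb[i, 3], tb[i, 4]),
                 tolerance = 1e-12)
    expect_equal(got$p_value[i],
                 stats::fisher.test(matrix(tb[i, ], 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Storey q-values reduce to BH at pi0 = 1 and stay monotone", {
  expect_equal(suppressMessages(storey_qvalues(rep(1, 10))), rep(1, 10))

  withr::with_seed(41L, {
    p <- c(runif(150)^2, runif(150))        # some signal, some null
  })
  q1 <- storey_qvalues(p, pi0 = 1)
  expect_equal(q1, p.adjust(p, "BH"), tolerance = 1e-12)

  q <- storey_qvalues(p)
  expect_true(!is.unsorted(q[order(p)]))
  expect_true(all(q <= 1 & q >= 0))

  # uniform p-values: pi0 estimated near 1
  pu <- withr::with_seed(42L, runif(10000))
  qu <- storey_qvalues(pu)
  pi0_hat <- max(qu) / max(p.adjust(pu, "BH"))
  expect_gte(pi0_hat, 0.9)
  expect_lte(pi0_hat, 1.0)
})

test_that("GC-matched controls reproduce the target GC histogram", {
  # candidate blocks with exact, evenly spread GC fractions
  withr::with_seed(51L, {
    blocks <- vapply(seq_len(1200), function(i) {
      k <- round((i %% 40) * 2.5)     # exact GC count per 100 bp
      paste(sample(c(rep("G", k), rep("A", 100 - k))), collapse = "")
    }, character(1))
  })
  genome <- c(chr1 = paste(blocks, collapse = ""))
  cand <- feat_tbl((seq_len(1200) - 1L) * 100L, seq_len(1200) * 100L,
                   name = sprintf("c%04d", 1:1200))
  gc_of <- function(f) {
    vapply(seq_len(nrow(f)), function(i) {
      s <- strsplit(substr(genome, f$start[i] + 1, f$end[i]), "")[[1]]
      mean(s %in% c("G", "C"))
    }, numeric(1))
  }
  gc_all <- gc_of(cand)
  targets <- cand[gc_all == 0.5, ][1:20, ]
  ctrl <- matched_controls(cand, targets, genome, seed = 7L)
  expect_equal(nrow(ctrl), nrow(targets))
  # all 50%-GC targets draw controls from the same 2.5%-GC bin
  expect_true(all(gc_of(ctrl) >= 0.5 & gc_of(ctrl) < 0.525))

  ctrl2 <- matched_controls(cand, targets, genome, seed = 7L)
  expect_identical(ctrl, ctrl2)

  # broad target set: control GC histogram within 0.05 total variation
  tg <- cand[sample(nrow(cand), 400), ]
  cc <- matched_controls(cand, tg, genome, seed = 8L)
  bins <- seq(0, 1, by = 0.05)
  h1 <- hist(gc_of(tg), breaks = bins, plot = FALSE)$counts / 400
  h2 <- hist(gc_of(cc), breaks = bins, plot = FALSE)$counts / 400
  expect_lte(sum(abs(h1 - h2)) / 2, 0.05)
})

test_that("enrichment scans flag planted enrichment and respect the null", {
  withr::with_seed(91L, {
    n <- 20000L
    cat_x <- sample(c("X", "Y"), n, replace = TRUE)
    # pattern P twice as likely inside category X
    p_p <- ifelse(cat_x == "X", 0.5, 0.25)
    clus <- ifelse(runif(n) < p_p, 1L, 2L)
  })
  assignment <- tibble::tibble(molecule_id = sprintf("m%05d", 1:n),
                               cluster = clus)
  categories <- tibble::tibble(molecule_id = assignment$molecule_id,
                               category = cat_x)
  scan <- suppressMessages(enrichment_scan(assignment, categories))
  row <- scan[scan$cluster == 1L & scan$category == "X", ]
  expect_gt(row$odds_ratio, 1)
  expect_lt(row$q_value, 0.1)
  expect_true(row$significant)
  expect_equal(unique(scan$a + scan$b + scan$c + scan$d), n)

  # single cluster, single category: one row
  one <- suppressMessages(enrichment_scan(
    tibble::tibble(molecule_id = c("a", "b"), cluster = 1L),
    tibble::tibble(molecule_id = c("a", "b"), category = "X")
  ))
  expect_equal(nrow(one), 1L)
})
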