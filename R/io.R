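#' Read a kinetics table
#'
#' The kinetics table is the package's primary interchange format: one row
#' per molecule, tab-separated with header
#' `molecule_id ref_name ref_start ref_end strand bases ipd`, where `ipd` is
#' a comma-separated list of per-base IPD values (empty field = missing),
#' the same length as `bases`. Coordinates are 0-based half-open; per-base
#' vectors are stored in molecule (read) orientation.
#'
#' @param path Path to the TSV file.
#' @return Tibble of molecules with list-column `ipd`.
#' @export
read_kinetics <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    molecule_id = readr::col_character(), ref_name = readr::col_character(),
    ref_start = readr::col_integer(), ref_end = readr::col_integer(),
    strand = readr::col_character(), bases = readr::col_character(),
    ipd = readr::col_character()
  ), progress = FALSE)
  if (nrow(df) == 0) {
    return(dplyr::mutate(df, ipd = list()))
  }
  ipd <- purrr::map(df$ipd, parse_num_field)
  bad <- which(lengths(ipd) != nchar(df$bases))
  if (length(bad)) {
    stop("ipd/bases length mismatch for molecule(s) ",
         paste(df$molecule_id[bad], collapse = ", "),
         " (line ", paste(bad + 1L, collapse = ", "), ")", call. = FALSE)
  }
  neg <- purrr::map_lgl(ipd, ~ any(.x < 0, na.rm = TRUE))
  if (any(neg)) {
    stop("negative IPD values for molecule(s) ",
         paste(df$molecule_id[neg], collapse = ", "), call. = FALSE)
  }
  bad_strand <- !df$strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop("invalid strand for molecule(s) ",
         paste(df$molecule_id[bad_strand], collapse = ", "), call. = FALSE)
  }
  df$ipd <- ipd
  message(nrow(df), " molecules read from ", path)
  df
}

parse_num_field <- function(s) {
  if (is.na(s) || s == "") return(numeric(0))
  v <- strsplit(s, ",", fixed = TRUE)[[1]]
  n_fields <- nchar(gsub("[^,]", "", s)) + 1L   # strsplit drops trailing ""
  if (length(v) < n_fields) v <- c(v, rep("", n_fields - length(v)))
  out <- suppressWarnings(as.numeric(v))
  out[v == ""] <- NA_real_
  bad <- is.na(out) & v != "" & !v %in% c("NA", "NaN")
  if (any(bad)) stop("unparseable numeric field: ", v[which(bad)[1]], call. = FALSE)
  out
}

fmt_num_field <- function(x, digits = NULL) {
  if (!is.null(digits)) x <- round(x, digits)
  s <- sprintf("%.17g", x)
  if (!is.null(digits)) s <- sprintf(paste0("%.", digits, "f"), x)
  s[is.na(x)] <- ""
  paste(s, collapse = ",")
}

#' Write a kinetics table
#'
#' @param molecules Tibble as returned by [read_kinetics()] or
#'   [simulate_sample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinetics <- function(molecules, path) {
  df <- dplyr::mutate(molecules,
                      ipd = purrr::map_chr(.data$ipd, fmt_num_field))
  readr::write_tsv(df[, c("molecule_id", "ref_name", "ref_start", "ref_end",
                          "strand", "bases", "ipd")], path, progress = FALSE)
  invisible(path)
}

#' Read / write per-molecule modification tracks
#'
#' Tracks are stored as TSV with columns `molecule_id` and `prob`
#' (comma-separated posteriors, empty = missing, 6 decimals). Values must
#' lie in \[0, 1\]. `read_tracks()` can re-attach reference placement from a
#' molecules table so downstream feature-centric operations need no extra
#' join.
#'
#' @param tracks Tibble with `molecule_id` and list-column `prob`.
#' @param path File path.
#' @param molecules Optional molecules tibble to re-attach `ref_name`,
#'   `ref_start`, `ref_end`, `strand`.
#' @return `write_tracks()` returns `path` invisibly; `read_tracks()` a
#'   tibble of tracks.
#' @export
write_tracks <- function(tracks, path) {
  bad <- purrr::map_lgl(tracks$prob, ~ any(.x < 0 | .x > 1, na.rm = TRUE))
  if (any(bad)) {
    stop("posterior outside [0, 1] for molecule(s) ",
         paste(tracks$molecule_id[bad], collapse = ", "), call. = FALSE)
  }
  df <- tibble::tibble(
    molecule_id = tracks$molecule_id,
    prob = purrr::map_chr(tracks$prob, fmt_num_field, digits = 6L)
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path, molecules = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    molecule_id = readr::col_character(), prob = readr::col_character()
  ), progress = FALSE)
  df$prob <- purrr::map(df$prob, parse_num_field)
  bad <- purrr::map_lgl(df$prob, ~ any(.x < 0 | .x > 1, na.rm = TRUE))
  if (any(bad)) {
    stop("posterior outside [0, 1] for molecule(s) ",
         paste(df$molecule_id[bad], collapse = ", "), call. = FALSE)
  }
  if (!is.null(molecules)) {
    df <- dplyr::left_join(
      df,
      molecules[, c("molecule_id", "ref_name", "ref_start", "ref_end", "strand")],
      by = "molecule_id"
    )
  }
  df
}

#' Read a BED3/BED6 feature file
#'
#' @param path Path to a BED file (0-based half-open).
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (the last three defaulted for BED3).
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                        comment = "#", progress = FALSE)
  assert_that(ncol(df) >= 3, "BED needs at least 3 columns")
  out <- tibble::tibble(
    chrom = df[[1]],
    start = suppressWarnings(as.integer(df[[2]])),
    end = suppressWarnings(as.integer(df[[3]])),
    name = if (ncol(df) >= 4) df[[4]] else NA_character_,
    score = if (ncol(df) >= 5) suppressWarnings(as.numeric(df[[5]])) else 0,
    strand = if (ncol(df) >= 6) df[[6]] else "."
  )
  assert_that(!anyNA(out$start) && !anyNA(out$end),
              "non-integer BED coordinates")
  assert_that(all(out$start < out$end), "BED requires start < end")
  assert_that(all(out$strand %in% c("+", "-", ".")), "invalid BED strand")
  out
}

#' Write a feature tibble as BED6
#'
#' @param features Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(features, path) {
  out <- tibble::tibble(
    chrom = features$chrom, start = features$start, end = features$end,
    name = features$name %||% ".", score = features$score %||% 0,
    strand = features$strand %||% "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Map a molecule-coordinate position to reference coordinates
#'
#' Per-molecule vectors are stored in read orientation; on the minus strand
#' molecule position `p` (0-based) maps to reference position
#' `ref_start + (L - 1 - p)`.
#'
#' @param pos 0-based molecule positions.
#' @param ref_start Molecule's reference start (0-based).
#' @param length Molecule length.
#' @param strand `"+"` or `"-"`.
#' @return 0-based reference positions.
#' @export
molecule_to_ref <- function(pos, ref_start, length, strand) {
  neg <- rep_len(strand == "-", length(pos))
  ifelse(neg, ref_start + (length - 1L - pos), ref_start + pos)
}

#' Export dyad calls as BED
#'
#' Each dyad becomes a 1-bp interval (`start = dyad`, `end = dyad + 1`) on
#' the molecule's reference coordinates, converting from read orientation.
#'
#' @param callsets Dyad-call tibble from [call_dyads()].
#' @param molecules Molecules tibble providing reference placement.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dyads <- function(callsets, molecules, path) {
  mol <- molecules[, c("molecule_id", "ref_name", "ref_start", "ref_end", "strand")]
  df <- dplyr::inner_join(callsets, mol, by = "molecule_id")
  rows <- purrr::pmap(df, function(molecule_id, dyads, ref_name, ref_start,
                                   ref_end, strand, ...) {
    if (length(dyads) == 0) return(NULL)
    L <- ref_end - ref_start
    pos <- molecule_to_ref(dyads, ref_start, L, strand)
    tibble::tibble(chrom = ref_name, start = as.integer(pos),
                   end = as.integer(pos + 1L), name = molecule_id,
                   score = 0, strand = strand)
  })
  bed <- dplyr::bind_rows(rows)
  bed <- dplyr::arrange(bed, .data$chrom, .data$start)
  write_bed(bed, path)
}

#' Read molecules from an aligned BAM with per-base kinetics tags (optional)
#'
#' A thin adapter over Rsamtools for aligned PacBio CCS BAMs carrying the
#' standard per-base interpulse-duration tag (`ip`). Values are returned in
#' read orientation, as stored in the BAM record.
#'
#' @param path BAM file path.
#' @param tag Name of the per-base kinetics tag (default `"ip"`).
#' @return Tibble of molecules in the kinetics layout.
#' @export
bam_adapter <- function(path, tag = "ip") {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("bam_adapter requires the Rsamtools package", call. = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "seq", "qwidth"),
    tag = tag
  )
  res <- Rsamtools::scanBam(path, param = p)[[1]]
  ipd <- res$tag[[tag]]
  if (is.null(ipd) || all(purrr::map_lgl(ipd, is.null))) {
    stop("unsupported input: BAM lacks per-base kinetics tag '", tag, "'",
         call. = FALSE)
  }
  n <- length(res$qname)
  seqs <- as.character(res$seq)
  out <- tibble::tibble(
    molecule_id = res$qname,
    ref_name = as.character(res$rname),
    ref_start = as.integer(res$pos) - 1L,
    ref_end = as.integer(res$pos) - 1L + nchar(seqs),
    strand = as.character(res$strand),
    bases = seqs,
    ipd = purrr::map(seq_len(n), function(i) {
      v <- ipd[[i]]
      if (is.null(v)) rep(NA_real_, nchar(seqs[i])) else as.numeric(v)
    })
  )
  bad <- lengths(out$ipd) != nchar(out$bases)
  if (any(bad)) {
    stop("ipd/bases length mismatch for molecule(s) ",
         paste(out$molecule_id[bad], collapse = ", "), call. = FALSE)
  }
  message(nrow(out), " molecules read from ", path)
  out
}
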