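#' Write and read foci sets as TSV
#'
#' The native tabular dialect: a `#key=value` metadata comment line holding
#' the nucleus diameter (plus model and seed when known), a header line, and
#' one row per focus with columns `id`, `x_nm`, `y_nm`, `z_nm`,
#' `diameter_nm`, `zone`, `chain_id`, `chain_pos`.
#'
#' @param fs A `foci_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_foci_tsv <- function(fs, path) {
  stopifnot(inherits(fs, "foci_set"))
  nuc <- attr(fs, "nucleus")
  meta <- sprintf(
    "#nucleus_diameter_um=%s #focus_diameter_nm=%s #model=%s #seed=%s",
    format(nuc$nucleus_diameter_um), format(nuc$focus_diameter_nm),
    attr(fs, "model") %||% "NA", attr(fs, "seed") %||% "NA"
  )
  writeLines(meta, path)
  readr::write_tsv(as_tibble(fs), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_foci_tsv
#' @param validate Check that every focus lies fully inside the nucleus.
#' @export
read_foci_tsv <- function(path, validate = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 1L)
  meta <- parse_meta_line(first)
  diam <- as.numeric(meta[["nucleus_diameter_um"]] %||% NA)
  if (is.na(diam)) {
    abort("missing '#nucleus_diameter_um=' metadata comment line")
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          id = readr::col_integer(),
                          x_nm = readr::col_double(),
                          y_nm = readr::col_double(),
                          z_nm = readr::col_double(),
                          diameter_nm = readr::col_double(),
                          zone = readr::col_integer(),
                          chain_id = readr::col_integer(),
                          chain_pos = readr::col_integer()
                        ))
  prob <- readr::problems(df)
  if (nrow(prob) > 0L) {
    abort(sprintf("malformed foci TSV at line %d: %s",
                  prob$row[1] + 2L, prob$expected[1]))
  }
  need <- c("id", "x_nm", "y_nm", "z_nm", "diameter_nm", "zone",
            "chain_id", "chain_pos")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("foci TSV lacks columns: ", paste(missing, collapse = ", ")))
  }
  focus_diam <- as.numeric(meta[["focus_diameter_nm"]] %||% NA)
  if (is.na(focus_diam)) {
    focus_diam <- if (nrow(df)) df$diameter_nm[1] else 500
  }
  nuc <- nucleus_config(
    nucleus_diameter_um = diam,
    focus_diameter_nm = focus_diam,
    foci_per_zone = max(1L, if (nrow(df)) max(tabulate(df$zone)) else 1L),
    n_zones = max(1L, if (nrow(df)) max(df$zone) else 1L)
  )
  if (validate && nrow(df)) {
    r <- sqrt(df$x_nm^2 + df$y_nm^2 + df$z_nm^2) + df$diameter_nm / 2
    bad <- which(r > diam * 1000 / 2 + 1e-6)
    if (length(bad)) {
      abort(sprintf("focus outside nucleus at data line %d (id %d)",
                    bad[1], df$id[bad[1]]))
    }
  }
  model <- meta[["model"]] %||% NA_character_
  seed <- suppressWarnings(as.integer(meta[["seed"]] %||% NA))
  new_foci_set(df, nuc, model, seed)
}

parse_meta_line <- function(line) {
  if (!startsWith(line, "#")) return(list())
  parts <- strsplit(sub("^#", "", gsub(" #", " ", line)), "\\s+")[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  kv <- kv[lengths(kv) == 2L]
  setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
}

#' Write and read fiber track tables as TSV
#'
#' Columns: `fiber_id`, `channel` (1|2), `start_um`, `end_um`, and optional
#' `truth_class`, `truth_origins_kbp` (semicolon-separated) and
#' `fiber_length_um`.
#'
#' @param fibers A `fiber_set` or compatible tracks tibble.
#' @param path File path.
#' @return `path` invisibly (writer); a `fiber_set` (reader).
#' @export
write_fibers_tsv <- function(fibers, path) {
  df <- as_tibble(fibers)
  if ("truth_origins_kbp" %in% names(df)) {
    df$truth_origins_kbp <- vapply(
      df$truth_origins_kbp,
      function(x) paste(format(x, trim = TRUE, digits = 12), collapse = ";"),
      character(1)
    )
  }
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_fibers_tsv
#' @export
read_fibers_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("fiber_id", "channel", "start_um", "end_um")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("fiber TSV lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (any(df$start_um >= df$end_um)) {
    abort(sprintf("track with start >= end at data line %d",
                  which(df$start_um >= df$end_um)[1]))
  }
  df$channel <- as.integer(df$channel)
  df$fiber_id <- as.integer(df$fiber_id)
  if ("truth_origins_kbp" %in% names(df) &&
      is.character(df$truth_origins_kbp)) {
    df$truth_origins_kbp <- lapply(
      strsplit(df$truth_origins_kbp, ";", fixed = TRUE), as.numeric
    )
  }
  new_fiber_set(df)
}

#' Read and write binned timing profiles as bedGraph
#'
#' Four-column bedGraph (chrom, start, end, value), 0-based half-open, read
#' and written through rtracklayer (UCSC conventions). Overlapping intervals
#' are an error; unsorted input is sorted with a warning.
#'
#' @param path File path.
#' @return A `timing_profile` tibble (reader); `path` invisibly (writer).
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    value = gr$score
  )
  ord <- order(df$chrom, df$start)
  if (!identical(ord, seq_len(nrow(df)))) {
    warn("bedGraph was unsorted; sorting")
    df <- df[ord, , drop = FALSE]
  }
  by_chr <- split(seq_len(nrow(df)), df$chrom)
  for (idx in by_chr) {
    if (length(idx) > 1L && any(df$start[idx][-1] < df$end[idx][-length(idx)])) {
      abort("bedGraph has overlapping intervals")
    }
  }
  new_timing_profile(df)
}

#' @rdname read_bedgraph
#' @param p A `timing_profile`.
#' @export
write_bedgraph <- function(p, path) {
  gr <- GenomicRanges::GRanges(
    p$chrom, IRanges::IRanges(start = p$start + 1, end = p$end),
    score = p$value
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write called timing domains as BED6
#'
#' 0-based half-open, sorted; `name` carries the apex value, `score` the
#' domain length in kbp. An empty domain set writes a header comment only.
#'
#' @param domains Domains tibble from [call_domains()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_domains_bed <- function(domains, path) {
  if (nrow(domains) == 0L) {
    writeLines("#chrom\tstart\tend\tname\tscore\tstrand", path)
    return(invisible(path))
  }
  domains <- domains[order(domains$chrom, domains$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    domains$chrom,
    IRanges::IRanges(start = domains$start + 1, end = domains$end),
    name = format(domains$apex_value, digits = 6, trim = TRUE),
    score = domains$length_kbp
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
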