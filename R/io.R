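#' Read a bedGraph file
#'
#' Reads a 4-column bedGraph (`chrom`, `start`, `end`, `value`; 0-based,
#' half-open intervals). For the toy tracks written by this package the chrom
#' field holds the gene id. Track definition lines and `#` comments are
#' skipped. Malformed lines (wrong column count, non-numeric or negative
#' coordinates, `end <= start`) and overlapping intervals on the same chrom
#' raise an error naming the offending line. An empty file yields an empty
#' tibble, not an error.
#'
#' @param path File path.
#' @return A tibble: `gene_id`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(tibble(gene_id = character(), start = numeric(),
                  end = numeric(), value = numeric()))
  }
  fields <- strsplit(lines[idx], "\\s+")
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) {
    abort(sprintf("bedGraph parse error at line %d: expected 4 columns, got %d.",
                  idx[bad[1]], lengths(fields)[bad[1]]))
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad)) {
    abort(sprintf("bedGraph parse error at line %d: non-numeric field.", idx[bad[1]]))
  }
  bad <- which(start < 0 | end <= start)
  if (length(bad)) {
    abort(sprintf("bedGraph parse error at line %d: invalid interval [%s, %s).",
                  idx[bad[1]], m[bad[1], 2], m[bad[1], 3]))
  }
  out <- tibble(gene_id = m[, 1], start = start, end = end, value = value,
                .line = idx)
  overlaps <- out |>
    dplyr::arrange(.data$gene_id, .data$start) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(prev_end = dplyr::lag(.data$end)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$prev_end) & .data$start < .data$prev_end)
  if (nrow(overlaps)) {
    abort(sprintf("bedGraph parse error at line %d: interval overlaps the previous one.",
                  overlaps$.line[1]))
  }
  out |>
    dplyr::arrange(.data$gene_id, .data$start) |>
    dplyr::select(-".line")
}

#' Write a bedGraph file
#'
#' Writes intervals sorted by chrom then start, with values printed at 6
#' significant digits (fixed notation) for byte-stable output across
#' platforms. Integer values round-trip exactly.
#'
#' @param x A tibble with `gene_id` (or `chrom`), `start`, `end`, `value`
#'   columns, or a binned track with `bin_start` and a value column plus a
#'   `bin_size` attribute-free layout (`start`/`end` computed from
#'   `bin_start`).
#' @param path Output path.
#' @param header Optional `#` comment lines (e.g. config hash and seed),
#'   written before the data.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path, header = NULL) {
  if (!"gene_id" %in% names(x) && "chrom" %in% names(x)) {
    x$gene_id <- x$chrom
  }
  if (!"start" %in% names(x) && "bin_start" %in% names(x)) {
    widths <- x |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(w = min(diff(sort(unique(.data$bin_start))), na.rm = TRUE),
                       .groups = "drop")
    x <- dplyr::left_join(x, widths, by = "gene_id") |>
      dplyr::mutate(start = .data$bin_start,
                    end = .data$bin_start + .data$w)
  }
  value_col <- intersect(c("value", "density", "signal", "count"), names(x))[1]
  if (is.na(value_col)) abort("no value column to write.")
  need <- c("gene_id", "start", "end")
  if (!all(need %in% names(x))) abort("`x` must have gene_id, start, end columns.")
  x <- dplyr::arrange(x, .data$gene_id, .data$start)
  fmt <- function(v) {
    vapply(v, function(z) format(signif(z, 6), scientific = FALSE, trim = TRUE,
                                 drop0trailing = TRUE),
           character(1))
  }
  lines <- sprintf("%s\t%s\t%s\t%s", x$gene_id, fmt(x$start), fmt(x$end),
                   fmt(x[[value_col]]))
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Export trajectory snapshots as tidy TSV
#'
#' One row per engaged polymerase per snapshot (`time`, `gene_id`, `pol_id`,
#' `position`, `status`), preceded by a single `#` header comment carrying the
#' configuration hash and the seed, with positions printed at 6 significant
#' digits for byte-stable output.
#'
#' @param trajectory A `pol_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snapshot_tsv <- function(trajectory, path) {
  hdr <- sprintf("# config_hash=%s seed=%d", config_hash(trajectory$params),
                 trajectory$seed)
  d <- trajectory$snapshots |>
    dplyr::mutate(position = formatC(signif(.data$position, 6), format = "g", digits = 6))
  body <- c(paste(names(d), collapse = "\t"),
            do.call(paste, c(lapply(d, as.character), sep = "\t")))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record of a run: configuration hash, seed, tool version, wall-clock
#' start/end, output files, and the error message if the run failed. Written
#' even on failure so a run directory is always self-describing.
#'
#' @param path Output path.
#' @param config_hash,seed Run identity.
#' @param outputs Character vector of output file names.
#' @param started,finished POSIXct timestamps.
#' @param error Optional error message.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config_hash, seed, outputs = character(),
                               started = Sys.time(), finished = Sys.time(),
                               error = NULL) {
  manifest <- list(
    tool = "uvpolsim",
    version = as.character(utils::packageVersion("uvpolsim")),
    config_hash = config_hash,
    seed = as.integer(seed),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs),
    error = if (is.null(error)) NULL else as.character(error)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
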