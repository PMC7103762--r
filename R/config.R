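#' Parse a unit-suffixed quantity
#'
#' Configuration files may give lengths and times as unit-suffixed strings.
#' Lengths accept `nt`, `kb`, `Mb` (converted to nucleotides); times accept
#' `s`, `sec`, `min`, `h`, `hr` (converted to seconds). Bare numbers pass
#' through unchanged and are taken to be in the internal units (nt, s).
#'
#' @param x A number, or a string like `"100kb"`, `"45min"`, `"1.5h"`.
#' @return A numeric value in internal units.
#' @examples
#' parse_quantity("100kb")  # 1e5 nt
#' parse_quantity("1.5h")   # 5400 s
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.null(x)) return(NULL)
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^([-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?)\\s*([A-Za-z]*)$", s))[[1]]
    if (length(m) == 0) abort(sprintf("cannot parse quantity \"%s\".", s))
    val <- as.numeric(m[2])
    unit <- tolower(m[4])
    mult <- if (unit == "") 1 else switch(unit,
      "nt" = 1, "bp" = 1, "kb" = 1e3, "mb" = 1e6,
      "s" = 1, "sec" = 1, "min" = 60, "h" = 3600, "hr" = 3600,
      abort(sprintf("unknown unit \"%s\" in \"%s\".", m[4], s))
    )
    val * mult
  }, numeric(1), USE.NAMES = FALSE)
}

# canonical YAML text of a parameter set (full precision, sorted gene table)
.config_yaml <- function(params) {
  p <- unclass(params)
  p$genes <- lapply(seq_len(nrow(params$genes)), function(i) {
    g <- params$genes[i, ]
    list(gene_id = g$gene_id, length = g$length,
         initiation_weight = g$initiation_weight)
  })
  p$seed <- as.integer(p$seed)
  # disabled optional fields are simply absent from the file
  for (f in c("pause_site_offset", "pause_mean_dwell")) {
    if (length(p[[f]]) == 1 && is.na(p[[f]])) p[[f]] <- NULL
  }
  handlers <- list(numeric = function(x) {
    r <- ifelse(is.na(x), ".na.real",
                format(x, digits = 17, scientific = FALSE, trim = TRUE))
    attr(r, "quoted") <- FALSE
    r
  })
  yaml::as.yaml(p, handlers = handlers)
}

#' Write a simulation configuration file
#'
#' Serialises a parameter set to YAML in canonical internal units (nucleotides
#' and seconds, full precision). A written configuration reloads to an
#' identical `sim_params` object.
#'
#' @param params A [sim_params()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(params, path) {
  params <- validate_sim_params(params)
  writeLines(.config_yaml(params), path)
  invisible(path)
}

#' Read a simulation configuration file
#'
#' Reads a YAML (or JSON) configuration with one key per [sim_params()] field.
#' Length-valued fields (gene lengths, `footprint`, `pause_site_offset`,
#' `bin_size`) and time-valued fields (`lesion_halflife`, `pause_mean_dwell`,
#' `burn_in_time`, `snapshot_times`) accept unit-suffixed strings such as
#' `"100kb"`, `"45min"` or `"1.5h"` (see [parse_quantity()]).
#'
#' @param path Configuration file path.
#' @return A validated [sim_params()] object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$genes)) abort("config is missing the `genes` list.")
  gl <- raw$genes
  genes <- gene_ensemble(
    lengths = vapply(gl, function(g) parse_quantity(g$length), numeric(1)),
    weights = vapply(gl, function(g) as.numeric(g$initiation_weight), numeric(1)),
    gene_ids = vapply(gl, function(g) as.character(g$gene_id), character(1))
  )
  len_fields <- c("footprint", "pause_site_offset", "bin_size")
  time_fields <- c("lesion_halflife", "pause_mean_dwell", "burn_in_time")
  num_fields <- c("pool_size", "initiation_rate", "elongation_speed",
                  "lesion_density", "moving_removal_hazard",
                  "stalled_removal_hazard", "removal_recycle_prob",
                  "completion_recycle_prob", "n_replicates", "seed")
  args <- list(genes = genes)
  for (f in len_fields) if (!is.null(raw[[f]]) && !anyNA(raw[[f]])) args[[f]] <- parse_quantity(raw[[f]])
  for (f in time_fields) if (!is.null(raw[[f]]) && !anyNA(raw[[f]])) args[[f]] <- parse_quantity(raw[[f]])
  for (f in num_fields) if (!is.null(raw[[f]])) args[[f]] <- as.numeric(raw[[f]])
  if (!is.null(args$seed)) args$seed <- as.integer(args$seed)
  if (!is.null(raw$snapshot_times)) {
    args$snapshot_times <- sort(unname(vapply(
      unlist(raw$snapshot_times, use.names = FALSE), parse_quantity, numeric(1))))
  }
  for (f in c("degradation_enabled", "dissociation_enabled")) {
    if (!is.null(raw[[f]])) args[[f]] <- as.logical(raw[[f]])
  }
  do.call(sim_params, args)
}

#' Deterministic configuration hash
#'
#' MD5 of the canonical serialised configuration; identical parameter sets hash
#' identically regardless of how they were constructed or loaded.
#'
#' @param params A [sim_params()] object.
#' @return A hex string.
#' @export
config_hash <- function(params) {
  params <- validate_sim_params(params)
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  writeLines(.config_yaml(params), tf)
  unname(tools::md5sum(tf))
}
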