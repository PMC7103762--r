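#' Gene-length class boundaries
#'
#' Genes are stratified by genomic width into `short` (< 30 kb), `medium`
#' (>= 30 kb and < 100 kb) and `long` (>= 100 kb), the standard strata used for
#' length-resolved metagene analysis of nascent transcription after UV damage.
#' Both boundaries are lower-inclusive for the class they open.
#'
#' @param length Gene length(s) in nucleotides. Must be positive.
#' @param boundaries Numeric length-2 vector: the short/medium and medium/long
#'   boundaries in nucleotides. Defaults to `c(30000, 100000)` (30 kb, 100 kb).
#'
#' @return A character vector of class labels (`"short"`, `"medium"`, `"long"`),
#'   one per input length.
#' @examples
#' classify_gene_length(c(5e3, 29999, 30000, 63e3, 1e5))
#' @export
classify_gene_length <- function(length, boundaries = c(30000, 100000)) {
  if (!is.numeric(length) || any(!is.finite(length)) || any(length <= 0)) {
    abort("`length` must be positive and finite (nucleotides).")
  }
  if (length(boundaries) != 2L || boundaries[1] >= boundaries[2]) {
    abort("`boundaries` must be two increasing values.")
  }
  out <- ifelse(length < boundaries[1], "short",
                ifelse(length < boundaries[2], "medium", "long"))
  as.character(out)
}

#' Build a gene ensemble
#'
#' A gene ensemble is a tibble with one row per model gene: an identifier, the
#' gene length in nucleotides, an initiation weight (the probability that a
#' given initiation event is assigned to that gene; weights must sum to 1), and
#' the length class from [classify_gene_length()].
#'
#' @param lengths Gene lengths in nucleotides.
#' @param weights Initiation weights, one per gene. Renormalised if they sum to
#'   1 within `1e-6`, rejected otherwise.
#' @param gene_ids Optional gene identifiers; defaults to `gene_1`, `gene_2`, ...
#'
#' @return A tibble with columns `gene_id`, `length`, `initiation_weight`,
#'   `class_label`.
#' @examples
#' gene_ensemble(c(100e3, 63e3, 5e3), c(0.1, 0.2, 0.7))
#' @export
gene_ensemble <- function(lengths, weights, gene_ids = NULL) {
  if (length(lengths) < 1L) abort("at least one gene is required.")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    abort("gene `lengths` must be positive and finite.")
  }
  if (length(weights) != length(lengths)) {
    abort("`weights` must have one entry per gene.")
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    abort("initiation `weights` must be non-negative.")
  }
  s <- sum(weights)
  if (abs(s - 1) > 1e-6) {
    abort(sprintf("initiation weights must sum to 1 (got %.8f).", s))
  }
  weights <- weights / s
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_along(lengths))
  if (anyDuplicated(gene_ids)) abort("`gene_ids` must be unique.")
  tibble(
    gene_id = as.character(gene_ids),
    length = as.numeric(lengths),
    initiation_weight = as.numeric(weights),
    class_label = classify_gene_length(lengths)
  )
}

#' Preset gene ensembles
#'
#' Two ensembles used throughout: `single_100kb`, one 100-kb gene carrying all
#' initiation; and `three_gene`, a long (100 kb), medium (63 kb) and short
#' (5 kb) gene competing for the same polymerase pool with initiation weights
#' 0.1, 0.2 and 0.7 — the relative genomic representation of long, medium and
#' short genes.
#'
#' @param preset_name `"single_100kb"` or `"three_gene"`.
#' @return A gene ensemble tibble (see [gene_ensemble()]).
#' @examples
#' preset_ensemble("three_gene")
#' @export
preset_ensemble <- function(preset_name = c("single_100kb", "three_gene")) {
  if (!is.character(preset_name) || length(preset_name) != 1L ||
      !preset_name %in% c("single_100kb", "three_gene")) {
    abort("unknown ensemble preset; use \"single_100kb\" or \"three_gene\".")
  }
  switch(preset_name,
    single_100kb = gene_ensemble(100000, 1, gene_ids = "gene_100kb"),
    three_gene = gene_ensemble(
      lengths = c(100000, 63000, 5000),
      weights = c(0.1, 0.2, 0.7),
      gene_ids = c("long_100kb", "medium_63kb", "short_5kb")
    )
  )
}

#' Random gene ensembles
#'
#' Draws `n_genes` genes with class labels sampled from `class_proportions`
#' (long, medium, short), lengths log-uniform within each class's boundary
#' interval (long genes capped at 1 Mb, short genes bounded below at 1 kb), and
#' initiation weights split equally within each class so that each class as a
#' whole receives its proportion of initiation events.
#'
#' @param n_genes Number of genes (>= 1).
#' @param class_proportions Named or positional fractions for `long`, `medium`,
#'   `short`; must sum to 1.
#' @param seed Integer seed.
#' @return A gene ensemble tibble (see [gene_ensemble()]).
#' @examples
#' random_gene_ensemble(5, c(long = 0.1, medium = 0.2, short = 0.7), seed = 1)
#' @export
random_gene_ensemble <- function(n_genes,
                                 class_proportions = c(long = 0.1, medium = 0.2, short = 0.7),
                                 seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1) {
    abort("`n_genes` must be a positive integer.")
  }
  if (length(class_proportions) != 3L || abs(sum(class_proportions) - 1) > 1e-6 ||
      any(class_proportions < 0)) {
    abort("`class_proportions` must be three non-negative fractions summing to 1.")
  }
  classes <- c("long", "medium", "short")
  props <- setNames(as.numeric(class_proportions), classes)
  ranges <- list(long = c(1e5, 1e6), medium = c(3e4, 1e5), short = c(1e3, 3e4))
  set.seed(as.integer(seed))
  label <- sample(classes, size = n_genes, replace = TRUE, prob = props)
  len <- vapply(label, function(cl) {
    r <- ranges[[cl]]
    # upper bound open for short/medium so the draw classifies into its class
    exp(runif(1, log(r[1]), log(r[2] * (1 - 1e-9))))
  }, numeric(1))
  n_by <- table(factor(label, levels = classes))
  w <- props[label] / as.numeric(n_by[label])
  w <- w / sum(w) # renormalise when a class drew no gene
  gene_ensemble(len, w, gene_ids = sprintf("%s_%03d", label, seq_len(n_genes)))
}
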