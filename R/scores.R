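#' Regulatory disruption scores
#'
#' Quantifies how far an individual's converged network departs from the
#' genotype-agnostic baseline. The edge disruption score is
#' `d(E)[i, j] = |E*[i, j] - B*[i, j]|`; TF and gene disruption scores are
#' its row and column sums (`d(TF)[i] = sum_j d(E)[i, j]`,
#' `d(G)[j] = sum_i d(E)[i, j]`). All scores are nonnegative; only loss of
#' regulatory strength relative to baseline is modeled upstream, so large
#' values flag variant-disrupted regulation.
#'
#' @param genotype_fit [panda()] fit on an individual's penalized prior.
#' @param baseline_fit [panda()] fit on the reference motif prior. Must
#'   have been run with an identical configuration, otherwise the scores
#'   are incomparable and an error is raised.
#' @return A `disruption_scores` object: `edge` (m x n matrix), `tf`
#'   (length-m vector), `gene` (length-n vector), `individual_id`.
#' @export
disruption_scores <- function(genotype_fit, baseline_fit) {
  stopifnot(inherits(genotype_fit, "panda_fit"),
            inherits(baseline_fit, "panda_fit"))
  if (!identical(unclass(genotype_fit$config), unclass(baseline_fit$config))) {
    abort("the two fits used different message-passing configurations; disruption scores would be incomparable")
  }
  check_aligned(genotype_fit$network, baseline_fit$network, "the two networks")
  edge <- abs(genotype_fit$network - baseline_fit$network)
  structure(list(edge = edge, tf = rowSums(edge), gene = colSums(edge),
                 individual_id = genotype_fit$individual_id),
            class = "disruption_scores")
}

#' @export
print.disruption_scores <- function(x, ...) {
  cat("Regulatory disruption scores",
      if (!is.null(x$individual_id)) paste0(" [", x$individual_id, "]"),
      "\n", sep = "")
  cat("  ", nrow(x$edge), " TFs x ", ncol(x$edge), " genes; max edge score ",
      signif(max(x$edge), 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn disruption_scores Long table of scores at the requested
#'   level (`"edge"`, `"tf"` or `"gene"`).
#' @param x A `disruption_scores` object.
#' @param level Score level to return.
#' @param ... Unused.
#' @method tidy disruption_scores
#' @export
tidy.disruption_scores <- function(x, level = c("edge", "tf", "gene"), ...) {
  level <- match.arg(level)
  out <- switch(level,
    edge = matrix_to_edges(x$edge, value_name = "d_edge"),
    tf = tibble(tf = names(x$tf), d_tf = unname(x$tf)),
    gene = tibble(gene = names(x$gene), d_gene = unname(x$gene))
  )
  if (!is.null(x$individual_id)) out$individual_id <- x$individual_id
  out
}

#' @describeIn disruption_scores TF disruption scores as a bar chart.
#' @param object A `disruption_scores` object.
#' @method autoplot disruption_scores
#' @export
autoplot.disruption_scores <- function(object, ...) {
  df <- tidy(object, level = "tf")
  ggplot(df, aes(x = stats::reorder(.data$tf, -.data$d_tf), y = .data$d_tf)) +
    geom_col(fill = "grey30") +
    labs(x = "TF", y = "TF disruption score d(TF)") +
    theme_bw()
}

#' Regulatory difference scores between two genotypes
#'
#' `R(E)[i, j] = |d_a(E)[i, j] - d_b(E)[i, j]|` contrasts the disruption
#' profiles of two genotypes edge by edge; the gene-level score
#' `R(G)[j] = sum_i R(E)[i, j]` aggregates the differences impinging on
#' each gene. Symmetric in its two arguments. A numeric method is provided
#' so single printed disruption scores can be compared directly.
#'
#' @param a,b `disruption_scores` objects with matching labels, or plain
#'   numerics/matrices.
#' @return A `difference_scores` object (`edge`, `gene`, `pair`), or the
#'   elementwise `|a - b|` for bare numeric input.
#' @export
regulatory_difference <- function(a, b) {
  if (is.numeric(a) && is.numeric(b)) return(abs(a - b))
  stopifnot(inherits(a, "disruption_scores"), inherits(b, "disruption_scores"))
  check_aligned(a$edge, b$edge, "the two disruption matrices")
  edge <- abs(a$edge - b$edge)
  structure(list(edge = edge, gene = colSums(edge),
                 pair = c(a$individual_id %||% NA_character_,
                          b$individual_id %||% NA_character_)),
            class = "difference_scores")
}

#' @export
print.difference_scores <- function(x, ...) {
  cat("Regulatory difference scores (", x$pair[1], " vs ", x$pair[2], ")\n",
      sep = "")
  cat("  max edge score ", signif(max(x$edge), 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn regulatory_difference Long table of difference scores at
#'   edge or gene level.
#' @param x A `difference_scores` object.
#' @param level `"edge"` or `"gene"`.
#' @param ... Unused.
#' @method tidy difference_scores
#' @export
tidy.difference_scores <- function(x, level = c("edge", "gene"), ...) {
  level <- match.arg(level)
  switch(level,
    edge = matrix_to_edges(x$edge, value_name = "r_edge"),
    gene = tibble(gene = names(x$gene), r_gene = unname(x$gene)))
}

#' Scale TF disruption scores within groups
#'
#' Z-scores TF disruption scores within each (individual, cell type)
#' group so scores are comparable across individuals and cell types: each
#' group ends up with mean 0 and standard deviation 1. The sample standard
#' deviation (n - 1) is used; the convention is recorded in the output.
#' Groups with zero spread return all-zero scores and are flagged
#' `degenerate` instead of producing NaN, so cohort tables stay
#' rectangular.
#'
#' @param scores Data frame with columns `individual_id`, `cell_type`,
#'   `tf`, `d_tf` (e.g. row-bound [tidy()] output of
#'   [disruption_scores()]); or a list of `disruption_scores` objects,
#'   which is converted first (then `cell_type` defaults to `"all"`).
#' @return Tibble with the input columns plus `d_tf_scaled` and
#'   `degenerate`; `attr(, "sd_convention")` records `"sample"`.
#' @export
scale_tf_disruption <- function(scores) {
  if (!is.data.frame(scores)) {
    scores <- purrr::map(scores, function(s) {
      out <- tidy(s, level = "tf")
      if (!"individual_id" %in% names(out)) out$individual_id <- NA_character_
      out
    }) |> bind_rows()
    scores$cell_type <- "all"
  }
  scores <- as_tibble(scores)
  stopifnot(all(c("individual_id", "cell_type", "tf", "d_tf") %in% names(scores)))
  out <- scores |>
    group_by(.data$individual_id, .data$cell_type) |>
    mutate(
      .n = dplyr::n(),
      .sd = sd(.data$d_tf),
      degenerate = .data$.n < 2 | .data$.sd == 0,
      d_tf_scaled = ifelse(.data$degenerate, 0,
                           (.data$d_tf - mean(.data$d_tf)) / .data$.sd)
    ) |>
    ungroup() |>
    select(-".n", -".sd")
  if (any(out$degenerate)) {
    inform(paste0(sum(out$degenerate), " score(s) in degenerate groups set to 0"))
  }
  attr(out, "sd_convention") <- "sample"
  out
}

#' Plot scaled TF disruption scores by group
#'
#' One point per TF per individual, grouped by cell type — the cohort-level
#' view used to compare disruption burdens across cell types.
#'
#' @param scaled Output of [scale_tf_disruption()].
#' @param highlight Optional character vector of TF names drawn in color.
#' @return A ggplot object.
#' @export
plot_scaled_disruption <- function(scaled, highlight = NULL) {
  scaled$highlight <- scaled$tf %in% (highlight %||% character())
  p <- ggplot(scaled, aes(x = .data$cell_type, y = .data$d_tf_scaled)) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_jitter(aes(color = .data$highlight), width = 0.2, alpha = 0.6,
                show.legend = !is.null(highlight)) +
    ggplot2::scale_color_manual(values = c("FALSE" = "grey40",
                                           "TRUE" = "firebrick")) +
    labs(x = "cell type", y = "scaled TF disruption d(TF)'") +
    theme_bw()
  p
}

#' Select the top-scoring entries
#'
#' Boolean mask over a score vector or matrix. By default selects entries
#' at or above the `1 - fraction` quantile (quantile type 7); ties at the
#' quantile are all included, making the mask deterministic regardless of
#' input order. With `cutoff` set, an absolute threshold (`>= cutoff`) is
#' used instead — e.g. the variant-impacted edge-disruption cutoff 0.35.
#'
#' @param scores Numeric vector or matrix.
#' @param fraction Top fraction to select, in (0, 1). Default 0.10.
#' @param cutoff Optional absolute threshold overriding `fraction`.
#' @return Logical vector/matrix of the same shape.
#' @export
threshold_top_fraction <- function(scores, fraction = 0.10, cutoff = NULL) {
  if (length(scores) == 0) abort("empty input")
  if (!is.null(cutoff)) return(scores >= cutoff)
  stopifnot(fraction > 0, fraction < 1)
  q <- quantile(as.vector(scores), probs = 1 - fraction, names = FALSE)
  scores >= q
}
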