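#' ChIP-seq-derived regulatory network
#'
#' Binary TF x gene matrix: entry 1 iff at least one ChIP-seq peak for the
#' TF overlaps the gene's promoter window (>= 1 bp, same 0-based half-open
#' windows as the motif prior, so prediction and validation use identical
#' coordinates).
#'
#' @param peaks Tibble of peaks: `tf_name`, `chrom`, `start`, `end`
#'   (0-based half-open, as from [read_bed_peaks()]).
#' @param promoters Promoter windows from [build_promoters()].
#' @param tf_names Optional TF label space; TFs without any peak get an
#'   all-zero row (logged).
#' @return Binary matrix with TF rownames and gene colnames.
#' @export
build_chip_network <- function(peaks, promoters, tf_names = NULL) {
  peaks <- as_tibble(peaks)
  tf_names <- tf_names %||% sort(unique(peaks$tf_name))
  empty <- setdiff(tf_names, unique(peaks$tf_name))
  if (length(empty) > 0) {
    inform(paste0(length(empty), " TF(s) without peaks: all-zero rows"))
  }
  ov <- inner_join(
    peaks, promoters,
    by = join_by("chrom", x$start < y$end, x$end > y$start),
    suffix = c("", ".prom")
  )
  m <- matrix(0, length(tf_names), nrow(promoters),
              dimnames = list(tf_names, promoters$gene_id))
  if (nrow(ov) > 0) {
    pairs <- distinct(ov, .data$tf_name, .data$gene_id)
    keep <- pairs$tf_name %in% tf_names
    m[cbind(match(pairs$tf_name[keep], tf_names),
            match(pairs$gene_id[keep], colnames(m)))] <- 1
  }
  m
}

#' Differential ChIP-seq regulatory network
#'
#' Elementwise `|a - b|` of two binary ChIP networks — 1 where a TF binds a
#' gene's promoter in one condition but not the other (XOR), 0 where the
#' binding pattern agrees. Labels are intersected first, so only TFs and
#' genes assayed in both networks are compared.
#'
#' @param a,b Binary matrices from [build_chip_network()].
#' @return Binary matrix over the common label space.
#' @export
differential_chip_network <- function(a, b) {
  tfs <- intersect(rownames(a), rownames(b))
  genes <- intersect(colnames(a), colnames(b))
  if (length(tfs) == 0 || length(genes) == 0) {
    abort("no common TFs/genes between the two ChIP networks")
  }
  abs(a[tfs, genes, drop = FALSE] - b[tfs, genes, drop = FALSE])
}

#' Fisher enrichment of a selection against a truth mask
#'
#' Builds the 2x2 table of `selected` x `positive` and tests
#' over-representation of positives among the selected entries with a
#' one-sided Fisher's exact (hypergeometric) test. The odds ratio is the
#' sample odds ratio, with a Haldane correction (+0.5 to every cell) when
#' any cell is zero.
#'
#' @param selected,positive Logical vectors/matrices of the same shape
#'   (e.g. a [threshold_top_fraction()] mask and a differential ChIP
#'   network).
#' @return An `enrichment_result` list: `table` (2x2 counts),
#'   `odds_ratio`, `p_value`, `test = "fisher"`.
#' @export
enrichment_fisher <- function(selected, positive) {
  if (length(selected) == 0) abort("empty masks")
  if (!identical(dim(selected), dim(positive)) ||
      length(selected) != length(positive)) {
    abort("masks must have the same shape")
  }
  s <- as.logical(selected)
  p <- as.logical(positive)
  tab <- matrix(c(sum(s & p), sum(s & !p),
                  sum(!s & p), sum(!s & !p)),
                nrow = 2, byrow = TRUE,
                dimnames = list(selected = c("yes", "no"),
                                positive = c("yes", "no")))
  pval <- fisher.test(tab, alternative = "greater")$p.value
  ct <- tab
  if (any(ct == 0)) ct <- ct + 0.5
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  structure(list(table = tab, odds_ratio = unname(or), p_value = pval,
                 test = "fisher"),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Enrichment (one-sided Fisher)\n")
  print(x$table)
  cat("  odds ratio ", signif(x$odds_ratio, 4),
      ", p = ", format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @describeIn enrichment_fisher One-row summary of an enrichment test.
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, p_value = x$p_value, test = x$test,
         n = sum(x$table))
}

#' Area under the ROC curve for predicting a binary truth network
#'
#' Ranks all edges by score and computes the Mann-Whitney AUC (midranks,
#' so ties contribute 1/2), i.e. the probability that a random true edge
#' outscores a random non-edge. Invariant under strictly monotone
#' transformations of the scores.
#'
#' @param scores Numeric vector/matrix of edge scores.
#' @param truth Binary vector/matrix of the same shape with both classes
#'   present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, truth) {
  if (!identical(dim(scores), dim(truth)) ||
      length(scores) != length(truth)) {
    abort("scores and truth must have the same shape")
  }
  y <- as.logical(truth)
  if (all(y) || all(!y)) abort("truth must contain both classes")
  r <- rank(as.vector(scores))
  n1 <- sum(y)
  n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
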