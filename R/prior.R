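#' Build the reference motif prior M
#'
#' The reference prior is a binary TF x gene matrix: `M[i, j] = 1` iff at
#' least one occurrence of TF i's motif overlaps gene j's promoter window
#' (any overlap of >= 1 bp under the 0-based half-open convention).
#' Multiple occurrences in the same promoter still give 1; the prior is an
#' indicator, not a count.
#'
#' @param hits Motif occurrences ([read_fimo()] or equivalent tibble with
#'   `tf_name`, `chrom`, `start`, `end`), already filtered at the scan
#'   p-value cutoff.
#' @param promoters Promoter windows from [build_promoters()].
#' @param tf_names Optional TF label space; defaults to the TFs present in
#'   `hits`, sorted.
#' @return Binary matrix with TF rownames and gene colnames. Hits on
#'   chromosomes absent from the annotation are skipped; the skip count is
#'   reported and attached as `attr(, "n_skipped_chrom")`.
#' @export
build_motif_prior <- function(hits, promoters, tf_names = NULL) {
  hits <- as_tibble(hits)
  tf_names <- tf_names %||% sort(unique(hits$tf_name))
  gene_ids <- promoters$gene_id
  if (anyDuplicated(tf_names) || anyDuplicated(gene_ids)) {
    abort("TF and gene labels must be unique")
  }
  off_chrom <- !(hits$chrom %in% unique(promoters$chrom))
  if (any(off_chrom)) {
    inform(paste0(sum(off_chrom),
                  " motif hit(s) on chromosomes absent from annotation skipped"))
    hits <- hits[!off_chrom, , drop = FALSE]
  }
  ov <- inner_join(
    hits, promoters,
    by = join_by("chrom", x$start < y$end, x$end > y$start),
    suffix = c("", ".prom")
  )
  m <- matrix(0, length(tf_names), length(gene_ids),
              dimnames = list(tf_names, gene_ids))
  if (nrow(ov) > 0) {
    pairs <- distinct(ov, .data$tf_name, .data$gene_id)
    keep <- pairs$tf_name %in% tf_names
    m[cbind(match(pairs$tf_name[keep], tf_names),
            match(pairs$gene_id[keep], gene_ids))] <- 1
  }
  attr(m, "n_skipped_chrom") <- sum(off_chrom)
  m
}

#' Select candidate variant-TF-gene triples
#'
#' A triple (variant s, TF i, gene j) is a candidate for prior modification
#' iff the variant position lies inside an occurrence of TF i's motif, that
#' occurrence lies entirely within gene j's promoter window and — unless
#' disabled for ablation — the variant has a statistically significant eQTL
#' association whose eGene is gene j itself (the gene adjacent to the
#' promoter harboring the variant).
#'
#' Exclusion counts per filter are attached as `attr(, "filter_counts")`
#' (one row per filter, counting distinct variants removed at that step,
#' applied in order: promoter-motif membership, eQTL significance, eGene
#' match) and retrievable with [filter_report()].
#'
#' @param variants Tibble of variants: `variant_id`, `chrom`, `pos`
#'   (0-based), plus `egene`, `beta`, `significant` when the eQTL
#'   conditions are enforced. An eQTL table from [read_eqtl()] fits
#'   directly.
#' @param hits Motif occurrences (see [build_motif_prior()]).
#' @param promoters Promoter windows from [build_promoters()].
#' @param require_eqtl If `FALSE` (the eQTL ablation), significance and
#'   eGene-match filters are skipped and `beta` is not required.
#' @return Tibble of candidate triples: `variant_id`, `tf_name`, `gene_id`,
#'   `chrom`, `pos`, and `beta` (NA when `require_eqtl = FALSE` and absent).
#' @export
select_candidate_snps <- function(variants, hits, promoters,
                                  require_eqtl = TRUE) {
  variants <- as_tibble(variants)
  if (require_eqtl) {
    needed <- c("variant_id", "chrom", "pos", "egene", "beta", "significant")
  } else {
    needed <- c("variant_id", "chrom", "pos")
  }
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols) > 0) {
    abort(paste0("variant table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (require_eqtl) {
    orphan <- !(variants$egene %in% promoters$gene_id)
    if (any(orphan)) {
      inform(paste0(sum(orphan), " eQTL record(s) with eGene absent from ",
                    "annotation dropped"))
      variants <- variants[!orphan, , drop = FALSE]
    }
  }
  # motif occurrences fully contained in a promoter window
  hits_in_prom <- inner_join(
    as_tibble(hits), promoters,
    by = join_by("chrom", x$start >= y$start, x$end <= y$end),
    suffix = c("", ".prom")
  )
  # variant position inside such an occurrence (half-open)
  triples <- inner_join(
    variants, hits_in_prom,
    by = join_by("chrom", x$pos >= y$start, x$pos < y$end),
    suffix = c(".var", ".hit")
  )
  counts <- tibble(filter = character(), n_excluded = integer())
  tally <- function(counts, name, before, after) {
    bind_rows(counts, tibble(
      filter = name,
      n_excluded = length(setdiff(unique(before$variant_id),
                                  unique(after$variant_id)))))
  }
  counts <- tally(counts, "not_in_promoter_motif", variants, triples)
  if (require_eqtl) {
    sig <- filter(triples, .data$significant)
    counts <- tally(counts, "eqtl_not_significant", triples, sig)
    matched <- filter(sig, .data$egene == .data$gene_id)
    counts <- tally(counts, "egene_mismatch", sig, matched)
    triples <- matched
  } else {
    triples$beta <- if ("beta" %in% names(variants)) triples$beta else NA_real_
  }
  out <- triples |>
    distinct(.data$variant_id, .data$tf_name, .data$gene_id,
             .data$chrom, .data$pos, .data$beta)
  attr(out, "filter_counts") <- counts
  out
}

#' Compute genotype-specific prior modifiers
#'
#' For one individual, the modifier of the (TF i, gene j) prior entry is
#' the sum over qualifying candidate variants s of `|q * A * beta|`, where
#' q is the predicted binding effect (kept only when negative — only
#' disruption of binding is modeled, never creation — and significant at
#' `qbic_p_threshold`), A the individual's alternate allele count and beta
#' the eQTL effect size. Ablation modes drop one factor: `drop = "qbic"`
#' sums `|A * beta|` over eQTL candidates without any binding-effect
#' requirement; `drop = "eqtl"` sums `|q * A|` (candidates must then come
#' from [select_candidate_snps()] with `require_eqtl = FALSE`).
#'
#' Per-filter exclusion counts (distinct variants) are attached as
#' `attr(, "filter_counts")`.
#'
#' @param candidates Candidate triples from [select_candidate_snps()].
#' @param qbic Binding effect predictions: `variant_id`, `tf_name`,
#'   `q_effect`, `p_value`. Ignored when `drop = "qbic"`.
#' @param genotype One individual's genotype: tibble with `variant_id`,
#'   `alt_count` (0/1/2). Candidate variants absent from the genotype count
#'   as 0 alternate alleles and are tallied.
#' @param qbic_p_threshold Significance threshold on the binding-effect
#'   p-value (interpreted as already corrected across a variant's
#'   predictions).
#' @param drop `"none"` (full model), `"qbic"` or `"eqtl"`.
#' @return Tibble with `tf_name`, `gene_id`, `modifier` (> 0; zero-total
#'   pairs are omitted).
#' @export
compute_modifiers <- function(candidates, qbic = NULL, genotype,
                              qbic_p_threshold = 0.05,
                              drop = c("none", "qbic", "eqtl")) {
  drop <- match.arg(drop)
  cand <- as_tibble(candidates)
  counts <- tibble(filter = character(), n_excluded = integer())
  tally <- function(counts, name, before, after) {
    bind_rows(counts, tibble(
      filter = name,
      n_excluded = length(setdiff(unique(before$variant_id),
                                  unique(after$variant_id)))))
  }
  if (drop != "qbic") {
    if (is.null(qbic)) abort("qbic table required unless drop = \"qbic\"")
    cand <- left_join(cand, as_tibble(qbic),
                      by = c("variant_id", "tf_name"))
    with_pred <- filter(cand, !is.na(.data$q_effect))
    counts <- tally(counts, "no_binding_prediction", cand, with_pred)
    neg <- filter(with_pred, .data$q_effect < 0)
    counts <- tally(counts, "q_nonnegative", with_pred, neg)
    sig <- filter(neg, .data$p_value <= qbic_p_threshold)
    counts <- tally(counts, "q_not_significant", neg, sig)
    cand <- sig
  }
  gt <- as_tibble(genotype)
  stopifnot(all(c("variant_id", "alt_count") %in% names(gt)))
  cand <- left_join(cand, select(gt, "variant_id", "alt_count"),
                    by = "variant_id")
  n_unknown <- length(unique(cand$variant_id[is.na(cand$alt_count)]))
  if (n_unknown > 0) {
    inform(paste0(n_unknown, " candidate variant(s) missing from genotype; ",
                  "treated as homozygous reference"))
  }
  counts <- bind_rows(counts, tibble(filter = "genotype_missing",
                                     n_excluded = n_unknown))
  cand$alt_count[is.na(cand$alt_count)] <- 0L
  carried <- filter(cand, .data$alt_count >= 1)
  counts <- tally(counts, "allele_count_zero", cand, carried)
  contribution <- switch(
    drop,
    none = abs(carried$q_effect * carried$alt_count * carried$beta),
    qbic = abs(carried$alt_count * carried$beta),
    eqtl = abs(carried$q_effect * carried$alt_count)
  )
  out <- carried |>
    mutate(contribution = contribution) |>
    group_by(.data$tf_name, .data$gene_id) |>
    summarise(modifier = sum(.data$contribution), .groups = "drop") |>
    filter(.data$modifier > 0)
  attr(out, "filter_counts") <- counts
  out
}

#' Retrieve per-filter exclusion counts
#'
#' [select_candidate_snps()] and [compute_modifiers()] record how many
#' distinct variants each filter removed; this accessor returns that log.
#'
#' @param x Object carrying a `filter_counts` attribute.
#' @return Tibble with `filter`, `n_excluded`.
#' @export
filter_report <- function(x) {
  fc <- attr(x, "filter_counts")
  if (is.null(fc)) abort("object carries no filter log")
  fc
}

#' Assemble an individual's genotype-penalized prior E
#'
#' `E = M - modifier`, elementwise, with modifier 0 where no qualifying
#' variant exists. E is deliberately not clamped at zero: the formula has
#' no floor and the message-passing normalization absorbs scale, so large
#' dosage-weighted penalties may push entries negative.
#'
#' @param motif_prior Binary matrix from [build_motif_prior()].
#' @param modifiers Tibble from [compute_modifiers()].
#' @param individual_id Optional identifier stored as an attribute.
#' @return Numeric matrix, same dimnames as `motif_prior`, with
#'   `attr(, "individual_id")` set. Errors if a modifier key falls outside
#'   the prior's label space (an upstream label mismatch).
#' @export
build_genotype_prior <- function(motif_prior, modifiers,
                                 individual_id = NULL) {
  stopifnot(is.matrix(motif_prior))
  e <- motif_prior
  attr(e, "n_skipped_chrom") <- NULL
  if (nrow(modifiers) > 0) {
    bad_tf <- setdiff(modifiers$tf_name, rownames(e))
    bad_gene <- setdiff(modifiers$gene_id, colnames(e))
    if (length(bad_tf) > 0 || length(bad_gene) > 0) {
      abort(paste0("modifier keys outside the prior label space: ",
                   paste(c(bad_tf, bad_gene), collapse = ", ")))
    }
    idx <- cbind(match(modifiers$tf_name, rownames(e)),
                 match(modifiers$gene_id, colnames(e)))
    e[idx] <- e[idx] - modifiers$modifier
  }
  attr(e, "individual_id") <- individual_id
  e
}
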