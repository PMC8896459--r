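#' Symmetric TF cooperativity matrix from an edge list
#'
#' @param edges Tibble with `tf1`, `tf2`, `weight`.
#' @param tf_names TF label space. TFs without edges keep only their
#'   diagonal self-interaction of 1.
#' @return Symmetric m x m matrix with unit diagonal.
#' @export
ppi_matrix <- function(edges, tf_names) {
  m <- diag(1, length(tf_names))
  dimnames(m) <- list(tf_names, tf_names)
  edges <- filter(as_tibble(edges),
                  .data$tf1 %in% tf_names & .data$tf2 %in% tf_names)
  if (nrow(edges) > 0) {
    i <- match(edges$tf1, tf_names)
    j <- match(edges$tf2, tf_names)
    m[cbind(i, j)] <- edges$weight
    m[cbind(j, i)] <- edges$weight
  }
  m
}

#' Run the full genotype-specific network pipeline on a cohort
#'
#' For the cohort as a whole: builds promoter windows, the reference motif
#' prior M, the coexpression matrix C (after the low-expression filter) and
#' the TF cooperativity matrix P, and refines M into the genotype-agnostic
#' baseline network B* by message passing. For each genotyped individual:
#' selects candidate variants, computes prior modifiers, assembles the
#' penalized prior E, refines it into the individual's network E*, and
#' scores the disruption |E* - B*|. Deterministic given its inputs.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()] or a `grn_cohort`
#'   from [read_cohort()] (any list with `annotation`, `motif_hits`,
#'   `genotypes`, `eqtls`, `qbic`, `expression`, `ppi` works).
#' @param individuals Individuals to process; default all in the genotype
#'   table.
#' @param config Message-passing settings, a [panda_config()].
#' @param qbic_p_threshold Binding-effect significance threshold.
#' @param min_nonzero Low-expression filter (see
#'   [pearson_coexpression()]).
#' @param message_passing If `FALSE` (ablation), the penalized priors are
#'   returned as the networks themselves and disruption is scored as
#'   |E - M|.
#' @param drop Prior-modifier ablation passed to [compute_modifiers()]:
#'   `"none"`, `"qbic"` or `"eqtl"`.
#' @return A `grn_pipeline` list: `motif_prior`, `baseline` (a
#'   [panda()] fit, or M when `message_passing = FALSE`), `candidates`,
#'   `individuals` (per-individual list with `modifiers`, `prior`, `fit`,
#'   `scores`), `config`, `mode`.
#' @export
run_pipeline <- function(cohort, individuals = NULL,
                         config = panda_config(),
                         qbic_p_threshold = 0.05, min_nonzero = 50,
                         message_passing = TRUE,
                         drop = c("none", "qbic", "eqtl")) {
  drop <- match.arg(drop)
  promoters <- cohort$promoters %||% build_promoters(cohort$annotation)
  m <- build_motif_prior(cohort$motif_hits, promoters)
  tfs <- rownames(m)

  cc <- pearson_coexpression(cohort$expression, min_nonzero = min_nonzero)
  genes <- intersect(colnames(m), rownames(cc))
  if (length(genes) < 2) abort("fewer than 2 genes survive the expression filter")
  m <- m[, genes, drop = FALSE]
  cc <- cc[genes, genes, drop = FALSE]
  p <- ppi_matrix(cohort$ppi, tfs)

  if (drop == "eqtl") {
    sites <- distinct(cohort$genotypes, .data$variant_id, .data$chrom,
                      .data$pos)
    candidates <- select_candidate_snps(sites, cohort$motif_hits,
                                        promoters, require_eqtl = FALSE)
  } else {
    candidates <- select_candidate_snps(cohort$eqtls, cohort$motif_hits,
                                        promoters)
  }

  baseline <- if (message_passing) panda(m, p, cc, config) else m

  ids <- individuals %||% sort(unique(cohort$genotypes$individual_id))
  per_ind <- purrr::map(ids, function(id) {
    gt <- filter(cohort$genotypes, .data$individual_id == id)
    mods <- compute_modifiers(candidates, cohort$qbic, gt,
                              qbic_p_threshold = qbic_p_threshold,
                              drop = drop)
    mods_in <- filter(mods, .data$gene_id %in% genes)
    prior <- build_genotype_prior(m, mods_in, individual_id = id)
    if (message_passing) {
      fit <- panda(prior, p, cc, config)
      scores <- disruption_scores(fit, baseline)
    } else {
      fit <- prior
      scores <- structure(list(edge = abs(prior - m),
                               tf = rowSums(abs(prior - m)),
                               gene = colSums(abs(prior - m)),
                               individual_id = id),
                          class = "disruption_scores")
    }
    list(modifiers = mods, prior = prior, fit = fit, scores = scores)
  })
  names(per_ind) <- ids
  structure(list(motif_prior = m, baseline = baseline,
                 candidates = candidates, individuals = per_ind,
                 config = config,
                 mode = list(message_passing = message_passing,
                             drop = drop)),
            class = "grn_pipeline")
}

#' Run a pipeline ablation
#'
#' Re-runs [run_pipeline()] with one evidence source removed, mirroring
#' the sensitivity analyses of the method: `"qbic"` drops the
#' binding-effect requirement (modifiers become `|A * beta|` over eQTL
#' candidates), `"eqtl"` drops the eQTL requirement (modifiers become
#' `|q * A|` over promoter-motif variants with significant negative
#' binding effects), and `"message_passing"` skips the refinement so the
#' penalized prior E itself is the output network.
#'
#' @param cohort As in [run_pipeline()].
#' @param drop One of `"qbic"`, `"eqtl"`, `"message_passing"`.
#' @param ... Passed on to [run_pipeline()].
#' @return A `grn_pipeline` object.
#' @export
run_ablation <- function(cohort,
                         drop = c("qbic", "eqtl", "message_passing"),
                         ...) {
  drop <- match.arg(drop)
  if (drop == "message_passing") {
    run_pipeline(cohort, message_passing = FALSE, ...)
  } else {
    run_pipeline(cohort, drop = drop, ...)
  }
}

#' @export
print.grn_pipeline <- function(x, ...) {
  cat("Genotype-specific GRN pipeline\n")
  cat("  ", nrow(x$motif_prior), " TFs x ", ncol(x$motif_prior),
      " genes, ", length(x$individuals), " individual(s)\n", sep = "")
  cat("  mode: message_passing=", x$mode$message_passing,
      ", drop=", x$mode$drop, "\n", sep = "")
  invisible(x)
}

#' @describeIn run_pipeline Long edge-level disruption table across all
#'   individuals (one row per individual x TF x gene).
#' @param x A `grn_pipeline`.
#' @param ... Unused.
#' @method tidy grn_pipeline
#' @export
tidy.grn_pipeline <- function(x, ...) {
  purrr::imap(x$individuals, function(res, id) {
    out <- matrix_to_edges(res$scores$edge, value_name = "d_edge")
    out$individual_id <- id
    out
  }) |> bind_rows()
}

#' Write pipeline outputs to a directory
#'
#' Per individual: penalized prior, converged network and the three score
#' tables; once per cohort: motif prior and baseline network; plus a
#' `manifest.json` with MD5 checksums of every file.
#'
#' @param result A `grn_pipeline`.
#' @param dir Output directory.
#' @return The manifest list, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  emit <- function(obj, name, writer = write_network_tsv) {
    p <- file.path(dir, name)
    writer(obj, p)
    files <<- c(files, name)
  }
  emit(result$motif_prior, "motif_prior.tsv")
  baseline_net <- if (inherits(result$baseline, "panda_fit")) {
    result$baseline$network
  } else {
    result$baseline
  }
  emit(baseline_net, "baseline_network.tsv")
  purrr::iwalk(result$individuals, function(res, id) {
    emit(res$prior, paste0(id, "_prior.tsv"))
    net <- if (inherits(res$fit, "panda_fit")) res$fit$network else res$fit
    emit(net, paste0(id, "_network.tsv"))
    emit(tidy(res$scores, level = "edge"), paste0(id, "_d_edge.tsv"),
         writer = function(o, p) readr::write_tsv(o, p))
    emit(tidy(res$scores, level = "tf"), paste0(id, "_d_tf.tsv"),
         writer = function(o, p) readr::write_tsv(o, p))
    emit(tidy(res$scores, level = "gene"), paste0(id, "_d_gene.tsv"),
         writer = function(o, p) readr::write_tsv(o, p))
  })
  manifest <- list(
    mode = result$mode,
    files = as.list(setNames(unname(tools::md5sum(file.path(dir, files))),
                             files))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Planted-versus-background separation by disruption score
#'
#' Benchmarks a pipeline run against the simulator's planted truth: pools
#' per-individual edge disruption scores and asks how well they separate
#' planted, carried disruptions (a planted TF-gene edge in an individual
#' who carries at least one alternate allele of the planting variant) from
#' all other (individual, edge) observations, as a Mann-Whitney AUC.
#'
#' @param result A `grn_pipeline` run on a simulated cohort.
#' @param cohort The `sim_cohort` (provides `truth` and genotypes).
#' @param contrast `"planted_vs_rest"` (default, the recovery metric) or
#'   `"carrier_vs_noncarrier"` (restricted to planted edges: do scores
#'   identify which individuals carry the variant? — the quantity a
#'   genotype permutation destroys). The carrier contrast is stratified:
#'   an AUC is computed within each planted edge (where carrier and
#'   non-carrier observations are exchangeable under genotype
#'   permutation) and averaged over edges, so edges with many carriers do
#'   not bias the null away from 0.5. Edges where all individuals fall in
#'   one class are skipped.
#' @return AUC in \[0, 1\].
#' @export
planted_edge_auc <- function(result, cohort,
                             contrast = c("planted_vs_rest",
                                          "carrier_vs_noncarrier")) {
  contrast <- match.arg(contrast)
  obs <- planted_edge_table(result, cohort)
  if (contrast == "planted_vs_rest") {
    roc_auc(obs$d_edge, obs$planted_carried)
  } else {
    vals <- carrier_auc_by_edge(obs)
    mean(vals)
  }
}

# per-planted-edge carrier-vs-noncarrier AUCs (single-class edges dropped)
carrier_auc_by_edge <- function(obs) {
  at_planted <- filter(obs, .data$planted)
  strata <- split(at_planted, paste(at_planted$tf, at_planted$gene))
  vals <- purrr::map_dbl(strata, function(o) {
    if (all(o$carrier) || all(!o$carrier)) return(NA_real_)
    roc_auc(o$d_edge, o$carrier)
  })
  vals[!is.na(vals)]
}

#' Permutation null for carrier identification
#'
#' Repeatedly shuffles genotypes among individuals
#' ([permute_genotypes()]), reruns the pipeline, and collects the
#' per-planted-edge carrier-vs-noncarrier AUCs against the *original*
#' carrier labels. With genotypes decoupled from individuals the
#' expected AUC is 0.5; the pooled mean estimates how close a finite
#' cohort gets.
#'
#' @param cohort A `sim_cohort`.
#' @param n_perm Number of permutations pooled.
#' @param seed Base seed; permutation k uses `seed + k`.
#' @param ... Passed to [run_pipeline()].
#' @return List with `auc` (pooled mean), `per_edge` (all per-edge AUCs),
#'   `n_perm`.
#' @export
permuted_carrier_auc <- function(cohort, n_perm = 24, seed = 1, ...) {
  vals <- purrr::map(seq_len(n_perm), function(k) {
    perm <- permute_genotypes(cohort, seed = seed + k)
    res <- run_pipeline(perm, ...)
    carrier_auc_by_edge(planted_edge_table(res, cohort))
  })
  all_vals <- unlist(vals)
  list(auc = mean(all_vals), per_edge = all_vals, n_perm = n_perm)
}

# per-(individual, edge) disruption with planted/carrier labels
planted_edge_table <- function(result, cohort) {
  truth <- cohort$truth
  carriers <- cohort$genotypes |>
    semi_join(truth, by = "variant_id") |>
    filter(.data$alt_count >= 1) |>
    left_join(select(truth, "variant_id", "tf_name", "gene_id"),
              by = "variant_id") |>
    distinct(.data$individual_id, tf = .data$tf_name,
             gene = .data$gene_id) |>
    mutate(carrier = TRUE)
  tidy(result) |>
    mutate(planted = paste(.data$tf, .data$gene) %in%
             paste(truth$tf_name, truth$gene_id)) |>
    left_join(carriers, by = c("tf", "gene", "individual_id")) |>
    mutate(carrier = !is.na(.data$carrier),
           planted_carried = .data$planted & .data$carrier)
}

#' Mean planted-edge disruption by allele dosage
#'
#' For every planted edge and individual, pairs the edge disruption score
#' with the individual's alternate allele count at the planting variant;
#' returns the mean score per dosage group. Under the model, disruption
#' should be non-decreasing in dosage (homozygous carriers most affected).
#'
#' @param result A `grn_pipeline` run on a simulated cohort.
#' @param cohort The `sim_cohort`.
#' @return Tibble with `alt_count`, `n`, `mean_disruption`.
#' @export
dosage_disruption <- function(result, cohort) {
  truth <- cohort$truth
  dose <- cohort$genotypes |>
    semi_join(truth, by = "variant_id") |>
    left_join(select(truth, "variant_id", "tf_name", "gene_id"),
              by = "variant_id") |>
    select("individual_id", tf = "tf_name", gene = "gene_id", "alt_count")
  tidy(result) |>
    inner_join(dose, by = c("tf", "gene", "individual_id")) |>
    group_by(.data$alt_count) |>
    summarise(n = dplyr::n(), mean_disruption = mean(.data$d_edge),
              .groups = "drop") |>
    arrange(.data$alt_count)
}
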