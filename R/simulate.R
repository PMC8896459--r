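#' Simulation configuration
#'
#' Defines a self-consistent synthetic cohort: a one-chromosome gene
#' annotation, motif occurrences in promoter windows, a genotyped cohort
#' with planted disrupting variants (promoter-motif eQTLs with negative
#' binding effects), decoy variants exercising every filter branch, an
#' expression matrix generated from a linear TF-activity model in which
#' carried planted variants attenuate the TF's contribution to its target,
#' a TF-TF interaction edge list, and binary ChIP-style truth networks for
#' two conditions.
#'
#' Defaults describe a small cohort sized so the full pipeline runs in
#' seconds: 5 TFs x 40 genes, 60 expression samples, 10 genotyped
#' individuals, 8 planted disruptions at a common-variant allele frequency
#' of 0.3, eQTL effect magnitudes around `beta_scale` and binding-effect
#' magnitudes around `q_scale`.
#'
#' @param n_tfs,n_genes,n_samples,n_individuals Cohort dimensions.
#' @param n_planted Number of planted disrupting variants (each in its own
#'   TF-gene promoter motif).
#' @param maf Minor (alternate) allele frequency of every simulated
#'   variant, in (0, 0.5]; genotypes are Hardy-Weinberg draws.
#' @param beta_scale Typical magnitude of eQTL effect sizes.
#' @param q_scale Typical magnitude of predicted binding effects.
#' @param noise_sd Standard deviation of the Gaussian expression noise.
#' @param motif_density Probability a TF's motif occurs in a given
#'   promoter.
#' @param ppi_density Probability of a TF-TF interaction edge.
#' @param attenuation Fractional loss of a TF's contribution to a planted
#'   target at homozygous-alternate dosage (`1 - attenuation * A / 2`).
#' @param n_decoys_per_class Decoy variants per class; the six classes are
#'   `non_promoter`, `nonsig_eqtl`, `wrong_egene`, `positive_q`,
#'   `q_nonsig`, `zero_allele`, each designed to fail exactly one pipeline
#'   filter while passing all others.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tfs = 5, n_genes = 40, n_samples = 60,
                       n_individuals = 10, n_planted = 8, maf = 0.3,
                       beta_scale = 0.5, q_scale = 0.5, noise_sd = 0.5,
                       motif_density = 0.35, ppi_density = 0.2,
                       attenuation = 0.5, n_decoys_per_class = 2,
                       seed = 1) {
  stopifnot(n_planted <= n_tfs * n_genes, maf > 0, maf <= 0.5,
            beta_scale > 0, q_scale > 0, noise_sd > 0,
            attenuation >= 0, attenuation <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# decoy classes, in the documented draw order
DECOY_CLASSES <- c("non_promoter", "nonsig_eqtl", "wrong_egene",
                   "positive_q", "q_nonsig", "zero_allele")

#' Simulate a synthetic cohort
#'
#' Deterministic given the seed. Randomness is consumed in a documented
#' order from derived seeds (all draws are column-major, variants before
#' individuals/samples):
#' \describe{
#'   \item{`seed`}{motif occurrence indicators (one Bernoulli per TF x
#'     gene pair, TF-major), motif offsets within promoters, planted and
#'     decoy slot sampling, eQTL betas, binding effects.}
#'   \item{`seed + 1`}{cohort genotypes: for each variant in order (planted
#'     `1..n_planted`, then decoys by class in `non_promoter`,
#'     `nonsig_eqtl`, `wrong_egene`, `positive_q`, `q_nonsig`,
#'     `zero_allele` order), `rbinom(n_individuals, 2, maf)`; zero-allele
#'     decoys are then forced to 0.}
#'   \item{`seed + 2`}{expression: TF-gene weights, per-sample genotypes at
#'     planted variants, TF activities, Gaussian noise.}
#'   \item{`seed + 3`}{TF-TF interaction edges.}
#' }
#'
#' @param config A [sim_config()].
#' @return A `sim_cohort` list with elements `annotation`, `promoters`,
#'   `motif_hits`, `variants`, `genotypes` (long: variant x individual),
#'   `eqtls`, `qbic`, `expression` (genes x samples matrix), `ppi`
#'   (edge list), `truth` (planted variant-TF-gene table), `chip`
#'   (two binary networks differing exactly at planted edges), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  genes <- sprintf("g%02d", seq_len(cfg$n_genes))
  tfs <- sprintf("TF%d", seq_len(cfg$n_tfs))
  individuals <- sprintf("ind%02d", seq_len(cfg$n_individuals))
  samples <- sprintf("s%02d", seq_len(cfg$n_samples))

  annotation <- tibble(
    gene_id = genes, chrom = "chr1",
    tss = as.integer(100000 + (seq_len(cfg$n_genes) - 1) * 10000),
    strand = rep(c("+", "-"), length.out = cfg$n_genes)
  )
  promoters <- build_promoters(annotation)

  set.seed(cfg$seed)
  # motif occurrences: TF-major Bernoulli grid, then one offset per hit
  occ <- matrix(rbinom(cfg$n_tfs * cfg$n_genes, 1, cfg$motif_density),
                nrow = cfg$n_tfs, byrow = TRUE,
                dimnames = list(tfs, genes))
  motif_width <- 11L
  slots <- expand_grid(tf_name = tfs, gene_id = genes) |>
    mutate(present = as.vector(t(occ))[
      (match(.data$tf_name, tfs) - 1) * cfg$n_genes +
        match(.data$gene_id, genes)]) |>
    filter(.data$present == 1) |>
    select(-"present")
  slots <- left_join(slots, promoters, by = "gene_id")
  slots$offset <- floor(runif(nrow(slots), 0,
                              (slots$end - slots$start) - motif_width + 1))
  motif_hits <- slots |>
    mutate(start = .data$start + as.integer(.data$offset),
           end = .data$start + motif_width,
           strand = "+", score = 12.0, p_value = 1e-5) |>
    select("tf_name", "chrom", "start", "end", "strand", "score", "p_value")

  n_slots <- nrow(motif_hits)
  slot_classes <- setdiff(DECOY_CLASSES, "non_promoter")
  n_needed <- cfg$n_planted + cfg$n_decoys_per_class * length(slot_classes)
  if (n_slots < n_needed) {
    abort(paste0("infeasible planting: ", n_slots, " promoter motif slots ",
                 "but ", n_needed, " needed; raise motif_density or n_genes"))
  }
  picked <- sample(n_slots, n_needed)
  planted_idx <- picked[seq_len(cfg$n_planted)]
  decoy_idx <- split(
    picked[cfg$n_planted + seq_len(n_needed - cfg$n_planted)],
    rep(slot_classes, each = cfg$n_decoys_per_class)
  )

  snv_at <- function(hit_rows, ids) {
    h <- motif_hits[hit_rows, , drop = FALSE]
    prom_gene <- promoters$gene_id[
      match_interval(h$start, promoters$start, promoters$end)]
    tibble(variant_id = ids, chrom = h$chrom,
           pos = as.integer(h$start + motif_width %/% 2),
           ref = "A", alt = "C", tf_name = h$tf_name, gene_id = prom_gene)
  }

  planted <- snv_at(planted_idx, sprintf("var_p%d", seq_len(cfg$n_planted)))
  planted$beta <- -abs(rnorm(cfg$n_planted, cfg$beta_scale,
                             0.2 * cfg$beta_scale))
  planted$q <- -runif(cfg$n_planted, 0.5, 1.5) * cfg$q_scale

  nd <- cfg$n_decoys_per_class
  decoys <- list()
  # non_promoter: intergenic position, real eQTL for the nearest gene,
  # disruptive binding prediction -- only the promoter-motif filter removes it
  np_genes <- sample(genes, nd)
  decoys$non_promoter <- tibble(
    variant_id = sprintf("var_np%d", seq_len(nd)), chrom = "chr1",
    pos = annotation$tss[match(np_genes, genes)] + 5000L,
    ref = "A", alt = "C",
    tf_name = sample(tfs, nd, replace = TRUE), gene_id = np_genes)
  for (cl in slot_classes) {
    decoys[[cl]] <- snv_at(decoy_idx[[cl]],
                           sprintf("var_%s%d", abbrev_class(cl), seq_len(nd)))
  }
  decoys <- imap(decoys, function(d, cl) {
    d$class <- cl
    d$beta <- -abs(rnorm(nrow(d), cfg$beta_scale, 0.2 * cfg$beta_scale))
    d$q <- -runif(nrow(d), 0.5, 1.5) * cfg$q_scale
    d
  })
  decoys$wrong_egene$egene <- purrr::map_chr(
    decoys$wrong_egene$gene_id,
    function(g) sample(setdiff(genes, g), 1))
  decoy_tab <- bind_rows(decoys)
  decoy_tab$egene <- decoy_tab$egene %||% NA_character_
  decoy_tab$egene[is.na(decoy_tab$egene)] <-
    decoy_tab$gene_id[is.na(decoy_tab$egene)]

  variants <- bind_rows(
    planted |> mutate(class = "planted", egene = .data$gene_id),
    decoy_tab
  )

  # eQTL table: every variant gets a record; significance false only for
  # the nonsig_eqtl class
  eqtls <- variants |>
    mutate(significant = .data$class != "nonsig_eqtl",
           pval = ifelse(.data$significant, 1e-8, 0.4)) |>
    select("variant_id", "chrom", "pos", "ref", "alt",
           egene = "egene", "beta", "significant", "pval")

  # binding-effect table: q flipped positive for positive_q, p inflated for
  # q_nonsig
  qbic <- variants |>
    mutate(q_effect = ifelse(.data$class == "positive_q", abs(.data$q), .data$q),
           p_value = ifelse(.data$class == "q_nonsig", 0.5, 1e-6)) |>
    select("variant_id", "tf_name", "q_effect", "p_value")

  # cohort genotypes: derived seed, variant-major draw order
  set.seed(cfg$seed + 1)
  geno <- matrix(0L, nrow(variants), cfg$n_individuals,
                 dimnames = list(variants$variant_id, individuals))
  for (v in seq_len(nrow(variants))) {
    geno[v, ] <- rbinom(cfg$n_individuals, 2, cfg$maf)
  }
  geno[variants$class == "zero_allele", ] <- 0L
  genotypes <- matrix_to_edges(geno, value_name = "alt_count",
                               row_name = "variant_id",
                               col_name = "individual_id") |>
    mutate(alt_count = as.integer(.data$alt_count)) |>
    left_join(select(variants, "variant_id", "chrom", "pos", "ref", "alt"),
              by = "variant_id") |>
    select("variant_id", "chrom", "pos", "ref", "alt",
           "individual_id", "alt_count")

  # expression: linear TF-activity model with dosage attenuation at
  # planted pairs
  set.seed(cfg$seed + 2)
  w <- matrix(runif(cfg$n_tfs * cfg$n_genes, 0.5, 1.5),
              nrow = cfg$n_tfs, dimnames = list(tfs, genes))
  planted_expr <- variants |> filter(.data$class == "planted")
  sample_geno <- matrix(0L, nrow(planted_expr), cfg$n_samples,
                        dimnames = list(planted_expr$variant_id, samples))
  for (v in seq_len(nrow(planted_expr))) {
    sample_geno[v, ] <- rbinom(cfg$n_samples, 2, cfg$maf)
  }
  activity <- matrix(rnorm(cfg$n_tfs * cfg$n_samples), nrow = cfg$n_tfs,
                     dimnames = list(tfs, samples))
  expr <- matrix(0, cfg$n_genes, cfg$n_samples,
                 dimnames = list(genes, samples))
  for (j in seq_len(cfg$n_genes)) {
    contrib <- occ[, j] * w[, j] * activity          # n_tfs x n_samples
    pj <- which(planted_expr$gene_id == genes[j])
    for (v in pj) {
      i <- match(planted_expr$tf_name[v], tfs)
      contrib[i, ] <- contrib[i, ] *
        (1 - cfg$attenuation * sample_geno[v, ] / 2)
    }
    expr[j, ] <- colSums(contrib)
  }
  expr <- expr + matrix(rnorm(length(expr), 0, cfg$noise_sd),
                        nrow = nrow(expr))

  # TF-TF interactions
  set.seed(cfg$seed + 3)
  pairs <- which(upper.tri(matrix(0, cfg$n_tfs, cfg$n_tfs)), arr.ind = TRUE)
  on <- rbinom(nrow(pairs), 1, cfg$ppi_density) == 1
  ppi <- tibble(tf1 = tfs[pairs[on, 1]], tf2 = tfs[pairs[on, 2]], weight = 1)

  truth <- planted |>
    select("variant_id", "tf_name", "gene_id", "chrom", "pos", "beta", "q")

  m <- build_motif_prior(motif_hits, promoters, tf_names = tfs)
  chip_b <- m
  chip_b[cbind(match(truth$tf_name, tfs), match(truth$gene_id, genes))] <- 0
  structure(list(
    annotation = annotation, promoters = promoters,
    motif_hits = motif_hits, variants = variants, genotypes = genotypes,
    eqtls = eqtls, qbic = qbic, expression = expr, ppi = ppi,
    truth = truth, chip = list(reference = m, variant = chip_b),
    config = cfg
  ), class = "sim_cohort")
}

abbrev_class <- function(cl) {
  c(non_promoter = "np", nonsig_eqtl = "ns", wrong_egene = "we",
    positive_q = "pq", q_nonsig = "qn", zero_allele = "za")[[cl]]
}

# index of the (first) half-open interval containing each position
match_interval <- function(pos, starts, ends) {
  purrr::map_int(pos, function(p) {
    hit <- which(starts <= p & p < ends)
    if (length(hit) == 0) NA_integer_ else hit[1]
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort: ", x$config$n_tfs, " TFs x ", x$config$n_genes,
      " genes, ", x$config$n_individuals, " individuals, ",
      x$config$n_samples, " expression samples\n", sep = "")
  cat("  ", nrow(x$truth), " planted disrupting variant(s), ",
      sum(x$variants$class != "planted"), " decoys (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Shuffle genotypes among individuals
#'
#' No-signal control: redistributes the individuals' genotype vectors by a
#' uniformly drawn permutation, leaving every other cohort component
#' untouched. Carrier frequencies at every variant are preserved, but
#' which individual carries what becomes exchangeable with respect to the
#' original labels, so downstream disruption scores can no longer identify
#' the true carriers (a uniform permutation — rather than one forbidding
#' fixed points — is what makes the labels exactly exchangeable).
#'
#' @param cohort A `sim_cohort`.
#' @param seed Seed for drawing the permutation.
#' @return The cohort with permuted genotype assignments;
#'   `attr(, "permutation")` maps each individual to the individual whose
#'   genotypes they received.
#' @export
permute_genotypes <- function(cohort, seed = 1) {
  stopifnot(inherits(cohort, "sim_cohort"))
  individuals <- sort(unique(cohort$genotypes$individual_id))
  n <- length(individuals)
  if (n < 2) abort("need at least 2 individuals to permute")
  set.seed(seed)
  perm <- sample(n)
  map <- setNames(individuals[perm], individuals)
  out <- cohort
  out$genotypes$individual_id <- names(map)[
    match(out$genotypes$individual_id, unname(map))]
  out$genotypes <- arrange(out$genotypes, .data$variant_id,
                           .data$individual_id)
  attr(out, "permutation") <- map
  out
}
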