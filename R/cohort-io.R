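#' Write a simulated cohort to standard-format files
#'
#' Emits one file per data type — annotation TSV (1-based TSS), FIMO-style
#' motif hit TSV (1-based inclusive), VCF with per-individual GT columns
#' (sorted, 1-based), eQTL TSV, binding-effect TSV, expression TSV, PPI
#' TSV, the two ChIP-style truth networks as sparse TSV, a machine-readable
#' planted-truth TSV, and a `manifest.json` listing every file with its
#' MD5 checksum and the seed. [read_cohort()] reconstructs the cohort from
#' the directory.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest as a list, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory ", dir))
  }
  path <- function(f) file.path(dir, f)

  readr::write_tsv(cohort$annotation |> mutate(tss = .data$tss + 1L),
                   path("annotation.tsv"))
  readr::write_tsv(
    cohort$motif_hits |>
      mutate(start = .data$start + 1L, stop = .data$end) |>
      select(motif_id = "tf_name", sequence_name = "chrom", "start",
             "stop", "strand", "score", `p-value` = "p_value"),
    path("motif_hits.tsv"))
  write_vcf(cohort$genotypes, path("genotypes.vcf"))
  readr::write_tsv(cohort$eqtls |> mutate(pos = .data$pos + 1L),
                   path("eqtls.tsv"))
  readr::write_tsv(cohort$qbic, path("qbic.tsv"))
  readr::write_tsv(as_tibble(cohort$expression, rownames = "gene_id"),
                   path("expression.tsv"))
  readr::write_tsv(cohort$ppi, path("ppi.tsv"))
  readr::write_tsv(cohort$truth, path("truth.tsv"))
  write_network_tsv(cohort$chip$reference, path("chip_reference.tsv"))
  write_network_tsv(cohort$chip$variant, path("chip_variant.tsv"))

  files <- c("annotation.tsv", "motif_hits.tsv", "genotypes.vcf",
             "eqtls.tsv", "qbic.tsv", "expression.tsv", "ppi.tsv",
             "truth.tsv", "chip_reference.tsv", "chip_variant.tsv")
  manifest <- list(
    seed = cohort$config$seed,
    config = unclass(cohort$config),
    files = as.list(setNames(unname(tools::md5sum(file.path(dir, files))),
                             files))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

# minimal sorted VCFv4.2 with GT-only FORMAT; read back via vcfR
write_vcf <- function(genotypes, path) {
  gt <- genotypes |>
    mutate(gt = c("0/0", "0/1", "1/1")[.data$alt_count + 1L]) |>
    select("variant_id", "chrom", "pos", "ref", "alt",
           "individual_id", "gt") |>
    pivot_wider(names_from = "individual_id", values_from = "gt")
  gt <- arrange(gt, .data$chrom, .data$pos)
  individuals <- setdiff(names(gt), c("variant_id", "chrom", "pos",
                                      "ref", "alt"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gsgrn-simulator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", individuals), collapse = "\t")
  )
  body <- apply(gt, 1, function(r) {
    paste(c(r[["chrom"]], as.integer(r[["pos"]]) + 1L, r[["variant_id"]],
            r[["ref"]], r[["alt"]], ".", "PASS", ".", "GT",
            unname(r[individuals])), collapse = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return A `sim_cohort`-shaped list (class `grn_cohort`) with the same
#'   tabular components, ready for [run_pipeline()].
#' @export
read_cohort <- function(dir) {
  path <- function(f) file.path(dir, f)
  annotation <- read_annotation(path("annotation.tsv"))
  promoters <- build_promoters(annotation)
  genotypes <- read_vcf_genotypes(path("genotypes.vcf"))
  tfs <- sort(unique(read_qbic(path("qbic.tsv"))$tf_name))
  chip <- NULL
  if (file.exists(path("chip_reference.tsv"))) {
    genes <- annotation$gene_id
    chip <- list(
      reference = read_network_tsv(path("chip_reference.tsv"), tfs, genes),
      variant = read_network_tsv(path("chip_variant.tsv"), tfs, genes))
  }
  truth <- if (file.exists(path("truth.tsv"))) {
    readr::read_tsv(path("truth.tsv"), show_col_types = FALSE)
  }
  structure(list(
    annotation = annotation, promoters = promoters,
    motif_hits = read_fimo(path("motif_hits.tsv")),
    genotypes = genotypes,
    eqtls = read_eqtl(path("eqtls.tsv")),
    qbic = read_qbic(path("qbic.tsv")),
    expression = read_expression(path("expression.tsv")),
    ppi = read_ppi(path("ppi.tsv")),
    truth = truth, chip = chip
  ), class = "grn_cohort")
}
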