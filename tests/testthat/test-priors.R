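toy_hits <- function() {
  tibble::tibble(
    tf_name = c("TF1", "TF1", "TF1", "TF2", "TF3"),
    chrom = "chr1",
    # three TF1 hits in gA's promoter [9250, 10250); TF2 in gB's
    # [49750, 50750); TF3 outside any promoter
    start = c(9300L, 9400L, 9500L, 50000L, 20000L),
    end = c(9311L, 9411L, 9511L, 50011L, 20011L),
    strand = "+", score = 10, p_value = 1e-5)
}

test_that("motif prior is a binary occupancy indicator", {
  pr <- toy_promoters()
  m <- build_motif_prior(toy_hits(), pr)
  expect_true(all(m %in% c(0, 1)))
  expect_equal(m["TF1", "gA"], 1)   # three hits still give 1
  expect_equal(m["TF2", "gB"], 1)
  expect_equal(m["TF3", "gA"], 0)
  expect_equal(m["TF3", "gB"], 0)
  # brute-force occupancy oracle, then binarize
  counts <- oracle_overlap_matrix(toy_hits(), pr, rownames(m))
  expect_equal(unname(m), unname(1 * (counts > 0)), ignore_attr = TRUE)
  expect_equal(counts["TF1", "gA"], 3)
})

test_that("motif prior handles empty input and foreign chromosomes", {
  pr <- toy_promoters()
  empty <- toy_hits()[0, ]
  m <- build_motif_prior(empty, pr, tf_names = c("TF1", "TF2"))
  expect_equal(sum(m), 0)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(colnames(m), pr$gene_id)
  foreign <- toy_hits()
  foreign$chrom[1] <- "chrUn"
  expect_message(m2 <- build_motif_prior(foreign, pr), "skipped")
  expect_equal(attr(m2, "n_skipped_chrom"), 1)
  expect_equal(m2["TF1", "gA"], 1)  # other TF1 hits still there
})

toy_eqtls <- function() {
  tibble::tibble(
    variant_id = paste0("v", 1:5),
    chrom = "chr1",
    pos = c(9305L,   # in TF1 motif, egene gA, significant -> retained
            9405L,   # in TF1 motif but egene gB -> excluded (eGene mismatch)
            9505L,   # in TF1 motif, egene gA, not significant -> excluded
            20005L,  # in TF3 motif outside promoters -> excluded
            50005L), # in TF2 motif in gB promoter, egene gB -> retained
    ref = "A", alt = "C",
    egene = c("gA", "gB", "gA", "gA", "gB"),
    beta = c(0.3, 0.2, 0.4, 0.5, -0.6),
    significant = c(TRUE, TRUE, FALSE, TRUE, TRUE))
}

test_that("candidate selection matches the exhaustive triple-loop oracle", {
  pr <- toy_promoters()
  cand <- select_candidate_snps(toy_eqtls(), toy_hits(), pr)
  oracle <- oracle_candidates(toy_eqtls(), toy_hits(), pr)
  got <- dplyr::arrange(cand[, c("variant_id", "tf_name", "gene_id")],
                        variant_id)
  attr(got, "filter_counts") <- NULL
  want <- dplyr::arrange(tibble::as_tibble(oracle), variant_id)
  expect_equal(got, want)
  expect_setequal(cand$variant_id, c("v1", "v5"))
})

test_that("candidate filters log exclusions per reason", {
  cand <- select_candidate_snps(toy_eqtls(), toy_hits(), toy_promoters())
  fc <- filter_report(cand)
  expect_equal(fc$n_excluded[fc$filter == "not_in_promoter_motif"], 1) # v4
  expect_equal(fc$n_excluded[fc$filter == "eqtl_not_significant"], 1)  # v3
  expect_equal(fc$n_excluded[fc$filter == "egene_mismatch"], 1)        # v2
})

test_that("eGene must be the promoter's own gene", {
  pr <- toy_promoters()
  e <- toy_eqtls()[2, ]  # inside a gA-promoter motif, but eGene is gB
  cand <- select_candidate_snps(e, toy_hits(), pr)
  expect_equal(nrow(cand), 0)
})

toy_qbic <- function() {
  tibble::tibble(
    variant_id = c("v1", "v5"),
    tf_name = c("TF1", "TF2"),
    q_effect = c(-0.5, -0.8),
    p_value = c(1e-4, 1e-4))
}

test_that("modifiers multiply |q|, allele count and |beta| and sum over SNPs", {
  pr <- toy_promoters()
  cand <- select_candidate_snps(toy_eqtls(), toy_hits(), pr)
  gt <- tibble::tibble(variant_id = c("v1", "v5"), alt_count = c(2L, 0L))
  mods <- compute_modifiers(cand, toy_qbic(), gt)
  # |q| * A * |beta| = 0.5 * 2 * 0.3, independently: 0.30
  expect_equal(nrow(mods), 1)
  expect_equal(mods$modifier, 0.5 * 2 * 0.3)

  # two qualifying SNPs in the same TF-gene promoter motif sum
  cand2 <- tibble::tibble(variant_id = c("s1", "s2"), tf_name = "TF1",
                          gene_id = "gA", chrom = "chr1",
                          pos = c(1L, 2L), beta = c(0.2, 0.1))
  qb2 <- tibble::tibble(variant_id = c("s1", "s2"), tf_name = "TF1",
                        q_effect = c(-1, -1), p_value = 1e-6)
  gt2 <- tibble::tibble(variant_id = c("s1", "s2"), alt_count = c(1L, 1L))
  mods2 <- compute_modifiers(cand2, qb2, gt2)
  expect_equal(mods2$modifier, 0.2 + 0.1)
})

test_that("homozygous-reference genotypes produce no modifiers", {
  cand <- select_candidate_snps(toy_eqtls(), toy_hits(), toy_promoters())
  gt0 <- tibble::tibble(variant_id = c("v1", "v5"), alt_count = c(0L, 0L))
  mods <- compute_modifiers(cand, toy_qbic(), gt0)
  expect_equal(nrow(mods), 0)
})

test_that("only significant negative binding effects qualify", {
  cand <- select_candidate_snps(toy_eqtls(), toy_hits(), toy_promoters())
  gt <- tibble::tibble(variant_id = c("v1", "v5"), alt_count = c(1L, 1L))
  pos_q <- toy_qbic()
  pos_q$q_effect <- abs(pos_q$q_effect)
  expect_equal(nrow(compute_modifiers(cand, pos_q, gt)), 0)
  weak_q <- toy_qbic()
  weak_q$p_value <- 0.5
  expect_equal(nrow(compute_modifiers(cand, weak_q, gt)), 0)
  fc <- filter_report(compute_modifiers(cand, pos_q, gt))
  expect_equal(fc$n_excluded[fc$filter == "q_nonnegative"], 2)
})

test_that("modifier is linear in allele count", {
  cand <- select_candidate_snps(toy_eqtls(), toy_hits(), toy_promoters())
  m1 <- compute_modifiers(cand, toy_qbic(),
                          tibble::tibble(variant_id = "v1", alt_count = 1L))
  m2 <- compute_modifiers(cand, toy_qbic(),
                          tibble::tibble(variant_id = "v1", alt_count = 2L))
  expect_equal(m2$modifier, 2 * m1$modifier)
})

test_that("candidates missing from the genotype contribute nothing but are logged", {
  cand <- select_candidate_snps(toy_eqtls(), toy_hits(), toy_promoters())
  gt <- tibble::tibble(variant_id = "v1", alt_count = 1L)  # v5 absent
  expect_message(mods <- compute_modifiers(cand, toy_qbic(), gt),
                 "missing from genotype")
  fc <- filter_report(mods)
  expect_equal(fc$n_excluded[fc$filter == "genotype_missing"], 1)
  expect_setequal(mods$tf_name, "TF1")
})

test_that("genotype prior subtracts modifiers without clamping", {
  m <- matrix(c(1, 0, 1, 1), 2, 2,
              dimnames = list(c("TF1", "TF2"), c("gA", "gB")))
  empty <- tibble::tibble(tf_name = character(), gene_id = character(),
                          modifier = numeric())
  e0 <- build_genotype_prior(m, empty)
  expect_equal(unname(e0), unname(m))

  mods <- tibble::tibble(tf_name = c("TF1", "TF2"), gene_id = c("gA", "gB"),
                         modifier = c(0.3, 1.4))
  e <- build_genotype_prior(m, mods, individual_id = "x")
  expect_equal(e["TF1", "gA"], 0.7)
  expect_equal(e["TF2", "gB"], 1 - 1.4)  # negative values are allowed
  expect_equal(attr(e, "individual_id"), "x")

  stray <- tibble::tibble(tf_name = "TFX", gene_id = "gA", modifier = 0.1)
  expect_error(build_genotype_prior(m, stray), "label space")
})

test_that("penalized prior never exceeds the motif prior", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(rbinom(12, 1, 0.5), 3, 4,
                dimnames = list(paste0("TF", 1:3), paste0("g", 1:4)))
    k <- sample(3, 1)
    mods <- tibble::tibble(
      tf_name = sample(rownames(m), k, replace = TRUE),
      gene_id = sample(colnames(m), k, replace = TRUE),
      modifier = runif(k, 0, 2)) |>
      dplyr::distinct(tf_name, gene_id, .keep_all = TRUE)
    e <- build_genotype_prior(m, mods)
    expect_true(all(e <= m + 1e-15))
    untouched <- !(paste(rownames(m)[row(m)], colnames(m)[col(m)]) %in%
                     paste(mods$tf_name, mods$gene_id))
    expect_equal(e[untouched], m[untouched])
  }
})
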