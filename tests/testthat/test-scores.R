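fake_fit <- function(net, cfg = panda_config(), id = NULL) {
  structure(list(network = net, config = cfg, individual_id = id,
                 iterations = 1L, converged = TRUE, hamming_trace = 0),
            class = "panda_fit")
}

toy_nets <- function() {
  dn <- list(c("TF1", "TF2"), c("g1", "g2"))
  b <- matrix(0, 2, 2, dimnames = dn)
  e <- matrix(c(0.1, 0, -0.2, 0.3), 2, 2, dimnames = dn)
  list(b = fake_fit(b, id = "base"), e = fake_fit(e, id = "x"))
}

test_that("disruption scores are |E* - B*| with marginal sums", {
  nets <- toy_nets()
  d <- disruption_scores(nets$e, nets$b)
  expect_equal(unname(d$edge), matrix(c(0.1, 0, 0.2, 0.3), 2, 2))
  expect_equal(unname(d$tf), c(0.3, 0.3))
  expect_equal(unname(d$gene), c(0.1, 0.5))
  expect_equal(d$individual_id, "x")
  d0 <- disruption_scores(nets$b, nets$b)
  expect_true(all(d0$edge == 0))
})

test_that("marginals equal row/column sums on random matrices", {
  set.seed(8)
  for (rep in 1:5) {
    dn <- list(paste0("TF", 1:4), paste0("g", 1:7))
    a <- matrix(rnorm(28), 4, 7, dimnames = dn)
    b <- matrix(rnorm(28), 4, 7, dimnames = dn)
    d <- disruption_scores(fake_fit(a), fake_fit(b))
    expect_true(all(d$edge >= 0))
    expect_equal(d$tf, rowSums(d$edge))
    expect_equal(d$gene, colSums(d$edge))
  }
})

test_that("mismatched message-passing configurations are rejected", {
  nets <- toy_nets()
  other <- fake_fit(nets$b$network, cfg = panda_config(alpha = 0.2))
  expect_error(disruption_scores(nets$e, other), "configuration")
})

test_that("regulatory difference reproduces the published worked examples", {
  # RELA -> SLC16A9: disruption 0.000256 in one genotype, 6.1 in the other
  expect_equal(regulatory_difference(0.000256, 6.1), 6.099744)
  # ARID3A -> PMS2CL
  expect_equal(regulatory_difference(0.0096, 1.066), 1.0564)
})

test_that("regulatory difference is symmetric, bounded and zero on identity", {
  set.seed(9)
  dn <- list(paste0("TF", 1:3), paste0("g", 1:5))
  base <- fake_fit(matrix(rnorm(15), 3, 5, dimnames = dn))
  d1 <- disruption_scores(fake_fit(matrix(rnorm(15), 3, 5, dimnames = dn),
                                   id = "a"), base)
  d2 <- disruption_scores(fake_fit(matrix(rnorm(15), 3, 5, dimnames = dn),
                                   id = "b"), base)
  r12 <- regulatory_difference(d1, d2)
  r21 <- regulatory_difference(d2, d1)
  expect_equal(r12$edge, r21$edge)
  expect_true(all(r12$edge >= 0))
  # triangle-style bound
  expect_true(all(r12$edge <= d1$edge + d2$edge + 1e-15))
  expect_equal(r12$gene, colSums(r12$edge))
  expect_true(all(regulatory_difference(d1, d1)$edge == 0))
  expect_equal(r12$pair, c("a", "b"))
})

test_that("TF disruption scaling z-scores within each group", {
  tab <- tibble::tibble(
    individual_id = rep(c("i1", "i2"), each = 3),
    cell_type = "LCL",
    tf = rep(paste0("TF", 1:3), 2),
    d_tf = c(1, 2, 3, 5, 5, 5))
  expect_message(out <- scale_tf_disruption(tab), "degenerate")
  i1 <- out$d_tf_scaled[out$individual_id == "i1"]
  # sample-sd z-score of (1,2,3) is (-1, 0, 1)
  expect_equal(i1, c(-1, 0, 1))
  i2 <- out[out$individual_id == "i2", ]
  expect_true(all(i2$degenerate))
  expect_equal(i2$d_tf_scaled, c(0, 0, 0))
  expect_equal(attr(out, "sd_convention"), "sample")
})

test_that("scaled scores have near-zero mean and unit sd per group", {
  set.seed(10)
  tab <- tidyr::expand_grid(individual_id = paste0("i", 1:4),
                            cell_type = c("LCL", "CM"),
                            tf = paste0("TF", 1:6))
  tab$d_tf <- rexp(nrow(tab))
  out <- scale_tf_disruption(tab)
  stats <- out |>
    dplyr::group_by(individual_id, cell_type) |>
    dplyr::summarise(mu = mean(d_tf_scaled), s = sd(d_tf_scaled),
                     .groups = "drop")
  expect_true(all(abs(stats$mu) < 1e-10))
  expect_equal(stats$s, rep(1, nrow(stats)), tolerance = 1e-10)
})

test_that("top-fraction thresholding keeps quantile ties deterministically", {
  v <- 1:10
  expect_equal(sum(threshold_top_fraction(v, 0.10)), 1)
  expect_true(threshold_top_fraction(v, 0.10)[10])
  tied <- rep(2, 6)
  expect_true(all(threshold_top_fraction(tied, 0.10)))
  set.seed(12)
  x <- rnorm(200)
  mask <- threshold_top_fraction(x, 0.25)
  # sort-based oracle
  cut <- sort(x)[ceiling(0.75 * 200)]
  expect_true(all(x[mask] >= quantile(x, 0.75)))
  expect_gte(sum(mask), floor(0.25 * 200))
  expect_equal(mask, x >= quantile(x, 0.75, names = FALSE))
  m <- matrix(x[1:20], 4, 5)
  expect_equal(dim(threshold_top_fraction(m, 0.2)), dim(m))
  expect_equal(threshold_top_fraction(c(0.2, 0.36, 0.5), cutoff = 0.35),
               c(FALSE, TRUE, TRUE))
  expect_error(threshold_top_fraction(numeric(0)), "empty")
})
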