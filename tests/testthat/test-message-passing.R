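seeded_system <- function(m = 3, n = 4, seed = 42) {
  set.seed(seed)
  prior <- matrix(rbinom(m * n, 1, 0.5) + rnorm(m * n, 0, 0.01), m, n,
                  dimnames = list(paste0("TF", 1:m), paste0("g", 1:n)))
  p <- matrix(rnorm(m * m), m, m)
  p <- (p + t(p)) / 2
  diag(p) <- 1
  dimnames(p) <- list(rownames(prior), rownames(prior))
  cc <- matrix(rnorm(n * n), n, n)
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  dimnames(cc) <- list(colnames(prior), colnames(prior))
  list(prior = prior, ppi = p, coexpr = cc)
}

test_that("coexpression equals the textbook Pearson formula", {
  set.seed(7)
  expr <- matrix(rnorm(50), 5, 10,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  cc <- pearson_coexpression(expr, min_nonzero = 1)
  # direct formula oracle
  for (i in 1:5) {
    for (j in 1:5) {
      x <- expr[i, ]
      y <- expr[j, ]
      r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(cc[i, j], r, tolerance = 1e-12)
    }
  }
  expect_equal(diag(cc), setNames(rep(1, 5), rownames(expr)))
})

test_that("coexpression handles duplicates, anticorrelation, filters and flat genes", {
  expr <- rbind(a = c(1, 2, 3), dup = c(1, 2, 3), anti = c(3, 2, 1),
                rare = c(0, 0, 5), flat = c(2, 2, 2))
  colnames(expr) <- paste0("s", 1:3)
  expect_message(cc <- pearson_coexpression(expr, min_nonzero = 2),
                 "low-expression")
  expect_false("rare" %in% rownames(cc))      # nonzero in only 1 sample
  expect_equal(cc["a", "dup"], 1)
  expect_equal(cc["a", "anti"], -1)
  expect_equal(cc["a", "flat"], 0)            # zero variance -> 0
  expect_equal(cc["flat", "flat"], 1)
  expect_true(isSymmetric(cc))
})

test_that("normalization matches the hand-computed z-score average", {
  x <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalize_network(x), matrix(c(-1, 1, 1, -1), 2, 2))
  set.seed(3)
  y <- matrix(rnorm(30), 5, 6)
  expect_equal(normalize_network(y), oracle_normalize(y), tolerance = 1e-12)
})

test_that("normalization is row-permutation equivariant and zero-mean", {
  set.seed(4)
  x <- matrix(rnorm(24), 4, 6)
  z <- normalize_network(x)
  expect_lt(abs(mean(z)), 1e-12)
  perm <- c(3, 1, 4, 2)
  expect_equal(normalize_network(x[perm, ]), z[perm, ])
})

test_that("zero-variance slices fall back to the whole-matrix z-score", {
  x <- matrix(c(5, 5, 5, 1, 2, 3), 3, 2)  # column 1 constant
  z <- normalize_network(x)
  expect_true(all(is.finite(z)))
  expect_equal(z, oracle_normalize(x), tolerance = 1e-12)
  expect_error(normalize_network(matrix(1, 3, 3)), "degenerate")
})

test_that("tanimoto similarity follows the continuous-Jaccard formula", {
  e1 <- c(1, 0, 0)
  expect_equal(tanimoto(e1, e1), 1)              # unit self-similarity
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)    # orthogonal
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0)    # all-zero convention
  x <- c(1, 2)
  y <- c(2, 1)
  expect_equal(tanimoto(x, y), oracle_tanimoto(x, y))
  expect_equal(tanimoto(x, y), 4 / sqrt(5 + 5 - 4))
  expect_error(tanimoto(1:3, 1:4), "length")
})

test_that("responsibility and availability match per-entry oracles", {
  sys <- seeded_system()
  r <- responsibility(sys$ppi, sys$prior)
  a <- availability(sys$prior, sys$coexpr)
  for (i in 1:3) {
    for (j in 1:4) {
      expect_equal(r[i, j], oracle_tanimoto(sys$ppi[i, ], sys$prior[, j]),
                   tolerance = 1e-12)
      expect_equal(a[i, j], oracle_tanimoto(sys$prior[i, ], sys$coexpr[, j]),
                   tolerance = 1e-12)
    }
  }
  zero_w <- sys$prior * 0
  expect_true(all(responsibility(sys$ppi, zero_w) == 0))
  # TF-relabeling equivariance
  perm <- c(2, 3, 1)
  rp <- responsibility(sys$ppi[perm, perm], sys$prior[perm, ])
  expect_equal(unname(rp), unname(r[perm, ]))
  bad <- sys$ppi
  rownames(bad) <- c("A", "B", "C")
  expect_error(responsibility(bad, sys$prior), "aligned")
})

test_that("hamming distance is the mean absolute entrywise difference", {
  a <- matrix(0, 2, 2)
  b <- matrix(1, 2, 2)
  expect_equal(hamming_distance(a, a), 0)
  expect_equal(hamming_distance(a, b), 1)
  set.seed(5)
  x <- matrix(rnorm(12), 3, 4)
  y <- matrix(rnorm(12), 3, 4)
  expect_equal(hamming_distance(x, y), sum(abs(x - y)) / 12)
  expect_error(hamming_distance(x, matrix(0, 2, 2)), "shape")
})

test_that("a single message-passing step matches the brute-force oracle", {
  sys <- seeded_system(3, 4, seed = 42)
  fit <- suppressWarnings(
    panda(sys$prior, sys$ppi, sys$coexpr,
          panda_config(alpha = 0.1, max_iter = 1)))
  oracle <- oracle_one_step(sys$prior, sys$ppi, sys$coexpr, alpha = 0.1)
  expect_equal(unname(fit$network), unname(oracle), tolerance = 1e-10)
})

test_that("alpha = 0 converges immediately with zero change", {
  sys <- seeded_system()
  fit <- panda(sys$prior, sys$ppi, sys$coexpr, panda_config(alpha = 0))
  expect_true(fit$converged)
  expect_equal(fit$iterations, 1L)
  expect_equal(fit$hamming_trace, 0)
  expect_equal(fit$network, normalize_network(sys$prior))
})

test_that("message passing converges on seeded toy systems and is deterministic", {
  for (seed in c(42, 99)) {
    sys <- seeded_system(4, 6, seed = seed)
    fit <- panda(sys$prior, sys$ppi, sys$coexpr)
    expect_true(fit$converged)
    expect_lt(fit$iterations, panda_config()$max_iter)
    expect_lt(dplyr::last(fit$hamming_trace), 1e-3)
    expect_equal(length(fit$hamming_trace), fit$iterations)
    expect_true(all(is.finite(fit$network)))  # complete bipartite output
    fit2 <- panda(sys$prior, sys$ppi, sys$coexpr)
    expect_identical(fit$network, fit2$network)
    expect_identical(fit$hamming_trace, fit2$hamming_trace)
  }
})

test_that("identical priors give identical converged networks", {
  sys <- seeded_system()
  f1 <- panda(sys$prior, sys$ppi, sys$coexpr)
  f2 <- panda(sys$prior + 0, sys$ppi, sys$coexpr)
  expect_identical(f1$network, f2$network)
})

test_that("label misalignment is rejected", {
  sys <- seeded_system()
  swapped <- sys$coexpr[c(2, 1, 3, 4), c(2, 1, 3, 4)]
  expect_error(panda(sys$prior, sys$ppi, swapped), "aligned")
})

test_that("fit accessors summarise the run", {
  sys <- seeded_system()
  fit <- panda(sys$prior, sys$ppi, sys$coexpr)
  td <- tidy(fit)
  expect_equal(nrow(td), 12)
  expect_named(td, c("tf", "gene", "weight"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$iterations, fit$iterations)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit, type = "trace"), "ggplot")
})
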