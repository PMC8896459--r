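#' Gene coexpression network from an expression matrix
#'
#' Pearson correlation between gene expression profiles across samples.
#' Genes failing the low-expression filter — fewer than `min_nonzero`
#' samples with nonzero expression — are removed before computing
#' correlations. No thresholding is applied to the resulting edge weights.
#'
#' @param expr Numeric matrix, genes x samples (gene rownames), or a data
#'   frame with a `gene_id` first column.
#' @param min_nonzero Minimum number of samples with nonzero expression a
#'   gene needs to be retained.
#' @return Symmetric correlation matrix (diagonal 1) over the retained
#'   genes. Zero-variance genes get correlation 0 with every other gene
#'   (diagonal stays 1), with a message.
#' @export
pearson_coexpression <- function(expr, min_nonzero = 50) {
  m <- as_expression_matrix(expr)
  if (ncol(m) < 2) abort("need at least 2 samples for coexpression")
  keep <- rowSums(m != 0) >= min_nonzero
  if (any(!keep)) {
    inform(paste0(sum(!keep), " gene(s) removed by the low-expression ",
                  "filter (nonzero in < ", min_nonzero, " samples)"))
  }
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) abort("no genes pass the expression filter")
  flat <- apply(m, 1, sd) == 0
  cc <- suppressWarnings(cor(t(m)))
  if (any(flat)) {
    inform(paste0(sum(flat), " zero-variance gene(s): correlations set to 0"))
    cc[flat, ] <- 0
    cc[, flat] <- 0
  }
  diag(cc) <- 1
  cc
}

as_expression_matrix <- function(expr) {
  if (is.matrix(expr)) {
    storage.mode(expr) <- "double"
    return(expr)
  }
  if (is.data.frame(expr)) {
    m <- as.matrix(expr[, -1, drop = FALSE])
    rownames(m) <- as.character(expr[[1]])
    storage.mode(m) <- "double"
    return(m)
  }
  abort("expression must be a matrix or a data frame with a gene id column")
}

#' Z-score normalization of a network matrix
#'
#' Each entry is replaced by the average of its row z-score and column
#' z-score, scaled by 1/sqrt(2): `Z = (Z_rows + Z_cols) / sqrt(2)`. Where a
#' row (or column) has zero variance, its term falls back to the z-score
#' computed over the whole matrix, so every entry stays finite. Z-scores
#' use the sample standard deviation (n - 1).
#'
#' @param x Finite numeric matrix.
#' @return Normalized matrix, same dimnames.
#' @export
normalize_network <- function(x) {
  stopifnot(is.matrix(x))
  if (!all(is.finite(x))) abort("network contains non-finite entries")
  overall_sd <- sd(as.vector(x))
  if (overall_sd == 0) abort("degenerate network: all entries identical")
  overall_z <- (x - mean(x)) / overall_sd
  row_mu <- rowMeans(x)
  row_sd <- apply(x, 1, sd)
  col_mu <- colMeans(x)
  col_sd <- apply(x, 2, sd)
  z_rows <- (x - row_mu) / row_sd
  z_cols <- sweep(sweep(x, 2, col_mu), 2, col_sd, "/")
  bad_rows <- row_sd == 0
  bad_cols <- col_sd == 0
  if (any(bad_rows)) z_rows[bad_rows, ] <- overall_z[bad_rows, ]
  if (any(bad_cols)) z_cols[, bad_cols] <- overall_z[, bad_cols]
  (z_rows + z_cols) / sqrt(2)
}

#' Continuous Tanimoto similarity between two vectors
#'
#' `T(x, y) = (x . y) / sqrt(||x||^2 + ||y||^2 - |x . y|)`, the continuous
#' extension of the Jaccard index used throughout the message-passing
#' updates. Two all-zero vectors have similarity 0 by convention.
#'
#' @param x,y Equal-length finite numeric vectors.
#' @return Scalar similarity.
#' @export
tanimoto <- function(x, y) {
  if (length(x) != length(y)) abort("tanimoto: length mismatch")
  dot <- sum(x * y)
  denom2 <- sum(x^2) + sum(y^2) - abs(dot)
  if (denom2 <= 0) return(0)
  dot / sqrt(denom2)
}

# all-pairs tanimoto between rows of A (a x k) and columns of B (k x b)
tanimoto_cross <- function(a, b) {
  dot <- a %*% b
  na <- rowSums(a^2)
  nb <- colSums(b^2)
  denom2 <- outer(na, nb, "+") - abs(dot)
  out <- dot / sqrt(denom2)
  out[denom2 <= 0] <- 0
  out
}

#' Responsibility matrix
#'
#' `R[i, j]` is the Tanimoto similarity between TF i's interaction-partner
#' profile (row i of the TF-TF cooperativity matrix P) and gene j's
#' regulator profile (column j of the current regulatory matrix W): how
#' well the TFs that target gene j match the partners of TF i.
#'
#' @param ppi m x m TF cooperativity matrix.
#' @param w m x n regulatory matrix, TF labels aligned with `ppi`.
#' @return m x n matrix.
#' @export
responsibility <- function(ppi, w) {
  if (!identical(rownames(ppi), rownames(w)) ||
      !identical(colnames(ppi), rownames(w))) {
    abort("responsibility: TF labels of ppi and network are not aligned")
  }
  tanimoto_cross(ppi, w)
}

#' Availability matrix
#'
#' `A[i, j]` is the Tanimoto similarity between TF i's target profile
#' (row i of W) and gene j's coexpression profile (column j of C): how well
#' TF i's targets match the genes coexpressed with gene j.
#'
#' @param w m x n regulatory matrix.
#' @param coexpr n x n gene coexpression matrix, gene labels aligned.
#' @return m x n matrix.
#' @export
availability <- function(w, coexpr) {
  if (!identical(colnames(w), rownames(coexpr)) ||
      !identical(rownames(coexpr), colnames(coexpr))) {
    abort("availability: gene labels of network and coexpression are not aligned")
  }
  tanimoto_cross(w, coexpr)
}

#' Mean absolute entrywise difference between two networks
#'
#' The convergence criterion of the message-passing loop: the mean of
#' `|W_new - W_old|` over all entries (a scale-stable continuous analog of
#' a Hamming distance between adjacency structures).
#'
#' @param w_new,w_old Same-shape numeric matrices.
#' @return Scalar distance.
#' @export
hamming_distance <- function(w_new, w_old) {
  if (!identical(dim(w_new), dim(w_old))) abort("hamming: shape mismatch")
  mean(abs(w_new - w_old))
}

#' Message-passing configuration
#'
#' @param alpha Update rate in \[0, 1): each iteration moves the networks
#'   by a fraction `alpha` toward the responsibility/availability evidence.
#'   Default 0.1.
#' @param tol Convergence threshold on the mean absolute change of the
#'   regulatory matrix between iterations. Default 1e-3.
#' @param max_iter Iteration cap; hitting it flags non-convergence.
#' @param alpha_ppi,alpha_coexpr Optional per-matrix update rates for the
#'   cooperativity and coexpression updates; default equal to `alpha`.
#' @param inflate_diagonal Refill the diagonal of the updated P and C each
#'   iteration with (per-row sd over off-diagonal entries) x dimension x
#'   exp(2 * alpha * t); without this, self-similarity dominates and the
#'   fixed point degenerates. On by default.
#' @return A `panda_config` list.
#' @export
panda_config <- function(alpha = 0.1, tol = 1e-3, max_iter = 200,
                         alpha_ppi = NULL, alpha_coexpr = NULL,
                         inflate_diagonal = TRUE) {
  stopifnot(alpha >= 0, alpha < 1, tol > 0, max_iter >= 1)
  structure(list(alpha = alpha, tol = tol, max_iter = max_iter,
                 alpha_ppi = alpha_ppi %||% alpha,
                 alpha_coexpr = alpha_coexpr %||% alpha,
                 inflate_diagonal = isTRUE(inflate_diagonal)),
            class = "panda_config")
}

# refill the diagonal after an update: off-diagonal per-row sample sd,
# scaled by the matrix dimension and exp(2*alpha*t), t = 0-based iteration
inflate_diag <- function(m, alpha, t) {
  md <- m
  diag(md) <- NA
  row_sd <- apply(md, 1, sd, na.rm = TRUE)
  row_sd[is.na(row_sd)] <- 0
  diag(m) <- row_sd * nrow(m) * exp(2 * alpha * t)
  m
}

#' Refine a regulatory prior by message passing
#'
#' Iteratively reconciles a TF x gene prior with TF-TF cooperativity (P)
#' and gene coexpression (C) evidence. All three inputs are z-score
#' normalized once ([normalize_network()]); then each iteration updates the
#' regulatory matrix with a fraction `alpha` of the average of its
#' responsibility and availability, re-estimates P from the similarity of
#' TF target profiles and C from the similarity of gene regulator profiles
#' (same damping), and refills their diagonals (see [panda_config()]).
#' Iteration stops when the mean absolute change of the regulatory matrix
#' drops below `tol`.
#'
#' Running on the reference motif prior yields the genotype-agnostic
#' baseline network; running on an individual's penalized prior yields that
#' individual's network. The output is a complete bipartite graph: every
#' TF-gene pair carries a finite weight.
#'
#' @param prior m x n prior matrix (TF rownames, gene colnames).
#' @param ppi m x m symmetric TF cooperativity matrix, same TF labels.
#' @param coexpr n x n symmetric gene coexpression matrix, same gene
#'   labels.
#' @param config A [panda_config()].
#' @return A `panda_fit` object: `network` (converged m x n matrix),
#'   `ppi_final`, `coexpr_final`, `iterations`, `converged`,
#'   `hamming_trace`, `config`, and the `individual_id` attribute carried
#'   over from the prior, if any. The update loop is fully deterministic.
#' @export
panda <- function(prior, ppi, coexpr, config = panda_config()) {
  stopifnot(inherits(config, "panda_config"))
  if (!identical(rownames(prior), rownames(ppi)) ||
      !identical(rownames(ppi), colnames(ppi))) {
    abort("TF labels of prior and ppi are not aligned")
  }
  if (!identical(colnames(prior), rownames(coexpr)) ||
      !identical(rownames(coexpr), colnames(coexpr))) {
    abort("gene labels of prior and coexpression are not aligned")
  }
  w <- normalize_network(prior)
  p <- normalize_network(ppi)
  cc <- normalize_network(coexpr)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  for (t in seq_len(config$max_iter)) {
    iter <- t
    r <- tanimoto_cross(p, w)
    a <- tanimoto_cross(w, cc)
    w_new <- (1 - config$alpha) * w + config$alpha * (r + a) / 2
    if (!all(is.finite(w_new))) {
      abort(paste0("non-finite values in message passing at iteration ", t))
    }
    ham <- hamming_distance(w_new, w)
    trace <- c(trace, ham)
    w <- w_new
    p_tilde <- tanimoto_cross(w, t(w))
    p <- (1 - config$alpha_ppi) * p + config$alpha_ppi * p_tilde
    c_tilde <- tanimoto_cross(t(w), w)
    cc <- (1 - config$alpha_coexpr) * cc + config$alpha_coexpr * c_tilde
    if (config$inflate_diagonal) {
      p <- inflate_diag(p, config$alpha_ppi, t - 1)
      cc <- inflate_diag(cc, config$alpha_coexpr, t - 1)
    }
    if (ham < config$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(paste0("message passing did not converge in ", config$max_iter,
                " iterations (last change ", signif(trace[iter], 3), ")"))
  }
  structure(list(network = w, ppi_final = p, coexpr_final = cc,
                 iterations = iter, converged = converged,
                 hamming_trace = trace, config = config,
                 individual_id = attr(prior, "individual_id")),
            class = "panda_fit")
}

#' @export
print.panda_fit <- function(x, ...) {
  cat("Message-passing network fit\n")
  cat("  ", nrow(x$network), " TFs x ", ncol(x$network), " genes\n", sep = "")
  cat("  iterations: ", x$iterations,
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  cat("  final change: ", signif(utils::tail(x$hamming_trace, 1), 4),
      " (tol ", x$config$tol, ")\n", sep = "")
  if (!is.null(x$individual_id)) cat("  individual: ", x$individual_id, "\n", sep = "")
  invisible(x)
}

#' @describeIn panda Edge table of a fit: one row per TF-gene pair with the
#'   converged weight.
#' @param x A `panda_fit`.
#' @param ... Unused.
#' @method tidy panda_fit
#' @export
tidy.panda_fit <- function(x, ...) {
  out <- matrix_to_edges(x$network)
  if (!is.null(x$individual_id)) out$individual_id <- x$individual_id
  out
}

#' @describeIn panda One-row fit summary (dimensions, iterations,
#'   convergence, final change).
#' @method glance panda_fit
#' @export
glance.panda_fit <- function(x, ...) {
  tibble(n_tfs = nrow(x$network), n_genes = ncol(x$network),
         iterations = x$iterations, converged = x$converged,
         final_hamming = utils::tail(x$hamming_trace, 1),
         alpha = x$config$alpha, tol = x$config$tol)
}

#' @describeIn panda Heatmap of the converged edge weights (or the
#'   convergence trace with `type = "trace"`).
#' @param object A `panda_fit`.
#' @param type `"network"` or `"trace"`.
#' @method autoplot panda_fit
#' @export
autoplot.panda_fit <- function(object, type = c("network", "trace"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    df <- tibble(iteration = seq_along(object$hamming_trace),
                 change = object$hamming_trace)
    return(ggplot(df, aes(x = .data$iteration, y = .data$change)) +
             geom_line() +
             ggplot2::scale_y_log10() +
             labs(x = "iteration", y = "mean |Δ weight|",
                  title = "Message-passing convergence") +
             theme_bw())
  }
  df <- tidy(object)
  ggplot(df, aes(x = .data$gene, y = .data$tf, fill = .data$weight)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    labs(x = "gene", y = "TF", fill = "weight") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
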