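# Independent brute-force oracles. These deliberately use scalar loops and
# textbook formulas, never the package's vectorized code paths.

oracle_tanimoto <- function(x, y) {
  dot <- 0
  nx <- 0
  ny <- 0
  for (k in seq_along(x)) {
    dot <- dot + x[k] * y[k]
    nx <- nx + x[k]^2
    ny <- ny + y[k]^2
  }
  denom2 <- nx + ny - abs(dot)
  if (denom2 <= 0) return(0)
  unname(dot / sqrt(denom2))
}

oracle_zscore <- function(v) {
  mu <- sum(v) / length(v)
  s <- sqrt(sum((v - mu)^2) / (length(v) - 1))
  (v - mu) / s
}

oracle_normalize <- function(x) {
  all_z <- oracle_zscore(as.vector(x))
  overall <- matrix(all_z, nrow(x), ncol(x))
  zr <- x
  zc <- x
  for (i in seq_len(nrow(x))) {
    if (sd(x[i, ]) == 0) zr[i, ] <- overall[i, ] else zr[i, ] <- oracle_zscore(x[i, ])
  }
  for (j in seq_len(ncol(x))) {
    if (sd(x[, j]) == 0) zc[, j] <- overall[, j] else zc[, j] <- oracle_zscore(x[, j])
  }
  (zr + zc) / sqrt(2)
}

# one message-passing step, entry by entry
oracle_one_step <- function(prior, ppi, coexpr, alpha) {
  w <- oracle_normalize(prior)
  p <- oracle_normalize(ppi)
  cc <- oracle_normalize(coexpr)
  m <- nrow(w)
  n <- ncol(w)
  r <- matrix(0, m, n)
  a <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      r[i, j] <- oracle_tanimoto(p[i, ], w[, j])
      a[i, j] <- oracle_tanimoto(w[i, ], cc[, j])
    }
  }
  (1 - alpha) * w + alpha * (r + a) / 2
}

# exhaustive (s, i, j) triple loop for candidate selection
oracle_candidates <- function(eqtls, hits, promoters) {
  out <- list()
  for (s in seq_len(nrow(eqtls))) {
    for (h in seq_len(nrow(hits))) {
      for (p in seq_len(nrow(promoters))) {
        e <- eqtls[s, ]
        hh <- hits[h, ]
        pp <- promoters[p, ]
        if (e$chrom == hh$chrom && hh$chrom == pp$chrom &&
            e$pos >= hh$start && e$pos < hh$end &&
            hh$start >= pp$start && hh$end <= pp$end &&
            isTRUE(e$significant) && e$egene == pp$gene_id) {
          out[[length(out) + 1]] <-
            data.frame(variant_id = e$variant_id, tf_name = hh$tf_name,
                       gene_id = pp$gene_id)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(variant_id = character(), tf_name = character(),
                      gene_id = character()))
  }
  unique(do.call(rbind, out))
}

# brute-force interval-overlap counter for TF x gene occupancy
oracle_overlap_matrix <- function(hits, promoters, tf_names) {
  m <- matrix(0, length(tf_names), nrow(promoters),
              dimnames = list(tf_names, promoters$gene_id))
  for (h in seq_len(nrow(hits))) {
    for (p in seq_len(nrow(promoters))) {
      if (hits$chrom[h] == promoters$chrom[p] &&
          hits$start[h] < promoters$end[p] &&
          hits$end[h] > promoters$start[p]) {
        m[hits$tf_name[h], promoters$gene_id[p]] <-
          m[hits$tf_name[h], promoters$gene_id[p]] + 1
      }
    }
  }
  m
}

# one-sided hypergeometric tail by direct enumeration over the support
oracle_hypergeom_p <- function(tab) {
  a <- tab[1, 1]
  n_sel <- tab[1, 1] + tab[1, 2]
  n_pos <- tab[1, 1] + tab[2, 1]
  n_tot <- sum(tab)
  ks <- max(0, n_sel + n_pos - n_tot):min(n_sel, n_pos)
  probs <- sapply(ks, function(k) {
    choose(n_pos, k) * choose(n_tot - n_pos, n_sel - k) / choose(n_tot, n_sel)
  })
  sum(probs[ks >= a])
}

# Mann-Whitney AUC over all positive/negative pairs, ties at 1/2
oracle_auc_pairwise <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# small fixed annotation/promoter fixture shared by several tests
toy_promoters <- function() {
  ann <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1",
    tss = c(10000L, 50000L), strand = c("+", "-"))
  build_promoters(ann)
}

# configurable small cohort for the simulator/pipeline/io tests
sim_small <- function(...) {
  args <- utils::modifyList(
    list(n_tfs = 4, n_genes = 20, n_samples = 60, n_individuals = 6,
         n_planted = 4, seed = 7),
    list(...))
  do.call(sim_config, args)
}
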