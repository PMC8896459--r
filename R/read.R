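#' Read a gene annotation table
#'
#' Accepts either a 4-column TSV (`gene_id`, `chrom`, `tss`, `strand`, with a
#' header; TSS 1-based) or a GFF3 file (`.gff`/`.gff3`, read through
#' rtracklayer; the TSS is taken as the strand-aware start of each `gene`
#' feature). Positions are converted once here to the package-internal
#' 0-based convention.
#'
#' @param path Annotation file path.
#' @return Tibble with `gene_id`, `chrom`, `tss` (0-based), `strand`.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GFF3 requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    tss1 <- ifelse(as.character(BiocGenerics::strand(gr)) == "-",
                   BiocGenerics::end(gr), BiocGenerics::start(gr))
    return(tibble(
      gene_id = as.character(gr$ID %||% gr$gene_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      tss = as.integer(tss1) - 1L,
      strand = as.character(BiocGenerics::strand(gr))
    ))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = "c", chrom = "c",
                           tss = "i", strand = "c"))
  tab |> mutate(tss = .data$tss - 1L)
}

#' Read motif-scan hits (FIMO-style TSV)
#'
#' Expects the FIMO column layout (`motif_id`, `sequence_name`, `start`,
#' `stop`, `strand`, `score`, `p-value`, ...; 1-based inclusive
#' coordinates). Column names are matched loosely so both FIMO 4 and FIMO 5
#' headers work. Coordinates are converted to 0-based half-open; hits are
#' filtered at `p_max` (the scan p-value cutoff, default 1e-4).
#'
#' @param path TSV file of motif occurrences.
#' @param p_max Maximum scan p-value retained.
#' @return Tibble with `tf_name`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `score`, `p_value`.
#' @export
read_fimo <- function(path, p_max = 1e-4) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  nm <- tolower(names(tab))
  pick <- function(...) {
    hit <- which(nm %in% c(...))
    if (length(hit) == 0) abort(paste0("motif hit file lacks a column among: ",
                                       paste(c(...), collapse = ", ")))
    tab[[hit[1]]]
  }
  out <- tibble(
    tf_name = as.character(pick("motif_id", "tf", "tf_name", "motif")),
    chrom = as.character(pick("sequence_name", "sequence name", "chrom", "seqnames")),
    start = as.integer(pick("start")) - 1L,
    end = as.integer(pick("stop", "end")),
    strand = as.character(pick("strand")),
    score = as.numeric(pick("score")),
    p_value = as.numeric(pick("p-value", "p_value", "pvalue"))
  )
  out |> filter(.data$p_value <= p_max)
}

#' Read an eQTL association table
#'
#' TSV with columns `variant_id`, `chrom`, `pos` (1-based), `ref`, `alt`,
#' `gene_id` (the eGene), `beta`, and either a logical `significant` column
#' or a `pval` column to filter at `p_max`. Positions are converted to
#' 0-based.
#'
#' @param path TSV file path.
#' @param p_max Optional p-value threshold used to derive `significant` when
#'   the file carries `pval` instead of a precomputed flag.
#' @return Tibble with `variant_id`, `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `egene`, `beta`, `significant`.
#' @export
read_eqtl <- function(path, p_max = 0.05) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"significant" %in% names(tab)) {
    if (!"pval" %in% names(tab)) {
      abort("eQTL table needs a 'significant' or 'pval' column")
    }
    tab$significant <- tab$pval <= p_max
  }
  egene_col <- if ("egene" %in% names(tab)) "egene" else "gene_id"
  out <- tibble(
    variant_id = as.character(tab$variant_id),
    chrom = as.character(tab$chrom),
    pos = as.integer(tab$pos) - 1L,
    ref = as.character(tab$ref),
    alt = as.character(tab$alt),
    egene = as.character(tab[[egene_col]]),
    beta = as.numeric(tab$beta),
    significant = as.logical(tab$significant)
  )
  if ("pval" %in% names(tab)) out$pval <- as.numeric(tab$pval)
  out
}

#' Read variant TF-binding effect predictions (QBiC-style TSV)
#'
#' TSV with columns `variant_id`, `tf` (or `tf_name`), `q` (or `q_effect`;
#' the predicted binding change, negative = reduced binding) and `pval`
#' (or `p_value`).
#'
#' @param path TSV file path.
#' @return Tibble with `variant_id`, `tf_name`, `q_effect`, `p_value`.
#' @export
read_qbic <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  nm <- names(tab)
  col <- function(...) tab[[intersect(c(...), nm)[1]]]
  tibble(
    variant_id = as.character(col("variant_id")),
    tf_name = as.character(col("tf_name", "tf")),
    q_effect = as.numeric(col("q_effect", "q")),
    p_value = as.numeric(col("p_value", "pval", "p"))
  )
}

#' Read genotypes from a VCF
#'
#' Reads a (possibly gzipped) VCF through vcfR and returns one row per
#' variant per sample with the alternate allele count. Only biallelic SNVs
#' are retained; multiallelic records are dropped with a log message (the
#' pipeline models single-nucleotide substitutions only).
#'
#' @param path VCF file path.
#' @return Tibble with `variant_id`, `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `individual_id`, `alt_count` (0/1/2; NA genotypes count 0 and
#'   are reported).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  if (any(!keep)) {
    inform(paste0(sum(!keep), " multiallelic/non-SNV record(s) skipped"))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  n_missing <- sum(is.na(gt))
  if (n_missing > 0) {
    inform(paste0(n_missing, " missing genotype call(s) treated as 0 alt alleles"))
  }
  counts <- matrix(stringr::str_count(gt, "1"), nrow = nrow(gt),
                   dimnames = dimnames(gt))
  counts[is.na(counts)] <- 0L
  tibble(
    variant_id = rep(ids, ncol(gt)),
    chrom = rep(fix$CHROM, ncol(gt)),
    pos = rep(as.integer(fix$POS) - 1L, ncol(gt)),
    ref = rep(fix$REF, ncol(gt)),
    alt = rep(fix$ALT, ncol(gt)),
    individual_id = rep(colnames(gt), each = nrow(gt)),
    alt_count = as.integer(counts)
  )
}

#' Read a gene expression matrix
#'
#' TSV with a `gene_id` first column and one column per sample.
#'
#' @param path TSV file path.
#' @return Numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read a TF-TF interaction edge list
#'
#' TSV with columns `tf1`, `tf2` and optionally `weight` (default 1).
#'
#' @param path TSV file path.
#' @return Tibble with `tf1`, `tf2`, `weight`.
#' @export
read_ppi <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"weight" %in% names(tab)) tab$weight <- 1
  tibble(tf1 = as.character(tab$tf1), tf2 = as.character(tab$tf2),
         weight = as.numeric(tab$weight))
}

#' Read ChIP-seq peaks from BED files
#'
#' @param paths Named character vector of BED file paths; names are TF
#'   names. BED is 0-based half-open, no conversion needed.
#' @return Tibble with `tf_name`, `chrom`, `start`, `end`.
#' @export
read_bed_peaks <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    abort("`paths` must be a named vector: names are TF names")
  }
  purrr::imap(paths, function(p, tf) {
    bed <- readr::read_tsv(p, col_names = FALSE, show_col_types = FALSE)
    tibble(tf_name = tf, chrom = as.character(bed[[1]]),
           start = as.integer(bed[[2]]), end = as.integer(bed[[3]]))
  }) |> bind_rows()
}

#' Write a TF x gene network to TSV
#'
#' @param network Numeric matrix with TF rownames and gene colnames, or an
#'   object with such a matrix (a [panda()] fit).
#' @param path Output path.
#' @param format `"sparse"` writes three columns (tf, gene, weight),
#'   dropping zeros; `"dense"` writes the full matrix with a `tf` id column.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path, format = c("sparse", "dense")) {
  format <- match.arg(format)
  m <- if (inherits(network, "panda_fit")) network$network else network
  stopifnot(is.matrix(m))
  if (format == "sparse") {
    edges <- matrix_to_edges(m) |> filter(.data$weight != 0)
    readr::write_tsv(edges, path)
  } else {
    df <- as_tibble(m, rownames = "tf")
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' Read a network TSV written by [write_network_tsv()]
#'
#' @param path File path.
#' @param tf_names,gene_ids Label space for sparse input (absent pairs are
#'   0). Ignored for dense input.
#' @return Numeric matrix.
#' @export
read_network_tsv <- function(path, tf_names = NULL, gene_ids = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (identical(names(tab)[1:2], c("tf", "gene"))) {
    tf_names <- tf_names %||% unique(tab$tf)
    gene_ids <- gene_ids %||% unique(tab$gene)
    return(edges_to_matrix(tab, tf_names, gene_ids))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}
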