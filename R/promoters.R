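#' Build promoter windows around transcription start sites
#'
#' Each gene gets a single fixed-width promoter window oriented in the
#' direction of transcription: `upstream` bases before the TSS and
#' `downstream` bases after it (defaults \[-750, +250\], a 1 kb window).
#' On the minus strand the window is mirrored through the TSS so that
#' "upstream" still means upstream of transcription.
#'
#' All coordinates are 0-based, half-open. File readers
#' ([read_annotation()]) perform the 1-based-to-0-based conversion once at
#' parse time; `tss` here is already 0-based.
#'
#' @param annotation Data frame with columns `gene_id`, `chrom`, `tss`
#'   (0-based position of the TSS base) and `strand` (`"+"` or `"-"`).
#' @param upstream,downstream Window extent in bases relative to the TSS in
#'   transcription direction. Must sum to a positive width.
#' @return A tibble with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `start`, `end` (0-based half-open). Records with a missing TSS or an
#'   unrecognized strand are dropped with a warning.
#' @examples
#' ann <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
#'                       tss = c(10000L, 10000L), strand = c("+", "-"))
#' build_promoters(ann)
#' @export
build_promoters <- function(annotation, upstream = 750, downstream = 250) {
  stopifnot(is.data.frame(annotation))
  if (upstream + downstream <= 0) {
    abort("empty promoter window: upstream + downstream must be positive")
  }
  ann <- as_tibble(annotation)
  required <- c("gene_id", "chrom", "tss", "strand")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- is.na(ann$tss) | !(ann$strand %in% c("+", "-"))
  if (any(bad)) {
    warn(paste0(sum(bad), " annotation record(s) rejected ",
                "(missing TSS or strand)"))
    ann <- ann[!bad, , drop = FALSE]
  }
  out <- ann |>
    mutate(
      start = ifelse(.data$strand == "+",
                     .data$tss - upstream, .data$tss - downstream),
      end   = ifelse(.data$strand == "+",
                     .data$tss + downstream, .data$tss + upstream),
      start = pmax(.data$start, 0)
    ) |>
    select("gene_id", "chrom", "tss", "strand", "start", "end")
  dup <- duplicated(out$gene_id)
  if (any(dup)) {
    abort("annotation assigns more than one TSS to a gene; supply one designated TSS per gene")
  }
  out
}

#' Write promoter windows as a BED file
#'
#' Standard 6-column BED (0-based half-open), for inspection in a genome
#' browser or intersection with external tools.
#'
#' @param promoters Output of [build_promoters()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_promoters_bed <- function(promoters, path) {
  bed <- promoters |>
    mutate(score = 0L) |>
    select("chrom", "start", "end", name = "gene_id", "score", "strand")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
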