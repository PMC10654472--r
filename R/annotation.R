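# Gene-neighbourhood annotation: GFF3 in/out and window queries around
# differentiation peaks. Coordinates are 1-based inclusive (GFF3
# convention); peak windows of `flank` bp on both sides therefore span
# 2 * flank in total (the "100 kbp around the peak" convention).

#' Read gene models from a GFF3 file
#'
#' Imports a GFF3 annotation and keeps `gene`-type features with their
#' `ID`/`Name` attributes.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `gene_name`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type %||% rep("gene", length(gr)))
  gr <- gr[type == "gene"]
  md <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else
    sprintf("gene%03d", seq_along(gr))
  nm <- if ("Name" %in% names(md)) as.character(md$Name) else ids
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr),
         end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)),
         gene_id = ids, gene_name = nm)
}

#' Write gene models to a GFF3 file
#'
#' Emits minimal `gene` features with `ID` and `Name` attributes.
#'
#' @param genes A tibble with columns `chrom`, `start`, `end`, `gene_id`,
#'   `gene_name` (and optionally `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  strand <- if ("strand" %in% names(genes)) genes$strand else rep("+", nrow(genes))
  lines <- c("##gff-version 3",
             sprintf("%s\tdomescan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     genes$chrom, genes$start, genes$end, strand,
                     genes$gene_id, genes$gene_name))
  writeLines(lines, path)
  invisible(path)
}

#' Genes within a window around a position
#'
#' Returns every gene whose span intersects `[pos - flank, pos + flank]`
#' on the given chromosome.
#'
#' @param genes Gene models: a tibble as from [read_gene_annotation()], or a
#'   path to a GFF3 file.
#' @param chrom Chromosome of the query position.
#' @param pos Query position (bp, 1-based).
#' @param flank Window half-width in bp on each side (default 50,000).
#' @return A tibble of overlapping genes with a `distance` column (0 for
#'   genes containing `pos`, else bp from `pos` to the nearer gene edge).
#'   Empty annotation gives an empty tibble.
#' @examples
#' g <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L,
#'                     strand = "+", gene_id = "g1", gene_name = "g1")
#' genes_near(g, "chr1", 150, flank = 10)
#' @export
genes_near <- function(genes, chrom, pos, flank = 50000) {
  if (is.character(genes) && length(genes) == 1L) {
    genes <- read_gene_annotation(genes)
  }
  if (nrow(genes) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), gene_id = character(),
                  gene_name = character(), distance = integer()))
  }
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  win <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(max(1, pos - flank), pos + flank))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, win))
  out <- genes[S4Vectors::queryHits(hits), , drop = FALSE]
  out$distance <- pmax(0L, as.integer(out$start) - as.integer(pos),
                       as.integer(pos) - as.integer(out$end))
  out[order(out$start), , drop = FALSE]
}
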