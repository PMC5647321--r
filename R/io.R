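# File-format helpers: GFF3 gene tables via rtracklayer, CDS FASTA via
# Biostrings. Internal gene tables are plain data frames with columns
# gene_id, chrom, start, end, strand.

.write_gene_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand %||% "+")
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".gff3")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  rtracklayer::export(gr, tmp, format = "gff3")
  if (!file.rename(tmp, path)) stop("failed to write ", path)
  invisible(path)
}

#' Read gene records from a GFF3 file
#'
#' Imports a GFF3 via rtracklayer and returns the `gene` features as the flat
#' gene table used throughout the package.
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  data.frame(gene_id = as.character(S4Vectors::mcols(gr)$ID),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read a CDS FASTA into a named character vector
#'
#' @param path Path to a (possibly wrapped) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

# Normalize a gene-table argument: either a data frame or a GFF3 path.
.as_gene_table <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- read_gene_gff3(x)
  if (!is.data.frame(x) ||
      !all(c("gene_id", "chrom", "start") %in% names(x)))
    stop("gene table must be a GFF3 path or a data frame with gene_id/chrom/start")
  x
}

# Normalize a hit-table argument: data frame or TSV path with qid/sid columns.
.as_hit_table <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- .read_tsv(x)
  if (!is.data.frame(x) || !all(c("qid", "sid") %in% names(x)))
    stop("hit table must be a TSV path or a data frame with qid/sid columns")
  x
}
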