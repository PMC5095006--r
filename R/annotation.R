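#' Read a genome FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that truncates
#' sequence names at the first whitespace, so chromosome names match the
#' bare identifiers used in GTF/GFF annotation.
#'
#' @param path Path to a (possibly multi-sequence) FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Load gene models from a GTF/GFF annotation
#'
#' Parses exon records, collapses them per gene to unique genomic intervals
#' across transcripts, converts to 0-based half-open coordinates and ranks
#' exons 5'->3' in the transcribed direction (reverse of genomic order on the
#' minus strand). The resulting exon table is the substrate for backsplice
#' enumeration: one row per distinct exon of each gene.
#'
#' @param annotation_path GTF or GFF3 file (1-based inclusive coordinates).
#' @param genome A [Biostrings::DNAStringSet] or path to the genome FASTA.
#'   Every chromosome referenced by the annotation must be present.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` and `rank` (1-based, transcribed order).
#' @export
load_annotation <- function(annotation_path, genome) {
  if (is.character(genome)) genome <- read_genome(genome)
  gr <- rtracklayer::import(annotation_path)
  is_exon <- tolower(as.character(gr$type)) == "exon"
  if (!any(is_exon)) rlang::abort("annotation contains no exon records")
  ex <- gr[is_exon]

  missing_chr <- setdiff(unique(as.character(GenomeInfoDb::seqnames(ex))), names(genome))
  if (length(missing_chr) > 0) {
    rlang::abort(sprintf(
      "chromosome(s) absent from genome FASTA: %s",
      paste(missing_chr, collapse = ", ")))
  }

  exons <- tibble::tibble(
    gene_id = as.character(ex$gene_id),
    chrom   = as.character(GenomeInfoDb::seqnames(ex)),
    start   = BiocGenerics::start(ex) - 1L,   # to 0-based half-open
    end     = BiocGenerics::end(ex),
    strand  = as.character(BiocGenerics::strand(ex))
  ) |>
    dplyr::distinct(.data$gene_id, .data$chrom, .data$start, .data$end,
                    .data$strand)

  # genes present only as gene/transcript records carry no exons: warn + skip
  all_genes <- unique(as.character(gr$gene_id))
  all_genes <- all_genes[!is.na(all_genes)]
  empty <- setdiff(all_genes, exons$gene_id)
  if (length(empty) > 0) {
    rlang::warn(sprintf("skipping %d gene(s) with zero exon records: %s",
                        length(empty), paste(empty, collapse = ", ")))
  }

  exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(rank = if (.data$strand[1] == "-") dplyr::n():1L
                  else seq_len(dplyr::n())) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene_id, .data$rank)
}

# Transcribed-orientation sequence of one exon (0-based half-open coords).
exon_sequence <- function(genome, chrom, start, end, strand) {
  chr <- genome[[chrom]]
  if (is.null(chr)) rlang::abort(sprintf("chromosome '%s' not in genome", chrom))
  if (start < 0 || end > length(chr)) {
    rlang::abort(sprintf("exon [%d,%d) outside bounds of chromosome '%s' (length %d)",
                         start, end, chrom, length(chr)))
  }
  s <- Biostrings::subseq(chr, start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}
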