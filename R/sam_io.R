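#' Export alignments to SAM
#'
#' Writes the built-in mapper's paired alignments as a minimal, valid SAM
#' file (header `@SQ` lines from the reference entries; ungapped CIGARs;
#' sequences omitted), so results can be inspected with samtools or
#' re-imported with [import_alignments()].
#'
#' @param alignments Alignment tibble from [map_reads()].
#' @param entries Junction entry tibble the reads were mapped against.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
export_sam <- function(alignments, entries, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", entries$junction_id,
                   nchar(entries$sequence)))
  recs <- character(0)
  if (nrow(alignments) > 0) {
    a <- alignments
    flag1 <- 0x1 + 0x2 + 0x40 +
      ifelse(a$m1_strand == "-", 0x10, 0) +
      ifelse(a$m2_strand == "-", 0x20, 0)
    flag2 <- 0x1 + 0x2 + 0x80 +
      ifelse(a$m2_strand == "-", 0x10, 0) +
      ifelse(a$m1_strand == "-", 0x20, 0)
    frag_start <- pmin(a$m1_start, a$m2_start)
    frag_end <- pmax(a$m1_end, a$m2_end)
    tlen1 <- ifelse(a$m1_start <= a$m2_start, frag_end - frag_start,
                    -(frag_end - frag_start))
    rec <- function(flag, s, e, ps, tlen) {
      sprintf("%s\t%d\t%s\t%d\t255\t%dM\t=\t%d\t%d\t*\t*",
              a$fragment_id, flag, a$entry_id, s + 1L, e - s, ps + 1L, tlen)
    }
    recs <- as.vector(rbind(
      rec(flag1, a$m1_start, a$m1_end, a$m2_start, tlen1),
      rec(flag2, a$m2_start, a$m2_end, a$m1_start, -tlen1)))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

# Reference-space width of an ungapped-or-spliced CIGAR.
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    type <- sub("^\\d+", "", ops)
    sum(n[type %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Import paired-end alignments from SAM/BAM
#'
#' Streams a SAM or BAM file of alignments against the junction reference
#' into the pipeline's alignment table. Secondary (0x100) and supplementary
#' (0x800) records are dropped — only primary alignments are kept — as are
#' unpaired or half-mapped fragments. Coordinates are converted to 0-based
#' half-open.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param manifest Optional entry tibble (or character vector of entry ids);
#'   records on unknown references are skipped with a warning.
#' @param sample_id Sample label attached to every alignment.
#' @return Alignment tibble with the same columns as [map_reads()].
#' @export
import_alignments <- function(path, manifest = NULL, sample_id = "S1") {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE,
                                  hasUnmappedMate = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  res <- Rsamtools::scanBam(
    path, param = Rsamtools::ScanBamParam(
      flag = flags,
      what = c("qname", "flag", "rname", "pos", "cigar", "strand")))[[1]]
  if (length(res$qname) == 0L) {
    return(empty_alignments(sample_id))
  }
  tb <- tibble::tibble(
    fragment_id = res$qname,
    entry_id = as.character(res$rname),
    start = res$pos - 1L,
    end = res$pos - 1L + cigar_ref_width(res$cigar),
    strand = as.character(res$strand),
    first = bitwAnd(res$flag, 0x40L) > 0L)
  if (!is.null(manifest)) {
    known <- if (is.character(manifest)) manifest else manifest$junction_id
    bad <- !(tb$entry_id %in% known)
    if (any(bad)) {
      rlang::warn(sprintf("skipping %d record(s) on unknown reference(s): %s",
                          sum(bad),
                          paste(unique(tb$entry_id[bad]), collapse = ", ")))
      tb <- tb[!bad, ]
    }
  }
  m1 <- dplyr::filter(tb, .data$first)
  m2 <- dplyr::filter(tb, !.data$first)
  paired <- dplyr::inner_join(
    dplyr::rename(m1, m1_start = "start", m1_end = "end", m1_strand = "strand"),
    dplyr::select(dplyr::rename(m2, m2_start = "start", m2_end = "end",
                                m2_strand = "strand"), -"first"),
    by = c("fragment_id", "entry_id"))
  paired |>
    dplyr::transmute(.data$fragment_id, sample_id = sample_id, .data$entry_id,
                     .data$m1_start, .data$m1_end, .data$m1_strand,
                     .data$m2_start, .data$m2_end, .data$m2_strand,
                     n_mismatch = NA_integer_, primary = TRUE) |>
    dplyr::arrange(.data$fragment_id)
}

empty_alignments <- function(sample_id = character(0)) {
  tibble::tibble(fragment_id = character(), sample_id = character(),
                 entry_id = character(), m1_start = integer(),
                 m1_end = integer(), m1_strand = character(),
                 m2_start = integer(), m2_end = integer(),
                 m2_strand = character(), n_mismatch = integer(),
                 primary = logical())
}

#' Write read pairs to paired FASTQ files
#'
#' Standard 4-line records with `/1` and `/2` mate suffixes and uniform
#' quality (the simulator carries no quality model).
#'
#' @param reads Read-pair tibble (`fragment_id`, `read1`, `read2`).
#' @param prefix Output prefix; files are `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    seqs <- reads[[paste0("read", m)]]
    writeLines(as.vector(rbind(
      sprintf("@%s/%d", reads$fragment_id, m), seqs, "+",
      strrep("I", nchar(seqs)))), paths[m])
  }
  invisible(paths)
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' @param path1,path2 Mate FASTQ files in matching order.
#' @return Tibble with `fragment_id`, `read1`, `read2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  rd <- function(p) {
    lines <- readLines(p)
    list(id = sub("/[12]$", "", sub("^@", "", lines[seq(1, length(lines), 4)])),
         seq = lines[seq(2, length(lines), 4)])
  }
  f1 <- rd(path1); f2 <- rd(path2)
  if (!identical(f1$id, f2$id)) {
    rlang::abort("mate FASTQ files are not in matching order")
  }
  tibble::tibble(fragment_id = f1$id, read1 = f1$seq, read2 = f2$seq)
}
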