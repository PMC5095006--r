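#' Enumerate all intragenic backsplice exon pairs
#'
#' For each gene, every ordered pair (exon1, exon2) with
#' `exon1$rank <= exon2$rank` is a potential backsplice: the 3' end of the
#' downstream exon (exon2) joined head-to-tail to the 5' start of the
#' upstream exon (exon1). Equality gives the single-exon backsplice. A gene
#' with n exons therefore yields n(n+1)/2 pairs.
#'
#' @param exons Exon tibble as returned by [load_annotation()].
#' @param max_exons Optional cap: genes with more exons than this are skipped
#'   with a warning (guards against pathological annotations). Default `Inf`.
#' @return A tibble with one row per pair: `junction_id`
#'   (`"gene|e1rank|e2rank"`), `gene_id`, `chrom`, `strand`, exon1 and exon2
#'   coordinates (`e1_start`, `e1_end`, `e1_rank`, `e2_start`, `e2_end`,
#'   `e2_rank`), ordered by gene, then e1 rank, then e2 rank.
#' @export
enumerate_backsplices <- function(exons, max_exons = Inf) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand", "rank") %in%
                  names(exons)))
  per_gene <- split(exons, exons$gene_id)
  n_ex <- vapply(per_gene, nrow, integer(1))
  if (any(n_ex > max_exons)) {
    skip <- names(per_gene)[n_ex > max_exons]
    rlang::warn(sprintf("skipping %d gene(s) exceeding max_exons=%s: %s",
                        length(skip), format(max_exons),
                        paste(skip, collapse = ", ")))
    per_gene <- per_gene[n_ex <= max_exons]
  }
  purrr::map(per_gene, function(g) {
    g <- dplyr::arrange(g, .data$rank)
    n <- nrow(g)
    idx <- which(upper.tri(matrix(0L, n, n), diag = TRUE), arr.ind = TRUE)
    idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
    e1 <- g[idx[, "row"], ]  # upstream acceptor
    e2 <- g[idx[, "col"], ]  # downstream donor
    tibble::tibble(
      junction_id = paste(g$gene_id[1], e1$rank, e2$rank, sep = "|"),
      gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
      e1_start = e1$start, e1_end = e1$end, e1_rank = e1$rank,
      e2_start = e2$start, e2_end = e2$end, e2_rank = e2$rank)
  }) |>
    purrr::list_rbind()
}

#' Build the scrambled-exome junction reference
#'
#' Each backsplice pair becomes one reference entry whose sequence is the
#' transcribed-orientation sequence of exon2 followed by exon1, so that the
#' head-to-tail junction (exon2 3' end joined to exon1 5' start) sits at
#' `junction_offset = length(exon2)`. Minus-strand exons are
#' reverse-complemented. Single-exon backsplices duplicate the exon
#' (sequence + sequence) so a junction-spanning read aligns contiguously.
#'
#' @param pairs Backsplice pair tibble from [enumerate_backsplices()].
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @return The `pairs` tibble extended with `exon1_len`, `exon2_len`,
#'   `junction_offset` and `sequence` columns (one junction entry per row).
#' @export
build_junction_reference <- function(pairs, genome) {
  if (is.character(genome)) genome <- read_genome(genome)
  seq_cache <- exon_seq_cache(pairs, genome)
  assemble_entries(pairs, seq_cache, mode = "backsplice")
}

#' Build a negative-control junction reference
#'
#' Two controls probe for alignment artifacts with the identical downstream
#' pipeline. `"randomized"` shuffles each exon's sequence once (composition
#' preserved, seed recorded) before assembling the same backsplice entries;
#' genuine reads should find no junction. `"flipped_exon2"` keeps real
#' sequence but reverse-complements the downstream exon and joins it
#' head-to-head after exon1 (`exon1 + revcomp(exon2)`,
#' `junction_offset = length(exon1)`).
#'
#' @inheritParams build_junction_reference
#' @param mode `"randomized"` or `"flipped_exon2"`.
#' @param seed Integer RNG seed, required for `"randomized"`.
#' @return Entry tibble as in [build_junction_reference()], with attributes
#'   `control_mode` and (randomized) `control_seed`.
#' @export
build_control_reference <- function(pairs, genome,
                                    mode = c("randomized", "flipped_exon2"),
                                    seed = NULL) {
  mode <- rlang::arg_match(mode)
  if (is.character(genome)) genome <- read_genome(genome)
  seq_cache <- exon_seq_cache(pairs, genome)
  if (mode == "randomized") {
    if (is.null(seed)) rlang::abort("randomized mode requires a seed")
    seq_cache <- withr::with_seed(seed, {
      lapply(seq_cache, function(s) {
        paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
      })
    })
  }
  out <- assemble_entries(pairs, seq_cache,
                          mode = if (mode == "randomized") "backsplice" else "flipped")
  attr(out, "control_mode") <- mode
  if (mode == "randomized") attr(out, "control_seed") <- seed
  out
}

# One transcribed-orientation sequence per distinct exon used by `pairs`.
exon_seq_cache <- function(pairs, genome) {
  exons <- dplyr::distinct(
    dplyr::bind_rows(
      dplyr::transmute(pairs, .data$chrom, start = .data$e1_start,
                       end = .data$e1_end, .data$strand),
      dplyr::transmute(pairs, .data$chrom, start = .data$e2_start,
                       end = .data$e2_end, .data$strand)))
  key <- exon_key(exons$chrom, exons$start, exons$end, exons$strand)
  seqs <- purrr::pmap_chr(exons, function(chrom, start, end, strand) {
    exon_sequence(genome, chrom, start, end, strand)
  })
  stats::setNames(as.list(seqs), key)
}

exon_key <- function(chrom, start, end, strand) {
  paste(chrom, start, end, strand, sep = ":")
}

assemble_entries <- function(pairs, seq_cache, mode) {
  s1 <- unlist(seq_cache[exon_key(pairs$chrom, pairs$e1_start, pairs$e1_end,
                                  pairs$strand)], use.names = FALSE)
  s2 <- unlist(seq_cache[exon_key(pairs$chrom, pairs$e2_start, pairs$e2_end,
                                  pairs$strand)], use.names = FALSE)
  if (mode == "backsplice") {
    sequence <- paste0(s2, s1)
    offset <- nchar(s2)
  } else {  # flipped_exon2: head-to-head, exon1 then reverse-complemented exon2
    sequence <- paste0(s1, revcomp(s2))
    offset <- nchar(s1)
  }
  dplyr::mutate(pairs,
                exon1_len = nchar(s1),
                exon2_len = nchar(s2),
                junction_offset = offset,
                sequence = sequence)
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write a junction reference to FASTA
#'
#' Headers are machine-readable:
#' `>junction_id|chrom|e1start-e1end|e2start-e2end|strand|offset=<int>`.
#' Control references carry their mode (and seed) in a leading `;` comment.
#'
#' @param entries Entry tibble from [build_junction_reference()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_junction_fasta <- function(entries, path) {
  headers <- sprintf(">%s|%s|%d-%d|%d-%d|%s|offset=%d",
                     entries$junction_id, entries$chrom,
                     entries$e1_start, entries$e1_end,
                     entries$e2_start, entries$e2_end,
                     entries$strand, entries$junction_offset)
  lines <- as.vector(rbind(headers, entries$sequence))
  mode <- attr(entries, "control_mode")
  if (!is.null(mode)) {
    note <- sprintf(";control_mode=%s", mode)
    if (!is.null(attr(entries, "control_seed"))) {
      note <- sprintf("%s seed=%d", note, attr(entries, "control_seed"))
    }
    lines <- c(note, lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a junction reference FASTA written by [write_junction_fasta()]
#'
#' @param path FASTA path.
#' @return Entry tibble with coordinates parsed from the headers.
#' @export
read_junction_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, ";")]
  hdr_idx <- which(startsWith(lines, ">"))
  headers <- sub("^>", "", lines[hdr_idx])
  seqs <- lines[hdr_idx + 1L]
  parts <- stringr::str_split(headers, stringr::fixed("|"))
  junction_id <- vapply(parts, function(p) paste(p[1:3], collapse = "|"), "")
  f <- function(i) vapply(parts, `[`, "", i + 3L)
  e1 <- stringr::str_split_fixed(f(2), "-", 2)
  e2 <- stringr::str_split_fixed(f(3), "-", 2)
  tibble::tibble(
    junction_id = junction_id,
    gene_id = vapply(parts, `[`, "", 1),
    chrom = f(1),
    strand = f(4),
    e1_start = as.integer(e1[, 1]), e1_end = as.integer(e1[, 2]),
    e1_rank = as.integer(vapply(parts, `[`, "", 2)),
    e2_start = as.integer(e2[, 1]), e2_end = as.integer(e2[, 2]),
    e2_rank = as.integer(vapply(parts, `[`, "", 3)),
    junction_offset = as.integer(sub("offset=", "", f(5), fixed = TRUE)),
    sequence = seqs) |>
    dplyr::mutate(exon1_len = .data$e1_end - .data$e1_start,
                  exon2_len = .data$e2_end - .data$e2_start)
}

#' Write the TSV manifest of a junction reference
#'
#' @param entries Entry tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_junction_manifest <- function(entries, path) {
  utils::write.table(
    dplyr::select(entries, -"sequence"),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
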