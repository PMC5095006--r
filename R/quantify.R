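#' Summarise circRNA expression counts
#'
#' Per junction and sample, expression is the number of distinct
#' backsplice-consistent fragments: junctional plus supportive evidence.
#'
#' @param evidence Evidence tibble from [classify_pairs()].
#' @return Wide count tibble: `junction_id` then one integer column per
#'   sample.
#' @export
circ_counts <- function(evidence) {
  evidence |>
    dplyr::filter(.data$class != "none") |>
    dplyr::distinct(.data$junction_id, .data$sample_id, .data$fragment_id) |>
    dplyr::count(.data$junction_id, .data$sample_id) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0L) |>
    dplyr::arrange(.data$junction_id)
}

#' Count linear-transcript fragments over backsplice exon pairs
#'
#' A genomic fragment in concordant (FR, non-divergent) orientation counts
#' as linear evidence for every exon pair where either mate overlaps either
#' exon by at least one base — the conservative rule that any read within a
#' backsplice-capable exon is taken as linear evidence. Divergent
#' (outward-facing) pairs are excluded: they are circular evidence by
#' definition. Each fragment is counted once per junction.
#'
#' @param fragments Genomic fragment tibble (from [read_genome_pairs()] or
#'   built directly): `fragment_id`, `sample_id`, `chrom`, `m1_start`,
#'   `m1_end`, `m2_start`, `m2_end`, `divergent` (logical).
#' @param pairs Backsplice pair tibble from [enumerate_backsplices()].
#' @return Wide count tibble: `junction_id` then one column per sample.
#' @export
linear_counts <- function(fragments, pairs) {
  conc <- dplyr::filter(fragments, !.data$divergent)
  exon_iv <- dplyr::bind_rows(
    dplyr::transmute(pairs, .data$junction_id, .data$chrom,
                     start = .data$e1_start, end = .data$e1_end),
    dplyr::transmute(pairs, .data$junction_id, .data$chrom,
                     start = .data$e2_start, end = .data$e2_end)) |>
    dplyr::distinct()
  mate_iv <- dplyr::bind_rows(
    dplyr::transmute(conc, .data$fragment_id, .data$sample_id, .data$chrom,
                     start = .data$m1_start, end = .data$m1_end),
    dplyr::transmute(conc, .data$fragment_id, .data$sample_id, .data$chrom,
                     start = .data$m2_start, end = .data$m2_end))
  hits <- purrr::map(split(seq_len(nrow(mate_iv)), mate_iv$chrom),
                     function(ix) {
    chrom <- mate_iv$chrom[ix[1]]
    ex <- exon_iv[exon_iv$chrom == chrom, ]
    if (nrow(ex) == 0) return(NULL)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(mate_iv$start[ix] + 1L, mate_iv$end[ix]),
      IRanges::IRanges(ex$start + 1L, ex$end))
    tibble::tibble(
      fragment_id = mate_iv$fragment_id[ix][S4Vectors::queryHits(ov)],
      sample_id = mate_iv$sample_id[ix][S4Vectors::queryHits(ov)],
      junction_id = ex$junction_id[S4Vectors::subjectHits(ov)])
  }) |>
    purrr::list_rbind()
  hits |>
    dplyr::distinct(.data$junction_id, .data$sample_id, .data$fragment_id) |>
    dplyr::count(.data$junction_id, .data$sample_id) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0L) |>
    dplyr::arrange(.data$junction_id)
}

#' Read genomic paired alignments into a fragment table
#'
#' Extracts primary, properly mapped pairs from a genome SAM/BAM and flags
#' divergent (outward-facing) fragments, ready for [linear_counts()].
#'
#' @param path SAM or BAM file of genome alignments.
#' @param sample_id Sample label.
#' @return Fragment tibble with `fragment_id`, `sample_id`, `chrom`, mate
#'   intervals (0-based half-open) and `divergent`.
#' @export
read_genome_pairs <- function(path, sample_id = "S1") {
  aln <- import_alignments(path, sample_id = sample_id)
  aln |>
    dplyr::transmute(.data$fragment_id, .data$sample_id,
                     chrom = .data$entry_id,
                     .data$m1_start, .data$m1_end,
                     .data$m2_start, .data$m2_end,
                     divergent = is_divergent(.data$m1_start, .data$m1_strand,
                                              .data$m2_start, .data$m2_strand))
}

# Outward-facing pair: the leftmost mate is on the minus strand.
is_divergent <- function(m1_start, m1_strand, m2_start, m2_strand) {
  left_strand <- ifelse(m1_start <= m2_start, m1_strand, m2_strand)
  right_strand <- ifelse(m1_start <= m2_start, m2_strand, m1_strand)
  left_strand == "-" & right_strand == "+"
}

#' Circular-to-linear abundance ratio
#'
#' For each backsplice-capable exon pair, the ratio of fragments supporting
#' the circular form to fragments supporting the linear form estimates the
#' usage of those exons as circRNA versus linear transcript. Junctions with
#' circular but no linear evidence get `ratio = Inf` and are flagged
#' `circ_only`; junctions with neither are dropped.
#'
#' @param circ,linear Wide count tibbles ([circ_counts()], [linear_counts()]).
#' @return Long tibble: `junction_id`, `sample_id`, `circ_count`,
#'   `linear_count`, `ratio`, `circ_only`.
#' @export
circ_linear_ratio <- function(circ, linear) {
  long <- function(x, value) {
    tidyr::pivot_longer(x, -"junction_id", names_to = "sample_id",
                        values_to = value)
  }
  dplyr::full_join(long(circ, "circ_count"), long(linear, "linear_count"),
                   by = c("junction_id", "sample_id")) |>
    dplyr::mutate(dplyr::across(c("circ_count", "linear_count"),
                                ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::filter(.data$circ_count + .data$linear_count > 0) |>
    dplyr::mutate(ratio = .data$circ_count / .data$linear_count,
                  circ_only = .data$linear_count == 0L)
}

#' Fragments per kilobase per million mapped fragments
#'
#' `fpkm = count / (length_kb * mapped_millions)`.
#'
#' @param counts Wide count tibble (`feature_id` or `junction_id` first
#'   column, then sample columns).
#' @param lengths Tibble with the feature id column and `length` (bases), or
#'   a named numeric vector.
#' @param totals Mapped fragments per sample: named numeric vector; defaults
#'   to the column sums of `counts`.
#' @return Tibble of the same shape with FPKM values.
#' @export
fpkm <- function(counts, lengths, totals = NULL) {
  id_col <- names(counts)[1]
  samples <- names(counts)[-1]
  if (!is.numeric(lengths)) {
    lengths <- stats::setNames(lengths$length, lengths[[1]])
  }
  len <- unname(lengths[counts[[id_col]]])
  if (anyNA(len) || any(len <= 0)) {
    rlang::abort("every feature needs a positive length for FPKM")
  }
  if (is.null(totals)) {
    totals <- vapply(counts[samples], sum, numeric(1))
  }
  if (any(totals <= 0)) rlang::abort("mapped totals must be positive")
  out <- counts
  for (s in samples) {
    out[[s]] <- counts[[s]] / ((len / 1e3) * (totals[[s]] / 1e6))
  }
  out
}

#' RNase-R-style enrichment fold change, circRNA versus mRNA
#'
#' Per-feature fold change `(treated + pc) / (untreated + pc)` between an
#' exonuclease-treated and an untreated sample, restricted to the gene
#' universe with at least one detected circular isoform, followed by a
#' one-sided Wilcoxon rank-sum test that circRNA fold changes exceed mRNA
#' fold changes (circles resist RNase R; linear RNAs are depleted).
#'
#' @param treated,untreated Tibbles with a feature id first column and one
#'   numeric column of FPKM (or count) values.
#' @param classes Tibble mapping feature id to `class` (`"circRNA"` or
#'   `"mRNA"`).
#' @param pseudocount Added to both values before the ratio (default 1).
#' @return Object of class `circ_enrichment`: list with `fold_changes`
#'   (feature, class, treated, untreated, fold_change), `medians` (per
#'   class) and `test` (the `htest`).
#' @export
enrichment_fold_change <- function(treated, untreated, classes,
                                   pseudocount = 1) {
  stopifnot(pseudocount > 0)
  id <- names(treated)[1]
  tr <- stats::setNames(treated[[2]], treated[[id]])
  un <- stats::setNames(untreated[[2]], untreated[[1]])
  common <- intersect(names(tr), names(un))
  if (length(common) == 0) rlang::abort("no overlapping features")
  fc <- tibble::tibble(
    feature_id = common,
    treated = unname(tr[common]),
    untreated = unname(un[common]),
    fold_change = (unname(tr[common]) + pseudocount) /
      (unname(un[common]) + pseudocount)) |>
    dplyr::inner_join(stats::setNames(classes[, 1:2],
                                      c("feature_id", "class")),
                      by = "feature_id")
  medians <- fc |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(median_fold_change = stats::median(.data$fold_change),
                     n = dplyr::n(), .groups = "drop")
  has_both <- all(c("circRNA", "mRNA") %in% fc$class)
  test <- if (has_both) {
    stats::wilcox.test(
      fc$fold_change[fc$class == "circRNA"],
      fc$fold_change[fc$class == "mRNA"],
      alternative = "greater", exact = FALSE)
  }
  structure(list(fold_changes = fc, medians = medians, test = test),
            class = "circ_enrichment")
}

#' @export
print.circ_enrichment <- function(x, ...) {
  cat("<circ_enrichment>\n")
  print(x$medians)
  if (!is.null(x$test)) {
    cat(sprintf("one-sided Wilcoxon rank-sum p = %.3g\n", x$test$p.value))
  }
  invisible(x)
}

#' @export
tidy.circ_enrichment <- function(x, ...) x$fold_changes

#' @export
glance.circ_enrichment <- function(x, ...) {
  med <- stats::setNames(x$medians$median_fold_change, x$medians$class)
  tibble::tibble(median_fc_circ = unname(med["circRNA"]),
                 median_fc_mrna = unname(med["mRNA"]),
                 statistic = if (is.null(x$test)) NA_real_ else
                   unname(x$test$statistic),
                 p_value = if (is.null(x$test)) NA_real_ else x$test$p.value)
}

#' Prefilter a count matrix for differential expression
#'
#' Keeps rows expressed at a minimum of `min_count` in at least
#' `min_samples` samples — the standard low-expression filter applied
#' before handing counts to edgeR/DESeq2-class tools.
#'
#' @param counts Wide count tibble (id column first).
#' @param min_count Minimum count (default 3).
#' @param min_samples Minimum number of samples at that count (default 3).
#' @return Filtered tibble.
#' @export
prefilter_counts <- function(counts, min_count = 3L, min_samples = 3L) {
  samples <- names(counts)[-1]
  if (length(samples) < min_samples) {
    rlang::abort("fewer sample columns than min_samples")
  }
  m <- as.matrix(counts[samples])
  counts[rowSums(m >= min_count) >= min_samples, ]
}

#' Z-scored log2 counts-per-million
#'
#' `cpm = 1e6 * count / column_total`; each row of `log2(cpm + pseudocount)`
#' is centred and scaled to unit variance. Constant rows map to zeros
#' rather than NaN.
#'
#' @param counts Wide count tibble (id column first).
#' @param pseudocount Added inside the log (default 0.5).
#' @return Tibble of the same shape with z-scores.
#' @export
zscore_log2cpm <- function(counts, pseudocount = 0.5) {
  samples <- names(counts)[-1]
  m <- as.matrix(counts[samples])
  totals <- colSums(m)
  if (any(totals <= 0)) rlang::abort("column totals must be positive")
  lg <- log2(sweep(m, 2, totals, "/") * 1e6 + pseudocount)
  mu <- rowMeans(lg)
  sd <- apply(lg, 1, stats::sd)
  z <- (lg - mu) / ifelse(sd == 0, 1, sd)
  out <- counts
  out[samples] <- as.data.frame(z)
  out
}
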