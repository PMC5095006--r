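#' Classify read-pair alignments as backsplice evidence
#'
#' Applies the evidence rules on the junction entry. A pair is
#' **junctional** when either mate crosses the backsplice point
#' (`junction_offset`) with at least `min_overlap` bases anchored on each
#' side — i.e. overlapping both exons — while its mate lies anywhere on the
#' entry. It is **supportive** when no mate crosses the junction but the
#' forward mate lies wholly within the downstream-exon (left) segment and
#' the reverse mate wholly within the upstream-exon (right) segment: mates
#' concordant on the entry are divergent on the genome, consistent only
#' with a circular template. Anything else (for example both mates inside
#' one exon segment, indistinguishable from a linear read) is `"none"`.
#'
#' @param alignments Deduplicated primary alignment tibble.
#' @param entries Junction entry tibble (provides `junction_offset`).
#' @param min_overlap Minimum anchor on each side of the junction for
#'   junctional evidence, in bases (default 10).
#' @return Evidence tibble: `fragment_id`, `sample_id`, `junction_id`,
#'   `class` (`junctional`/`supportive`/`none`), and `overlap_left`,
#'   `overlap_right` for the best junction-crossing mate (NA when no mate
#'   crosses).
#' @export
classify_pairs <- function(alignments, entries, min_overlap = 10L) {
  ev <- dplyr::inner_join(
    alignments,
    dplyr::select(entries, junction_id = "junction_id",
                  "junction_offset", "exon1_len", "exon2_len"),
    by = c(entry_id = "junction_id"))
  if (nrow(ev) < nrow(alignments)) {
    rlang::abort("alignment refers to an entry absent from the reference")
  }
  entry_len <- ev$exon1_len + ev$exon2_len
  if (any(ev$m1_start < 0 | ev$m2_start < 0 |
          ev$m1_end > entry_len | ev$m2_end > entry_len)) {
    rlang::abort("alignment outside entry bounds: caller bug upstream")
  }
  off <- ev$junction_offset
  # anchor widths of each mate around the junction point
  l1 <- off - ev$m1_start; r1 <- ev$m1_end - off
  l2 <- off - ev$m2_start; r2 <- ev$m2_end - off
  span1 <- l1 > 0 & r1 > 0
  span2 <- l2 > 0 & r2 > 0
  anch1 <- ifelse(span1, pmin(l1, r1), -1L)
  anch2 <- ifelse(span2, pmin(l2, r2), -1L)
  best <- pmax(anch1, anch2)
  junctional <- best >= min_overlap
  # forward mate wholly left of the junction, reverse mate wholly right
  fwd_end <- ifelse(ev$m1_strand == "+", ev$m1_end, ev$m2_end)
  rev_start <- ifelse(ev$m1_strand == "+", ev$m2_start, ev$m1_start)
  supportive <- !junctional & !span1 & !span2 &
    fwd_end <= off & rev_start >= off
  use1 <- anch1 >= anch2
  tibble::tibble(
    fragment_id = ev$fragment_id,
    sample_id = ev$sample_id,
    junction_id = ev$entry_id,
    class = dplyr::case_when(junctional ~ "junctional",
                             supportive ~ "supportive",
                             TRUE ~ "none"),
    overlap_left = dplyr::if_else(use1 & span1, l1,
                                  dplyr::if_else(span2, l2, NA_integer_)),
    overlap_right = dplyr::if_else(use1 & span1, r1,
                                   dplyr::if_else(span2, r2, NA_integer_)))
}

#' Call candidate circRNAs from classified evidence
#'
#' Aggregates distinct evidence fragments per junction and sample and
#' applies the calling thresholds. Under policy `"A"` (default) a candidate
#' passes with at least `min_junctional` junctional fragments, or with at
#' least `min_supported` backsplice-consistent fragments in total
#' (junctional + supportive). Policy `"B"` requires `min_junctional`
#' junctional or `min_supported` supportive-only fragments. A fragment
#' contributing junctional evidence is never double-counted as supportive
#' (classes are exclusive).
#'
#' @param evidence Evidence tibble from [classify_pairs()].
#' @param entries Junction entry tibble (for output coordinates).
#' @param min_junctional Junctional-fragment threshold (default 3).
#' @param min_supported Supporting-fragment threshold (default 10).
#' @param policy `"A"` (total ≥ min_supported) or `"B"` (supportive-only).
#' @return A `circ_calls` tibble: one row per junction × sample with
#'   `junctional_count`, `supported_count`, `passed`, plus `passed_any`
#'   (cross-sample union call) and genomic coordinates, ordered by
#'   coordinate. Thresholds and policy are carried as attributes.
#' @export
call_candidates <- function(evidence, entries, min_junctional = 3L,
                            min_supported = 10L, policy = c("A", "B")) {
  policy <- rlang::arg_match(policy)
  counts <- evidence |>
    dplyr::filter(.data$class != "none") |>
    dplyr::distinct(.data$junction_id, .data$sample_id, .data$fragment_id,
                    .data$class) |>
    dplyr::count(.data$junction_id, .data$sample_id, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (col in c("junctional", "supportive")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  calls <- counts |>
    dplyr::rename(junctional_count = "junctional",
                  supported_count = "supportive") |>
    dplyr::mutate(passed = candidate_passes(
      .data$junctional_count, .data$supported_count,
      min_junctional, min_supported, policy)) |>
    dplyr::inner_join(
      dplyr::select(entries, "junction_id", "gene_id", "chrom", "strand",
                    "e1_start", "e2_end"),
      by = "junction_id") |>
    dplyr::group_by(.data$junction_id) |>
    dplyr::mutate(passed_any = any(.data$passed)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$e1_start, .data$e2_end,
                   .data$junction_id, .data$sample_id) |>
    dplyr::relocate("junction_id", "gene_id", "chrom", "e1_start", "e2_end",
                    "strand", "sample_id", "junctional_count",
                    "supported_count", "passed", "passed_any")
  structure(calls,
            class = c("circ_calls", class(calls)),
            min_junctional = min_junctional, min_supported = min_supported,
            policy = policy)
}

candidate_passes <- function(junctional, supported, min_junctional,
                             min_supported, policy) {
  if (policy == "A") {
    junctional >= min_junctional | (junctional + supported) >= min_supported
  } else {
    junctional >= min_junctional | supported >= min_supported
  }
}

#' Junction ids called in at least one sample
#'
#' @param calls A `circ_calls` tibble.
#' @return Character vector of junction ids with `passed_any`.
#' @export
called_junctions <- function(calls) {
  unique(calls$junction_id[calls$passed_any])
}

#' @export
tidy.circ_calls <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.circ_calls <- function(x, ...) {
  tibble::tibble(
    n_junctions = dplyr::n_distinct(x$junction_id),
    n_samples = dplyr::n_distinct(x$sample_id),
    n_called_union = length(called_junctions(x)),
    policy = attr(x, "policy"),
    min_junctional = attr(x, "min_junctional"),
    min_supported = attr(x, "min_supported"))
}

#' Run reads through a negative-control reference
#'
#' Applies the identical map → deduplicate → classify → call pipeline to a
#' control reference (randomized or flipped-exon2) and reports the control
#' candidate set and its intersection with the real candidates.
#'
#' @param reads Read-pair tibble.
#' @param control_entries Control reference from [build_control_reference()].
#' @param real_calls Optional `circ_calls` from the real reference, for the
#'   overlap report.
#' @param sample_id,min_overlap,min_junctional,min_supported,policy,k,max_mismatch
#'   Passed through to the underlying stages.
#' @return List of class `circ_control_report`: `calls` (control
#'   `circ_calls`), `n_control` (junctions called on the control), and
#'   `overlap` (junction ids shared with the real candidate set).
#' @export
run_control <- function(reads, control_entries, real_calls = NULL,
                        sample_id = "S1", min_overlap = 10L,
                        min_junctional = 3L, min_supported = 10L,
                        policy = "A", k = 15L, max_mismatch = 2L) {
  calls <- run_detection(reads, control_entries, sample_id = sample_id,
                         min_overlap = min_overlap,
                         min_junctional = min_junctional,
                         min_supported = min_supported, policy = policy,
                         k = k, max_mismatch = max_mismatch)$calls
  ctrl <- called_junctions(calls)
  overlap <- if (is.null(real_calls)) character(0) else
    intersect(ctrl, called_junctions(real_calls))
  structure(list(calls = calls, n_control = length(ctrl), overlap = overlap),
            class = "circ_control_report")
}

#' @export
print.circ_control_report <- function(x, ...) {
  cat(sprintf("<circ_control_report> %d control candidate(s), %d overlapping real candidates\n",
              x$n_control, length(x$overlap)))
  invisible(x)
}

#' One-call detection: map, deduplicate, classify, call
#'
#' Convenience wrapper running the full evidence chain of the detection
#' pipeline on an in-memory read set against one junction reference.
#'
#' @inheritParams run_control
#' @param entries Junction entry tibble.
#' @return List with `alignments` (deduplicated), `evidence` and `calls`.
#' @export
run_detection <- function(reads, entries, sample_id = "S1", min_overlap = 10L,
                          min_junctional = 3L, min_supported = 10L,
                          policy = "A", k = 15L, max_mismatch = 2L) {
  index <- index_reference(entries, k = k)
  aln <- map_reads(reads, index, sample_id = sample_id,
                   max_mismatch = max_mismatch)
  aln <- suppressMessages(remove_duplicates(aln))
  evidence <- classify_pairs(aln, entries, min_overlap = min_overlap)
  calls <- call_candidates(evidence, entries,
                           min_junctional = min_junctional,
                           min_supported = min_supported, policy = policy)
  list(alignments = aln, evidence = evidence, calls = calls)
}
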