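#' Build a k-mer index over a junction reference
#'
#' Exact-match seed lookup from every k-mer of every entry to its
#' (entry, offset) positions. This backs the built-in ungapped
#' seed-and-extend mapper; external aligners can be used instead via
#' [import_alignments()].
#'
#' @param entries Entry tibble from [build_junction_reference()] (needs
#'   `junction_id` and `sequence`).
#' @param k Seed length in bases (default 15; must not exceed read length).
#' @return An object of class `kmer_index`.
#' @export
index_reference <- function(entries, k = 15L) {
  k <- as.integer(k)
  seqs <- entries$sequence
  ids <- entries$junction_id
  lens <- nchar(seqs)
  n_pos <- pmax(lens - k + 1L, 0L)
  entry_idx <- rep.int(seq_along(seqs), n_pos)
  pos <- unlist(lapply(n_pos, function(n) seq_len(n) - 1L), use.names = FALSE)
  kmers <- substring(rep.int(seqs, n_pos), pos + 1L, pos + k)
  hits <- split(entry_idx * 2^32 + pos, kmers)  # packed (entry, pos)
  structure(
    list(k = k, ids = ids, seqs = seqs, lens = lens,
         env = list2env(hits, hash = TRUE, size = max(length(hits), 29L)),
         n_indexed = sum(n_pos)),
    class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d entries, %d indexed positions\n",
              x$k, length(x$ids), x$n_indexed))
  invisible(x)
}

#' Look up a k-mer in the index
#'
#' @param index A `kmer_index`.
#' @param kmer A single k-mer string.
#' @return Tibble of hits: `entry_id`, `pos` (0-based). Empty if absent.
#' @export
lookup_kmer <- function(index, kmer) {
  packed <- index$env[[kmer]]
  if (is.null(packed)) {
    return(tibble::tibble(entry_id = character(), pos = integer()))
  }
  entry <- as.integer(packed %/% 2^32)
  tibble::tibble(entry_id = index$ids[entry],
                 pos = as.integer(packed - entry * 2^32))
}

# Candidate ungapped placements of one reference-forward read sequence.
# Returns matrix cols (entry, start, mm); mm <= max_mm only.
seed_candidates <- function(seq, index, max_mm) {
  len <- nchar(seq)
  k <- index$k
  offs <- unique(c(0L, (len - k) %/% 2L, len - k))
  offs <- offs[offs >= 0L]
  entry <- integer(0); start <- integer(0)
  for (o in offs) {
    h <- index$env[[substr(seq, o + 1L, o + k)]]
    if (is.null(h)) next
    e <- as.integer(h %/% 2^32)
    s <- as.integer(h %% 2^32) - o  # shift hit position back to read start
    ok <- s >= 0L & (s + len) <= index$lens[e]
    entry <- c(entry, e[ok]); start <- c(start, s[ok])
  }
  if (length(entry) == 0L) return(matrix(integer(0), ncol = 3))
  dup <- duplicated(entry * 2^32 + start)
  entry <- entry[!dup]; start <- start[!dup]
  if (length(entry) == 0L) return(matrix(integer(0), ncol = 3))
  rraw <- charToRaw(seq)
  mm <- integer(length(entry))
  for (j in seq_along(entry)) {
    win <- substr(index$seqs[entry[j]], start[j] + 1L, start[j] + len)
    mm[j] <- sum(charToRaw(win) != rraw)
  }
  keep <- mm <= max_mm
  cbind(entry = entry[keep], start = start[keep], mm = mm[keep])
}

# Best FR placement for one pair given precomputed reverse complements.
map_pair_core <- function(r1, r2, r1rc, r2rc, index, max_mismatch, max_span) {
  l1 <- nchar(r1); l2 <- nchar(r2)
  best <- NULL
  for (orient in 1:2) {
    if (orient == 1L) {  # mate1 forward, mate2 reverse
      cf <- seed_candidates(r1, index, max_mismatch)
      cr <- seed_candidates(r2rc, index, max_mismatch)
      lf <- l1; lr <- l2
    } else {             # mate2 forward, mate1 reverse
      cf <- seed_candidates(r2, index, max_mismatch)
      cr <- seed_candidates(r1rc, index, max_mismatch)
      lf <- l2; lr <- l1
    }
    if (nrow(cf) == 0L || nrow(cr) == 0L) next
    for (i in seq_len(nrow(cf))) {
      same <- cr[, "entry"] == cf[i, "entry"]
      if (!any(same)) next
      crs <- cr[same, , drop = FALSE]
      ok <- crs[, "start"] >= cf[i, "start"] &
        (crs[, "start"] + lr - cf[i, "start"]) <= max_span
      for (j in which(ok)) {
        cand <- stats::setNames(
          c(cf[i, "entry"], cf[i, "start"], crs[j, "start"],
            cf[i, "mm"] + crs[j, "mm"], orient),
          c("entry", "fstart", "rstart", "mm", "orient"))
        if (is.null(best) || better_placement(cand, best, index$ids)) best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  if (best[["orient"]] == 1L) {
    m1s <- best[["fstart"]]; m1e <- m1s + l1; m1str <- "+"
    m2s <- best[["rstart"]]; m2e <- m2s + l2; m2str <- "-"
  } else {
    m2s <- best[["fstart"]]; m2e <- m2s + l2; m2str <- "+"
    m1s <- best[["rstart"]]; m1e <- m1s + l1; m1str <- "-"
  }
  list(entry_id = index$ids[best[["entry"]]],
       m1_start = m1s, m1_end = m1e, m1_strand = m1str,
       m2_start = m2s, m2_end = m2e, m2_strand = m2str,
       n_mismatch = best[["mm"]])
}

# Deterministic ordering: fewest mismatches, then lexicographically lowest
# entry id, then leftmost fragment start, then mate1-forward orientation.
better_placement <- function(a, b, ids) {
  if (a[["mm"]] != b[["mm"]]) return(a[["mm"]] < b[["mm"]])
  ia <- ids[a[["entry"]]]; ib <- ids[b[["entry"]]]
  if (ia != ib) return(ia < ib)
  if (a[["fstart"]] != b[["fstart"]]) return(a[["fstart"]] < b[["fstart"]])
  a[["orient"]] < b[["orient"]]
}

#' Map one read pair to the junction reference
#'
#' Ungapped seed-and-extend placement of a paired-end fragment: seeds are
#' exact k-mer matches, extension counts mismatches over the full read, and
#' the pair must land on one entry in proper inward (FR) orientation within
#' `max_span`. The best placement (fewest total mismatches; deterministic
#' tie-break by entry id, then leftmost position) is reported as the primary
#' alignment.
#'
#' @param read1,read2 Mate sequences (as sequenced; read2 is matched as its
#'   reverse complement).
#' @param index A `kmer_index` from [index_reference()].
#' @param max_mismatch Per-mate mismatch ceiling (default 2).
#' @param max_span Maximum fragment span on the entry (default 1000).
#' @return A one-row alignment tibble, or `NULL` if unmappable.
#' @export
map_read_pair <- function(read1, read2, index, max_mismatch = 2L,
                          max_span = 1000L) {
  hit <- map_pair_core(read1, read2, revcomp(read1), revcomp(read2),
                       index, max_mismatch, max_span)
  if (is.null(hit)) return(NULL)
  tibble::tibble(fragment_id = NA_character_, sample_id = NA_character_,
                 entry_id = hit$entry_id,
                 m1_start = hit$m1_start, m1_end = hit$m1_end,
                 m1_strand = hit$m1_strand,
                 m2_start = hit$m2_start, m2_end = hit$m2_end,
                 m2_strand = hit$m2_strand,
                 n_mismatch = hit$n_mismatch, primary = TRUE)
}

#' Map a table of read pairs
#'
#' Vectorised driver for [map_read_pair()] over a read-pair tibble (as
#' produced by [simulate_reads()] or [read_fastq_pairs()]).
#'
#' @param reads Tibble with `fragment_id`, `read1`, `read2`.
#' @param index A `kmer_index`.
#' @param sample_id Sample label attached to every alignment.
#' @inheritParams map_read_pair
#' @return Alignment tibble (one primary alignment per mapped fragment):
#'   `fragment_id`, `sample_id`, `entry_id`, mate coordinates
#'   (0-based half-open), strands, `n_mismatch`, `primary`.
#' @export
map_reads <- function(reads, index, sample_id = "S1", max_mismatch = 2L,
                      max_span = 1000L) {
  n <- nrow(reads)
  rc1 <- revcomp(reads$read1)
  rc2 <- revcomp(reads$read2)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    hit <- map_pair_core(reads$read1[i], reads$read2[i], rc1[i], rc2[i],
                         index, max_mismatch, max_span)
    if (!is.null(hit)) out[[i]] <- hit
  }
  mapped <- !vapply(out, is.null, logical(1))
  out <- out[mapped]
  tibble::tibble(
    fragment_id = reads$fragment_id[mapped],
    sample_id = sample_id,
    entry_id = vapply(out, `[[`, "", "entry_id"),
    m1_start = vapply(out, function(x) as.integer(x$m1_start), 1L),
    m1_end = vapply(out, function(x) as.integer(x$m1_end), 1L),
    m1_strand = vapply(out, `[[`, "", "m1_strand"),
    m2_start = vapply(out, function(x) as.integer(x$m2_start), 1L),
    m2_end = vapply(out, function(x) as.integer(x$m2_end), 1L),
    m2_strand = vapply(out, `[[`, "", "m2_strand"),
    n_mismatch = vapply(out, function(x) as.integer(x$n_mismatch), 1L),
    primary = TRUE)
}

#' Remove PCR duplicates from paired alignments
#'
#' Fragments sharing outer coordinates and orientation on an entry
#' (samtools-rmdup semantics: identical fragment start, fragment end and
#' forward-mate identity) are collapsed to one representative — the first
#' fragment id in sort order, so the survivor set is independent of input
#' order.
#'
#' @param alignments Alignment tibble from [map_reads()] or
#'   [import_alignments()].
#' @return Deduplicated alignment tibble; the number of removed fragments is
#'   reported via a message and the `n_duplicates` attribute.
#' @export
remove_duplicates <- function(alignments) {
  out <- alignments |>
    dplyr::mutate(.frag_start = pmin(.data$m1_start, .data$m2_start),
                  .frag_end = pmax(.data$m1_end, .data$m2_end)) |>
    dplyr::arrange(.data$fragment_id) |>
    dplyr::distinct(.data$sample_id, .data$entry_id, .data$.frag_start,
                    .data$.frag_end, .data$m1_strand, .keep_all = TRUE) |>
    dplyr::select(-".frag_start", -".frag_end")
  n_dup <- nrow(alignments) - nrow(out)
  if (n_dup > 0) message(sprintf("removed %d duplicate fragment(s)", n_dup))
  attr(out, "n_duplicates") <- n_dup
  out
}
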