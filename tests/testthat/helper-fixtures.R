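# Shared fixtures, built in code at test time.

# Hand-crafted two-gene genome with known exon sequences:
#   chrT: AAAA CCCC ACGT TTGG  (exons of geneP, plus strand)
#   chrM: minus-strand gene with two exons
tiny_genome <- function() {
  Biostrings::DNAStringSet(c(
    chrT = "AAAACCCCACGTTTGG",
    chrM = paste0(strrep("T", 10), "GATTACAGAT", strrep("A", 10),
                  "CCGGAATTCC", strrep("T", 10))))
}

tiny_exons <- function() {
  tibble::tibble(
    gene_id = c("geneP", "geneP", "geneP", "geneM", "geneM"),
    chrom = c("chrT", "chrT", "chrT", "chrM", "chrM"),
    start = c(0L, 4L, 8L, 10L, 30L),
    end = c(4L, 8L, 12L, 20L, 40L),
    strand = c("+", "+", "+", "-", "-"),
    rank = c(1L, 2L, 3L, 2L, 1L))
}

# Standard simulation fixture (memoised per test session).
fixture_env <- new.env(parent = emptyenv())
std_fixture <- function() {
  if (is.null(fixture_env$fix)) {
    fix <- make_fixture_genome(n_genes = 50L, seed = 20L)
    fix$pairs <- enumerate_backsplices(fix$exons)
    fix$entries <- build_junction_reference(fix$pairs, fix$genome)
    fixture_env$fix <- fix
  }
  fixture_env$fix
}

# Minimal junction-entry row for classifier tests: two 100 bp exon segments,
# junction at offset 100. Sequence content is irrelevant to classification.
crafted_entry <- function(junction_id = "geneX|1|2", offset = 100L,
                          exon1_len = 100L, exon2_len = offset) {
  tibble::tibble(
    junction_id = junction_id, gene_id = sub("\\|.*", "", junction_id),
    chrom = "chr1", strand = "+",
    e1_start = 1000L, e1_end = 1000L + exon1_len, e1_rank = 1L,
    e2_start = 2000L, e2_end = 2000L + exon2_len, e2_rank = 2L,
    exon1_len = exon1_len, exon2_len = exon2_len,
    junction_offset = offset,
    sequence = strrep("A", exon1_len + exon2_len))
}

# Alignment row on a crafted entry (FR orientation unless stated).
crafted_alignment <- function(fragment_id, entry_id, m1, m2,
                              m1_strand = "+", m2_strand = "-",
                              sample_id = "S1") {
  tibble::tibble(
    fragment_id = fragment_id, sample_id = sample_id, entry_id = entry_id,
    m1_start = m1[1], m1_end = m1[2], m1_strand = m1_strand,
    m2_start = m2[1], m2_end = m2[2], m2_strand = m2_strand,
    n_mismatch = 0L, primary = TRUE)
}

# Independent re-implementation of the evidence rules, one row at a time,
# straight from the definitions (used as a brute-force oracle).
oracle_classify <- function(aln, entry, min_overlap = 10L) {
  off <- entry$junction_offset
  crosses <- function(s, e) s < off && e > off
  anchor <- function(s, e) if (crosses(s, e)) min(off - s, e - off) else -1L
  a1 <- anchor(aln$m1_start, aln$m1_end)
  a2 <- anchor(aln$m2_start, aln$m2_end)
  if (max(a1, a2) >= min_overlap) return("junctional")
  fwd_end <- if (aln$m1_strand == "+") aln$m1_end else aln$m2_end
  rev_start <- if (aln$m1_strand == "+") aln$m2_start else aln$m1_start
  if (!crosses(aln$m1_start, aln$m1_end) &&
      !crosses(aln$m2_start, aln$m2_end) &&
      fwd_end <= off && rev_start >= off) {
    return("supportive")
  }
  "none"
}

# Random alignments within a crafted entry, for property-style tests.
random_alignments <- function(entry, n, seed) {
  withr::with_seed(seed, {
    L <- entry$exon1_len + entry$exon2_len
    m1s <- sample.int(L - 50L, n, replace = TRUE) - 1L
    m2s <- pmin(m1s + sample.int(60L, n, replace = TRUE), L - 50L)
    tibble::tibble(
      fragment_id = sprintf("f%04d", seq_len(n)), sample_id = "S1",
      entry_id = entry$junction_id,
      m1_start = m1s, m1_end = m1s + 50L, m1_strand = "+",
      m2_start = m2s, m2_end = m2s + 50L, m2_strand = "-",
      n_mismatch = 0L, primary = TRUE)
  })
}
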