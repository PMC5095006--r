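#' Generate a toy genome with annotation and truth manifest
#'
#' Seed-deterministic random genome: non-overlapping multi-exon genes laid
#' out along one chromosome, strands drawn at random, uniform base
#' composition. Defaults reflect typical short internal human exons and
#' compact toy genes; the manifest is the ground truth for annotation tests.
#'
#' @param n_genes Number of genes (default 50).
#' @param exons_per_gene Integer range, exons per gene (default `c(2, 4)`).
#' @param exon_len Integer range of exon lengths in bases (default
#'   `c(90, 120)`).
#' @param intron_len Integer range of intron lengths (default `c(80, 200)`).
#' @param intergenic Integer range of gaps between genes (default
#'   `c(200, 400)`).
#' @param seed RNG seed.
#' @param dir If given, `genome.fa` and `annotation.gtf` are written there.
#' @return List with `genome` (DNAStringSet), `exons` (truth manifest in
#'   the [load_annotation()] layout), and `genome_path` / `annotation_path`
#'   when `dir` is given.
#' @export
make_fixture_genome <- function(n_genes = 50L, exons_per_gene = c(2L, 4L),
                                exon_len = c(90L, 120L),
                                intron_len = c(80L, 200L),
                                intergenic = c(200L, 400L),
                                seed = 1L, dir = NULL) {
  stopifnot(n_genes >= 1, all(exon_len > 0), all(intron_len > 0))
  withr::with_seed(seed, {
    runif_int <- function(rng) sample(rng[1]:rng[2], 1L)
    pos <- 0L
    rows <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      pos <- pos + runif_int(intergenic)
      n_ex <- runif_int(exons_per_gene)
      strand <- sample(c("+", "-"), 1L)
      starts <- ends <- integer(n_ex)
      for (e in seq_len(n_ex)) {
        len <- runif_int(exon_len)
        starts[e] <- pos; ends[e] <- pos + len
        pos <- ends[e] + if (e < n_ex) runif_int(intron_len) else 0L
      }
      gene_id <- sprintf("gene%03d", g)
      rank <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      rows[[g]] <- tibble::tibble(gene_id = gene_id, chrom = "chr1",
                                  start = starts, end = ends,
                                  strand = strand, rank = rank)
    }
    exons <- purrr::list_rbind(rows) |>
      dplyr::arrange(.data$gene_id, .data$rank)
    total_len <- pos + runif_int(intergenic)
    genome_seq <- paste(sample(c("A", "C", "G", "T"), total_len,
                               replace = TRUE), collapse = "")
    genome <- Biostrings::DNAStringSet(stats::setNames(genome_seq, "chr1"))
    out <- list(genome = genome, exons = exons)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      out$genome_path <- file.path(dir, "genome.fa")
      Biostrings::writeXStringSet(genome, out$genome_path)
      out$annotation_path <- file.path(dir, "annotation.gtf")
      write_gtf(exons, out$annotation_path)
    }
    out
  })
}

# Minimal single-transcript-per-gene GTF (1-based inclusive).
write_gtf <- function(exons, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                   exons$gene_id, exons$gene_id)
  lines <- sprintf("chr1\tfixture\texon\t%d\t%d\t.\t%s\t.\t%s",
                   exons$start + 1L, exons$end, exons$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Select backsplice junctions to plant as true circles
#'
#' Uniform selection without replacement over the junction reference,
#' deterministic under the seed.
#'
#' @param entries Junction entry (or pair) tibble.
#' @param n_circles Number of circles to plant (default 200).
#' @param seed RNG seed.
#' @return Truth tibble (`junction_id`) with attribute `seed`.
#' @export
plant_circles <- function(entries, n_circles = 200L, seed = 1L) {
  ids <- entries$junction_id
  if (n_circles > length(ids)) {
    rlang::abort(sprintf("n_circles (%d) exceeds available junctions (%d)",
                         n_circles, length(ids)))
  }
  chosen <- withr::with_seed(seed, sample(ids, n_circles))
  structure(tibble::tibble(junction_id = sort(chosen)), seed = seed)
}

# Circularised sequence of an entry: single copy of the circle. For
# single-exon backsplices the reference entry is the doubled exon, so the
# circle is its first half; for exon pairs it is the whole entry.
circle_sequence <- function(entries) {
  ifelse(entries$e1_rank == entries$e2_rank,
         substr(entries$sequence, 1L, entries$exon2_len),
         entries$sequence)
}

#' Simulate paired-end reads from planted circles and linear background
#'
#' Circle fragments are drawn uniformly from the circularised backsplice
#' sequence — positions wrap modulo the circle length, so junction-spanning
#' and non-spanning fragments both occur. Linear fragments are drawn from
#' each gene's canonical transcript (exons concatenated in transcribed
#' order). Fragment lengths are normal, truncated below at twice the read
#' length (or at the read length when overlapping mates are allowed);
#' substitution errors are i.i.d. per base; mates are FR-oriented. Depth is
#' a fragment count, not per-base coverage.
#'
#' @param truth Truth tibble from [plant_circles()] (may be empty for
#'   linear-only simulations).
#' @param entries Junction reference the truth refers to.
#' @param exons Exon table ([load_annotation()] layout) for the linear
#'   background; `NULL` disables the background.
#' @param genome Genome (DNAStringSet or FASTA path); required with `exons`.
#' @param read_len Read length (default 50).
#' @param frag_mean,frag_sd Fragment-length distribution (default 100, 5).
#' @param circle_depth Fragments per planted circle (default 20).
#' @param linear_depth Fragments per gene of background (default 10).
#' @param error_rate Per-base substitution rate (default 0.01).
#' @param allow_overlap Allow mates to overlap (fragment down to one read
#'   length); default `FALSE`.
#' @param seed RNG seed.
#' @param fastq_prefix If given, mates are also written via [write_fastq()].
#' @return Read-pair tibble: `fragment_id`, `read1`, `read2`, `origin`
#'   (`"circle"`/`"linear"`), `source_id` (junction or gene id).
#' @export
simulate_reads <- function(truth, entries, exons = NULL, genome = NULL,
                           read_len = 50L, frag_mean = 100L, frag_sd = 5L,
                           circle_depth = 20L, linear_depth = 10L,
                           error_rate = 0.01, allow_overlap = FALSE,
                           seed = 1L, fastq_prefix = NULL) {
  min_frag <- if (allow_overlap) read_len else 2L * read_len
  withr::with_seed(seed, {
    circ <- simulate_circle_fragments(truth, entries, read_len, frag_mean,
                                      frag_sd, min_frag, circle_depth)
    lin <- simulate_linear_fragments(exons, genome, read_len, frag_mean,
                                     frag_sd, min_frag, linear_depth)
    reads <- dplyr::bind_rows(circ, lin)
    if (nrow(reads) > 0 && error_rate > 0) {
      reads$read1 <- inject_errors(reads$read1, error_rate)
      reads$read2 <- inject_errors(reads$read2, error_rate)
    }
    if (!is.null(fastq_prefix) && nrow(reads) > 0) {
      write_fastq(reads, fastq_prefix)
    }
    reads
  })
}

simulate_circle_fragments <- function(truth, entries, read_len, frag_mean,
                                      frag_sd, min_frag, depth) {
  if (is.null(truth) || nrow(truth) == 0 || depth == 0) return(NULL)
  ent <- dplyr::inner_join(truth, entries, by = "junction_id")
  if (nrow(ent) < nrow(truth)) {
    rlang::abort("truth references junctions absent from the reference")
  }
  circ_seq <- circle_sequence(ent)
  rows <- vector("list", nrow(ent))
  for (i in seq_len(nrow(ent))) {
    L <- nchar(circ_seq[i])
    f <- pmax(min_frag, round(stats::rnorm(depth, frag_mean, frag_sd)))
    s <- sample.int(L, depth, replace = TRUE) - 1L
    # circular template: unroll enough copies, then take a linear substring
    tmpl <- strrep(circ_seq[i], ceiling((max(f) + L) / L))
    frag <- substring(tmpl, s + 1L, s + f)
    rows[[i]] <- tibble::tibble(
      fragment_id = sprintf("c:%s:%d", ent$junction_id[i], seq_len(depth)),
      read1 = substring(frag, 1L, read_len),
      read2 = revcomp(substring(frag, f - read_len + 1L, f)),
      origin = "circle", source_id = ent$junction_id[i])
  }
  purrr::list_rbind(rows)
}

simulate_linear_fragments <- function(exons, genome, read_len, frag_mean,
                                      frag_sd, min_frag, depth) {
  if (is.null(exons) || depth == 0) return(NULL)
  if (is.character(genome)) genome <- read_genome(genome)
  per_gene <- split(dplyr::arrange(exons, .data$rank), exons$gene_id)
  rows <- vector("list", length(per_gene))
  n_short <- 0L
  for (gi in seq_along(per_gene)) {
    g <- per_gene[[gi]]
    tx <- paste(purrr::pmap_chr(
      g[c("chrom", "start", "end", "strand")],
      function(chrom, start, end, strand) {
        exon_sequence(genome, chrom, start, end, strand)
      }), collapse = "")
    L <- nchar(tx)
    f <- pmax(min_frag, round(stats::rnorm(depth, frag_mean, frag_sd)))
    too_long <- f > L
    if (any(too_long)) {       # resample at the transcript length
      n_short <- n_short + sum(too_long)
      f[too_long] <- L
    }
    s <- vapply(L - f, function(m) sample.int(m + 1L, 1L) - 1L, 1L)
    frag <- substring(tx, s + 1L, s + f)
    rows[[gi]] <- tibble::tibble(
      fragment_id = sprintf("l:%s:%d", names(per_gene)[gi], seq_len(depth)),
      read1 = substring(frag, 1L, read_len),
      read2 = revcomp(substring(frag, f - read_len + 1L, f)),
      origin = "linear", source_id = names(per_gene)[gi])
  }
  if (n_short > 0) {
    message(sprintf("%d fragment(s) longer than their transcript; clamped",
                    n_short))
  }
  purrr::list_rbind(rows)
}

# i.i.d. substitution errors at the given per-base rate.
inject_errors <- function(reads, rate) {
  n_err <- stats::rbinom(length(reads), nchar(reads), rate)
  todo <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in todo) {
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(chars), n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Score called candidates against simulation truth
#'
#' Set algebra over junction ids: `TP = called ∩ truth`,
#' `FP = called \ truth`, `FN = truth \ called`;
#' `sensitivity = TP/(TP+FN)`, `precision = TP/(TP+FP)` (NA when the
#' denominator is zero).
#'
#' @param called A `circ_calls` object or character vector of called
#'   junction ids.
#' @param truth Truth tibble from [plant_circles()] or character vector.
#' @return Object of class `circ_eval` (a one-row tibble with `tp`, `fp`,
#'   `fn`, `sensitivity`, `precision`), with id sets as attributes.
#' @export
evaluate_calls <- function(called, truth) {
  called_ids <- unique(if (inherits(called, "circ_calls"))
    called_junctions(called) else as.character(called))
  truth_ids <- unique(if (is.data.frame(truth)) truth$junction_id
                      else as.character(truth))
  tp <- intersect(called_ids, truth_ids)
  fp <- setdiff(called_ids, truth_ids)
  fn <- setdiff(truth_ids, called_ids)
  n_tp <- length(tp); n_fp <- length(fp); n_fn <- length(fn)
  res <- tibble::tibble(
    tp = n_tp, fp = n_fp, fn = n_fn,
    sensitivity = if (n_tp + n_fn > 0) n_tp / (n_tp + n_fn) else NA_real_,
    precision = if (n_tp + n_fp > 0) n_tp / (n_tp + n_fp) else NA_real_)
  structure(res, class = c("circ_eval", class(res)),
            tp_ids = tp, fp_ids = fp, fn_ids = fn)
}

#' @export
tidy.circ_eval <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.circ_eval <- function(x, ...) tibble::as_tibble(x)

#' Sensitivity/precision across planted read depths
#'
#' Runs the full simulate → detect → evaluate loop at each depth, mirroring
#' a read-depth titration of detection performance.
#'
#' @param entries Junction reference.
#' @param exons,genome Linear-background inputs (see [simulate_reads()]).
#' @param depths Fragment depths per circle to titrate (default
#'   `c(2, 5, 10, 20)`).
#' @param n_circles Circles planted per run (default 200).
#' @param seed RNG seed (circle selection and reads).
#' @param ... Passed to [simulate_reads()].
#' @return Tibble with one row per depth: depth, tp, fp, fn, sensitivity,
#'   precision.
#' @export
depth_titration <- function(entries, exons = NULL, genome = NULL,
                            depths = c(2L, 5L, 10L, 20L), n_circles = 200L,
                            seed = 1L, ...) {
  truth <- plant_circles(entries, n_circles = n_circles, seed = seed)
  purrr::map(depths, function(d) {
    reads <- simulate_reads(truth, entries, exons = exons, genome = genome,
                            circle_depth = d, seed = seed + d, ...)
    det <- run_detection(reads, entries)
    ev <- evaluate_calls(det$calls, truth)
    dplyr::mutate(tibble::as_tibble(ev), depth = d, .before = 1)
  }) |>
    purrr::list_rbind()
}

#' Simulate an RNase-R enrichment experiment at the count level
#'
#' Models exoribonuclease digestion as a simple depletion factor: circular
#' features keep their expected abundance in the treated library while
#' linear (mRNA) features are depleted `depletion`-fold; observed counts
#' are Poisson around lognormal feature means. Returns treated/untreated
#' counts plus the feature lengths and classes needed for
#' [fpkm()] and [enrichment_fold_change()].
#'
#' @param n_circ,n_mrna Features per class (default 60 each).
#' @param depletion Fold depletion of linear features (default 10).
#' @param mean_log,sd_log Lognormal parameters of feature means (defaults
#'   `log(200)`, 0.6).
#' @param len_range Feature length range in bases (default `c(200, 2000)`).
#' @param seed RNG seed.
#' @return List with `treated`, `untreated` (feature_id + count tibbles),
#'   `lengths`, `classes`, and the per-feature `truth` means.
#' @export
simulate_rnase_r <- function(n_circ = 60L, n_mrna = 60L, depletion = 10,
                             mean_log = log(200), sd_log = 0.6,
                             len_range = c(200L, 2000L), seed = 1L) {
  withr::with_seed(seed, {
    n <- n_circ + n_mrna
    feature_id <- c(sprintf("circ%03d", seq_len(n_circ)),
                    sprintf("mrna%03d", seq_len(n_mrna)))
    class <- rep(c("circRNA", "mRNA"), c(n_circ, n_mrna))
    mu <- stats::rlnorm(n, mean_log, sd_log)
    mu_treated <- ifelse(class == "circRNA", mu, mu / depletion)
    untreated <- stats::rpois(n, mu)
    treated <- stats::rpois(n, mu_treated)
    list(
      treated = tibble::tibble(feature_id = feature_id, count = treated),
      untreated = tibble::tibble(feature_id = feature_id, count = untreated),
      lengths = tibble::tibble(feature_id = feature_id,
                               length = sample(len_range[1]:len_range[2], n,
                                               replace = TRUE)),
      classes = tibble::tibble(feature_id = feature_id, class = class),
      truth = tibble::tibble(feature_id = feature_id, mean = mu,
                             mean_treated = mu_treated))
  })
}
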