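#' Assemble a pipeline configuration
#'
#' Collects paths, thresholds, mapper settings and seeds into a validated
#' config list. Either real inputs (`genome`, `annotation`, plus `reads_*`
#' FASTQ or an `alignments` SAM/BAM) or a `simulate` scenario block must be
#' supplied.
#'
#' @param genome,annotation Input genome FASTA and GTF/GFF3 paths.
#' @param reads_1,reads_2 Paired FASTQ paths (mate 1 / mate 2).
#' @param alignments SAM/BAM of alignments against the junction reference
#'   (alternative to FASTQ input).
#' @param outdir Output directory.
#' @param sample_id Sample label.
#' @param min_overlap,min_junctional,min_supported,policy Calling
#'   thresholds (defaults 10, 3, 10, `"A"`).
#' @param k,max_mismatch,max_span Built-in mapper settings.
#' @param seed Master RNG seed.
#' @param simulate Optional scenario list for a self-contained simulated
#'   run: fields `n_genes`, `n_circles`, `circle_depth`, `linear_depth`,
#'   `error_rate` (all optional).
#' @param control Which negative controls to run: subset of
#'   `c("randomized", "flipped_exon2")`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(genome = NULL, annotation = NULL,
                            reads_1 = NULL, reads_2 = NULL,
                            alignments = NULL, outdir = tempfile("circrun"),
                            sample_id = "S1", min_overlap = 10L,
                            min_junctional = 3L, min_supported = 10L,
                            policy = "A", k = 15L, max_mismatch = 2L,
                            max_span = 1000L, seed = 1L, simulate = NULL,
                            control = "randomized") {
  cfg <- list(genome = genome, annotation = annotation, reads_1 = reads_1,
              reads_2 = reads_2, alignments = alignments, outdir = outdir,
              sample_id = sample_id, min_overlap = min_overlap,
              min_junctional = min_junctional, min_supported = min_supported,
              policy = policy, k = k, max_mismatch = max_mismatch,
              max_span = max_span, seed = seed, simulate = simulate,
              control = control)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

validate_config <- function(cfg) {
  for (key in c("min_overlap", "min_junctional", "min_supported", "k",
                "max_mismatch", "max_span")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || (key != "max_mismatch" && v <= 0)) {
      rlang::abort(sprintf("config key '%s' must be a positive scalar", key))
    }
  }
  if (!cfg$policy %in% c("A", "B")) {
    rlang::abort("config key 'policy' must be \"A\" or \"B\"")
  }
  if (is.null(cfg$simulate)) {
    for (key in c("genome", "annotation")) {
      if (is.null(cfg[[key]])) {
        rlang::abort(sprintf("config key '%s' is required (no simulate scenario given)", key))
      }
      if (!file.exists(cfg[[key]])) {
        rlang::abort(sprintf("config key '%s': file not found: %s", key, cfg[[key]]))
      }
    }
    if (is.null(cfg$alignments) && (is.null(cfg$reads_1) || is.null(cfg$reads_2))) {
      rlang::abort("config needs either 'alignments' or 'reads_1'+'reads_2'")
    }
  }
  invisible(cfg)
}

#' Run the full circRNA detection pipeline
#'
#' Stages: build reference → map or import alignments → remove duplicates →
#' classify evidence → call candidates → quantify, plus the configured
#' negative controls (and, for simulated scenarios, truth-based
#' evaluation). Every TSV written carries a provenance header (config
#' hash, seed, package version). The run is deterministic for a fixed
#' config.
#'
#' @param config A `pipeline_config` (or YAML path).
#' @return List of class `circ_pipeline`: `entries`, `alignments`,
#'   `evidence`, `calls`, `counts`, `controls`, and for simulated runs
#'   `truth` + `eval`; `outdir` holds the written artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  sim <- !is.null(config$simulate)
  if (sim) {
    sc <- config$simulate
    fix <- make_fixture_genome(n_genes = sc$n_genes %||% 50L,
                               seed = config$seed)
    genome <- fix$genome
    exons <- fix$exons
  } else {
    genome <- read_genome(config$genome)
    exons <- load_annotation(config$annotation, genome)
  }

  pairs <- enumerate_backsplices(exons)
  entries <- build_junction_reference(pairs, genome)

  truth <- NULL
  if (sim) {
    sc <- config$simulate
    truth <- plant_circles(entries, n_circles = sc$n_circles %||% 200L,
                           seed = config$seed)
    reads <- simulate_reads(truth, entries, exons = exons, genome = genome,
                            circle_depth = sc$circle_depth %||% 20L,
                            linear_depth = sc$linear_depth %||% 10L,
                            error_rate = sc$error_rate %||% 0.01,
                            seed = config$seed)
  } else if (!is.null(config$reads_1)) {
    reads <- read_fastq_pairs(config$reads_1, config$reads_2)
  } else {
    reads <- NULL
  }

  if (is.null(reads)) {
    aln <- import_alignments(config$alignments, manifest = entries,
                             sample_id = config$sample_id)
  } else {
    index <- index_reference(entries, k = config$k)
    aln <- map_reads(reads, index, sample_id = config$sample_id,
                     max_mismatch = config$max_mismatch,
                     max_span = config$max_span)
  }
  aln <- suppressMessages(remove_duplicates(aln))
  evidence <- classify_pairs(aln, entries, min_overlap = config$min_overlap)
  calls <- call_candidates(evidence, entries,
                           min_junctional = config$min_junctional,
                           min_supported = config$min_supported,
                           policy = config$policy)
  counts <- circ_counts(evidence)

  controls <- list()
  if (!is.null(reads)) {
    for (mode in intersect(unlist(config$control),
                           c("randomized", "flipped_exon2"))) {
      ctrl_entries <- build_control_reference(
        pairs, genome, mode = mode,
        seed = if (mode == "randomized") config$seed else NULL)
      controls[[mode]] <- run_control(
        reads, ctrl_entries, real_calls = calls,
        sample_id = config$sample_id, min_overlap = config$min_overlap,
        min_junctional = config$min_junctional,
        min_supported = config$min_supported, policy = config$policy,
        k = config$k, max_mismatch = config$max_mismatch)
    }
  }

  result <- list(entries = entries, alignments = aln, evidence = evidence,
                 calls = calls, counts = counts, controls = controls,
                 outdir = config$outdir, config = config)
  if (sim) {
    result$truth <- truth
    result$eval <- evaluate_calls(calls, truth)
  }
  write_pipeline_outputs(result, config)
  structure(result, class = "circ_pipeline")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

provenance_header <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL  # identical analyses hash equal wherever they are written
  c(sprintf("# scramblex %s", as.character(utils::packageVersion("scramblex"))),
    sprintf("# config_hash: %s", rlang::hash(cfg)),
    sprintf("# seed: %d", config$seed))
}

write_tsv_provenance <- function(x, path, config) {
  writeLines(provenance_header(config), path)
  suppressWarnings(utils::write.table(
    x, path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}

write_pipeline_outputs <- function(result, config) {
  out <- config$outdir
  write_junction_fasta(result$entries, file.path(out, "junctions.fa"))
  write_junction_manifest(result$entries, file.path(out, "junctions.tsv"))
  candidates <- result$calls |>
    dplyr::transmute(.data$chrom, .data$e1_start, .data$e2_end,
                     .data$junction_id, .data$junctional_count,
                     .data$strand, .data$supported_count, .data$gene_id,
                     .data$sample_id, .data$passed, .data$passed_any)
  write_tsv_provenance(candidates, file.path(out, "candidates.tsv"), config)
  write_tsv_provenance(result$counts, file.path(out, "circ_counts.tsv"),
                       config)
  if (!is.null(result$eval)) {
    write_tsv_provenance(tibble::as_tibble(result$eval),
                         file.path(out, "evaluation.tsv"), config)
  }
  for (mode in names(result$controls)) {
    rep <- result$controls[[mode]]
    write_tsv_provenance(
      tibble::tibble(mode = mode, n_control = rep$n_control,
                     n_overlap = length(rep$overlap)),
      file.path(out, sprintf("control_%s.tsv", mode)), config)
  }
  invisible(out)
}

#' @export
print.circ_pipeline <- function(x, ...) {
  cat("<circ_pipeline>\n")
  cat(sprintf("  junction entries: %d\n", nrow(x$entries)))
  cat(sprintf("  mapped fragments: %d\n", nrow(x$alignments)))
  cat(sprintf("  candidates called (union): %d\n",
              length(called_junctions(x$calls))))
  for (mode in names(x$controls)) {
    cat(sprintf("  control %s: %d candidate(s), %d overlap\n", mode,
                x$controls[[mode]]$n_control,
                length(x$controls[[mode]]$overlap)))
  }
  if (!is.null(x$eval)) {
    cat(sprintf("  sensitivity %.3f, precision %.3f\n",
                x$eval$sensitivity, x$eval$precision))
  }
  invisible(x)
}
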