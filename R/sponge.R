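#' Scan target sequences for miRNA seed matches
#'
#' Canonical seed-site classes on the target (read 5'→3'):
#' * **8mer** — reverse complement of miRNA bases 2–8 followed by an A;
#' * **7mer-m8** — reverse complement of bases 2–8;
#' * **7mer-A1** — reverse complement of bases 2–7 followed by an A.
#'
#' All (possibly overlapping) sites are reported; each target position is
#' reported once with its strongest type (8mer > 7mer-m8 > 7mer-A1).
#' Windows containing ambiguous bases are skipped. RNA input (U) is
#' normalised to DNA (T). With `circular = TRUE` the scan wraps across the
#' end of the sequence, so sites straddling a backsplice junction on a
#' covalently closed circle are found.
#'
#' @param targets Named character vector of target sequences, or a tibble
#'   with id and sequence columns.
#' @param mirnas Named character vector of mature miRNA sequences (RNA or
#'   DNA alphabet), or a tibble with id and sequence columns.
#' @param circular Treat targets as circular (default `FALSE`).
#' @return Tibble: `mirna_id`, `target_id`, `site_type`, `position`
#'   (0-based start on the target), `site_seq`.
#' @export
find_seed_matches <- function(targets, mirnas, circular = FALSE) {
  targets <- as_named_seqs(targets)
  mirnas <- as_named_seqs(mirnas)
  targets[] <- normalize_dna(targets)
  mirnas[] <- normalize_dna(mirnas)
  short <- nchar(mirnas) < 8L
  if (any(short)) {
    rlang::abort(sprintf("miRNA(s) shorter than 8 nt: %s",
                         paste(names(mirnas)[short], collapse = ", ")))
  }
  sites <- tibble::tibble(
    mirna_id = names(mirnas),
    site_8mer = paste0(revcomp(substr(mirnas, 2L, 8L)), "A"),
    site_7m8 = revcomp(substr(mirnas, 2L, 8L)),
    site_7a1 = paste0(revcomp(substr(mirnas, 2L, 7L)), "A"))
  out <- vector("list", length(targets))
  for (t in seq_along(targets)) {
    seq <- targets[[t]]
    L <- nchar(seq)
    if (L == 0L) next
    scan_seq <- if (circular) paste0(seq, substr(seq, 1L, 7L)) else seq
    n8 <- nchar(scan_seq) - 7L
    if (n8 < 1L) next
    w8 <- substring(scan_seq, 1:n8, 8:(n8 + 7L))
    w7 <- substr(w8, 1L, 7L)
    clean <- !grepl("[^ACGT]", w8)
    hits <- vector("list", nrow(sites))
    for (m in seq_len(nrow(sites))) {
      is8 <- w8 == sites$site_8mer[m]
      is7m8 <- !is8 & w7 == sites$site_7m8[m]
      is7a1 <- !is8 & !is7m8 & w7 == sites$site_7a1[m]
      any_hit <- (is8 | is7m8 | is7a1) & clean
      if (!any(any_hit)) next
      pos <- which(any_hit)
      hits[[m]] <- tibble::tibble(
        mirna_id = sites$mirna_id[m],
        target_id = names(targets)[t],
        site_type = dplyr::case_when(is8[pos] ~ "8mer",
                                     is7m8[pos] ~ "7mer-m8",
                                     TRUE ~ "7mer-A1"),
        position = pos - 1L,
        site_seq = ifelse(is7a1[pos] | is7m8[pos], w7[pos], w8[pos]))
    }
    out[[t]] <- purrr::list_rbind(hits)
  }
  res <- purrr::list_rbind(out)
  if (nrow(res) == 0) return(res)
  if (circular) res <- dplyr::filter(res, TRUE)  # positions already < L
  dplyr::arrange(res, .data$target_id, .data$mirna_id, .data$position)
}

as_named_seqs <- function(x) {
  if (is.data.frame(x)) {
    stats::setNames(as.character(x[[2]]), as.character(x[[1]]))
  } else {
    stopifnot(!is.null(names(x)))
    x
  }
}

normalize_dna <- function(x) chartr("uU", "tT", toupper(x))

#' Seed-match density per target
#'
#' Total seed matches per kilobase of target sequence, the statistic used
#' to compare circRNA sequences against 3'UTR / 5'UTR / CDS backgrounds.
#'
#' @param targets Named character vector or tibble (id, sequence).
#' @param mirnas Named character vector or tibble of mature miRNAs.
#' @param classes Optional tibble mapping target id to a sequence class
#'   (e.g. `circRNA`, `3UTR`, `5UTR`, `CDS`).
#' @param circular Passed to [find_seed_matches()].
#' @return Tibble: `target_id`, `length`, `n_matches`, `density`
#'   (matches/kb) and `class` when supplied.
#' @export
seed_density <- function(targets, mirnas, classes = NULL, circular = FALSE) {
  targets <- as_named_seqs(targets)
  stopifnot(all(nchar(targets) > 0))
  matches <- find_seed_matches(targets, mirnas, circular = circular)
  counts <- if (nrow(matches) > 0) {
    dplyr::count(matches, .data$target_id, name = "n_matches")
  } else {
    tibble::tibble(target_id = character(), n_matches = integer())
  }
  out <- tibble::tibble(target_id = names(targets),
                        length = unname(nchar(targets))) |>
    dplyr::left_join(counts, by = "target_id") |>
    dplyr::mutate(n_matches = tidyr::replace_na(.data$n_matches, 0L),
                  density = .data$n_matches * 1000 / .data$length)
  if (!is.null(classes)) {
    out <- dplyr::left_join(
      out, stats::setNames(classes[, 1:2], c("target_id", "class")),
      by = "target_id")
  }
  out
}

#' Weighted expression of circRNAs targeting one miRNA (E_circ)
#'
#' `E_circ = (sum_i n_i * x_i) / N` over the `N` circRNAs targeting the
#' miRNA, where `n_i` is the seed-match count of circRNA `i` for this miRNA
#' and `x_i` its fold-change expression (log2 fold change from an upstream
#' differential-expression table).
#'
#' @param n_sites Integer vector of per-circRNA seed-match counts.
#' @param fold_change Numeric vector of per-circRNA fold changes.
#' @return The E_circ scalar; `NA` with a warning for empty input.
#' @export
e_circ <- function(n_sites, fold_change) {
  stopifnot(length(n_sites) == length(fold_change))
  if (length(n_sites) == 0L) {
    rlang::warn("E_circ undefined for zero targeting circRNAs")
    return(NA_real_)
  }
  sum(n_sites * fold_change) / length(n_sites)
}

#' E_circ for every miRNA of a circRNA–miRNA network
#'
#' @param network Tibble with `mirna_id`, `circ_id`, `n_sites`,
#'   `fold_change` (one row per circRNA–miRNA edge).
#' @return Tibble: `mirna_id`, `n_circ` (N) and `e_circ`.
#' @export
e_circ_scores <- function(network) {
  network |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(n_circ = dplyr::n(),
                     e_circ = e_circ(.data$n_sites, .data$fold_change),
                     .groups = "drop")
}

#' Average E_circ per downstream target gene
#'
#' The arithmetic mean of E_circ over the miRNAs targeting each gene.
#' miRNA→gene edges are supplied as an input table (external target
#' predictions are consumed, not computed). Genes whose targeting miRNAs
#' all lack a defined E_circ are dropped with a message.
#'
#' @param scores E_circ table from [e_circ_scores()].
#' @param gene_edges Tibble with `mirna_id`, `gene_id`.
#' @return Tibble: `gene_id`, `n_mirnas`, `average_e_circ`.
#' @export
average_e_circ <- function(scores, gene_edges) {
  joined <- gene_edges |>
    dplyr::inner_join(scores, by = "mirna_id") |>
    dplyr::filter(!is.na(.data$e_circ))
  dropped <- setdiff(unique(gene_edges$gene_id), unique(joined$gene_id))
  if (length(dropped) > 0) {
    message(sprintf("dropping %d gene(s) with no defined E_circ",
                    length(dropped)))
  }
  joined |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_mirnas = dplyr::n(),
                     average_e_circ = mean(.data$e_circ), .groups = "drop")
}
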