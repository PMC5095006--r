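mk_evidence <- function(junction, sample, n_junc, n_supp, prefix = "f") {
  tibble::tibble(
    fragment_id = sprintf("%s_%s_%s_%03d", prefix, junction, sample,
                          seq_len(n_junc + n_supp)),
    sample_id = sample, junction_id = junction,
    class = rep(c("junctional", "supportive"), c(n_junc, n_supp)),
    overlap_left = NA_integer_, overlap_right = NA_integer_)
}

test_that("circ counts sum junctional and supportive fragments and conserve totals", {
  ev <- dplyr::bind_rows(
    mk_evidence("jA", "S1", 3L, 2L),
    mk_evidence("jA", "S2", 1L, 0L),
    mk_evidence("jB", "S1", 0L, 4L),
    # 'none' class fragments never count
    dplyr::mutate(mk_evidence("jB", "S2", 2L, 0L, prefix = "n"),
                  class = "none"))
  cm <- circ_counts(ev)
  expect_equal(cm$S1[cm$junction_id == "jA"], 5L)
  expect_equal(cm$S2[cm$junction_id == "jB"], 0L)
  expect_equal(cm$S1[cm$junction_id == "jB"], 4L)
  # conservation: column sums equal classified (non-none) fragments per sample
  classified <- dplyr::count(dplyr::filter(ev, class != "none"), sample_id)
  expect_equal(colSums(cm[, c("S1", "S2")]),
               stats::setNames(as.double(classified$n), classified$sample_id))
})

test_that("linear counts follow the one-base-overlap rule and exclude divergent pairs", {
  pairs <- tibble::tibble(
    junction_id = "g|1|2", gene_id = "g", chrom = "chr1", strand = "+",
    e1_start = 100L, e1_end = 200L, e1_rank = 1L,
    e2_start = 300L, e2_end = 400L, e2_rank = 2L)
  frag <- function(id, m1, m2, divergent = FALSE) {
    tibble::tibble(fragment_id = id, sample_id = "S1", chrom = "chr1",
                   m1_start = m1[1], m1_end = m1[2],
                   m2_start = m2[1], m2_end = m2[2], divergent = divergent)
  }
  fragments <- dplyr::bind_rows(
    frag("in_exon1", c(120L, 170L), c(130L, 180L)),
    frag("one_base", c(40L, 101L), c(40L, 101L)),       # 1 base into exon1
    frag("in_exon2", c(310L, 360L), c(320L, 370L)),
    frag("spans_intron", c(150L, 200L), c(300L, 350L)),
    frag("between", c(210L, 260L), c(220L, 270L)),      # intronic: no overlap
    frag("outside", c(500L, 550L), c(560L, 610L)),
    frag("divergent", c(120L, 170L), c(310L, 360L), divergent = TRUE),
    frag("in_exon1_b", c(125L, 175L), c(125L, 175L)))
  lc <- linear_counts(fragments, pairs)
  expect_equal(lc$S1, 5L)   # 7 overlapping candidates minus 1 divergent, minus dup ids counted once

  # brute-force interval oracle on random fragments
  set.seed(17)
  rnd <- purrr::map(1:200, function(i) {
    s1 <- sample(0:600, 1); s2 <- sample(0:600, 1)
    frag(sprintf("r%03d", i), c(s1, s1 + 50L), c(s2, s2 + 50L),
         divergent = stats::runif(1) < 0.2)
  }) |> purrr::list_rbind()
  got <- linear_counts(rnd, pairs)
  overlaps <- function(s, e, a, b) s < b && e > a
  brute <- sum(vapply(seq_len(nrow(rnd)), function(i) {
    f <- rnd[i, ]
    !f$divergent && (overlaps(f$m1_start, f$m1_end, 100L, 200L) ||
                       overlaps(f$m2_start, f$m2_end, 100L, 200L) ||
                       overlaps(f$m1_start, f$m1_end, 300L, 400L) ||
                       overlaps(f$m2_start, f$m2_end, 300L, 400L))
  }, logical(1)))
  expect_equal(got$S1, brute)
})

test_that("circular-to-linear ratios handle zeros by sentinel and row dropping", {
  circ <- tibble::tibble(junction_id = c("a", "b", "c"), S1 = c(5L, 10L, 0L))
  linear <- tibble::tibble(junction_id = c("a", "b", "c"), S1 = c(50L, 0L, 0L))
  r <- circ_linear_ratio(circ, linear)
  expect_equal(r$ratio[r$junction_id == "a"], 0.1)
  expect_true(is.infinite(r$ratio[r$junction_id == "b"]))
  expect_true(r$circ_only[r$junction_id == "b"])
  expect_false("c" %in% r$junction_id)          # both zero: dropped
})

test_that("FPKM matches its definition, is linear, and matches a step-by-step recomputation", {
  counts <- tibble::tibble(feature_id = "f1", S1 = 10L)
  lengths <- tibble::tibble(feature_id = "f1", length = 1000L)
  expect_equal(fpkm(counts, lengths, totals = c(S1 = 1e6))$S1, 10)
  expect_equal(fpkm(dplyr::mutate(counts, S1 = S1 * 2L), lengths,
                    totals = c(S1 = 1e6))$S1, 20)

  set.seed(5)
  cm <- tibble::tibble(feature_id = sprintf("f%02d", 1:20),
                       A = rpois(20, 40), B = rpois(20, 60))
  lens <- tibble::tibble(feature_id = cm$feature_id,
                         length = sample(200:2000, 20))
  totals <- c(A = 2.5e5, B = 4e5)
  got <- fpkm(cm, lens, totals)
  # independent spreadsheet-style evaluation, cell by cell
  for (i in 1:20) {
    for (s in c("A", "B")) {
      expect_equal(got[[s]][i],
                   cm[[s]][i] / (lens$length[i] / 1000) / (totals[[s]] / 1e6),
                   tolerance = 1e-9)
    }
  }
  # scaling counts and totals together leaves FPKM unchanged
  scaled <- fpkm(dplyr::mutate(cm, A = A * 3, B = B * 3), lens, totals * 3)
  expect_equal(scaled$A, got$A, tolerance = 1e-12)
  expect_error(fpkm(cm, lens, totals = c(A = 0, B = 1)), "positive")
})

test_that("fold-change enrichment recovers planted RNase-R depletion", {
  ids <- sprintf("f%02d", 1:10)
  same <- tibble::tibble(feature_id = ids, fpkm = runif(10, 1, 100))
  classes <- tibble::tibble(feature_id = ids,
                            class = rep(c("circRNA", "mRNA"), 5))
  enr <- enrichment_fold_change(same, same, classes)
  expect_true(all(enr$fold_changes$fold_change == 1))

  one <- enrichment_fold_change(
    tibble::tibble(feature_id = "x", fpkm = 400),
    tibble::tibble(feature_id = "x", fpkm = 200),
    tibble::tibble(feature_id = "x", class = "circRNA"))
  expect_equal(one$fold_changes$fold_change, 2, tolerance = 0.05)

  sim <- simulate_rnase_r(n_circ = 60L, n_mrna = 60L, depletion = 10,
                          seed = 33L)
  fp <- function(counts) {
    f <- fpkm(counts, sim$lengths)
    stats::setNames(f, c("feature_id", "fpkm"))
  }
  enr <- enrichment_fold_change(fp(sim$treated), fp(sim$untreated),
                                sim$classes)
  med <- stats::setNames(enr$medians$median_fold_change, enr$medians$class)
  expect_gt(med[["circRNA"]], med[["mRNA"]])
  expect_lt(enr$test$p.value, 0.01)
  expect_error(enrichment_fold_change(
    tibble::tibble(feature_id = "a", fpkm = 1),
    tibble::tibble(feature_id = "b", fpkm = 1),
    tibble::tibble(feature_id = "a", class = "circRNA")), "overlap")
})

test_that("the count prefilter is exact at its boundary and idempotent", {
  cm <- tibble::tibble(feature_id = c("keep", "drop"),
                       S1 = c(3L, 3L), S2 = c(3L, 3L),
                       S3 = c(3L, 2L), S4 = c(0L, 2L))
  kept <- prefilter_counts(cm)
  expect_equal(kept$feature_id, "keep")

  set.seed(8)
  rnd <- tibble::tibble(feature_id = sprintf("f%03d", 1:100))
  for (s in sprintf("S%d", 1:6)) rnd[[s]] <- rpois(100, 2)
  got <- prefilter_counts(rnd, min_count = 3L, min_samples = 3L)
  brute <- rnd$feature_id[vapply(seq_len(100), function(i) {
    sum(unlist(rnd[i, -1]) >= 3) >= 3
  }, logical(1))]
  expect_equal(got$feature_id, brute)
  expect_equal(prefilter_counts(got), got)        # idempotent
  expect_error(prefilter_counts(rnd[, 1:3], min_samples = 3L), "sample")
})

test_that("z-scored log2-cpm rows are standardised and match manual recomputation", {
  # equal column totals so the constant row is constant after CPM too
  cm <- tibble::tibble(feature_id = c("const", "var1", "var2"),
                       A = c(5L, 10L, 100L), B = c(5L, 40L, 70L),
                       C = c(5L, 90L, 20L))
  z <- zscore_log2cpm(cm)
  expect_equal(unlist(z[z$feature_id == "const", -1]),
               c(A = 0, B = 0, C = 0))
  m <- as.matrix(z[, -1])
  expect_equal(unname(rowMeans(m)), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(m[-1, ], 1, sd)), c(1, 1), tolerance = 1e-9)

  # manual step-by-step recomputation for one cell
  totals <- colSums(as.matrix(cm[, -1]))
  lg <- log2(10L / totals[["A"]] * 1e6 + 0.5)
  row_lg <- log2(c(10L, 40L, 90L) / totals * 1e6 + 0.5)
  manual <- (lg - mean(row_lg)) / sd(row_lg)
  expect_equal(z$A[z$feature_id == "var1"], unname(manual), tolerance = 1e-9)
})
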