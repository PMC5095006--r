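test_that("the fixture generator is seed-deterministic and honours n_genes", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_fixture_genome(n_genes = 50L, seed = 12L, dir = d1)
  make_fixture_genome(n_genes = 50L, seed = 12L, dir = d2)
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
  expect_identical(readLines(file.path(d1, "annotation.gtf")),
                   readLines(file.path(d2, "annotation.gtf")))
  gtf <- readLines(file.path(d1, "annotation.gtf"))
  genes <- unique(sub('.*gene_id "([^"]+)".*', "\\1", gtf))
  expect_length(genes, 50L)

  diff <- make_fixture_genome(n_genes = 50L, seed = 13L)
  expect_false(identical(as.character(diff$genome),
                         as.character(make_fixture_genome(seed = 12L)$genome)))
})

test_that("circle planting is uniform, exact and bounded", {
  fix <- std_fixture()
  truth <- plant_circles(fix$entries, 200L, seed = 4L)
  expect_equal(nrow(truth), 200L)
  expect_true(all(truth$junction_id %in% fix$entries$junction_id))
  all_of_them <- plant_circles(fix$entries, nrow(fix$entries), seed = 4L)
  expect_setequal(all_of_them$junction_id, fix$entries$junction_id)
  expect_error(plant_circles(fix$entries, nrow(fix$entries) + 1L, seed = 1L),
               "exceeds")

  # overlap of two independent draws matches the hypergeometric expectation
  N <- nrow(fix$entries)
  t1 <- plant_circles(fix$entries, 100L, seed = 21L)
  t2 <- plant_circles(fix$entries, 100L, seed = 22L)
  ov <- length(intersect(t1$junction_id, t2$junction_id))
  mu <- 100 * 100 / N
  sigma <- sqrt(100 * (100 / N) * (1 - 100 / N) * (N - 100) / (N - 1))
  expect_lt(abs(ov - mu), 4 * sigma)
})

test_that("error-free circle fragments are exact substrings at the planted depth", {
  fix <- std_fixture()
  truth <- plant_circles(fix$entries, 25L, seed = 6L)
  reads <- simulate_reads(truth, fix$entries, circle_depth = 7L,
                          linear_depth = 0L, error_rate = 0, seed = 7L)
  expect_equal(nrow(reads), 25L * 7L)            # depth is a fragment count
  per_circle <- table(reads$source_id)
  expect_true(all(per_circle == 7L))

  ent <- fix$entries[match(reads$source_id, fix$entries$junction_id), ]
  circ <- ifelse(ent$e1_rank == ent$e2_rank,
                 substr(ent$sequence, 1L, ent$exon2_len), ent$sequence)
  tmpl <- strrep(circ, 3L)                       # unrolled circular template
  expect_true(all(mapply(grepl, reads$read1, tmpl, fixed = TRUE)))
  expect_true(all(mapply(grepl, revcomp(reads$read2), tmpl, fixed = TRUE)))

  # determinism under the seed
  again <- simulate_reads(truth, fix$entries, circle_depth = 7L,
                          linear_depth = 0L, error_rate = 0, seed = 7L)
  expect_identical(reads, again)
})

test_that("junction-spanning fraction matches the closed-form position count", {
  fix <- std_fixture()
  # one two-exon junction, fixed fragment length for a clean closed form
  two_exon <- fix$entries[fix$entries$e1_rank != fix$entries$e2_rank, ][3, ]
  truth <- tibble::tibble(junction_id = two_exon$junction_id)
  depth <- 3000L
  f <- 100L
  reads <- simulate_reads(truth, fix$entries, circle_depth = depth,
                          linear_depth = 0L, error_rate = 0,
                          frag_mean = f, frag_sd = 0L, seed = 13L)
  L <- nchar(two_exon$sequence)
  off <- two_exon$junction_offset
  # recover each fragment's start from its error-free mate sequence
  tmpl <- strrep(two_exon$sequence, 3L)
  s <- (vapply(reads$read1, function(r) regexpr(r, tmpl, fixed = TRUE)[[1]],
               1L) - 1L) %% L
  crosses <- function(a, b) (a < off & b > off) |
    (a < off + L & b > off + L)                  # junction recurs every turn
  spanning <- crosses(s, s + 50L) | crosses(s + f - 50L, s + f)
  # exact position enumeration of the same event
  s_all <- 0:(L - 1L)
  p <- mean(crosses(s_all, s_all + 50L) |
              crosses(s_all + f - 50L, s_all + f))
  expect_lt(abs(sum(spanning) - depth * p), 3 * sqrt(depth * p * (1 - p)))
})

test_that("evaluation implements the TP/FP/FN formulas and set identities", {
  ev <- evaluate_calls(called = sprintf("j%02d", 1:90),
                       truth = sprintf("j%02d", 1:100))
  expect_equal(ev$tp, 90L)
  expect_equal(ev$fn, 10L)
  expect_equal(ev$sensitivity, 0.9)
  expect_equal(ev$precision, 1.0)

  ident <- evaluate_calls(letters, letters)
  expect_equal(c(ident$sensitivity, ident$precision), c(1, 1))

  # random call sets against an independent set-algebra recomputation
  set.seed(23)
  universe <- sprintf("u%03d", 1:300)
  for (rep in 1:20) {
    called <- sample(universe, sample(0:150, 1))
    truth <- sample(universe, sample(1:150, 1))
    ev <- evaluate_calls(called, truth)
    expect_equal(ev$tp, sum(called %in% truth))
    expect_equal(ev$fp, sum(!called %in% truth))
    expect_equal(ev$fn, sum(!truth %in% called))
    expect_equal(ev$tp + ev$fn, length(truth))         # TP + FN = |truth|
    expect_equal(ev$tp + ev$fp, length(unique(called)))# TP + FP = |called|
  }
  none <- evaluate_calls(character(0), character(0))
  expect_true(is.na(none$sensitivity) && is.na(none$precision))
})

test_that("RNase-R count simulation depletes only the linear class", {
  sim <- simulate_rnase_r(n_circ = 50L, n_mrna = 50L, depletion = 10,
                          seed = 2L)
  joined <- dplyr::inner_join(
    dplyr::inner_join(sim$treated, sim$untreated, by = "feature_id",
                      suffix = c("_t", "_u")),
    sim$classes, by = "feature_id")
  ratio <- joined |>
    dplyr::group_by(class) |>
    dplyr::summarise(r = sum(count_t) / sum(count_u), .groups = "drop")
  expect_gt(ratio$r[ratio$class == "circRNA"], 0.8)
  expect_lt(ratio$r[ratio$class == "mRNA"], 0.2)
})
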