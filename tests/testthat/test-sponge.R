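test_that("seed sites of each class are found at constructed positions", {
  expect_equal(nrow(find_seed_matches(c(t = ""), LET7)), 0L)

  t8 <- c(t = paste0("GGG", SITE_8MER, "GGG"))
  m <- find_seed_matches(t8, LET7)
  # the constructed 8mer, plus the 7mer-A1 its suffix necessarily contains
  expect_equal(m$site_type, c("8mer", "7mer-A1"))
  expect_equal(m$position, c(3L, 4L))
  # at the 8mer position itself only the strongest type is reported
  expect_equal(m$site_type[m$position == 3L], "8mer")
  t7m8 <- c(t = paste0("GG", SITE_7M8, "GG"))   # followed by G: not an 8mer
  expect_equal(find_seed_matches(t7m8, LET7)$site_type, "7mer-m8")
  t7a1 <- c(t = paste0("GG", SITE_7A1, "GG"))
  expect_equal(find_seed_matches(t7a1, LET7)$site_type, "7mer-A1")

  # RNA and DNA alphabets are equivalent
  rna_target <- chartr("T", "U", t8)
  expect_equal(find_seed_matches(rna_target, LET7)$position,
               find_seed_matches(t8, LET7)$position)

  # ambiguous bases void the window
  tn <- c(t = paste0("GGG", sub("A$", "N", SITE_8MER), "GGG"))
  expect_equal(nrow(find_seed_matches(tn, LET7)), 0L)

  expect_error(find_seed_matches(c(t = "ACGT"), c(m = "ACGUA")), "shorter")
})

test_that("a circular scan finds sites straddling the backsplice seam", {
  # split the 7mer-m8 site across the end/start of a circular target
  seam <- c(t = paste0("TC", strrep("G", 30), "CTACC"))
  expect_equal(nrow(find_seed_matches(seam, LET7, circular = FALSE)), 0L)
  m <- find_seed_matches(seam, LET7, circular = TRUE)
  expect_equal(nrow(m), 1L)
  expect_equal(m$position, 32L)        # 0-based start within the circle
  expect_equal(m$site_type, "7mer-m8")
})

test_that("vectorised scanning equals the naive oracle on random sequences", {
  set.seed(101)
  mirnas <- stats::setNames(
    vapply(1:12, function(i) paste(sample(c("A", "C", "G", "U"), 22,
                                          replace = TRUE), collapse = ""), ""),
    sprintf("mir%02d", 1:12))
  target <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                  collapse = "")
  got <- find_seed_matches(c(tgt = target), mirnas)
  for (mid in names(mirnas)) {
    oracle <- oracle_scan(target, mirnas[[mid]])
    sub <- got[got$mirna_id == mid, ]
    expect_equal(sub$position,
                 as.integer(vapply(oracle, `[[`, "", "pos")))
    expect_equal(sub$site_type, vapply(oracle, `[[`, "", "type"))
  }
})

test_that("seed density is per-kilobase, recovers planted sites, and is scale invariant", {
  # 7mer-m8 plants followed by G create exactly one site each
  one_kb <- paste0(SITE_7M8, strrep("G", 493), SITE_7M8, strrep("G", 493))
  expect_equal(nchar(one_kb), 1000L)
  d <- seed_density(c(t = one_kb), LET7)
  expect_equal(d$n_matches, 2L)
  expect_equal(d$density, 2.0)

  # planted-site recovery across several targets
  set.seed(3)
  k <- c(1L, 3L, 5L)
  targets <- stats::setNames(vapply(k, function(n) {
    paste0(paste(rep(c(SITE_7M8, strrep("G", 40)), n), collapse = ""),
           strrep("G", 50))
  }, ""), sprintf("t%d", k))
  d <- seed_density(targets, LET7)
  expect_equal(d$n_matches, k)

  # doubling a (seam-free) target leaves density unchanged
  dd <- seed_density(c(t = paste0(one_kb, one_kb)), LET7)
  expect_equal(dd$density, 2.0)
})

test_that("density contrast between planted classes yields the circ > UTR ordering", {
  set.seed(9)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  plant <- function(base, n_sites) {
    chunks <- c(rep(c(SITE_8MER, rand_seq(60)), n_sites), rand_seq(100))
    paste(chunks, collapse = "")
  }
  circ <- stats::setNames(vapply(1:15, function(i) plant(NULL, 4L), ""),
                          sprintf("circ%02d", 1:15))
  utr <- stats::setNames(vapply(1:15, function(i) plant(NULL, 1L), ""),
                         sprintf("utr%02d", 1:15))
  classes <- tibble::tibble(
    target_id = c(names(circ), names(utr)),
    class = rep(c("circRNA", "3UTR"), each = 15L))
  d <- seed_density(c(circ, utr), LET7, classes = classes)
  test <- stats::wilcox.test(d$density[d$class == "circRNA"],
                             d$density[d$class == "3UTR"],
                             alternative = "greater", exact = FALSE)
  expect_lt(test$p.value, 0.01)
})

test_that("E_circ is the exact mean of site-weighted fold changes", {
  expect_equal(e_circ(3L, 2.0), 6.0)
  expect_equal(e_circ(c(2L, 1L), c(1.0, -2.0)), 0.0)   # exact cancellation
  expect_warning(res <- e_circ(integer(0), numeric(0)), "undefined")
  expect_true(is.na(res))

  set.seed(44)
  for (rep in 1:10) {
    n <- sample(1:30, 1)
    ns <- sample(0:8, n, replace = TRUE)
    x <- rnorm(n)
    acc <- 0
    for (i in seq_len(n)) acc <- acc + ns[i] * x[i]   # brute-force loop
    expect_equal(e_circ(ns, x), acc / n, tolerance = 1e-12)
    # linearity in the fold changes
    expect_equal(e_circ(ns, 3.5 * x), 3.5 * e_circ(ns, x), tolerance = 1e-12)
  }
})

test_that("Average E_circ averages per-miRNA scores over each gene's miRNAs", {
  scores <- tibble::tibble(mirna_id = c("m1", "m2", "m3"),
                           n_circ = c(1L, 2L, 1L),
                           e_circ = c(1.0, 3.0, NA_real_))
  edges <- tibble::tibble(mirna_id = c("m1", "m2", "m1", "m3"),
                          gene_id = c("gA", "gA", "gB", "gC"))
  avg <- suppressMessages(average_e_circ(scores, edges))
  expect_equal(avg$average_e_circ[avg$gene_id == "gA"], 2.0)
  expect_equal(avg$average_e_circ[avg$gene_id == "gB"], 1.0)
  expect_false("gC" %in% avg$gene_id)       # no defined E_circ: dropped
  expect_message(average_e_circ(scores, edges), "dropping")

  # network-level scores against direct recomputation
  set.seed(55)
  net <- tibble::tibble(
    mirna_id = sample(sprintf("m%02d", 1:8), 60, replace = TRUE),
    circ_id = sprintf("c%02d", 1:60),
    n_sites = sample(1:5, 60, replace = TRUE),
    fold_change = rnorm(60))
  sc <- e_circ_scores(net)
  for (mid in sc$mirna_id) {
    sub <- net[net$mirna_id == mid, ]
    expect_equal(sc$e_circ[sc$mirna_id == mid],
                 sum(sub$n_sites * sub$fold_change) / nrow(sub))
  }
})
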