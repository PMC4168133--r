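test_that("reference bundle satisfies its construction invariants", {
  b <- small_bundle()
  # every mature is an exact substring of its precursor
  expect_true(all(mapply(grepl, b$mature_mirnas, b$precursors,
                         MoreArgs = list(fixed = TRUE))))
  # every precursor occurs exactly once in the genome
  g <- paste(b$genome, collapse = "NNNN")
  occ <- vapply(b$precursors, function(p)
    length(gregexpr(p, g, fixed = TRUE)[[1]]), integer(1))
  expect_true(all(occ == 1L))
  # DNA alphabet everywhere
  all_seq <- c(b$genome, b$mature_mirnas, b$precursors,
               unlist(b$ncrna), b$mrna_frags, b$repeats, b$pirnas)
  expect_false(any(grepl("[^ACGT]", all_seq)))
  # piRNA reference lengths lie in 26-31 nt
  expect_true(all(nchar(b$pirnas) >= 26 & nchar(b$pirnas) <= 31))
})

test_that("same seed gives byte-identical reference FASTA, new seed differs", {
  b1 <- generate_reference(n_mirnas = 5, n_pirnas = 10,
                           n_ncrna_per_class = 2, genome_len = 5000,
                           seed = 11)
  b2 <- generate_reference(n_mirnas = 5, n_pirnas = 10,
                           n_ncrna_per_class = 2, genome_len = 5000,
                           seed = 11)
  d1 <- file.path(tempdir(), "ref1"); d2 <- file.path(tempdir(), "ref2")
  write_reference(b1, d1); write_reference(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  b3 <- generate_reference(n_mirnas = 5, n_pirnas = 10,
                           n_ncrna_per_class = 2, genome_len = 5000,
                           seed = 12)
  expect_false(identical(b1$genome, b3$genome))
})

test_that("over-full genome raises a capacity error", {
  expect_error(generate_reference(n_mirnas = 50, n_pirnas = 5,
                                  n_ncrna_per_class = 2, genome_len = 3000,
                                  seed = 1),
               "cannot host|without overlap")
})

test_that("simulated library has exact depth and a complete manifest", {
  b <- small_bundle()
  p <- simulation_profile(depth = 10000, seed = 5)
  sim <- simulate_library(b, p, "XX")
  expect_identical(nrow(sim$reads), 10000L)
  expect_identical(nrow(sim$truth), 10000L)
  # category totals in the manifest sum to depth exactly
  expect_identical(sum(table(sim$truth$category)), 10000L)
  # insert length support: miRNA sources 22-23 nt, piRNA sources 26-31 nt
  mir_src <- sim$truth$source[sim$truth$category == "miRNA"]
  expect_true(all(nchar(b$mature_mirnas[mir_src]) %in% 22:23))
  pir_src <- sim$truth$source[sim$truth$category == "piRNA"]
  expect_true(all(nchar(b$pirnas[pir_src]) %in% 26:31))
})

test_that("fixed seed reproduces the library bit for bit", {
  b <- small_bundle()
  p <- simulation_profile(depth = 3000, seed = 9)
  s1 <- simulate_library(b, p, "XY")
  s2 <- simulate_library(b, p, "XY")
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_library(s1, f1); write_library(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("group-exclusive miRNAs never appear outside their group", {
  b <- small_bundle()
  ids <- names(b$mature_mirnas)
  p <- simulation_profile(depth = 20000, seed = 3,
                          exclusive_spec = list(XX = ids[1], XY = ids[2]))
  for (g in c("XY", "YY")) {
    sim <- simulate_library(b, p, g)
    expect_identical(sum(sim$truth$source == ids[1]), 0L)
  }
  sim_xx <- simulate_library(b, p, "XX")
  expect_identical(sum(sim_xx$truth$source == ids[2]), 0L)
  expect_gt(sum(sim_xx$truth$source == ids[1]), 0L)
})

test_that("a +2 log2FC DE spec scales realized counts by about 4", {
  b <- small_bundle()
  ids <- names(b$mature_mirnas)
  # uniform base weights isolate the engineered fold change
  w <- stats::setNames(rep(1, length(ids)), ids)
  p <- simulation_profile(depth = 50000, seed = 17,
                          mirna_base_abundance = w,
                          de_spec = data.frame(mirna = ids[3], group = "XY",
                                               log2fc = 2),
                          error_rate = 0, junk_fraction = 0)
  xy <- simulate_library(b, p, "XY")
  xx <- simulate_library(b, p, "XX")
  # expected counts from the mixture weights: XY weight is 4x, and the
  # within-category normalization shifts both groups' totals
  n_mir <- length(ids)
  exp_xx <- 0.35 * 50000 / n_mir
  exp_xy <- 0.35 * 50000 * 4 / (n_mir + 3)
  expect_lt(abs(xx$mirna_counts[[ids[3]]] / exp_xx - 1), 0.2)
  expect_lt(abs(xy$mirna_counts[[ids[3]]] / exp_xy - 1), 0.2)
  ratio <- xy$mirna_counts[[ids[3]]] / xx$mirna_counts[[ids[3]]]
  expect_lt(abs(ratio / (4 * n_mir / (n_mir + 3)) - 1), 0.2)
})

test_that("invalid profiles and groups are rejected", {
  b <- small_bundle()
  expect_error(simulation_profile(category_fractions = c(miRNA = 1)),
               "named over")
  fr <- c(miRNA = 0.5, piRNA = 0.2, rRNA = 0.1, tRNA = 0.05, snRNA = 0.05,
          snoRNA = 0.02, mRNA = 0.03, "repeat" = 0.02, random = 0.05)
  expect_error(simulation_profile(category_fractions = fr + 0.01),
               "sum to 1")
  expect_error(simulation_profile(error_rate = 0.5), "error_rate")
  p <- simulation_profile(depth = 100, seed = 1)
  expect_error(simulate_library(b, p, "ZZ"), "unknown group")
  p2 <- simulation_profile(depth = 100, seed = 1,
                           exclusive_spec = list(XX = "mir-999"))
  expect_error(simulate_library(b, p2, "XX"), "unknown miRNA")
})
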