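ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming finds exact and 1-mismatch placements", {
  insert <- "ACGTACGTACGTACGTACGTAC"
  read <- substr(paste0(insert, ADAPTER), 1, 36)
  tr <- trim_adapter(read, ADAPTER, max_mismatch = 0)
  expect_identical(tr$sequence, insert)
  expect_true(tr$adapter_found)
  # one substitution inside the adapter still trims under max_mismatch = 1
  mut <- read
  substr(mut, nchar(insert) + 3, nchar(insert) + 3) <- "A"
  expect_identical(trim_adapter(mut, ADAPTER, max_mismatch = 1)$sequence,
                   insert)
  expect_false(trim_adapter(mut, ADAPTER, max_mismatch = 0)$adapter_found)
})

test_that("adapter-free reads are returned whole and flagged", {
  set.seed(31)
  for (i in 1:25) {
    read <- paste(sample(c("A", "C", "G", "T"), 36, replace = TRUE),
                  collapse = "")
    tr <- trim_adapter(read, ADAPTER, max_mismatch = 1, min_overlap = 6)
    # exhaustive scan oracle over every offset
    hit <- NA
    for (st in 1:(36 - 6 + 1)) {
      L <- min(nchar(ADAPTER), 36 - st + 1)
      mm <- sum(strsplit(substr(read, st, st + L - 1), "")[[1]] !=
                  strsplit(substr(ADAPTER, 1, L), "")[[1]])
      if (mm <= 1) { hit <- st; break }
    }
    if (is.na(hit)) {
      expect_false(tr$adapter_found)
      expect_identical(tr$sequence, read)
    } else {
      expect_true(tr$adapter_found)
      expect_identical(tr$sequence, substr(read, 1, hit - 1))
    }
  }
})

test_that("length bounds are inclusive and drop reasons partition the input", {
  seqs <- c(strrep("A", 15), strrep("C", 16), strrep("G", 30),
            strrep("T", 31), paste0(strrep("A", 19), "N"), strrep("C", 20))
  quals <- strrep("I", nchar(seqs))
  fl <- filter_reads(seqs, quals)
  expect_identical(sort(fl$sequences),
                   sort(c(strrep("C", 16), strrep("G", 30), strrep("C", 20))))
  st <- fl$stats
  expect_identical(unname(st["total"]),
                   unname(st["kept"] + st["drop_length"] + st["drop_N"] +
                            st["drop_quality"]))
  expect_identical(unname(st["drop_length"]), 2L)
  expect_identical(unname(st["drop_N"]), 1L)
  # low-quality read dropped by the quality rule
  fl2 <- filter_reads(strrep("A", 20), strrep("#", 20), min_mean_qual = 20)
  expect_identical(unname(fl2$stats["drop_quality"]), 1L)
})

test_that("collapse produces exact per-library counts and is order-independent", {
  a20 <- strrep("A", 20); c20 <- strrep("C", 20)
  t1 <- collapse_tags(list(L1 = c(a20, a20, c20)))
  expect_identical(t1$count_L1[t1$sequence == a20], 2L)
  expect_identical(t1$count_L1[t1$sequence == c20], 1L)
  # empty library gives an all-zero column
  t2 <- collapse_tags(list(L1 = c(a20, c20), L2 = character(0)))
  expect_identical(sum(t2$count_L2), 0L)
  # order independence
  set.seed(8)
  pool <- sample(c(a20, c20, strrep("G", 18)), 50, replace = TRUE)
  expect_identical(collapse_tags(list(x = pool)),
                   collapse_tags(list(x = rev(pool))))
})

test_that("read counts are conserved from simulator through collapse", {
  b <- small_bundle()
  p <- simulation_profile(depth = 10000, seed = 21)
  sim <- simulate_library(b, p, "YY")
  pp <- preprocess_fastq(list(YY = sim), adapter = p$adapter)
  st <- pp$stats$YY
  expect_identical(unname(st["total"]), 10000L)
  expect_identical(unname(st["kept"]), sum(pp$tags$count_YY))
  expect_identical(unname(st["kept"] + st["drop_length"] + st["drop_N"] +
                            st["drop_quality"]), 10000L)
})

test_that("length profile reports single peaks and flat histograms correctly", {
  tags22 <- data.frame(sequence = random_seqs(40, 22), count_x = 1L)
  lp <- length_profile(tags22)
  expect_length(lp$peaks, 1)
  expect_identical(lp$peaks[[1]], 22L)
  # uniform histogram: no bin exceeds 1.5x the median
  tagsu <- data.frame(sequence = random_seqs(150, rep(16:30, each = 10)),
                      count_x = 1L)
  expect_length(length_profile(tagsu)$peaks, 0)
  expect_error(length_profile(tags22[0, , drop = FALSE]), "empty")
})

test_that("default simulated library shows Dicer and piRNA length peaks", {
  b <- generate_reference(seed = 77)  # default-size bundle
  p <- simulation_profile(seed = 77)  # default depth/error/mixture
  sim <- simulate_library(b, p, "XX")
  pp <- preprocess_fastq(list(XX = sim), adapter = p$adapter)
  lp <- length_profile(pp$tags, by = "distinct")
  covered <- sort(unique(unlist(lp$peaks)))
  expect_true(all(22:23 %in% covered))
  expect_true(all(26:28 %in% covered))
})

test_that("error-free non-random tags all originate from bundle sequences", {
  b <- small_bundle()
  p <- simulation_profile(depth = 5000, seed = 13, error_rate = 0,
                          junk_fraction = 0)
  sim <- simulate_library(b, p, "XX")
  pp <- preprocess_fastq(list(XX = sim), adapter = p$adapter)
  universe <- paste(c(b$genome, unlist(b$ncrna), b$mrna_frags, b$repeats,
                      b$pirnas, b$mature_mirnas), collapse = "#")
  # trimmed inserts of reads from the unassignable category
  rnd_reads <- sim$reads$sequence[sim$truth$category == "random"]
  rnd_inserts <- trim_adapter(rnd_reads, p$adapter)$sequence
  from_bundle <- vapply(pp$tags$sequence, grepl, logical(1), x = universe,
                        fixed = TRUE)
  expect_true(all(pp$tags$sequence[!from_bundle] %in% rnd_inserts))
})
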