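# Independent oracles and shared fixtures for the test suite.

# Brute-force substring scan: all placements of query in each reference with
# <= max_mm substitutions, by direct character comparison.
oracle_scan <- function(query, refs, max_mm) {
  q <- strsplit(query, "")[[1]]
  out <- list()
  for (nm in sort(names(refs))) {
    r <- strsplit(refs[[nm]], "")[[1]]
    if (length(r) < length(q)) next
    for (off in 1:(length(r) - length(q) + 1)) {
      mm <- sum(r[off:(off + length(q) - 1)] != q)
      if (mm <= max_mm) {
        out[[length(out) + 1]] <- data.frame(ref = nm, offset = off,
                                             mismatches = mm,
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(ref = character(0), offset = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Memoized recursive Nussinov maximum-pairing count (pair rules: WC + G:T).
oracle_max_pairs <- function(seq, min_loop = 3) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  pairs_ok <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  memo <- matrix(NA_integer_, n, n)
  rec <- function(i, j) {
    if (i >= j || j - i <= min_loop) return(0L)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (pairs_ok(s[i], s[k])) {
        v <- 1L + rec(i + 1L, k - 1L) + if (k < j) rec(k + 1L, j) else 0L
        if (v > best) best <- v
      }
    }
    memo[i, j] <<- best
    best
  }
  rec(1L, n)
}

# Direct (non-log) summation of the Audic-Claverie conditional tails.
oracle_ac_direct <- function(x, y, N1, N2) {
  r <- N2 / N1
  pk <- function(k) exp(k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) -
                          lgamma(k + 1) - (x + k + 1) * log1p(r))
  lower <- sum(vapply(0:y, pk, numeric(1)))
  upper <- if (y == 0) 1 else {
    # sum the upper tail directly until terms vanish
    tot <- 0
    k <- y
    repeat {
      t <- pk(k)
      tot <- tot + t
      k <- k + 1
      if (t < 1e-20 * max(tot, 1e-300) && k > y + 10) break
      if (k > y + 5e5) break
    }
    tot
  }
  min(1, 2 * min(lower, upper))
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher p-value
# (point-probability rule) for the 2x2 table with fixed margins.
oracle_fisher_enum <- function(x, y, N1, N2) {
  k_tot <- x + y
  probs <- vapply(0:k_tot, function(k) {
    if (k > N1 || (k_tot - k) > N2) return(0)
    exp(lchoose(N1, k) + lchoose(N2, k_tot - k) - lchoose(N1 + N2, k_tot))
  }, numeric(1))
  p_obs <- probs[x + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive O(n^3) agglomerative clustering; returns the cophenetic matrix.
oracle_agglom_cophenetic <- function(v, linkage = "complete") {
  n <- nrow(v)
  d <- as.matrix(dist(v))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        link <- if (linkage == "complete") max(dd) else min(dd)
        if (link < best_d) { best_d <- link; best <- c(i, j) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d
    coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters <- clusters[-best[2]]
  }
  coph
}

# n random DNA sequences; `len` recycles over sequences.
random_seqs <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = ""), character(1))
}

# Shared fixtures, built once per test run ------------------------------------

.fixture_env <- new.env()

small_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- generate_reference(
      n_mirnas = 10, n_pirnas = 50, n_ncrna_per_class = 3,
      genome_len = 8000, seed = 42)
  }
  .fixture_env$bundle
}

# The study-condition experiment: three libraries at depth 1e5, 50 miRNAs,
# 10 true-DE species at |log2FC| = 2 (5 up and 5 down in XY vs XX), one
# exclusive species per group, no sequencing error.
study_experiment <- function() {
  if (is.null(.fixture_env$study)) {
    bundle <- generate_reference(n_mirnas = 50, n_pirnas = 300,
                                 n_ncrna_per_class = 10,
                                 genome_len = 20000, seed = 2024)
    ids <- names(bundle$mature_mirnas)
    de <- data.frame(
      mirna = ids[1:10],
      group = "XY",
      log2fc = c(rep(2, 5), rep(-2, 5)),
      stringsAsFactors = FALSE)
    excl <- list(XX = ids[11], XY = ids[12], YY = ids[13])
    profile <- simulation_profile(depth = 1e5, de_spec = de,
                                  exclusive_spec = excl,
                                  error_rate = 0, junk_fraction = 0.02,
                                  seed = 2024)
    expt <- simulate_experiment(bundle, profile)
    .fixture_env$study <- list(bundle = bundle, profile = profile,
                               expt = expt)
  }
  .fixture_env$study
}

# Preprocessed + annotated view of the study experiment.
study_analysis <- function() {
  if (is.null(.fixture_env$analysis)) {
    st <- study_experiment()
    pp <- preprocess_fastq(st$expt$libraries, adapter = st$profile$adapter)
    ann <- classify_cascade(pp$tags$sequence, st$bundle,
                            backend = "nussinov")
    em <- expression_from_annotation(ann, pp$tags)
    .fixture_env$analysis <- list(pp = pp, ann = ann, em = em)
  }
  .fixture_env$analysis
}

# An engineered perfect stem-loop precursor with the mature in the 5' arm.
perfect_hairpin <- function(mature = "ACGTGCATCGTAGCTAGCTAAC", loop = 8) {
  arm <- paste0("GCA", mature, "TGC")
  loop_seq <- paste(rep("A", loop), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(arm)))
  list(sequence = paste0(arm, loop_seq, rc), mature = mature, arm = arm)
}
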