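#' Trim the 3' adapter from reads
#'
#' Scans every alignment of the adapter prefix (overlap of at least
#' `min_overlap` nt) against each read, accepting at most `max_mismatch`
#' substitutions (no indels); the leftmost accepted placement wins and the
#' read is cut there. Reads without an accepted placement are returned whole
#' and flagged.
#'
#' @param reads character vector of read sequences.
#' @param adapter 3' adapter sequence.
#' @param max_mismatch maximum substitutions in the adapter overlap.
#' @param min_overlap minimum adapter prefix length considered.
#' @return data.frame with `sequence` (trimmed insert, or the whole read when
#'   no adapter was found) and `adapter_found` (logical flag).
#' @examples
#' trim_adapter(c("ACGTACGTTGGAATTCTCGG"), "TGGAATTCTCGGGTGCCAAGG")
#' @export
trim_adapter <- function(reads, adapter, max_mismatch = 1L,
                         min_overlap = 6L) {
  stopifnot(nchar(adapter) > 0, max_mismatch >= 0,
            min_overlap >= 1, min_overlap <= nchar(adapter))
  cut <- cpp_trim_adapter(as.character(reads), adapter,
                          as.integer(max_mismatch), as.integer(min_overlap))
  found <- cut >= 0L
  out <- as.character(reads)
  out[found] <- substr(out[found], 1L, cut[found])
  data.frame(sequence = out, adapter_found = found,
             stringsAsFactors = FALSE)
}

#' Filter trimmed reads by length, ambiguity and quality
#'
#' Retains reads whose trimmed length lies in `[min_len, max_len]`
#' (inclusive), with at most `max_N` ambiguous bases and mean Phred quality
#' at least `min_mean_qual`. Each dropped read is charged to exactly one
#' reason, checked in the order length, N content, quality, so the returned
#' statistics partition the input.
#'
#' @param seqs character vector of trimmed read sequences.
#' @param quals character vector of Phred+33 quality strings for the
#'   *untrimmed* reads (only the first `nchar(seqs)` characters are scored),
#'   or `NULL` to skip the quality rule.
#' @param min_len,max_len inclusive length bounds (default 16-30 nt).
#' @param max_N maximum number of N bases.
#' @param min_mean_qual minimum mean Phred score.
#' @return list with `sequences` (kept reads) and `stats` (named counts:
#'   `total`, `kept`, `drop_length`, `drop_N`, `drop_quality`).
#' @export
filter_reads <- function(seqs, quals = NULL, min_len = 16L, max_len = 30L,
                         max_N = 0L, min_mean_qual = 20) {
  stopifnot(min_len <= max_len)
  n <- length(seqs)
  len <- nchar(seqs)
  bad_len <- len < min_len | len > max_len
  n_count <- vapply(gregexpr("N", seqs, fixed = TRUE),
                    function(m) sum(m > 0L), integer(1))
  bad_N <- !bad_len & n_count > max_N
  if (!is.null(quals)) {
    stopifnot(length(quals) == n)
    meanq <- vapply(seq_len(n), function(i) {
      q <- utf8ToInt(substr(quals[i], 1L, max(len[i], 1L))) - 33L
      mean(q)
    }, numeric(1))
    bad_q <- !bad_len & !bad_N & meanq < min_mean_qual
  } else {
    bad_q <- rep(FALSE, n)
  }
  keep <- !bad_len & !bad_N & !bad_q
  stats <- c(total = n, kept = sum(keep), drop_length = sum(bad_len),
             drop_N = sum(bad_N), drop_quality = sum(bad_q))
  stopifnot(stats[["total"]] ==
              stats[["kept"]] + stats[["drop_length"]] +
              stats[["drop_N"]] + stats[["drop_quality"]])
  list(sequences = seqs[keep], stats = stats)
}

#' Collapse clean reads into a unique-tag table
#'
#' One row per distinct sequence, one count column per library. Column sums
#' equal the number of clean reads per library exactly; the row order is
#' lexicographic in the sequence, so the result is independent of input
#' order.
#'
#' @param libs named list (library id -> character vector of clean read
#'   sequences).
#' @return data.frame with column `sequence` and one `count_<lib>` column per
#'   library.
#' @export
collapse_tags <- function(libs) {
  stopifnot(is.list(libs), !is.null(names(libs)))
  all_seq <- sort(unique(unlist(libs, use.names = FALSE)))
  out <- data.frame(sequence = all_seq, stringsAsFactors = FALSE)
  for (nm in names(libs)) {
    tab <- table(factor(libs[[nm]], levels = all_seq))
    out[[paste0("count_", nm)]] <- as.integer(tab)
  }
  rownames(out) <- NULL
  out
}

#' Read length distribution with peak detection
#'
#' Histogram of sequence lengths over the 16-30 nt range (out-of-range
#' lengths are pooled into a `31+` bin), computed either over distinct
#' sequences or weighted by total read count. Peak windows are maximal runs
#' of consecutive lengths whose counts exceed `peak_factor` times the median
#' bin count.
#'
#' @param tags a tag table from [collapse_tags()] (or any data.frame with a
#'   `sequence` column and `count_*` columns).
#' @param by `"distinct"` (each sequence once; the convention used for
#'   library quality assessment) or `"total"` (weighted by summed counts).
#' @param peak_factor multiple of the median bin count a bin must exceed to
#'   belong to a peak.
#' @return class `length_profile`: list with `counts` (named vector over
#'   bins 16..30 and `31+`), `peaks` (list of integer vectors, each a maximal
#'   peak window), and `by`.
#' @export
length_profile <- function(tags, by = c("distinct", "total"),
                           peak_factor = 1.5) {
  by <- match.arg(by)
  if (nrow(tags) == 0L) stopf("length_profile: empty input")
  len <- nchar(tags$sequence)
  w <- if (by == "distinct") rep(1L, nrow(tags)) else {
    cc <- grep("^count_", names(tags), value = TRUE)
    as.integer(rowSums(tags[, cc, drop = FALSE]))
  }
  bins <- c(16:30, "31+")
  binned <- ifelse(len >= 31L, "31+", as.character(pmax(len, 16L)))
  binned[len < 16L] <- "16"  # filtered inputs should not reach here
  counts <- vapply(bins, function(b) sum(w[binned == b]), numeric(1))
  names(counts) <- bins
  core <- counts[as.character(16:30)]
  thr <- peak_factor * median(core)
  hot <- unname(which(core > thr))
  peaks <- list()
  if (length(hot)) {
    brk <- c(0L, which(diff(hot) > 1L), length(hot))
    for (i in seq_len(length(brk) - 1L)) {
      peaks[[i]] <- 15L + hot[(brk[i] + 1L):brk[i + 1L]]
    }
  }
  structure(list(counts = counts, peaks = peaks, by = by,
                 threshold = thr), class = "length_profile")
}

#' @export
print.length_profile <- function(x, ...) {
  cat(sprintf("Length profile (%s sequences)\n", x$by))
  print(x$counts)
  if (length(x$peaks)) {
    cat("peak windows:",
        paste(vapply(x$peaks, function(p)
          sprintf("%d-%d nt", min(p), max(p)), character(1)),
          collapse = ", "), "\n")
  } else cat("no peak windows detected\n")
  invisible(x)
}

#' Preprocess raw FASTQ libraries into a unique-tag table
#'
#' For each library: read FASTQ (Phred+33), trim the 3' adapter, filter by
#' length/ambiguity/quality, then collapse across libraries into one
#' unique-tag table.
#'
#' @param fastq named character vector (library id -> FASTQ path) or named
#'   list of `sim_library` objects (in-memory use).
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len,max_N,min_mean_qual see [filter_reads()].
#' @param max_mismatch,min_overlap see [trim_adapter()].
#' @return list with `tags` (tag table), `stats` (per-library filter stats,
#'   including `no_adapter` counts), `profiles` (per-library
#'   `length_profile`s over distinct sequences).
#' @export
preprocess_fastq <- function(fastq, adapter = "TGGAATTCTCGGGTGCCAAGG",
                             min_len = 16L, max_len = 30L, max_N = 0L,
                             min_mean_qual = 20, max_mismatch = 1L,
                             min_overlap = 6L) {
  stopifnot(!is.null(names(fastq)))
  clean <- list()
  stats <- list()
  for (nm in names(fastq)) {
    x <- if (is.list(fastq)) fastq[[nm]] else fastq[[nm]]
    if (inherits(x, "sim_library")) {
      seqs <- x$reads$sequence
      quals <- x$reads$quality
    } else {
      rec <- read_fastq(x)
      seqs <- rec$sequence
      quals <- rec$quality
    }
    tr <- trim_adapter(seqs, adapter, max_mismatch, min_overlap)
    fl <- filter_reads(tr$sequence, quals, min_len, max_len, max_N,
                       min_mean_qual)
    clean[[nm]] <- fl$sequences
    stats[[nm]] <- c(fl$stats, no_adapter = sum(!tr$adapter_found))
  }
  tags <- collapse_tags(clean)
  profiles <- lapply(names(clean), function(nm) {
    sub <- tags[tags[[paste0("count_", nm)]] > 0L,
                c("sequence", paste0("count_", nm))]
    if (nrow(sub)) length_profile(sub) else NULL
  })
  names(profiles) <- names(clean)
  list(tags = tags, stats = stats, profiles = profiles)
}

# Minimal FASTQ reader (Phred+33) built on Biostrings.
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  data.frame(id = names(x), sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}
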