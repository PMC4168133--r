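#' Generate a toy small RNA reference bundle
#'
#' Builds a self-consistent reference set for simulation and annotation: a toy
#' genome, mature miRNAs embedded in near-palindromic stem-loop precursors
#' placed on the genome, known ncRNA classes (rRNA, tRNA, snRNA, snoRNA),
#' mRNA fragments, repeat elements and a piRNA set. Precursors are built as
#' arm + loop + reverse-complement arm with at most three engineered
#' mismatches on the arm opposite the mature sequence, so hairpin validation
#' succeeds by construction while the duplex is imperfect, as in real
#' pre-miRNAs.
#'
#' @param n_mirnas number of mature miRNA / precursor pairs.
#' @param n_pirnas number of piRNA reference sequences (26-31 nt, length
#'   distribution peaked at 26-28 nt as in germline small RNA data).
#' @param n_ncrna_per_class sequences per ncRNA class (rRNA, tRNA, snRNA,
#'   snoRNA).
#' @param genome_len total toy genome length in nt, split across
#'   `n_chromosomes` chromosomes.
#' @param seed integer seed; the same seed reproduces the bundle byte for
#'   byte.
#' @param n_mrna,n_repeats number of mRNA fragment / repeat references.
#' @param n_chromosomes number of toy chromosomes.
#' @return an object of class `ref_bundle`: list with elements `genome`,
#'   `mature_mirnas`, `precursors`, `mature_arm`, `ncrna` (list keyed by
#'   class), `mrna_frags`, `repeats`, `pirnas`, `precursor_loci`
#'   (data.frame), and `frag_table` (canonical degradation fragments used by
#'   the simulator).
#' @examples
#' b <- generate_reference(n_mirnas = 5, n_pirnas = 20,
#'                         n_ncrna_per_class = 2, genome_len = 6000, seed = 1)
#' all(mapply(grepl, b$mature_mirnas, b$precursors, fixed = TRUE))
#' @export
generate_reference <- function(n_mirnas = 150, n_pirnas = 800,
                               n_ncrna_per_class = 10, genome_len = 60000,
                               seed = 1, n_mrna = 20, n_repeats = 10,
                               n_chromosomes = 2) {
  stopifnot(n_mirnas >= 1, n_pirnas >= 1, n_ncrna_per_class >= 1,
            genome_len >= 1, n_mrna >= 1, n_repeats >= 1,
            n_chromosomes >= 1)
  with_seed(derive_seed(seed, "reference"), {
    mature_len <- sample(22:23, n_mirnas, replace = TRUE,
                         prob = c(0.6, 0.4))  # 22 nt is the modal length
    mature <- random_seq(n_mirnas, mature_len)
    while (anyDuplicated(mature)) {
      dup <- duplicated(mature)
      mature[dup] <- random_seq(sum(dup), mature_len[dup])
    }
    names(mature) <- sprintf("mir-%03d", seq_len(n_mirnas))

    arm_of <- sample(c("5p", "3p"), n_mirnas, replace = TRUE)
    prec <- character(n_mirnas)
    for (i in seq_len(n_mirnas)) {
      pad5 <- random_seq(1, sample(3:6, 1))
      pad3 <- random_seq(1, sample(3:6, 1))
      arm <- paste0(pad5, mature[i], pad3)            # 28-35 nt
      loop <- random_seq(1, 8)
      other <- revcomp(arm)
      # engineer up to 3 mismatches on the arm opposite the mature sequence
      n_mm <- sample(0:3, 1)
      if (n_mm > 0) {
        oth <- strsplit(other, "")[[1]]
        pos <- sample(seq_along(oth), n_mm)
        for (p in pos) oth[p] <- sample(setdiff(BASES, oth[p]), 1)
        other <- paste(oth, collapse = "")
      }
      prec[i] <- if (arm_of[i] == "5p") paste0(arm, loop, other)
                 else paste0(other, loop, arm)
    }
    names(prec) <- names(arm_of) <- names(mature)

    # place precursors on the genome without overlap
    chrom_len <- rep(genome_len %/% n_chromosomes, n_chromosomes)
    chrom_len[1] <- chrom_len[1] + genome_len %% n_chromosomes
    plen <- nchar(prec)
    if (sum(plen) > genome_len) {
      stopf("genome_len %d cannot host %d precursors totalling %d nt",
            genome_len, n_mirnas, sum(plen))
    }
    genome <- random_seq(n_chromosomes, chrom_len)
    names(genome) <- sprintf("chr%d", seq_len(n_chromosomes))
    loci <- data.frame(precursor = names(prec), chrom = NA_character_,
                       start = NA_integer_, end = NA_integer_,
                       stringsAsFactors = FALSE)
    occupied <- lapply(chrom_len, function(L) logical(L))
    for (i in order(plen, decreasing = TRUE)) {
      placed <- FALSE
      for (attempt in seq_len(2000)) {
        ch <- sample.int(n_chromosomes, 1)
        if (chrom_len[ch] < plen[i]) next
        st <- sample.int(chrom_len[ch] - plen[i] + 1L, 1)
        span <- st:(st + plen[i] - 1L)
        if (!any(occupied[[ch]][span])) {
          occupied[[ch]][span] <- TRUE
          g <- genome[[ch]]
          substr(g, st, st + plen[i] - 1L) <- prec[[i]]
          genome[[ch]] <- g
          loci$chrom[i] <- names(genome)[ch]
          loci$start[i] <- st
          loci$end[i] <- st + plen[i] - 1L
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stopf("could not place precursor %s on the genome without overlap",
              names(prec)[i])
      }
    }

    class_len <- c(rRNA = 500L, tRNA = 75L, snRNA = 140L, snoRNA = 90L)
    ncrna <- lapply(names(class_len), function(cl) {
      s <- random_seq(n_ncrna_per_class,
                      rep(class_len[[cl]], n_ncrna_per_class))
      names(s) <- sprintf("%s-%02d", cl, seq_len(n_ncrna_per_class))
      s
    })
    names(ncrna) <- names(class_len)

    mrna <- random_seq(n_mrna, sample(200:400, n_mrna, replace = TRUE))
    names(mrna) <- sprintf("mRNA-%02d", seq_len(n_mrna))
    reps <- random_seq(n_repeats, sample(150:300, n_repeats, replace = TRUE))
    names(reps) <- sprintf("repeat-%02d", seq_len(n_repeats))

    pir_len <- sample(26:31, n_pirnas, replace = TRUE,
                      prob = c(0.30, 0.30, 0.25, 0.08, 0.05, 0.02))
    pir <- random_seq(n_pirnas, pir_len)
    while (anyDuplicated(pir)) {
      dup <- duplicated(pir)
      pir[dup] <- random_seq(sum(dup), pir_len[dup])
    }
    names(pir) <- sprintf("piR-%04d", seq_len(n_pirnas))

    # canonical degradation fragments: real ncRNA/mRNA/repeat fragments are
    # stereotyped, so each reference exposes a small fixed fragment set
    frag <- list()
    for (cl in c(names(ncrna), "mRNA", "repeat")) {
      seqs <- switch(cl, mRNA = mrna, "repeat" = reps, ncrna[[cl]])
      for (nm in names(seqs)) {
        k <- 25L
        len <- sample(16:30, k, replace = TRUE)
        start <- vapply(len, function(l)
          sample.int(nchar(seqs[[nm]]) - l + 1L, 1), integer(1))
        frag[[length(frag) + 1L]] <- data.frame(
          class = cl, ref = nm,
          fragment = substring(seqs[[nm]], start, start + len - 1L),
          stringsAsFactors = FALSE)
      }
    }
    frag_table <- unique(do.call(rbind, frag))

    structure(list(genome = genome, mature_mirnas = mature,
                   precursors = prec, mature_arm = arm_of, ncrna = ncrna,
                   mrna_frags = mrna, repeats = reps, pirnas = pir,
                   precursor_loci = loci, frag_table = frag_table),
              class = "ref_bundle")
  })
}

#' @export
print.ref_bundle <- function(x, ...) {
  cat("Reference bundle\n")
  cat(sprintf("  genome: %d chromosome(s), %d nt\n",
              length(x$genome), sum(nchar(x$genome))))
  cat(sprintf("  mature miRNAs: %d (precursors placed on genome)\n",
              length(x$mature_mirnas)))
  cat(sprintf("  ncRNA: %s\n",
              paste(sprintf("%s=%d", names(x$ncrna),
                            lengths(x$ncrna)), collapse = ", ")))
  cat(sprintf("  mRNA fragments: %d, repeats: %d, piRNAs: %d\n",
              length(x$mrna_frags), length(x$repeats), length(x$pirnas)))
  invisible(x)
}

#' Write a reference bundle to FASTA files
#'
#' One FASTA per collection (`genome.fa`, `mature.fa`, `precursors.fa`,
#' `rRNA.fa`, ..., `pirnas.fa`) under `dir`.
#'
#' @param bundle a `ref_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_reference <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sets <- c(list(genome = bundle$genome, mature = bundle$mature_mirnas,
                 precursors = bundle$precursors),
            bundle$ncrna,
            list(mRNA = bundle$mrna_frags, repeats = bundle$repeats,
                 pirnas = bundle$pirnas))
  paths <- character(0)
  for (nm in names(sets)) {
    p <- file.path(dir, paste0(nm, ".fa"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sets[[nm]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
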