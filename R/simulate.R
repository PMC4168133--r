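#' Build a simulation profile
#'
#' Describes one sequencing experiment: read depth, the small RNA category
#' mixture, per-miRNA base abundances, differential-expression and
#' group-exclusive specifications, the 3' adapter, and error/junk rates.
#' Defaults emulate a gonad small RNA library: a Dicer-product peak at
#' 22-23 nt, a piRNA peak at 26-28 nt, a substantial known-ncRNA/repeat/mRNA
#' degradation background and a residue of unassignable sequence.
#'
#' @param depth reads per library.
#' @param category_fractions named mixture weights over miRNA, piRNA, rRNA,
#'   tRNA, snRNA, snoRNA, mRNA, repeat, random; must sum to 1 within 1e-9.
#' @param mirna_base_abundance named relative weights per miRNA id; `NULL`
#'   draws log-normal weights (sdlog 1) when the profile is applied to a
#'   bundle.
#' @param de_spec data.frame with columns `mirna`, `group`, `log2fc`: the
#'   miRNA's mixture weight in `group` is scaled by `2^log2fc` relative to
#'   the other groups.
#' @param exclusive_spec named list (names in XX/XY/YY) of miRNA ids detected
#'   only in that group.
#' @param adapter 3' adapter sequence appended after each insert up to the
#'   machine read length (default: TruSeq small RNA adapter).
#' @param error_rate per-base substitution probability, in `[0, 0.1)`.
#' @param junk_fraction fraction of reads replaced by random low-quality
#'   sequence, exercising the quality filter.
#' @param dispersion gamma perturbation (squared coefficient of variation) of
#'   species weights; 0 gives a pure multinomial.
#' @param read_len fixed machine read length.
#' @param seed integer; combined with the group id to give each library its
#'   own reproducible RNG stream.
#' @return an object of class `sim_profile`.
#' @export
simulation_profile <- function(depth = 1e5,
                               category_fractions = c(
                                 miRNA = 0.35, piRNA = 0.20, rRNA = 0.10,
                                 tRNA = 0.08, snRNA = 0.03, snoRNA = 0.03,
                                 mRNA = 0.08, "repeat" = 0.05,
                                 random = 0.08),
                               mirna_base_abundance = NULL,
                               de_spec = NULL,
                               exclusive_spec = NULL,
                               adapter = "TGGAATTCTCGGGTGCCAAGG",
                               error_rate = 0.008,
                               junk_fraction = 0.02,
                               dispersion = 0,
                               read_len = 36L,
                               seed = 1L) {
  cats <- c("miRNA", "piRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "mRNA",
            "repeat", "random")
  if (!setequal(names(category_fractions), cats)) {
    stopf("category_fractions must be named over: %s",
          paste(cats, collapse = ", "))
  }
  category_fractions <- category_fractions[cats]
  if (abs(sum(category_fractions) - 1) > 1e-9)
    stopf("category_fractions must sum to 1 (got %.12f)",
          sum(category_fractions))
  if (depth <= 0) stopf("depth must be positive")
  if (error_rate < 0 || error_rate >= 0.1)
    stopf("error_rate must lie in [0, 0.1)")
  stopifnot(nchar(adapter) > 0, junk_fraction >= 0, junk_fraction < 1,
            dispersion >= 0, read_len >= 16)
  if (!is.null(de_spec)) {
    stopifnot(is.data.frame(de_spec),
              all(c("mirna", "group", "log2fc") %in% names(de_spec)),
              all(de_spec$group %in% GROUPS))
  }
  if (!is.null(exclusive_spec)) {
    stopifnot(is.list(exclusive_spec), all(names(exclusive_spec) %in% GROUPS))
  }
  structure(list(depth = as.integer(depth),
                 category_fractions = category_fractions,
                 mirna_base_abundance = mirna_base_abundance,
                 de_spec = de_spec, exclusive_spec = exclusive_spec,
                 adapter = adapter, error_rate = error_rate,
                 junk_fraction = junk_fraction, dispersion = dispersion,
                 read_len = as.integer(read_len), seed = as.integer(seed)),
            class = "sim_profile")
}

#' @export
print.sim_profile <- function(x, ...) {
  cat(sprintf("Simulation profile: depth %d, error rate %.4g, junk %.3g\n",
              x$depth, x$error_rate, x$junk_fraction))
  cat("  category fractions:",
      paste(sprintf("%s=%.2f", names(x$category_fractions),
                    x$category_fractions), collapse = " "), "\n")
  if (!is.null(x$de_spec))
    cat(sprintf("  DE spec: %d entries\n", nrow(x$de_spec)))
  if (!is.null(x$exclusive_spec))
    cat(sprintf("  exclusive: %s\n",
                paste(sprintf("%s=%d", names(x$exclusive_spec),
                              lengths(x$exclusive_spec)), collapse = " ")))
  invisible(x)
}

# Per-miRNA mixture weights for one group: base abundance, DE fold changes
# applied to the target group, exclusives zeroed outside their home group.
mirna_group_weights <- function(bundle, profile, group) {
  ids <- names(bundle$mature_mirnas)
  w <- profile$mirna_base_abundance
  if (is.null(w)) {
    w <- with_seed(derive_seed(profile$seed, "abundance"),
                   stats::setNames(rlnorm(length(ids), 0, 1), ids))
  }
  if (!all(names(w) %in% ids) || !all(ids %in% names(w)))
    stopf("mirna_base_abundance must cover exactly the bundle's miRNA ids")
  w <- w[ids]
  ds <- profile$de_spec
  if (!is.null(ds)) {
    unknown <- setdiff(ds$mirna, ids)
    if (length(unknown))
      stopf("de_spec references unknown miRNA id(s): %s",
            paste(unknown, collapse = ", "))
    hit <- ds$group == group
    if (any(hit)) w[ds$mirna[hit]] <- w[ds$mirna[hit]] * 2^ds$log2fc[hit]
  }
  ex <- profile$exclusive_spec
  if (!is.null(ex)) {
    unknown <- setdiff(unlist(ex), ids)
    if (length(unknown))
      stopf("exclusive_spec references unknown miRNA id(s): %s",
            paste(unknown, collapse = ", "))
    for (g in names(ex)) if (g != group) w[ex[[g]]] <- 0
  }
  w
}

#' Simulate one small RNA library
#'
#' Draws `depth` reads from the profile's category mixture. miRNA reads are
#' mature sequences (22-23 nt), piRNA reads full piRNA sequences (26-31 nt),
#' known-RNA reads canonical degradation fragments, and `random` reads
#' unassignable sequence. Each insert is extended with the 3' adapter to the
#' fixed machine read length, substitution errors are applied at
#' `error_rate`, and a `junk_fraction` of reads is replaced by low-quality
#' noise. Group-exclusive miRNAs are absent outside their home group, and
#' DE-spec miRNAs have their expected counts scaled by `2^log2fc` in the
#' target group.
#'
#' @param bundle a `ref_bundle` from [generate_reference()].
#' @param profile a `sim_profile`.
#' @param group one of "XX", "XY", "YY".
#' @return class `sim_library`: list with `reads` (data.frame `id`,
#'   `sequence`, `quality`), `truth` (per-read data.frame `id`, `category`,
#'   `source`), `mirna_counts` (named integer vector of realized per-species
#'   counts), `group`, and `expected_mirna_weights`.
#' @export
simulate_library <- function(bundle, profile, group) {
  stopifnot(inherits(bundle, "ref_bundle"), inherits(profile, "sim_profile"))
  if (!group %in% GROUPS)
    stopf("unknown group '%s' (expected one of %s)", group,
          paste(GROUPS, collapse = ", "))
  w_mirna <- mirna_group_weights(bundle, profile, group)
  with_seed(derive_seed(profile$seed, paste0("library-", group)), {
    depth <- profile$depth
    n_cat <- as.vector(rmultinom(1, depth, profile$category_fractions))
    names(n_cat) <- names(profile$category_fractions)

    seqs <- character(depth)
    cat_lab <- character(depth)
    src_lab <- character(depth)
    pos <- 1L

    emit <- function(s, categ, src) {
      n <- length(s)
      if (n == 0L) return(invisible())
      idx <- pos:(pos + n - 1L)
      seqs[idx] <<- s
      cat_lab[idx] <<- categ
      src_lab[idx] <<- src
      pos <<- pos + n
      invisible()
    }

    draw_species <- function(n, weights) {
      w <- weights
      if (profile$dispersion > 0) {
        shp <- 1 / profile$dispersion
        pos_w <- w > 0
        w[pos_w] <- w[pos_w] * rgamma(sum(pos_w), shape = shp, rate = shp)
      }
      if (sum(w) <= 0) stopf("all species weights are zero")
      as.vector(rmultinom(1, n, w))
    }

    # miRNA: mature sequences
    nm <- draw_species(n_cat[["miRNA"]], w_mirna)
    emit(rep(unname(bundle$mature_mirnas), nm), "miRNA",
         rep(names(bundle$mature_mirnas), nm))

    # piRNA: full-length piRNA sequences, uniform over species
    np <- draw_species(n_cat[["piRNA"]], rep(1, length(bundle$pirnas)))
    emit(rep(unname(bundle$pirnas), np), "piRNA",
         rep(names(bundle$pirnas), np))

    # known-RNA degradation fragments from the canonical fragment table
    for (cl in c("rRNA", "tRNA", "snRNA", "snoRNA", "mRNA", "repeat")) {
      ft <- bundle$frag_table[bundle$frag_table$class == cl, ]
      pick <- sample.int(nrow(ft), n_cat[[cl]], replace = TRUE)
      emit(ft$fragment[pick], cl, ft$ref[pick])
    }

    # unassignable sequence
    nr <- n_cat[["random"]]
    emit(random_seq(nr, sample(16:30, nr, replace = TRUE)), "random",
         sprintf("%s-rand-%06d", group, seq_len(nr)))

    stopifnot(pos == depth + 1L)

    # machine read: insert + adapter, clipped/padded to read_len
    rl <- profile$read_len
    reads <- substr(paste0(seqs, profile$adapter,
                           strrep("A", rl)), 1L, rl)

    # substitution errors over the full read
    if (profile$error_rate > 0) {
      n_err <- stats::rbinom(depth, rl, profile$error_rate)
      has <- which(n_err > 0)
      for (i in has) {
        p <- sample.int(rl, n_err[i])
        r <- strsplit(reads[i], "")[[1]]
        for (q in p) r[q] <- sample(setdiff(BASES, r[q]), 1)
        reads[i] <- paste(r, collapse = "")
      }
    }

    qual <- rep(strrep("I", rl), depth)

    # junk reads: random insert + adapter, uniformly low quality, so they
    # survive trimming and the length rule but fail the quality filter
    if (profile$junk_fraction > 0) {
      jk <- which(runif(depth) < profile$junk_fraction)
      if (length(jk)) {
        ins <- random_seq(length(jk), sample(16:30, length(jk),
                                             replace = TRUE))
        reads[jk] <- substr(paste0(ins, profile$adapter, strrep("A", rl)),
                            1L, rl)
        qual[jk] <- strrep("#", rl)
        cat_lab[jk] <- "junk"
        src_lab[jk] <- "junk"
      }
    }

    # shuffle read order so downstream code cannot rely on generation order
    ord <- sample.int(depth)
    ids <- sprintf("%s_read_%07d", group, seq_len(depth))
    truth <- data.frame(id = ids, category = cat_lab[ord],
                        source = src_lab[ord], stringsAsFactors = FALSE)
    # realized miRNA counts after junk replacement
    surviving <- truth$source[truth$category == "miRNA"]
    mirna_counts <- as.integer(table(factor(surviving,
                                            levels = names(w_mirna))))
    names(mirna_counts) <- names(w_mirna)

    structure(list(reads = data.frame(id = ids, sequence = reads[ord],
                                      quality = qual[ord],
                                      stringsAsFactors = FALSE),
                   truth = truth, mirna_counts = mirna_counts,
                   group = group, expected_mirna_weights = w_mirna),
              class = "sim_library")
  })
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("Simulated %s library: %d reads\n", x$group, nrow(x$reads)))
  print(table(x$truth$category))
  invisible(x)
}

#' Write a simulated library as FASTQ (and its truth manifest as TSV)
#'
#' @param sim a `sim_library`.
#' @param fastq output FASTQ path (Phred+33).
#' @param manifest optional TSV path for the per-read truth manifest.
#' @return invisibly, `fastq`.
#' @export
write_library <- function(sim, fastq, manifest = NULL) {
  stopifnot(inherits(sim, "sim_library"))
  dna <- Biostrings::DNAStringSet(sim$reads$sequence)
  names(dna) <- sim$reads$id
  qual <- Biostrings::BStringSet(sim$reads$quality)
  Biostrings::writeXStringSet(dna, fastq, format = "fastq",
                              qualities = qual)
  if (!is.null(manifest)) {
    write.table(sim$truth, manifest, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(fastq)
}

#' Simulate all three libraries
#'
#' Convenience wrapper running [simulate_library()] for XX, XY and YY and
#' assembling a combined truth manifest: per-read labels, per-miRNA true
#' counts per library, true DE labels and true group-exclusive sets.
#'
#' @inheritParams simulate_library
#' @return list with `libraries` (named list of `sim_library`), and `truth`:
#'   `mirna_counts` (miRNA x group matrix), `de_spec`, `exclusive_spec`.
#' @export
simulate_experiment <- function(bundle, profile) {
  libs <- lapply(GROUPS, function(g) simulate_library(bundle, profile, g))
  names(libs) <- GROUPS
  cnt <- vapply(libs, function(l) l$mirna_counts,
                integer(length(bundle$mature_mirnas)))
  rownames(cnt) <- names(bundle$mature_mirnas)
  list(libraries = libs,
       truth = list(mirna_counts = cnt,
                    de_spec = profile$de_spec,
                    exclusive_spec = profile$exclusive_spec))
}
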