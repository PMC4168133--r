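#' All near-exact substring alignments of a query against a reference set
#'
#' Ungapped scan of the full query against every position of every reference
#' sequence, accepting at most `max_mismatch` substitutions (no indels).
#' Hits are ordered by reference id (lexicographic), then offset.
#'
#' @param query nucleotide query string (>= 16 nt by small-RNA convention,
#'   not enforced below 1 nt).
#' @param refs named character vector of reference sequences.
#' @param max_mismatch maximum substitutions (default 1, the conventional
#'   small-RNA homology tolerance).
#' @return data.frame with columns `ref`, `offset` (1-based start in the
#'   reference) and `mismatches`.
#' @export
match_le1 <- function(query, refs, max_mismatch = 1L) {
  stopifnot(length(query) == 1L, nchar(query) >= 1, !is.null(names(refs)))
  ord <- order(names(refs))
  refs <- refs[ord]
  h <- cpp_match_scan(query, unname(refs), as.integer(max_mismatch))
  out <- data.frame(ref = names(refs)[h$ref_idx], offset = h$offset,
                    mismatches = h$mismatches, stringsAsFactors = FALSE)
  out[order(out$ref, out$offset), , drop = FALSE]
}

# Best hit per query (fewest mismatches, then lexicographic reference id,
# then offset). Vectorized over queries; returns NA rows for misses.
best_hit <- function(queries, refs, max_mismatch = 1L) {
  if (length(refs) == 0L || length(queries) == 0L) {
    return(data.frame(ref = rep(NA_character_, length(queries)),
                      offset = NA_integer_, mismatches = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  ord <- order(names(refs))
  refs <- refs[ord]
  h <- cpp_best_hits(as.character(queries), unname(refs),
                     as.integer(max_mismatch))
  data.frame(ref = ifelse(h$ref_idx > 0L, names(refs)[pmax(h$ref_idx, 1L)],
                          NA_character_),
             offset = h$offset, mismatches = h$mismatches,
             stringsAsFactors = FALSE)
}

#' Fold a candidate precursor and validate it as a miRNA hairpin
#'
#' Predicts a secondary structure for `sequence` and tests the canonical
#' pre-miRNA criteria: the structure must be a single stem-loop (exactly one
#' hairpin loop, no top-level multiloop), the mature sequence must lie
#' entirely within one stem arm, at least `min_duplex` of its bases must be
#' paired with the opposite arm, and the folding score must beat a
#' threshold. Two backends are available: `"rnafold"` calls the ViennaRNA
#' `RNAfold` binary (thermodynamic minimum free energy; pass threshold
#' `mfe_max` kcal/mol), `"nussinov"` uses the built-in maximum base-pairing
#' dynamic program (pass threshold: paired fraction >= `min_paired_frac`).
#' `"auto"` picks RNAfold when the binary is on the PATH.
#'
#' @param sequence candidate precursor (50-200 nt).
#' @param mature mature miRNA sequence; must be a substring of `sequence`.
#' @param backend `"auto"`, `"nussinov"` or `"rnafold"`.
#' @param mfe_max MFE pass threshold in kcal/mol (thermodynamic backend).
#' @param min_paired_frac paired-fraction pass threshold (built-in backend).
#' @param min_duplex minimum mature bases paired with the opposite arm.
#' @param min_loop minimum hairpin loop size for the built-in backend.
#' @return class `hairpin_result`: list with `structure` (dot-bracket),
#'   `score` (MFE in kcal/mol, or pair count for the built-in backend),
#'   `mature_arm` ("5p", "3p" or "spanning"), `paired_bases_in_duplex`,
#'   `passes`, `backend`.
#' @export
fold_hairpin <- function(sequence, mature,
                         backend = c("auto", "nussinov", "rnafold"),
                         mfe_max = -18, min_paired_frac = 0.55,
                         min_duplex = 14L, min_loop = 3L) {
  backend <- match.arg(backend)
  n <- nchar(sequence)
  stopifnot(n >= 50, n <= 200)
  mstart <- regexpr(mature, sequence, fixed = TRUE)
  if (mstart < 0) stopf("mature sequence is not a substring of the candidate")
  mend <- mstart + nchar(mature) - 1L
  if (backend == "auto") {
    backend <- if (nzchar(Sys.which("RNAfold"))) "rnafold" else "nussinov"
  }
  if (backend == "rnafold") {
    fr <- rnafold_structure(sequence)
    structure_db <- fr$structure
    score <- fr$mfe
    score_ok <- score <= mfe_max
  } else {
    fr <- cpp_nussinov(sequence, as.integer(min_loop))
    structure_db <- fr$structure
    score <- fr$pairs
    score_ok <- (2 * fr$pairs / n) >= min_paired_frac
  }
  pt <- pair_table(structure_db)
  # keep only helices of >= 3 stacked pairs: stray isolated pairs (common
  # in maximum-pairing structures of the random flanks) must not count as
  # extra stems when deciding whether one stem-loop predominates
  pt <- filter_short_helices(pt, min_helix = 3L)
  hp <- hairpin_loops(pt)
  single_stem <- length(hp) == 1L
  if (single_stem) {
    loop_lo <- hp[[1]][1]
    loop_hi <- hp[[1]][2]
    mature_arm <- if (mend <= loop_lo) "5p"
                  else if (mstart >= loop_hi) "3p"
                  else "spanning"
  } else {
    mature_arm <- "spanning"
    loop_lo <- loop_hi <- NA_integer_
  }
  span <- mstart:mend
  partners <- pt[span]
  if (single_stem && mature_arm == "5p") {
    duplex <- sum(partners > 0 & partners >= loop_hi)
  } else if (single_stem && mature_arm == "3p") {
    duplex <- sum(partners > 0 & partners <= loop_lo)
  } else {
    duplex <- sum(partners > 0)
  }
  passes <- single_stem && mature_arm %in% c("5p", "3p") &&
    duplex >= min_duplex && score_ok
  structure(list(structure = structure_db, score = score,
                 mature_arm = mature_arm,
                 paired_bases_in_duplex = as.integer(duplex),
                 passes = passes, backend = backend),
            class = "hairpin_result")
}

#' @export
print.hairpin_result <- function(x, ...) {
  cat(sprintf("Hairpin (%s backend): %s\n", x$backend,
              if (x$passes) "PASS" else "fail"))
  cat(sprintf("  mature arm %s, %d bases in duplex, score %.2f\n",
              x$mature_arm, x$paired_bases_in_duplex, x$score))
  cat(" ", x$structure, "\n")
  invisible(x)
}

# partner index per position (0 = unpaired) from a dot-bracket string
pair_table <- function(db) {
  ch <- strsplit(db, "")[[1]]
  n <- length(ch)
  pt <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stopf("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stopf("unbalanced dot-bracket string")
  pt
}

# drop pairs belonging to helices (runs of stacked pairs (i,j),(i+1,j-1),...)
# shorter than min_helix
filter_short_helices <- function(pt, min_helix = 3L) {
  n <- length(pt)
  out <- pt
  i <- 1L
  while (i <= n) {
    j <- pt[i]
    if (j > i) {
      # walk the stacked run starting at (i, j)
      len <- 1L
      while (i + len <= n && pt[i + len] == j - len && j - len > i + len) {
        len <- len + 1L
      }
      if (len < min_helix) {
        for (k in 0:(len - 1L)) {
          out[i + k] <- 0L
          out[j - k] <- 0L
        }
      }
      i <- i + len
    } else {
      i <- i + 1L
    }
  }
  out
}

# hairpin loops: pairs (i,j) with no pair strictly inside; returns list of
# c(i, j)
hairpin_loops <- function(pt) {
  loops <- list()
  n <- length(pt)
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j > i) {
      inside <- if (j - i > 1) pt[(i + 1):(j - 1)] else integer(0)
      if (!any(inside > 0)) loops[[length(loops) + 1L]] <- c(i, j)
    }
  }
  loops
}

# Call the ViennaRNA RNAfold binary for an MFE structure.
rnafold_structure <- function(sequence) {
  out <- system2("RNAfold", c("--noPS"), input = sequence, stdout = TRUE)
  line <- out[2]
  db <- sub("^([.()]+).*$", "\\1", line)
  mfe <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
  list(structure = db, mfe = mfe)
}

#' Ungapped Karlin-Altschul E-value
#'
#' E = K * m * n * exp(-lambda * S) with S = matches * s_match +
#' mismatches * s_mismatch; lambda is the positive root of
#' sum_ij p_i p_j exp(lambda * s_ij) = 1 on uniform base composition
#' (lambda ~ 1.3401 for the default +1/-2 scoring).
#'
#' @param matches,mismatches aligned match / mismatch counts.
#' @param m query length; `n` total database length (nt).
#' @param n database length.
#' @param s_match,s_mismatch scoring (default +1/-2).
#' @param K Karlin-Altschul proportionality constant (0.1, a typical
#'   ungapped value).
#' @return the E-value (numeric).
#' @export
ka_evalue <- function(matches, mismatches, m, n, s_match = 1,
                      s_mismatch = -2, K = 0.1) {
  lam <- ka_lambda(s_match, s_mismatch)
  S <- matches * s_match + mismatches * s_mismatch
  K * m * n * exp(-lam * S)
}

#' @rdname ka_evalue
#' @export
ka_lambda <- function(s_match = 1, s_mismatch = -2) {
  key <- sprintf("%.10g_%.10g", s_match, s_mismatch)
  cached <- .lambda_cache[[key]]
  if (!is.null(cached)) return(cached)
  f <- function(l) 0.25 * exp(l * s_match) + 0.75 * exp(l * s_mismatch) - 1
  lam <- uniroot(f, c(1e-6, 10), tol = 1e-12)$root
  .lambda_cache[[key]] <- lam
  lam
}
.lambda_cache <- new.env(parent = emptyenv())

#' piRNA homology search with E-value filter
#'
#' Finds the best <= `max_mismatch` ungapped alignment of the tag against the
#' piRNA set and accepts it iff its Karlin-Altschul E-value (database length
#' = total piRNA set length) is below `evalue_max`.
#'
#' @param tag tag sequence (screened after the miRNA steps of the cascade).
#' @param pirnas named character vector of piRNA sequences.
#' @param max_mismatch maximum substitutions (default 1).
#' @param evalue_max E-value acceptance threshold (default 1e-4).
#' @param ... passed to [ka_evalue()] (`s_match`, `s_mismatch`, `K`).
#' @return `NULL` if no acceptable hit; otherwise list with `ref`,
#'   `mismatches`, `evalue`.
#' @export
pirna_homology <- function(tag, pirnas, max_mismatch = 1L,
                           evalue_max = 1e-4, ...) {
  h <- best_hit(tag, pirnas, max_mismatch)
  if (is.na(h$ref[1])) return(NULL)
  m <- nchar(tag)
  ev <- ka_evalue(m - h$mismatches[1], h$mismatches[1], m,
                  sum(nchar(pirnas)), ...)
  if (ev >= evalue_max) return(NULL)
  list(ref = h$ref[1], mismatches = h$mismatches[1], evalue = ev)
}

#' Classify unique tags through the sequential annotation cascade
#'
#' Applies the cascade in fixed priority order. (1) Known-RNA removal: exact
#' match (configurable mismatch tolerance) against mRNA, rRNA, tRNA, snRNA,
#' snoRNA and repeat references, first matching class wins. (2) Conserved
#' miRNA: tag matches a mature miRNA with <= 1 mismatch; if the hit's
#' precursor occurs in the genome the tag is `conserved_miRNA_genome`;
#' otherwise, if the tag itself maps to the genome and its extended genomic
#' context folds into a valid hairpin it is `conserved_miRNA_hairpin`.
#' (3) Novel miRNA: no mature hit, but the tag maps to the genome (exact,
#' either strand) and a flanking window (default 70 nt, both sides tried)
#' passes [fold_hairpin()]. (4) piRNA homology via [pirna_homology()].
#' (5) `nohit`.
#'
#' @param tags character vector of unique tag sequences.
#' @param bundle a `ref_bundle`.
#' @param removal_mismatch mismatch tolerance for the known-RNA removal
#'   steps (default 0, exact).
#' @param mirna_mismatch mismatch tolerance against mature miRNAs
#'   (default 1).
#' @param flank flank size (nt) for novel-miRNA candidate windows.
#' @param backend folding backend passed to [fold_hairpin()].
#' @param evalue_max piRNA homology E-value threshold.
#' @return data.frame (one row per tag): `sequence`, `category`, `best_hit`,
#'   `mismatches`, `evalue`.
#' @export
classify_cascade <- function(tags, bundle, removal_mismatch = 0L,
                             mirna_mismatch = 1L, flank = 70L,
                             backend = "auto", evalue_max = 1e-4) {
  stopifnot(inherits(bundle, "ref_bundle"))
  n <- length(tags)
  category <- rep(NA_character_, n)
  hit <- rep(NA_character_, n)
  mism <- rep(NA_integer_, n)
  eval_ <- rep(NA_real_, n)

  removal_sets <- list(
    mRNA = bundle$mrna_frags, rRNA = bundle$ncrna$rRNA,
    tRNA = bundle$ncrna$tRNA, snRNA = bundle$ncrna$snRNA,
    snoRNA = bundle$ncrna$snoRNA, "repeat" = bundle$repeats)

  todo <- seq_len(n)
  for (cl in REMOVAL_CLASSES) {
    if (!length(todo)) break
    h <- best_hit(tags[todo], removal_sets[[cl]], removal_mismatch)
    got <- !is.na(h$ref)
    idx <- todo[got]
    category[idx] <- cl
    hit[idx] <- h$ref[got]
    mism[idx] <- h$mismatches[got]
    todo <- todo[!got]
  }

  # genome (both strands) used by the miRNA steps
  genome_fwd <- bundle$genome
  genome_rev <- revcomp(bundle$genome)
  names(genome_rev) <- paste0(names(bundle$genome), "_rc")
  genome_both <- c(genome_fwd, genome_rev)

  # which precursors occur in the genome (exact)
  prec_in_genome <- vapply(bundle$precursors, function(p)
    any(vapply(genome_both, function(g)
      grepl(p, g, fixed = TRUE), logical(1))), logical(1))

  if (length(todo)) {
    h <- best_hit(tags[todo], bundle$mature_mirnas, mirna_mismatch)
    got <- which(!is.na(h$ref))
    for (k in got) {
      i <- todo[k]
      id <- h$ref[k]
      if (isTRUE(prec_in_genome[[id]])) {
        category[i] <- "conserved_miRNA_genome"
        hit[i] <- id
        mism[i] <- h$mismatches[k]
      } else {
        # precursor absent from genome: require the tag's own genomic
        # context to fold
        win <- genome_windows(tags[i], genome_both, flank)
        ok <- FALSE
        for (w in win) {
          fh <- try(fold_hairpin(w, tags[i], backend = backend),
                    silent = TRUE)
          if (!inherits(fh, "try-error") && fh$passes) { ok <- TRUE; break }
        }
        if (ok) {
          category[i] <- "conserved_miRNA_hairpin"
          hit[i] <- id
          mism[i] <- h$mismatches[k]
        }
      }
    }
    todo <- todo[is.na(category[todo])]
  }

  # novel miRNA: exact genome hit + folding flank window
  if (length(todo)) {
    for (i in todo) {
      win <- genome_windows(tags[i], genome_both, flank)
      if (!length(win)) next
      for (w in win) {
        fh <- try(fold_hairpin(w, tags[i], backend = backend),
                  silent = TRUE)
        if (!inherits(fh, "try-error") && fh$passes) {
          category[i] <- "novel_miRNA"
          hit[i] <- attr(win, "locus")
          break
        }
      }
    }
    todo <- todo[is.na(category[todo])]
  }

  # piRNA homology on the remainder
  if (length(todo)) {
    h <- best_hit(tags[todo], bundle$pirnas, 1L)
    got <- which(!is.na(h$ref))
    db_len <- sum(nchar(bundle$pirnas))
    for (k in got) {
      i <- todo[k]
      m <- nchar(tags[i])
      ev <- ka_evalue(m - h$mismatches[k], h$mismatches[k], m, db_len)
      if (ev < evalue_max) {
        category[i] <- "piRNA_homolog"
        hit[i] <- h$ref[k]
        mism[i] <- h$mismatches[k]
        eval_[i] <- ev
      }
    }
    todo <- todo[is.na(category[todo])]
  }

  category[todo] <- "nohit"
  data.frame(sequence = tags, category = category, best_hit = hit,
             mismatches = mism, evalue = eval_, stringsAsFactors = FALSE)
}

# Candidate precursor windows around the tag's exact genomic loci: the tag
# plus `flank` nt on one side (and a short pad on the other), both
# orientations of extension tried. Returns character vector (possibly
# empty) with attribute "locus" describing the first locus.
genome_windows <- function(tag, genome_both, flank, pad = 15L) {
  wins <- character(0)
  locus <- NA_character_
  for (g in names(genome_both)) {
    st <- regexpr(tag, genome_both[[g]], fixed = TRUE)
    if (st < 0) next
    en <- st + nchar(tag) - 1L
    L <- nchar(genome_both[[g]])
    if (is.na(locus)) locus <- sprintf("%s:%d-%d", g, st, en)
    left <- substr(genome_both[[g]], max(1L, st - flank), min(L, en + pad))
    right <- substr(genome_both[[g]], max(1L, st - pad), min(L, en + flank))
    for (w in c(left, right)) {
      if (nchar(w) >= 50 && nchar(w) <= 200) wins <- c(wins, w)
    }
  }
  attr(wins, "locus") <- locus
  wins
}

#' Per-category tag and read counts for an annotation table
#'
#' @param annotation output of [classify_cascade()].
#' @param tags tag table from [collapse_tags()] aligned to `annotation` by
#'   sequence.
#' @return data.frame: `category`, `n_tags`, and one `reads_<lib>` column per
#'   library.
#' @export
annotation_summary <- function(annotation, tags) {
  stopifnot(identical(annotation$sequence, tags$sequence))
  cc <- grep("^count_", names(tags), value = TRUE)
  cats <- unique(annotation$category)
  out <- data.frame(category = cats, stringsAsFactors = FALSE)
  out$n_tags <- vapply(cats, function(cl)
    sum(annotation$category == cl), integer(1))
  for (col in cc) {
    out[[sub("^count_", "reads_", col)]] <- vapply(cats, function(cl)
      sum(tags[[col]][annotation$category == cl]), integer(1))
  }
  out[order(-out$n_tags), , drop = FALSE]
}
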