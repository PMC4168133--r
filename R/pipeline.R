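#' Build the miRNA expression matrix from annotated tags
#'
#' Tags classified as conserved miRNAs are aggregated under their mature
#' miRNA id; novel miRNA tags get stable `novel-NNN` ids (assigned in
#' lexicographic sequence order). Counts are summed per id and library.
#'
#' @param annotation output of [classify_cascade()].
#' @param tags matching tag table from [collapse_tags()].
#' @param norm_total `"mirna"` (normalize to summed miRNA counts, the
#'   default) or `"clean"` (normalize to the library's clean-read total).
#' @return an `expression_matrix` (see [normalize_expression()]).
#' @export
expression_from_annotation <- function(annotation, tags,
                                       norm_total = c("mirna", "clean")) {
  norm_total <- match.arg(norm_total)
  stopifnot(identical(annotation$sequence, tags$sequence))
  is_cons <- annotation$category %in%
    c("conserved_miRNA_genome", "conserved_miRNA_hairpin")
  is_nov <- annotation$category == "novel_miRNA"
  id <- rep(NA_character_, nrow(tags))
  id[is_cons] <- annotation$best_hit[is_cons]
  nov_seq <- sort(annotation$sequence[is_nov])
  if (length(nov_seq)) {
    nov_ids <- stats::setNames(sprintf("novel-%03d", seq_along(nov_seq)),
                               nov_seq)
    id[is_nov] <- nov_ids[annotation$sequence[is_nov]]
  }
  keep <- !is.na(id)
  cc <- grep("^count_", names(tags), value = TRUE)
  libs <- sub("^count_", "", cc)
  ids <- sort(unique(id[keep]))
  counts <- matrix(0L, length(ids), length(libs),
                   dimnames = list(ids, libs))
  for (j in seq_along(cc)) {
    agg <- tapply(tags[[cc[j]]][keep], id[keep], sum)
    counts[names(agg), j] <- as.integer(agg)
  }
  totals <- if (norm_total == "mirna") colSums(counts)
            else stats::setNames(as.numeric(colSums(tags[, cc, drop = FALSE])),
                                 libs)
  normalize_expression(counts, totals)
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

#' Run the full small RNA analysis pipeline
#'
#' Executes preprocess -> annotate -> differential expression -> set report
#' on either simulated libraries (config block `simulate`) or FASTQ inputs
#' (config block `fastq`, a named XX/XY/YY path map), and writes all report
#' tables plus a JSON run log under `outdir`.
#'
#' Config keys (all optional unless noted): `simulate` (list passed to
#' [generate_reference()] / [simulation_profile()]: `n_mirnas`, `n_pirnas`,
#' `n_ncrna_per_class`, `genome_len`, `depth`, `error_rate`,
#' `junk_fraction`, plus `de_spec` / `exclusive_spec`) or `fastq` (+
#' `reference` unsupported for external FASTA in this release —
#' simulated-bundle runs only), `adapter`, `alpha`, `lfc`, `policy`,
#' `norm_total`, `seed`, `outdir` (required unless `write = FALSE`).
#'
#' @param config list or YAML file path.
#' @param write write report files (default TRUE; requires `outdir`).
#' @return (invisibly) list with `tags`, `stats`, `profiles`, `annotation`,
#'   `summary`, `expression`, `de` (named list per pair), `venn`,
#'   `cluster`, `scatter`, `truth` (when simulated), `files`.
#' @export
run_pipeline <- function(config, write = TRUE) {
  cfg <- read_pipeline_config(config)
  seed <- cfg$seed %||% 1L
  adapter <- cfg$adapter %||% "TGGAATTCTCGGGTGCCAAGG"
  outdir <- cfg$outdir
  if (write && is.null(outdir)) stopf("config must name an outdir")

  stage <- "simulate"
  res <- tryCatch({
    truth <- NULL
    bundle <- NULL
    if (!is.null(cfg$simulate)) {
      s <- cfg$simulate
      bundle <- generate_reference(
        n_mirnas = s$n_mirnas %||% 50,
        n_pirnas = s$n_pirnas %||% 300,
        n_ncrna_per_class = s$n_ncrna_per_class %||% 10,
        genome_len = s$genome_len %||% 20000,
        seed = seed)
      de_spec <- s$de_spec
      if (!is.null(de_spec) && !is.data.frame(de_spec))
        de_spec <- do.call(rbind, lapply(de_spec, as.data.frame))
      profile <- simulation_profile(
        depth = s$depth %||% 1e5,
        de_spec = de_spec,
        exclusive_spec = s$exclusive_spec,
        adapter = adapter,
        error_rate = s$error_rate %||% 0.005,
        junk_fraction = s$junk_fraction %||% 0.02,
        seed = seed)
      expt <- simulate_experiment(bundle, profile)
      inputs <- expt$libraries
      truth <- expt$truth
    } else if (!is.null(cfg$fastq)) {
      stage <- "preprocess"
      missing <- !file.exists(unlist(cfg$fastq))
      if (any(missing))
        stopf("FASTQ input not found: %s",
              paste(unlist(cfg$fastq)[missing], collapse = ", "))
      if (is.null(cfg$bundle))
        stopf("FASTQ input requires a reference bundle (cfg$bundle)")
      bundle <- cfg$bundle
      inputs <- cfg$fastq
    } else stopf("config must contain a 'simulate' or 'fastq' block")

    stage <- "preprocess"
    pp <- preprocess_fastq(inputs, adapter = adapter)

    stage <- "annotate"
    ann <- classify_cascade(pp$tags$sequence, bundle,
                            backend = cfg$backend %||% "auto")
    summ <- annotation_summary(ann, pp$tags)

    stage <- "destats"
    em <- expression_from_annotation(ann, pp$tags,
                                     norm_total = cfg$norm_total %||% "mirna")
    pairs <- list(c("XY", "XX"), c("YY", "XX"), c("XY", "YY"))
    de <- lapply(pairs, function(p)
      call_de(em, p, alpha = cfg$alpha %||% 0.05, lfc = cfg$lfc %||% 1.0,
              policy = cfg$policy %||% "ac"))
    names(de) <- vapply(pairs, paste, character(1), collapse = "_vs_")
    scatter <- lapply(pairs, function(p) plot_values(em, p))
    names(scatter) <- names(de)

    stage <- "setrep"
    detected <- lapply(GROUPS, function(g)
      rownames(em$ne)[em$ne[, g] > 0])
    names(detected) <- GROUPS
    venn <- venn_partition(detected$XX, detected$XY, detected$YY)
    de_xy_yy <- de[["XY_vs_YY"]]
    clu_ids <- de_xy_yy$mirna[de_xy_yy$status %in% c("up", "down")]
    if (length(clu_ids) < 2)
      clu_ids <- de_xy_yy$mirna[!is.na(de_xy_yy$p_adjusted)]
    clu <- if (length(clu_ids) >= 2) cluster_order(em, clu_ids) else NULL

    list(tags = pp$tags, stats = pp$stats, profiles = pp$profiles,
         annotation = ann, summary = summ, expression = em, de = de,
         venn = venn, cluster = clu, scatter = scatter, truth = truth,
         bundle = bundle)
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })

  if (write) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    tsv <- function(x, f) {
      p <- file.path(outdir, f)
      write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    files <- c(
      tsv(res$tags, "tags.tsv"),
      tsv(res$annotation, "annotation.tsv"),
      tsv(res$summary, "annotation_summary.tsv"),
      tsv(data.frame(mirna = rownames(res$expression$counts),
                     res$expression$counts, ne = res$expression$ne,
                     check.names = FALSE), "expression.tsv"))
    for (nm in names(res$de))
      files <- c(files, tsv(res$de[[nm]], sprintf("de_%s.tsv", nm)))
    for (nm in names(res$scatter))
      files <- c(files, tsv(res$scatter[[nm]], sprintf("scatter_%s.tsv", nm)))
    files <- c(files, tsv(data.frame(region = names(res$venn$regions),
                                     count = as.integer(res$venn$regions),
                                     pct_of_union = res$venn$percentages),
                          "venn.tsv"))
    if (!is.null(res$cluster))
      files <- c(files, tsv(data.frame(order = res$cluster$order),
                            "cluster_order.tsv"))
    log <- list(package = "gonomiR",
                version = as.character(utils::packageVersion("gonomiR")),
                r_version = R.version.string,
                seed = seed,
                adapter = adapter,
                parameters = list(alpha = cfg$alpha %||% 0.05,
                                  lfc = cfg$lfc %||% 1.0,
                                  policy = cfg$policy %||% "ac",
                                  norm_total = cfg$norm_total %||% "mirna"),
                filter_stats = res$stats)
    jf <- file.path(outdir, "run_log.json")
    jsonlite::write_json(log, jf, auto_unbox = TRUE, pretty = TRUE)
    res$files <- c(files, jf)
  }
  invisible(res)
}
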