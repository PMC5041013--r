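.log_info <- function(..., quiet = FALSE) {
  if (!quiet) message("[bipyrimidine] ", ...)
}

# Every run directory records its resolved configuration, seed and package
# version; no timestamps, so reruns are byte-identical (reproducibility
# contract).
.write_run_config <- function(out_dir, command, params, seed = NULL) {
  cfg <- list(
    command = command,
    package = "bipyrimidine",
    version = as.character(utils::packageVersion("bipyrimidine")),
    seed = seed,
    params = params
  )
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cfg)
}

.as_scores <- function(scores) {
  if (is.character(scores) && length(scores) == 1L) read_scores_tsv(scores)
  else as.data.frame(scores)
}

#' Simulate grouped synthetic genome collections to disk
#'
#' Runs [simulate_group()] for every row of a group-specification table,
#' writes one FASTA file per genome plus a manifest TSV and the resolved
#' configuration. Group seeds are split deterministically from `seed`.
#'
#' @param specs Group specification: a data.frame like
#'   [reference_group_specs()] (columns `group_label`, `n_genomes`,
#'   `gc_mean_percent`, `gc_sd_percent`, `length_min`, `length_max`), or a
#'   path to a JSON file holding the same fields.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param quiet Suppress progress messages?
#' @return Invisibly, the manifest data.frame (`genome_label`,
#'   `group_label`, `path`, `target_gc_percent`, `length_bases`, `seed`).
#' @export
run_simulate <- function(specs, out_dir, seed, quiet = FALSE) {
  if (is.character(specs) && length(specs) == 1L) {
    specs <- as.data.frame(jsonlite::read_json(specs, simplifyVector = TRUE))
  }
  specs <- as.data.frame(specs)
  needed <- c("group_label", "n_genomes", "gc_mean_percent", "gc_sd_percent",
              "length_min", "length_max")
  miss <- setdiff(needed, names(specs))
  if (length(miss) > 0L) {
    stop("group spec is missing field(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(specs) == 0L) stop("group spec has no rows")
  if (any(specs$n_genomes < 1L)) {
    stop("invalid n_genomes for group(s): ",
         paste(specs$group_label[specs$n_genomes < 1L], collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  group_seeds <- .with_seed(
    seed, sample.int(.Machine$integer.max, nrow(specs), replace = TRUE)
  )
  manifests <- vector("list", nrow(specs))
  for (g in seq_len(nrow(specs))) {
    sp <- specs[g, ]
    sim <- simulate_group(
      group_label = sp$group_label, n_genomes = sp$n_genomes,
      gc_mean_percent = sp$gc_mean_percent, gc_sd_percent = sp$gc_sd_percent,
      length_range = c(sp$length_min, sp$length_max), seed = group_seeds[g]
    )
    paths <- file.path(out_dir, paste0(sim$manifest$genome_label, ".fasta"))
    for (i in seq_along(paths)) {
      write_fasta(sim$records[i], paths[i])
    }
    m <- sim$manifest
    m$path <- paths
    manifests[[g]] <- m[, c("genome_label", "group_label", "path",
                            "target_gc_percent", "length_bases", "seed")]
    .log_info("simulated group ", sp$group_label, ": ", sp$n_genomes,
              " genomes", quiet = quiet)
  }
  manifest <- do.call(rbind, manifests)
  mf <- manifest
  # store paths relative to the manifest's own directory so reruns into
  # different directories are byte-identical; run_score resolves them
  mf$path <- basename(mf$path)
  mf$target_gc_percent <- signif(mf$target_gc_percent, 6)
  utils::write.table(mf, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .write_run_config(out_dir, "simulate",
                    list(groups = specs), seed = seed)
  invisible(manifest)
}

#' Score genomes from FASTA files or a manifest
#'
#' Computes the per-genome dinucleotide counts, bipyrimidine incidences and
#' P_g for each input genome (one FASTA file = one genome) and writes
#' `scores.tsv` plus the resolved configuration to `out_dir`.
#'
#' @param inputs Character vector of FASTA paths, or (with
#'   `manifest = TRUE`) the path of a manifest TSV with columns `path`,
#'   `genome_label` and optionally `group_label` (as written by
#'   [run_simulate()]).
#' @param out_dir Output directory.
#' @param manifest Treat `inputs` as a manifest path?
#' @param both_strands Count both strands? Default `FALSE`.
#' @param keep_going Continue past unreadable files? Default `FALSE`.
#' @param quiet Suppress per-genome log lines?
#' @return Invisibly, the score data.frame.
#' @export
run_score <- function(inputs, out_dir, manifest = FALSE, both_strands = FALSE,
                      keep_going = FALSE, quiet = FALSE) {
  if (length(inputs) == 0L) stop("no inputs given")
  if (manifest) {
    mf <- utils::read.delim(inputs[[1L]], sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("path", "genome_label") %in% names(mf))) {
      stop("manifest must have 'path' and 'genome_label' columns")
    }
    rel <- !file.exists(mf$path)
    if (any(rel)) { # allow paths relative to the manifest location
      mf$path[rel] <- file.path(dirname(inputs[[1L]]), basename(mf$path[rel]))
    }
    paths <- mf$path
    genome_labels <- mf$genome_label
    group_labels <- if ("group_label" %in% names(mf)) mf$group_label else NA_character_
  } else {
    paths <- inputs
    genome_labels <- NULL
    group_labels <- NA_character_
  }
  scores <- score_files(paths, group_labels = group_labels,
                        genome_labels = genome_labels,
                        both_strands = both_strands, keep_going = keep_going)
  if (!quiet) {
    for (i in seq_len(nrow(scores))) {
      .log_info(sprintf("%s: %d bases, P_g = %.6g", scores$genome_label[i],
                        scores$total_length_bases[i], scores$pg[i]))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_scores_tsv(scores, file.path(out_dir, "scores.tsv"))
  .write_run_config(out_dir, "score",
                    list(inputs = inputs, manifest = manifest,
                         both_strands = both_strands, keep_going = keep_going))
  invisible(scores)
}

#' Group comparison stage: summaries, ANOVA and Tukey contrasts
#'
#' For each metric (G+C percent, the four bipyrimidine incidences and P_g)
#' present in the score table, writes per-group summaries
#' (mean/median/1.96-SE half-width) and, when at least two groups are
#' present, the one-way ANOVA with all pairwise Tukey HSD contrasts.
#'
#' @param scores Score data.frame or path of a `scores.tsv` (needs a
#'   `group_label` column).
#' @param out_dir Output directory (`summary.tsv`, `anova.tsv`,
#'   `pairwise.tsv`).
#' @param metrics Metric columns to analyse; defaults to those present
#'   among `gc_percent`, `tc_i`, `tt_i`, `ct_i`, `cc_i`, `pg`.
#' @param summary_only Allow a single group and write summaries only?
#' @param quiet Suppress log lines?
#' @return Invisibly, list with `summary`, `anova` and `pairwise`
#'   data.frames (the latter two `NULL` in summary-only mode).
#' @export
run_compare <- function(scores, out_dir,
                        metrics = c("gc_percent", "tc_i", "tt_i", "ct_i",
                                    "cc_i", "pg"),
                        summary_only = FALSE, quiet = FALSE) {
  scores <- .as_scores(scores)
  if (!"group_label" %in% names(scores)) {
    stop("score table has no 'group_label' column")
  }
  metrics <- intersect(metrics, names(scores))
  if (length(metrics) == 0L) stop("none of the requested metrics is present")
  groups <- unique(scores$group_label)
  if (length(groups) < 2L && !summary_only) {
    stop("need at least 2 groups for comparison (use summary_only = TRUE ",
         "for a single group)")
  }
  summaries <- do.call(rbind, lapply(metrics, function(m) {
    s <- do.call(rbind, lapply(groups, function(g) {
      summarize_group(scores[[m]][scores$group_label == g], g)
    }))
    cbind(metric = m, s)
  }))
  anova_rows <- pairwise_rows <- NULL
  if (length(groups) >= 2L) {
    res <- lapply(metrics, function(m) {
      a <- anova_tukey(scores[[m]], scores$group_label)
      list(
        anova = data.frame(metric = m, f_statistic = a$f_statistic,
                           df_between = a$df_between, df_within = a$df_within,
                           p_value = a$p_value, stringsAsFactors = FALSE),
        pairwise = cbind(metric = m, a$pairwise)
      )
    })
    anova_rows <- do.call(rbind, lapply(res, `[[`, "anova"))
    pairwise_rows <- do.call(rbind, lapply(res, `[[`, "pairwise"))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .tsv <- function(d, f) {
    num <- vapply(d, is.double, logical(1L))
    d[num] <- lapply(d[num], function(x) signif(x, 6))
    utils::write.table(d, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  .tsv(summaries, "summary.tsv")
  if (!is.null(anova_rows)) {
    .tsv(anova_rows, "anova.tsv")
    .tsv(pairwise_rows, "pairwise.tsv")
  }
  .write_run_config(out_dir, "compare",
                    list(metrics = metrics, summary_only = summary_only,
                         n_groups = length(groups)))
  .log_info("compared ", length(groups), " group(s) on ",
            length(metrics), " metric(s)", quiet = quiet)
  invisible(list(summary = summaries, anova = anova_rows,
                 pairwise = pairwise_rows))
}

#' Regression stage: P_g versus G+C content
#'
#' Fits [regress_pg_gc()] on a score table and writes the fit as JSON plus a
#' plot-ready scatter TSV (`gc_percent`, `pg`, `group_label`).
#'
#' @param scores Score data.frame or path of a `scores.tsv`.
#' @param out_dir Output directory (`regression.json`, `scatter.tsv`).
#' @param quiet Suppress log lines?
#' @return Invisibly, the `pg_regression` fit.
#' @export
run_regress <- function(scores, out_dir, quiet = FALSE) {
  scores <- .as_scores(scores)
  if (!all(c("gc_percent", "pg") %in% names(scores))) {
    stop("score table needs 'gc_percent' and 'pg' columns")
  }
  fit <- regress_pg_gc(scores$gc_percent, scores$pg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(slope = fit$slope, intercept = fit$intercept,
         r_squared = fit$r_squared, pearson_r = fit$pearson_r,
         p_value = fit$p_value, n_points = fit$n_points),
    file.path(out_dir, "regression.json"), auto_unbox = TRUE, digits = NA
  )
  scatter <- data.frame(
    gc_percent = signif(scores$gc_percent, 6), pg = signif(scores$pg, 6),
    group_label = if ("group_label" %in% names(scores)) scores$group_label else NA,
    stringsAsFactors = FALSE
  )
  utils::write.table(scatter, file.path(out_dir, "scatter.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .write_run_config(out_dir, "regress", list(n_points = fit$n_points))
  .log_info(sprintf("regression: slope = %.4g, R^2 = %.4f", fit$slope,
                    fit$r_squared), quiet = quiet)
  invisible(fit)
}
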