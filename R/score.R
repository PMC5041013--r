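#' Score one genome
#'
#' Runs the full per-genome pipeline -- aggregate dinucleotide counts across
#' records, derive bipyrimidine incidences and G+C content, compute P_g --
#' and returns a one-row data frame in the interchange layout used by
#' [run_score()] and the statistics stage.
#'
#' With `both_strands = TRUE` the reverse complement of every record is
#' counted as an additional record (doubling the length denominator), so the
#' incidences average the two strands. The default counts the given strand
#' only, 5' to 3': the score takes directional incidences (TC differs from
#' CT) and the reference analyses all use single-strand counting.
#'
#' @param records Character vector of residue strings (the records of one
#'   genome, e.g. from [read_fasta()]).
#' @param genome_label Genome identifier; defaults to the first record name.
#' @param group_label Optional sample-group label.
#' @param both_strands Count both strands? Default `FALSE`.
#' @return A one-row data.frame with columns `genome_label`, `group_label`,
#'   `record_count`, `total_length_bases`, `A`, `C`, `G`, `T`, `ambiguous`,
#'   the 16 dinucleotide counts `AA`..`TT`, `tc_i`, `tt_i`, `ct_i`, `cc_i`,
#'   `gc_percent`, `pg`.
#' @examples
#' score_genome(c(g = "TTCC"))$pg # 0.8275
#' @export
score_genome <- function(records, genome_label = NULL, group_label = NA_character_,
                         both_strands = FALSE) {
  if (isTRUE(both_strands)) {
    fwd_names <- names(records)
    rc <- reverse_complement(records)
    names(rc) <- if (is.null(fwd_names)) NULL else paste0(fwd_names, "_rc")
    if (is.null(genome_label) && !is.null(fwd_names)) genome_label <- fwd_names[1L]
    records <- c(records, rc)
  }
  counts <- aggregate_genome(records, genome_label = genome_label)
  inc <- incidences(counts)
  score <- photoreactivity(inc, genome_label = counts$genome_label,
                           group_label = group_label)
  row <- data.frame(
    genome_label = counts$genome_label,
    group_label = group_label,
    record_count = counts$record_count,
    total_length_bases = counts$total_length_bases,
    stringsAsFactors = FALSE
  )
  row <- cbind(
    row,
    as.data.frame(as.list(counts$base_counts)),
    ambiguous = counts$ambiguous_base_count,
    as.data.frame(as.list(counts$dinucleotide_counts)),
    tc_i = inc$tc_i, tt_i = inc$tt_i, ct_i = inc$ct_i, cc_i = inc$cc_i,
    gc_percent = inc$gc_percent,
    pg = score$pg
  )
  rownames(row) <- NULL
  row
}

#' Score a collection of FASTA genome files
#'
#' One genome per FASTA file; all records inside a file are aggregated as one
#' genome (chromosome plus plasmids). The genome label defaults to the file
#' name without extension.
#'
#' @param paths Character vector of FASTA paths.
#' @param group_labels Optional character vector of group labels, recycled to
#'   `length(paths)`.
#' @param genome_labels Optional character vector of genome labels.
#' @param both_strands Count both strands? Default `FALSE`.
#' @param keep_going Continue past unreadable files (with a warning) instead
#'   of stopping? Default `FALSE`.
#' @return data.frame with one row per genome (see [score_genome()]).
#' @export
score_files <- function(paths, group_labels = NA_character_,
                        genome_labels = NULL, both_strands = FALSE,
                        keep_going = FALSE) {
  if (length(paths) == 0L) stop("no input FASTA files given")
  group_labels <- rep_len(as.character(group_labels), length(paths))
  if (is.null(genome_labels)) {
    genome_labels <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(paths),
                         ignore.case = TRUE)
  }
  rows <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    res <- tryCatch(
      {
        recs <- read_fasta(paths[[i]])
        score_genome(recs, genome_label = genome_labels[[i]],
                     group_label = group_labels[[i]],
                     both_strands = both_strands)
      },
      error = function(e) {
        msg <- paste0("failed to score ", paths[[i]], ": ", conditionMessage(e))
        if (keep_going) {
          warning(msg, call. = FALSE)
          NULL
        } else {
          stop(msg, call. = FALSE)
        }
      }
    )
    rows[[i]] <- res
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) stop("no genome could be scored")
  do.call(rbind, rows)
}

#' Write a per-genome score table as TSV
#'
#' Tab-separated, header row, '.' decimal point, floats at 6 significant
#' digits; the interchange format consumed by [run_compare()] and
#' [run_regress()].
#'
#' @param scores data.frame from [score_files()] / [score_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  out <- scores
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a per-genome score table written by [write_scores_tsv()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_scores_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
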