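.BASES <- c("A", "C", "G", "T")
.DINUCS <- paste0(rep(.BASES, each = 4L), .BASES) # AA, AC, ..., TT

# byte -> base code lookup (A=1, C=2, G=3, T=4, anything else 0);
# case-insensitive so the engine does not depend on upstream normalization
.base_code <- local({
  lk <- integer(256L)
  for (ch in c("A", "C", "G", "T")) {
    code <- match(ch, c("A", "C", "G", "T"))
    lk[utf8ToInt(ch)] <- code
    lk[utf8ToInt(tolower(ch))] <- code
  }
  lk
})

.count_one <- function(residues) {
  n <- nchar(residues)
  if (n == 0L) stop("cannot count an empty sequence")
  codes <- .base_code[utf8ToInt(residues)]
  base_counts <- tabulate(codes, nbins = 4L)
  names(base_counts) <- .BASES
  dinuc <- integer(16L)
  if (n >= 2L) {
    a <- codes[-n]
    b <- codes[-1L]
    ok <- a > 0L & b > 0L
    dinuc <- tabulate((a[ok] - 1L) * 4L + b[ok], nbins = 16L)
  }
  names(dinuc) <- .DINUCS
  list(
    dinucleotide_counts = dinuc,
    base_counts = base_counts,
    ambiguous_base_count = sum(codes == 0L),
    total_length_bases = n
  )
}

#' Count overlapping dinucleotides in one sequence record
#'
#' Slides a window of width 2 (step 1) along the given strand, 5' to 3', and
#' tallies each of the 16 ordered dinucleotides. A window containing any
#' non-ACGT character contributes to no dinucleotide count; the offending
#' bases are tallied as ambiguous but still count toward the genome length.
#' The sequence is treated as linear: no window wraps from the last base to
#' the first, even for circular chromosomes (at most one lost count per
#' record, negligible at genome scale).
#'
#' @param record A single residue string (one-element character vector,
#'   optionally named with the record identifier), as returned by
#'   [read_fasta()].
#' @param genome_label Label for the resulting counts; defaults to the
#'   record's name.
#' @return A `genome_counts` object: list with `genome_label`,
#'   `dinucleotide_counts` (named integer, AA..TT in lexicographic order),
#'   `base_counts` (A/C/G/T), `ambiguous_base_count`, `total_length_bases`
#'   and `record_count`.
#' @examples
#' count_dinucleotides(c(chr = "TTCC"))
#' @export
count_dinucleotides <- function(record, genome_label = NULL) {
  if (!is.character(record) || length(record) != 1L) {
    stop("'record' must be a single residue string; see aggregate_genome() ",
         "for multi-record genomes")
  }
  if (is.null(genome_label)) {
    genome_label <- if (!is.null(names(record))) names(record) else NA_character_
  }
  out <- .count_one(record[[1L]])
  structure(
    c(list(genome_label = genome_label), out, list(record_count = 1L)),
    class = "genome_counts"
  )
}

#' Aggregate dinucleotide counts over the records of one genome
#'
#' Sums per-record counts element-wise across all records of a genome
#' (chromosome plus plasmids). No window spans a record boundary:
#' chromosome/plasmid junctions are not biological adjacency, so
#' `aggregate_genome(c("TT", "CC"))` counts no TC while
#' `count_dinucleotides("TTCC")` counts one.
#'
#' @param records Character vector of residue strings (one per record), e.g.
#'   the value of [read_fasta()].
#' @param genome_label Label for the genome; defaults to the first record's
#'   name.
#' @return A `genome_counts` object (see [count_dinucleotides()]) with
#'   `record_count = length(records)`.
#' @examples
#' aggregate_genome(c(chr = "TT", plasmid = "CC"))
#' @export
aggregate_genome <- function(records, genome_label = NULL) {
  if (!is.character(records) || length(records) == 0L) {
    stop("'records' must be a non-empty character vector of residue strings")
  }
  if (is.null(genome_label)) {
    genome_label <- if (!is.null(names(records))) names(records)[1L] else NA_character_
  }
  parts <- lapply(unname(unclass(records)), .count_one)
  structure(
    list(
      genome_label = genome_label,
      dinucleotide_counts = Reduce(`+`, lapply(parts, `[[`, "dinucleotide_counts")),
      base_counts = Reduce(`+`, lapply(parts, `[[`, "base_counts")),
      ambiguous_base_count = sum(vapply(parts, `[[`, 0L, "ambiguous_base_count")),
      total_length_bases = sum(vapply(parts, `[[`, 0L, "total_length_bases")),
      record_count = length(records)
    ),
    class = "genome_counts"
  )
}

#' @export
print.genome_counts <- function(x, ...) {
  cat("Genome dinucleotide counts")
  if (!is.na(x$genome_label)) cat(" for", sQuote(x$genome_label))
  cat("\n  records:", x$record_count,
      " length:", x$total_length_bases, "bases",
      sprintf("(%d ambiguous)\n", x$ambiguous_base_count))
  cat("  bases: ", paste(names(x$base_counts), x$base_counts,
                         sep = "=", collapse = " "), "\n")
  m <- matrix(x$dinucleotide_counts, 4L, 4L, byrow = TRUE,
              dimnames = list(first = .BASES, second = .BASES))
  print(m)
  invisible(x)
}

#' Bipyrimidine incidences and G+C content of a genome
#'
#' Normalizes the four bipyrimidine counts (TC, TT, CT, CC read 5' to 3') by
#' the genome size in bases -- the total residue count, including ambiguous
#' bases, not the number of windows. G+C content is computed over unambiguous
#' bases only, the usual convention (genome "size" includes Ns; G+C% does
#' not).
#'
#' @param counts A `genome_counts` object.
#' @return A `bipyrimidine_incidences` object: list with `tc_i`, `tt_i`,
#'   `ct_i`, `cc_i` (dimensionless fractions) and `gc_percent`.
#' @examples
#' incidences(count_dinucleotides(c(g = "TTCC")))
#' @export
incidences <- function(counts) {
  if (!inherits(counts, "genome_counts")) {
    stop("'counts' must be a genome_counts object")
  }
  L <- counts$total_length_bases
  if (L <= 0L) stop("genome has zero length")
  acgt <- sum(counts$base_counts)
  if (acgt == 0L) stop("genome has no unambiguous A/C/G/T bases")
  d <- counts$dinucleotide_counts
  structure(
    list(
      genome_label = counts$genome_label,
      tc_i = d[["TC"]] / L,
      tt_i = d[["TT"]] / L,
      ct_i = d[["CT"]] / L,
      cc_i = d[["CC"]] / L,
      gc_percent = 100 * (counts$base_counts[["G"]] + counts$base_counts[["C"]]) / acgt
    ),
    class = "bipyrimidine_incidences"
  )
}

#' @export
print.bipyrimidine_incidences <- function(x, digits = 6, ...) {
  cat(sprintf(
    "Bipyrimidine incidences: TC=%.*g TT=%.*g CT=%.*g CC=%.*g  G+C=%.2f%%\n",
    digits, x$tc_i, digits, x$tt_i, digits, x$ct_i, digits, x$cc_i,
    x$gc_percent
  ))
  invisible(x)
}

#' Reverse complement of residue strings
#'
#' Used by the optional both-strands scoring mode; handles IUPAC ambiguity
#' codes.
#'
#' @param residues Character vector of residue strings.
#' @return Character vector of reverse complements, names preserved.
#' @keywords internal
reverse_complement <- function(residues) {
  out <- vapply(
    unname(unclass(residues)),
    function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1L)
  )
  names(out) <- names(residues)
  out
}
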