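# Valid residue alphabet after normalization: DNA bases plus IUPAC ambiguity
# codes. 'U' is accepted on input and mapped to 'T'; gaps are rejected.
.valid_residues <- "ACGTNRYSWKMBDHV"

.is_gzipped <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

#' Read a FASTA genome file
#'
#' Reads a (possibly gzipped) multi-record FASTA file into a named character
#' vector of residue strings, one element per record. Sequence lines are
#' concatenated, lowercase is mapped to uppercase and `U` to `T` (DNA-only
#' downstream: RNA input must not silently produce zero T counts). Gap
#' characters `-` and `.` are rejected rather than stripped, since stripping
#' would silently change coordinates of aligned input. Gzip is detected from
#' the leading magic bytes, not the file extension.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of residues; names are record identifiers
#'   (first whitespace-delimited token of each header). The full remainder of
#'   each header is kept in the `"descriptions"` attribute. Records appear in
#'   file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("'path' must be a single file path")
  }
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  real_path <- path
  if (.is_gzipped(path)) {
    real_path <- tempfile(fileext = ".fasta")
    on.exit(unlink(real_path), add = TRUE)
    con_in <- gzfile(path, "rb")
    con_out <- file(real_path, "wb")
    while (length(chunk <- readBin(con_in, "raw", n = 1048576L)) > 0L) {
      writeBin(chunk, con_out)
    }
    close(con_in)
    close(con_out)
  }
  head_lines <- readLines(real_path, n = 50L, warn = FALSE)
  first_real <- head_lines[nzchar(trimws(head_lines))]
  if (length(first_real) == 0L || !startsWith(first_real[1L], ">")) {
    stop("not a FASTA file (no '>' header found): ", path)
  }
  set <- Biostrings::readBStringSet(real_path)
  if (length(set) == 0L) {
    stop("no records in FASTA file: ", path)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    stop("FASTA record with empty identifier in ", path)
  }
  seqs <- as.character(set)
  seqs <- gsub("[ \t\r]", "", seqs)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop(
      "FASTA record with empty sequence: ",
      paste(ids[empty], collapse = ", ")
    )
  }
  if (any(grepl("[-.]", seqs, fixed = FALSE))) {
    bad <- ids[grepl("[-.]", seqs)]
    stop(
      "gap characters ('-' or '.') are not supported (record ",
      paste(bad, collapse = ", "), "); aligned FASTA is out of scope"
    )
  }
  seqs <- chartr("U", "T", toupper(seqs))
  stray <- gsub(sprintf("[%s]", .valid_residues), "", seqs)
  if (any(nzchar(stray))) {
    bad_chars <- unique(strsplit(paste(stray, collapse = ""), "")[[1L]])
    stop(
      "invalid residue character(s) ",
      paste(dQuote(bad_chars, FALSE), collapse = ", "), " in ", path
    )
  }
  names(seqs) <- ids
  names(descs) <- ids
  attr(seqs, "descriptions") <- descs
  seqs
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: writes a named character vector of residues to a
#' FASTA file with a fixed line width. Reading the written file back
#' reproduces identifiers and residues exactly.
#'
#' @param records Named character vector of residue strings (optionally with a
#'   `"descriptions"` attribute as produced by [read_fasta()]).
#' @param path Output file path.
#' @param line_width Positive integer; residues per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 70L) {
  if (length(records) == 0L) {
    stop("'records' is empty: nothing to write")
  }
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("every record must have a non-empty identifier (names(records))")
  }
  if (any(!nzchar(records))) {
    stop("record with empty residues: ", paste(
      names(records)[!nzchar(records)],
      collapse = ", "
    ))
  }
  line_width <- as.integer(line_width)
  if (is.na(line_width) || line_width < 1L) {
    stop("'line_width' must be a positive integer")
  }
  descs <- attr(records, "descriptions")
  headers <- names(records)
  if (!is.null(descs)) {
    has_desc <- nzchar(descs[headers])
    headers[has_desc] <- paste(headers[has_desc], descs[headers][has_desc])
  }
  set <- Biostrings::BStringSet(unname(unclass(records)))
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = line_width)
  invisible(path)
}
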