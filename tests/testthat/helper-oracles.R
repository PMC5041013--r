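# Independent oracles and fixture builders, kept deliberately naive so they
# share no code path with the package internals.

BASES <- c("A", "C", "G", "T")
DINUCS <- paste0(rep(BASES, each = 4), BASES)

rand_seq <- function(n, alphabet = BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Position-by-position sliding-window scan: the brute-force counting oracle.
naive_dinuc_counts <- function(s) {
  s <- toupper(s)
  counts <- setNames(integer(16), DINUCS)
  n <- nchar(s)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      w <- substr(s, i, i + 1)
      if (w %in% DINUCS) counts[w] <- counts[w] + 1L
    }
  }
  counts
}

naive_base_counts <- function(s) {
  s <- toupper(s)
  chars <- strsplit(s, "")[[1]]
  setNames(vapply(BASES, function(b) sum(chars == b), 0L), BASES)
}

write_tmp_fasta <- function(text) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(text, path)
  path
}
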