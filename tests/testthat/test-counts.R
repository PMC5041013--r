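test_that("count_dinucleotides matches hand enumeration on fixtures", {
  gc <- count_dinucleotides(c(chr = "TTCC"))
  expect_identical(gc$genome_label, "chr")
  expect_identical(gc$dinucleotide_counts[["TT"]], 1L)
  expect_identical(gc$dinucleotide_counts[["TC"]], 1L)
  expect_identical(gc$dinucleotide_counts[["CC"]], 1L)
  expect_identical(sum(gc$dinucleotide_counts), 3L)
  expect_identical(unname(gc$base_counts), c(0L, 2L, 0L, 2L))
  expect_identical(gc$total_length_bases, 4L)
  expect_identical(gc$record_count, 1L)

  # any window touching a non-ACGT base counts toward no dinucleotide
  amb <- count_dinucleotides("TNT")
  expect_identical(sum(amb$dinucleotide_counts), 0L)
  expect_identical(amb$base_counts[["T"]], 2L)
  expect_identical(amb$ambiguous_base_count, 1L)
  expect_identical(amb$total_length_bases, 3L)

  expect_error(count_dinucleotides(""), "empty")
})

test_that("counting engine agrees with brute-force and Biostrings oracles", {
  set.seed(101)
  for (i in 1:60) {
    s <- rand_seq(sample(1:200, 1), c(BASES, "N", "a", "c", "g", "t"))
    got <- count_dinucleotides(s)
    expect_identical(got$dinucleotide_counts, naive_dinuc_counts(s))
    expect_identical(got$base_counts, naive_base_counts(s))
  }
  # independent library oracle on pure-ACGT sequences
  for (i in 1:10) {
    s <- rand_seq(sample(2:500, 1))
    got <- count_dinucleotides(s)$dinucleotide_counts
    ref <- Biostrings::dinucleotideFrequency(Biostrings::DNAString(s))
    expect_identical(as.integer(got[names(ref)]), as.integer(ref))
  }
})

test_that("pure-ACGT counts conserve: sum equals record length - 1", {
  set.seed(11)
  for (i in 1:20) {
    s <- rand_seq(sample(2:300, 1))
    expect_identical(sum(count_dinucleotides(s)$dinucleotide_counts),
                     nchar(s) - 1L)
  }
})

test_that("aggregate_genome never counts across record boundaries", {
  two <- aggregate_genome(c("TT", "CC"))
  expect_identical(two$dinucleotide_counts[["TT"]], 1L)
  expect_identical(two$dinucleotide_counts[["CC"]], 1L)
  expect_identical(two$dinucleotide_counts[["TC"]], 0L) # contrast with "TTCC"
  expect_identical(two$total_length_bases, 4L)
  expect_identical(two$record_count, 2L)

  one <- aggregate_genome(c(x = "TTACGCC"))
  expect_identical(one$dinucleotide_counts,
                   count_dinucleotides(c(x = "TTACGCC"))$dinucleotide_counts)

  # a length-1 record contributes zero windows
  frag <- aggregate_genome(c("ACG", "T"))
  expect_identical(sum(frag$dinucleotide_counts), 2L)
  expect_error(aggregate_genome(character(0)), "non-empty")
})

test_that("incidences normalize by genome size and report conventional G+C", {
  inc <- incidences(count_dinucleotides("TTCC"))
  expect_equal(inc$tt_i, 0.25)
  expect_equal(inc$tc_i, 0.25)
  expect_equal(inc$cc_i, 0.25)
  expect_equal(inc$ct_i, 0)
  expect_equal(inc$gc_percent, 50)

  g4 <- incidences(count_dinucleotides("GGGG"))
  expect_equal(g4$tc_i + g4$tt_i + g4$ct_i + g4$cc_i, 0)
  expect_equal(g4$gc_percent, 100)

  # genome size includes ambiguous bases; G+C% excludes them
  nn <- incidences(count_dinucleotides("GCNN"))
  expect_equal(nn$gc_percent, 100)
  expect_equal(nn$cc_i, 0)

  expect_error(incidences(count_dinucleotides("NNN")), "unambiguous")
})

test_that("incidences of an i.i.d. uniform sequence match the binomial expectation", {
  set.seed(5)
  L <- 1000
  inc <- incidences(count_dinucleotides(rand_seq(L)))
  p <- 1 / 16
  expected <- p * (L - 1) / L
  mc_sd <- sqrt(p * (1 - p) * (L - 1)) / L
  for (v in c(inc$tc_i, inc$tt_i, inc$ct_i, inc$cc_i)) {
    expect_lt(abs(v - expected), 5 * mc_sd)
  }
})

test_that("incidences and pg are invariant under genome duplication", {
  set.seed(21)
  for (i in 1:5) {
    recs <- vapply(1:3, function(k) rand_seq(sample(5:100, 1)), "")
    names(recs) <- paste0("r", 1:3)
    inc1 <- incidences(aggregate_genome(recs))
    half <- incidences(aggregate_genome(c(recs, recs)))
    # counts and length both double exactly, so equality is exact
    expect_identical(inc1, half)
  }
})

test_that("both-strands mode averages the two strand readings", {
  # forward TTCC: TT, TC, CC; reverse complement GGAA has no pyrimidine pair
  row <- score_genome(c(g = "TTCC"), both_strands = TRUE)
  expect_equal(row$total_length_bases, 8)
  expect_equal(row$tt_i, 1 / 8)
  expect_equal(row$tc_i, 1 / 8)
  expect_equal(row$cc_i, 1 / 8)
  expect_equal(row$gc_percent, 50)
  expect_equal(row$pg, (1.73 + 1.19 + 0.39) / 8)
})
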