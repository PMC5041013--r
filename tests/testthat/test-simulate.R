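test_that("simulate_genome honours degenerate and deterministic specs", {
  t10 <- simulate_genome(10, seed = 1, base_probs = c(A = 0, C = 0, G = 0, T = 1))
  expect_identical(unname(unclass(t10)), "TTTTTTTTTT")

  # deterministic 2-cycle chain: T -> C -> T -> ...
  P <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  P["T", "C"] <- 1; P["C", "T"] <- 1; P["A", "A"] <- 1; P["G", "G"] <- 1
  alt <- simulate_genome(4, seed = 9, transition_matrix = P,
                         initial = c(0, 0, 0, 1))
  expect_identical(unname(unclass(alt)), "TCTC")

  expect_identical(simulate_genome(500, seed = 42, gc = 0.4),
                   simulate_genome(500, seed = 42, gc = 0.4))
  expect_false(identical(simulate_genome(500, seed = 42, gc = 0.4),
                         simulate_genome(500, seed = 43, gc = 0.4)))
})

test_that("simulate_genome validates its specification", {
  expect_error(simulate_genome(1, seed = 1, gc = 0.5), ">= 2")
  expect_error(simulate_genome(10, seed = 1), "exactly one")
  expect_error(simulate_genome(10, seed = 1, gc = 0.5,
                               transition_matrix = diag(4)), "exactly one")
  expect_error(simulate_genome(10, seed = 1,
                               base_probs = c(A = 0.5, C = 0.5, G = 0.5, T = 0.5)),
               "sum to 1")
  expect_error(simulate_genome(10, seed = 1, gc = 1.2), "\\[0, 1\\]")
})

test_that("i.i.d. composition converges to the target G+C", {
  s <- simulate_genome(1e5, seed = 8, gc = 0.63)
  gc <- incidences(count_dinucleotides(s))$gc_percent
  binom_sd <- 100 * sqrt(0.63 * 0.37 / 1e5)
  expect_lt(abs(gc - 63), 3 * binom_sd)
})

test_that("markov mode recovers the specified transition frequencies", {
  P <- matrix(c(
    0.10, 0.40, 0.30, 0.20,
    0.25, 0.25, 0.25, 0.25,
    0.50, 0.10, 0.10, 0.30,
    0.20, 0.30, 0.40, 0.10
  ), 4, 4, byrow = TRUE, dimnames = list(BASES, BASES))
  s <- simulate_genome(1e5, seed = 77, transition_matrix = P)
  counts <- count_dinucleotides(s)$dinucleotide_counts
  m <- matrix(counts, 4, 4, byrow = TRUE, dimnames = list(BASES, BASES))
  row_tot <- rowSums(m)
  for (a in BASES) {
    for (b in BASES) {
      phat <- m[a, b] / row_tot[a]
      se <- sqrt(P[a, b] * (1 - P[a, b]) / row_tot[a])
      expect_lt(abs(phat - P[a, b]), 5 * se)
    }
  }
})

test_that("simulate_group is reproducible and stable under extension", {
  g1 <- simulate_group("halo", 5, 63.1, 3.5, c(1e4, 1e4), seed = 123)
  g2 <- simulate_group("halo", 5, 63.1, 3.5, c(1e4, 1e4), seed = 123)
  expect_identical(g1, g2)
  expect_identical(nrow(g1$manifest), 5L)
  expect_true(all(nchar(g1$records) == 1e4))

  # stream splitting: adding genomes never changes earlier ones
  g3 <- simulate_group("halo", 3, 63.1, 3.5, c(1e4, 1e4), seed = 123)
  expect_identical(g3$records, g1$records[1:3])

  # realized G+C mean within sampling error of the group target
  gcs <- vapply(g1$records, function(s) {
    incidences(count_dinucleotides(s))$gc_percent
  }, 0)
  expect_lt(abs(mean(gcs) - 63.1), 3 * 3.5 / sqrt(5))
})

test_that("simulate_group validates its specification", {
  expect_error(simulate_group("g", 1, 50, 2, c(100, 200), seed = 1), ">= 2")
  expect_error(simulate_group("g", 3, 10, 2, c(100, 200), seed = 1), "\\(20, 80\\)")
  expect_error(simulate_group("g", 3, 50, 2, c(200, 100), seed = 1), "increasing")
})

test_that("groups simulated at high G+C score lower than at low G+C", {
  hi <- simulate_group("hi_gc", 5, 63, 2, c(2e4, 2e4), seed = 5)
  lo <- simulate_group("lo_gc", 5, 44, 2, c(2e4, 2e4), seed = 6)
  pg_of <- function(grp) {
    vapply(grp$records, function(s) {
      photoreactivity(incidences(count_dinucleotides(s)))$pg
    }, 0)
  }
  expect_lt(mean(pg_of(hi)), mean(pg_of(lo)))
})

test_that("sample_representatives keeps exactly one strain per group", {
  tab <- data.frame(
    species = rep(c("sp1", "sp2"), c(3, 1)),
    genus = "gen1",
    strain = paste0("s", 1:4),
    path = paste0("p", 1:4),
    stringsAsFactors = FALSE
  )
  one <- sample_representatives(tab, "species", seed = 4)
  expect_identical(nrow(one), 2L)
  expect_identical(sort(unique(one$species)), c("sp1", "sp2"))
  expect_identical(one[one$species == "sp2", "strain"], "s4")

  # already unique at the level -> identity
  uni <- tab[c(1, 4), ]
  expect_identical(sample_representatives(uni, "species", seed = 9), uni)

  expect_identical(sample_representatives(tab, "genus", seed = 2) |> nrow(), 1L)
  expect_error(sample_representatives(tab[, c("strain", "path")], "species", 1),
               "not found")
  expect_identical(sample_representatives(tab, "species", seed = 11),
                   sample_representatives(tab, "species", seed = 11))
})

test_that("representative selection is uniform over strains", {
  tab <- expand.grid(strain = paste0("s", 1:4), species = paste0("sp", 1:10),
                     stringsAsFactors = FALSE)
  picks <- matrix(0L, nrow = 10, ncol = 4,
                  dimnames = list(paste0("sp", 1:10), paste0("s", 1:4)))
  n_seeds <- 500
  for (seed in seq_len(n_seeds)) {
    sel <- sample_representatives(tab, "species", seed = seed)
    for (i in seq_len(nrow(sel))) {
      picks[sel$species[i], sel$strain[i]] <- picks[sel$species[i], sel$strain[i]] + 1L
    }
  }
  freq <- picks / n_seeds
  # 10 species x 500 seeds: every strain near the uniform 0.25
  expect_true(all(abs(freq - 0.25) < 0.07))
})
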