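# Run expr with the RNG seeded to `seed`, restoring the caller's RNG state.
# `seed` is forced before the state is captured: if the caller computes it
# from the global stream (e.g. sample.int(...)), that draw must not be
# rewound by the restore.
.with_seed <- function(seed, expr) {
  force(seed)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.check_probs <- function(p, what, tol = 1e-9) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0)) {
    stop(what, " must be non-negative numeric probabilities")
  }
  if (abs(sum(p) - 1) > tol) {
    stop(what, " must sum to 1 (got ", format(sum(p)), ")")
  }
}

#' Base probabilities for a strand-symmetric i.i.d. genome
#'
#' `p(A) = p(T) = (1 - gc)/2`, `p(C) = p(G) = gc/2`: the composition model
#' with a given G+C fraction and no strand bias.
#'
#' @param gc_fraction G+C content as a fraction in \[0, 1\].
#' @return Named numeric vector over A, C, G, T.
#' @export
gc_to_probs <- function(gc_fraction) {
  if (!is.numeric(gc_fraction) || length(gc_fraction) != 1L || is.na(gc_fraction) ||
      gc_fraction < 0 || gc_fraction > 1) {
    stop("'gc_fraction' must be a single number in [0, 1]")
  }
  c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
    G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
}

#' Simulate one genome sequence
#'
#' Generates a random residue string under either an i.i.d. base model or a
#' first-order Markov chain, fully reproducible from `seed`. The i.i.d. mode
#' is the default composition model for grouped simulations (specify
#' `base_probs`, or just `gc` for the strand-symmetric model); the Markov
#' mode (`transition_matrix`) exists to generate controlled dinucleotide
#' structure that the i.i.d. model cannot express.
#'
#' @param length_bases Genome length (>= 2).
#' @param seed Integer seed; identical inputs give identical sequences.
#' @param base_probs Named probabilities over A, C, G, T (i.i.d. mode).
#' @param gc Shorthand for `base_probs = gc_to_probs(gc)`.
#' @param transition_matrix 4x4 row-stochastic matrix with rows/columns in
#'   A, C, G, T order (Markov mode).
#' @param initial Initial base distribution for Markov mode; defaults to the
#'   stationary distribution of the chain.
#' @param label Record identifier on the returned vector.
#' @return One-element named character vector (a sequence record).
#' @examples
#' simulate_genome(10, seed = 1, base_probs = c(A = 0, C = 0, G = 0, T = 1))
#' @export
simulate_genome <- function(length_bases, seed, base_probs = NULL, gc = NULL,
                            transition_matrix = NULL, initial = NULL,
                            label = "genome") {
  length_bases <- as.integer(length_bases)
  if (is.na(length_bases) || length_bases < 2L) {
    stop("'length_bases' must be an integer >= 2")
  }
  if (!is.null(gc)) {
    if (!is.null(base_probs)) stop("give either 'gc' or 'base_probs', not both")
    base_probs <- gc_to_probs(gc)
  }
  if (is.null(base_probs) == is.null(transition_matrix)) {
    stop("give exactly one of 'base_probs'/'gc' (i.i.d. mode) or ",
         "'transition_matrix' (Markov mode)")
  }
  seq <- if (!is.null(base_probs)) {
    base_probs <- base_probs[.BASES]
    .check_probs(base_probs, "'base_probs'")
    .with_seed(seed, paste(
      sample(.BASES, length_bases, replace = TRUE, prob = base_probs),
      collapse = ""
    ))
  } else {
    P <- as.matrix(transition_matrix)
    if (!identical(dim(P), c(4L, 4L))) stop("'transition_matrix' must be 4x4")
    for (i in 1:4) .check_probs(P[i, ], sprintf("transition row %d (%s)", i, .BASES[i]))
    if (is.null(initial)) {
      # stationary distribution: left eigenvector of P for eigenvalue 1
      ev <- eigen(t(P))
      k <- which.min(abs(ev$values - 1))
      v <- abs(Re(ev$vectors[, k]))
      initial <- v / sum(v)
    }
    .check_probs(initial, "'initial'")
    cum <- t(apply(P, 1L, cumsum))
    .with_seed(seed, {
      states <- integer(length_bases)
      states[1L] <- sample.int(4L, 1L, prob = initial)
      u <- stats::runif(length_bases - 1L)
      for (i in 2:length_bases) {
        states[i] <- findInterval(u[i - 1L], cum[states[i - 1L], ]) + 1L
      }
      paste(.BASES[states], collapse = "")
    })
  }
  names(seq) <- label
  seq
}

# Truncated-normal draw by rejection; bounds guard against degenerate
# compositions when group SDs are large.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0L)
  for (i in 1:1000) {
    draw <- stats::rnorm(2L * n, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("truncated-normal rejection sampling failed; check mean/sd against [",
       lower, ", ", upper, "]")
}

#' Simulate a grouped collection of genomes
#'
#' Emulates one taxonomic sample group: `n_genomes` i.i.d. strand-symmetric
#' genomes whose per-genome G+C percentages are drawn from a normal
#' distribution truncated to \[20, 80\] and whose lengths are uniform on
#' `length_range`. Each genome gets its own RNG stream derived from the group
#' seed, so enlarging `n_genomes` leaves earlier genomes unchanged.
#'
#' @param group_label Group name, used to label genomes.
#' @param n_genomes Number of genomes (>= 2; groups feed variance-based
#'   statistics).
#' @param gc_mean_percent,gc_sd_percent Mean and SD of the per-genome G+C
#'   percentage (mean must lie in (20, 80)).
#' @param length_range Inclusive integer interval of genome lengths.
#' @param seed Integer group seed.
#' @return List with `records` (named character vector of sequences) and
#'   `manifest` (data.frame: `genome_label`, `group_label`,
#'   `target_gc_percent`, `length_bases`, `seed`).
#' @export
simulate_group <- function(group_label, n_genomes, gc_mean_percent,
                           gc_sd_percent, length_range, seed) {
  n_genomes <- as.integer(n_genomes)
  if (is.na(n_genomes) || n_genomes < 2L) {
    stop("'n_genomes' must be an integer >= 2")
  }
  if (gc_mean_percent <= 20 || gc_mean_percent >= 80) {
    stop("'gc_mean_percent' must lie in (20, 80)")
  }
  if (gc_sd_percent < 0) stop("'gc_sd_percent' must be >= 0")
  length_range <- as.integer(round(length_range))
  if (length(length_range) != 2L || anyNA(length_range) ||
      length_range[1L] > length_range[2L] || length_range[1L] < 2L) {
    stop("'length_range' must be an increasing integer pair with min >= 2")
  }
  # Stream splitting: the group stream yields one sub-seed per genome, and
  # every per-genome quantity (G+C, length, sequence) is drawn from that
  # genome's own stream, so growing n_genomes never changes earlier genomes.
  genome_seeds <- .with_seed(
    seed, sample.int(.Machine$integer.max, n_genomes, replace = TRUE)
  )
  labels <- sprintf("%s_g%03d", gsub("[^A-Za-z0-9_.-]+", "_", group_label),
                    seq_len(n_genomes))
  records <- character(n_genomes)
  gc <- len <- numeric(n_genomes)
  for (i in seq_len(n_genomes)) {
    .with_seed(genome_seeds[i], {
      gc[i] <- .rtruncnorm(1L, gc_mean_percent, gc_sd_percent, 20, 80)
      len[i] <- sample.int(length_range[2L] - length_range[1L] + 1L, 1L) +
        length_range[1L] - 1L
      seq_seed <- sample.int(.Machine$integer.max, 1L)
    })
    records[i] <- simulate_genome(len[i], seed = seq_seed,
                                  gc = gc[i] / 100, label = labels[i])
  }
  names(records) <- labels
  list(
    records = records,
    manifest = data.frame(
      genome_label = labels,
      group_label = group_label,
      target_gc_percent = gc,
      length_bases = as.integer(len),
      seed = genome_seeds,
      stringsAsFactors = FALSE
    )
  )
}

#' Reference group specifications for the five taxonomic sample groups
#'
#' Desk-scale emulation targets for the five groups compared in the study:
#' group sizes and mean G+C with 1.96-standard-error half-widths as reported
#' for the NCBI samples ([gc_group_reference]), with per-group SD
#' back-derived as `halfwidth / 1.96 * sqrt(n)`. Genome lengths default to
#' 1e5--2e5 bases: long enough that incidence noise is far below intergroup
#' differences, short enough for routine desk runs (real genomes are 2--6
#' Mb; incidences are length-normalized, so the group comparison is
#' insensitive to this choice).
#'
#' @param length_range Genome-length interval applied to every group.
#' @return data.frame with columns `group_label`, `n_genomes`,
#'   `gc_mean_percent`, `gc_sd_percent`, `length_min`, `length_max`.
#' @export
reference_group_specs <- function(length_range = c(1e5, 2e5)) {
  ref <- gc_group_reference
  data.frame(
    group_label = ref$group_label,
    n_genomes = ref$n,
    gc_mean_percent = ref$gc_mean_percent,
    gc_sd_percent = ref$gc_halfwidth_196se / 1.96 * sqrt(ref$n),
    length_min = as.integer(length_range[1L]),
    length_max = as.integer(length_range[2L]),
    stringsAsFactors = FALSE
  )
}

#' Pick one representative strain per species or genus
#'
#' Bias-reduction step used when assembling genome sample groups: from a
#' table of candidate strains, keeps exactly one row per distinct value of
#' the chosen taxonomic level, selected uniformly at random and
#' reproducibly from `seed`.
#'
#' @param table data.frame with at least the grouping column (`species` or
#'   `genus`).
#' @param level Grouping column name: `"species"` or `"genus"`.
#' @param seed Integer seed.
#' @return Subset of `table` rows, one per distinct `level` value, in order
#'   of first appearance.
#' @export
sample_representatives <- function(table, level = c("species", "genus"), seed) {
  level <- match.arg(level)
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("'table' must be a non-empty data.frame")
  }
  if (!level %in% names(table)) {
    stop("grouping column ", sQuote(level), " not found in table")
  }
  keys <- as.character(table[[level]])
  groups <- split(seq_len(nrow(table)), factor(keys, levels = unique(keys)))
  picked <- .with_seed(seed, vapply(
    groups,
    function(idx) if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)],
    integer(1L)
  ))
  table[sort(unname(picked)), , drop = FALSE]
}
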