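#' Intrinsic bipyrimidine photoreactivity coefficients
#'
#' Weights applied to the four bipyrimidine incidences when computing the
#' theoretical genomic photoreactivity score \eqn{P_g}:
#' \deqn{P_g = 1.73\,TC_i + 1.19\,TT_i + 0.61\,CT_i + 0.39\,CC_i}
#' The coefficients are the experimentally determined intrinsic
#' photoreactivities of each 5'-to-3' bipyrimidine doublet (ratio of UV-B
#' photoproduct yield, CPDs plus 6-4PPs, to doublet incidence), treated here
#' as fixed constants of the score. This vector is the single configuration
#' point for the weights.
#'
#' @format Named numeric vector with elements `TC`, `TT`, `CT`, `CC`.
#' @seealso [photoreactivity()], [expected_pg_iid()]
#' @export
pg_coefficients <- c(TC = 1.73, TT = 1.19, CT = 0.61, CC = 0.39)

#' Theoretical genomic photoreactivity score
#'
#' Computes the scalar photoreactivity score \eqn{P_g} of a genome from its
#' bipyrimidine incidences: the weighted sum of the TC, TT, CT and CC
#' incidences with weights [pg_coefficients]. Because every incidence lies in
#' \eqn{[0, 1)} and sums to less than 1, \eqn{0 \le P_g < 1.73}.
#'
#' @param inc A `bipyrimidine_incidences` object from [incidences()], or a
#'   numeric vector containing elements named `tc_i`, `tt_i`, `ct_i`, `cc_i`.
#' @param genome_label Optional genome identifier carried on the result.
#' @param group_label Optional sample-group label carried on the result.
#' @return A `pg_score` object: list with `genome_label`, `group_label`,
#'   `pg` (the score) and `incidences`.
#' @examples
#' rec <- c(g = "TTCC")
#' photoreactivity(incidences(count_dinucleotides(rec)))
#' @export
photoreactivity <- function(inc, genome_label = NULL, group_label = NULL) {
  if (inherits(inc, "genome_counts")) {
    inc <- incidences(inc)
  }
  if (is.null(genome_label) && !is.null(inc$genome_label)) {
    genome_label <- inc$genome_label
  }
  v <- unlist(inc[c("tc_i", "tt_i", "ct_i", "cc_i")], use.names = FALSE)
  if (length(v) != 4L || anyNA(v)) {
    stop("'inc' must supply the four incidences tc_i, tt_i, ct_i, cc_i")
  }
  pg <- sum(pg_coefficients[c("TC", "TT", "CT", "CC")] * v)
  structure(
    list(
      genome_label = if (is.null(genome_label)) NA_character_ else genome_label,
      group_label = if (is.null(group_label)) NA_character_ else group_label,
      pg = as.numeric(pg),
      incidences = inc
    ),
    class = "pg_score"
  )
}

#' @export
print.pg_score <- function(x, digits = 6, ...) {
  cat("Theoretical genomic photoreactivity (P_g)\n")
  if (!is.na(x$genome_label)) cat("  genome:", x$genome_label, "\n")
  if (!is.na(x$group_label)) cat("  group: ", x$group_label, "\n")
  cat("  P_g =", signif(x$pg, digits), "\n")
  inc <- x$incidences
  cat(sprintf(
    "  incidences: TC=%.*g TT=%.*g CT=%.*g CC=%.*g  (G+C %.2f%%)\n",
    digits, inc$tc_i, digits, inc$tt_i, digits, inc$ct_i, digits, inc$cc_i,
    inc$gc_percent
  ))
  invisible(x)
}

#' Expected P_g of an i.i.d. strand-symmetric genome
#'
#' Closed-form expectation of the photoreactivity score for an infinitely long
#' genome whose bases are drawn independently with no strand bias: base
#' probabilities \eqn{p_T = p_A = (1-g)/2} and \eqn{p_C = p_G = g/2} where `g`
#' is the G+C fraction. Each overlapping doublet XY then has expected
#' incidence \eqn{p_X p_Y}, giving
#' \deqn{E[P_g] = 1.19\,t^2 + (1.73 + 0.61)\,t c + 0.39\,c^2,\quad
#'   t = (1-g)/2,\; c = g/2.}
#' The function is strictly decreasing in `g` on \eqn{[0, 1]} (derivative
#' \eqn{-(0.04 + 1.52 g)/4 < 0}), the idealized form of the negative
#' relationship between P_g and G+C content observed across real genomes.
#'
#' @param gc_fraction G+C content as a fraction in \eqn{[0, 1]} (vectorized).
#' @return Expected P_g, same length as `gc_fraction`.
#' @examples
#' expected_pg_iid(c(0, 0.5, 1))
#' @export
expected_pg_iid <- function(gc_fraction) {
  if (!is.numeric(gc_fraction) || anyNA(gc_fraction) ||
      any(gc_fraction < 0 | gc_fraction > 1)) {
    stop("'gc_fraction' must be numeric in [0, 1]")
  }
  t <- (1 - gc_fraction) / 2
  c <- gc_fraction / 2
  unname(pg_coefficients[["TT"]] * t^2 +
    (pg_coefficients[["TC"]] + pg_coefficients[["CT"]]) * t * c +
    pg_coefficients[["CC"]] * c^2)
}
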