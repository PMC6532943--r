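# Genetic interaction pattern classifier shared between simulated token
# profiles and experimental expression profiles. The unit of classification
# is the triple (M1, M2, O): log2 fold-changes of one gene in the two single
# mutants and the double mutant. E = M1 + M2 is the additive expectation; a
# genetic interaction exists when |O - E| exceeds the epsilon threshold, and
# the pattern class is determined by the direction calls of the three
# measurements.

#' Pattern class levels
#' @export
gi_pattern_levels <- c("none", "buffering", "quantitative_buffering",
                       "suppression", "quantitative_suppression",
                       "masking", "inversion")

#' Genetic interaction effect size
#'
#' Absolute deviation of the observed double-mutant change from the additive
#' expectation of the single mutants, on the log2 scale.
#'
#' @param M1,M2 single-mutant log2 fold-changes.
#' @param O double-mutant log2 fold-change.
#' @return `|O - (M1 + M2)|`, vectorised.
#' @export
gi_epsilon <- function(M1, M2, O) {
  stopifnot(is.finite(M1), is.finite(M2), is.finite(O))
  abs(O - (M1 + M2))
}

#' Direction calls
#'
#' Simulated profiles call a change when |M| exceeds the fold-change
#' threshold; expression profiles call a change when the adjusted p-value
#' passes the significance cutoff (the direction is the sign of M).
#'
#' @param M log2 fold-changes.
#' @param threshold fold-change threshold on |M| (default log2(1.7)).
#' @return integer vector in {-1, 0, +1}.
#' @export
direction_call <- function(M, threshold = log2(1.7)) {
  as.integer(sign(M)) * as.integer(abs(M) > threshold)
}

#' @rdname direction_call
#' @param p adjusted p-values parallel to `M`.
#' @param p_cutoff significance cutoff (default 0.01).
#' @export
direction_call_expr <- function(M, p, p_cutoff = 0.01) {
  as.integer(sign(M)) * as.integer(p <= p_cutoff)
}

#' Classify observed/expected triples into genetic interaction patterns
#'
#' Rule table, applied to genes whose effect size exceeds
#' `epsilon_threshold` (all others are `none`); d1, d2, dO are the direction
#' calls of M1, M2, O and S the shared single-mutant direction (the nonzero
#' one, or the common sign when both agree):
#'
#' * buffering: both singles unchanged, double changed (redundancy
#'   signature);
#' * suppression: at least one single changed, double restored to wild type;
#' * masking: singles changed in opposite directions and the double
#'   resembles the dominant single (within `epsilon_threshold` of the
#'   larger-|M| single);
#' * inversion: double changed in the direction opposite to S;
#' * quantitative buffering: double changed in the direction of S and
#'   stronger than the additive expectation;
#' * quantitative suppression: double changed in the direction of S but
#'   weaker than expected.
#'
#' Rules are tested in that order; anything left is `none`. The table is
#' invariant under a global sign flip of all inputs.
#'
#' @param M1,M2,O log2 fold-change triples (vectorised).
#' @param d1,d2,dO direction calls in {-1, 0, +1}; by default derived from
#'   the M values with [direction_call()] at `direction_threshold`.
#' @param epsilon_threshold minimum effect size (log2(1.7) for simulated
#'   profiles, log2(1.5) for expression data).
#' @param direction_threshold threshold for the default direction caller.
#' @return factor with [gi_pattern_levels()].
#' @examples
#' classify_gi(2.27, 0, -5.67)  # the inversion signature
#' @export
classify_gi <- function(M1, M2, O,
                        d1 = direction_call(M1, direction_threshold),
                        d2 = direction_call(M2, direction_threshold),
                        dO = direction_call(O, direction_threshold),
                        epsilon_threshold = log2(1.7),
                        direction_threshold = log2(1.7)) {
  n <- length(M1)
  stopifnot(length(M2) == n, length(O) == n,
            length(d1) == n, length(d2) == n, length(dO) == n,
            all(c(d1, d2, dO) %in% -1:1))
  E <- M1 + M2
  eligible <- gi_epsilon(M1, M2, O) > epsilon_threshold
  M_dom <- ifelse(abs(M1) >= abs(M2), M1, M2)
  S <- ifelse(d1 == 0L, d2, ifelse(d2 == 0L, d1, ifelse(d1 == d2, d1, 0L)))
  pat <- integer(n)  # 0 = none
  buf <- eligible & d1 == 0L & d2 == 0L & dO != 0L
  sup <- eligible & !buf & dO == 0L & (d1 != 0L | d2 != 0L)
  mask <- eligible & !buf & !sup &
    d1 == -d2 & d1 != 0L & dO != 0L & abs(O - M_dom) <= epsilon_threshold
  inv <- eligible & !buf & !sup & !mask & S != 0L & dO == -S
  qbuf <- eligible & !buf & !sup & !mask & !inv &
    S != 0L & dO == S & sign(O - E) == S
  qsup <- eligible & !buf & !sup & !mask & !inv & !qbuf &
    S != 0L & dO == S & sign(O - E) == -S
  pat[buf] <- 1L; pat[qbuf] <- 2L; pat[sup] <- 3L
  pat[qsup] <- 4L; pat[mask] <- 5L; pat[inv] <- 6L
  factor(gi_pattern_levels[pat + 1L], levels = gi_pattern_levels)
}

#' Classify a simulated model
#'
#' Applies the rule table to the G1 and G2 fold-change triples of a
#' [simulate_model()] result, using the simulation thresholds (|M| >
#' log2(1.7) for directions and the same bound for the effect size).
#'
#' @param result a `sim_result`.
#' @param epsilon_threshold,direction_threshold see [classify_gi()].
#' @return named factor of length 2 (G1, G2).
#' @export
classify_model <- function(result, epsilon_threshold = log2(1.7),
                           direction_threshold = log2(1.7)) {
  stopifnot(inherits(result, "sim_result"))
  out <- classify_gi(result$M["R1d", ], result$M["R2d", ], result$M["R1dR2d", ],
                     epsilon_threshold = epsilon_threshold,
                     direction_threshold = direction_threshold)
  names(out) <- c("G1", "G2")
  out
}
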