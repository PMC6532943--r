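# Pure-R reference implementation of the Petri net semantics. The compiled
# engine in src/ is the workhorse for surveys; this version exists to make
# the firing rules explicit and testable step by step, and the two are
# cross-checked on random models in the test suite.

#' Simulation configuration
#'
#' @param initial_tokens tokens provisioned to an unregulated regulator
#'   (mRNA resource pool; 200 by default, enough that a regulator feeding
#'   three transitions cannot be exhausted within the run).
#' @param steps number of synchronous firing steps (50).
#' @param runs repeated stochastic simulations used for the stability filter
#'   (5).
#' @param pseudo_count added to token counts before the log2 ratio to avoid
#'   division by zero (1).
#' @param strong_weight magnitude W of a strong edge (5; 9 in sensitivity
#'   runs).
#' @param source_rate tokens per step delivered by the constitutive source of
#'   an inhibitor-only node. Defaults to `strong_weight`: a constitutively
#'   expressed node is driven as strongly as a strong activating input, and
#'   the sensitivity rerun rescales it together with the edge weights.
#' @param seed global integer seed for stochastic conflict resolution.
#' @return list of class `petri_config`.
#' @export
petri_config <- function(initial_tokens = 200L, steps = 50L, runs = 5L,
                         pseudo_count = 1L, strong_weight = 5L,
                         source_rate = strong_weight, seed = 1L) {
  cfg <- list(initial_tokens = as.integer(initial_tokens),
              steps = as.integer(steps), runs = as.integer(runs),
              pseudo_count = as.integer(pseudo_count),
              strong_weight = as.integer(strong_weight),
              source_rate = as.integer(source_rate),
              seed = as.integer(seed))
  stopifnot(all(vapply(cfg, function(x) x > 0L || identical(x, cfg$seed), logical(1))))
  class(cfg) <- "petri_config"
  cfg
}

#' Log2 expression ratio of mutant versus wild-type token counts
#'
#' @param tokens_mut,tokens_wt non-negative final token counts.
#' @param pseudo pseudo-count added to both (default 1).
#' @return `log2((tokens_mut + pseudo) / (tokens_wt + pseudo))`.
#' @examples
#' m_value(245, 50)  # ~ +2.27
#' @export
m_value <- function(tokens_mut, tokens_wt, pseudo = 1L) {
  if (any(tokens_mut < 0) || any(tokens_wt < 0))
    stop("token counts must be non-negative")
  log2((tokens_mut + pseudo) / (tokens_wt + pseudo))
}

#' Compile a model into a Petri net for one deletion condition
#'
#' Token provisioning: a regulator receives the full token pool unless the
#' other regulator points an edge at it; an activating edge means the node is
#' fed dynamically through that edge's transition, an inhibiting edge means
#' the node is silenced while its inhibitor is present. Nodes whose only
#' inputs are inhibitors receive a constitutive source transition delivering
#' `source_rate` tokens per step. Inhibition dominates: every transition
#' producing into a node is disabled while an inhibitor of that node holds at
#' least one token (for the AND variant of a double-inhibitor node, only
#' while both do). Deleting a regulator empties its place and removes all
#' output effects into it; transitions keep consuming from their inputs.
#'
#' @param m 4x4 edge-weight matrix (rows = sources).
#' @param and_flags integer 4-vector, 1 where a node's two same-magnitude
#'   inputs combine with AND logic.
#' @param deleted character subset of `c("R1", "R2")`.
#' @param config a [petri_config()].
#' @return list of class `petri_net` with `transitions` and `marking`.
#' @export
compile_petri_net <- function(m, and_flags = integer(4), deleted = character(),
                              config = petri_config()) {
  m <- .check_matrix(m, config$strong_weight)
  stopifnot(all(deleted %in% c("R1", "R2")))
  del <- NODE_NAMES %in% deleted
  marking <- stats::setNames(integer(4L), NODE_NAMES)
  for (j in 1:2)
    if (!del[j] && m[3L - j, j] == 0L) marking[j] <- config$initial_tokens
  trans <- list()
  for (j in 1:4) {
    w <- m[, j]; w[j] <- 0L
    acts <- which(w > 0L); inhs <- which(w < 0L)
    mult <- if (del[j]) 0L else 1L
    is_and <- and_flags[j] == 1L
    gate_all <- is_and && length(inhs) == 2L
    node_tr <- list()
    if (length(acts) == 2L && is_and) {
      node_tr[[1L]] <- list(inputs = acts, out = j, delta = w[acts[1L]] * mult)
    } else {
      for (a in acts)
        node_tr[[length(node_tr) + 1L]] <- list(inputs = a, out = j,
                                                delta = w[a] * mult)
    }
    if (length(acts) == 0L && length(inhs) >= 1L) {
      node_tr[[length(node_tr) + 1L]] <- list(inputs = integer(0), out = j,
                                              delta = config$source_rate * mult)
    }
    for (tr in node_tr) {
      tr$gates <- inhs
      tr$gate_all <- gate_all
      trans[[length(trans) + 1L]] <- tr
    }
  }
  structure(list(transitions = trans, marking = marking, deleted = deleted),
            class = "petri_net")
}

#' @export
print.petri_net <- function(x, ...) {
  cat("Petri net:", length(x$transitions), "transitions")
  if (length(x$deleted)) cat(" |", paste0(x$deleted, "Δ", collapse = " "))
  cat("\n marking:", paste(NODE_NAMES, x$marking, sep = "=", collapse = " "), "\n")
  for (tr in x$transitions) {
    src <- if (length(tr$inputs)) paste(NODE_NAMES[tr$inputs], collapse = "+") else "(source)"
    gate <- if (length(tr$gates))
      paste0(" unless ", paste(NODE_NAMES[tr$gates],
                               collapse = if (tr$gate_all) " & " else " | "))
    else ""
    cat(sprintf("  %s -> %+d %s%s\n", src, tr$delta, NODE_NAMES[tr$out], gate))
  }
  invisible(x)
}

#' One synchronous maximal-parallel firing step
#'
#' Enablement is evaluated on the pre-step marking: a transition is enabled
#' when each consumed input place holds at least one token and its inhibitor
#' gate is inactive. All enabled transitions fire once, each consuming one
#' token per input arc and applying its output delta; when simultaneous
#' demands exceed a place's tokens, enabled transitions are funded greedily
#' in randomly shuffled order, skipping those no longer fundable. Token
#' counts floor at zero. The shuffle is the only use of randomness; on
#' conflict-free steps the result is order-independent.
#'
#' @param net a [compile_petri_net()] result.
#' @param marking named integer vector of current token counts.
#' @return list with the next `marking` and a `conflict` flag.
#' @export
pn_step <- function(net, marking) {
  trs <- net$transitions
  enabled <- logical(length(trs))
  demand <- integer(4L)
  for (k in seq_along(trs)) {
    tr <- trs[[k]]
    ok <- all(marking[tr$inputs] >= 1L)
    if (ok && length(tr$gates)) {
      active <- if (tr$gate_all) all(marking[tr$gates] >= 1L)
                else any(marking[tr$gates] >= 1L)
      if (active) ok <- FALSE
    }
    if (ok) {
      enabled[k] <- TRUE
      demand[tr$inputs] <- demand[tr$inputs] + 1L
    }
  }
  conflict <- any(demand > marking)
  prod <- integer(4L)
  idx <- which(enabled)
  if (conflict) idx <- idx[sample.int(length(idx))]
  for (k in idx) {
    tr <- trs[[k]]
    if (any(marking[tr$inputs] < 1L)) next
    marking[tr$inputs] <- marking[tr$inputs] - 1L
    prod[tr$out] <- prod[tr$out] + tr$delta
  }
  marking <- pmax(marking + prod, 0L)
  list(marking = marking, conflict = conflict)
}

#' Simulate one model across all four deletion conditions (reference)
#'
#' Runs the wild type and the three deletion conditions for `config$steps`
#' synchronous steps each and converts the final G1/G2 token counts into
#' log2 fold-changes against the wild type.
#'
#' @param m 4x4 edge-weight matrix.
#' @param and_flags per-node AND logic flags.
#' @param config a [petri_config()]; `config$seed` seeds conflict shuffles.
#' @return list of class `sim_result` with `tokens` (4 conditions x 2 genes),
#'   `M` (3 mutant conditions x 2 genes) and `conflict` (any step needed
#'   stochastic resolution).
#' @examples
#' # weak R1 -| R2, weak R1 -> G1, strong R2 -> G1: the minimal inversion motif
#' m <- matrix(0L, 4, 4)
#' m[1, 2] <- -1L; m[1, 3] <- 1L; m[2, 3] <- 5L
#' simulate_model(m)$M  # G1: up in R1d, flat in R2d, down in the double
#' @export
simulate_model <- function(m, and_flags = integer(4), config = petri_config()) {
  conds <- list(character(0), "R1", "R2", c("R1", "R2"))
  tokens <- matrix(0L, 4L, 2L,
                   dimnames = list(c("WT", "R1d", "R2d", "R1dR2d"),
                                   c("G1", "G2")))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  conflict <- FALSE
  for (ci in seq_along(conds)) {
    net <- compile_petri_net(m, and_flags, conds[[ci]], config)
    mk <- net$marking
    for (s in seq_len(config$steps)) {
      st <- pn_step(net, mk)
      mk <- st$marking
      conflict <- conflict || st$conflict
    }
    tokens[ci, ] <- mk[c("G1", "G2")]
  }
  M <- m_value(tokens[2:4, , drop = FALSE],
               rep(tokens[1L, ], each = 3L), config$pseudo_count)
  dimnames(M) <- list(c("R1d", "R2d", "R1dR2d"), c("G1", "G2"))
  structure(list(tokens = tokens, M = M, conflict = conflict),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("tokens:\n"); print(x$tokens)
  cat("M values (log2 vs WT):\n"); print(round(x$M, 3))
  if (x$conflict) cat("(stochastic conflict resolution occurred)\n")
  invisible(x)
}
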