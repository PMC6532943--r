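# Shared fixtures, all built in code.

# the minimal inversion motif: weak R1 -| R2, weak R1 -> G1, strong R2 -> G1
fig_motif <- function(inhibition = -1L, W = 5L) {
  m <- matrix(0L, 4L, 4L)
  m[1L, 2L] <- inhibition
  m[1L, 3L] <- 1L
  m[2L, 3L] <- W
  m
}

# rejection-sample admissible matrices (uniform over the constrained space)
random_admissible <- function(n, seed, W = 5L) {
  set.seed(seed)
  vals <- weight_alphabet(W)
  out <- vector("list", n)
  got <- 0L
  while (got < n) {
    m <- matrix(sample(vals, 16L, replace = TRUE), 4L, 4L)
    diag(m) <- 0L
    if (passes_conditions(m, W)) {
      got <- got + 1L
      out[[got]] <- m
    }
  }
  out
}

# random logic variant for a matrix
random_variant <- function(m, W = 5L) {
  vars <- expand_logic(m, W)
  vars[[sample.int(length(vars), 1L)]]
}

# recompute adjusted p-values from the generator's noise model and classify a
# (optionally slow-growth-corrected) synthetic pair against its planted truth
planted_accuracy <- function(pair, noise_sd, correct = TRUE) {
  pr <- pair$profile
  if (correct) {
    for (cn in c("M_x", "M_y", "M_xy"))
      pr[[cn]] <- slow_growth_correct(pr[[cn]], pair$signature)
    for (k in c("x", "y", "xy"))
      pr[[paste0("p_", k)]] <-
        stats::p.adjust(2 * stats::pnorm(-abs(pr[[paste0("M_", k)]]) / noise_sd),
                        method = "BH")
  }
  gi <- pair_gi_profile(pr)
  planted <- pair$truth$planted != "none"
  mean(as.character(gi$calls$pattern[planted]) ==
       as.character(pair$truth$planted[planted]))
}

# shared model space (cheap to build, reused across test files)
shared_space <- local({
  sp <- NULL
  function() {
    if (is.null(sp)) sp <<- model_space()
    sp
  }
})
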