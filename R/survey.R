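# Survey orchestration: batch simulation through the compiled engine,
# stability filtering over repeated runs, and the aggregate analytics of the
# full-space exploration (pattern-by-complexity tables, co-pattern
# distribution of the companion gene, quantitative-difference contingency,
# strong-weight sensitivity rerun).

#' Batch-simulate models with the compiled engine
#'
#' @param mats integer matrix of models (rows; 16 row-major entries each).
#' @param and_flags models x 4 integer matrix of AND-logic flags.
#' @param config a [petri_config()].
#' @param sim_seeds per-model seeds; defaults to a mix of `config$seed` with
#'   each model's key so that chunked runs reproduce single-pass results.
#' @return numeric array `[gene(2), condition(4), run, model]` of final token
#'   counts; conditions ordered WT, R1d, R2d, R1dR2d.
#' @export
simulate_models <- function(mats, and_flags, config = petri_config(),
                            sim_seeds = NULL) {
  stopifnot(is.matrix(mats), ncol(mats) == 16L,
            is.matrix(and_flags), ncol(and_flags) == 4L,
            nrow(and_flags) == nrow(mats))
  storage.mode(mats) <- "integer"
  storage.mode(and_flags) <- "integer"
  if (is.null(sim_seeds)) {
    keys <- apply(mats, 1L, function(v) {
      matrix_key(matrix(v, 4L, 4L, byrow = TRUE), W = max(c(abs(v), 5L)))
    })
    sim_seeds <- derive_sim_seeds(config$seed, keys)
  }
  raw <- .engine_simulate(mats, and_flags, config$steps, config$runs,
                          config$initial_tokens, config$source_rate,
                          as.numeric(sim_seeds))
  array(raw, dim = c(2L, 4L, config$runs, nrow(mats)),
        dimnames = list(c("G1", "G2"),
                        c("WT", "R1d", "R2d", "R1dR2d"), NULL, NULL))
}

# tokens array -> integer pattern codes [gene, run, model]; codes index
# gi_pattern_levels - 1
.pattern_codes <- function(tokens, pseudo = 1L,
                           epsilon_threshold = log2(1.7),
                           direction_threshold = log2(1.7)) {
  dm <- dim(tokens)
  runs <- dm[3L]; n <- dm[4L]
  M <- log2(sweep(tokens[, 2:4, , , drop = FALSE] + pseudo, c(1L, 3L, 4L),
                  tokens[, 1L, , , drop = FALSE] + pseudo, "/"))
  out <- array(0L, c(2L, runs, n))
  for (g in 1:2) for (r in seq_len(runs)) {
    cls <- classify_gi(M[g, 1L, r, ], M[g, 2L, r, ], M[g, 3L, r, ],
                       epsilon_threshold = epsilon_threshold,
                       direction_threshold = direction_threshold)
    out[g, r, ] <- as.integer(cls) - 1L
  }
  out
}

#' Run the simulation survey over a set of models
#'
#' Simulates every model `config$runs` times across the four deletion
#' conditions, classifies the per-run G1/G2 pattern tuple, and flags a model
#' as stable when all runs agree. The consensus tuple is reported for stable
#' models only; unstable models are excluded from all aggregate analytics.
#'
#' @param models list with elements `matrix`, `and_flags` and optionally
#'   `key`/`sim_seeds`, as returned by [sample_models()]; or a plain integer
#'   matrix of models (with `and_flags` passed separately).
#' @param config a [petri_config()].
#' @param and_flags used when `models` is a plain matrix.
#' @return data frame of class `survey_outcomes`: `key`, `complexity`,
#'   `quant_diff`, `stable`, `g1`, `g2` (consensus patterns, NA when
#'   unstable).
#' @export
run_survey <- function(models, config = petri_config(), and_flags = NULL) {
  if (is.matrix(models)) {
    models <- list(matrix = models,
                   and_flags = if (is.null(and_flags))
                     matrix(0L, nrow(models), 4L) else and_flags)
  }
  mats <- models$matrix
  tokens <- simulate_models(mats, models$and_flags, config, models$sim_seeds)
  codes <- .pattern_codes(tokens, config$pseudo_count)
  runs <- dim(codes)[2L]
  stable <- rep(TRUE, dim(codes)[3L])
  for (r in seq_len(runs)[-1L])
    stable <- stable & codes[1L, 1L, ] == codes[1L, r, ] &
                       codes[2L, 1L, ] == codes[2L, r, ]
  lv <- gi_pattern_levels
  g1 <- factor(ifelse(stable, lv[codes[1L, 1L, ] + 1L], NA), levels = lv)
  g2 <- factor(ifelse(stable, lv[codes[2L, 1L, ] + 1L], NA), levels = lv)
  cx <- rowSums(mats != 0L)
  qd <- apply(mats, 1L, function(v) {
    a <- abs(v[v != 0L])
    length(a) > 0L && any(a == 1L) && any(a > 1L)
  })
  key <- if (!is.null(models$key)) models$key else rep(NA_real_, nrow(mats))
  structure(data.frame(key = key, complexity = cx, quant_diff = qd,
                       stable = stable, g1 = g1, g2 = g2),
            class = c("survey_outcomes", "data.frame"))
}

#' Pattern frequency by model complexity
#'
#' For each pattern and complexity (edge count), the percentage of stable
#' models of that complexity showing the pattern in G1 or G2, split by the
#' quantitative-edge-difference flag.
#'
#' @param outcomes a [run_survey()] result.
#' @return data frame with `pattern`, `complexity`, `n_models`, `n_pattern`,
#'   `n_pattern_quant`, `percent`, `percent_no_quant_diff`.
#' @export
inversion_by_complexity <- function(outcomes) {
  st <- outcomes[outcomes$stable, ]
  res <- list()
  for (p in gi_pattern_levels[-1L]) {
    hit <- st$g1 == p | st$g2 == p
    for (cx in sort(unique(st$complexity))) {
      sel <- st$complexity == cx
      nm <- sum(sel)
      np <- sum(hit & sel)
      nq <- sum(hit & sel & st$quant_diff)
      res[[length(res) + 1L]] <- data.frame(
        pattern = p, complexity = cx, n_models = nm, n_pattern = np,
        n_pattern_quant = nq,
        percent = 100 * np / max(nm, 1L),
        percent_no_quant_diff = if (np > 0L) 100 * (np - nq) / np else NA_real_)
    }
  }
  do.call(rbind, res)
}

# companion pattern of each stable inversion model: the other downstream
# gene's class (G2 when G1 inverts, else G1); models inverting in both genes
# report "inversion"
.companion <- function(outcomes) {
  st <- outcomes[outcomes$stable, ]
  inv1 <- st$g1 == "inversion"
  inv2 <- st$g2 == "inversion"
  sel <- inv1 | inv2
  comp <- ifelse(inv1[sel], as.character(st$g2[sel]), as.character(st$g1[sel]))
  data.frame(companion = factor(comp, levels = gi_pattern_levels),
             quant_diff = st$quant_diff[sel])
}

#' Companion-gene pattern distribution for inversion models
#'
#' Among stable models showing inversion in one downstream gene, the
#' distribution of pattern classes in the other downstream gene (gene
#' mirrors folded together).
#'
#' @param outcomes a [run_survey()] result.
#' @return data frame with `pattern`, `n`, `percent` (summing to 100).
#' @export
co_pattern_distribution <- function(outcomes) {
  comp <- .companion(outcomes)
  tab <- table(comp$companion)
  data.frame(pattern = names(tab), n = as.integer(tab),
             percent = 100 * as.integer(tab) / max(sum(tab), 1L))
}

#' Quantitative-difference x intermediate-buffering contingency
#'
#' Cross-tabulates, separately for stable inversion models and for all
#' stable models with at least one patterned gene, whether the model has a
#' quantitative edge difference against whether a qualifying gene's
#' companion (the other downstream gene) falls in the buffering superclass
#' (buffering or quantitative buffering). A chi-square test (Fisher fallback
#' on degenerate margins) compares the inversion models' both-true share
#' against all models.
#'
#' @param outcomes a [run_survey()] result.
#' @return list with 2x2 `inversion` and `all` tables (counts), the matching
#'   `inversion_percent`/`all_percent`, and `p_value`.
#' @export
quantdiff_buffering_contingency <- function(outcomes) {
  st <- outcomes[outcomes$stable, ]
  buf <- c("buffering", "quantitative_buffering")
  cells <- function(qd, isbuf) {
    t <- matrix(c(sum(qd & isbuf), sum(!qd & isbuf),
                  sum(qd & !isbuf), sum(!qd & !isbuf)), 2L, 2L, byrow = TRUE,
                dimnames = list(buffering = c("yes", "no"),
                                quant_diff = c("yes", "no")))
    t
  }
  strata <- function(c1, c2) {
    sel <- c1 | c2
    isbuf <- (c1 & st$g2 %in% buf) | (c2 & st$g1 %in% buf)
    cells(st$quant_diff[sel], isbuf[sel])
  }
  inv_tab <- strata(st$g1 == "inversion", st$g2 == "inversion")
  all_tab <- strata(st$g1 != "none", st$g2 != "none")
  test_tab <- rbind(inversion = c(both = inv_tab[1L, 1L],
                                  rest = sum(inv_tab) - inv_tab[1L, 1L]),
                    all = c(both = all_tab[1L, 1L],
                            rest = sum(all_tab) - all_tab[1L, 1L]))
  p <- tryCatch(stats::chisq.test(test_tab, correct = FALSE)$p.value,
                warning = function(w) stats::fisher.test(test_tab)$p.value,
                error = function(e) stats::fisher.test(test_tab)$p.value)
  list(inversion = inv_tab, all = all_tab,
       inversion_percent = 100 * inv_tab / max(sum(inv_tab), 1L),
       all_percent = 100 * all_tab / max(sum(all_tab), 1L),
       p_value = p)
}

#' Strong-weight sensitivity rerun
#'
#' Re-simulates a set of models with the strong edge weight changed (by
#' default from 5 to 9, rescaling the constitutive source rate alongside)
#' and reports the fraction of previously inversion-stable models that still
#' show stable inversion.
#'
#' @param models model list (see [run_survey()]); typically the subset that
#'   showed inversion at W = 5.
#' @param config the original [petri_config()].
#' @param W_new new strong-edge magnitude.
#' @return list with `outcomes` (the rerun survey) and `persistence`
#'   (fraction still inversion).
#' @export
sensitivity_rerun <- function(models, config = petri_config(), W_new = 9L) {
  mats <- models$matrix
  W_old <- config$strong_weight
  mats[mats == W_old] <- as.integer(W_new)
  mats[mats == -W_old] <- as.integer(-W_new)
  cfg <- petri_config(initial_tokens = config$initial_tokens,
                      steps = config$steps, runs = config$runs,
                      pseudo_count = config$pseudo_count,
                      strong_weight = as.integer(W_new),
                      seed = config$seed)
  models$matrix <- mats
  out <- run_survey(models, cfg)
  inv <- out$stable & (out$g1 == "inversion" | out$g2 == "inversion")
  list(outcomes = out, persistence = mean(inv))
}
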