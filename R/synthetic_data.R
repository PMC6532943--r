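# Fully synthetic mutant-pair cohorts with planted ground truth. The
# generator emulates the statistical shape of expression-based genetic
# interaction profiles -- per-gene log2 fold-change triples with planted
# pattern classes, Gaussian measurement noise, significance values derived
# from the noise model, a shared slow-growth signature component scaled per
# mutant, and a fitness record -- so that every scoring, correction,
# clustering and selection step can be validated against known truth without
# any external data.

#' Smooth random signature vector
#'
#' Stand-in for the first principal component of a large deletion-strain
#' compendium: a smooth (locally averaged) random unit vector.
#'
#' @param n_genes length.
#' @param seed integer seed.
#' @param window smoothing window (running mean).
#' @return unit-norm numeric vector.
#' @export
signature_vector <- function(n_genes, seed = 1L, window = 25L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x <- stats::rnorm(n_genes)
  x <- stats::filter(x, rep(1 / window, window), sides = 2L, circular = TRUE)
  x <- as.numeric(x)
  x / sqrt(sum(x^2))
}

# planted (M1, M2, O) triple for one pattern, in units of the effect size e;
# the margin to every classification boundary is at least e (>= 2x the
# expression epsilon threshold at the defaults e = 1.5, T = log2(1.5))
.planted_triple <- function(pattern, e) {
  switch(pattern,
    buffering = c(0, 0, e),
    quantitative_buffering = c(e, 0, 2.5 * e),
    suppression = c(e, 0, 0),
    quantitative_suppression = c(2 * e, 0, 0.8 * e),
    masking = c(2 * e, -e, 2 * e),
    inversion = c(e, 0, -e),
    none = c(0, 0, 0),
    stop("unknown pattern: ", pattern))
}

#' Generate one synthetic mutant pair with planted patterns
#'
#' For each planted pattern class, (M1, M2, O) triples are drawn to satisfy
#' the class definition with a margin of at least twice the classification
#' threshold before noise; which single mutant carries the effect and the
#' global sign are randomised per gene (the rule table is sign-symmetric).
#' Unplanted genes are null. Independent Gaussian noise is added to all
#' three profiles, adjusted p-values are synthesised from the noise model
#' (two-sided z-test against the known noise sd, Benjamini-Hochberg per
#' profile), and a shared signature component is added with a per-mutant
#' loading.
#'
#' @param n_genes total genes.
#' @param planted named integer vector of planted counts per pattern (names
#'   among the six pattern classes); the remainder is null.
#' @param effect effect size in log2 units (1.5).
#' @param noise_sd Gaussian noise sd on M values (> 0).
#' @param fitness named or plain numeric triple (x, y, xy) of mutant fitness
#'   values.
#' @param signature unit signature vector (length `n_genes`); generated from
#'   the seed when NULL.
#' @param signature_loadings per-mutant loadings of the signature component
#'   (length 3, on the per-gene scale of `signature * sqrt(n_genes)`); the
#'   default couples the loading to the slow-growth burden `1 - fitness`.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list with `profile` (data frame: gene, M_x, p_x, M_y, p_y, M_xy,
#'   p_xy), `truth` (gene, planted class), `growth` (fitness triple and
#'   [growth_epsilon()]), and `signature`.
#' @export
generate_pair <- function(n_genes = 6000L,
                          planted = c(buffering = 40L, inversion = 40L),
                          effect = 1.5, noise_sd = 0.2,
                          fitness = c(x = 0.95, y = 0.9, xy = 0.6),
                          signature = NULL,
                          signature_loadings = 0.5 * (1 - fitness),
                          seed = 1L) {
  stopifnot(noise_sd > 0, effect > 0, all(fitness > 0),
            length(signature_loadings) == 3L)
  bad <- setdiff(names(planted), gi_pattern_levels[-1L])
  if (length(bad)) stop("unknown planted classes: ", paste(bad, collapse = ", "))
  if (sum(planted) > n_genes) stop("planted counts exceed n_genes")
  if (is.null(signature)) signature <- signature_vector(n_genes, seed)
  stopifnot(length(signature) == n_genes)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  truth <- rep("none", n_genes)
  slots <- sample.int(n_genes, sum(planted))
  truth[slots] <- rep(names(planted), planted)

  M <- matrix(0, n_genes, 3L)
  for (i in which(truth != "none")) {
    tri <- .planted_triple(truth[i], effect)
    if (stats::runif(1) < 0.5) tri <- tri[c(2L, 1L, 3L)]  # swap carrier
    if (stats::runif(1) < 0.5) tri <- -tri                # global sign flip
    M[i, ] <- tri
  }
  M <- M + matrix(stats::rnorm(3L * n_genes, sd = noise_sd), n_genes, 3L)
  sig_scaled <- signature * sqrt(n_genes)
  for (k in 1:3) M[, k] <- M[, k] + signature_loadings[k] * sig_scaled

  p <- apply(M, 2L, function(col) {
    stats::p.adjust(2 * stats::pnorm(-abs(col) / noise_sd), method = "BH")
  })
  genes <- sprintf("g%04d", seq_len(n_genes))
  profile <- data.frame(gene = genes,
                        M_x = M[, 1L], p_x = p[, 1L],
                        M_y = M[, 2L], p_y = p[, 2L],
                        M_xy = M[, 3L], p_xy = p[, 3L])
  fitness <- stats::setNames(as.numeric(fitness), c("x", "y", "xy"))
  growth <- c(fitness,
              eps = growth_epsilon(fitness["x"], fitness["y"], fitness["xy"]))
  list(profile = profile,
       truth = data.frame(gene = genes,
                          planted = factor(truth, levels = gi_pattern_levels)),
       growth = growth, signature = signature)
}

# planted count mixes defining the cohort archetypes (loosely shaped after
# the clusters seen in real pair cohorts: redundancy-dominated pairs,
# inversion-dominated pairs, and mixed epistasis)
.archetype_mix <- list(
  buffering_dominated = c(buffering = 60L, quantitative_buffering = 20L,
                          suppression = 5L, inversion = 5L),
  inversion_dominated = c(inversion = 60L, buffering = 10L,
                          quantitative_buffering = 10L, masking = 5L),
  mixed_epistasis = c(buffering = 20L, quantitative_buffering = 15L,
                      suppression = 20L, quantitative_suppression = 15L,
                      masking = 10L, inversion = 15L))

#' Generate a labelled cohort of synthetic pairs
#'
#' @param n_pairs number of pairs.
#' @param archetypes archetype proportions (named, summing to 1) over
#'   `names(petrigi:::.archetype_mix)`; pairs are assigned round-robin by
#'   proportion.
#' @param n_genes,effect,noise_sd,seed passed to [generate_pair()]; the
#'   signature vector is shared across the cohort and each pair gets a
#'   derived seed.
#' @return list with `pairs` (list of [generate_pair()] outputs),
#'   `archetype` (factor), `counts` (pair x pattern matrix of planted
#'   counts) and `signature`.
#' @export
generate_cohort <- function(n_pairs = 12L,
                            archetypes = c(buffering_dominated = 1 / 3,
                                           inversion_dominated = 1 / 3,
                                           mixed_epistasis = 1 / 3),
                            n_genes = 2000L, effect = 1.5, noise_sd = 0.2,
                            seed = 1L) {
  stopifnot(abs(sum(archetypes) - 1) < 1e-8,
            all(names(archetypes) %in% names(.archetype_mix)))
  n_each <- round(archetypes * n_pairs)
  while (sum(n_each) < n_pairs) n_each[which.max(archetypes)] <- n_each[which.max(archetypes)] + 1L
  while (sum(n_each) > n_pairs) n_each[which.max(n_each)] <- n_each[which.max(n_each)] - 1L
  labels <- rep(names(n_each), n_each)
  signature <- signature_vector(n_genes, seed)
  pairs <- vector("list", n_pairs)
  counts <- matrix(0L, n_pairs, 6L,
                   dimnames = list(NULL, gi_pattern_levels[-1L]))
  for (i in seq_len(n_pairs)) {
    planted <- .archetype_mix[[labels[i]]]
    pairs[[i]] <- generate_pair(n_genes = n_genes, planted = planted,
                                effect = effect, noise_sd = noise_sd,
                                signature = signature,
                                seed = seed * 1000L + i)
    counts[i, names(planted)] <- planted
  }
  names(pairs) <- sprintf("%s_%02d", labels, seq_len(n_pairs))
  rownames(counts) <- names(pairs)
  list(pairs = pairs,
       archetype = factor(labels, levels = names(.archetype_mix)),
       counts = counts, signature = signature)
}
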