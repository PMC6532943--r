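# Expression- and growth-based genetic interaction scoring of mutant-pair
# profiles: per-gene epsilon scores and pattern calls, slow-growth signature
# correction, mutant-pair selection criteria, pattern-count clustering and
# group statistics, and hypergeometric enrichment.

#' Growth-based genetic interaction score
#'
#' Deviation of the double mutant's fitness from the multiplicative
#' expectation of the single mutants. Fitness is on the ratio scale with
#' wild type at 1 and slow growers below 1, so redundant (negative) pairs
#' give negative scores.
#'
#' @param W_x,W_y,W_xy single- and double-mutant fitness values (> 0).
#' @return `W_xy - W_x * W_y`, vectorised.
#' @export
growth_epsilon <- function(W_x, W_y, W_xy) {
  if (any(c(W_x, W_y, W_xy) <= 0)) stop("fitness values must be positive")
  W_xy - W_x * W_y
}

#' Significance of growth interaction scores
#'
#' Converts scores to Z-scores against a supplied background (mean/sd of a
#' null score distribution), assigns one-sided p-values for negative
#' interactions, and adjusts with Benjamini-Hochberg.
#'
#' @param eps growth interaction scores.
#' @param null_mean,null_sd background distribution parameters; `null_sd`
#'   must be positive.
#' @param alpha significance level on the adjusted p-value (0.05).
#' @return data frame with `eps`, `z`, `p`, `p_adj`, `significant`.
#' @export
growth_significance <- function(eps, null_mean = 0, null_sd, alpha = 0.05) {
  if (null_sd <= 0) stop("null_sd must be positive")
  z <- (eps - null_mean) / null_sd
  p <- stats::pnorm(z)  # one-sided, negative interactions
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(eps = eps, z = z, p = p, p_adj = p_adj,
             significant = p_adj < alpha)
}

#' Wild-type similarity of a single-mutant profile
#'
#' A deletion mutant is considered transcriptionally silent (similar to wild
#' type) when fewer than `max_changed` genes change significantly, i.e. have
#' an adjusted p-value below `p_cutoff` and a fold-change beyond
#' `fc_threshold`.
#'
#' @param M log2 fold-changes of one mutant profile.
#' @param p_adj adjusted p-values parallel to `M`.
#' @param max_changed changed-gene bound (8: "fewer than eight").
#' @param p_cutoff,fc_threshold significance and fold-change cutoffs
#'   (0.05 and 1.7).
#' @return logical scalar.
#' @export
wt_similarity <- function(M, p_adj, max_changed = 8L, p_cutoff = 0.05,
                          fc_threshold = 1.7) {
  stopifnot(length(M) == length(p_adj))
  sum(p_adj < p_cutoff & abs(M) > log2(fc_threshold), na.rm = TRUE) < max_changed
}

#' Remove the slow-growth expression signature from a profile
#'
#' Slow-growing deletion strains share a common expression component (the
#' first principal component over a large mutant compendium). Correction
#' removes the projection of a profile onto that unit signature vector, so
#' the corrected profile has zero inner product with the signature. The
#' operation is an orthogonal projection: idempotent and norm-non-increasing.
#'
#' @param M log2 fold-change vector of one mutant profile.
#' @param signature signature loadings, same length; normalised internally.
#' @return corrected vector of the same length.
#' @export
slow_growth_correct <- function(M, signature) {
  if (length(M) != length(signature))
    stop("profile and signature lengths differ")
  nrm <- sqrt(sum(signature^2))
  if (nrm == 0) stop("signature vector is all zero")
  v <- signature / nrm
  M - sum(M * v) * v
}

#' Per-gene genetic interaction profile of a mutant pair
#'
#' Computes each gene's interaction effect `|O - (M1 + M2)|`, classifies the
#' genes above the effect threshold with the shared rule table (directions
#' from significance and sign), and summarises the pair as a pattern-count
#' vector. Pairs with fewer than `min_genes` contributing genes are flagged
#' for exclusion.
#'
#' @param profile data frame with columns `gene`, `M_x`, `p_x`, `M_y`,
#'   `p_y`, `M_xy`, `p_xy` (M = log2 fold-change, p = adjusted p-value).
#' @param epsilon_threshold effect-size bound (log2(1.5) for expression
#'   data).
#' @param p_cutoff direction-call significance cutoff (0.01).
#' @param min_genes minimum number of contributing genes (10).
#' @return list of class `pair_gi` with `calls` (per-gene data frame),
#'   `counts` (named pattern-count vector over the six patterns),
#'   `score` (number of contributing genes) and `excluded`.
#' @export
pair_gi_profile <- function(profile, epsilon_threshold = log2(1.5),
                            p_cutoff = 0.01, min_genes = 10L) {
  need <- c("gene", "M_x", "p_x", "M_y", "p_y", "M_xy", "p_xy")
  if (!all(need %in% names(profile)))
    stop("profile must have columns ", paste(need, collapse = ", "))
  eps <- gi_epsilon(profile$M_x, profile$M_y, profile$M_xy)
  pattern <- classify_gi(
    profile$M_x, profile$M_y, profile$M_xy,
    d1 = direction_call_expr(profile$M_x, profile$p_x, p_cutoff),
    d2 = direction_call_expr(profile$M_y, profile$p_y, p_cutoff),
    dO = direction_call_expr(profile$M_xy, profile$p_xy, p_cutoff),
    epsilon_threshold = epsilon_threshold)
  calls <- data.frame(gene = profile$gene, epsilon = eps, pattern = pattern)
  contributing <- sum(eps > epsilon_threshold)
  counts <- table(pattern[eps > epsilon_threshold])
  counts <- as.vector(counts[gi_pattern_levels[-1L]])
  counts[is.na(counts)] <- 0L
  names(counts) <- gi_pattern_levels[-1L]
  structure(list(calls = calls, counts = counts, score = contributing,
                 excluded = contributing < min_genes),
            class = "pair_gi")
}

#' Cluster mutant pairs by their pattern-count vectors
#'
#' Average-linkage agglomerative clustering on the distance
#' `1 - cosine similarity` between raw pattern-count vectors (gene identity
#' is disregarded; only how often each pattern occurs enters). Leaf order is
#' made deterministic by seriating ties on the pair label.
#'
#' @param counts matrix of pattern counts, one pair per row (rownames are
#'   pair labels); or a list of `pair_gi` objects.
#' @return object of class `hclust`.
#' @export
cluster_pairs <- function(counts) {
  if (is.list(counts) && !is.matrix(counts) && !is.data.frame(counts)) {
    labels <- names(counts)
    counts <- do.call(rbind, lapply(counts, function(p) {
      if (is.list(p)) p$counts else p
    }))
    rownames(counts) <- labels
  }
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stop("need at least two pairs to cluster")
  nrm <- sqrt(rowSums(counts^2))
  if (any(nrm == 0)) stop("all-zero pattern-count vector")
  unit <- counts / nrm
  dmat <- 1 - tcrossprod(unit)
  dmat[dmat < 0] <- 0
  d <- stats::as.dist(dmat)
  hc <- stats::hclust(d, method = "average")
  # deterministic leaf order: rotate branches toward lexicographic labels
  if (!is.null(rownames(counts)))
    hc <- stats::as.hclust(stats::reorder(stats::as.dendrogram(hc),
                                          order(order(rownames(counts)))))
  hc
}

#' Export a pair dendrogram in Newick format
#'
#' @param hc an `hclust` from [cluster_pairs()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_dendrogram_newick <- function(hc, file) {
  ape::write.tree(ape::as.phylo(hc), file = file)
  invisible(file)
}

#' Compare per-pair inversion fractions between groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests on the percentage of
#' genes showing inversion per pair, for every group pair, with
#' Benjamini-Hochberg adjustment across the comparisons.
#'
#' @param fractions numeric vector of per-pair inversion percentages.
#' @param groups factor of group labels, parallel to `fractions`; every
#'   group needs at least two pairs.
#' @return data frame with `group1`, `group2`, `p`, `p_adj`.
#' @export
compare_inversion_fraction <- function(fractions, groups) {
  groups <- droplevels(as.factor(groups))
  stopifnot(length(fractions) == length(groups))
  if (any(table(groups) < 2L)) stop("each group needs at least two pairs")
  lv <- levels(groups)
  cmb <- utils::combn(lv, 2L)
  p <- apply(cmb, 2L, function(gg) {
    stats::wilcox.test(fractions[groups == gg[1L]],
                       fractions[groups == gg[2L]],
                       alternative = "two.sided", exact = NULL)$p.value
  })
  data.frame(group1 = cmb[1L, ], group2 = cmb[2L, ], p = p,
             p_adj = stats::p.adjust(p, method = "BH"))
}

#' Hypergeometric enrichment of a gene set in annotations
#'
#' Upper-tail hypergeometric test of the overlap between a hit set and each
#' annotation set against a fixed background population, Bonferroni-adjusted
#' over the annotations tested.
#'
#' @param hits character vector of hit genes.
#' @param annotations named list of annotation gene sets.
#' @param background background population size (6359, the annotated yeast
#'   genome used throughout) or a character vector of background genes.
#' @return data frame with `annotation`, `overlap`, `set_size`, `hit_size`,
#'   `expected`, `p`, `p_adj`.
#' @export
hypergeom_enrich <- function(hits, annotations, background = 6359L) {
  if (is.character(background)) {
    bg_n <- length(background)
    hits <- intersect(hits, background)
    annotations <- lapply(annotations, intersect, background)
  } else {
    bg_n <- as.integer(background)
  }
  hits <- unique(hits)
  if (length(hits) > bg_n) stop("hit set larger than the background")
  res <- lapply(names(annotations), function(nm) {
    set <- unique(annotations[[nm]])
    k <- length(intersect(hits, set))
    # P(X >= k) for X ~ Hypergeom(set, bg - set, draws = hits)
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1L, length(set), bg_n - length(set),
                    length(hits), lower.tail = FALSE)
    data.frame(annotation = nm, overlap = k, set_size = length(set),
               hit_size = length(hits),
               expected = length(hits) * length(set) / bg_n, p = p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$p * nrow(out))  # Bonferroni
  out
}

#' Read and write the pair-profile TSV dialect
#'
#' Gene-by-column tables with columns `gene`, `M_x`, `p_x`, `M_y`, `p_y`,
#' `M_xy`, `p_xy`.
#'
#' @param file path.
#' @return data frame.
#' @export
read_pair_profile <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' @rdname read_pair_profile
#' @param profile data frame to write.
#' @export
write_pair_profile <- function(profile, file) {
  utils::write.table(profile, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
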