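test_that("growth scores follow the multiplicative model", {
  expect_identical(growth_epsilon(1, 1, 1), 0)
  expect_equal(growth_epsilon(0.9, 0.8, 0.5), -0.22)
  expect_equal(growth_epsilon(0.9, 0.8, 0.72), 0)
  expect_error(growth_epsilon(0, 1, 1), "positive")
})

test_that("growth significance matches normal-tail and BH oracles", {
  gs <- growth_significance(c(-0.3, -0.2, 0.1), null_mean = -0.2, null_sd = 0.1)
  expect_equal(gs$z, c(-1, 0, 3))
  expect_equal(gs$p[2L], 0.5)
  g3 <- growth_significance(0.0 - 3 * 0.1, null_mean = 0, null_sd = 0.1)
  expect_equal(g3$p, stats::pnorm(-3), tolerance = 1e-9)
  expect_equal(g3$p, 0.00135, tolerance = 1e-2)
  # hand-computed BH ladder: sorted p * n/rank, cumulative minimum from the top
  p <- c(0.01, 0.02, 0.9)
  hand <- rev(cummin(rev(sort(p) * length(p) / seq_along(p))))[order(order(p))]
  expect_equal(hand, c(0.03, 0.03, 0.9))
  gs2 <- growth_significance(stats::qnorm(p), null_mean = 0, null_sd = 1)
  expect_equal(gs2$p_adj, hand, tolerance = 1e-9)
  expect_error(growth_significance(0, 0, 0), "positive")
})

test_that("wild-type similarity counts significantly changed genes", {
  M <- c(rep(2, 7), rep(0.1, 93))
  p <- c(rep(0.001, 7), rep(0.5, 93))
  expect_true(wt_similarity(M, p))                     # 7 changed
  M[8L] <- 2; p[8L] <- 0.001
  expect_false(wt_similarity(M, p))                    # boundary at 8
  expect_true(wt_similarity(numeric(0), numeric(0)))   # empty profile
  # significance alone is not enough without the fold-change
  expect_true(wt_similarity(rep(0.2, 20), rep(0.001, 20)))
})

test_that("slow-growth correction is an orthogonal projection", {
  set.seed(41)
  v <- signature_vector(500L, seed = 2L)
  expect_equal(sum(v^2), 1)
  expect_equal(slow_growth_correct(2 * v, v), rep(0, 500L))
  w <- stats::rnorm(500L)
  w <- w - sum(w * v) * v  # orthogonal component
  expect_equal(slow_growth_correct(w, v), w)
  M <- stats::rnorm(500L) + 0.8 * v * sqrt(500)
  corr <- slow_growth_correct(M, v)
  expect_equal(sum(corr * v), 0, tolerance = 1e-9)
  expect_equal(slow_growth_correct(corr, v), corr)     # idempotent
  expect_lte(sqrt(sum(corr^2)), sqrt(sum(M^2)))        # norm non-increasing
  expect_gt(abs(stats::cor(M, v)), 0.4)
  expect_lt(abs(stats::cor(corr, v)), 0.05)
  expect_error(slow_growth_correct(1:3, 1:2), "length")
})

test_that("pair profiles classify planted genes and apply the gene floor", {
  pair <- generate_pair(n_genes = 1500L, planted = c(buffering = 40L),
                        noise_sd = 0.1, signature_loadings = rep(0, 3L),
                        seed = 4L)
  gi <- pair_gi_profile(pair$profile)
  expect_false(gi$excluded)
  planted <- pair$truth$planted == "buffering"
  expect_gte(sum(gi$calls$pattern[planted] == "buffering"), 38L)
  # a flat profile contributes no genes and is excluded
  flat <- data.frame(gene = sprintf("g%02d", 1:20), M_x = 0, p_x = 1,
                     M_y = 0, p_y = 1, M_xy = 0, p_xy = 1)
  expect_true(pair_gi_profile(flat)$excluded)
  expect_identical(pair_gi_profile(flat)$score, 0L)
  # a planted inversion triple lands in the inversion class
  one <- data.frame(gene = "g1", M_x = 1.5, p_x = 1e-6, M_y = 0, p_y = 1,
                    M_xy = -1.5, p_xy = 1e-6)
  expect_identical(as.character(pair_gi_profile(one)$calls$pattern), "inversion")
  expect_error(pair_gi_profile(flat[, -1L]), "columns")
})

test_that("pattern counts ignore gene order", {
  pair <- generate_pair(n_genes = 800L,
                        planted = c(buffering = 20L, inversion = 20L),
                        noise_sd = 0.1, signature_loadings = rep(0, 3L),
                        seed = 6L)
  a <- pair_gi_profile(pair$profile)
  set.seed(1)
  b <- pair_gi_profile(pair$profile[sample.int(800L), ])
  expect_identical(a$counts, b$counts)
})

test_that("cosine clustering merges duplicates and separates orthogonals", {
  counts <- rbind(a = c(10, 0, 0, 0, 0, 0), b = c(20, 0, 0, 0, 0, 0),
                  c = c(0, 0, 0, 0, 0, 7))
  hc <- cluster_pairs(counts)
  merge_h <- sort(hc$height)
  expect_equal(merge_h[1L], 0)          # scaled duplicates merge at 0
  expect_equal(merge_h[2L], 1)          # orthogonal counts at distance 1
  expect_error(cluster_pairs(counts[1L, , drop = FALSE]), "two pairs")
  expect_error(cluster_pairs(rbind(counts, d = rep(0, 6))), "all-zero")
})

test_that("planted archetype clusters are recovered exactly", {
  coh <- generate_cohort(n_pairs = 12L, n_genes = 1200L, noise_sd = 0.1,
                         seed = 2L)
  counts <- t(vapply(coh$pairs,
                     function(p) pair_gi_profile(p$profile)$counts,
                     numeric(6L)))
  hc <- cluster_pairs(counts)
  k3 <- stats::cutree(hc, k = 3L)
  expect_identical(length(unique(k3)), 3L)
  # clusters coincide with the planted archetypes
  expect_true(all(tapply(k3, coh$archetype, function(x) length(unique(x))) == 1L))
})

test_that("group comparison reproduces the exact rank-sum distribution", {
  cmp <- compare_inversion_fraction(c(1, 2, 3, 10, 11, 12),
                                    rep(c("a", "b"), each = 3L))
  expect_equal(cmp$p, 0.1)              # U = 0, exact two-sided, n = m = 3
  # identical groups: maximal p
  same <- suppressWarnings(
    compare_inversion_fraction(c(5, 6, 7, 5, 6, 7), rep(c("a", "b"), each = 3L)))
  expect_equal(same$p, 1)
  # label symmetry
  flip <- compare_inversion_fraction(c(10, 11, 12, 1, 2, 3),
                                     rep(c("a", "b"), each = 3L))
  expect_equal(flip$p, cmp$p)
  expect_error(compare_inversion_fraction(1:3, c("a", "a", "b")), "two pairs")
})

test_that("hypergeometric enrichment matches the exact urn computation", {
  res <- hypergeom_enrich(letters[1:5], list(set = letters[1:5]),
                          background = 10L)
  expect_equal(res$p, 1 / choose(10, 5))
  expect_equal(res$p_adj, min(1, res$p * 1))
  # expected overlap under independence is unremarkable
  set.seed(3)
  bg <- sprintf("g%03d", 1:200)
  res2 <- hypergeom_enrich(bg[1:50], list(s = bg[c(1:13, 60:96)]),
                           background = bg)
  expect_gt(res2$p, 0.3)
  # empty hit set
  expect_equal(hypergeom_enrich(character(0), list(s = bg[1:10]), 200L)$p, 1)
  expect_error(hypergeom_enrich(bg, list(s = bg[1:5]), background = 100L),
               "larger")
})

test_that("the pair-selection rule reproduces planted selections", {
  # negative significant growth interaction AND at least one wild-type-like
  # single mutant
  set.seed(9)
  n <- 40L
  eps <- c(rep(-0.25, 10L), rep(0, 30L)) + stats::rnorm(n, sd = 0.02)
  gs <- growth_significance(eps, null_mean = 0, null_sd = 0.05)
  wt_like <- c(rep(TRUE, 20L), rep(FALSE, 20L))
  selected <- gs$significant & gs$z < 0 & wt_like
  expect_identical(which(selected), 1:10)
})

test_that("profile tables round-trip through the TSV dialect", {
  pair <- generate_pair(n_genes = 50L, planted = c(inversion = 5L), seed = 3L)
  f <- tempfile(fileext = ".tsv")
  write_pair_profile(pair$profile, f)
  back <- read_pair_profile(f)
  expect_equal(back$M_xy, pair$profile$M_xy, tolerance = 1e-12)
  expect_identical(back$gene, pair$profile$gene)
})
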