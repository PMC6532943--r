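test_that("m_value matches the pseudo-counted log ratio", {
  expect_identical(m_value(50L, 50L), 0)
  expect_equal(m_value(0L, 50L), log2(1 / 51))
  expect_equal(m_value(245L, 50L), log2(246 / 51), tolerance = 1e-12)
  expect_error(m_value(-1L, 50L), "non-negative")
})

test_that("compilation provisions tokens and performs deletion surgery", {
  cfg <- petri_config()
  net <- compile_petri_net(fig_motif(), config = cfg)
  expect_identical(unname(net$marking), c(200L, 0L, 0L, 0L))
  expect_length(net$transitions, 3L)  # R1->G1, R2->G1, source of R2
  # the source transition of R2 is gated by R1
  src <- Filter(function(tr) length(tr$inputs) == 0L, net$transitions)[[1L]]
  expect_identical(src$out, 2L)
  expect_identical(src$delta, cfg$source_rate)
  expect_identical(src$gates, 1L)
  # deletion: empty marking and no output into the deleted place
  netd <- compile_petri_net(fig_motif(), deleted = "R1", config = cfg)
  expect_identical(unname(netd$marking), c(0L, 0L, 0L, 0L))
  into_r1 <- Filter(function(tr) tr$out == 1L && tr$delta != 0L, netd$transitions)
  expect_length(into_r1, 0L)
  expect_error(compile_petri_net(fig_motif(), deleted = "G1"), "R1")
})

test_that("a single activating transition moves one token per step", {
  m <- matrix(0L, 4L, 4L); m[1L, 3L] <- 1L; m[2L, 4L] <- 1L  # keeps condition 3
  net <- compile_petri_net(m)
  st <- pn_step(net, net$marking)
  expect_identical(unname(st$marking), c(199L, 199L, 1L, 1L))
  expect_false(st$conflict)
})

test_that("the minimal inversion motif reproduces the hand-stepped trajectory", {
  for (inh in c(-1L, -5L)) {
    r <- simulate_model(fig_motif(inh))
    expect_identical(unname(r$tokens[, "G1"]), c(50L, 245L, 50L, 0L))
    expect_identical(unname(r$tokens[, "G2"]), c(0L, 0L, 0L, 0L))
    expect_equal(unname(r$M[, "G1"]),
                 c(log2(246 / 51), 0, log2(1 / 51)), tolerance = 1e-12)
    expect_false(r$conflict)
    expect_identical(as.character(classify_model(r)), c("inversion", "none"))
  }
})

test_that("a gene without producers stays empty in every condition", {
  m <- matrix(0L, 4L, 4L); m[1L, 3L] <- 1L; m[2L, 3L] <- 1L
  r <- simulate_model(m)
  expect_true(all(r$tokens[, "G2"] == 0L))
  expect_true(all(r$M[, "G2"] == 0))
})

test_that("markings stay non-negative and supplies are sufficient", {
  mats <- random_admissible(30L, seed = 11L)
  for (m in mats) {
    sp <- random_variant(m)
    net <- compile_petri_net(sp$matrix, sp$and_flags)
    mk <- net$marking
    set.seed(1)
    for (s in 1:50) {
      mk <- pn_step(net, mk)$marking
      expect_true(all(mk >= 0L))
    }
  }
  # a provisioned regulator with three outgoing transitions cannot exhaust
  m <- matrix(0L, 4L, 4L); m[1L, 2:4] <- c(1L, 1L, 1L)
  net <- compile_petri_net(m)
  mk <- net$marking
  for (s in 1:50) mk <- pn_step(net, mk)$marking
  expect_gte(mk["R1"], 200L - 3L * 50L)
})

test_that("reference and compiled engines agree on conflict-free models", {
  mats <- random_admissible(60L, seed = 21L)
  checked <- 0L
  for (m in mats) {
    sp <- random_variant(m)
    r <- simulate_model(sp$matrix, sp$and_flags)
    if (r$conflict) next
    checked <- checked + 1L
    am <- matrix(as.integer(t(sp$matrix)), 1L)
    af <- matrix(sp$and_flags, 1L)
    for (seed in c(3, 99)) {  # conflict-free nets are seed-independent
      tok <- simulate_models(am, af, petri_config(runs = 2L, seed = seed))
      for (run in 1:2)
        expect_equal(unname(t(tok[, , run, 1L])), unname(r$tokens) + 0)
    }
  }
  expect_gte(checked, 20L)
})

test_that("identical seeds give identical batch results", {
  sp <- shared_space()
  s <- sample_models(sp, 150L, seed = 5L)
  t1 <- simulate_models(s$matrix, s$and_flags, sim_seeds = s$sim_seeds)
  t2 <- simulate_models(s$matrix, s$and_flags, sim_seeds = s$sim_seeds)
  expect_identical(t1, t2)
})

test_that("mirror relabelings permute conditions and genes coherently", {
  mats <- random_admissible(40L, seed = 31L)
  for (m in mats) {
    sp <- random_variant(m)
    r <- simulate_model(sp$matrix, sp$and_flags)
    if (r$conflict) next
    # regulator swap: R1d and R2d trade places, genes unchanged
    pr <- c(2L, 1L, 3L, 4L)
    rs <- simulate_model(sp$matrix[pr, pr], sp$and_flags[pr])
    if (!rs$conflict)
      expect_identical(rs$tokens[c(1L, 3L, 2L, 4L), ], r$tokens,
                       ignore_attr = TRUE)
    # gene swap: G1 and G2 trade places, conditions unchanged
    pg <- c(1L, 2L, 4L, 3L)
    gs <- simulate_model(sp$matrix[pg, pg], sp$and_flags[pg])
    if (!gs$conflict)
      expect_identical(gs$tokens[, c(2L, 1L)], r$tokens, ignore_attr = TRUE)
  }
})
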