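test_that("structural conditions accept and reject the right matrices", {
  expect_true(passes_conditions(fig_motif()))
  expect_false(passes_conditions(matrix(0L, 4L, 4L)))
  # crossing-only regulator-to-gene pair is excluded
  m <- matrix(0L, 4L, 4L); m[1L, 3L] <- 1L; m[2L, 4L] <- 1L
  expect_false(passes_conditions(m))
  # shared source qualifies
  m <- matrix(0L, 4L, 4L); m[1L, 3L] <- 1L; m[1L, 4L] <- 5L
  expect_true(passes_conditions(m))
  # self-edge and in-degree violations
  m <- fig_motif(); m[3L, 3L] <- 1L
  expect_false(passes_conditions(m))
  m <- fig_motif(); m[4L, 3L] <- 1L  # G1 gains a third input
  expect_false(passes_conditions(m))
  expect_error(passes_conditions(matrix(2L, 4L, 4L)), "alphabet")
})

test_that("column-state counts match brute-force enumeration", {
  # 5^3 incoming-edge combinations per node, at most two nonzero
  grid <- expand.grid(a = 0:4, b = 0:4, c = 0:4)
  expect_identical(sum(rowSums(grid > 0L) <= 2L), 61L)
  sp <- shared_space()
  expect_identical(sp$n_col_states, 61L)
  # condition-3-filtered gene-column pairs, checked with an independent
  # whole-matrix predicate
  states <- as.matrix(grid[rowSums(grid > 0L) <= 2L, ])
  vals <- weight_alphabet(5L)
  ok <- 0L
  for (i in seq_len(61L)) for (j in seq_len(61L)) {
    m <- matrix(0L, 4L, 4L)
    m[c(1L, 2L, 4L), 3L] <- vals[states[i, ] + 1L]
    m[c(1L, 2L, 3L), 4L] <- vals[states[j, ] + 1L]
    if (passes_conditions(m)) ok <- ok + 1L
  }
  expect_identical(ok, nrow(sp$Gs))
  expect_identical(ok, 2496L)
})

test_that("space counts factorise and the orbit count matches Burnside", {
  sp <- shared_space()
  cnt <- space_counts(sp)
  expect_identical(cnt[["unconstrained"]], 5^16)
  expect_identical(cnt[["constrained"]], 61^2 * 2496)
  # Burnside: orbit count = mean number of fixed points over the group
  fixed <- vapply(c("id", "R", "G", "RG"), function(p) {
    f <- 0
    for (g in seq_len(nrow(sp$Gs)))
      f <- f + sum(sp$keyR$id + sp$keyG$id[g] == sp$keyR[[p]] + sp$keyG[[p]][g])
    f
  }, numeric(1))
  expect_identical(cnt[["canonical"]], sum(fixed) / 4)
})

test_that("mirror orbits behave and structural measures are orbit-invariant", {
  mats <- random_admissible(40L, seed = 101L)
  for (m in mats) {
    orb <- mirror_orbit(m)
    can <- canonicalize(m)
    expect_identical(canonicalize(can), can)            # idempotent
    for (o in orb) {
      expect_identical(canonicalize(o), can)            # shared representative
      expect_identical(passes_conditions(o), passes_conditions(m))
      expect_identical(complexity(o), complexity(m))
      expect_identical(has_quant_edge_difference(o), has_quant_edge_difference(m))
      expect_identical(logic_expansion_count(o), logic_expansion_count(m))
    }
  }
  # a matrix symmetric under both swaps is its own orbit
  m <- matrix(0L, 4L, 4L); m[1L, 3L] <- 1L; m[1L, 4L] <- 1L
  m[2L, 3L] <- 1L; m[2L, 4L] <- 1L
  expect_identical(length(unique(vapply(mirror_orbit(m), matrix_key,
                                        numeric(1)))), 1L)
})

test_that("logic expansion follows the equal-magnitude rule", {
  # two weak activating inputs: AND and OR variants
  m <- matrix(0L, 4L, 4L); m[1L, 3L] <- 1L; m[2L, 3L] <- 1L
  vars <- expand_logic(m)
  expect_length(vars, 2L)
  expect_setequal(vapply(vars, function(v) v$logic[3L], character(1)),
                  c("AND", "OR"))
  # weak + strong: OR only
  vars <- expand_logic(fig_motif())
  expect_length(vars, 1L)
  expect_identical(vars[[1L]]$logic[3L], "OR")
  # equal-magnitude opposite directions: two variants, inhibition dominant
  m <- matrix(0L, 4L, 4L); m[1L, 3L] <- 1L; m[2L, 3L] <- -1L; m[1L, 4L] <- 1L
  m[2L, 4L] <- 1L
  vars <- expand_logic(m)
  expect_length(vars, 4L)  # G1 mixed pair x G2 equal pair
  expect_true(all(vapply(vars, function(v) v$logic[3L], character(1)) ==
                  "INHIBITION_DOMINANT"))
  # expansion count formula on random matrices
  for (m in random_admissible(25L, seed = 7L))
    expect_length(expand_logic(m), logic_expansion_count(m))
})

test_that("complexity, active nodes and quantitative difference", {
  m <- fig_motif()
  expect_identical(complexity(m), 3L)
  expect_identical(active_nodes(m), c("R1", "R2", "G1"))
  expect_true(has_quant_edge_difference(m))
  m2 <- matrix(0L, 4L, 4L); m2[1L, 3L] <- 1L; m2[2L, 3L] <- 1L
  m2[1L, 2L] <- -1L; m2[1L, 4L] <- 1L
  expect_false(has_quant_edge_difference(m2))
})

test_that("decode/canonical machinery agrees with single-matrix operations", {
  sp <- shared_space()
  canon <- canonical_models(sp)
  set.seed(5)
  i <- sample.int(length(canon$r), 200L)
  mats <- decode_models(sp, canon$r[i], canon$g[i])
  for (q in seq_len(nrow(mats))) {
    m <- matrix(mats[q, ], 4L, 4L, byrow = TRUE)
    expect_true(passes_conditions(m))
    expect_identical(matrix_key(m), canon$key[i[q]])
    expect_identical(matrix_key(canonicalize(m)), canon$key[i[q]])
  }
})

test_that("serialization round-trips model specs", {
  mats <- random_admissible(15L, seed = 33L)
  specs <- unlist(lapply(mats, expand_logic), recursive = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_model_table(specs, f)
  back <- read_model_table(f)
  expect_length(back, length(specs))
  for (k in seq_along(specs)) {
    expect_identical(back[[k]]$matrix, specs[[k]]$matrix)
    expect_identical(back[[k]]$logic, specs[[k]]$logic)
    expect_identical(back[[k]]$and_flags, specs[[k]]$and_flags)
  }
})

test_that("model sampling is reproducible and respects expansion weights", {
  sp <- shared_space()
  canon <- canonical_models(sp)
  s1 <- sample_models(sp, 100L, seed = 9L, canon = canon)
  s2 <- sample_models(sp, 100L, seed = 9L, canon = canon)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$and_flags, s2$and_flags)
  expect_identical(s1$sim_seeds, s2$sim_seeds)
  # every sampled variant is a legal expansion of its matrix
  for (q in seq_len(20L)) {
    m <- matrix(s1$matrix[q, ], 4L, 4L, byrow = TRUE)
    expect_lt(s1$variant[q], logic_expansion_count(m))
  }
})
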