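#' @useDynLib petrigi, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Node order is fixed throughout the package: R1, R2 (regulators), G1, G2
# (downstream genes). Edge matrices are 4x4 signed integer matrices with rows
# as sources and columns as targets, entries drawn from {0, +1, +W, -1, -W}.
# Internally each entry is a code 0..4 mapping to (0, +1, +W, -1, -W); a
# whole matrix is a 16-digit base-5 number ("key"), read row-major, which
# gives an exact double below 2^53 and a total lexicographic order.

NODE_NAMES <- c("R1", "R2", "G1", "G2")
.CODE_SIGN <- c(0L, 1L, 1L, -1L, -1L)
.CODE_MAG <- c(0L, 1L, 2L, 1L, 2L)  # 0 none, 1 weak, 2 strong

#' Weight alphabet for a given strong-edge magnitude
#'
#' Edges are absent (0), weak activating (+1), strong activating (+W), weak
#' inhibiting (-1) or strong inhibiting (-W).
#'
#' @param W strong-edge magnitude (5 by default; 9 for the sensitivity runs).
#' @return integer vector `c(0, 1, W, -1, -W)`, ordered by internal code.
#' @export
weight_alphabet <- function(W = 5L) {
  W <- as.integer(W)
  stopifnot(W > 1L)
  c(0L, 1L, W, -1L, -W)
}

.codes_to_values <- function(codes, W = 5L) weight_alphabet(W)[codes + 1L]

.values_to_codes <- function(values, W = 5L) {
  idx <- match(as.integer(values), weight_alphabet(W))
  if (anyNA(idx))
    stop("matrix entries must lie in the weight alphabet {0, +-1, +-", W, "}")
  idx - 1L
}

.check_matrix <- function(m, W = 5L) {
  if (is.vector(m) && length(m) == 16L) m <- matrix(as.integer(m), 4, 4, byrow = TRUE)
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)))
  .values_to_codes(m, W)  # validates the alphabet
  storage.mode(m) <- "integer"
  m
}

#' Structural admissibility of an edge-weight matrix
#'
#' A matrix is kept for simulation when (1) it has no self-edges, (2) no node
#' has more than two incoming edges, and (3) the regulator-to-gene edges
#' contain at least two edges sharing a source regulator or a target gene.
#' Condition 3 excludes the degenerate case where the only regulator-to-gene
#' edges form a "crossing" pair (R1 to one gene, R2 to the other), which
#' cannot couple the two deletions on a common readout.
#'
#' @param m 4x4 integer matrix (rows = sources) over the weight alphabet,
#'   or its 16-entry row-major vector.
#' @param W strong-edge magnitude used to validate entries.
#' @param condition3 predicate taking the four regulator-to-gene entries
#'   (R1G1, R2G1, R1G2, R2G2) and returning TRUE/FALSE. The default is the
#'   shared source-or-target rule; it is pluggable so alternative readings of
#'   the constraint can be compared against the enumeration count.
#' @return logical scalar.
#' @export
passes_conditions <- function(m, W = 5L, condition3 = condition3_shared) {
  m <- .check_matrix(m, W)
  if (any(diag(m) != 0L)) return(FALSE)
  if (any(colSums(m != 0L) > 2L)) return(FALSE)
  condition3(m[1L, 3L], m[2L, 3L], m[1L, 4L], m[2L, 4L])
}

#' @rdname passes_conditions
#' @param r1g1,r2g1,r1g2,r2g2 the four regulator-to-gene entries.
#' @export
condition3_shared <- function(r1g1, r2g1, r1g2, r2g2) {
  a <- r1g1 != 0L; b <- r2g1 != 0L; cc <- r1g2 != 0L; d <- r2g2 != 0L
  (a & b) | (cc & d) | (a & cc) | (b & d)
}

# ---------------------------------------------------------------------------
# column-state machinery
#
# Because conditions 1 and 2 act per column (incoming edges of one node),
# enumeration is organised column-wise: each column has 3 free off-diagonal
# entries over 5 symbols with at most two nonzero, giving 61 admissible
# states. The full constrained space factorises as (61 x 61 regulator-column
# pairs) x (condition-3-filtered gene-column pairs).

.column_states <- function() {
  g <- as.matrix(expand.grid(a = 0:4, b = 0:4, c = 0:4))
  g <- g[rowSums(g > 0L) <= 2L, , drop = FALSE]
  storage.mode(g) <- "integer"
  dimnames(g) <- NULL
  g
}

# position weight of entry (i, j) in the row-major base-5 key
.pos_weight <- function(i, j) 5^(16L - ((i - 1L) * 4L + j))

# per-column-state properties used across the package
.col_props <- function(s3) {
  n <- nrow(s3)
  nz <- rowSums(s3 > 0L)
  mag <- matrix(.CODE_MAG[s3 + 1L], nrow = n)
  two <- nz == 2L
  eqmag <- logical(n)
  sgn <- matrix(.CODE_SIGN[s3 + 1L], nrow = n)
  mixed <- logical(n)
  for (r in which(two)) {
    mm <- mag[r, ][mag[r, ] > 0L]
    eqmag[r] <- mm[1L] == mm[2L]
    ss <- sgn[r, ][sgn[r, ] != 0L]
    mixed[r] <- ss[1L] != ss[2L]
  }
  list(nz = nz, and_or = two & eqmag, mixed = two & mixed,
       has_weak = rowSums(mag == 1L) > 0L, has_strong = rowSums(mag == 2L) > 0L)
}

#' Build the enumerable model space
#'
#' Precomputes the column-state decomposition of the constrained 4-node
#' edge-weight matrix space: the 61 admissible incoming-edge states per node,
#' all regulator-column pairs, the condition-3-filtered gene-column pairs, and
#' the base-5 keys of every matrix under the four mirror relabelings. All
#' space-level counting, canonicalization and sampling works off this object;
#' no 9.3-million-row matrix is ever materialised.
#'
#' @param W strong-edge magnitude (a label for decoding; the combinatorics do
#'   not depend on it).
#' @param condition3 see [passes_conditions()].
#' @return an object of class `model_space`.
#' @examples
#' sp <- model_space()
#' space_counts(sp)
#' @export
model_space <- function(W = 5L, condition3 = condition3_shared) {
  cols <- .column_states()
  n <- nrow(cols)
  ri <- rep(seq_len(n), each = n)
  ci <- rep(seq_len(n), times = n)
  # regulator columns: col R1 holds (R2->R1, G1->R1, G2->R1),
  #                    col R2 holds (R1->R2, G1->R2, G2->R2)
  Rs <- cbind(cols[ri, , drop = FALSE], cols[ci, , drop = FALSE])
  colnames(Rs) <- c("m21", "m31", "m41", "m12", "m32", "m42")
  # gene columns: col G1 holds (R1->G1, R2->G1, G2->G1), col G2 similarly
  Gs <- cbind(cols[ri, , drop = FALSE], cols[ci, , drop = FALSE])
  colnames(Gs) <- c("m13", "m23", "m43", "m14", "m24", "m34")
  keep <- condition3(Gs[, "m13"], Gs[, "m23"], Gs[, "m14"], Gs[, "m24"])
  Gs <- Gs[keep, , drop = FALSE]

  perms <- list(id = 1:4, R = c(2L, 1L, 3L, 4L),
                G = c(1L, 2L, 4L, 3L), RG = c(2L, 1L, 4L, 3L))
  block_keys <- function(states, s) {
    wts <- numeric(ncol(states))
    names(wts) <- colnames(states)
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      nm <- paste0("m", s[i], s[j])
      if (nm %in% names(wts)) wts[nm] <- wts[nm] + .pos_weight(i, j)
    }
    as.vector(states %*% wts)
  }
  keyR <- lapply(perms, function(s) block_keys(Rs, s))
  keyG <- lapply(perms, function(s) block_keys(Gs, s))

  propR1 <- .col_props(Rs[, 1:3, drop = FALSE])
  propR2 <- .col_props(Rs[, 4:6, drop = FALSE])
  propG1 <- .col_props(Gs[, 1:3, drop = FALSE])
  propG2 <- .col_props(Gs[, 4:6, drop = FALSE])

  structure(list(
    W = as.integer(W), Rs = Rs, Gs = Gs, keyR = keyR, keyG = keyG,
    n_col_states = n,
    # per-pair aggregates, ready for weighting and filtering
    kR = propR1$and_or + propR2$and_or,
    kG = propG1$and_or + propG2$and_or,
    nzR = propR1$nz + propR2$nz, nzG = propG1$nz + propG2$nz,
    weakR = propR1$has_weak | propR2$has_weak,
    weakG = propG1$has_weak | propG2$has_weak,
    strongR = propR1$has_strong | propR2$has_strong,
    strongG = propG1$has_strong | propG2$has_strong
  ), class = "model_space")
}

#' @export
print.model_space <- function(x, ...) {
  cnt <- space_counts(x)
  cat("4-node regulatory model space (weights 1/", x$W, ")\n", sep = "")
  cat("  admissible column states:  ", x$n_col_states, "\n", sep = "")
  cat("  constrained matrices:      ", format(cnt["constrained"], big.mark = ","), "\n", sep = "")
  cat("  canonical (mirror orbits): ", format(cnt["canonical"], big.mark = ","), "\n", sep = "")
  cat("  logic-expanded models:     ", format(cnt["expanded"], big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Exact counts of the constrained, canonical and logic-expanded space
#'
#' Iterates over gene-column pairs (vectorised over all regulator-column
#' pairs) computing, for every admissible matrix, its key under the four
#' mirror relabelings. A matrix is canonical when its own key is the orbit
#' minimum; the logic expansion contributes a factor 2 per node whose two
#' incoming edges have equal weight magnitude.
#'
#' @param space a [model_space()] object.
#' @return named numeric vector with elements `unconstrained` (5^16),
#'   `constrained`, `canonical` and `expanded`.
#' @export
space_counts <- function(space) {
  stopifnot(inherits(space, "model_space"))
  cache <- attr(space, "counts")
  if (!is.null(cache)) return(cache)
  nG <- nrow(space$Gs)
  facR <- 2^space$kR
  canonical <- 0
  expanded <- 0
  for (g in seq_len(nG)) {
    k1 <- space$keyR$id + space$keyG$id[g]
    kmin <- pmin(k1,
                 space$keyR$R + space$keyG$R[g],
                 space$keyR$G + space$keyG$G[g],
                 space$keyR$RG + space$keyG$RG[g])
    can <- k1 == kmin
    canonical <- canonical + sum(can)
    expanded <- expanded + sum(facR[can]) * 2^space$kG[g]
  }
  out <- c(unconstrained = 5^16,
           constrained = as.numeric(nrow(space$Rs)) * nG,
           canonical = canonical, expanded = expanded)
  out
}

#' Enumerate canonical matrices
#'
#' Returns the (regulator-pair, gene-pair) state indices of every canonical
#' matrix, i.e. one representative (the key-minimal member) per mirror orbit.
#' With about 2.3 million rows this is the largest object the model-space
#' module creates (~40 MB); decode slices on demand with [decode_models()].
#'
#' @param space a [model_space()] object.
#' @return list with integer vectors `r`, `g` and the numeric `key` of each
#'   canonical matrix, in key order within gene-column blocks.
#' @export
canonical_models <- function(space) {
  stopifnot(inherits(space, "model_space"))
  nG <- nrow(space$Gs)
  rs <- vector("list", nG)
  for (g in seq_len(nG)) {
    k1 <- space$keyR$id + space$keyG$id[g]
    kmin <- pmin(k1,
                 space$keyR$R + space$keyG$R[g],
                 space$keyR$G + space$keyG$G[g],
                 space$keyR$RG + space$keyG$RG[g])
    rs[[g]] <- which(k1 == kmin)
  }
  r <- unlist(rs)
  g <- rep.int(seq_len(nG), lengths(rs))
  list(r = r, g = g, key = space$keyR$id[r] + space$keyG$id[g])
}

#' Decode state indices into edge-weight matrices
#'
#' @param space a [model_space()] object.
#' @param r,g parallel state-index vectors as returned by
#'   [canonical_models()] or [sample_models()].
#' @param W strong-edge magnitude to resolve codes with (defaults to the
#'   space's W).
#' @return integer matrix, one model per row, 16 row-major entries.
#' @export
decode_models <- function(space, r, g, W = space$W) {
  stopifnot(inherits(space, "model_space"), length(r) == length(g))
  vals <- weight_alphabet(W)
  M <- matrix(0L, length(r), 16L)
  fill <- function(states, idx) {
    for (nm in colnames(states)) {
      i <- as.integer(substr(nm, 2L, 2L))
      j <- as.integer(substr(nm, 3L, 3L))
      M[, (i - 1L) * 4L + j] <<- vals[states[idx, nm] + 1L]
    }
  }
  fill(space$Rs, r)
  fill(space$Gs, g)
  M
}

# ---------------------------------------------------------------------------
# single-matrix operations

#' Base-5 key of an edge-weight matrix
#'
#' @inheritParams passes_conditions
#' @return numeric scalar; exact integer below 2^53.
#' @export
matrix_key <- function(m, W = 5L) {
  m <- .check_matrix(m, W)
  codes <- .values_to_codes(t(m), W)  # row-major flattening
  sum(codes * 5^(15:0))
}

#' Mirror orbit of a matrix
#'
#' The biological labels R1/R2 and G1/G2 are arbitrary, so each matrix has up
#' to three mirror images under swapping the regulators, the genes, or both
#' (rows and columns are relabelled jointly).
#'
#' @inheritParams passes_conditions
#' @return list of 4 matrices (with duplicates for symmetric matrices):
#'   identity, regulator swap, gene swap, both.
#' @export
mirror_orbit <- function(m, W = 5L) {
  m <- .check_matrix(m, W)
  perms <- list(1:4, c(2L, 1L, 3L, 4L), c(1L, 2L, 4L, 3L), c(2L, 1L, 4L, 3L))
  lapply(perms, function(s) m[s, s, drop = FALSE])
}

#' Canonical representative of a mirror orbit
#'
#' @inheritParams passes_conditions
#' @return the orbit member with the smallest row-major base-5 key;
#'   idempotent.
#' @export
canonicalize <- function(m, W = 5L) {
  orb <- mirror_orbit(m, W)
  keys <- vapply(orb, matrix_key, numeric(1), W = W)
  orb[[which.min(keys)]]
}

#' Model complexity, active nodes and quantitative edge difference
#'
#' Complexity is the number of edges. A model has a quantitative edge
#' difference when its nonzero edges span both magnitudes (weak and strong),
#' the property the survey shows to be near-required for inversion.
#'
#' @inheritParams passes_conditions
#' @return `complexity()`: integer; `active_nodes()`: character vector of
#'   node names touched by an edge; `has_quant_edge_difference()`: logical.
#' @export
complexity <- function(m, W = 5L) {
  m <- .check_matrix(m, W)
  sum(m != 0L)
}

#' @rdname complexity
#' @export
active_nodes <- function(m, W = 5L) {
  m <- .check_matrix(m, W)
  used <- rowSums(m != 0L) > 0L | colSums(m != 0L) > 0L
  NODE_NAMES[used]
}

#' @rdname complexity
#' @export
has_quant_edge_difference <- function(m, W = 5L) {
  m <- .check_matrix(m, W)
  a <- abs(m[m != 0L])
  length(a) > 0L && any(a == 1L) && any(a > 1L)
}

# ---------------------------------------------------------------------------
# logic expansion

.incoming <- function(m, j) {
  w <- m[, j]
  w[j] <- 0L
  w[w != 0L]
}

# per-node logic possibilities for one matrix: returns list with
# $expandable (two incoming edges of equal magnitude) and $tag (fixed tag
# for non-expandable nodes)
.node_logic <- function(m) {
  expandable <- logical(4L)
  tag <- character(4L)
  for (j in 1:4) {
    w <- .incoming(m, j)
    if (length(w) <= 1L) {
      tag[j] <- "SINGLE"
    } else if (abs(w[1L]) == abs(w[2L])) {
      expandable[j] <- TRUE
      tag[j] <- NA_character_
    } else if (sign(w[1L]) != sign(w[2L])) {
      tag[j] <- "INHIBITION_DOMINANT"
    } else {
      tag[j] <- "OR"
    }
  }
  list(expandable = expandable, tag = tag)
}

#' Expand a matrix into its Petri-net logic variants
#'
#' Each node with two incoming edges of equal weight magnitude yields two
#' model variants, one combining the inputs with AND logic and one with OR
#' logic; two incoming edges of different magnitude use OR only, and nodes
#' with one incoming edge need no combination rule. When the two inputs point
#' in opposite directions, inhibition dominates the activation in both
#' generated variants. The expansion factor is therefore 2^k with k the
#' number of equal-magnitude input pairs.
#'
#' @inheritParams passes_conditions
#' @return list of model specs; each has elements `matrix`, `and_flags`
#'   (integer 4-vector, 1 = AND) and `logic` (per-node tags among SINGLE, OR,
#'   AND, INHIBITION_DOMINANT).
#' @export
expand_logic <- function(m, W = 5L) {
  m <- .check_matrix(m, W)
  nl <- .node_logic(m)
  idx <- which(nl$expandable)
  k <- length(idx)
  out <- vector("list", 2^k)
  for (v in seq_len(2^k) - 1L) {
    and_flags <- integer(4L)
    if (k > 0L)
      and_flags[idx] <- bitwAnd(bitwShiftR(v, seq_len(k) - 1L), 1L)
    tag <- nl$tag
    for (j in idx) {
      w <- .incoming(m, j)
      if (sign(w[1L]) != sign(w[2L])) {
        # inhibition dominates in both generated variants; the AND/OR flag
        # has no dynamical meaning, so normalise it away
        tag[j] <- "INHIBITION_DOMINANT"
        and_flags[j] <- 0L
      } else {
        tag[j] <- if (and_flags[j] == 1L) "AND" else "OR"
      }
    }
    out[[v + 1L]] <- list(matrix = m, and_flags = and_flags, logic = tag)
  }
  out
}

#' @rdname expand_logic
#' @return `logic_expansion_count()`: the number of variants, 2^k.
#' @export
logic_expansion_count <- function(m, W = 5L) {
  m <- .check_matrix(m, W)
  2L^sum(.node_logic(m)$expandable)
}

# ---------------------------------------------------------------------------
# sampling and serialization

#' Sample logic-expanded models uniformly
#'
#' Draws models uniformly from the expanded space by sampling canonical
#' matrices with probability proportional to their logic-expansion factor and
#' then a uniform logic variant. Per-model rng seeds are derived from the
#' global seed and the model key, so chunked or parallel simulation of the
#' same sample reproduces identical results.
#'
#' @param space a [model_space()] object.
#' @param n number of models to draw.
#' @param seed integer seed governing both the draw and downstream
#'   simulation seeds.
#' @param canon optionally a precomputed [canonical_models()] list, to avoid
#'   recomputing it across samples.
#' @return list with `matrix` (n x 16 integer), `and_flags` (n x 4 integer),
#'   `key`, `variant` and `sim_seeds`.
#' @export
sample_models <- function(space, n, seed, canon = NULL) {
  stopifnot(inherits(space, "model_space"))
  if (is.null(canon)) canon <- canonical_models(space)
  kk <- space$kR[canon$r] + space$kG[canon$g]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  i <- sample.int(length(canon$r), n, replace = TRUE, prob = 2^kk)
  variant <- floor(stats::runif(n) * 2^kk[i])
  mats <- decode_models(space, canon$r[i], canon$g[i])
  and_flags <- matrix(0L, n, 4L)
  for (q in seq_len(n)) {
    nl <- .node_logic(matrix(mats[q, ], 4L, 4L, byrow = TRUE))
    idx <- which(nl$expandable)
    if (length(idx))
      and_flags[q, idx] <- bitwAnd(bitwShiftR(as.integer(variant[q]),
                                              seq_along(idx) - 1L), 1L)
  }
  key <- canon$key[i]
  list(matrix = mats, and_flags = and_flags, key = key,
       variant = as.integer(variant),
       sim_seeds = derive_sim_seeds(seed, key, variant))
}

#' Per-model simulation seeds
#'
#' Deterministic mix of the global seed with the model key and logic-variant
#' index. Models are independent work items: the same (seed, model) pair maps
#' to the same stream regardless of batch composition or order.
#'
#' @param seed global integer seed.
#' @param key model matrix keys ([matrix_key()]).
#' @param variant logic-variant indices.
#' @return numeric vector of seeds (exact integers below 2^53).
#' @export
derive_sim_seeds <- function(seed, key, variant = 0L) {
  (key * 16L + (variant %% 16L)) * 1024 + (as.numeric(seed) %% 1024)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Read and write model tables
#'
#' One model per line: 16 tab-separated integers (row-major edge weights)
#' followed by the four per-node logic tags joined with `,`.
#'
#' @param models list of model specs as produced by [expand_logic()].
#' @param file path.
#' @return `read_model_table()` returns a list of model specs.
#' @export
write_model_table <- function(models, file) {
  lines <- vapply(models, function(sp) {
    paste(c(as.integer(t(sp$matrix)), paste(sp$logic, collapse = ",")),
          collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_model_table
#' @param W strong-edge magnitude for validation.
#' @export
read_model_table <- function(file, W = 5L) {
  lines <- readLines(file)
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    stopifnot(length(f) == 17L)
    m <- matrix(as.integer(f[1:16]), 4L, 4L, byrow = TRUE)
    logic <- strsplit(f[17L], ",", fixed = TRUE)[[1L]]
    list(matrix = .check_matrix(m, W),
         and_flags = as.integer(logic == "AND"),
         logic = logic)
  })
}
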