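# Independent naive-loop reference implementations used as oracles.

naive_gd <- function(A, B, t_steps = 3L) {
  n <- nrow(A)
  norm_rows <- function(M) {
    out <- M
    for (i in 1:n) {
      s <- sum(M[i, ])
      if (s > 0) out[i, ] <- M[i, ] / s
    }
    out
  }
  pw <- function(M, t) {
    R <- diag(n)
    for (k in seq_len(t)) R <- R %*% M
    R
  }
  Ta <- norm_rows(A); Tb <- norm_rows(B)
  inf <- 0
  for (i in 1:n) if (sum(A[i, ]) > 0 || sum(B[i, ]) > 0) inf <- inf + 1
  ds <- sapply(t_steps, function(t) sum(abs(pw(Ta, t) - pw(Tb, t))) / inf)
  max(1 - mean(ds) / 2, -1)
}

naive_scc <- function(A, B, max_stratum) {
  n <- nrow(A)
  num <- 0; den <- 0
  for (s in 1:max_stratum) {
    x <- c(); y <- c()
    for (i in 1:(n - s)) {
      x <- c(x, A[i, i + s]); y <- c(y, B[i, i + s])
    }
    if (stats::var(x) == 0 || stats::var(y) == 0) next
    w <- length(x) * sqrt(stats::var(rank(x)) * stats::var(rank(y)))
    num <- num + w * stats::cor(x, y)
    den <- den + w
  }
  num / den
}

naive_insulation <- function(M, w) {
  n <- nrow(M)
  prof <- rep(NA_real_, n)
  for (b in w:(n - w)) {
    acc <- 0; cnt <- 0
    for (i in (b - w + 1):b) for (j in (b + 1):(b + w)) {
      acc <- acc + M[i, j]; cnt <- cnt + 1
    }
    prof[b + 1] <- acc / cnt
  }
  prof
}

test_that("identical maps score 1 on both similarity metrics", {
  for (seed in 1:3) {
    mp <- random_sym_map(30, seed = seed, sparsity = 0.2)
    expect_equal(genomedisco_score(mp, mp), 1)
    expect_equal(scc_score(mp, mp), 1)
  }
})

test_that("GenomeDISCO matches a hand-computed disjoint-support toy", {
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 1
  B <- matrix(0, 4, 4); B[3, 4] <- B[4, 3] <- 1
  # transition matrices are permutations; A^3 and B^3 disagree on 4 unit
  # rows over 4 informative rows: d = 4/4 = 1 -> score = 1 - 1/2 = 0.5
  expect_equal(genomedisco_score(A, B), 0.5)
  expect_equal(genomedisco_score(A, B), naive_gd(A, B))
})

test_that("similarity metrics are symmetric in their arguments", {
  a <- random_sym_map(25, seed = 4, sparsity = 0.3)
  b <- random_sym_map(25, seed = 5, sparsity = 0.3)
  expect_equal(genomedisco_score(a, b), genomedisco_score(b, a))
  expect_equal(scc_score(a, b), scc_score(b, a))
})

test_that("GD and SCC agree with naive implementations on random maps", {
  for (seed in 1:3) {
    a <- random_sym_map(50, seed = seed, sparsity = 0.4)$matrix
    b <- random_sym_map(50, seed = seed + 10, sparsity = 0.4)$matrix
    expect_equal(genomedisco_score(a, b, t_steps = c(1L, 3L)),
                 naive_gd(a, b, c(1L, 3L)), tolerance = 1e-8)
    expect_equal(scc_score(a, b, max_stratum = 20),
                 naive_scc(a, b, 20), tolerance = 1e-8)
  }
})

test_that("SCC detects decorrelation and anti-correlation", {
  n <- 200
  mp <- random_sym_map(n, seed = 8)
  A <- mp$matrix
  # per-stratum independent shuffle kills the correlation
  set.seed(42)
  B <- A
  for (s in 1:(n - 1)) {
    idx <- seq_len(n - s)
    vals <- A[cbind(idx, idx + s)]
    sh <- vals[sample.int(length(vals))]
    B[cbind(idx, idx + s)] <- sh
    B[cbind(idx + s, idx)] <- sh
  }
  expect_lt(abs(scc_score(A, B, max_stratum = 64)), 0.1)
  # strict anti-correlation: every stratum Pearson is -1
  C <- max(A) + 1 - A
  expect_equal(scc_score(A, C, max_stratum = 64), -1, tolerance = 1e-12)
})

test_that("SCC is invariant to shared monotone affine rescaling", {
  a <- random_sym_map(40, seed = 2)$matrix
  b <- random_sym_map(40, seed = 3)$matrix
  s0 <- scc_score(a, b, max_stratum = 15)
  s1 <- scc_score(3.7 * a + 2, 3.7 * b + 2, max_stratum = 15)
  expect_equal(s0, s1, tolerance = 1e-10)
})

test_that("degenerate strata are rejected", {
  expect_error(scc_score(matrix(1, 5, 5), matrix(1, 5, 5), max_stratum = 3),
               "no informative strata")
})

test_that("insulation calling finds the junction of two TAD blocks", {
  mp <- two_tad_map(block = 8)
  bs <- call_tad_boundaries(mp, window = 4)
  expect_identical(bs$boundaries, 8L)
  # the profile itself matches the naive double loop
  prof <- naive_insulation(mp$matrix, 4)
  expect_equal(prof[9], 0.5)  # cross-block square is all-outside contact
})

test_that("constant maps yield no boundaries; scaling leaves calls fixed", {
  expect_length(call_tad_boundaries(contact_map(matrix(2, 20, 20)),
                                    window = 4)$boundaries, 0L)
  mp <- random_sym_map(48, seed = 12)
  b1 <- call_tad_boundaries(mp, window = 5)
  b2 <- call_tad_boundaries(contact_map(7.3 * mp$matrix), window = 5)
  expect_identical(b1$boundaries, b2$boundaries)
  expect_error(call_tad_boundaries(mp, window = 30), "too large")
})

test_that("TAD F1 matching follows the exhaustive oracle", {
  r <- tad_f1(c(10, 20, 30), c(11, 25), tol = 1)
  expect_identical(r$TP, 1L)
  expect_identical(r$FP, 2L)
  expect_identical(r$FN, 1L)
  expect_equal(r$f1, 0.4)
  ident <- tad_f1(c(1, 5, 9, 13, 17), c(1, 5, 9, 13, 17), tol = 1)
  expect_equal(ident$f1, 1)
  expect_identical(ident$TP, 5L)
  empty <- tad_f1(integer(0), c(3, 8))
  expect_equal(empty$f1, 0)
  expect_identical(empty$FN, 2L)
})

test_that("TAD F1 is symmetric and one-to-one (no double matches)", {
  a <- c(4, 9, 15); b <- c(5, 10, 22)
  expect_equal(tad_f1(a, b)$f1, tad_f1(b, a)$f1)
  # two predictions near one target: only one may match
  r <- tad_f1(c(9, 11), c(10), tol = 1)
  expect_identical(r$TP, 1L)
  expect_identical(r$FP, 1L)
})

test_that("F1 matches a brute-force assignment search on random sets", {
  brute_best_tp <- function(p, t, tol) {
    # maximum bipartite matching by exhaustive recursion (small sets)
    rec <- function(pi, used) {
      if (pi > length(p)) return(0L)
      best <- rec(pi + 1L, used)
      for (ti in seq_along(t)) {
        if (!used[ti] && abs(p[pi] - t[ti]) <= tol) {
          u2 <- used; u2[ti] <- TRUE
          best <- max(best, 1L + rec(pi + 1L, u2))
        }
      }
      best
    }
    rec(1L, rep(FALSE, length(t)))
  }
  for (seed in 1:5) {
    set.seed(seed)
    p <- sort(sample(0:40, 6))
    t_ <- sort(sample(0:40, 5))
    got <- tad_f1(p, t_, tol = 2)
    best <- brute_best_tp(p, t_, 2)
    # greedy nearest-first is optimal for interval matching on a line
    expect_identical(got$TP, best)
    expect_equal(got$f1, 2 * best / (2 * best + (6 - best) + (5 - best)))
  }
})
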