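test_that("cosine similarity matches hand-evaluated cases", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 4, 4)), 1)
  expect_equal(cosine_similarity(c(3, 4), c(4, 3)), 24 / 25)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "grid")
})

test_that("pearson similarity matches hand-evaluated cases", {
  expect_equal(pearson_similarity(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_similarity(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson_similarity(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_similarity(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("spearman similarity is a rank-transform pearson", {
  x <- c(2, 7, 1, 9, 4)
  # invariant under strictly monotone transforms
  expect_equal(spearman_similarity(x, exp(x)), 1)
  expect_equal(spearman_similarity(x^3, x), 1)
  expect_equal(spearman_similarity(c(1, 2, 3), c(9, 1, 5)), -0.5)
  # order reversal with distinct values
  expect_equal(spearman_similarity(x, -x), -1)
  # ties receive average ranks (matches cor method = "spearman")
  y <- c(5, 5, 1, 9, 9)
  expect_equal(spearman_similarity(x, y),
               suppressWarnings(cor(x, y, method = "spearman")))
})

test_that("similarity measures obey scale invariance", {
  set.seed(71)
  for (rep in 1:5) {
    x <- rexp(12) + 0.1
    y <- rexp(12) + 0.1
    a <- runif(1, 0.5, 10)
    expect_equal(cosine_similarity(a * x, y), cosine_similarity(x, y))
    expect_equal(pearson_similarity(a * x, y), pearson_similarity(x, y))
    expect_equal(spearman_similarity(a * x, y), spearman_similarity(x, y))
    expect_equal(cosine_similarity(x, y), cosine_similarity(y, x))
    expect_equal(pearson_similarity(x, y), pearson_similarity(y, x))
    expect_true(cosine_similarity(x, y) >= 0 && cosine_similarity(x, y) <= 1)
    expect_true(abs(pearson_similarity(x, y)) <= 1 + 1e-12)
  }
})

test_that("partial and part correlations match the two-regression oracle", {
  x <- c(2, 4, 6, 9)
  yi <- c(1, 2, 3, 5)
  z <- c(1, 1, 2, 2)
  got_partial <- partial_similarity(x, yi, list(z))
  got_part <- part_similarity(x, yi, list(z))
  expect_equal(got_partial, oracle_partial(x, yi, cbind(z)),
               tolerance = 1e-12)
  expect_equal(got_part, oracle_part(x, yi, cbind(z)), tolerance = 1e-12)
  # semipartial conditions one side only, so the two values differ here
  expect_false(isTRUE(all.equal(got_partial, got_part)))
  # and part is asymmetric in (x, yi)
  expect_false(isTRUE(all.equal(part_similarity(x, yi, list(z)),
                                part_similarity(yi, x, list(z)))))
  # empty conditioning set: both reduce to Pearson exactly
  expect_identical(partial_similarity(x, yi, NULL),
                   pearson_similarity(x, yi))
  expect_identical(part_similarity(x, yi, list()),
                   pearson_similarity(x, yi))
})

test_that("conditioning spectra orthogonal to the pair leave Pearson unchanged", {
  set.seed(5)
  for (rep in 1:20) {
    tr <- orthogonal_triple(g = 24, h = 3)
    r0 <- pearson_similarity(tr$x, tr$yi)
    expect_equal(partial_similarity(tr$x, tr$yi, tr$Z), r0,
                 tolerance = 1e-10)
    expect_equal(part_similarity(tr$x, tr$yi, tr$Z), r0, tolerance = 1e-10)
  }
})

test_that("two-step conditioning set equals the full-ranking oracle", {
  set.seed(13)
  for (rep in 1:25) {
    g <- sample(8:30, 1)
    m <- sample(4:9, 1)
    q <- sample(2:5, 1)
    Rm <- rand_spectrum_matrix(g, m)
    ref <- pl_from_matrix(Rm)
    x <- rexp(g) + 0.01
    i <- sample(m, 1)
    expect_equal(two_step_conditioning_set(x, ref, i, q),
                 oracle_two_step_set(x, Rm, i, q))
  }
  # q >= m - 1 returns everything except i
  Rm <- rand_spectrum_matrix(10, 5)
  ref <- pl_from_matrix(Rm)
  expect_equal(two_step_conditioning_set(Rm[, 2], ref, 2, 10),
               c(1L, 3L, 4L, 5L))
  # constructed case: only two reference peaks correlate positively
  base <- c(1, 2, 3, 4, 5, 6)
  Rm2 <- cbind(base + rnorm(6, 0, 0.05), base + rnorm(6, 0, 0.05),
               rev(base), rev(base) + rnorm(6, 0, 0.05), rev(base) * 2)
  ref2 <- pl_from_matrix(Rm2)
  # the two positively correlated peaks fill the window when i is not
  # one of them; otherwise the remaining one plus the least-negative
  expect_equal(two_step_conditioning_set(base, ref2, 5, 2), c(1L, 2L))
  expect_equal(two_step_conditioning_set(base, ref2, 3, 2), c(1L, 2L))
  expect_equal(two_step_conditioning_set(base, ref2, 1, 2),
               oracle_two_step_set(base, Rm2, 1, 2))
})

test_that("two-step partial/part equal the residual-regression oracle", {
  set.seed(29)
  for (rep in 1:30) {
    g <- sample(10:50, 1)
    m <- sample(4:10, 1)
    q <- sample(2:5, 1)
    Rm <- rand_spectrum_matrix(g, m)
    ref <- pl_from_matrix(Rm)
    x <- rexp(g) + 0.01
    i <- sample(m, 1)
    for (kind in c("partial", "part")) {
      got <- two_step_similarity(x, ref, i, similarity_spec(kind, q = q))
      expect_equal(got, oracle_two_step(x, Rm, i, q, kind),
                   tolerance = 1e-10)
    }
  }
  # q >= m - 1 with g > m reduces to full conditioning
  Rm <- rand_spectrum_matrix(20, 6)
  ref <- pl_from_matrix(Rm)
  x <- rexp(20)
  expect_equal(two_step_similarity(x, ref, 3, similarity_spec("partial", q = 5)),
               partial_similarity(x, Rm[, 3], Rm[, -3]), tolerance = 1e-10)
  expect_equal(two_step_similarity(x, ref, 3, similarity_spec("part", q = 5)),
               part_similarity(x, Rm[, 3], Rm[, -3]), tolerance = 1e-10)
})

test_that("duplicate spectra in the conditioning set do not crash", {
  set.seed(31)
  Rm <- rand_spectrum_matrix(15, 5)
  Rm[, 4] <- Rm[, 2]          # exact duplicate pair
  ref <- pl_from_matrix(Rm)
  x <- Rm[, 2] * rlnorm(15, 0, 0.05)
  # peak 2's duplicate (peak 4) ranks into the window; the residual of
  # peak 2 given its duplicate collapses, so the score is NA in matrix
  # form rather than a crash
  S <- similarity_matrix(pl_from_matrix(cbind(x), role = "target"), ref,
                         similarity_spec("partial", q = 3))
  expect_true(all(is.na(S[1, c(2, 4)])))
  expect_true(all(is.finite(S[1, c(1, 3, 5)])))
  expect_error(two_step_similarity(x, ref, 2, similarity_spec("partial", q = 3)),
               "undefined")
})

test_that("similarity_matrix equals pairwise recomputation for all measures", {
  set.seed(47)
  g <- 40
  Tm <- rand_spectrum_matrix(g, 5)
  Rm <- rand_spectrum_matrix(g, 7)
  target <- pl_from_matrix(Tm, role = "target")
  ref <- pl_from_matrix(Rm)
  specs <- list(similarity_spec("cosine"), similarity_spec("pearson"),
                similarity_spec("spearman"),
                similarity_spec("partial"), similarity_spec("part"),
                similarity_spec("partial", q = 3),
                similarity_spec("part", q = 4))
  for (spec in specs) {
    S <- similarity_matrix(target, ref, spec)
    expect_equal(dim(S), c(5L, 7L))
    for (j in 1:5) {
      for (i in 1:7) {
        expect_equal(S[j, i], oracle_sim_value(Tm[, j], Rm, i, spec),
                     tolerance = 1e-10,
                     info = sprintf("%s q=%s (%d,%d)", spec$kind,
                                    deparse(spec$q), j, i))
      }
    }
  }
  # self-comparison under cosine has a unit diagonal
  Sc <- similarity_matrix(ref, ref, similarity_spec("cosine"))
  expect_equal(diag(Sc), rep(1, 7), tolerance = 1e-12)
  # 1x1 matrix equals the single-pair call
  S1 <- similarity_matrix(target[1], ref[1], similarity_spec("cosine"))
  expect_equal(S1[1, 1], cosine_similarity(Tm[, 1], Rm[, 1]))
})
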