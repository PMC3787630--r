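test_that("mixture score combines distance and similarity as specified", {
  expect_equal(mixture_score(3, 0.8, 0), 0.8)
  expect_equal(mixture_score(0, -0.4, 1), 1)
  expect_equal(mixture_score(1, 0.8, 0.5), 0.65)
  # distance term is strictly decreasing in d
  expect_true(mixture_score(1, 0, 1) > mixture_score(2, 0, 1))
  expect_error(mixture_score(1, 0.5, 1.2), "\\[0, 1\\]")
  expect_error(mixture_score(-1, 0.5, 0.5), "non-negative")
})

make_fixture <- function(seed, n = NULL, m = NULL, g = 25) {
  set.seed(seed)
  if (is.null(n)) n <- sample(3:12, 1)
  if (is.null(m)) m <- sample(3:12, 1)
  target <- pl_from_matrix(rand_spectrum_matrix(g, n), role = "target")
  ref <- pl_from_matrix(rand_spectrum_matrix(g, m))
  list(target = target, ref = ref)
}

test_that("every aligner equals the enumerate-and-select oracle", {
  specs <- list(similarity_spec("cosine"), similarity_spec("pearson"),
                similarity_spec("partial", q = 3))
  for (seed in 1:8) {
    fx <- make_fixture(seed)
    dspec <- distance_spec(sample(c("euclidean", "maximum",
                                    "manhattan", "canberra"), 1))
    sspec <- specs[[1 + seed %% length(specs)]]
    k <- sample(1:6, 1)
    rho <- runif(1, 0.1, 0.9)
    w <- runif(1)
    expect_equal(match_df(align_pad(fx$target, fx$ref, dspec)),
                 oracle_align("pad", fx$target, fx$ref, dspec))
    expect_equal(match_df(align_pas(fx$target, fx$ref, sspec)),
                 oracle_align("pas", fx$target, fx$ref, sspec = sspec))
    expect_equal(match_df(align_dw_pas(fx$target, fx$ref, dspec, k, sspec)),
                 oracle_align("dw_pas", fx$target, fx$ref, dspec,
                              sspec = sspec, k = k))
    expect_equal(match_df(align_sw_pad(fx$target, fx$ref, sspec, rho, dspec)),
                 oracle_align("sw_pad", fx$target, fx$ref, dspec,
                              sspec = sspec, rho = rho))
    expect_equal(match_df(align_pam(fx$target, fx$ref, w, dspec, sspec)),
                 oracle_align("pam", fx$target, fx$ref, dspec,
                              sspec = sspec, w = w))
  }
})

test_that("the reduction chain between aligners holds", {
  for (seed in 11:15) {
    fx <- make_fixture(seed)
    m <- n_peaks(fx$ref)
    sspec <- similarity_spec("cosine")
    dspec <- distance_spec("euclidean")
    # DW-PAS with a vacuous window is PAS
    expect_equal(match_df(align_dw_pas(fx$target, fx$ref, dspec, m, sspec)),
                 match_df(align_pas(fx$target, fx$ref, sspec)))
    # DW-PAS with a singleton window is PAD
    expect_equal(match_df(align_dw_pas(fx$target, fx$ref, dspec, 1, sspec)),
                 match_df(align_pad(fx$target, fx$ref, dspec)))
    # SW-PAD at rho = 0 with a nonnegative measure is PAD
    expect_equal(match_df(align_sw_pad(fx$target, fx$ref, sspec, 0, dspec)),
                 match_df(align_pad(fx$target, fx$ref, dspec)))
    # PAM collapses to PAS at w = 0 and to PAD at w = 1
    expect_equal(match_df(align_pam(fx$target, fx$ref, 0, dspec, sspec)),
                 match_df(align_pas(fx$target, fx$ref, sspec)))
    expect_equal(match_df(align_pam(fx$target, fx$ref, 1, dspec, sspec)),
                 match_df(align_pad(fx$target, fx$ref, dspec)))
  }
})

test_that("ties break by distance then lower reference index", {
  # two references with identical spectra: similarity ties at the max
  M <- cbind(c(5, 1, 2), c(5, 1, 2), c(1, 6, 1))
  ref <- pl_from_matrix(M, rt1 = c(100, 40, 70), rt2 = c(1, 1, 1))
  target <- pl_from_matrix(cbind(c(5, 1, 2)), rt1 = 50, rt2 = 1,
                           role = "target")
  r <- align_pas(target, ref, similarity_spec("cosine"))
  expect_equal(r$matches$ref, 2L)   # closer of the two tied references
  # exact distance tie: lower index wins
  ref2 <- pl_from_matrix(M, rt1 = c(60, 40, 70), rt2 = c(1, 1, 1))
  r2 <- align_pad(target, ref2, distance_spec("euclidean"))
  expect_equal(r2$matches$ref, 1L)
})

test_that("targets with empty windows or undefined rows stay unmatched", {
  fx <- make_fixture(21, n = 5, m = 6)
  # a cut-off above every similarity leaves zero matches
  r <- align_sw_pad(fx$target, fx$ref, similarity_spec("cosine"), 1,
                    distance_spec("euclidean"))
  expect_equal(n_matched(r), 0L)
  ev <- evaluate_alignment(r, true_pair_set(1:3, 1:3))
  expect_true(is.na(ev$F1))
  expect_equal(ev$TPR, 0)
  # a target whose similarity row is all-undefined is skipped by PAS
  Tm <- rand_spectrum_matrix(10, 3)
  Tm[, 2] <- 7                       # constant spectrum: Pearson undefined
  target <- pl_from_matrix(Tm, role = "target")
  ref <- pl_from_matrix(rand_spectrum_matrix(10, 4))
  r2 <- align_pas(target, ref, similarity_spec("pearson"))
  expect_equal(r2$matches$target, c(1L, 3L))
})

test_that("nearest-neighbour matching recovers truth when jitter is small", {
  # reference peaks on a coarse grid; jitter far below half the spacing
  set.seed(99)
  m <- 20
  rt1 <- seq(100, 2000, length.out = m)
  rt2 <- rep(c(1, 3), length.out = m)
  ref <- pl_from_matrix(rand_spectrum_matrix(8, m), rt1 = rt1, rt2 = rt2)
  jitter <- runif(m, -5, 5)     # spacing is 100, jitter at most 5
  target <- pl_from_matrix(rand_spectrum_matrix(8, m),
                           rt1 = rt1 + jitter, rt2 = rt2, role = "target")
  r <- align_pad(target, ref, distance_spec("euclidean"))
  expect_equal(r$matches$ref, seq_len(m))
  expect_equal(evaluate_alignment(r, true_pair_set(1:m, 1:m))$F1, 1)
})

test_that("alignment is deterministic and one-to-one mode avoids reuse", {
  fx <- make_fixture(33, n = 10, m = 6)
  sspec <- similarity_spec("cosine")
  a <- align_pas(fx$target, fx$ref, sspec)
  b <- align_pas(fx$target, fx$ref, sspec)
  expect_identical(a$matches, b$matches)
  # more targets than references: per-target mode reuses references,
  # greedy one-to-one mode does not
  expect_true(any(duplicated(a$matches$ref)))
  g <- align_pas(fx$target, fx$ref, sspec, one_to_one = TRUE)
  expect_false(any(duplicated(g$matches$ref)))
  expect_lte(n_matched(g), 6L)
})

test_that("alignment results serialize to the match CSV dialect", {
  fx <- make_fixture(41, n = 4, m = 5)
  r <- align_pam(fx$target, fx$ref, 0.3, distance_spec("canberra"),
                 similarity_spec("cosine"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_alignment(r, path)
  df <- utils::read.csv(path)
  expect_named(df, c("target_index", "ref_index", "score", "method"))
  expect_equal(df$target_index, r$matches$target - 1L)
  expect_equal(df$method, rep("pam", nrow(df)))
})
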