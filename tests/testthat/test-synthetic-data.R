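test_that("generation is deterministic and respects the config contract", {
  cfg <- synthetic_config(n_compounds = 30, shared_fraction = 0.8,
                          extra_ref = 3, extra_target = 2, seed = 77)
  a <- generate_run_pair(cfg)
  b <- generate_run_pair(cfg)
  expect_identical(a$reference$rt1, b$reference$rt1)
  expect_identical(intensity_matrix(a$target), intensity_matrix(b$target))
  expect_identical(a$truth, b$truth)
  # sizes: s shared, plus run-specific extras
  s <- round(0.8 * 30)
  expect_equal(nrow(a$truth), s)
  expect_equal(n_peaks(a$reference), s + 3)
  expect_equal(n_peaks(a$target), s + 2)
  # truth is one-to-one and in range
  expect_false(anyDuplicated(a$truth$ref) > 0)
  expect_false(anyDuplicated(a$truth$target) > 0)
  expect_true(all(a$truth$ref <= n_peaks(a$reference)))
  # same grid, valid spectra after harmonization
  Mr <- intensity_matrix(a$reference)
  Mt <- intensity_matrix(a$target)
  expect_identical(rownames(Mr), rownames(Mt))
  expect_true(all(Mr >= 0))
  expect_true(all(colSums(Mr) > 0))
  # different seed changes the draw
  c2 <- generate_run_pair(synthetic_config(n_compounds = 30,
                                           shared_fraction = 0.8,
                                           extra_ref = 3, extra_target = 2,
                                           seed = 78))
  expect_false(identical(a$reference$rt1, c2$reference$rt1))
  # config validation
  expect_error(synthetic_config(n_compounds = 10, shared_fraction = 1,
                                extra_ref = 1), "exceeds")
})

test_that("library generation is reproducible and label-complete", {
  cfg <- synthetic_config(n_compounds = 25, shared_fraction = 0.8,
                          seed = 5)
  lib1 <- generate_compound_library(cfg)
  lib2 <- generate_compound_library(cfg)
  expect_identical(lib1, lib2)
  expect_length(lib1, 25)
  expect_equal(anyDuplicated(vapply(lib1, `[[`, character(1), "label")), 0L)
  for (comp in lib1[1:5]) {
    expect_true(all(comp$intensity >= 0))
    expect_equal(max(comp$intensity), 999)
  }
})

test_that("disjoint fragment supports give near-zero cross-compound cosine", {
  cfg <- synthetic_config(n_compounds = 8, shared_fraction = 0.5,
                          extra_ref = 0, shared_fragment_pool = 0,
                          n_shared_fragments = 0, family_rate = 0,
                          n_baseline_fragments = 0, seed = 2)
  lib <- generate_compound_library(cfg)
  grid <- cfg$mz_min:cfg$mz_max
  M <- vapply(lib, function(cp) {
    v <- numeric(length(grid)); v[match(cp$mz, grid)] <- cp$intensity; v
  }, numeric(length(grid)))
  C <- crossprod(M) / outer(sqrt(colSums(M^2)), sqrt(colSums(M^2)))
  expect_equal(max(abs(C[upper.tri(C)])), 0)
})

test_that("a crowded grid raises cross-compound spectral correlation", {
  # equal pool sizes; only the compound count differs. The sparse library
  # can give many compounds globally unique channels before the grid is
  # exhausted; the dense library must reuse channels, so the average
  # off-diagonal cosine rises. A weak backbone isolates the effect.
  mk <- function(n, seed) {
    cfg <- synthetic_config(n_compounds = n, shared_fraction = 0.9,
                            extra_ref = 0, n_baseline_fragments = 0,
                            family_rate = 0, shared_intensity_frac = 0.05,
                            seed = seed)
    lib <- generate_compound_library(cfg)
    grid <- cfg$mz_min:cfg$mz_max
    M <- vapply(lib, function(cp) {
      v <- numeric(length(grid)); v[match(cp$mz, grid)] <- cp$intensity; v
    }, numeric(length(grid)))
    C <- crossprod(M) / outer(sqrt(colSums(M^2)), sqrt(colSums(M^2)))
    mean(C[upper.tri(C)])
  }
  for (seed in c(1, 31)) {
    expect_gt(mk(450, seed), mk(75, seed))
  }
})

test_that("the noise-free limit reproduces shared peaks exactly", {
  cfg <- synthetic_preset("data1_like", seed = 21,
                          rt_jitter_sd = c(0, 0), spectral_noise_cv = 0)
  p <- generate_run_pair(cfg)
  Mr <- intensity_matrix(p$reference)
  Mt <- intensity_matrix(p$target)
  for (row in seq_len(nrow(p$truth))) {
    i <- p$truth$ref[row]; j <- p$truth$target[row]
    expect_identical(Mt[, j], Mr[, i])
    expect_identical(p$target$rt1[j], p$reference$rt1[i])
  }
  # full-sharing corner: s = m = n
  cfg2 <- synthetic_config(n_compounds = 10, shared_fraction = 1,
                           extra_ref = 0, extra_target = 0, seed = 4)
  p2 <- generate_run_pair(cfg2)
  expect_equal(nrow(p2$truth), 10)
  expect_equal(n_peaks(p2$reference), 10)
  expect_equal(n_peaks(p2$target), 10)
})

test_that("sparse standards align near-perfectly, dense biology does not", {
  f1 <- function(preset, seed, ...) {
    p <- generate_run_pair(synthetic_preset(preset, seed = seed, ...))
    evaluate_alignment(align_pas(p$target, p$reference,
                                 similarity_spec("cosine")), p$truth)$F1
  }
  sparse <- mean(vapply(1:3, function(s) f1("data1_like", s), numeric(1)))
  dense <- mean(vapply(1:3, function(s) {
    f1("data2_like", s, n_compounds = 150, extra_ref = 8)
  }, numeric(1)))
  expect_gt(sparse, dense)
  expect_gt(sparse, 0.9)
})

test_that("alignment quality degrades monotonically with noise and jitter", {
  mean_f1 <- function(align_fn, seeds, ...) {
    mean(vapply(seeds, function(sd) {
      p <- generate_run_pair(synthetic_config(n_compounds = 40,
                                              shared_fraction = 0.9,
                                              extra_ref = 4, seed = sd, ...))
      evaluate_alignment(align_fn(p), p$truth)$F1
    }, numeric(1)))
  }
  pas_cos <- function(p) align_pas(p$target, p$reference,
                                   similarity_spec("cosine"))
  pad_euc <- function(p) align_pad(p$target, p$reference,
                                   distance_spec("euclidean"))
  seeds <- 1:10
  # PAS F1 is non-increasing in spectral noise (averaged over seeds)
  f1_noise <- vapply(c(0, 0.4, 1.2), function(cv) {
    mean_f1(pas_cos, seeds, spectral_noise_cv = cv)
  }, numeric(1))
  expect_true(all(diff(f1_noise) <= 1e-9))
  # PAD F1 is non-increasing in retention time jitter
  f1_jit <- vapply(c(0, 5, 25), function(sd1) {
    mean_f1(pad_euc, seeds, rt_jitter_sd = c(sd1, 0.02 * sd1 / 5))
  }, numeric(1))
  expect_true(all(diff(f1_jit) <= 1e-9))
})
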