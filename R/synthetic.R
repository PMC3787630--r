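## Synthetic GCxGC-MS peak list generator.
##
## Emulates two regimes: a sparse mixture-of-standards run (~75
## compounds) and a dense biological run (~450 compounds). Compound
## spectra are sparse nonnegative vectors on a nominal-mass grid, built
## from a shared fragment pool (inducing inter-compound spectral
## correlation, the regime where conditioning-based measures matter)
## plus compound-specific fragments. Compound-specific channels are drawn
## without replacement from the unused part of the grid while any remains,
## so a crowded grid (many compounds) produces more accidental spectral
## overlap between distinct compounds -- the key difficulty of dense
## biological data.

#' Synthetic data configuration
#'
#' @param n_compounds Number of compounds in the library.
#' @param shared_fraction Fraction of compounds present in both runs;
#'   `s = round(shared_fraction * n_compounds)` true pairs.
#' @param extra_ref,extra_target Compounds present only in the reference
#'   (resp. target) run. `s + extra_ref + extra_target` must not exceed
#'   `n_compounds`.
#' @param mz_min,mz_max Integer bounds of the nominal-mass m/z grid.
#' @param n_fragments Fragment channels per compound spectrum.
#' @param n_shared_fragments Of those, how many are drawn from the shared
#'   fragment pool.
#' @param shared_fragment_pool Size (channels) of the shared fragment
#'   pool; 0 disables shared fragments entirely.
#' @param shared_intensity_frac Fraction of each compound's total ion
#'   intensity carried by its shared-pool channels. Pool channels follow
#'   one global intensity profile (the common-fragment backbone, e.g.
#'   derivatization fragments) modulated per compound, so this parameter
#'   directly controls the baseline correlation between spectra of
#'   different compounds.
#' @param family_rate Probability that a compound is generated as a
#'   spectral variant of an earlier compound (near-identical fragment
#'   pattern, as for isomers or in-source fragments of related
#'   metabolites). Variants elute at their own retention times.
#' @param family_sdlog Log-normal sd of the intensity perturbation
#'   applied to a variant's parent spectrum.
#' @param n_baseline_fragments Number of low-intensity background
#'   channels ("grass") per compound spectrum, drawn from a background
#'   pool common to all compounds (column bleed, carry-over and
#'   deconvolution residue ions). They sit near the detection floor, are
#'   erratically censored between runs and carry no compound-specific
#'   information -- the component that degrades rank-based similarity on
#'   real data.
#' @param baseline_intensity_frac Fraction of total ion intensity spread
#'   over the baseline channels.
#' @param rt1_range,rt2_range Retention time ranges in seconds.
#' @param rt1_density `"uniform"` or `"bimodal"` first-dimension
#'   retention time density.
#' @param rt_jitter_sd Length-2 run-to-run retention time jitter standard
#'   deviations (seconds) for the two dimensions.
#' @param spectral_noise_cv Coefficient of variation of the multiplicative
#'   log-normal per-channel spectral noise (0 = none). Relative noise
#'   grows as channel intensity falls (shot-noise-like heteroscedasticity,
#'   capped at 5x the base-peak level).
#' @param channel_dropout Probability that a non-base channel is lost
#'   entirely in one observation of a spectrum (deconvolution fragment
#'   misassignment); 0 = none.
#' @param detection_floor Channels falling below this intensity after
#'   noise are censored to zero (the base peak is always kept).
#' @param area_meanlog,area_sdlog Log-normal peak area parameters.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_compounds = 75,
                             shared_fraction = 0.95,
                             extra_ref = 4,
                             extra_target = 0,
                             mz_min = 50, mz_max = 250,
                             n_fragments = 14,
                             n_shared_fragments = 8,
                             shared_fragment_pool = 12,
                             shared_intensity_frac = 0.5,
                             family_rate = 0.1,
                             family_sdlog = 0.4,
                             n_baseline_fragments = 200,
                             baseline_intensity_frac = 0.15,
                             rt1_range = c(300, 3300),
                             rt2_range = c(0.5, 5.5),
                             rt1_density = c("uniform", "bimodal"),
                             rt_jitter_sd = c(5, 0.05),
                             spectral_noise_cv = 0.4,
                             channel_dropout = 0,
                             detection_floor = 0,
                             area_meanlog = log(1e5),
                             area_sdlog = 1,
                             seed = 1) {
  rt1_density <- match.arg(rt1_density)
  cfg <- list(n_compounds = as.integer(n_compounds),
              shared_fraction = shared_fraction,
              extra_ref = as.integer(extra_ref),
              extra_target = as.integer(extra_target),
              mz_min = as.integer(mz_min), mz_max = as.integer(mz_max),
              n_fragments = as.integer(n_fragments),
              n_shared_fragments = as.integer(n_shared_fragments),
              shared_fragment_pool = as.integer(shared_fragment_pool),
              shared_intensity_frac = shared_intensity_frac,
              family_rate = family_rate,
              family_sdlog = family_sdlog,
              n_baseline_fragments = as.integer(n_baseline_fragments),
              baseline_intensity_frac = baseline_intensity_frac,
              rt1_range = rt1_range, rt2_range = rt2_range,
              rt1_density = rt1_density,
              rt_jitter_sd = rt_jitter_sd,
              spectral_noise_cv = spectral_noise_cv,
              channel_dropout = channel_dropout,
              detection_floor = detection_floor,
              area_meanlog = area_meanlog, area_sdlog = area_sdlog,
              seed = as.integer(seed))
  .validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

.validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_compounds >= 1L,
              shared_fraction >= 0, shared_fraction <= 1,
              extra_ref >= 0L, extra_target >= 0L,
              mz_max > mz_min,
              n_fragments >= 1L,
              n_shared_fragments >= 0L,
              n_shared_fragments <= n_fragments,
              shared_fragment_pool >= 0L,
              shared_intensity_frac >= 0, shared_intensity_frac < 1,
              family_rate >= 0, family_rate < 1, family_sdlog >= 0,
              n_baseline_fragments >= 0L,
              baseline_intensity_frac >= 0,
              shared_intensity_frac + baseline_intensity_frac < 1,
              all(rt_jitter_sd >= 0), length(rt_jitter_sd) == 2L,
              spectral_noise_cv >= 0,
              channel_dropout >= 0, channel_dropout < 1,
              detection_floor >= 0)
    s <- round(shared_fraction * n_compounds)
    if (s < 1L) stop("config yields no shared compounds", call. = FALSE)
    if (s + extra_ref + extra_target > n_compounds) {
      stop("s + extra_ref + extra_target exceeds n_compounds", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' Preset configurations for the two data regimes
#'
#' `"data1_like"` emulates a sparse mixture-of-standards run (~75
#' compounds per run); `"data2_like"` a dense biological run (~450
#' compounds per run). Both use the homogeneous-data convention: the
#' two runs share retention time ranges, and the target run's peaks are a
#' subset of the reference run's compounds (the reference is the more
#' complete run), so ground truth covers every target peak.
#'
#' @param preset `"data1_like"` or `"data2_like"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
synthetic_preset <- function(preset = c("data1_like", "data2_like"),
                             seed = 1, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    data1_like = list(n_compounds = 75, shared_fraction = 0.95,
                      extra_ref = 3, extra_target = 0,
                      shared_intensity_frac = 0.4, family_rate = 0.05,
                      spectral_noise_cv = 0.3),
    data2_like = list(n_compounds = 450, shared_fraction = 0.95,
                      extra_ref = 22, extra_target = 0,
                      shared_intensity_frac = 0.55, family_rate = 0.25,
                      spectral_noise_cv = 0.4)
  )
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(synthetic_config, args)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %d compounds (s = %d shared, +%d ref-only, +%d target-only), grid %d-%d, jitter sd (%.3g, %.3g) s, noise cv %.3g, seed %d\n",
    x$n_compounds, round(x$shared_fraction * x$n_compounds),
    x$extra_ref, x$extra_target, x$mz_min, x$mz_max,
    x$rt_jitter_sd[1], x$rt_jitter_sd[2], x$spectral_noise_cv, x$seed))
  invisible(x)
}

.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate the compound library for a configuration
#'
#' Deterministic from `cfg$seed`. Each compound receives a base spectrum
#' (fragment channels and exponential intensities scaled to a 999 base
#' peak), base retention times, a base peak area and a label.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of compounds, each a list with `label`, `mz`,
#'   `intensity`, `rt1`, `rt2`, `area`.
#' @export
generate_compound_library <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  .with_seed(cfg$seed, .compound_library(cfg))
}

# Library construction. Three sources of inter-compound spectral
# correlation, all present in real nominal-mass GCxGC-TOF data:
#   1. a shared fragment pool whose channels follow one global intensity
#      profile (common low-mass and derivatization fragments), carrying
#      `shared_intensity_frac` of each compound's total intensity;
#   2. accidental reuse of compound-specific channels once the grid is
#      crowded: unique channels are drawn without replacement from the
#      still-unused part of the grid while any remains, then with
#      replacement -- so dense libraries overlap more than sparse ones;
#   3. spectral families: with probability `family_rate` a compound is a
#      perturbed copy of an earlier compound's spectrum (isomers,
#      related metabolites), eluting at its own retention times.
.compound_library <- function(cfg) {
  grid <- cfg$mz_min:cfg$mz_max
  pool_n <- min(cfg$shared_fragment_pool, length(grid))
  pool <- if (pool_n > 0L) sort(sample(grid, pool_n)) else integer(0)
  profile <- if (pool_n > 0L) stats::rexp(pool_n) + 0.05 else numeric(0)
  nonpool <- setdiff(grid, pool)
  # background ("grass") pool: low-intensity channels shared by all
  # compounds; sized at 3x the per-compound draw so supports overlap
  grass_n <- min(3L * cfg$n_baseline_fragments, length(nonpool))
  grass_pool <- if (grass_n > 0L) sample(nonpool, grass_n) else integer(0)
  # flat background profile: background ranks carry no information and
  # are re-shuffled by measurement noise on every observation
  grass_profile <- if (grass_n > 0L) rep(1, grass_n) else numeric(0)
  unused <- setdiff(nonpool, grass_pool)
  n_sh <- min(cfg$n_shared_fragments, pool_n)
  n_un <- cfg$n_fragments - n_sh
  lib <- vector("list", cfg$n_compounds)
  for (i in seq_len(cfg$n_compounds)) {
    if (i > 1L && stats::runif(1) < cfg$family_rate) {
      parent <- lib[[sample.int(i - 1L, 1L)]]
      intensity <- parent$intensity *
        stats::rlnorm(length(parent$intensity), 0, cfg$family_sdlog)
      mz <- parent$mz
    } else {
      sh <- if (n_sh > 0L) sample(pool, n_sh) else integer(0)
      take <- min(n_un, length(unused))
      un <- if (take > 0L) sample(unused, take) else integer(0)
      unused <- setdiff(unused, un)
      if (n_un > take && length(nonpool) > 0L) {
        un <- c(un, sample(nonpool, n_un - take))
      }
      un <- unique(un)
      sh_int <- if (length(sh) > 0L) {
        profile[match(sh, pool)] * stats::rlnorm(length(sh), 0, 0.3)
      } else numeric(0)
      un_int <- stats::rexp(length(un)) + 0.02
      # low-intensity grass drawn from the shared background pool
      gr <- if (cfg$n_baseline_fragments > 0L && grass_n > 0L) {
        free <- setdiff(grass_pool, c(sh, un))
        sample(free, min(cfg$n_baseline_fragments, length(free)))
      } else integer(0)
      gr_int <- grass_profile[match(gr, grass_pool)] *
        stats::rlnorm(length(gr), 0, 0.1)
      # split the total ion intensity between backbone, unique and grass
      fr <- if (length(sh) > 0L) cfg$shared_intensity_frac else 0
      gf <- if (length(gr) > 0L) cfg$baseline_intensity_frac else 0
      uf <- 1 - fr - gf
      if (fr > 0) sh_int <- sh_int / sum(sh_int) * fr else {
        sh <- integer(0); sh_int <- numeric(0)
      }
      if (gf > 0) gr_int <- gr_int / sum(gr_int) * gf else {
        gr <- integer(0); gr_int <- numeric(0)
      }
      un_int <- if (length(un) > 0L) un_int / sum(un_int) * uf
                else numeric(0)
      mz <- c(sh, un, gr)
      intensity <- c(sh_int, un_int, gr_int)
      ord <- order(mz)
      mz <- mz[ord]; intensity <- intensity[ord]
    }
    intensity <- intensity / max(intensity) * 999
    lib[[i]] <- list(label = sprintf("C%04d", i), mz = mz,
                     intensity = intensity,
                     rt1 = .draw_rt1(1L, cfg),
                     rt2 = stats::runif(1, cfg$rt2_range[1], cfg$rt2_range[2]),
                     area = stats::rlnorm(1, cfg$area_meanlog, cfg$area_sdlog))
  }
  lib
}

.draw_rt1 <- function(n, cfg) {
  lo <- cfg$rt1_range[1]; hi <- cfg$rt1_range[2]
  if (cfg$rt1_density == "uniform") return(stats::runif(n, lo, hi))
  # bimodal: mixture of two normals at 30% and 70% of the range
  span <- hi - lo
  mu <- lo + span * ifelse(stats::runif(n) < 0.5, 0.3, 0.7)
  pmin(hi, pmax(lo, stats::rnorm(n, mu, span / 10)))
}

# One observed appearance of a library compound: retention time jitter,
# multiplicative log-normal spectral noise, detection-floor censoring.
.observe_compound <- function(comp, cfg) {
  rt1 <- max(0, comp$rt1 + stats::rnorm(1, 0, cfg$rt_jitter_sd[1]))
  rt2 <- max(0, comp$rt2 + stats::rnorm(1, 0, cfg$rt_jitter_sd[2]))
  intensity <- comp$intensity
  if (cfg$spectral_noise_cv > 0) {
    # heteroscedastic counting noise: relative noise grows as intensity
    # falls (shot-noise-like), capped at 5x the base-peak noise level
    sdlog <- sqrt(log(1 + cfg$spectral_noise_cv^2))
    rel <- intensity / max(intensity)
    sdlog_i <- sdlog * pmin(2.5, rel^(-0.25))
    intensity <- intensity * stats::rlnorm(length(intensity), 0, sdlog_i)
  }
  keep <- intensity >= cfg$detection_floor
  if (cfg$channel_dropout > 0) {
    keep <- keep &
      stats::runif(length(intensity)) >= cfg$channel_dropout
  }
  keep[which.max(intensity)] <- TRUE     # the base peak survives censoring
  area <- comp$area * stats::rlnorm(1, 0, 0.1)
  peak(rt1, rt2, area,
       mass_spectrum(comp$mz[keep], intensity[keep]),
       comp$label)
}

#' Generate a reference/target run pair with known ground truth
#'
#' Draws the compound library, lets the first `s` compounds appear in
#' both runs (with independent retention time jitter and spectral noise
#' per run), appends the reference-only and target-only compounds, sorts
#' each run by first-dimension retention time, harmonizes the two lists
#' onto one m/z grid and records the true peak pairs.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with elements `reference` and `target` (`peak_list`s on
#'   a common m/z grid) and `truth` (a [true_pair_set()]).
#' @export
generate_run_pair <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  .with_seed(cfg$seed, {
    lib <- .compound_library(cfg)
    s <- round(cfg$shared_fraction * cfg$n_compounds)
    shared <- lib[seq_len(s)]
    ref_only <- if (cfg$extra_ref > 0L)
      lib[s + seq_len(cfg$extra_ref)] else list()
    target_only <- if (cfg$extra_target > 0L)
      lib[s + cfg$extra_ref + seq_len(cfg$extra_target)] else list()
    ref_peaks <- lapply(c(shared, ref_only), .observe_compound, cfg = cfg)
    tgt_peaks <- lapply(c(shared, target_only), .observe_compound, cfg = cfg)
    R <- peak_list(ref_peaks, run_id = sprintf("sim%d_ref", cfg$seed),
                   role = "reference")
    T_ <- peak_list(tgt_peaks, run_id = sprintf("sim%d_target", cfg$seed),
                    role = "target")
    ord_r <- order(R$rt1, seq_len(n_peaks(R)))
    ord_t <- order(T_$rt1, seq_len(n_peaks(T_)))
    R <- R[ord_r]; T_ <- T_[ord_t]
    truth <- true_pair_set(
      ref = match(vapply(shared, `[[`, character(1), "label"), R$label),
      target = match(vapply(shared, `[[`, character(1), "label"), T_$label))
    both <- harmonize_mz_grid(list(R, T_))
    list(reference = both[[1L]], target = both[[2L]], truth = truth)
  })
}

#' Add split detections to a peak list
#'
#' Emulates deconvolution software reporting several peaks for one
#' compound: `n_extra` duplicate detections of randomly chosen labeled
#' peaks are appended, each with slightly perturbed retention times and a
#' strictly smaller area, so [merge_peaks_by_area()] recovers exactly the
#' original list.
#'
#' @param pl A `peak_list` with labeled peaks.
#' @param n_extra Number of duplicate detections to append.
#' @param seed Integer seed.
#' @return A `peak_list` with `n_peaks(pl) + n_extra` peaks.
#' @export
with_split_detections <- function(pl, n_extra, seed = 1) {
  stopifnot(inherits(pl, "peak_list"), n_extra >= 0)
  if (n_extra == 0L) return(pl)
  labeled <- which(!is.na(pl$label))
  if (length(labeled) == 0L) stop("no labeled peaks to split", call. = FALSE)
  .with_seed(seed, {
    picks <- sample(labeled, n_extra, replace = TRUE)
    dups <- lapply(picks, function(i) {
      peak(max(0, pl$rt1[i] + stats::rnorm(1, 0, 1)),
           max(0, pl$rt2[i] + stats::rnorm(1, 0, 0.02)),
           pl$area[i] * stats::runif(1, 0.1, 0.8),
           pl$spectra[[i]], pl$label[i])
    })
    orig <- lapply(seq_len(n_peaks(pl)), function(i) get_peak(pl, i))
    peak_list(c(orig, dups), run_id = pl$run_id, role = pl$role)
  })
}
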