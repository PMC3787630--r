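## Parameter-sweep benchmarking harness: runs every requested
## method/measure/distance/parameter combination over a collection of
## reference-target pairs with known truth, and reports the confusion
## metrics plus the ROC AUC per run together with per-combination means
## and standard errors across pairs.

#' Sweep grid specification
#'
#' Defaults follow the canonical benchmarking grids: distance-window
#' ranks `k` in \{3, 5, 10, 15, 20\}; 13 equally spaced similarity
#' cut-offs `rho` in \[0.1, 0.99\]; 13 equally spaced mixture weights `w`
#' in \[0.01, 0.99\]; conditioning ranks `q` in
#' \{3, 5, 7, 10, 15, 20, 30, 50, 70, 100\}.
#'
#' @param methods Subset of `c("pad", "pas", "dw_pas", "sw_pad", "pam")`.
#' @param measures Subset of the five similarity measure names.
#' @param distances Subset of the four distance measure names.
#' @param k_values Distance-window ranks for DW-PAS.
#' @param rho_values Similarity cut-offs for SW-PAD.
#' @param w_values Mixture weights for PAM.
#' @param q_values Two-step conditioning ranks for partial/part.
#' @return An object of class `sweep_grid`.
#' @export
sweep_grid <- function(methods = c("pas", "dw_pas", "sw_pad", "pam"),
                       measures = c("cosine", "pearson", "spearman",
                                    "partial", "part"),
                       distances = c("euclidean", "maximum", "manhattan",
                                     "canberra"),
                       k_values = c(3, 5, 10, 15, 20),
                       rho_values = seq(0.1, 0.99, length.out = 13),
                       w_values = seq(0.01, 0.99, length.out = 13),
                       q_values = c(3, 5, 7, 10, 15, 20, 30, 50, 70, 100)) {
  methods <- match.arg(methods, c("pad", "pas", "dw_pas", "sw_pad", "pam"),
                       several.ok = TRUE)
  measures <- match.arg(measures,
                        c("cosine", "pearson", "spearman", "partial", "part"),
                        several.ok = TRUE)
  distances <- match.arg(distances,
                         c("euclidean", "maximum", "manhattan", "canberra"),
                         several.ok = TRUE)
  structure(list(methods = methods, measures = measures,
                 distances = distances,
                 k_values = as.integer(k_values), rho_values = rho_values,
                 w_values = w_values, q_values = as.integer(q_values)),
            class = "sweep_grid")
}

# Enumerate the parameter combinations of a grid as a data frame with
# columns method, measure, distance, k, rho, w, q (NA where not
# applicable). Measures needing no q get q = NA; partial/part expand over
# q_values (NA-q rows mean full conditioning and are only emitted when
# q_values is empty).
.grid_rows <- function(grid) {
  rows <- list()
  add <- function(method, measure = NA, distance = NA, k = NA, rho = NA,
                  w = NA, q = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, measure = measure, distance = distance,
      k = k, rho = rho, w = w, q = q, stringsAsFactors = FALSE)
  }
  measure_q <- function(measure) {
    if (measure %in% c("partial", "part") && length(grid$q_values) > 0L) {
      grid$q_values
    } else NA_integer_
  }
  for (method in grid$methods) {
    switch(method,
      pad = for (d in grid$distances) add("pad", distance = d),
      pas = for (msr in grid$measures) for (q in measure_q(msr))
        add("pas", measure = msr, q = q),
      dw_pas = for (d in grid$distances) for (k in grid$k_values)
        for (msr in grid$measures) for (q in measure_q(msr))
          add("dw_pas", measure = msr, distance = d, k = k, q = q),
      sw_pad = for (msr in grid$measures) for (q in measure_q(msr))
        for (rho in grid$rho_values) for (d in grid$distances)
          add("sw_pad", measure = msr, distance = d, rho = rho, q = q),
      pam = for (w in grid$w_values) for (d in grid$distances)
        for (msr in grid$measures) for (q in measure_q(msr))
          add("pam", measure = msr, distance = d, w = w, q = q)
    )
  }
  do.call(rbind, rows)
}

.run_one <- function(row, pair, sim_cache = NULL, pair_key = "") {
  sspec <- if (!is.na(row$measure)) {
    similarity_spec(row$measure, q = if (!is.na(row$q)) row$q else NULL)
  } else NULL
  dspec <- if (!is.na(row$distance)) distance_spec(row$distance) else NULL
  sim <- NULL
  if (!is.null(sspec) && !is.null(sim_cache)) {
    key <- paste(pair_key, sspec$kind, row$q, sep = "|")
    sim <- sim_cache[[key]]
    if (is.null(sim)) {
      sim <- similarity_matrix(pair$target, pair$reference, sspec)
      sim_cache[[key]] <- sim
    }
  }
  res <- switch(row$method,
    pad = align_pad(pair$target, pair$reference, dspec),
    pas = align_pas(pair$target, pair$reference, sspec, sim = sim),
    dw_pas = align_dw_pas(pair$target, pair$reference, dspec, row$k, sspec,
                          sim = sim),
    sw_pad = align_sw_pad(pair$target, pair$reference, sspec, row$rho, dspec,
                          sim = sim),
    pam = align_pam(pair$target, pair$reference, row$w, dspec, sspec,
                    sim = sim))
  rep <- evaluate_alignment(res, pair$truth)
  auc <- if (nrow(res$matches) > 0L) {
    alignment_roc(res, pair$truth)$auc
  } else NA_real_
  c(TPR = rep$TPR, FPR = rep$FPR, PPV = rep$PPV, F1 = rep$F1,
    AUC = auc, u = rep$u, TP = rep$TP)
}

#' Run a benchmarking sweep
#'
#' Applies every parameter combination of `grid` to every
#' reference/target pair and evaluates it against the pair's ground
#' truth. Combinations that are infeasible for a pair (a two-step rank
#' `q >= m`) are flagged `skipped` rather than failing the sweep. Row
#' order is deterministic: pairs vary fastest within each combination.
#'
#' @param pairs A list of pairs as produced by [generate_run_pair()]
#'   (elements `reference`, `target`, `truth`), or a single such pair.
#' @param grid A [sweep_grid()].
#' @return A list of class `sweep_result`: `results` (one row per
#'   combination x pair) and `summary` (per-combination mean and standard
#'   error of each metric across pairs).
#' @export
run_sweep <- function(pairs, grid = sweep_grid()) {
  stopifnot(inherits(grid, "sweep_grid"))
  if (!is.null(pairs$reference)) pairs <- list(pairs)
  combos <- .grid_rows(grid)
  sim_cache <- new.env(parent = emptyenv())
  metric_names <- c("TPR", "FPR", "PPV", "F1", "AUC", "u", "TP")
  out <- vector("list", nrow(combos) * length(pairs))
  pos <- 0L
  for (ci in seq_len(nrow(combos))) {
    row <- combos[ci, ]
    for (pi in seq_along(pairs)) {
      pair <- pairs[[pi]]
      m <- n_peaks(pair$reference)
      skipped <- !is.na(row$q) && row$q >= m
      vals <- if (skipped) {
        stats::setNames(rep(NA_real_, length(metric_names)), metric_names)
      } else {
        .run_one(row, pair, sim_cache, pair_key = as.character(pi))
      }
      pos <- pos + 1L
      out[[pos]] <- cbind(data.frame(combo = ci, pair = pi,
                                     skipped = skipped),
                          row, t(vals), row.names = NULL)
    }
  }
  results <- do.call(rbind, out)
  summary <- .summarize_sweep(results, metric_names)
  structure(list(results = results, summary = summary, grid = grid),
            class = "sweep_result")
}

.summarize_sweep <- function(results, metric_names) {
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  split_by <- split(results, results$combo)
  rows <- lapply(split_by, function(df) {
    base <- df[1L, c("combo", "method", "measure", "distance",
                     "k", "rho", "w", "q")]
    base$n_pairs <- sum(!df$skipped)
    for (mname in metric_names) {
      base[[paste0("mean_", mname)]] <- mean(df[[mname]], na.rm = TRUE)
      base[[paste0("se_", mname)]] <- se(df[[mname]])
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d combinations x %d pairs (%d skipped rows)\n",
              max(x$results$combo), max(x$results$pair),
              sum(x$results$skipped)))
  invisible(x)
}

#' Best parameter combination per method
#'
#' Scans a sweep summary for the combination with the highest mean of
#' `metric` (default F1) within each method.
#'
#' @param sweep A `sweep_result`.
#' @param metric Metric column to rank by (`"F1"`, `"AUC"`, ...).
#' @return A data frame with one row per method.
#' @export
best_per_method <- function(sweep, metric = "F1") {
  stopifnot(inherits(sweep, "sweep_result"))
  col <- paste0("mean_", metric)
  if (!col %in% names(sweep$summary)) {
    stop("unknown metric: ", metric, call. = FALSE)
  }
  parts <- split(sweep$summary, sweep$summary$method)
  out <- lapply(parts, function(df) {
    vals <- df[[col]]
    if (all(is.na(vals))) return(df[1L, ])
    df[which.max(vals), ]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
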