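# Independent oracles and fixture builders. Every oracle here is a
# deliberately naive re-derivation (explicit regressions, full sorts,
# exhaustive enumeration) kept separate from the package's vectorized
# implementations.

# ---- fixtures ----------------------------------------------------------

rand_spectrum_matrix <- function(g, n) {
  matrix(stats::rexp(g * n) + 0.01, nrow = g)
}

# peak_list from an intensity matrix (columns = peaks) and rt vectors
pl_from_matrix <- function(M, rt1 = NULL, rt2 = NULL, labels = NULL,
                           role = "reference") {
  n <- ncol(M)
  grid <- seq_len(nrow(M)) + 49L
  if (is.null(rt1)) rt1 <- stats::runif(n, 0, 1000)
  if (is.null(rt2)) rt2 <- stats::runif(n, 0, 5)
  if (is.null(labels)) labels <- rep(NA_character_, n)
  peaks <- lapply(seq_len(n), function(i) {
    peak(rt1[i], rt2[i], area = 1,
         spectrum = mass_spectrum(grid, M[, i]), label = labels[i])
  })
  peak_list(peaks, run_id = "fix", role = role)
}

simple_spectrum <- function(x) mass_spectrum(seq_along(x) + 49L, x)

# ---- similarity oracles ------------------------------------------------

oracle_partial <- function(x, yi, Z) {
  if (is.null(Z) || NCOL(Z) == 0L) return(stats::cor(x, yi))
  Z <- as.matrix(Z)
  rx <- stats::residuals(stats::lm(x ~ Z))
  ry <- stats::residuals(stats::lm(yi ~ Z))
  stats::cor(rx, ry)
}

oracle_part <- function(x, yi, Z) {
  if (is.null(Z) || NCOL(Z) == 0L) return(stats::cor(x, yi))
  Z <- as.matrix(Z)
  ry <- stats::residuals(stats::lm(yi ~ Z))
  stats::cor(x, ry)
}

# full-ranking conditioning set: rank all reference peaks except i by
# Pearson correlation with x (descending, ties by lower index, NA last)
oracle_two_step_set <- function(x, Rmat, i, q) {
  m <- ncol(Rmat)
  r <- vapply(seq_len(m), function(j) {
    suppressWarnings(stats::cor(x, Rmat[, j]))
  }, numeric(1))
  r[is.na(r)] <- -Inf
  cand <- setdiff(seq_len(m), i)
  ranked <- cand[order(-r[cand], cand)]
  sort(ranked[seq_len(min(q, length(ranked)))])
}

oracle_two_step <- function(x, Rmat, i, q, kind) {
  idx <- oracle_two_step_set(x, Rmat, i, q)
  Z <- if (length(idx) > 0L) Rmat[, idx, drop = FALSE] else NULL
  if (kind == "partial") oracle_partial(x, Rmat[, i], Z)
  else oracle_part(x, Rmat[, i], Z)
}

# spectra sample-orthogonal to the span of centered conditioning spectra:
# X and Yi are built inside the orthogonal complement of span(1, Z)
orthogonal_triple <- function(g = 24, h = 3) {
  Z <- matrix(stats::rnorm(g * h), g)
  basis <- qr.Q(qr(cbind(1, Z)))
  proj_out <- function(v) v - basis %*% crossprod(basis, v)
  x <- as.numeric(proj_out(stats::rnorm(g))) + 5
  y <- as.numeric(proj_out(stats::rnorm(g))) + 5
  list(x = x, yi = y, Z = Z)
}

# ---- alignment oracles -------------------------------------------------

oracle_sim_value <- function(x, Rmat, i, spec) {
  kind <- spec$kind
  if (kind == "cosine") {
    y <- Rmat[, i]
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) return(NA_real_)
    return(sum(x * y) / (nx * ny))
  }
  if (kind == "pearson") {
    return(suppressWarnings(stats::cor(x, Rmat[, i])))
  }
  if (kind == "spearman") {
    return(suppressWarnings(stats::cor(x, Rmat[, i], method = "spearman")))
  }
  q <- spec$q
  if (is.null(q)) {
    Z <- if (ncol(Rmat) > 1L) Rmat[, -i, drop = FALSE] else NULL
    return(tryCatch(
      if (kind == "partial") oracle_partial(x, Rmat[, i], Z)
      else oracle_part(x, Rmat[, i], Z),
      error = function(e) NA_real_))
  }
  tryCatch(oracle_two_step(x, Rmat, i, q, kind), error = function(e) NA_real_)
}

oracle_distance <- function(t1, t2, r1, r2, kind) {
  d1 <- abs(t1 - r1); d2 <- abs(t2 - r2)
  switch(kind,
    euclidean = sqrt(d1^2 + d2^2),
    maximum = max(d1, d2),
    manhattan = d1 + d2,
    canberra = {
      a <- if (abs(t1) + abs(r1) == 0) 0 else d1 / (abs(t1) + abs(r1))
      b <- if (abs(t2) + abs(r2) == 0) 0 else d2 / (abs(t2) + abs(r2))
      a + b
    })
}

oracle_dist_row <- function(target, reference, j, kind) {
  vapply(seq_len(n_peaks(reference)), function(i) {
    oracle_distance(target$rt1[j], target$rt2[j],
                    reference$rt1[i], reference$rt2[i], kind)
  }, numeric(1))
}

# shared selection rule: argmax score, ties by smaller tie-break
# distance, then lower index; all-NA rows unmatched
oracle_pick <- function(score, tie_d) {
  ok <- which(!is.na(score))
  if (length(ok) == 0L) return(NA_integer_)
  best <- ok[score[ok] == max(score[ok])]
  if (length(best) > 1L) {
    best <- best[tie_d[best] == min(tie_d[best])]
  }
  min(best)
}

oracle_align <- function(method, target, reference, dspec = NULL,
                         sspec = NULL, k = NULL, rho = NULL, w = NULL) {
  n <- n_peaks(target); m <- n_peaks(reference)
  Tm <- intensity_matrix(target); Rm <- intensity_matrix(reference)
  out <- data.frame(target = integer(0), ref = integer(0))
  for (j in seq_len(n)) {
    d <- if (!is.null(dspec)) oracle_dist_row(target, reference, j,
                                              dspec$kind) else NULL
    d_euc <- oracle_dist_row(target, reference, j, "euclidean")
    s <- if (!is.null(sspec)) {
      vapply(seq_len(m), function(i) {
        oracle_sim_value(Tm[, j], Rm, i, sspec)
      }, numeric(1))
    } else NULL
    pick <- switch(method,
      pad = oracle_pick(-d, d),
      pas = oracle_pick(s, d_euc),
      dw_pas = {
        win <- order(d, seq_len(m))[seq_len(min(k, m))]
        sw <- rep(NA_real_, m); sw[win] <- s[win]
        oracle_pick(sw, d)
      },
      sw_pad = {
        keep <- !is.na(s) & s >= rho
        dd <- rep(NA_real_, m); dd[keep] <- -d[keep]
        oracle_pick(dd, d)
      },
      pam = {
        msc <- if (w == 1) 1 / (1 + d) else w / (1 + d) + (1 - w) * s
        oracle_pick(msc, d)
      })
    if (!is.na(pick)) {
      out <- rbind(out, data.frame(target = j, ref = pick))
    }
  }
  out
}

match_df <- function(result) {
  df <- result$matches[, c("target", "ref")]
  rownames(df) <- NULL
  df
}

# ---- evaluation oracle -------------------------------------------------

oracle_auc_mw <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
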