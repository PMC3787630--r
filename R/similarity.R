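## Mass spectral similarity measures.
##
## Five measures between intensity vectors on a shared m/z grid: cosine
## (dot product), Pearson, Spearman, partial correlation and part
## (semipartial) correlation, plus the two-step rank-q variants of the
## latter two that condition only on the q reference spectra most
## Pearson-correlated with the query. The two-step restriction is what
## keeps partial/part correlation defined when the number of peaks
## exceeds the number of m/z channels (singular covariance).

#' Similarity measure specification
#'
#' @param kind One of `"cosine"`, `"pearson"`, `"spearman"`, `"partial"`,
#'   `"part"`.
#' @param q Optional rank for the two-step partial/part variants: only the
#'   `q` reference spectra most Pearson-correlated with the query enter
#'   the conditioning set. `NULL` (default) means full conditioning on all
#'   other reference spectra, which requires more m/z channels than peaks.
#'   Ignored for cosine/pearson/spearman.
#' @return An object of class `similarity_spec`.
#' @examples
#' similarity_spec("partial", q = 10)
#' @export
similarity_spec <- function(kind = c("cosine", "pearson", "spearman",
                                     "partial", "part"),
                            q = NULL) {
  kind <- match.arg(kind)
  if (!is.null(q)) {
    q <- as.integer(q)
    if (length(q) != 1L || is.na(q) || q < 2L) {
      stop("`q` must be a single integer >= 2", call. = FALSE)
    }
    if (!kind %in% c("partial", "part")) q <- NULL
  }
  structure(list(kind = kind, q = q), class = "similarity_spec")
}

#' @export
print.similarity_spec <- function(x, ...) {
  cat("<similarity_spec> ", x$kind,
      if (!is.null(x$q)) paste0(" (two-step, q = ", x$q, ")") else "",
      "\n", sep = "")
  invisible(x)
}

## ---- internal kernels: return NA_real_ on undefined scores ----

.spec_vec <- function(x) {
  if (inherits(x, "mass_spectrum")) x$intensity else as.numeric(x)
}

.cosine_kernel <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  sum(x * y) / (nx * ny)
}

.pearson_kernel <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

.spearman_kernel <- function(x, y) {
  .pearson_kernel(rank(x), rank(y))
}

# Residuals of each column of `ys` after least-squares regression (with
# intercept) on the columns of `z`. Rank-deficient designs are handled by
# lm.fit's pivoting, i.e. redundant columns are dropped.
.residualize <- function(ys, z) {
  ys <- as.matrix(ys)
  if (is.null(z) || NCOL(z) == 0L) {
    return(sweep(ys, 2L, colMeans(ys)))
  }
  design <- cbind(1, as.matrix(z))
  fit <- stats::lm.fit(design, ys)
  as.matrix(fit$residuals)
}

# Residual correlations: a residual whose spread collapses below 1e-10 of
# the original column's spread (e.g. the conditioning set contains an
# exact duplicate) carries no signal and yields an undefined score.
.resid_defined <- function(res, orig) {
  s0 <- stats::sd(orig)
  s0 > 0 && stats::sd(res) > 1e-10 * s0
}

.partial_kernel <- function(x, yi, z) {
  if (is.null(z) || NCOL(z) == 0L) return(.pearson_kernel(x, yi))
  res <- .residualize(cbind(x, yi), z)
  if (!.resid_defined(res[, 1L], x) || !.resid_defined(res[, 2L], yi)) {
    return(NA_real_)
  }
  .pearson_kernel(res[, 1L], res[, 2L])
}

.part_kernel <- function(x, yi, z) {
  if (is.null(z) || NCOL(z) == 0L) return(.pearson_kernel(x, yi))
  res <- .residualize(cbind(yi), z)
  if (!.resid_defined(res[, 1L], yi)) return(NA_real_)
  .pearson_kernel(x, res[, 1L])
}

.as_z_matrix <- function(z) {
  if (is.null(z) || length(z) == 0L) return(NULL)
  if (is.matrix(z)) return(z)
  if (inherits(z, "mass_spectrum")) return(cbind(.spec_vec(z)))
  if (is.list(z)) return(do.call(cbind, lapply(z, .spec_vec)))
  cbind(as.numeric(z))
}

## ---- exported single-pair measures (error on undefined scores) ----

#' Cosine similarity (dot product) of two spectra
#'
#' The cosine of the angle between the two intensity vectors; the
#' classical library-search score. On non-negative spectra the value lies
#' in \[0, 1\].
#'
#' @param x,y `mass_spectrum` objects on the same m/z grid, or plain
#'   numeric vectors of equal length.
#' @return A single numeric score.
#' @export
cosine_similarity <- function(x, y) {
  v <- .check_pair(x, y)
  s <- .cosine_kernel(v$x, v$y)
  if (is.na(s)) stop("cosine similarity undefined: zero-norm spectrum",
                     call. = FALSE)
  s
}

#' Pearson correlation of two spectra
#' @inheritParams cosine_similarity
#' @return A single numeric score in \[-1, 1\].
#' @export
pearson_similarity <- function(x, y) {
  v <- .check_pair(x, y)
  s <- .pearson_kernel(v$x, v$y)
  if (is.na(s)) stop("Pearson similarity undefined: constant spectrum",
                     call. = FALSE)
  s
}

#' Spearman rank correlation of two spectra
#'
#' Pearson correlation of the rank-transformed intensity vectors; ties
#' receive average ranks. Invariant under strictly monotone transforms of
#' either spectrum.
#'
#' @inheritParams cosine_similarity
#' @return A single numeric score in \[-1, 1\].
#' @export
spearman_similarity <- function(x, y) {
  v <- .check_pair(x, y)
  s <- .spearman_kernel(v$x, v$y)
  if (is.na(s)) stop("Spearman similarity undefined: constant spectrum",
                     call. = FALSE)
  s
}

#' Partial correlation of two spectra given conditioning spectra
#'
#' Pearson correlation between the residuals of `x` and `yi` after
#' least-squares linear regression (with intercept) of each on the
#' conditioning spectra `z`. With an empty `z` this reduces to the plain
#' Pearson correlation. Rank-deficient conditioning designs (duplicate
#' spectra) are resolved by pivoting, equivalent to dropping redundant
#' columns.
#'
#' @inheritParams cosine_similarity
#' @param yi Second spectrum (same grid as `x`).
#' @param z Conditioning spectra: a list of `mass_spectrum`/numeric
#'   vectors, a numeric matrix (one spectrum per column), or `NULL`.
#' @return A single numeric score in \[-1, 1\].
#' @export
partial_similarity <- function(x, yi, z = NULL) {
  v <- .check_pair(x, yi)
  zm <- .as_z_matrix(z)
  if (!is.null(zm) && nrow(zm) != length(v$x)) {
    stop("conditioning spectra must share the pair's m/z grid",
         call. = FALSE)
  }
  s <- .partial_kernel(v$x, v$y, zm)
  if (is.na(s)) stop("partial correlation undefined: zero-variance residual",
                     call. = FALSE)
  s
}

#' Part (semipartial) correlation of two spectra given conditioning spectra
#'
#' Pearson correlation between the raw `x` and the residual of `yi` on the
#' conditioning spectra `z`; the conditioning set is regressed out of one
#' side only, so the measure is asymmetric in `(x, yi)` in general. With
#' an empty `z` it reduces to the plain Pearson correlation.
#'
#' @inheritParams partial_similarity
#' @return A single numeric score in \[-1, 1\].
#' @export
part_similarity <- function(x, yi, z = NULL) {
  v <- .check_pair(x, yi)
  zm <- .as_z_matrix(z)
  if (!is.null(zm) && nrow(zm) != length(v$x)) {
    stop("conditioning spectra must share the pair's m/z grid",
         call. = FALSE)
  }
  s <- .part_kernel(v$x, v$y, zm)
  if (is.na(s)) stop("part correlation undefined: zero-variance residual",
                     call. = FALSE)
  s
}

.check_pair <- function(x, y) {
  xv <- .spec_vec(x); yv <- .spec_vec(y)
  if (length(xv) != length(yv)) {
    stop("spectra must share one m/z grid (equal length); ",
         "call harmonize_mz_grid() first", call. = FALSE)
  }
  if (inherits(x, "mass_spectrum") && inherits(y, "mass_spectrum") &&
      !identical(x$mz, y$mz)) {
    stop("spectra are on different m/z grids; call harmonize_mz_grid() first",
         call. = FALSE)
  }
  list(x = xv, y = yv)
}

## ---- two-step conditioning ----

#' Two-step conditioning set
#'
#' For a query spectrum `x` and a reference peak `i`, returns the indices
#' of the reference peaks (excluding `i`) whose Pearson correlation with
#' `x` ranks among the top `q` in descending order. Ranking is computed
#' over the reference list with peak `i` removed, so `i` never consumes a
#' rank slot. Ties break by lower reference index; undefined Pearson
#' scores rank below all defined scores.
#'
#' @param x Query spectrum (`mass_spectrum` or numeric vector on the
#'   reference grid).
#' @param reference A harmonized `peak_list`.
#' @param i Index of the reference peak being scored (excluded from the
#'   set).
#' @param q Rank cut-off, integer >= 2.
#' @return Integer vector of reference indices, sorted ascending; at most
#'   `q` entries.
#' @export
two_step_conditioning_set <- function(x, reference, i, q) {
  stopifnot(inherits(reference, "peak_list"))
  m <- n_peaks(reference)
  if (i < 1L || i > m) stop("reference index out of range", call. = FALSE)
  q <- as.integer(q)
  if (q < 2L) stop("`q` must be >= 2", call. = FALSE)
  if (m < 2L) return(integer(0))
  R <- intensity_matrix(reference)
  xv <- .spec_vec(x)
  if (length(xv) != nrow(R)) {
    stop("query spectrum is not on the reference m/z grid", call. = FALSE)
  }
  r <- suppressWarnings(as.numeric(stats::cor(xv, R)))
  r[!is.finite(r)] <- -Inf
  cand <- setdiff(seq_len(m), i)
  ord <- cand[order(-r[cand], cand)]
  sort(ord[seq_len(min(q, length(ord)))])
}

#' Two-step partial or part correlation against a reference list
#'
#' Computes the partial or part correlation between a query spectrum and
#' reference peak `i`, conditioning only on the spectra selected by
#' [two_step_conditioning_set()]. This is the measure used when peaks
#' outnumber m/z channels and full conditioning would be singular.
#'
#' @inheritParams two_step_conditioning_set
#' @param spec A [similarity_spec()] with `kind` `"partial"` or `"part"`
#'   and `q` set.
#' @return A single numeric score.
#' @export
two_step_similarity <- function(x, reference, i, spec) {
  stopifnot(inherits(spec, "similarity_spec"))
  if (!spec$kind %in% c("partial", "part")) {
    stop("two-step variants exist only for partial/part correlation",
         call. = FALSE)
  }
  if (is.null(spec$q)) stop("`spec$q` must be set", call. = FALSE)
  idx <- two_step_conditioning_set(x, reference, i, spec$q)
  R <- intensity_matrix(reference)
  xv <- .spec_vec(x)
  z <- if (length(idx) > 0L) R[, idx, drop = FALSE] else NULL
  s <- if (spec$kind == "partial") .partial_kernel(xv, R[, i], z)
       else .part_kernel(xv, R[, i], z)
  if (is.na(s)) {
    stop("two-step ", spec$kind,
         " correlation undefined: zero-variance residual", call. = FALSE)
  }
  s
}

## ---- pairwise similarity matrices ----

#' Pairwise similarity matrix between two peak lists
#'
#' Entry `(j, i)` is the similarity of target peak `j` to reference peak
#' `i` under `spec`. For the two-step partial/part measures the
#' conditioning set is recomputed for every `(j, i)` pair; the
#' implementation batches the regressions per target row, which is exactly
#' equivalent to the per-pair definition. Undefined scores (constant or
#' zero-norm spectra, zero-variance residuals) are recorded as `NA`, not
#' raised as errors.
#'
#' @param target,reference Harmonized `peak_list`s on one m/z grid.
#' @param spec A [similarity_spec()].
#' @return An `n x m` numeric matrix of class `similarity_matrix` with the
#'   spec stored in attribute `"spec"`.
#' @export
similarity_matrix <- function(target, reference, spec) {
  stopifnot(inherits(target, "peak_list"), inherits(reference, "peak_list"),
            inherits(spec, "similarity_spec"))
  Tm <- intensity_matrix(target)
  Rm <- intensity_matrix(reference)
  if (nrow(Tm) != nrow(Rm) ||
      !identical(rownames(Tm), rownames(Rm))) {
    stop("target and reference are on different m/z grids; ",
         "harmonize_mz_grid() them together", call. = FALSE)
  }
  n <- ncol(Tm); m <- ncol(Rm)
  S <- switch(spec$kind,
    cosine = {
      nx <- sqrt(colSums(Tm^2)); ny <- sqrt(colSums(Rm^2))
      out <- crossprod(Tm, Rm) / outer(nx, ny)
      out[!is.finite(out)] <- NA_real_
      out
    },
    pearson = suppressWarnings(stats::cor(Tm, Rm)),
    spearman = suppressWarnings(
      stats::cor(apply(Tm, 2L, rank), apply(Rm, 2L, rank))),
    partial = .conditioned_matrix(Tm, Rm, spec$q, kind = "partial"),
    part = .conditioned_matrix(Tm, Rm, spec$q, kind = "part")
  )
  S <- matrix(as.numeric(S), nrow = n, ncol = m)
  structure(S, class = c("similarity_matrix", class(S)), spec = spec)
}

# Partial/part similarity of every target column against every reference
# column. With a rank q the conditioning set for (j, i) is the top-q
# Pearson ranking of reference peaks (i excluded). For a fixed target j,
# every i outside the overall top-q shares one conditioning set, so those
# m - q regressions collapse into a single multi-response least-squares
# fit; the <= q reference peaks inside the top-q get individual designs.
.conditioned_matrix <- function(Tm, Rm, q, kind) {
  n <- ncol(Tm); m <- ncol(Rm)
  out <- matrix(NA_real_, n, m)
  full <- is.null(q)
  for (j in seq_len(n)) {
    x <- Tm[, j]
    if (full) {
      for (i in seq_len(m)) {
        z <- if (m > 1L) Rm[, -i, drop = FALSE] else NULL
        out[j, i] <- if (kind == "partial") .partial_kernel(x, Rm[, i], z)
                     else .part_kernel(x, Rm[, i], z)
      }
      next
    }
    r <- suppressWarnings(as.numeric(stats::cor(x, Rm)))
    r[!is.finite(r)] <- -Inf
    ordAll <- order(-r, seq_len(m))
    k <- min(q, m - 1L)
    if (k < 1L) {
      for (i in seq_len(m)) {
        out[j, i] <- if (kind == "partial") .partial_kernel(x, Rm[, i], NULL)
                     else .part_kernel(x, Rm[, i], NULL)
      }
      next
    }
    top <- ordAll[seq_len(k)]
    nxt <- if (m > k) ordAll[k + 1L] else NA_integer_
    # shared design: conditioning set for every i outside `top`
    z_common <- Rm[, sort(top), drop = FALSE]
    outside <- setdiff(seq_len(m), top)
    if (length(outside) > 0L) {
      if (kind == "partial") {
        res <- .residualize(cbind(x, Rm[, outside, drop = FALSE]), z_common)
        rx <- res[, 1L]
        for (a in seq_along(outside)) {
          out[j, outside[a]] <- .pearson_kernel(rx, res[, a + 1L])
        }
      } else {
        res <- .residualize(Rm[, outside, drop = FALSE], z_common)
        for (a in seq_along(outside)) {
          out[j, outside[a]] <- .pearson_kernel(x, res[, a])
        }
      }
    }
    # individual designs: i inside the top-q ranking
    for (i in top) {
      cand <- setdiff(seq_len(m), i)
      ordi <- cand[order(-r[cand], cand)]
      idx <- sort(ordi[seq_len(min(q, length(ordi)))])
      z <- Rm[, idx, drop = FALSE]
      out[j, i] <- if (kind == "partial") .partial_kernel(x, Rm[, i], z)
                   else .part_kernel(x, Rm[, i], z)
    }
  }
  out
}
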