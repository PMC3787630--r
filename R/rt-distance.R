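## Retention time distances between peaks in the two-dimensional
## (rt1, rt2) plane, and the rank-based distance windows used by the
## window-based aligners.

#' Distance measure specification
#'
#' @param kind One of `"euclidean"`, `"maximum"`, `"manhattan"`,
#'   `"canberra"`.
#' @return An object of class `distance_spec`.
#' @export
distance_spec <- function(kind = c("euclidean", "maximum", "manhattan",
                                   "canberra")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "distance_spec")
}

#' @export
print.distance_spec <- function(x, ...) {
  cat("<distance_spec>", x$kind, "\n")
  invisible(x)
}

#' Retention time distance between two peaks
#'
#' Distances operate on the raw retention times in seconds (no
#' standardization): Euclidean `sqrt(d1^2 + d2^2)`, Maximum (Chebyshev)
#' `max(|d1|, |d2|)`, Manhattan `|d1| + |d2|`, and Canberra
#' `|d1|/(|a1|+|b1|) + |d2|/(|a2|+|b2|)` where a zero denominator makes
#' that term contribute 0. Canberra is self-normalizing per dimension,
#' which compensates for the very different scales of the first and
#' second dimension retention times.
#'
#' @param a,b [peak()] objects (or lists with `rt1`/`rt2` fields).
#' @param spec A [distance_spec()].
#' @return A single non-negative number.
#' @examples
#' p1 <- peak(10, 2, 1, mass_spectrum(70, 1))
#' p2 <- peak(30, 2, 1, mass_spectrum(70, 1))
#' rt_distance(p1, p2, distance_spec("canberra"))
#' @export
rt_distance <- function(a, b, spec) {
  stopifnot(inherits(spec, "distance_spec"))
  .rt_distance_matrix(a$rt1, a$rt2, b$rt1, b$rt2, spec$kind)[1L, 1L]
}

# Vectorized n x m distance matrix between target rts (t1, t2) and
# reference rts (r1, r2).
.rt_distance_matrix <- function(t1, t2, r1, r2, kind) {
  d1 <- abs(outer(t1, r1, "-"))
  d2 <- abs(outer(t2, r2, "-"))
  switch(kind,
    euclidean = sqrt(d1^2 + d2^2),
    maximum = pmax(d1, d2),
    manhattan = d1 + d2,
    canberra = {
      den1 <- outer(abs(t1), abs(r1), "+")
      den2 <- outer(abs(t2), abs(r2), "+")
      term1 <- ifelse(den1 == 0, 0, d1 / den1)
      term2 <- ifelse(den2 == 0, 0, d2 / den2)
      term1 + term2
    },
    stop("unknown distance kind: ", kind, call. = FALSE)
  )
}

#' Distance matrix between two peak lists
#'
#' Entry `(j, i)` is the retention time distance between target peak `j`
#' and reference peak `i`.
#'
#' @param target,reference `peak_list`s.
#' @param spec A [distance_spec()].
#' @return An `n x m` numeric matrix.
#' @export
rt_distance_matrix <- function(target, reference, spec) {
  stopifnot(inherits(target, "peak_list"), inherits(reference, "peak_list"),
            inherits(spec, "distance_spec"))
  .rt_distance_matrix(target$rt1, target$rt2,
                      reference$rt1, reference$rt2, spec$kind)
}

#' Distance-rank window around a target peak
#'
#' The indices of the `k` reference peaks nearest to `t` under the chosen
#' distance (all reference indices when `k >= m`). Ties at the window
#' boundary break by lower reference index.
#'
#' @param t A [peak()] (or list with `rt1`/`rt2`).
#' @param reference A `peak_list`.
#' @param spec A [distance_spec()].
#' @param k Window rank, integer >= 1.
#' @return Integer vector of reference indices, sorted ascending.
#' @export
distance_rank_window <- function(t, reference, spec, k) {
  stopifnot(inherits(reference, "peak_list"), inherits(spec, "distance_spec"))
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  d <- .rt_distance_matrix(t$rt1, t$rt2, reference$rt1, reference$rt2,
                           spec$kind)[1L, ]
  m <- length(d)
  ord <- order(d, seq_len(m))
  sort(ord[seq_len(min(k, m))])
}
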