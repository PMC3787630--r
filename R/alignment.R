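## Peak matching alignment procedures.
##
## PAD    : nearest reference peak by retention time distance alone.
## PAS    : most spectrally similar reference peak alone.
## DW-PAS : spectral similarity restricted to the k nearest references
##          by retention time distance (distance window).
## SW-PAD : retention time distance restricted to references whose
##          spectral similarity exceeds a cut-off rho (similarity window).
## PAM    : mixture score combining a distance-decreasing term and the
##          spectral similarity, no window.
##
## All procedures match per target peak; a reference peak may be matched
## by several targets unless `one_to_one = TRUE` requests a greedy
## one-to-one assignment. Score ties break by smaller retention time
## distance, then by lower reference index.

#' Mixture similarity score
#'
#' Combines a retention time distance `d` and a spectral similarity `s`
#' as `w / (1 + d) + (1 - w) * s`. The first term is 1 at zero distance
#' and decreases towards 0, so `w` close to 1 lets the retention time
#' distance drive the alignment while `w` close to 0 leaves it to the
#' mass spectral similarity.
#'
#' @param d Non-negative distance (vectorized).
#' @param s Similarity score (vectorized).
#' @param w Mixture weight in \[0, 1\].
#' @return Numeric score(s).
#' @export
mixture_score <- function(d, s, w) {
  if (length(w) != 1L || is.na(w) || w < 0 || w > 1) {
    stop("`w` must be a single number in [0, 1]", call. = FALSE)
  }
  if (any(d < 0, na.rm = TRUE)) stop("`d` must be non-negative", call. = FALSE)
  dist_term <- w / (1 + d)
  sim_term <- if (w == 1) 0 else (1 - w) * s
  dist_term + sim_term
}

.alignment_result <- function(target, ref, score, method, params, n, m,
                              extra = NULL) {
  matches <- data.frame(target = as.integer(target), ref = as.integer(ref),
                        score = as.numeric(score))
  if (!is.null(extra)) matches <- cbind(matches, extra)
  structure(list(matches = matches, method = method, params = params,
                 n = n, m = m),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s: u = %d of n = %d target peaks matched (m = %d references)\n",
              x$method, nrow(x$matches), x$n, x$m))
  invisible(x)
}

#' Number of matched peak pairs in an alignment result
#' @param result An `alignment_result`.
#' @return Integer count `u`.
#' @export
n_matched <- function(result) {
  stopifnot(inherits(result, "alignment_result"))
  nrow(result$matches)
}

# Per-target selection: pick argmax of `score` per row; ties break by
# smaller `tie_d`, then lower column index. Rows that are all-NA are left
# unmatched. With `one_to_one`, a greedy global assignment in decreasing
# score order.
.select_matches <- function(score, tie_d, one_to_one = FALSE) {
  n <- nrow(score); m <- ncol(score)
  if (!one_to_one) {
    target <- integer(0); ref <- integer(0); sc <- numeric(0)
    for (j in seq_len(n)) {
      row <- score[j, ]
      ok <- which(!is.na(row))
      if (length(ok) == 0L) next
      best <- ok[row[ok] == max(row[ok])]
      if (length(best) > 1L) {
        d <- tie_d[j, best]
        best <- best[d == min(d)]
        best <- min(best)
      }
      target <- c(target, j); ref <- c(ref, best)
      sc <- c(sc, score[j, best])
    }
    return(list(target = target, ref = ref, score = sc))
  }
  idx <- which(!is.na(score), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list(target = integer(0), ref = integer(0),
                                   score = numeric(0)))
  vals <- score[idx]
  ties <- tie_d[idx]
  ord <- order(-vals, ties, idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]; vals <- vals[ord]
  t_free <- rep(TRUE, n); r_free <- rep(TRUE, m)
  target <- integer(0); ref <- integer(0); sc <- numeric(0)
  for (a in seq_len(nrow(idx))) {
    j <- idx[a, 1L]; i <- idx[a, 2L]
    if (t_free[j] && r_free[i]) {
      t_free[j] <- FALSE; r_free[i] <- FALSE
      target <- c(target, j); ref <- c(ref, i); sc <- c(sc, vals[a])
    }
  }
  o <- order(target)
  list(target = target[o], ref = ref[o], score = sc[o])
}

.check_pair_lists <- function(target, reference) {
  stopifnot(inherits(target, "peak_list"), inherits(reference, "peak_list"))
}

#' PAD: peak alignment by distance
#'
#' Matches each target peak to the reference peak at minimal retention
#' time distance, without any window or spectral information. The match
#' score is the negated distance.
#'
#' @param target,reference `peak_list`s.
#' @param dspec A [distance_spec()].
#' @param one_to_one Greedy one-to-one assignment instead of independent
#'   per-target matching (default `FALSE`).
#' @return An `alignment_result`.
#' @export
align_pad <- function(target, reference, dspec = distance_spec("euclidean"),
                      one_to_one = FALSE) {
  .check_pair_lists(target, reference)
  D <- rt_distance_matrix(target, reference, dspec)
  sel <- .select_matches(-D, D, one_to_one)
  .alignment_result(sel$target, sel$ref, sel$score, "pad",
                    list(distance = dspec$kind),
                    n_peaks(target), n_peaks(reference),
                    extra = data.frame(distance = D[cbind(sel$target, sel$ref)]))
}

#' PAS: peak alignment by spectral similarity
#'
#' Matches each target peak to the reference peak of maximal mass
#' spectral similarity, ignoring retention times entirely (except as a
#' deterministic tie-break on exactly equal scores). Targets whose entire
#' similarity row is undefined are left unmatched.
#'
#' @param target,reference Harmonized `peak_list`s.
#' @param sspec A [similarity_spec()].
#' @param sim Optional precomputed [similarity_matrix()] for
#'   `(target, reference, sspec)`; avoids recomputation in sweeps.
#' @inheritParams align_pad
#' @return An `alignment_result`.
#' @export
align_pas <- function(target, reference, sspec = similarity_spec("cosine"),
                      one_to_one = FALSE, sim = NULL) {
  .check_pair_lists(target, reference)
  S <- if (is.null(sim)) similarity_matrix(target, reference, sspec) else sim
  D <- rt_distance_matrix(target, reference, distance_spec("euclidean"))
  sel <- .select_matches(unclass(S), D, one_to_one)
  .alignment_result(sel$target, sel$ref, sel$score, "pas",
                    list(measure = sspec$kind, q = sspec$q),
                    n_peaks(target), n_peaks(reference))
}

#' DW-PAS: similarity matching inside a distance window
#'
#' Restricts each target peak's candidates to its `k` nearest reference
#' peaks by retention time distance, then picks the most spectrally
#' similar candidate.
#'
#' @inheritParams align_pas
#' @param dspec A [distance_spec()] defining the window.
#' @param k Window rank (number of nearest references kept), >= 1.
#' @return An `alignment_result`.
#' @export
align_dw_pas <- function(target, reference,
                         dspec = distance_spec("euclidean"), k = 5,
                         sspec = similarity_spec("cosine"),
                         one_to_one = FALSE, sim = NULL) {
  .check_pair_lists(target, reference)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  D <- rt_distance_matrix(target, reference, dspec)
  S <- unclass(if (is.null(sim)) similarity_matrix(target, reference, sspec)
               else sim)
  m <- ncol(D)
  for (j in seq_len(nrow(D))) {
    ord <- order(D[j, ], seq_len(m))
    outside <- ord[-seq_len(min(k, m))]
    if (length(outside) > 0L) S[j, outside] <- NA_real_
  }
  sel <- .select_matches(S, D, one_to_one)
  .alignment_result(sel$target, sel$ref, sel$score, "dw_pas",
                    list(distance = dspec$kind, k = k,
                         measure = sspec$kind, q = sspec$q),
                    n_peaks(target), n_peaks(reference))
}

#' SW-PAD: distance matching inside a similarity window
#'
#' Restricts each target peak's candidates to the reference peaks whose
#' spectral similarity is at least `rho`, then picks the candidate at
#' minimal retention time distance. Targets with an empty window are left
#' unmatched, so fewer pairs than target peaks may be reported. The match
#' score is the negated distance; the similarity of the chosen pair is
#' kept in the `similarity` column.
#'
#' @inheritParams align_pas
#' @param rho Similarity cut-off in \[0, 1\]. Signed measures are
#'   thresholded on their raw score, so negative similarities never pass.
#' @param dspec A [distance_spec()].
#' @return An `alignment_result`.
#' @export
align_sw_pad <- function(target, reference,
                         sspec = similarity_spec("cosine"), rho = 0.5,
                         dspec = distance_spec("euclidean"),
                         one_to_one = FALSE, sim = NULL) {
  .check_pair_lists(target, reference)
  if (length(rho) != 1L || is.na(rho) || rho < 0 || rho > 1) {
    stop("`rho` must be a single number in [0, 1]", call. = FALSE)
  }
  S <- unclass(if (is.null(sim)) similarity_matrix(target, reference, sspec)
               else sim)
  D <- rt_distance_matrix(target, reference, dspec)
  negD <- -D
  negD[is.na(S) | S < rho] <- NA_real_
  sel <- .select_matches(negD, D, one_to_one)
  sim <- S[cbind(sel$target, sel$ref)]
  .alignment_result(sel$target, sel$ref, sel$score, "sw_pad",
                    list(measure = sspec$kind, q = sspec$q, rho = rho,
                         distance = dspec$kind),
                    n_peaks(target), n_peaks(reference),
                    extra = if (length(sel$target) > 0L)
                      data.frame(similarity = sim) else NULL)
}

#' PAM: peak alignment by mixture similarity
#'
#' Matches each target peak to the reference peak maximizing the
#' [mixture_score()] of retention time distance and spectral similarity,
#' without any window. `w = 0` reduces to PAS; `w = 1` reduces to PAD
#' (the distance term `1/(1+d)` is strictly decreasing in `d`).
#'
#' @inheritParams align_pas
#' @param w Mixture weight in \[0, 1\].
#' @param dspec A [distance_spec()].
#' @return An `alignment_result`.
#' @export
align_pam <- function(target, reference, w = 0.5,
                      dspec = distance_spec("euclidean"),
                      sspec = similarity_spec("cosine"),
                      one_to_one = FALSE, sim = NULL) {
  .check_pair_lists(target, reference)
  D <- rt_distance_matrix(target, reference, dspec)
  if (w == 1) {
    M <- 1 / (1 + D)
  } else {
    S <- unclass(if (is.null(sim)) similarity_matrix(target, reference, sspec)
                 else sim)
    M <- mixture_score(D, S, w)
  }
  sel <- .select_matches(M, D, one_to_one)
  .alignment_result(sel$target, sel$ref, sel$score, "pam",
                    list(w = w, distance = dspec$kind,
                         measure = sspec$kind, q = sspec$q),
                    n_peaks(target), n_peaks(reference))
}
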