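#' Construct a mass spectrum
#'
#' A fragment-ion mass spectrum on an integer (nominal-mass) m/z grid.
#' Intensities are in arbitrary units; no normalization is applied at
#' construction time because the similarity measures decide their own
#' scaling behaviour.
#'
#' @param mz Integer vector of m/z values, strictly increasing after
#'   unit-mass binning. Non-integer values are binned to the nearest
#'   integer (intensities at colliding bins are summed).
#' @param intensity Non-negative numeric vector, same length as `mz`.
#' @return An object of class `mass_spectrum` with fields `mz` and
#'   `intensity`.
#' @examples
#' ms <- mass_spectrum(c(70, 75), c(12, 100))
#' sum(ms$intensity)
#' @export
mass_spectrum <- function(mz, intensity) {
  if (length(mz) != length(intensity)) {
    stop("`mz` and `intensity` must have the same length", call. = FALSE)
  }
  if (length(mz) == 0L) {
    stop("a mass spectrum needs at least one channel", call. = FALSE)
  }
  if (anyNA(mz) || anyNA(intensity)) {
    stop("NA values are not allowed in a mass spectrum", call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  mzb <- as.integer(round(mz))
  if (anyDuplicated(mzb)) {
    intensity <- as.numeric(tapply(intensity, mzb, sum))
    mzb <- sort(unique(mzb))
  } else if (is.unsorted(mzb)) {
    ord <- order(mzb)
    mzb <- mzb[ord]
    intensity <- intensity[ord]
  }
  if (all(intensity == 0)) {
    stop("a mass spectrum must contain at least one non-zero intensity",
         call. = FALSE)
  }
  structure(list(mz = mzb, intensity = as.numeric(intensity)),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat("<mass_spectrum> ", length(x$mz), " channels, m/z ",
      min(x$mz), "-", max(x$mz),
      ", base peak ", x$mz[which.max(x$intensity)], "\n", sep = "")
  invisible(x)
}

#' Construct a single chromatographic peak
#'
#' @param rt1 First-dimension retention time (seconds), non-negative.
#' @param rt2 Second-dimension retention time (seconds), non-negative.
#' @param area Peak area, non-negative.
#' @param spectrum A [mass_spectrum()].
#' @param label Optional compound label (`NA` for unidentified peaks).
#' @return An object of class `peak`.
#' @export
peak <- function(rt1, rt2, area, spectrum, label = NA_character_) {
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (rt1 < 0 || rt2 < 0 || area < 0) {
    stop("rt1, rt2 and area must be non-negative", call. = FALSE)
  }
  structure(list(rt1 = as.numeric(rt1), rt2 = as.numeric(rt2),
                 area = as.numeric(area), spectrum = spectrum,
                 label = as.character(label)),
            class = "peak")
}

#' @export
print.peak <- function(x, ...) {
  cat(sprintf("<peak> rt = (%.4g, %.4g) s, area = %.4g, label = %s\n",
              x$rt1, x$rt2, x$area,
              if (is.na(x$label)) "<none>" else x$label))
  invisible(x)
}

#' Construct a peak list
#'
#' The per-run table of deconvoluted peaks: one row per detected compound
#' peak with two retention times, an area, an optional compound label and a
#' fragment mass spectrum. Column-oriented storage keeps the aligners fast
#' on dense runs.
#'
#' @param peaks A list of [peak()] objects.
#' @param run_id Identifier of the chromatographic run.
#' @param role `"reference"` or `"target"`.
#' @return An object of class `peak_list` with vector fields `rt1`, `rt2`,
#'   `area`, `label` and a list field `spectra`.
#' @export
peak_list <- function(peaks, run_id = "run", role = c("reference", "target")) {
  role <- match.arg(role)
  if (length(peaks) < 1L) {
    stop("a peak list needs at least one peak", call. = FALSE)
  }
  ok <- vapply(peaks, inherits, logical(1), what = "peak")
  if (!all(ok)) stop("all elements must be `peak` objects", call. = FALSE)
  structure(list(
    rt1 = vapply(peaks, `[[`, numeric(1), "rt1"),
    rt2 = vapply(peaks, `[[`, numeric(1), "rt2"),
    area = vapply(peaks, `[[`, numeric(1), "area"),
    label = vapply(peaks, `[[`, character(1), "label"),
    spectra = lapply(peaks, `[[`, "spectrum"),
    run_id = run_id, role = role
  ), class = "peak_list")
}

#' Number of peaks in a peak list
#' @param pl A `peak_list`.
#' @return Integer peak count.
#' @export
n_peaks <- function(pl) {
  stopifnot(inherits(pl, "peak_list"))
  length(pl$spectra)
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> run '%s' (%s): %d peaks, %d labeled\n",
              x$run_id, x$role, n_peaks(x), sum(!is.na(x$label))))
  invisible(x)
}

#' @export
`[.peak_list` <- function(x, i) {
  idx <- seq_along(x$spectra)[i]
  if (length(idx) < 1L || anyNA(idx)) {
    stop("invalid peak_list subset", call. = FALSE)
  }
  structure(list(rt1 = x$rt1[idx], rt2 = x$rt2[idx], area = x$area[idx],
                 label = x$label[idx], spectra = x$spectra[idx],
                 run_id = x$run_id, role = x$role),
            class = "peak_list")
}

#' Extract a single peak from a peak list
#' @param pl A `peak_list`.
#' @param i Peak index.
#' @return A `peak`.
#' @export
get_peak <- function(pl, i) {
  stopifnot(inherits(pl, "peak_list"), i >= 1L, i <= n_peaks(pl))
  peak(pl$rt1[i], pl$rt2[i], pl$area[i], pl$spectra[[i]], pl$label[i])
}

#' Construct a set of ground-truth peak correspondences
#'
#' Records which reference peak and which target peak originate from the
#' same compound. The pairing is one-to-one: no index may appear twice on
#' its own side.
#'
#' @param ref Integer vector of reference-peak indices (1-based).
#' @param target Integer vector of target-peak indices (1-based), same
#'   length as `ref`.
#' @return An object of class `true_pair_set`; a data frame with columns
#'   `ref` and `target`.
#' @export
true_pair_set <- function(ref, target) {
  ref <- as.integer(ref)
  target <- as.integer(target)
  if (length(ref) != length(target)) {
    stop("`ref` and `target` must have the same length", call. = FALSE)
  }
  if (anyNA(ref) || anyNA(target) || any(ref < 1L) || any(target < 1L)) {
    stop("pair indices must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(ref) || anyDuplicated(target)) {
    stop("true pairs must be one-to-one: an index repeats", call. = FALSE)
  }
  structure(data.frame(ref = ref, target = target),
            class = c("true_pair_set", "data.frame"))
}

#' @export
print.true_pair_set <- function(x, ...) {
  cat(sprintf("<true_pair_set> s = %d true peak pairs\n", nrow(x)))
  invisible(x)
}

#' Shared-grid intensity matrix of a peak list
#'
#' Stacks the spectra of a peak list into a `g x n` matrix (channels in
#' rows, peaks in columns). All spectra must already share one m/z grid;
#' run [harmonize_mz_grid()] first when lists come from different runs.
#'
#' @param pl A `peak_list` with harmonized spectra.
#' @return Numeric matrix with `rownames` set to the m/z grid.
#' @export
intensity_matrix <- function(pl) {
  stopifnot(inherits(pl, "peak_list"))
  grid <- pl$spectra[[1L]]$mz
  same <- vapply(pl$spectra, function(s) identical(s$mz, grid), logical(1))
  if (!all(same)) {
    stop("spectra do not share one m/z grid; call harmonize_mz_grid() first",
         call. = FALSE)
  }
  m <- vapply(pl$spectra, `[[`, numeric(length(grid)), "intensity")
  m <- matrix(m, nrow = length(grid))
  rownames(m) <- grid
  m
}

#' Harmonize peak lists onto one common m/z grid
#'
#' Re-expresses every spectrum on the union of all m/z grids so that the
#' intensity vectors of any two peaks are directly comparable (same number
#' of channels `g`). Channels absent from a spectrum are filled with
#' intensity zero; the total ion intensity of each spectrum is conserved.
#'
#' @param lists A single `peak_list` or a list of them.
#' @return The input lists (same order) with all spectra on the union grid.
#'   A single `peak_list` input returns a single `peak_list`.
#' @export
harmonize_mz_grid <- function(lists) {
  single <- inherits(lists, "peak_list")
  if (single) lists <- list(lists)
  if (length(lists) < 1L) stop("need at least one peak list", call. = FALSE)
  stopifnot(all(vapply(lists, inherits, logical(1), "peak_list")))
  grid <- sort(unique(unlist(lapply(lists, function(pl) {
    unlist(lapply(pl$spectra, `[[`, "mz"), use.names = FALSE)
  }), use.names = FALSE)))
  out <- lapply(lists, function(pl) {
    pl$spectra <- lapply(pl$spectra, function(s) {
      y <- numeric(length(grid))
      y[match(s$mz, grid)] <- s$intensity
      structure(list(mz = grid, intensity = y), class = "mass_spectrum")
    })
    pl
  })
  if (single) out[[1L]] else out
}

#' Merge split peak detections by largest area
#'
#' Deconvolution software often reports several peaks for one compound.
#' For each distinct compound label only the peak with the largest area is
#' kept; unlabeled peaks pass through unmerged. Output order is the order
#' of first occurrence. Ties in area break by earliest position.
#'
#' @param pl A `peak_list`.
#' @return A `peak_list` with one peak per label.
#' @export
merge_peaks_by_area <- function(pl) {
  stopifnot(inherits(pl, "peak_list"))
  n <- n_peaks(pl)
  keep <- rep(TRUE, n)
  lab <- pl$label
  for (l in unique(lab[!is.na(lab)])) {
    idx <- which(!is.na(lab) & lab == l)
    if (length(idx) > 1L) {
      best <- idx[which.max(pl$area[idx])]   # which.max: earliest wins ties
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  # first-occurrence order: position of the label's first detection
  ord <- order(vapply(which(keep), function(i) {
    if (is.na(lab[i])) i else min(which(!is.na(lab) & lab == lab[i]))
  }, numeric(1)))
  pl[which(keep)[ord]]
}
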