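#' Read a peak table
#'
#' Reads the plain-text peak-list dialect used throughout the package: a
#' UTF-8 CSV with header `rt1,rt2,area,label,spectrum`. The `spectrum`
#' cell holds space-separated `mz:intensity` tokens with integer m/z and
#' non-negative decimal intensity ("." decimal separator). Retention
#' times are interpreted in seconds in both dimensions unless
#' `rt_unit = "min"`, in which case they are converted to seconds.
#'
#' Malformed rows are rejected with an error naming the offending row;
#' they are never silently dropped.
#'
#' @param path Path to the CSV file.
#' @param run_id Run identifier; defaults to the file name without
#'   extension.
#' @param role `"reference"` or `"target"`.
#' @param rt_unit `"sec"` (default) or `"min"`.
#' @return A [peak_list()] preserving row order.
#' @export
read_peak_table <- function(path, run_id = NULL,
                            role = c("reference", "target"),
                            rt_unit = c("sec", "min")) {
  role <- match.arg(role)
  rt_unit <- match.arg(rt_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(run_id)) run_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  required <- c("rt1", "rt2", "area", "spectrum")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("peak table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"label" %in% names(df)) df$label <- ""
  if (nrow(df) < 1L) stop("peak table has no rows", call. = FALSE)
  scale <- if (rt_unit == "min") 60 else 1
  peaks <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    rt1 <- suppressWarnings(as.numeric(df$rt1[i]))
    rt2 <- suppressWarnings(as.numeric(df$rt2[i]))
    area <- suppressWarnings(as.numeric(df$area[i]))
    if (anyNA(c(rt1, rt2, area))) {
      stop("row ", i, ": rt1/rt2/area must be numeric", call. = FALSE)
    }
    spec <- .parse_spectrum_cell(df$spectrum[i], row = i)
    lab <- df$label[i]
    if (is.na(lab) || !nzchar(trimws(lab))) lab <- NA_character_
    peaks[[i]] <- peak(rt1 * scale, rt2 * scale, area, spec, lab)
  }
  peak_list(peaks, run_id = run_id, role = role)
}

.parse_spectrum_cell <- function(cell, row) {
  tokens <- strsplit(trimws(cell), "[[:space:]]+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop("row ", row, ": empty spectrum cell", call. = FALSE)
  }
  parts <- strsplit(tokens, ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) {
    stop("row ", row, ": malformed spectrum token '",
         tokens[which(bad)[1L]], "'", call. = FALSE)
  }
  mz_chr <- vapply(parts, `[[`, character(1), 1L)
  int_chr <- vapply(parts, `[[`, character(1), 2L)
  if (!all(grepl("^[0-9]+$", mz_chr))) {
    stop("row ", row, ": non-integer m/z in spectrum", call. = FALSE)
  }
  mz <- as.integer(mz_chr)
  intensity <- suppressWarnings(as.numeric(int_chr))
  if (anyNA(intensity)) {
    stop("row ", row, ": non-numeric intensity in spectrum", call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("row ", row, ": negative intensity in spectrum", call. = FALSE)
  }
  mass_spectrum(mz, intensity)
}

#' Write a peak table
#'
#' Inverse of [read_peak_table()]: writes the `rt1,rt2,area,label,spectrum`
#' CSV dialect. Numeric fields are written with enough digits that a
#' read/write round trip reproduces all fields to within 1e-6 relative
#' tolerance (in practice exactly for typical values). Unlabeled peaks get
#' an empty label cell.
#'
#' @param pl A `peak_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(pl, path) {
  stopifnot(inherits(pl, "peak_list"))
  spec_chr <- vapply(pl$spectra, function(s) {
    nz <- s$intensity != 0
    if (!any(nz)) nz[which.max(s$intensity)] <- TRUE
    paste(sprintf("%d:%s", s$mz[nz], .fmt_num(s$intensity[nz])),
          collapse = " ")
  }, character(1))
  df <- data.frame(
    rt1 = .fmt_num(pl$rt1), rt2 = .fmt_num(pl$rt2),
    area = .fmt_num(pl$area),
    label = ifelse(is.na(pl$label), "", pl$label),
    spectrum = spec_chr,
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.fmt_num <- function(x) {
  trimws(formatC(x, digits = 12, format = "g", drop0trailing = TRUE))
}

#' Read ground-truth peak pairs
#'
#' CSV with header `ref_index,target_index` holding 0-based indices into
#' the (merged) reference and target peak lists.
#'
#' @param path Path to the truth CSV.
#' @return A [true_pair_set()] (1-based internally).
#' @export
read_true_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  required <- c("ref_index", "target_index")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("truth file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  true_pair_set(df$ref_index + 1L, df$target_index + 1L)
}

#' Write ground-truth peak pairs
#' @param truth A `true_pair_set`.
#' @param path Output path (0-based indices on disk).
#' @return `path`, invisibly.
#' @export
write_true_pairs <- function(truth, path) {
  stopifnot(inherits(truth, "true_pair_set"))
  utils::write.csv(
    data.frame(ref_index = truth$ref - 1L, target_index = truth$target - 1L),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an alignment result
#'
#' CSV with header `target_index,ref_index,score,method`; 0-based indices;
#' unmatched targets are omitted.
#'
#' @param result An `alignment_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(result, path) {
  stopifnot(inherits(result, "alignment_result"))
  m <- result$matches
  utils::write.csv(
    data.frame(target_index = m$target - 1L, ref_index = m$ref - 1L,
               score = .fmt_num(m$score), method = result$method),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
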