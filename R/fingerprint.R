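# Retention-time-window peak alignment, median reference fingerprint and
# batch similarity.

#' Construct a peak table
#'
#' A peak table holds the picked chromatographic peaks of one sample:
#' retention times in minutes and non-negative areas. Peaks are stored
#' sorted by retention time.
#'
#' @param sample_id sample identifier.
#' @param rt retention times (minutes).
#' @param area peak areas (>= 0), same length as `rt`.
#' @return data frame of class `"peak_table"` with columns `sample_id`,
#'   `rt_min`, `area`.
#' @export
peak_table <- function(sample_id, rt, area) {
  if (length(rt) != length(area))
    stop("rt and area must have equal length", call. = FALSE)
  if (!length(rt)) stop("empty peak table", call. = FALSE)
  if (any(!is.finite(rt)) || any(!is.finite(area)))
    stop("non-finite rt or area", call. = FALSE)
  if (any(area < 0)) stop("areas must be non-negative", call. = FALSE)
  ord <- order(rt)
  structure(data.frame(sample_id = as.character(sample_id),
                       rt_min = rt[ord], area = area[ord],
                       stringsAsFactors = FALSE),
            class = c("peak_table", "data.frame"))
}

#' Read peak tables from CSV
#'
#' Expects columns `sample_id`, `rt_min`, `area`; one file may hold several
#' samples stacked long-form.
#'
#' @param path CSV file path.
#' @return named list of [peak_table()] objects, one per sample.
#' @export
read_peak_tables <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "rt_min", "area")
  if (!all(need %in% names(d)))
    stop("peak table CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  split_d <- split(d, d$sample_id)
  lapply(split_d, function(s) peak_table(s$sample_id[1], s$rt_min, s$area))
}

#' Align peak tables across samples by a retention-time window
#'
#' Pools the peaks of all samples, sorts them by retention time, and forms
#' consensus peaks by single-linkage grouping: a new group starts wherever
#' the gap between consecutive pooled retention times exceeds `window`.
#' The consensus retention time of a group is the median of its member
#' RTs; samples contributing no peak to a group get area 0 there; if one
#' sample contributes several peaks to a group their areas are summed. A
#' consensus peak present with nonzero area in every sample is a common
#' peak.
#'
#' Because consensus RTs of distinct groups are separated by more than
#' `window`, re-matching the consensus output leaves it unchanged.
#'
#' @param tables list of [peak_table()] objects (>= 2).
#' @param window half-width of the matching window in minutes
#'   (default 0.1).
#' @return object of class `"fingerprint_matrix"`: list with
#'   `sample_ids`, `peak_rts` (strictly increasing consensus RTs), `areas`
#'   (samples x peaks matrix) and `common_mask`.
#' @export
match_peaks <- function(tables, window = 0.1) {
  if (length(tables) < 2) stop("need at least two peak tables", call. = FALSE)
  if (!is.numeric(window) || window <= 0)
    stop("window must be positive", call. = FALSE)
  tables <- lapply(tables, function(t) {
    if (!inherits(t, "peak_table")) peak_table(t$sample_id[1], t$rt_min, t$area)
    else t
  })
  sample_ids <- vapply(tables, function(t) t$sample_id[1], character(1))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids", call. = FALSE)
  pool <- do.call(rbind, tables)
  ord <- order(pool$rt_min)
  pool <- pool[ord, , drop = FALSE]
  gap <- c(Inf, diff(pool$rt_min))
  grp <- cumsum(gap > window)
  rts <- tapply(pool$rt_min, grp, stats::median)
  n_grp <- length(rts)
  areas <- matrix(0, nrow = length(tables), ncol = n_grp,
                  dimnames = list(sample_ids, NULL))
  idx_s <- match(pool$sample_id, sample_ids)
  for (i in seq_len(nrow(pool)))
    areas[idx_s[i], grp[i]] <- areas[idx_s[i], grp[i]] + pool$area[i]
  # order columns by consensus RT (tapply sorts by group already, and
  # groups are RT-ordered, but keep it explicit)
  ordc <- order(rts)
  rts <- as.numeric(rts[ordc])
  areas <- areas[, ordc, drop = FALSE]
  structure(list(sample_ids = sample_ids, peak_rts = rts, areas = areas,
                 common_mask = apply(areas > 0, 2, all), window = window),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat("<fingerprint_matrix> ", length(x$sample_ids), " samples x ",
      length(x$peak_rts), " consensus peaks (",
      sum(x$common_mask), " common)\n", sep = "")
  invisible(x)
}

#' Median reference fingerprint
#'
#' Column-wise median of the aligned area matrix: the simulated "average"
#' chromatogram against which each batch is scored.
#'
#' @param m a [match_peaks()] result.
#' @return numeric vector over consensus peaks, class
#'   `"reference_fingerprint"`.
#' @export
reference_fingerprint <- function(m) {
  stopifnot(inherits(m, "fingerprint_matrix"))
  structure(apply(m$areas, 2, stats::median),
            rt = m$peak_rts, class = "reference_fingerprint")
}

#' Similarity between a sample and the reference fingerprint
#'
#' The congruence (cosine) coefficient
#' \eqn{\sum x y / (\lVert x\rVert\,\lVert y\rVert)}: scale-invariant,
#' symmetric, 1 iff the vectors are positively proportional. A
#' mean-centered Pearson alternative is available via `method`.
#'
#' @param x sample area vector.
#' @param r reference area vector (e.g. [reference_fingerprint()]).
#' @param method `"cosine"` (default) or `"correlation"`.
#' @return similarity in \[-1, 1\].
#' @export
similarity <- function(x, r, method = c("cosine", "correlation")) {
  method <- match.arg(method)
  x <- as.numeric(x); r <- as.numeric(r)
  if (length(x) != length(r))
    stop("vectors must have equal length", call. = FALSE)
  if (all(r == 0)) stop("reference fingerprint is all zero", call. = FALSE)
  if (all(x == 0))
    stop("similarity undefined for an all-zero sample", call. = FALSE)
  if (method == "cosine") {
    sum(x * r) / sqrt(sum(x^2) * sum(r^2))
  } else {
    stats::cor(x, r)
  }
}

#' Similarity report for a fingerprint matrix
#'
#' Scores every sample against the median reference fingerprint and
#' reports the intragroup range.
#'
#' @inheritParams similarity
#' @param m a [match_peaks()] result.
#' @return data frame `sample_id`, `similarity`, with attribute `range`
#'   (min, max).
#' @export
similarity_report <- function(m, method = c("cosine", "correlation")) {
  stopifnot(inherits(m, "fingerprint_matrix"))
  method <- match.arg(method)
  r <- reference_fingerprint(m)
  sim <- apply(m$areas, 1, similarity, r = r, method = method)
  out <- data.frame(sample_id = m$sample_ids, similarity = as.numeric(sim),
                    stringsAsFactors = FALSE)
  attr(out, "range") <- range(out$similarity)
  out
}

#' Write a fingerprint matrix to CSV
#'
#' One row per sample, one column per consensus peak, columns named by
#' consensus retention time.
#'
#' @param m a [match_peaks()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_matrix <- function(m, path) {
  stopifnot(inherits(m, "fingerprint_matrix"))
  d <- data.frame(sample_id = m$sample_ids, m$areas, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d) <- c("sample_id", sprintf("rt_%.3f", m$peak_rts))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
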