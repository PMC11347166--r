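# polysome: translation-rate quantification from A254 fractionation traces
# (polysome AUC / monosome AUC) and the KO-vs-WT comparison.

#' Construct a polysome trace
#' @param position strictly increasing positions (arbitrary units)
#' @param absorbance matching absorbance values
#' @param bounds optional named list of regions, e.g.
#'   `list(monosome = c(2, 4), polysome = c(5, 12))`
#' @return object of class `polysome_trace` (data frame)
#' @export
polysome_trace <- function(position, absorbance, bounds = NULL) {
  rd_assert(length(position) == length(absorbance), "vector lengths differ")
  rd_assert(all(diff(position) > 0), "positions must be strictly increasing")
  structure(data.frame(position = position, absorbance = absorbance),
            class = c("polysome_trace", "data.frame"), bounds = bounds)
}

#' Read / write a two-column trace TSV (`position  absorbance`)
#' @param trace a [polysome_trace()]
#' @param path TSV path
#' @return `path` (writer) or a [polysome_trace()] (reader)
#' @export
write_trace <- function(trace, path) {
  write_tsv_prov(as.data.frame(trace), path, params = list(kind = "trace"))
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read_tsv_prov(path)
  polysome_trace(df$position, df$absorbance)
}

.region_auc <- function(trace, bounds, baseline_mode) {
  sel <- trace$position >= bounds[1] & trace$position <= bounds[2]
  rd_assert(sum(sel) >= 2, "region [", bounds[1], ", ", bounds[2],
            "] holds fewer than 2 trace points")
  x <- trace$position[sel]; y <- trace$absorbance[sel]
  base <- switch(baseline_mode,
    none = rep(0, length(x)),
    constant = rep(min(y), length(x)),
    linear = y[1] + (y[length(y)] - y[1]) * (x - x[1]) / (x[length(x)] - x[1]))
  trapz(x, y - base)
}

#' Polysome-to-monosome area ratio of a trace
#'
#' Trapezoidal integrals over the two regions after baseline subtraction.
#' Baseline modes: `"none"`, `"constant"` (region minimum) or `"linear"`
#' (line through the region endpoints; default).
#'
#' @param trace a [polysome_trace()]
#' @param monosome_bounds,polysome_bounds position ranges `c(lo, hi)`; must
#'   lie within the trace and not overlap
#' @param baseline_mode baseline handling
#' @return polysome AUC / monosome AUC
#' @export
auc_ratio <- function(trace, monosome_bounds, polysome_bounds,
                      baseline_mode = c("linear", "none", "constant")) {
  baseline_mode <- match.arg(baseline_mode)
  pr <- range(trace$position)
  for (b in list(monosome_bounds, polysome_bounds)) {
    rd_assert(b[1] < b[2] && b[1] >= pr[1] && b[2] <= pr[2],
              "region bounds must lie within the trace position range")
  }
  rd_assert(monosome_bounds[2] <= polysome_bounds[1] ||
            polysome_bounds[2] <= monosome_bounds[1],
            "monosome and polysome regions must not overlap")
  mono <- .region_auc(trace, monosome_bounds, baseline_mode)
  poly <- .region_auc(trace, polysome_bounds, baseline_mode)
  if (mono <= 0) {
    rd_stop("monosome AUC is non-positive after baseline subtraction; ",
            "check the bounds or use baseline_mode = 'none'")
  }
  poly / mono
}

#' Locate candidate peak regions in a trace (optional helper)
#'
#' Local maxima above `min_height`, with region bounds at the adjacent
#' valleys. Never applied automatically; intended as a starting point for
#' user-supplied bounds.
#'
#' @param trace a [polysome_trace()]
#' @param min_height minimum absorbance of a reported peak
#' @return data frame `peak_position, height, lo, hi`
#' @export
find_trace_peaks <- function(trace, min_height = 0) {
  y <- trace$absorbance; x <- trace$position; n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE) &
    y > min_height
  idx <- which(is_peak)
  if (!length(idx)) return(data.frame(peak_position = numeric(0),
                                      height = numeric(0), lo = numeric(0),
                                      hi = numeric(0)))
  valleys <- c(1, which(c(FALSE, y[2:(n - 1)] < y[1:(n - 2)] &
                            y[2:(n - 1)] <= y[3:n], FALSE)), n)
  do.call(rbind, lapply(idx, function(i) {
    lo <- max(valleys[valleys < i]); hi <- min(valleys[valleys > i])
    data.frame(peak_position = x[i], height = y[i], lo = x[lo], hi = x[hi])
  }))
}

#' KO-vs-WT translation-rate comparison
#'
#' Fold changes are expressed relative to the WT median ratio; each clone is
#' tested against the WT ratios with a one-sided Welch t-test (alternative:
#' KO greater).
#'
#' @param ko_ratios named list: per KO clone, a numeric vector of
#'   polysome/monosome ratios (>= 2 each)
#' @param wt_ratios numeric vector of WT ratios (>= 2)
#' @return data frame `clone, n, fold_change, t, p`
#' @export
ratio_change_test <- function(ko_ratios, wt_ratios) {
  rd_assert(length(wt_ratios) >= 2, "WT group needs >= 2 ratios (no variance with n = 1)")
  wt_med <- stats::median(wt_ratios)
  rows <- lapply(names(ko_ratios), function(cl) {
    x <- ko_ratios[[cl]]
    rd_assert(length(x) >= 2, "clone ", cl, " needs >= 2 ratios (no variance with n = 1)")
    tt <- stats::t.test(x, wt_ratios, alternative = "greater", var.equal = FALSE)
    data.frame(clone = cl, n = length(x), fold_change = mean(x) / wt_med,
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
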