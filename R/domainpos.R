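# domainpos: coiled-coil positional enrichment along relative sequence
# position, and proportion enrichment of annotated proteins in a target set.

#' Per-protein fraction of residues covered by intervals, in relative bins
#'
#' Residue `r` (0-based) of a protein of length `L` maps to bin
#' `floor(n_bins * r / L)` (clamped to the last bin); the bin fraction is
#' covered residues / residues mapping to the bin.
#'
#' @param intervals data frame `start, end` (0-based half-open) for one
#'   protein; rows with NA start are treated as "no intervals"
#' @param length protein length (aa)
#' @param n_bins number of relative-position bins
#' @return numeric vector of length `n_bins`
#' @export
positional_fraction <- function(intervals, length, n_bins = 100) {
  rd_assert(length >= 1, "protein length must be positive")
  covered <- logical(length)
  if (!is.null(intervals) && nrow(intervals) > 0) {
    iv <- intervals[!is.na(intervals$start), , drop = FALSE]
    rd_assert(all(iv$start >= 0 & iv$end <= length & iv$start < iv$end),
              "intervals must lie within [0, length)")
    for (k in seq_len(nrow(iv))) covered[(iv$start[k] + 1):iv$end[k]] <- TRUE
  }
  r <- seq_len(length) - 1L
  bin <- pmin(floor(n_bins * r / length), n_bins - 1L)
  tot <- tabulate(bin + 1L, nbins = n_bins)
  cov <- vapply(0:(n_bins - 1L), function(b) sum(covered[bin == b]), 0L)
  ifelse(tot > 0, cov / tot, 0)
}

#' Positional-fraction matrix for a set of annotated proteins
#' @param domains data frame from [gen_domain_sets()] (or with columns
#'   `protein_id, start, end, length`)
#' @param n_bins number of bins
#' @return matrix proteins x bins
#' @export
positional_fraction_matrix <- function(domains, n_bins = 100) {
  ids <- unique(domains$protein_id)
  m <- t(vapply(ids, function(id) {
    d <- domains[domains$protein_id == id, , drop = FALSE]
    positional_fraction(d[, c("start", "end")], d$length[1], n_bins)
  }, numeric(n_bins)))
  rownames(m) <- ids
  m
}

#' Per-bin Mann-Whitney comparison of positional fractions
#'
#' Two-sided rank-sum test of target vs non-target bin fractions, one test
#' per bin; no cross-bin correction by default (per-bin profile display).
#'
#' @param target,nontarget matrices proteins x bins (e.g. from
#'   [positional_fraction_matrix()])
#' @return data frame `bin, rel_pos, U, p`
#' @export
binned_mannwhitney <- function(target, nontarget) {
  rd_assert(!is.null(target) && nrow(target) > 0, "empty target group")
  rd_assert(!is.null(nontarget) && nrow(nontarget) > 0, "empty non-target group")
  rd_assert(ncol(target) == ncol(nontarget), "bin counts differ")
  n_bins <- ncol(target)
  res <- lapply(seq_len(n_bins), function(j) {
    x <- target[, j]; y <- nontarget[, j]
    if (length(unique(c(x, y))) == 1) {
      return(data.frame(bin = j - 1L, rel_pos = (j - 0.5) / n_bins,
                        U = length(x) * length(y) / 2, p = 1))
    }
    u <- sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
    data.frame(bin = j - 1L, rel_pos = (j - 0.5) / n_bins,
               U = u, p = .ranksum_p(x, y))
  })
  do.call(rbind, res)
}

#' C-terminal-half summary comparison
#'
#' Mean fraction over bins in the C-terminal half (relative position >= 0.5),
#' compared between groups by a single two-sided Mann-Whitney test.
#'
#' @inheritParams binned_mannwhitney
#' @return list `target_mean, nontarget_mean, p`
#' @export
cterm_half_test <- function(target, nontarget) {
  n_bins <- ncol(target)
  half <- (floor(n_bins / 2) + 1):n_bins
  x <- rowMeans(target[, half, drop = FALSE])
  y <- rowMeans(nontarget[, half, drop = FALSE])
  p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  list(target_mean = mean(x), nontarget_mean = mean(y), p = p)
}

#' Fold enrichment and exact binomial tail for a proportion
#'
#' `fold = (k/n) / background_p`; p-value is the exact upper binomial tail
#' `P(X >= k)` under `Binomial(n, background_p)`.
#'
#' @param k successes in the target set
#' @param n target set size
#' @param background_p background proportion
#' @return list `fold, p.value`
#' @export
proportion_enrichment <- function(k, n, background_p) {
  rd_assert(k >= 0 && n >= 1 && k <= n, "need 0 <= k <= n, n >= 1")
  rd_assert(background_p > 0 && background_p < 1,
            "background_p must be in (0, 1)")
  list(fold = (k / n) / background_p,
       p.value = stats::pbinom(k - 1, n, background_p, lower.tail = FALSE))
}
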