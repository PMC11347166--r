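# paralog_ratio: core-RP selection and paralog-to-core expression-ratio
# statistics on bulk or single-cell count data.

#' Select core ribosomal proteins from stringency annotations
#'
#' Core RPs are rRNA-embedded, early-assembling, conserved across taxa, have
#' no strong paralog and no tissue-specific expression. The criteria are
#' consumed as boolean annotations (they derive from external structural and
#' phylogenetic resources).
#'
#' @param meta data frame with columns `gene, rrna_embedded, early_assembly,
#'   cross_taxa, strong_paralog, tissue_specific` (logical flags)
#' @return character vector of core RP genes
#' @export
select_core_rps <- function(meta) {
  need <- c("gene", "rrna_embedded", "early_assembly", "cross_taxa",
            "strong_paralog", "tissue_specific")
  rd_assert(all(need %in% names(meta)), "metadata must have columns: ",
            paste(need, collapse = ", "))
  pass <- meta$rrna_embedded & meta$early_assembly & meta$cross_taxa &
    !meta$strong_paralog & !meta$tissue_specific
  if (!any(pass)) {
    rd_stop("no gene passes all five core-RP criteria; consider relaxing ",
            "the annotation thresholds")
  }
  meta$gene[pass]
}

#' TPM-weighted gene length
#'
#' `sum(l_i * t_i) / sum(t_i)`; with all-zero TPM, falls back to the
#' unweighted mean with a warning.
#'
#' @param transcript_lengths lengths (nt) of a gene's transcripts
#' @param transcript_tpms matching TPM values
#' @return weighted mean length
#' @export
weighted_gene_length <- function(transcript_lengths, transcript_tpms) {
  rd_assert(length(transcript_lengths) == length(transcript_tpms),
            "lengths and TPMs must match")
  if (sum(transcript_tpms) == 0) {
    warning("all TPM values are zero; returning unweighted mean length")
    return(mean(transcript_lengths))
  }
  sum(transcript_lengths * transcript_tpms) / sum(transcript_tpms)
}

#' Reads per kilobase with pseudocount
#' @param raw_count raw gene count(s)
#' @param gene_length_nt gene length in nt
#' @param pseudocount added to the raw count (default 1)
#' @return `(count + pseudocount) / (length / 1000)`
#' @export
rpk <- function(raw_count, gene_length_nt, pseudocount = 1) {
  rd_assert(all(gene_length_nt > 0), "gene length must be positive")
  (raw_count + pseudocount) / (gene_length_nt / 1000)
}

#' Log2 ratio of a focal gene's RPK to the median core-RP RPK
#' @param sample_rpks named RPK vector for one sample (or RPK matrix
#'   genes x samples)
#' @param focal_gene focal gene name
#' @param core_set core RP gene names
#' @return log2 ratio (vector over samples if a matrix was given)
#' @export
ratio_to_core <- function(sample_rpks, focal_gene, core_set) {
  if (is.matrix(sample_rpks)) {
    rd_assert(all(c(focal_gene, core_set) %in% rownames(sample_rpks)),
              "missing genes in RPK matrix")
    core_med <- apply(sample_rpks[core_set, , drop = FALSE], 2, stats::median)
    return(log2(sample_rpks[focal_gene, ] / core_med))
  }
  rd_assert(all(c(focal_gene, core_set) %in% names(sample_rpks)),
            "missing genes in RPK vector")
  log2(sample_rpks[[focal_gene]] / stats::median(sample_rpks[core_set]))
}

#' Per-group ratio tests against a pooled reference group
#'
#' Each group's ratios are compared to the reference group's by a two-sided
#' Wilcoxon rank-sum test (exact mid-rank enumeration for combined n <= 12,
#' mid-ranks with normal approximation and continuity correction above); BH
#' correction across groups; direction is the sign of the median difference.
#'
#' @param ratios numeric vector of per-sample (or per-cell) ratios
#' @param groups group label per ratio
#' @param reference_group label of the reference group
#' @return data frame `group, n, p, q, direction` (class `ratio_tests`);
#'   empty groups are dropped with a warning
#' @export
group_ratio_tests <- function(ratios, groups, reference_group) {
  rd_assert(reference_group %in% groups, "reference group not present")
  ref <- ratios[groups == reference_group & !is.na(ratios)]
  rd_assert(length(ref) > 0, "reference group is empty")
  gl <- setdiff(unique(groups), reference_group)
  rows <- lapply(gl, function(g) {
    x <- ratios[groups == g & !is.na(ratios)]
    if (length(x) == 0) {
      warning("group '", g, "' is empty; excluded")
      return(NULL)
    }
    data.frame(group = g, n = length(x), p = .ranksum_p(x, ref),
               direction = sign(stats::median(x) - stats::median(ref)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rd_assert(!is.null(out), "no non-reference group with data")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("group", "n", "p", "q", "direction")]
  class(out) <- c("ratio_tests", "data.frame")
  out
}

# Two-sided Wilcoxon rank-sum p: complete mid-rank enumeration for combined
# n <= exact_max (ties included), otherwise stats::wilcox.test (mid-ranks,
# normal approximation, continuity correction). Two-sided p is twice the
# smaller tail probability, capped at 1.
.ranksum_p <- function(x, y, exact_max = 12) {
  N <- length(x) + length(y)
  if (N <= exact_max) {
    r <- rank(c(x, y))
    n <- length(x)
    w_obs <- sum(r[seq_len(n)])
    combos <- utils::combn(N, n)
    w_all <- colSums(matrix(r[combos], nrow = n))
    min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  } else {
    suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                        exact = NULL, correct = TRUE)$p.value)
  }
}

# Ansari-Bradley scores from mid-ranks of the combined sample
.ab_scores <- function(z) {
  r <- rank(z)
  N <- length(z)
  pmin(r, N + 1 - r)
}

#' Ansari-Bradley two-sample scale (dispersion) test
#'
#' Exact null by complete enumeration for combined n <= `exact_max` (no-tie
#' case enumerates all assignments; ties use mid-rank scores), normal
#' approximation above. Two-sided p is twice the smaller tail, capped at 1.
#'
#' @param group_a,group_b numeric samples
#' @param exact_max maximal combined size for exact enumeration
#' @return list `statistic` (AB score sum of group_a), `p.value`, `method`
#' @export
dispersion_test <- function(group_a, group_b, exact_max = 20) {
  group_a <- group_a[!is.na(group_a)]; group_b <- group_b[!is.na(group_b)]
  rd_assert(length(group_a) >= 2 && length(group_b) >= 2,
            "both groups need >= 2 observations")
  if (length(unique(group_a)) == 1 || length(unique(group_b)) == 1) {
    rd_stop("scale test undefined for a constant-valued group")
  }
  z <- c(group_a, group_b)
  a <- .ab_scores(z)
  n <- length(group_a); N <- length(z)
  ab <- sum(a[seq_len(n)])
  if (N <= exact_max) {
    combos <- utils::combn(N, n)
    stats_all <- colSums(matrix(a[combos], nrow = n))
    p <- min(1, 2 * min(mean(stats_all <= ab), mean(stats_all >= ab)))
    method <- "exact"
  } else {
    abar <- mean(a)
    v <- n * (N - n) / (N * (N - 1)) * sum((a - abar)^2)
    zstat <- (ab - n * abar) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(zstat)))
    method <- "normal"
  }
  list(statistic = ab, p.value = p, method = method)
}

#' Fraction of gene-a-positive cells that also express gene b
#' @param cell_counts gene x cell count matrix
#' @param gene_a,gene_b gene names
#' @return proportion, or NA when no cell expresses `gene_a`
#' @export
coexpression_fraction <- function(cell_counts, gene_a, gene_b) {
  rd_assert(all(c(gene_a, gene_b) %in% rownames(cell_counts)),
            "genes not found in count matrix")
  a_pos <- cell_counts[gene_a, ] > 0
  if (!any(a_pos)) return(NA_real_)
  sum(a_pos & cell_counts[gene_b, ] > 0) / sum(a_pos)
}
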