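# teglm: translation-efficiency values and the differential-TE interaction
# test: per gene, an NB log-linear model on combined RNA + RPF counts with
# terms intercept + genotype + assay + genotype:assay and offset log(size
# factor). The interaction coefficient is the TE log2 fold change; the Wald
# statistic uses the expected information at the MLE with the dispersion held
# at its Cox-Reid adjusted profile-ML estimate (floor 1e-8).

#' Median-of-ratios size factors
#'
#' `factor_s = median over genes with all-positive counts of
#' count[g, s] / geometric_mean_g`.
#'
#' @param counts gene x sample count matrix
#' @return named positive vector, one factor per sample
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  rd_assert(all(counts >= 0), "counts must be non-negative")
  logs <- log(counts)
  use <- rowSums(is.finite(logs)) == ncol(counts)
  rd_assert(any(use), "no gene has all-positive counts; cannot normalize")
  loggm <- rowMeans(logs[use, , drop = FALSE])
  sf <- apply(logs[use, , drop = FALSE], 2, function(lc) exp(stats::median(lc - loggm)))
  stats::setNames(sf, colnames(counts))
}

# NB log-likelihood; alpha below floor treated as Poisson
.nb_loglik <- function(y, mu, alpha) {
  if (alpha < 1e-8) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

# IRLS for beta given alpha; returns list(beta, mu, converged)
.nb_irls <- function(y, X, offset, alpha, beta0 = NULL, max_iter = 50, tol = 1e-10) {
  beta <- beta0
  if (is.null(beta)) {
    beta <- qr.solve(X, log(pmax(y, 0.5)) - offset)
  }
  eta <- drop(X %*% beta) + offset
  mu <- exp(pmin(eta, 30))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      return(list(beta = beta, mu = mu, converged = FALSE))
    }
    beta <- fit$coefficients
    eta <- drop(X %*% beta) + offset
    mu <- exp(pmin(eta, 30))
    ll <- .nb_loglik(y, mu, alpha)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(beta = beta, mu = mu, converged = TRUE)
}

# full fit: Cox-Reid adjusted profile-ML dispersion (floor 1e-8) + beta +
# expected-information SE. The CR term -0.5*log det(X'WX) removes the
# downward bias of plain ML dispersion at small replicate numbers.
.nb_fit <- function(y, X, offset) {
  prof <- function(log_alpha) {
    f <- .nb_irls(y, X, offset, exp(log_alpha))
    if (!f$converged) return(-1e300)
    w <- f$mu / (1 + exp(log_alpha) * f$mu)
    ll <- .nb_loglik(y, f$mu, exp(log_alpha)) -
      0.5 * as.numeric(determinant(crossprod(X, X * w))$modulus)
    if (!is.finite(ll)) -1e300 else ll
  }
  opt <- stats::optimize(prof, interval = log(c(1e-8, 50)), maximum = TRUE,
                         tol = 1e-6)
  alpha <- max(exp(opt$maximum), 1e-8)
  fit <- .nb_irls(y, X, offset, alpha)
  if (!fit$converged || any(!is.finite(fit$beta)) || max(abs(fit$beta)) > 20) {
    return(list(status = "degenerate"))
  }
  w <- fit$mu / (1 + alpha * fit$mu)
  info <- crossprod(X, X * w)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov) || any(diag(cov) <= 0)) return(list(status = "degenerate"))
  list(status = "ok", beta = fit$beta, se = sqrt(diag(cov)), alpha = alpha,
       loglik = .nb_loglik(y, fit$mu, alpha))
}

#' Differential translation efficiency (interaction NB GLM)
#'
#' Fits, per gene, an NB GLM on the combined RNA and RPF counts with design
#' `~ genotype + assay + genotype:assay` and `log(size factor)` offset; the
#' genotype:assay interaction is the TE log2 fold change (KO vs WT). Genes
#' with all-zero counts in any (assay, genotype) cell are excluded before
#' fitting; degenerate fits are flagged and excluded from BH correction.
#'
#' @param rna_counts,rpf_counts gene x sample count matrices; column names
#'   must match `design$sample_id`
#' @param design a [design_table()] covering both assays, >= 2 replicates per
#'   (genotype, clone, assay) group
#' @param alpha significance threshold recorded on the `sig` column
#'   (raw p-value, following the source convention)
#' @param test "wald" (default) or "lrt"
#' @return data frame (class `te_table`) with columns `gene,
#'   log2fc_interaction, se, stat, pvalue, padj, status`; attribute
#'   `"n_degenerate"` counts flagged genes
#' @export
delta_te_test <- function(rna_counts, rpf_counts, design, alpha = 0.01,
                          test = c("wald", "lrt")) {
  test <- match.arg(test)
  rna_counts <- as.matrix(rna_counts); rpf_counts <- as.matrix(rpf_counts)
  d_rna <- design[design$assay == "RNA", , drop = FALSE]
  d_rpf <- design[design$assay == "RPF", , drop = FALSE]
  rd_assert(nrow(d_rna) > 0 && nrow(d_rpf) > 0,
            "design must contain both RNA and RPF samples")
  for (g in c("WT", "KO")) {
    rd_assert(sum(d_rna$genotype == g) >= 2 && sum(d_rpf$genotype == g) >= 2,
              "need >= 2 replicates per (genotype, assay); missing for ", g)
  }
  rd_assert(all(d_rna$sample_id %in% colnames(rna_counts)),
            "rna_counts columns do not match design")
  rd_assert(all(d_rpf$sample_id %in% colnames(rpf_counts)),
            "rpf_counts columns do not match design")
  rd_assert(identical(rownames(rna_counts), rownames(rpf_counts)),
            "rna and rpf count matrices must share the same genes")
  counts <- cbind(rna_counts[, d_rna$sample_id, drop = FALSE],
                  rpf_counts[, d_rpf$sample_id, drop = FALSE])
  if (all(counts == 0)) rd_stop("all counts are zero; nothing to test")
  meta <- rbind(d_rna, d_rpf)
  sf <- size_factors(counts)
  offset <- log(unname(sf))
  geno <- as.integer(meta$genotype == "KO")
  assay <- as.integer(meta$assay == "RPF")
  X <- cbind(intercept = 1, genotype = geno, assay = assay,
             interaction = geno * assay)
  X0 <- X[, 1:3, drop = FALSE]

  cell <- interaction(meta$genotype, meta$assay)
  genes <- rownames(counts)
  res <- data.frame(gene = genes, log2fc_interaction = NA_real_, se = NA_real_,
                    stat = NA_real_, pvalue = NA_real_, padj = NA_real_,
                    status = "low_counts", stringsAsFactors = FALSE)
  for (gi in seq_along(genes)) {
    y <- counts[gi, ]
    if (any(tapply(y, cell, function(v) all(v == 0)))) next
    fit <- .nb_fit(y, X, offset)
    if (fit$status != "ok") { res$status[gi] <- "degenerate"; next }
    b <- fit$beta[["interaction"]]; s <- fit$se[["interaction"]]
    res$log2fc_interaction[gi] <- b / log(2)
    res$se[gi] <- s / log(2)
    if (test == "wald") {
      res$stat[gi] <- b / s
      res$pvalue[gi] <- 2 * stats::pnorm(-abs(b / s))
    } else {
      fit0 <- .nb_fit(y, X0, offset)
      if (fit0$status != "ok") { res$status[gi] <- "degenerate"; next }
      lr <- 2 * (fit$loglik - fit0$loglik)
      res$stat[gi] <- lr
      res$pvalue[gi] <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    }
    res$status[gi] <- "ok"
  }
  ok <- res$status == "ok"
  res$padj[ok] <- stats::p.adjust(res$pvalue[ok], method = "BH")
  res$sig <- !is.na(res$pvalue) & res$pvalue < alpha
  attr(res, "n_degenerate") <- sum(res$status == "degenerate")
  attr(res, "alpha") <- alpha
  class(res) <- c("te_table", "data.frame")
  res
}

#' Translation efficiency per gene and condition
#'
#' Density = size-factor-normalized counts / CDS length;
#' `TE = mean RPF density / mean RNA density` within each genotype. Genes with
#' zero mean RNA density get NA (missing), not infinity.
#'
#' @param rna_counts,rpf_counts gene x sample count matrices
#' @param design a [design_table()]
#' @param cds_lengths named vector of CDS lengths (nt) per gene
#' @return data frame `gene, te_wt, te_ko`
#' @export
te_values <- function(rna_counts, rpf_counts, design, cds_lengths) {
  rna_counts <- as.matrix(rna_counts); rpf_counts <- as.matrix(rpf_counts)
  genes <- rownames(rna_counts)
  rd_assert(all(genes %in% names(cds_lengths)), "cds_lengths must cover all genes")
  d_rna <- design[design$assay == "RNA", , drop = FALSE]
  d_rpf <- design[design$assay == "RPF", , drop = FALSE]
  counts <- cbind(rna_counts[, d_rna$sample_id, drop = FALSE],
                  rpf_counts[, d_rpf$sample_id, drop = FALSE])
  sf <- size_factors(counts)
  dens <- sweep(counts, 2, sf, "/") / (cds_lengths[genes] / 1000)
  nc_rna <- nrow(d_rna)
  te_for <- function(gt) {
    rna_m <- rowMeans(dens[, which(d_rna$genotype == gt), drop = FALSE])
    rpf_m <- rowMeans(dens[, nc_rna + which(d_rpf$genotype == gt), drop = FALSE])
    ifelse(rna_m > 0, rpf_m / rna_m, NA_real_)
  }
  data.frame(gene = genes, te_wt = te_for("WT"), te_ko = te_for("KO"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a TE result table as TSV
#' @param te a `te_table` from [delta_te_test()]
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_te_table <- function(te, path) {
  write_tsv_prov(as.data.frame(te), path, params = list(kind = "te_table"))
}
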