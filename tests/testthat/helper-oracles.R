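# Shared fixtures and independent oracles. Oracles deliberately use naive
# enumeration / nested loops so they share no code path with the package.

# small deterministic transcript set built by hand-ish (seeded generator at
# toy scale, or explicit CDS strings where codon content must be controlled)
toy_tx <- function(n_tx = 5, n_codons = 80, seed = 101) {
  gen_transcriptome(n_tx, n_codons, seed = seed)
}

# build a codon_coverage object from a function (tx_row, codon_positions) -> counts
make_cov <- function(tx, fn, sample_id = "s1") {
  counts <- lapply(seq_len(nrow(tx)), function(i) {
    as.integer(fn(i, seq_len(tx$n_codons[i])))
  })
  names(counts) <- tx$transcript_id
  ribodwell:::new_codon_coverage(counts, sample_id = sample_id)
}

# brute-force dwell-time oracle: explicit position enumeration
oracle_dwell <- function(cov, tx, min_tx_coverage = 0.5, trim_start = 20,
                         trim_end = 10, condition = NULL,
                         min_codon_positions = 1) {
  sense <- sense_codons()
  sums <- stats::setNames(numeric(61), sense)
  cnts <- stats::setNames(integer(61), sense)
  for (i in seq_len(nrow(tx))) {
    n <- tx$n_codons[i]
    x <- cov[[tx$transcript_id[i]]]
    keep <- seq(trim_start + 1, n - trim_end)
    m <- mean(x[keep])
    if (m < min_tx_coverage || m <= 0) next
    cods <- substring(tx$cds[i], 3 * (seq_len(n) - 1) + 1, 3 * seq_len(n))
    prot <- strsplit(tx$protein[i], "")[[1]]
    for (j in keep) {
      if (!cods[j] %in% sense) next
      if (!is.null(condition)) {
        up <- j - condition$offset
        if (up < 1 || up > length(prot) || prot[up] != condition$aa) next
      }
      sums[cods[j]] <- sums[cods[j]] + x[j] / m
      cnts[cods[j]] <- cnts[cods[j]] + 1L
    }
  }
  dw <- ifelse(cnts >= min_codon_positions & cnts > 0, sums / cnts, NA_real_)
  dw / mean(dw, na.rm = TRUE)
}

# exact two-sided Wilcoxon rank-sum p by complete enumeration (doubling
# convention, capped at 1) -- mirrors the exact definition, not the code path
oracle_wilcox_p <- function(x, y) {
  z <- c(x, y)
  n <- length(x)
  r <- rank(z)
  w_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(length(z), n)
  w_all <- colSums(matrix(r[combos], nrow = n))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# residue-level positional-fraction oracle
oracle_positional_fraction <- function(starts, ends, L, n_bins = 100) {
  covered <- logical(L)
  for (k in seq_along(starts)) covered[(starts[k] + 1):ends[k]] <- TRUE
  out <- numeric(n_bins)
  tot <- integer(n_bins)
  for (r in 0:(L - 1)) {
    b <- min(floor(n_bins * r / L), n_bins - 1) + 1
    tot[b] <- tot[b] + 1L
    if (covered[r + 1]) out[b] <- out[b] + 1
  }
  ifelse(tot > 0, out / tot, 0)
}

# independent NB interaction-GLM oracle: same statistic definition, fitted by
# generic optimizers (optim over beta; dense grid over log-dispersion with the
# Cox-Reid term), no IRLS
oracle_nb_wald <- function(y, X, offset) {
  loglik <- function(beta, alpha) {
    mu <- exp(drop(X %*% beta) + offset)
    sum(lgamma(y + 1 / alpha) - lgamma(1 / alpha) - lgamma(y + 1) +
          y * log(alpha * mu / (1 + alpha * mu)) -
          (1 / alpha) * log(1 + alpha * mu))
  }
  beta_hat <- function(alpha) {
    start <- qr.solve(X, log(pmax(y, 0.5)) - offset)
    stats::optim(start, function(b) -loglik(b, alpha), method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 1000))$par
  }
  cr_obj <- function(alpha) {
    b <- beta_hat(alpha)
    mu <- exp(drop(X %*% b) + offset)
    w <- mu / (1 + alpha * mu)
    loglik(b, alpha) - 0.5 * as.numeric(determinant(crossprod(X, X * w))$modulus)
  }
  la_grid <- seq(log(1e-6), log(10), length.out = 400)
  vals <- vapply(la_grid, function(la) cr_obj(exp(la)), 0)
  la0 <- la_grid[which.max(vals)]
  opt <- stats::optimize(function(la) cr_obj(exp(la)),
                         interval = c(la0 - 0.2, la0 + 0.2), maximum = TRUE,
                         tol = 1e-10)
  alpha <- exp(opt$maximum)
  b <- beta_hat(alpha)
  mu <- exp(drop(X %*% b) + offset)
  w <- mu / (1 + alpha * mu)
  cv <- solve(crossprod(X, X * w))
  k <- ncol(X)
  list(stat = b[k] / sqrt(cv[k, k]), beta = b, alpha = alpha)
}
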