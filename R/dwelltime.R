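# dwelltime: per-codon dwell-time estimation (optionally conditioned on the
# nascent-chain residue at a fixed distance upstream of the P site), KO-vs-WT
# dwell changes, and the cross-clone cosine-consistency grid.
#
# Estimator: per-transcript mean-normalized density averaged over qualifying
# codon positions, renormalized to mean 1 over non-missing codons. Offset d
# conditions on the residue synthesized d codons before the P-site residue
# (offset 0 = the P-site codon's own residue).

# Per-sample flat preprocessing: inclusion mask (trims + coverage floor) and
# per-transcript mean-normalized density.
.dwell_prep <- function(cov, tx, min_tx_coverage, trim_start, trim_end) {
  idx <- match(names(cov), tx$transcript_id)
  rd_assert(!anyNA(idx) && length(idx) == nrow(tx) && all(idx == seq_len(nrow(tx))),
            "coverage must cover the transcript set in order")
  n <- tx$n_codons
  pos <- unlist(lapply(n, seq_len), use.names = FALSE)
  tx_i <- rep(seq_len(nrow(tx)), n)
  x <- as.numeric(unlist(cov, use.names = FALSE))
  trimmed <- pos > trim_start & pos <= (n[tx_i] - trim_end)
  # per-transcript mean over trimmed positions
  sums <- rowsum(x * trimmed, tx_i)
  cnts <- rowsum(as.numeric(trimmed), tx_i)
  txmean <- as.numeric(sums / pmax(cnts, 1))
  include <- trimmed & (txmean[tx_i] >= min_tx_coverage) & txmean[tx_i] > 0
  nd <- x / txmean[tx_i]
  nd[!include] <- NA_real_
  list(pos = pos, tx_i = tx_i, include = include, nd = nd)
}

.norm_condition <- function(condition) {
  if (is.null(condition)) return(NULL)
  if (!is.list(condition)) condition <- list(aa = condition[[1]],
                                             offset = as.integer(condition[[2]]))
  rd_assert(condition$aa %in% standard_aas(), "unknown amino acid in condition")
  rd_assert(condition$offset >= 0, "condition offset must be >= 0")
  condition
}

#' Estimate per-codon dwell times for one sample
#'
#' `dwell(c)` is the mean over qualifying positions carrying codon `c` of the
#' per-transcript mean-normalized footprint density. Qualifying positions lie
#' outside the trimmed CDS ends, on transcripts with mean trimmed coverage of
#' at least `min_tx_coverage` footprints/codon, and - when `condition` is set -
#' have the conditioning residue at `offset` codons upstream of the P site
#' (positions with `i - offset < 1` never qualify). The vector is renormalized
#' to mean 1 over non-missing codons.
#'
#' @param cov a `codon_coverage` object (one sample)
#' @param tx a [transcript_set()]
#' @param min_tx_coverage minimum mean footprints/codon per transcript
#' @param trim_start,trim_end codons excluded at the CDS start/end
#'   (initiation/termination ramps)
#' @param condition `list(aa =, offset =)` or NULL for unconditioned
#' @param min_codon_positions codons observed at fewer qualifying positions
#'   are marked missing (NA), not zero
#' @return object of class `dwell_vector`: list with `dwell` (named over the
#'   61 sense codons, NA = missing), `n_positions`, `condition`
#' @export
dwell_times <- function(cov, tx, min_tx_coverage = 0.5, trim_start = 20,
                        trim_end = 10, condition = NULL,
                        min_codon_positions = 1) {
  condition <- .norm_condition(condition)
  fl <- .flatten_tx(tx)
  prep <- .dwell_prep(cov, tx, min_tx_coverage, trim_start, trim_end)
  sel <- prep$include & !is.na(fl$codon_id)
  if (!is.null(condition)) {
    d <- condition$offset
    pa <- .flat_prot_idx(tx, fl)
    cond_pa <- c(rep(NA_integer_, d), pa)[seq_along(pa)]
    sel <- sel & prep$pos > d & !is.na(cond_pa) &
      cond_pa == match(condition$aa, standard_aas())
    sel[is.na(sel)] <- FALSE
  }
  sums <- numeric(61); cnts <- integer(61)
  if (any(sel)) {
    tb <- rowsum(prep$nd[sel], fl$codon_id[sel])
    sums[as.integer(rownames(tb))] <- tb
    cnts <- tabulate(fl$codon_id[sel], nbins = 61)
  }
  dwell <- ifelse(cnts >= min_codon_positions & cnts > 0, sums / cnts, NA_real_)
  if (all(is.na(dwell))) {
    rd_stop("no qualifying positions for any codon",
            if (!is.null(condition)) paste0(" under condition (",
                                            condition$aa, ", +",
                                            condition$offset, ")") else "")
  }
  dwell <- dwell / mean(dwell, na.rm = TRUE)
  structure(list(dwell = stats::setNames(dwell, sense_codons()),
                 n_positions = stats::setNames(cnts, sense_codons()),
                 condition = condition,
                 sample_id = attr(cov, "sample_id")),
            class = "dwell_vector")
}

# amino-acid index (into standard_aas()) of the residue at each flat codon
# position; NA at the stop codon.
.flat_prot_idx <- function(tx, fl) {
  aas <- standard_aas()
  unlist(lapply(seq_len(nrow(tx)), function(i) {
    v <- match(fl$prot[[i]], aas)
    c(v, NA_integer_)                     # stop codon position
  }), use.names = FALSE)
}

#' @export
print.dwell_vector <- function(x, ...) {
  cat(sprintf("dwell_vector [%s]: %d/61 codons observed%s\n",
              x$sample_id %||% "?", sum(!is.na(x$dwell)),
              if (!is.null(x$condition)) sprintf(", condition (%s, +%d)",
                                                 x$condition$aa, x$condition$offset)
              else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log2 dwell-time change of a KO clone relative to WT
#'
#' `Delta(c) = log2(mean over clone replicates of dwell(c)) -
#' log2(mean over WT replicates of dwell(c))`. A codon is missing on a side
#' when it is missing in all of that side's replicates, and the result is
#' missing when either side is.
#'
#' @param clone_samples list of `dwell_vector`s (clone replicates)
#' @param wt_samples list of `dwell_vector`s (WT replicates)
#' @return named numeric vector over the 61 sense codons (NA = missing)
#' @export
dwell_change <- function(clone_samples, wt_samples) {
  if (inherits(clone_samples, "dwell_vector")) clone_samples <- list(clone_samples)
  if (inherits(wt_samples, "dwell_vector")) wt_samples <- list(wt_samples)
  side_mean <- function(dvs) {
    m <- sapply(dvs, function(v) v$dwell)
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    out <- rowMeans(m, na.rm = TRUE)
    out[!is.finite(out)] <- NA_real_
    out
  }
  log2(side_mean(clone_samples)) - log2(side_mean(wt_samples))
}

#' Cosine similarity of two dwell-change vectors
#'
#' Computed over the intersection of non-missing codons; requires at least 2
#' shared codons and non-zero norms (otherwise NA).
#'
#' @param u,v numeric vectors (may contain NA)
#' @return cosine similarity in `[-1, 1]`, or NA when undefined
#' @export
cosine_sim <- function(u, v) {
  ok <- !is.na(u) & !is.na(v)
  if (sum(ok) < 2) return(NA_real_)
  nu <- sqrt(sum(u[ok]^2)); nv <- sqrt(sum(v[ok]^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u[ok] * v[ok]) / (nu * nv)
}

#' Cross-clone consistency grid of conditional dwell-time changes
#'
#' For every (amino acid, offset) pair, estimates each KO clone's conditioned
#' dwell-change vector relative to the pooled WT (all WT replicates averaged),
#' computes the cosine similarity for each pair of clones, and stores the mean
#' over the `choose(k, 2)` pairs. A cell is missing when any clone pair's
#' cosine is undefined.
#'
#' @param coverages named list of `codon_coverage` objects (RPF samples)
#' @param design a [design_table()]
#' @param tx a [transcript_set()]
#' @param offsets conditioning offsets to scan (codons upstream of the P site)
#' @param aa_set amino acids to scan
#' @inheritParams dwell_times
#' @return object of class `dwell_grid`: matrix amino acids x offsets of mean
#'   pairwise cosine similarity, with attribute `"pair_cosines"` (long data
#'   frame) and `"clones"`
#' @export
consistency_grid <- function(coverages, design, tx, offsets = 20:45,
                             aa_set = standard_aas(), min_tx_coverage = 0.5,
                             trim_start = 20, trim_end = 10,
                             min_codon_positions = 1) {
  rpf <- design[design$assay == "RPF", , drop = FALSE]
  rpf <- rpf[rpf$sample_id %in% names(coverages), , drop = FALSE]
  clones <- unique(rpf$clone_id[rpf$genotype == "KO"])
  if (length(clones) < 2) {
    rd_stop("consistency requires >= 2 KO clones (got ", length(clones), ")")
  }
  wt_ids <- rpf$sample_id[rpf$genotype == "WT"]
  rd_assert(length(wt_ids) >= 1, "no WT RPF samples in design")
  aas <- standard_aas()
  aa_cols <- match(aa_set, aas)
  rd_assert(!anyNA(aa_cols), "aa_set contains unknown amino acids")

  fl <- .flatten_tx(tx)
  pa <- .flat_prot_idx(tx, fl)
  codon_ok <- !is.na(fl$codon_id)
  preps <- lapply(coverages[rpf$sample_id], .dwell_prep, tx = tx,
                  min_tx_coverage = min_tx_coverage,
                  trim_start = trim_start, trim_end = trim_end)

  # dwell[[sample]][[offset]] = 61 x 20 matrix of conditioned dwell vectors
  n_s <- nrow(rpf)
  dwell_arr <- vector("list", n_s)
  for (s in seq_len(n_s)) dwell_arr[[s]] <- vector("list", length(offsets))
  for (di in seq_along(offsets)) {
    d <- offsets[di]
    cond_pa <- c(rep(NA_integer_, d), pa)[seq_along(pa)]
    base_sel <- codon_ok & fl$pos > d & !is.na(cond_pa)
    g <- fl$codon_id + 61L * (cond_pa - 1L)          # 1..1220, NA-propagating
    for (s in seq_len(n_s)) {
      sel <- base_sel & preps[[s]]$include
      gs <- g[sel]
      sums <- numeric(1220)
      tb <- rowsum(preps[[s]]$nd[sel], gs)
      sums[as.integer(rownames(tb))] <- tb
      cnts <- tabulate(gs, nbins = 1220)
      m <- matrix(ifelse(cnts >= min_codon_positions & cnts > 0, sums / cnts,
                         NA_real_), nrow = 61)
      # renormalize each conditioned vector to mean 1 over non-missing codons
      mu <- colMeans(m, na.rm = TRUE)
      mu[!is.finite(mu) | mu == 0] <- NA_real_
      dwell_arr[[s]][[di]] <- sweep(m, 2, mu, "/")
    }
  }

  wt_rows <- which(rpf$genotype == "WT")
  grid <- matrix(NA_real_, length(aa_set), length(offsets),
                 dimnames = list(aa_set, offsets))
  pairs <- utils::combn(clones, 2)
  long <- vector("list", length(aa_set) * length(offsets))
  li <- 0L
  row_mean <- function(mat) {
    out <- rowMeans(mat, na.rm = TRUE)
    out[!is.finite(out)] <- NA_real_
    out
  }
  for (ai in seq_along(aa_set)) {
    j <- aa_cols[ai]
    for (di in seq_along(offsets)) {
      col_of <- function(s) dwell_arr[[s]][[di]][, j]
      wt_m <- row_mean(sapply(wt_rows, col_of))
      deltas <- sapply(clones, function(cl) {
        rows <- which(rpf$clone_id == cl)
        log2(row_mean(sapply(rows, col_of))) - log2(wt_m)
      })
      cs <- apply(pairs, 2, function(pr) {
        cosine_sim(deltas[, pr[1]], deltas[, pr[2]])
      })
      li <- li + 1L
      long[[li]] <- data.frame(aa = aa_set[ai], offset = offsets[di],
                               clone_a = pairs[1, ], clone_b = pairs[2, ],
                               cosine = cs, stringsAsFactors = FALSE)
      grid[ai, di] <- if (anyNA(cs)) NA_real_ else mean(cs)
    }
  }
  structure(grid, class = c("dwell_grid", "matrix"),
            pair_cosines = do.call(rbind, long), clones = clones,
            offsets = offsets)
}

#' Coordinates of the maximal consistency-grid cell
#'
#' Missing cells are skipped; ties resolve to the lexicographically smallest
#' (amino acid, offset).
#'
#' @param grid a `dwell_grid` (or plain matrix with aa rows / offset columns)
#' @return list `aa`, `offset`, `score`
#' @export
argmax_grid <- function(grid) {
  g <- unclass(grid)
  if (all(is.na(g))) rd_stop("all grid cells are missing")
  best <- max(g, na.rm = TRUE)
  aas <- rownames(g); offs <- colnames(g)
  for (i in order(aas)) {
    for (j in order(as.integer(offs))) {
      if (!is.na(g[i, j]) && g[i, j] == best) {
        return(list(aa = aas[i], offset = as.integer(offs[j]), score = best))
      }
    }
  }
}

#' Write a consistency grid as TSV (wide), plus per-pair cosines (long)
#' @param grid a `dwell_grid`
#' @param path output TSV for the grid
#' @param pairs_path optional output TSV for the per-pair cosine table
#' @return `path`, invisibly
#' @export
write_grid <- function(grid, path, pairs_path = NULL) {
  df <- data.frame(aa = rownames(grid), unclass(grid), check.names = FALSE)
  write_tsv_prov(df, path, params = list(kind = "dwell_grid"))
  if (!is.null(pairs_path)) {
    write_tsv_prov(attr(grid, "pair_cosines"), pairs_path,
                   params = list(kind = "pair_cosines"))
  }
  invisible(path)
}
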