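# synthio: seeded generators for every input the downstream stages consume.
# All generators call set.seed() on a child seed derived from (master seed,
# stage label), so outputs are bit-reproducible and independent of caller RNG
# state or of which other stages ran before.

#' Construct a codon dwell-time model
#'
#' Describes the expected ribosome density per codon and an optional planted
#' effect: whenever the nascent-chain residue `effect_offset` codons upstream
#' of the P site equals `effect_aa` and the P-site codon is in `effect_codons`,
#' the expected density is multiplied by `effect_factor`.
#'
#' @param base_dwell named positive vector over the 61 sense codons; it is
#'   renormalized to mean 1. Default: all equal.
#' @param effect_aa single amino acid (one-letter) or NULL for no effect
#' @param effect_offset conditioning offset in codons, in `[20, 45]`
#' @param effect_codons codons receiving the effect (default: all codons of
#'   `effect_aa`)
#' @param effect_factor positive multiplier
#' @param dispersion NB dispersion alpha (variance mu + alpha mu^2); 0 = Poisson
#' @param depth expected footprints per sample
#' @return object of class `dwell_model`
#' @export
dwell_model <- function(base_dwell = NULL, effect_aa = NULL, effect_offset = NULL,
                        effect_codons = NULL, effect_factor = 1,
                        dispersion = 0.1, depth = 1e6) {
  sense <- sense_codons()
  if (is.null(base_dwell)) base_dwell <- stats::setNames(rep(1, 61), sense)
  rd_assert(all(sense %in% names(base_dwell)),
            "base_dwell must cover all 61 sense codons")
  base_dwell <- base_dwell[sense]
  rd_assert(all(base_dwell > 0), "base_dwell must be positive")
  base_dwell <- base_dwell / mean(base_dwell)
  if (!is.null(effect_aa)) {
    rd_assert(effect_aa %in% standard_aas(), "unknown amino acid: ", effect_aa)
    rd_assert(!is.null(effect_offset) && effect_offset >= 20 && effect_offset <= 45,
              "effect_offset must lie in [20, 45] codons upstream of the P site")
    if (is.null(effect_codons)) {
      effect_codons <- sense[.codon_aa() == effect_aa]
    }
    rd_assert(all(effect_codons %in% sense), "effect_codons must be sense codons")
  }
  rd_assert(effect_factor > 0, "effect_factor must be positive")
  rd_assert(dispersion >= 0, "dispersion must be >= 0")
  structure(list(base_dwell = base_dwell, effect_aa = effect_aa,
                 effect_offset = if (is.null(effect_aa)) NULL else as.integer(effect_offset),
                 effect_codons = effect_codons, effect_factor = effect_factor,
                 dispersion = dispersion, depth = depth),
            class = "dwell_model")
}

#' Random codon-specific base dwell times (log-normal, mean 1)
#' @param seed seed
#' @param sdlog log-sd of codon dwell variation
#' @return named vector over the 61 sense codons with mean 1
#' @export
random_base_dwell <- function(seed, sdlog = 0.25) {
  set.seed(child_seed(seed, "base_dwell"))
  d <- stats::rlnorm(61, 0, sdlog)
  stats::setNames(d / mean(d), sense_codons())
}

# flat representation of a transcript set: one entry per codon position
.flatten_tx <- function(tx) {
  sense <- sense_codons()
  per <- lapply(seq_len(nrow(tx)), function(i) {
    cods <- .tx_codons(tx, i)
    prot <- strsplit(tx$protein[i], "")[[1]]
    list(codon = cods, prot = prot)
  })
  n <- tx$n_codons
  list(
    tx_idx    = rep(seq_len(nrow(tx)), n),
    pos       = unlist(lapply(n, seq_len), use.names = FALSE),     # 1-based codon
    codon     = unlist(lapply(per, `[[`, "codon"), use.names = FALSE),
    codon_id  = unlist(lapply(per, function(p) match(p$codon, sense)),
                       use.names = FALSE),                          # NA for stop
    prot      = lapply(per, `[[`, "prot")
  )
}

#' Positions receiving a planted dwell effect
#'
#' The generator's internal (amino acid, offset, codon) predicate, exposed so
#' it can be cross-checked against a brute-force scan.
#'
#' @param tx a [transcript_set()]
#' @param model a [dwell_model()] with a planted effect
#' @return named list: per transcript, a logical vector over codon positions
#' @export
planted_effect_mask <- function(tx, model) {
  out <- lapply(seq_len(nrow(tx)), function(i) {
    n <- tx$n_codons[i]
    if (is.null(model$effect_aa)) return(logical(n))
    cods <- .tx_codons(tx, i)
    prot <- strsplit(tx$protein[i], "")[[1]]
    pos <- seq_len(n)
    up <- pos - model$effect_offset
    cond <- up >= 1 & up <= length(prot)
    cond[cond] <- prot[up[cond]] == model$effect_aa
    cond & cods %in% model$effect_codons
  })
  stats::setNames(out, tx$transcript_id)
}

#' Simulate codon-resolved footprint coverage for all RPF samples
#'
#' Counts at codon i of transcript t are NB with mean
#' `depth_scaled * abundance_t * dwell(codon_i) * effect * init_boost(i)`,
#' where `effect` is `effect_factor` at positions satisfying the model's
#' planted predicate (see [planted_effect_mask()]) and 1 elsewhere, and
#' `init_boost` multiplies the start codon only. The depth scaling is computed
#' from the shared base model (no effect), so a planted effect changes the
#' mean at qualifying positions by exactly `effect_factor`.
#'
#' @param tx a [transcript_set()]
#' @param design a [design_table()]; one coverage object per RPF sample
#' @param wt_model,ko_model [dwell_model()]s sharing `base_dwell`; only
#'   `ko_model` may carry a planted effect
#' @param seed master seed
#' @param init_boost multiplier on the start-codon density (initiation peak;
#'   needed for start-codon metagene P-site calibration to be identifiable)
#' @param abundances optional named per-transcript abundances; default drawn
#'   log-normal(0, 1) from a child seed
#' @return named list of `codon_coverage` objects over RPF samples, with the
#'   abundances attached as attribute `"abundances"`
#' @export
simulate_footprints <- function(tx, design, wt_model, ko_model, seed,
                                init_boost = 5, abundances = NULL) {
  rd_assert(isTRUE(all.equal(wt_model$base_dwell, ko_model$base_dwell)),
            "wt_model and ko_model must share base_dwell")
  rd_assert(is.null(wt_model$effect_aa),
            "the WT model must not carry a planted effect")
  if (is.null(abundances)) {
    set.seed(child_seed(seed, "abundances"))
    abundances <- stats::setNames(stats::rlnorm(nrow(tx), 0, 1), tx$transcript_id)
  }
  rd_assert(all(abundances > 0), "abundances must be positive")
  fl <- .flatten_tx(tx)
  dwell <- wt_model$base_dwell[fl$codon_id]          # NA at stop codons
  dwell[is.na(dwell)] <- 1                           # terminating ribosomes
  boost <- ifelse(fl$pos == 1L, init_boost, 1)
  base_mean <- abundances[tx$transcript_id][fl$tx_idx] * dwell * boost
  scale_base <- sum(base_mean)
  mask <- unlist(planted_effect_mask(tx, ko_model), use.names = FALSE)
  eff <- ifelse(mask, ko_model$effect_factor, 1)

  rpf <- design[design$assay == "RPF", , drop = FALSE]
  rd_assert(nrow(rpf) > 0, "design contains no RPF samples")
  tx_f <- factor(fl$tx_idx, levels = seq_len(nrow(tx)))
  out <- lapply(seq_len(nrow(rpf)), function(k) {
    s <- rpf$sample_id[k]
    model <- if (rpf$genotype[k] == "KO") ko_model else wt_model
    mu <- model$depth / scale_base * base_mean *
      (if (rpf$genotype[k] == "KO") eff else 1)
    set.seed(child_seed(seed, paste0("footprints:", s)))
    cnt <- if (model$dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / model$dispersion)
    } else stats::rpois(length(mu), mu)
    counts <- split(cnt, tx_f)
    names(counts) <- tx$transcript_id
    new_codon_coverage(lapply(counts, as.integer), sample_id = s)
  })
  names(out) <- rpf$sample_id
  attr(out, "abundances") <- abundances
  out
}

#' Turn codon coverage into footprint read records
#'
#' Each codon-count unit becomes one read whose 5' end is
#' `codon_start - offset_map[length]`, with the read length drawn from
#' `lengths` and, with probability `frame_noise`, the 5' end jittered by a
#' uniformly chosen shift in `{-1, 0, +1}` nt (so the off-frame fraction is
#' `2/3 * frame_noise`).
#'
#' @param tx a [transcript_set()]
#' @param coverage a `codon_coverage` object or a named list of them
#' @param offset_map named integer vector, read length -> P-site offset (nt);
#'   must cover every emitted length
#' @param lengths read lengths to emit
#' @param length_probs sampling probabilities for `lengths` (default uniform)
#' @param frame_noise probability of frame jitter
#' @param seed master seed
#' @return data frame `transcript_id, pos5p, length, count` (0-based `pos5p`
#'   on the full transcript), or a named list of such tables; reads falling
#'   off the transcript are dropped and tallied in attribute `"dropped"`
#' @export
simulate_reads <- function(tx, coverage, offset_map = default_offset_map(),
                           lengths = 28:32, length_probs = NULL,
                           frame_noise = 0, seed = 1) {
  if (!inherits(coverage, "codon_coverage")) {
    out <- lapply(coverage, simulate_reads, tx = tx, offset_map = offset_map,
                  lengths = lengths, length_probs = length_probs,
                  frame_noise = frame_noise, seed = seed)
    return(out)
  }
  rd_assert(all(as.character(lengths) %in% names(offset_map)),
            "offset_map must define an offset for every emitted length")
  sid <- attr(coverage, "sample_id")
  set.seed(child_seed(seed, paste0("reads:", sid)))
  idx <- match(names(coverage), tx$transcript_id)
  rd_assert(!anyNA(idx), "coverage names not in transcript set")
  cnt <- unlist(coverage, use.names = FALSE)
  tx_i <- rep(rep(idx, tx$n_codons[idx]), cnt)
  cod_i <- rep(unlist(lapply(tx$n_codons[idx], seq_len), use.names = FALSE), cnt)
  n <- length(tx_i)
  len <- sample(rep(lengths, 2), n, replace = TRUE,
                prob = rep(if (is.null(length_probs)) rep(1, length(lengths))
                           else length_probs, 2))
  delta <- integer(n)
  jit <- stats::runif(n) < frame_noise
  delta[jit] <- sample(c(-1L, 0L, 1L), sum(jit), replace = TRUE)
  pos5p <- tx$cds_start[tx_i] + 3L * (cod_i - 1L) -
    unname(offset_map[as.character(len)]) + delta
  tx_len <- nchar(tx$utr5) + nchar(tx$cds) + nchar(tx$utr3)
  keep <- pos5p >= 0L & pos5p + len <= tx_len[tx_i]
  dt <- data.table::data.table(transcript_id = tx$transcript_id[tx_i[keep]],
                               pos5p = pos5p[keep], length = len[keep])
  agg <- dt[, .N, by = c("transcript_id", "pos5p", "length")]
  data.table::setnames(agg, "N", "count")
  data.table::setorder(agg, transcript_id, pos5p, length)
  out <- as.data.frame(agg)
  attr(out, "sample_id") <- sid
  attr(out, "dropped") <- c(off_transcript = sum(!keep))
  out
}

#' Default read-length to P-site-offset map (28-32 nt)
#' @return named integer vector
#' @export
default_offset_map <- function() {
  c(`28` = 12L, `29` = 12L, `30` = 13L, `31` = 13L, `32` = 14L)
}

#' Simulate gene-level RNA-seq and RPF count tables for the TE stage
#'
#' RNA counts are NB with genotype-independent means proportional to
#' `abundances`; RPF means are additionally multiplied by `2^te_log2fc` in KO
#' samples only, so a planted `te_log2fc` is exactly the genotype:assay
#' interaction on the log2 scale.
#'
#' @param tx a [transcript_set()] (genes = transcripts)
#' @param design a [design_table()] (both assays)
#' @param abundances named positive vector per gene; default log-normal(0, 1)
#' @param te_log2fc named vector of planted TE log2 fold changes (default 0)
#' @param depth expected reads per sample
#' @param dispersion NB dispersion alpha
#' @param seed master seed
#' @return integer matrix genes x samples (column order = design order)
#' @export
simulate_rnaseq <- function(tx, design, abundances = NULL, te_log2fc = NULL,
                            depth = 1e5, dispersion = 0.1, seed = 1) {
  genes <- tx$transcript_id
  if (is.null(abundances)) {
    set.seed(child_seed(seed, "rna_abundances"))
    abundances <- stats::setNames(stats::rlnorm(length(genes), 0, 1), genes)
  }
  rd_assert(all(abundances >= 0) && !any(abundances < 0), "negative abundance")
  rd_assert(all(abundances > 0), "abundances must be positive")
  rd_assert(depth >= 0, "depth must be >= 0")
  lfc <- stats::setNames(rep(0, length(genes)), genes)
  if (!is.null(te_log2fc)) lfc[names(te_log2fc)] <- te_log2fc
  base <- depth * abundances[genes] / sum(abundances[genes])
  counts <- sapply(seq_len(nrow(design)), function(k) {
    mu <- base
    if (design$assay[k] == "RPF" && design$genotype[k] == "KO") {
      mu <- mu * 2^lfc
    }
    set.seed(child_seed(seed, paste0("rnaseq:", design$sample_id[k])))
    if (dispersion > 0) stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    else stats::rpois(length(mu), mu)
  })
  dimnames(counts) <- list(genes, design$sample_id)
  counts
}

#' Simulate an A254-like polysome fractionation trace
#'
#' The trace is `baseline + sum of Gaussians + N(0, noise_sd)`; each peak's
#' analytic area is `height * width * sqrt(2*pi)`.
#'
#' @param peak_positions,peak_heights,peak_widths Gaussian parameters
#' @param baseline constant baseline
#' @param n_points grid points
#' @param noise_sd additive Gaussian noise SD
#' @param xlim position range (default spans all peaks +/- 4 widths)
#' @param seed seed (only used when `noise_sd > 0`)
#' @return object of class `polysome_trace` (data frame `position,
#'   absorbance`) with attribute `"peak_auc"`
#' @export
simulate_polysome_trace <- function(peak_positions, peak_heights, peak_widths,
                                    baseline = 0, n_points = 1000,
                                    noise_sd = 0, xlim = NULL, seed = 1) {
  rd_assert(length(peak_positions) == length(peak_heights) &&
            length(peak_positions) == length(peak_widths),
            "peak parameter vectors must have equal length")
  rd_assert(all(peak_widths > 0), "peak widths must be positive")
  if (is.null(xlim)) {
    # +/- 6 widths keeps the truncated Gaussian mass below 2e-9 of each peak
    xlim <- range(peak_positions) + c(-6, 6) * max(peak_widths)
  }
  x <- seq(xlim[1], xlim[2], length.out = n_points)
  y <- rep(baseline, n_points)
  for (j in seq_along(peak_positions)) {
    y <- y + peak_heights[j] * exp(-(x - peak_positions[j])^2 / (2 * peak_widths[j]^2))
  }
  if (noise_sd > 0) {
    set.seed(child_seed(seed, "polysome_noise"))
    y <- y + stats::rnorm(n_points, 0, noise_sd)
  }
  structure(polysome_trace(x, y),
            peak_auc = peak_heights * peak_widths * sqrt(2 * pi))
}

#' Simulate coiled-coil interval annotations with positional bias
#'
#' Target proteins place intervals preferentially in the C-terminal half: the
#' relative start position is Beta(1 + cterm_bias, 1) for targets and uniform
#' for the others (identical at `cterm_bias = 0`).
#'
#' @param n_target,n_other group sizes
#' @param cterm_bias non-negative bias strength (0 = no bias)
#' @param seed seed
#' @param len_range protein length range (aa)
#' @param mean_intervals Poisson mean of extra intervals (every protein draws
#'   `rpois(mean_intervals)` intervals; may be 0)
#' @param interval_len interval length range (aa)
#' @return data frame `protein_id, start, end, length, group` (0-based
#'   half-open intervals, merged per protein), one row per interval plus one
#'   zero-interval marker row (`start = end = NA`) for interval-free proteins
#' @export
gen_domain_sets <- function(n_target, n_other, cterm_bias = 0, seed = 1,
                            len_range = c(200, 800), mean_intervals = 1.5,
                            interval_len = c(20, 60)) {
  rd_assert(cterm_bias >= 0, "cterm_bias must be >= 0")
  set.seed(child_seed(seed, "domains"))
  ids <- c(if (n_target > 0) paste0("target_", seq_len(n_target)),
           if (n_other > 0) paste0("other_", seq_len(n_other)))
  grp <- c(rep("target", n_target), rep("other", n_other))
  rows <- lapply(seq_along(ids), function(i) {
    L <- sample(len_range[1]:len_range[2], 1)
    m <- stats::rpois(1, mean_intervals)
    if (m == 0) {
      return(data.frame(protein_id = ids[i], start = NA_integer_,
                        end = NA_integer_, length = L, group = grp[i]))
    }
    len <- pmin(sample(interval_len[1]:interval_len[2], m, replace = TRUE), L - 1)
    rel <- if (grp[i] == "target") stats::rbeta(m, 1 + cterm_bias, 1)
           else stats::runif(m)
    start <- floor(rel * (L - len))
    iv <- .merge_intervals(start, start + len)
    data.frame(protein_id = ids[i], start = iv$start, end = iv$end,
               length = L, group = grp[i])
  })
  do.call(rbind, rows)
}

# merge overlapping/adjacent 0-based half-open intervals
.merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]; rs <- c(); re <- c()
  for (j in seq_along(start)[-1]) {
    if (start[j] <= me) me <- max(me, end[j])
    else { rs <- c(rs, ms); re <- c(re, me); ms <- start[j]; me <- end[j] }
  }
  list(start = c(rs, ms), end = c(re, me))
}

#' Write footprint reads as FASTQ (optional, for the trim/filter stage)
#'
#' Emits each read record `count` times with the transcript subsequence as the
#' read, an optional 3' poly-A adapter tail, and constant base quality.
#'
#' @param tx a [transcript_set()]
#' @param fp footprint table from [simulate_reads()]
#' @param path output FASTQ
#' @param adapter adapter appended at the 3' end ("" for none)
#' @param qual_char quality character (Phred+33)
#' @return `path`, invisibly
#' @export
footprints_to_fastq <- function(tx, fp, path, adapter = "AAAAAAAAAA",
                                qual_char = "I") {
  full <- stats::setNames(paste0(tx$utr5, tx$cds, tx$utr3), tx$transcript_id)
  idx <- rep(seq_len(nrow(fp)), fp$count)
  seqs <- paste0(substr(full[fp$transcript_id[idx]], fp$pos5p[idx] + 1,
                        fp$pos5p[idx] + fp$length[idx]), adapter)
  ids <- sprintf("read_%06d %s:%d:%d", seq_along(idx), fp$transcript_id[idx],
                 fp$pos5p[idx], fp$length[idx])
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    vapply(nchar(seqs), function(n)
                      strrep(qual_char, n), "")), path)
  invisible(path)
}
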