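# synthio: generators are seeded, match their stated distributions, and the
# planted-effect predicate agrees with a brute-force scan.

test_that("gen_transcriptome enforces CDS structure and rejects short transcripts", {
  tx <- gen_transcriptome(1, 100, seed = 7)
  expect_identical(substr(tx$cds, 1, 3), "ATG")
  expect_true(substr(tx$cds, 298, 300) %in% stop_codons())
  expect_identical(nchar(tx$protein), 99L)
  expect_false(grepl("*", tx$protein, fixed = TRUE))
  expect_error(gen_transcriptome(5, 59, seed = 1), "offset")
})

test_that("gen_transcriptome is seed-deterministic (byte-identical FASTA)", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_transcripts(gen_transcriptome(50, 80, seed = 1), f1)
  write_transcripts(gen_transcriptome(50, 80, seed = 1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(gen_transcriptome(50, 80, seed = 2)$cds,
                         gen_transcriptome(50, 80, seed = 1)$cds))
})

test_that("internal codon usage is uniform over sense codons (binomial 3-SD)", {
  tx <- gen_transcriptome(200, 300, seed = 1)
  internal <- unlist(lapply(seq_len(nrow(tx)), function(i)
    ribodwell:::.tx_codons(tx, i)[2:299]))
  n <- length(internal)
  p <- 1 / 61
  counts <- table(factor(internal, levels = sense_codons()))
  # per-codon 3-SD bound has a ~15% family-wise false-alarm rate over 61
  # codons; use the Bonferroni-corrected normal bound for alpha = 0.01
  bound <- stats::qnorm(1 - 0.01 / (2 * 61)) * sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) <= bound))
})

test_that("FASTA round-trips through write/read_transcripts", {
  tx <- gen_transcriptome(10, 70, seed = 5)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_transcripts(tx, f)
  tx2 <- read_transcripts(f)
  expect_equal(as.data.frame(tx2), as.data.frame(tx))
})

test_that("planted-effect mask equals a brute-force predicate scan", {
  tx <- gen_transcriptome(30, 90, seed = 13)
  model <- dwell_model(effect_aa = "K", effect_offset = 27, effect_factor = 2)
  mask <- planted_effect_mask(tx, model)
  for (i in seq_len(nrow(tx))) {
    cods <- ribodwell:::.tx_codons(tx, i)
    prot <- strsplit(tx$protein[i], "")[[1]]
    brute <- vapply(seq_len(tx$n_codons[i]), function(j) {
      up <- j - 27
      up >= 1 && up <= length(prot) && prot[up] == "K" &&
        cods[j] %in% model$effect_codons
    }, TRUE)
    expect_identical(mask[[i]], brute)
  }
  # positions at or before the offset never receive the effect
  expect_true(all(vapply(mask, function(m) !any(m[1:27]), TRUE)))
})

test_that("dwell_model validates its planted effect", {
  expect_error(dwell_model(effect_aa = "L", effect_offset = 19), "\\[20, 45\\]")
  expect_error(dwell_model(effect_aa = "L", effect_offset = 46), "\\[20, 45\\]")
  expect_error(dwell_model(effect_aa = "B", effect_offset = 30), "amino acid")
  m <- dwell_model(effect_aa = "L", effect_offset = 31)
  expect_setequal(m$effect_codons, c("CTA", "CTC", "CTG", "CTT", "TTA", "TTG"))
  expect_equal(mean(m$base_dwell), 1)
  expect_equal(mean(random_base_dwell(3)), 1)
})

test_that("simulate_footprints: null effect gives exchangeable WT/KO; planted effect scales qualifying means", {
  tx <- gen_transcriptome(60, 120, seed = 21)
  design <- make_design(n_clones = 1, n_reps = 2)
  bd <- random_base_dwell(21)
  wt <- dwell_model(bd, dispersion = 0.1, depth = 3e5)
  ko_null <- dwell_model(bd, dispersion = 0.1, depth = 3e5)
  cov <- simulate_footprints(tx, design, wt, ko_null, seed = 21)
  tot <- vapply(cov, attr, 0, "total_assigned")
  # identical expected depth in every sample
  expect_true(all(abs(tot / 3e5 - 1) < 0.02))

  ko <- dwell_model(bd, effect_aa = "L", effect_offset = 31,
                    effect_factor = 1.5, dispersion = 0.1, depth = 1e6)
  wt2 <- dwell_model(bd, dispersion = 0.1, depth = 1e6)
  mask <- unlist(planted_effect_mask(tx, ko), use.names = FALSE)
  ratios <- vapply(1:3, function(s) {
    cv <- simulate_footprints(tx, design, wt2, ko, seed = 100 + s)
    wt_counts <- unlist(cv[["WT_RPF_1"]], use.names = FALSE)
    ko_counts <- unlist(cv[["KO_1_RPF_1"]], use.names = FALSE)
    sum(ko_counts[mask]) / sum(wt_counts[mask])
  }, 0)
  expect_equal(mean(ratios), 1.5, tolerance = 0.05)
})

test_that("simulated counts match their stated NB means (MC, <2% relative error)", {
  tx <- gen_transcriptome(100, 100, seed = 31)
  design <- make_design(n_clones = 1, n_reps = 2)
  wt <- dwell_model(random_base_dwell(31), dispersion = 0.1, depth = 1e6)
  cov <- simulate_footprints(tx, design, wt, wt, seed = 31,
                             init_boost = 5)
  # reconstruct the stated means independently
  a <- attr(cov, "abundances")
  mu <- unlist(lapply(seq_len(nrow(tx)), function(i) {
    cods <- ribodwell:::.tx_codons(tx, i)
    d <- wt$base_dwell[cods]
    d[is.na(d)] <- 1
    d[1] <- d[1] * 5
    a[tx$transcript_id[i]] * d
  }), use.names = FALSE)
  mu <- 1e6 * mu / sum(mu)
  obs <- rowMeans(sapply(cov, unlist, use.names = FALSE))
  # >= 1e5 draws in aggregate; compare total and high/low-mean strata
  expect_equal(sum(obs) / sum(mu), 1, tolerance = 0.02)
  hi <- mu > stats::median(mu)
  expect_equal(sum(obs[hi]) / sum(mu[hi]), 1, tolerance = 0.02)
  expect_equal(sum(obs[!hi]) / sum(mu[!hi]), 1, tolerance = 0.02)
})

test_that("simulate_reads places 5' ends at codon_start - offset and jitters frames as stated", {
  tx <- gen_transcriptome(10, 80, seed = 41)
  design <- make_design(n_clones = 1, n_reps = 2)
  wt <- dwell_model(depth = 5e4)
  cov <- simulate_footprints(tx, design, wt, wt, seed = 41)[[1]]
  fp <- simulate_reads(tx, cov, offset_map = c(`29` = 12L), lengths = 29,
                       frame_noise = 0, seed = 41)
  cs <- stats::setNames(tx$cds_start, tx$transcript_id)
  expect_true(all((fp$pos5p - (cs[fp$transcript_id] - 12)) %% 3 == 0))
  expect_true(all(fp$length == 29))
  # conservation: every coverage unit becomes exactly one read
  expect_identical(sum(fp$count) + unname(attr(fp, "dropped")["off_transcript"]),
                   as.integer(attr(cov, "total_assigned")))

  # frame_noise f: frame-0 fraction = (1-f) + f/3 (ledgered: 7/9 at f = 1/3)
  fp3 <- simulate_reads(tx, cov, offset_map = c(`29` = 12L), lengths = 29,
                        frame_noise = 1 / 3, seed = 41)
  frame <- (fp3$pos5p + 12 - cs[fp3$transcript_id]) %% 3
  f0 <- sum(fp3$count[frame == 0]) / sum(fp3$count)
  expect_equal(f0, 7 / 9, tolerance = 0.02)
  expect_error(simulate_reads(tx, cov, offset_map = c(`29` = 12L),
                              lengths = c(29, 30), seed = 1),
               "offset")
})

test_that("simulate_rnaseq: RNA means are genotype-independent, planted TE lfc lands on RPF/KO only", {
  tx <- gen_transcriptome(80, 70, seed = 51)
  design <- make_design(n_clones = 1, n_reps = 3)
  lfc <- stats::setNames(rep(0, 80), tx$transcript_id)
  lfc[1:8] <- 1
  counts <- simulate_rnaseq(tx, design, te_log2fc = lfc, depth = 2e5,
                            dispersion = 0.05, seed = 51)
  rna <- counts[, design$sample_id[design$assay == "RNA"]]
  rpf <- counts[, design$sample_id[design$assay == "RPF"]]
  rna_wt <- rowMeans(rna[, design$genotype[design$assay == "RNA"] == "WT"])
  rna_ko <- rowMeans(rna[, design$genotype[design$assay == "RNA"] == "KO"])
  expect_equal(sum(rna_ko) / sum(rna_wt), 1, tolerance = 0.03)
  rpf_wt <- rowMeans(rpf[, design$genotype[design$assay == "RPF"] == "WT"])
  rpf_ko <- rowMeans(rpf[, design$genotype[design$assay == "RPF"] == "KO"])
  expect_equal(mean(log2(rpf_ko[1:8] / rpf_wt[1:8])), 1, tolerance = 0.25)
  expect_equal(mean(log2(rpf_ko[-(1:8)] / rpf_wt[-(1:8)])), 0, tolerance = 0.15)
  expect_error(simulate_rnaseq(tx, design, abundances = stats::setNames(
    rep(-1, 80), tx$transcript_id), seed = 1), "positive|negative")
  # degenerate depth: all-zero table, downstream raises an informative error
  z <- simulate_rnaseq(tx, design, depth = 0, seed = 1)
  expect_true(all(z == 0))
  expect_error(delta_te_test(z[, design$sample_id[design$assay == "RNA"]],
                             z[, design$sample_id[design$assay == "RPF"]],
                             design), "zero")
})

test_that("simulate_polysome_trace matches closed-form Gaussian areas", {
  tr <- simulate_polysome_trace(0, 1, 1, baseline = 0, n_points = 4000)
  expect_equal(ribodwell:::trapz(tr$position, tr$absorbance), sqrt(2 * pi),
               tolerance = 1e-6)
  expect_equal(attr(tr, "peak_auc"), sqrt(2 * pi))
  tr2 <- simulate_polysome_trace(c(3, 9), c(1, 2), c(0.5, 0.5), n_points = 6000)
  r <- auc_ratio(tr2, c(1, 5), c(7, 11), baseline_mode = "none")
  expect_equal(r, 2, tolerance = 1e-4)
  # mild noise changes the AUC ratio by < 5% (MC over seeds)
  rs <- vapply(1:5, function(s) {
    trn <- simulate_polysome_trace(c(3, 9), c(1, 2), c(0.5, 0.5),
                                   n_points = 6000, noise_sd = 0.01, seed = s)
    auc_ratio(trn, c(1, 5), c(7, 11), baseline_mode = "none")
  }, 0)
  expect_true(all(abs(rs / 2 - 1) < 0.05))
})

test_that("gen_domain_sets: unbiased sets give uniform per-bin p, biased sets hit the C-terminus", {
  null_set <- gen_domain_sets(40, 40, cterm_bias = 0, seed = 61)
  tm <- positional_fraction_matrix(null_set[null_set$group == "target", ])
  om <- positional_fraction_matrix(null_set[null_set$group == "other", ])
  mw <- binned_mannwhitney(tm, om)
  expect_lte(mean(mw$p < 0.05), 0.12)
  expect_gt(mean(mw$p), 0.35)

  biased <- gen_domain_sets(40, 40, cterm_bias = 8, seed = 61)
  tb <- positional_fraction_matrix(biased[biased$group == "target", ])
  ob <- positional_fraction_matrix(biased[biased$group == "other", ])
  mwb <- binned_mannwhitney(tb, ob)
  # the two-sided test also flags depletion below the midpoint (the C-ward
  # shift drains the N-half), so the confinement claim applies to bins where
  # targets are enriched
  enriched <- colMeans(tb) > colMeans(ob)
  sig <- mwb[mwb$p < 1e-3 & enriched, ]
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$rel_pos > 0.5))
  expect_gt(mwb$rel_pos[which.min(mwb$p)], 0.5)
  # empty target group refuses downstream
  empty <- gen_domain_sets(0, 10, seed = 1)
  expect_error(binned_mannwhitney(NULL, positional_fraction_matrix(empty)),
               "empty target")
})

test_that("all generators are bit-reproducible given (parameters, seed)", {
  tx <- gen_transcriptome(20, 70, seed = 71)
  design <- make_design(n_clones = 1, n_reps = 2)
  wt <- dwell_model(depth = 1e4)
  expect_identical(simulate_footprints(tx, design, wt, wt, seed = 71),
                   simulate_footprints(tx, design, wt, wt, seed = 71))
  cov <- simulate_footprints(tx, design, wt, wt, seed = 71)[[1]]
  expect_identical(simulate_reads(tx, cov, frame_noise = 0.2, seed = 71),
                   simulate_reads(tx, cov, frame_noise = 0.2, seed = 71))
  expect_identical(simulate_rnaseq(tx, design, seed = 71),
                   simulate_rnaseq(tx, design, seed = 71))
  expect_identical(gen_domain_sets(5, 5, 1, seed = 71),
                   gen_domain_sets(5, 5, 1, seed = 71))
})
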