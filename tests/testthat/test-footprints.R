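# footprints: trimming/filtering rules, P-site calibration, coverage
# assignment and periodicity diagnostics.

mk_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  data.frame(id = paste0("r", seq_along(seqs)), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

test_that("trim_filter_reads applies the length and quality-trimming rules", {
  q30 <- strrep("?", 30)                       # '?' = Q30
  reads <- mk_reads(c(strrep("A", 19), strrep("C", 30), strrep("G", 30)),
                    c(strrep("?", 19), q30,
                      paste0(strrep("?", 26), strrep("$", 4))))  # '$' = Q3
  out <- trim_filter_reads(reads, adapter = "")
  # 19 nt read dropped; trailing Q3 tail is 3'-trimmed, read survives at 26 nt
  expect_identical(out$id, c("r2", "r3"))
  expect_identical(nchar(out$seq), c(30L, 26L))
  d <- attr(out, "dropped")
  expect_identical(as.integer(sum(d)) + nrow(out), nrow(reads))
  expect_identical(unname(d["min_length"]), 1L)
  # a leading low-quality base is not trimmed (3' only): 29/30 = 96.7% kept
  out2 <- trim_filter_reads(mk_reads(strrep("C", 30),
                                     paste0("$", strrep("?", 29))),
                            adapter = "")
  expect_identical(nrow(out2), 1L)
  expect_identical(nchar(out2$seq), 30L)
})

test_that("trim_filter_reads quality fraction boundary is exact", {
  # 27/30 >= Q20 (90%) kept; 26/30 (86.7%) dropped; low-quality bases are
  # internal so 3' quality trimming does not rescue them
  mk <- function(n_bad) {
    q <- rep("?", 30); q[10:(9 + n_bad)] <- "$"
    mk_reads(strrep("A", 30), paste(q, collapse = ""))
  }
  expect_identical(nrow(trim_filter_reads(mk(3), adapter = "")), 1L)
  expect_identical(nrow(trim_filter_reads(mk(4), adapter = "")), 0L)
})

test_that("adapter clipping removes poly-A tails; missing qualities error", {
  reads <- mk_reads(c(paste0(strrep("ACG", 9), "AAAAAAAAAA"),   # full adapter
                      paste0(strrep("ACG", 9), "AAAAA"),        # partial tail
                      strrep("ACG", 10)))                       # no adapter
  out <- trim_filter_reads(reads, quality_filter = FALSE)
  expect_identical(nchar(out$seq), c(27L, 27L, 30L))  # no A-suffix on read 3
  out2 <- trim_filter_reads(reads, quality_filter = FALSE,
                            discard_nonclipped = TRUE)
  expect_identical(attr(out2, "dropped")[["non_clipped"]], 1L)
  expect_error(trim_filter_reads(data.frame(id = "r", seq = "ACGT"),
                                 adapter = ""), "qualit")
  # reads with N discarded
  outN <- trim_filter_reads(mk_reads(c("ACGTNACGTACGTACGTACGTACGT",
                                       strrep("ACGT", 7))), adapter = "")
  expect_identical(attr(outN, "dropped")[["has_n"]], 1L)
})

test_that("FASTQ writer/reader round-trips and feeds trim_filter_reads", {
  tx <- gen_transcriptome(5, 70, seed = 8)
  design <- make_design(n_clones = 1, n_reps = 2)
  cov <- simulate_footprints(tx, design, dwell_model(depth = 500),
                             dwell_model(depth = 500), seed = 8)[[1]]
  fp <- simulate_reads(tx, cov, frame_noise = 0, seed = 8)
  f <- withr::local_tempfile(fileext = ".fastq")
  footprints_to_fastq(tx, fp, f, adapter = "AAAAAAAAAA")
  reads <- read_fastq(f)
  expect_identical(nrow(reads), as.integer(sum(fp$count)))
  trimmed <- trim_filter_reads(reads)
  # clipping recovers footprint lengths 28-32 except reads whose own 3' end
  # is A (absorbed into the suffix match)
  expect_true(all(nchar(trimmed$seq) <= 32))
  expect_gt(mean(nchar(trimmed$seq) >= 28), 0.7)
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f2)
  expect_identical(read_fastq(f2), reads)
})

test_that("infer_psite_offsets recovers offsets exactly (round-trip)", {
  tx <- gen_transcriptome(150, 90, seed = 18)
  design <- make_design(n_clones = 1, n_reps = 2)
  wt <- dwell_model(depth = 3e5)
  cov <- simulate_footprints(tx, design, wt, wt, seed = 18)[[1]]

  fp1 <- simulate_reads(tx, cov, offset_map = c(`29` = 12L), lengths = 29,
                        frame_noise = 0, seed = 18)
  off1 <- infer_psite_offsets(fp1, tx, lengths = 29)
  expect_identical(off1$offset, 12L)
  expect_identical(off1$status, "ok")

  omap <- c(`28` = 12L, `29` = 12L, `30` = 13L)
  for (s in 1:3) {
    fp <- simulate_reads(tx, cov, offset_map = omap, lengths = 28:30,
                         frame_noise = 0.1, seed = 200 + s)
    off <- infer_psite_offsets(fp, tx, lengths = 28:30)
    expect_identical(stats::setNames(off$offset, off$length), omap)
  }
})

test_that("low-support length flagged discarded; no length passing errors", {
  tx <- gen_transcriptome(100, 80, seed = 28)
  design <- make_design(n_clones = 1, n_reps = 2)
  wt <- dwell_model(depth = 2e5)
  cov <- simulate_footprints(tx, design, wt, wt, seed = 28)[[1]]
  fp <- simulate_reads(tx, cov, offset_map = c(`31` = 13L, `30` = 13L),
                       lengths = 30:31, length_probs = c(0.999, 0.001),
                       frame_noise = 0, seed = 28)
  off <- infer_psite_offsets(fp, tx, lengths = 30:31, min_reads = 200)
  expect_identical(off$status[off$length == 31], "discarded:low_support")
  expect_identical(off$status[off$length == 30], "ok")
  expect_error(infer_psite_offsets(fp, tx, lengths = 30:31, min_reads = 1e9),
               "threshold")
})

test_that("codon_coverage anchors P-sites and floors off-frame positions", {
  txm <- transcript_set("t1", paste0("ATG", strrep("GCT", 70), "TAA"))  # no UTR
  fp <- data.frame(transcript_id = "t1", pos5p = 0L, length = 29L, count = 1L)
  cc <- codon_coverage(fp, c(`29` = 12L), txm)
  expect_identical(which(cc$t1 == 1L), 5L)     # codon index 4 (0-based)
  # off-frame P-site at nt 13 -> codon floor(13/3) = 4 as well
  fp2 <- data.frame(transcript_id = "t1", pos5p = 1L, length = 29L, count = 1L)
  cc2 <- codon_coverage(fp2, c(`29` = 12L), txm)
  expect_identical(which(cc2$t1 == 1L), 5L)
  # P-site outside the CDS is dropped and tallied
  fp3 <- data.frame(transcript_id = "t1", pos5p = 215L, length = 29L, count = 2L)
  cc3 <- codon_coverage(fp3, c(`29` = 12L), txm)
  expect_identical(attr(cc3, "total_assigned"), 0)
  expect_identical(unname(attr(cc3, "dropped")["outside_cds"]), 2L)
  expect_error(codon_coverage(data.frame(transcript_id = "nope", pos5p = 0L,
                                         length = 29L, count = 1L),
                              c(`29` = 12L), txm), "unknown transcript")
})

test_that("coverage is order-invariant and round-trips the generator exactly", {
  tx <- gen_transcriptome(40, 80, seed = 38)
  design <- make_design(n_clones = 1, n_reps = 2)
  wt <- dwell_model(depth = 1e5)
  gen_cov <- simulate_footprints(tx, design, wt, wt, seed = 38)[[1]]
  fp <- simulate_reads(tx, gen_cov, frame_noise = 0, seed = 38)
  off <- infer_psite_offsets(fp, tx)
  cc <- codon_coverage(fp, off, tx)
  expect_identical(unname(lapply(cc, identity)), unname(lapply(gen_cov, identity)))
  # conservation and permutation invariance
  expect_equal(attr(cc, "total_assigned") + sum(attr(cc, "dropped")),
               sum(fp$count))
  perm <- fp[sample(nrow(fp)), ]
  cc_perm <- codon_coverage(perm, off, tx)
  expect_identical(unclass(cc_perm), unclass(cc))
  # sparse TSV round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_coverage(list(s1 = cc), f)
  cc_back <- read_coverage(f, tx)$s1
  expect_identical(unname(lapply(cc_back, identity)), unname(lapply(cc, identity)))
})

test_that("periodicity_stats reports frame fractions and the fundamental period", {
  tx <- gen_transcriptome(80, 80, seed = 48)
  design <- make_design(n_clones = 1, n_reps = 2)
  wt <- dwell_model(depth = 2e5)
  cov <- simulate_footprints(tx, design, wt, wt, seed = 48)[[1]]
  fp0 <- simulate_reads(tx, cov, frame_noise = 0, seed = 48)
  off <- infer_psite_offsets(fp0, tx)
  per0 <- periodicity_stats(fp0, off, tx)
  expect_equal(per0$frame_fractions, c(1, 0, 0))
  expect_identical(per0$dominant_period, 3L)
  expect_true(per0$stable)

  per1 <- periodicity_stats(simulate_reads(tx, cov, frame_noise = 0.1,
                                           seed = 49), off, tx)
  expect_identical(per1$dominant_period, 3L)
  expect_gt(per1$frame_fractions[1], 0.9)

  # uniform random positions: fractions ~ 1/3 each, call flagged unstable
  # (offset 0 so P-sites tile the whole CDS without boundary steps)
  set.seed(1)
  n <- 20000
  fpu <- data.frame(transcript_id = sample(tx$transcript_id, n, TRUE),
                    pos5p = sample(18:257, n, TRUE), length = 29L, count = 1L)
  peru <- periodicity_stats(fpu, c(`29` = 0L), tx)
  expect_true(all(abs(peru$frame_fractions - 1 / 3) < 0.02))
  expect_false(peru$stable)
})
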