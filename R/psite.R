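# footprints: P-site offset inference (start-codon metagene mode), P-site
# anchored codon coverage, and 3-nt periodicity diagnostics.
#
# Coordinates are 0-based half-open on the transcript; frame is defined
# relative to the annotated ATG.

#' Write / read a footprint table (`transcript_id  pos5p  length  count`)
#' @param fp footprint data frame
#' @param path TSV path
#' @return `path` (writer) or the footprint data frame (reader)
#' @export
write_footprints <- function(fp, path) {
  write_tsv_prov(fp[, c("transcript_id", "pos5p", "length", "count")], path,
                 params = list(kind = "footprints",
                               sample = attr(fp, "sample_id")))
}

#' @rdname write_footprints
#' @export
read_footprints <- function(path) read_tsv_prov(path)

#' Infer per-read-length P-site offsets by start-codon metagene
#'
#' For each read length, the offset is the mode of
#' `(start-codon position - 5' end)` over reads whose 5' end falls within
#' `window` nt of the annotated start codon. Lengths with fewer than
#' `min_reads` windowed reads, a modal bin holding less than
#' `min_modal_frac` of them, or a mode outside `[0, length - 3]` are flagged
#' discarded rather than assigned.
#'
#' @param fp footprint table (`transcript_id, pos5p, length, count`)
#' @param tx a [transcript_set()]
#' @param lengths read lengths to calibrate
#' @param min_reads minimum windowed reads per length
#' @param window window of 5' ends around the start codon, nt (relative to
#'   the start-codon position)
#' @param min_modal_frac minimum fraction of windowed reads in the modal bin
#' @return object of class `psite_offsets`: data frame `length, offset,
#'   n_reads, modal_frac, status` ("ok" or "discarded:<reason>")
#' @export
infer_psite_offsets <- function(fp, tx, lengths = 28:32, min_reads = 200,
                                window = c(-20, 10), min_modal_frac = 0.30) {
  cds_start <- stats::setNames(tx$cds_start, tx$transcript_id)
  rd_assert(all(fp$transcript_id %in% names(cds_start)),
            "footprints reference unknown transcripts: ",
            paste(unique(setdiff(fp$transcript_id, names(cds_start))), collapse = ", "))
  rel <- fp$pos5p - cds_start[fp$transcript_id]         # 5' end rel. to start
  out <- lapply(lengths, function(L) {
    sel <- fp$length == L & rel >= window[1] & rel <= window[2]
    n <- sum(fp$count[sel])
    if (n < min_reads) {
      return(data.frame(length = L, offset = NA_integer_, n_reads = n,
                        modal_frac = NA_real_, status = "discarded:low_support"))
    }
    dist <- -rel[sel]                                    # start pos - 5' end
    tab <- tapply(fp$count[sel], dist, sum)
    mode_d <- as.integer(names(tab)[which.max(tab)])
    frac <- max(tab) / n
    status <- if (frac < min_modal_frac) "discarded:ambiguous"
              else if (mode_d < 0 || mode_d > L - 3) "discarded:out_of_range"
              else "ok"
    data.frame(length = L, offset = if (status == "ok") mode_d else NA_integer_,
               n_reads = n, modal_frac = frac, status = status)
  })
  res <- do.call(rbind, out)
  if (!any(res$status == "ok")) {
    rd_stop("no read length passed P-site calibration (min_reads = ", min_reads,
            "); lower the support threshold or check the input")
  }
  class(res) <- c("psite_offsets", "data.frame")
  res
}

#' Serialize / load P-site offsets as JSON
#' @param offsets a `psite_offsets` object
#' @param path JSON path
#' @return `path` (writer) or a `psite_offsets` object (reader)
#' @export
write_psite_offsets <- function(offsets, path) {
  jsonlite::write_json(as.data.frame(offsets), path, auto_unbox = FALSE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_psite_offsets
#' @export
read_psite_offsets <- function(path) {
  res <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  class(res) <- c("psite_offsets", "data.frame")
  res
}

#' P-site anchored codon coverage
#'
#' Each read contributes its count to the codon containing
#' `pos5p + offset[length]`; off-frame P-sites are assigned to the containing
#' codon by floor division. Reads of discarded lengths and reads whose P-site
#' falls outside the CDS are dropped and tallied.
#'
#' @param fp footprint table
#' @param offsets a `psite_offsets` object (from [infer_psite_offsets()]) or a
#'   named length -> offset vector
#' @param tx a [transcript_set()]
#' @param sample_id sample label attached to the result
#' @return a `codon_coverage` object; attribute `"dropped"` tallies
#'   `discarded_length` and `outside_cds` reads
#' @export
codon_coverage <- function(fp, offsets, tx, sample_id = attr(fp, "sample_id")) {
  if (inherits(offsets, "psite_offsets") || is.data.frame(offsets)) {
    ok <- offsets$status == "ok"
    omap <- stats::setNames(offsets$offset[ok], offsets$length[ok])
  } else {
    omap <- offsets
  }
  unknown <- setdiff(unique(fp$transcript_id), tx$transcript_id)
  if (length(unknown)) {
    rd_stop("unknown transcript ids in footprints: ",
            paste(unknown, collapse = ", "))
  }
  known_len <- fp$length %in% as.integer(names(omap))
  dropped <- c(discarded_length = sum(fp$count[!known_len]))
  fp <- fp[known_len, , drop = FALSE]
  ti <- match(fp$transcript_id, tx$transcript_id)
  psite <- fp$pos5p + unname(omap[as.character(fp$length)])
  cod <- (psite - tx$cds_start[ti]) %/% 3L             # 0-based codon index
  inside <- cod >= 0L & cod < tx$n_codons[ti]
  dropped["outside_cds"] <- sum(fp$count[!inside])
  base <- c(0L, cumsum(tx$n_codons))                   # flat codon indexing
  flat <- base[ti] + cod + 1L
  all_counts <- numeric(base[length(base)])
  if (any(inside)) {
    tb <- rowsum(fp$count[inside], flat[inside])
    all_counts[as.integer(rownames(tb))] <- tb
  }
  counts <- lapply(stats::setNames(seq_len(nrow(tx)), tx$transcript_id),
                   function(i) as.integer(all_counts[(base[i] + 1L):base[i + 1L]]))
  new_codon_coverage(counts, sample_id = sample_id, dropped = dropped)
}

#' Frame fractions and dominant period of P-site positions
#'
#' Computes the fraction of P-sites in each frame (relative to the annotated
#' ATG) and the lag (over `lags`) maximizing the autocorrelation of the
#' nucleotide-resolution metagene P-site profile. The period call is flagged
#' unstable when the maximal autocorrelation is below `stability_min`.
#'
#' @param fp footprint table
#' @param offsets `psite_offsets` or named length -> offset vector
#' @param tx a [transcript_set()]
#' @param lags autocorrelation lags to scan
#' @param stability_min minimum autocorrelation for a stable period call
#' @return list with `frame_fractions` (length 3), `dominant_period`,
#'   `autocorr` (named by lag) and `stable`
#' @export
periodicity_stats <- function(fp, offsets, tx, lags = 2:6, stability_min = 0.1) {
  if (inherits(offsets, "psite_offsets") || is.data.frame(offsets)) {
    ok <- offsets$status == "ok"
    omap <- stats::setNames(offsets$offset[ok], offsets$length[ok])
  } else {
    omap <- offsets
  }
  fp <- fp[fp$length %in% as.integer(names(omap)), , drop = FALSE]
  ti <- match(fp$transcript_id, tx$transcript_id)
  rd_assert(!anyNA(ti), "unknown transcript ids in footprints")
  rel <- fp$pos5p + unname(omap[as.character(fp$length)]) - tx$cds_start[ti]
  inside <- rel >= 0L & rel < 3L * tx$n_codons[ti]
  rel <- rel[inside]; w <- fp$count[inside]
  rd_assert(length(rel) > 0, "no P-sites inside any CDS")
  frame <- rel %% 3L
  frame_fractions <- vapply(0:2, function(f) sum(w[frame == f]), 0) / sum(w)
  prof_len <- min(3L * tx$n_codons)
  keep <- rel < prof_len
  prof <- numeric(prof_len)
  tb <- rowsum(w[keep], rel[keep])
  prof[as.integer(rownames(tb)) + 1L] <- tb
  ac <- vapply(lags, function(l) {
    stats::cor(prof[1:(prof_len - l)], prof[(1 + l):prof_len])
  }, 0)
  names(ac) <- lags
  # a periodic profile has high autocorrelation at the fundamental lag and at
  # its multiples; report the smallest lag within 90% of the maximum so the
  # fundamental wins over its harmonics
  m <- max(ac, na.rm = TRUE)
  dom <- if (is.finite(m) && m > 0) min(lags[!is.na(ac) & ac >= 0.9 * m])
         else lags[which.max(ac)]
  # noise floor: autocorrelation of an aperiodic profile has SD ~ 1/sqrt(len)
  thr <- max(stability_min, 3 / sqrt(prof_len))
  list(frame_fractions = frame_fractions,
       dominant_period = dom,
       autocorr = ac,
       stable = is.finite(m) && m >= thr)
}
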