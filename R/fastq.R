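# FASTQ handling and the read trimming/filtering rules applied to raw
# footprint libraries: 3' poly-A adapter clipping, 3' quality trimming,
# minimum length 20 nt and >= 90% of bases at Q >= 20.

#' Read a FASTQ file into a data frame
#' @param path FASTQ path (uncompressed)
#' @return data frame `id, seq, qual`
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
  data.frame(id = sub(" .*", "", names(x)),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read data frame as FASTQ
#' @param reads data frame `id, seq, qual`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), path)
  invisible(path)
}

.phred <- function(qual) lapply(qual, function(s) utf8ToInt(s) - 33L)

#' Trim and filter footprint reads
#'
#' Applies, in order: (1) 3' adapter clipping as longest-suffix match of the
#' read against a prefix of `adapter` (full internal adapter occurrences are
#' clipped at their first position), optionally discarding non-clipped reads
#' and reads containing N; (2) 3' quality trimming: trailing bases with
#' quality below `min_quality` are removed; (3) filters: minimum length and a
#' minimum fraction of bases at or above `min_quality`.
#'
#' @param reads data frame `id, seq, qual` (as from [read_fastq()]), or a
#'   FASTQ path. `qual` may be absent only if `quality_filter = FALSE`.
#' @param min_length minimum surviving read length (nt)
#' @param min_quality Phred threshold
#' @param min_quality_fraction minimum fraction of bases `>= min_quality`
#' @param adapter 3' adapter to clip ("" disables clipping)
#' @param discard_nonclipped drop reads without any adapter match
#' @param discard_n drop reads containing N
#' @param quality_filter apply quality trimming/filtering (requires `qual`)
#' @return surviving reads data frame; attribute `"dropped"` tallies reads
#'   removed by each rule
#' @export
trim_filter_reads <- function(reads, min_length = 20, min_quality = 20,
                              min_quality_fraction = 0.90,
                              adapter = "AAAAAAAAAA",
                              discard_nonclipped = FALSE, discard_n = TRUE,
                              quality_filter = TRUE) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  if (quality_filter && is.null(reads$qual)) {
    rd_stop("quality filtering requested but reads carry no per-base qualities")
  }
  dropped <- c(has_n = 0L, non_clipped = 0L, min_length = 0L, quality_fraction = 0L)
  n_in <- nrow(reads)

  if (discard_n) {
    bad <- grepl("N", reads$seq, fixed = TRUE)
    dropped["has_n"] <- sum(bad)
    reads <- reads[!bad, , drop = FALSE]
  }
  if (nzchar(adapter)) {
    cut <- .adapter_cut(reads$seq, adapter)
    if (discard_nonclipped) {
      bad <- is.na(cut)
      dropped["non_clipped"] <- sum(bad)
      reads <- reads[!bad, , drop = FALSE]
      cut <- cut[!bad]
    }
    clip <- !is.na(cut)
    reads$seq[clip] <- substr(reads$seq[clip], 1, cut[clip])
    if (!is.null(reads$qual)) {
      reads$qual[clip] <- substr(reads$qual[clip], 1, cut[clip])
    }
  }
  if (quality_filter && nrow(reads)) {
    q <- .phred(reads$qual)
    keep_len <- vapply(q, function(v) {
      n <- length(v)
      while (n > 0 && v[n] < min_quality) n <- n - 1L
      n
    }, 0L)
    reads$seq <- substr(reads$seq, 1, keep_len)
    reads$qual <- substr(reads$qual, 1, keep_len)
  }
  long_enough <- nchar(reads$seq) >= min_length
  dropped["min_length"] <- sum(!long_enough)
  reads <- reads[long_enough, , drop = FALSE]
  if (quality_filter && nrow(reads)) {
    q <- .phred(reads$qual)
    frac <- vapply(q, function(v) mean(v >= min_quality), 0)
    ok <- frac >= min_quality_fraction
    dropped["quality_fraction"] <- sum(!ok)
    reads <- reads[ok, , drop = FALSE]
  }
  stopifnot(nrow(reads) + sum(dropped) == n_in)   # conservation
  attr(reads, "dropped") <- dropped
  rownames(reads) <- NULL
  reads
}

# 3' cut position per read: keep bases 1..cut. NA = no adapter found.
# Longest suffix of the read equal to a prefix of the adapter; a full adapter
# occurring internally clips at its first occurrence.
.adapter_cut <- function(seqs, adapter) {
  alen <- nchar(adapter)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- regexpr(adapter, s, fixed = TRUE)[1]
    if (hit > 0) return(hit - 1L)
    for (k in seq(min(alen - 1L, n), 1L)) {
      if (substr(s, n - k + 1L, n) == substr(adapter, 1L, k)) return(n - k)
    }
    NA_integer_
  }, 0L, USE.NAMES = FALSE)
}
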