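# CodonCoverage: per-sample transcript x codon-position count vectors.

new_codon_coverage <- function(counts, sample_id = NA_character_,
                               dropped = integer(0)) {
  rd_assert(is.list(counts) && !is.null(names(counts)),
            "coverage counts must be a named list")
  structure(counts, class = "codon_coverage", sample_id = sample_id,
            total_assigned = sum(vapply(counts, sum, 0)), dropped = dropped)
}

#' @export
print.codon_coverage <- function(x, ...) {
  cat(sprintf("codon_coverage [%s]: %d transcripts, %.0f assigned reads\n",
              attr(x, "sample_id"), length(x), attr(x, "total_assigned")))
  invisible(x)
}

#' Write per-sample codon coverage as sparse TSV
#'
#' Columns `sample  transcript_id  codon_index  count` (0-based codon index,
#' zero rows omitted).
#'
#' @param coverages named list of `codon_coverage` objects (or a single one)
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_coverage <- function(coverages, path) {
  if (inherits(coverages, "codon_coverage")) {
    coverages <- stats::setNames(list(coverages), attr(coverages, "sample_id"))
  }
  rows <- lapply(names(coverages), function(s) {
    cov <- coverages[[s]]
    do.call(rbind, lapply(names(cov), function(tx) {
      v <- cov[[tx]]
      nz <- which(v > 0)
      if (!length(nz)) return(NULL)
      data.frame(sample = s, transcript_id = tx, codon_index = nz - 1L,
                 count = v[nz], stringsAsFactors = FALSE)
    }))
  })
  write_tsv_prov(do.call(rbind, rows), path, params = list(kind = "coverage"))
}

#' Read sparse codon-coverage TSV written by [write_coverage()]
#' @param path TSV path
#' @param tx the [transcript_set()] defining codon-vector lengths
#' @return named list of `codon_coverage` objects
#' @export
read_coverage <- function(path, tx) {
  df <- read_tsv_prov(path)
  ncod <- stats::setNames(tx$n_codons, tx$transcript_id)
  lapply(split(df, df$sample), function(d) {
    counts <- lapply(stats::setNames(tx$transcript_id, tx$transcript_id),
                     function(id) {
      v <- integer(ncod[[id]])
      sel <- d$transcript_id == id
      v[d$codon_index[sel] + 1L] <- d$count[sel]
      v
    })
    new_codon_coverage(counts, sample_id = d$sample[1])
  })
}
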