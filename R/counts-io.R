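# gene x sample count-matrix TSV i/o (first column `gene`).

#' Write / read a gene x sample count matrix as TSV
#' @param counts matrix with gene rownames and sample colnames
#' @param path TSV path
#' @return `path` (writer) or a matrix (reader)
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write_tsv_prov(df, path, params = list(kind = "counts"))
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read_tsv_prov(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
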