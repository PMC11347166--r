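# Pairwise protein comparison helpers used for the RPL39/RPL39L worked
# example: substitution listing and lysine+arginine content. The bundled
# FASTA (inst/extdata/rpl39_mouse_protein.fasta) carries the two mouse
# paralog sequences.

#' List substitutions between two aligned protein sequences
#'
#' Sequences must have equal length (the two paralogs are end-to-end
#' alignable without gaps).
#'
#' @param a,b protein sequences (single strings)
#' @return data frame `position, from, to` (1-based), one row per difference;
#'   substitutions print as e.g. "S2A"
#' @export
protein_substitutions <- function(a, b) {
  rd_assert(nchar(a) == nchar(b), "sequences differ in length")
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  d <- which(va != vb)
  out <- data.frame(position = d, from = va[d], to = vb[d],
                    stringsAsFactors = FALSE)
  out$label <- paste0(out$from, out$position, out$to)
  out
}

#' Lysine + arginine content of a protein sequence
#' @param seq protein sequence (single string)
#' @return fraction of residues that are K or R
#' @export
kr_content <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  mean(v %in% c("K", "R"))
}

#' Load the bundled mouse RPL39/RPL39L protein sequences
#' @return named character vector `RPL39`, `RPL39L`
#' @export
rpl39_sequences <- function() {
  path <- system.file("extdata", "rpl39_mouse_protein.fasta",
                      package = "ribodwell")
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), sub(" .*", "", names(aa)))
}
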