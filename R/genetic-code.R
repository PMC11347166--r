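# Codon / amino-acid constants shared across modules.
# Codon tables come from Biostrings::GENETIC_CODE (standard code); only the
# orderings are fixed here so that grids and vectors serialize reproducibly.

.genetic_code <- function() Biostrings::GENETIC_CODE

#' Sense codons (61), alphabetical
#' @return character vector of the 61 non-stop codons
#' @export
sense_codons <- function() {
  gc <- .genetic_code()
  sort(names(gc)[gc != "*"])
}

#' Stop codons
#' @return character vector of the 3 stop codons
#' @export
stop_codons <- function() {
  gc <- .genetic_code()
  sort(names(gc)[gc == "*"])
}

#' Standard amino acids (20), alphabetical one-letter codes
#' @return character vector
#' @export
standard_aas <- function() {
  sort(unique(unname(.genetic_code()[.genetic_code() != "*"])))
}

# codon -> amino acid for sense codons, in sense_codons() order
.codon_aa <- function() {
  gc <- .genetic_code()
  unname(gc[sense_codons()])
}
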