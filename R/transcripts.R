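# TranscriptSet: CDS sequences with codon and amino-acid projections, plus
# short UTRs so that footprint 5' ends near the start codon stay on-transcript.

#' Construct a transcript set
#'
#' A transcript is a 5'UTR, a CDS (starts with ATG, ends with a stop codon, no
#' internal stop) and a 3'UTR. The protein sequence is derived from the CDS and
#' has length `n_codons - 1` (the stop codon is not translated).
#'
#' @param transcript_id character vector of unique ids
#' @param cds character vector of CDS sequences (length divisible by 3)
#' @param utr5,utr3 character vectors of UTR sequences (may be empty strings)
#' @return object of class `transcript_set`: a data frame with columns
#'   `transcript_id`, `utr5`, `cds`, `utr3`, `protein`, `cds_start` (0-based
#'   offset of the CDS on the full transcript) and `n_codons`
#' @export
transcript_set <- function(transcript_id, cds, utr5 = "", utr3 = "") {
  rd_assert(!anyDuplicated(transcript_id), "duplicate transcript ids")
  utr5 <- rep_len(utr5, length(cds))
  utr3 <- rep_len(utr3, length(cds))
  rd_assert(all(nchar(cds) %% 3 == 0), "CDS length must be divisible by 3")
  rd_assert(all(substr(cds, 1, 3) == "ATG"), "every CDS must start with ATG")
  aa_full <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cds), no.init.codon = TRUE))
  n_cod <- nchar(cds) / 3
  rd_assert(all(substr(aa_full, n_cod, n_cod) == "*"),
            "every CDS must end with a stop codon")
  protein <- substr(aa_full, 1, n_cod - 1)
  rd_assert(!any(grepl("\\*", protein)), "internal stop codon in CDS")
  out <- data.frame(transcript_id = as.character(transcript_id),
                    utr5 = utr5, cds = cds, utr3 = utr3,
                    protein = protein,
                    cds_start = nchar(utr5), n_codons = n_cod,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts, %d-%d codons\n",
              nrow(x), min(x$n_codons), max(x$n_codons)))
  invisible(x)
}

# codon strings of transcript row i, length n_codons
.tx_codons <- function(tx, i) {
  substring(tx$cds[i], seq(1, nchar(tx$cds[i]), 3), seq(3, nchar(tx$cds[i]), 3))
}

#' Generate a random transcriptome
#'
#' Internal codons are drawn uniformly over the 61 sense codons; the first
#' codon is forced to ATG and the last to a random stop codon. UTR lengths
#' default to values that keep all simulated 28-32 nt footprints (P-site
#' offsets up to 14 nt) on-transcript.
#'
#' @param n_tx number of transcripts
#' @param n_codons codons per transcript (including start and stop); must be
#'   at least 60 so that conditioning offsets up to 45 plus the trimming
#'   margins fit on the transcript
#' @param seed master seed
#' @param utr5_len,utr3_len UTR lengths in nt
#' @return a [transcript_set()]
#' @export
gen_transcriptome <- function(n_tx, n_codons, seed, utr5_len = 18, utr3_len = 21) {
  rd_assert(n_codons >= 60,
            "n_codons must be >= 60: the conditional dwell-time grid scans ",
            "offsets up to 45 codons and trims 20+10 codons at the CDS ends")
  rd_assert(n_tx >= 1, "n_tx must be positive")
  set.seed(child_seed(seed, "transcriptome"))
  sense <- sense_codons()
  stops <- stop_codons()
  ids <- sprintf("tx_%0*d", nchar(as.character(n_tx)), seq_len(n_tx))
  internal <- matrix(sample(sense, (n_codons - 2) * n_tx, replace = TRUE),
                     nrow = n_tx)
  cds <- paste0("ATG", apply(internal, 1, paste0, collapse = ""),
                sample(stops, n_tx, replace = TRUE))
  rand_nt <- function(len) {
    if (len == 0) return(rep("", n_tx))
    apply(matrix(sample(c("A", "C", "G", "T"), len * n_tx, replace = TRUE),
                 nrow = n_tx), 1, paste0, collapse = "")
  }
  transcript_set(ids, cds, utr5 = rand_nt(utr5_len), utr3 = rand_nt(utr3_len))
}

#' Write transcripts as FASTA
#'
#' Full transcript sequences (UTR5+CDS+UTR3); the header carries `cds_start`
#' and `cds_len` so that [read_transcripts()] can reconstruct the set.
#'
#' @param tx a [transcript_set()]
#' @param path output FASTA path
#' @return `path`, invisibly
#' @export
write_transcripts <- function(tx, path) {
  seqs <- Biostrings::DNAStringSet(paste0(tx$utr5, tx$cds, tx$utr3))
  names(seqs) <- sprintf("%s cds_start=%d cds_len=%d", tx$transcript_id,
                         tx$cds_start, tx$n_codons * 3L)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read transcripts from a FASTA written by [write_transcripts()]
#' @param path FASTA path
#' @return a [transcript_set()]
#' @export
read_transcripts <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)
  id <- sub(" .*", "", hdr)
  cs <- as.integer(sub(".*cds_start=(\\d+).*", "\\1", hdr))
  cl <- as.integer(sub(".*cds_len=(\\d+).*", "\\1", hdr))
  full <- as.character(seqs)
  transcript_set(id,
                 cds  = substr(full, cs + 1, cs + cl),
                 utr5 = substr(full, 1, cs),
                 utr3 = substr(full, cs + cl + 1, nchar(full)))
}
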