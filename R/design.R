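# DesignTable: sample -> (genotype, clone, replicate, assay).

#' Construct a sample design table
#'
#' @param sample_id unique sample ids
#' @param genotype "WT" or "KO"
#' @param clone_id clone label; must be non-empty for KO samples
#' @param replicate integer replicate index within (clone, assay)
#' @param assay "RPF" (ribosome footprints) or "RNA"
#' @param require_replicates if TRUE (default), require >= 2 replicates per
#'   (clone, assay) group, the precondition of all test stages
#' @return object of class `design_table` (a data frame)
#' @export
design_table <- function(sample_id, genotype, clone_id, replicate, assay,
                         require_replicates = TRUE) {
  rd_assert(!anyDuplicated(sample_id), "duplicate sample ids")
  rd_assert(all(genotype %in% c("WT", "KO")), "genotype must be WT or KO")
  rd_assert(all(assay %in% c("RPF", "RNA")), "assay must be RPF or RNA")
  clone_id <- as.character(clone_id)
  rd_assert(all(nzchar(clone_id[genotype == "KO"])),
            "KO samples must carry a non-empty clone_id")
  clone_id[genotype == "WT" & !nzchar(clone_id)] <- "WT"
  out <- data.frame(sample_id = as.character(sample_id), genotype = genotype,
                    clone_id = clone_id, replicate = as.integer(replicate),
                    assay = assay, stringsAsFactors = FALSE)
  if (require_replicates) {
    n <- stats::aggregate(out$sample_id, by = list(out$clone_id, out$assay), length)$x
    rd_assert(all(n >= 2), "each (clone, assay) group needs >= 2 replicates")
  }
  class(out) <- c("design_table", "data.frame")
  out
}

#' Standard multi-clone ribo-seq design (WT + k KO clones, n replicates each)
#'
#' Defaults mirror a 4-KO-clone, 3-replicate experiment with matched RPF and
#' RNA libraries.
#'
#' @param n_clones number of KO clones
#' @param n_reps replicates per clone (and for WT)
#' @param assays assays to include
#' @return a [design_table()]
#' @export
make_design <- function(n_clones = 4, n_reps = 3, assays = c("RPF", "RNA")) {
  clones <- c("WT", paste0("KO_", seq_len(n_clones)))
  grid <- expand.grid(replicate = seq_len(n_reps), clone_id = clones,
                      assay = assays, stringsAsFactors = FALSE)
  design_table(sample_id = paste(grid$clone_id, grid$assay, grid$replicate, sep = "_"),
               genotype = ifelse(grid$clone_id == "WT", "WT", "KO"),
               clone_id = grid$clone_id, replicate = grid$replicate,
               assay = grid$assay)
}

#' Write / read a design table as TSV
#' @param design a [design_table()]
#' @param path TSV path
#' @return `path` (writer) or a [design_table()] (reader)
#' @export
write_design <- function(design, path) {
  write_tsv_prov(as.data.frame(design), path, params = list(kind = "design"))
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- read_tsv_prov(path)
  design_table(df$sample_id, df$genotype, df$clone_id, df$replicate, df$assay,
               require_replicates = FALSE)
}
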