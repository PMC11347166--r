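#' ribodwell: dwell-time, translation-efficiency and RP-paralog analyses
#'
#' See the methods vignette (`vignette("ribodwell-methods")`) for the models,
#' estimators and design choices behind each analysis stage.
#'
#' @name ribodwell-package
#' @keywords internal
"_PACKAGE"

# data.table is used via :: only; declare awareness for correct dispatch
.datatable.aware <- TRUE

# ---- error handling ----------------------------------------------------------
# User-input problems signal condition class "rd_user_error" so the CLI can map
# them to exit code 1 (internal faults exit 2).

rd_stop <- function(..., class = "rd_user_error", call. = FALSE) {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

rd_assert <- function(cond, ...) {
  if (!isTRUE(cond)) rd_stop(...)
  invisible(TRUE)
}

# ---- seed management ---------------------------------------------------------
# One master seed; per-stage child seeds derived by hashing the stage label
# (32-bit FNV-1a) and combining with the master seed in a Lehmer step modulo
# the Mersenne prime 2^31-1. Deterministic across platforms, always < 2^31.

.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  h
}

#' Derive a per-stage child seed from a master seed
#'
#' @param seed master seed (integer)
#' @param stage character label of the stage (e.g. `"footprints:KO_1_r2"`)
#' @return an integer in `[1, 2^31-2]`
#' @export
child_seed <- function(seed, stage) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  h <- .fnv1a(as.character(stage)) %% m
  x <- (s * 48271 + h * 16807 + 1) %% m
  as.integer(if (x == 0) 1 else x)
}

# short deterministic hash of an R object (used for provenance headers)
.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", .fnv1a(as.character(s)))
}

# ---- numerics ----------------------------------------------------------------

#' Trapezoidal integral
#' @param x strictly increasing abscissae
#' @param y ordinates
#' @return numeric scalar
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# ---- provenance-stamped TSV i/o ---------------------------------------------
# All writers emit one '#'-prefixed header line with package version, a hash of
# the generating parameters and the seed; readers skip '#' lines. Headers carry
# no timestamps so reruns are byte-identical.

prov_header <- function(params = list(), seed = NULL) {
  paste0("# ribodwell ", as.character(utils::packageVersion("ribodwell")),
         "; params=", .config_hash(params),
         if (!is.null(seed)) paste0("; seed=", seed) else "")
}

#' Write a data frame as provenance-stamped TSV
#' @param df data frame
#' @param path output file
#' @param params parameter list folded into the provenance hash
#' @param seed seed recorded in the header (optional)
#' @return `path`, invisibly
#' @export
write_tsv_prov <- function(df, path, params = list(), seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(prov_header(params, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a provenance-stamped TSV
#' @param path input file
#' @return data frame
#' @export
read_tsv_prov <- function(path) {
  rd_assert(file.exists(path), "file not found: ", path)
  head_lines <- readLines(path, n = 100L)
  nskip <- sum(cumprod(startsWith(head_lines, "#")))
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE, skip = nskip,
                                  data.table = FALSE, showProgress = FALSE))
}
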