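# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code under a local RNG seed without disturbing the global stream
#' @noRd
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_if_not_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# cell keys are (sample_id, barcode); barcodes collide across samples
cell_key <- function(sample_id, barcode) paste(sample_id, barcode, sep = "\r")

#' Write a result table as deterministic TSV
#'
#' Writes any tabular result as a tab-separated UTF-8 file with a header row.
#' Floating-point columns are rendered with 6 significant digits so that
#' re-writing the same result yields a byte-identical file. Row order is
#' preserved as given (each producer documents its sort key).
#'
#' @param rows A data frame (zero rows allowed; the header is still written).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  if (is.null(rows)) stop("`rows` must be non-null", call. = FALSE)
  rows <- as.data.frame(rows)
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(
    paste(names(out), collapse = "\t"),
    if (nrow(out)) do.call(paste, c(lapply(out, as.character), sep = "\t"))
  )
  writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

# Standard codon table. The generator back-translates amino acids with the
# first codon listed per residue; forward translation is the inverse lookup.
.codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# first codon per amino acid, in table order (deterministic back-translation)
.aa_to_codon <- .codon_table[!duplicated(.codon_table)]
.aa_to_codon <- setNames(names(.aa_to_codon), .aa_to_codon)

#' Translate nucleotide CDR3 sequences with the standard codon table
#'
#' @param nt Character vector of nucleotide sequences (length divisible by 3).
#' @return Character vector of amino-acid sequences; codons containing
#'   characters outside ACGT translate to `"X"`.
#' @export
translate_cdr3 <- function(nt) {
  vapply(nt, function(s) {
    if (is.na(s)) return(NA_character_)
    s <- toupper(s)
    n <- nchar(s)
    if (n %% 3L != 0L)
      stop("nucleotide length not divisible by 3: ", s, call. = FALSE)
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- .codon_table[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Back-translate amino-acid CDR3 sequences to nucleotides
#'
#' Uses the first codon per residue in the standard table, so the mapping is
#' deterministic and `translate_cdr3(backtranslate_cdr3(aa)) == aa`.
#'
#' @param aa Character vector of amino-acid sequences.
#' @return Character vector of nucleotide sequences.
#' @export
backtranslate_cdr3 <- function(aa) {
  vapply(aa, function(s) {
    if (is.na(s)) return(NA_character_)
    res <- .aa_to_codon[strsplit(s, "")[[1]]]
    if (anyNA(res)) stop("cannot back-translate residue in: ", s, call. = FALSE)
    paste(res, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
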