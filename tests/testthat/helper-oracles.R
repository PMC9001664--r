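# Independent oracles and small fixture builders used across tests.

# O(n^2) pairwise-difference Gini, straight from the definition
gini_bruteforce <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# pure-R dynamic-programming OSA Damerau-Levenshtein oracle
osa_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    cost <- if (A[i] == B[j]) 0L else 1L
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
    if (i > 1 && j > 1 && A[i] == B[j - 1] && A[i - 1] == B[j])
      d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
  }
  d[n + 1, m + 1]
}

# two-sided Fisher exact p by full hypergeometric enumeration over the
# support, probabilities from choose() directly
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # col 1 total
  support <- max(0L, k - n2):min(k, m)
  pr <- choose(m, support) * choose(n2, k - support) / choose(m + n2, k)
  p_obs <- pr[match(a, support)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

random_aa_string <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# minimal contig data frame in the normalized layout
make_contigs <- function(barcode, chain, cdr3_aa = NA, cdr3_nt = NA,
                         productive = TRUE, umis = 5L, contig_id = NULL,
                         v_gene = "TRBV1-1", j_gene = "TRBJ1-1",
                         high_confidence = TRUE) {
  n <- length(barcode)
  data.frame(
    barcode = barcode,
    contig_id = contig_id %||% sprintf("ctg%03d", seq_len(n)),
    chain = rep_len(chain, n),
    v_gene = rep_len(v_gene, n), d_gene = rep_len(NA_character_, n),
    j_gene = rep_len(j_gene, n), c_gene = rep_len(NA_character_, n),
    cdr3_aa = rep_len(as.character(cdr3_aa), n),
    cdr3_nt = rep_len(as.character(cdr3_nt), n),
    productive = rep_len(productive, n),
    high_confidence = rep_len(high_confidence, n),
    umis = rep_len(as.integer(umis), n), reads = rep_len(50L, n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# paired-chain cells with given per-clone alpha/beta nucleotide CDR3s
make_paired_contigs <- function(a_nt, b_nt, n_cells_per_clone) {
  rows <- list()
  cell <- 0L
  for (i in seq_along(a_nt)) for (j in seq_len(n_cells_per_clone[i])) {
    cell <- cell + 1L
    bc <- sprintf("bc%04d", cell)
    rows[[length(rows) + 1L]] <- rbind(
      make_contigs(bc, "TRA", cdr3_aa = translate_cdr3(a_nt[i]),
                   cdr3_nt = a_nt[i], contig_id = paste0(bc, "_a")),
      make_contigs(bc, "TRB", cdr3_aa = translate_cdr3(b_nt[i]),
                   cdr3_nt = b_nt[i], contig_id = paste0(bc, "_b"))
    )
  }
  do.call(rbind, rows)
}

# clonotype table straight from a clone list (beta-only scheme keys)
make_beta_table <- function(b_nt, sizes, sample_id = "s1",
                            subject_id = "sub1") {
  aa <- translate_cdr3(b_nt)
  ctg <- make_contigs(
    barcode = rep(sprintf("bc%04d", seq_len(sum(sizes))), each = 1),
    chain = "TRB",
    cdr3_aa = rep(aa, sizes), cdr3_nt = rep(b_nt, sizes),
    contig_id = sprintf("c%04d", seq_len(sum(sizes))))
  call_clonotypes(build_cell_chains(ctg), "beta_nt_only",
                  sample_id = sample_id, subject_id = subject_id)
}

# deterministic nucleotide CDR3 inventory: distinct, translatable
nt_pool <- function(n, len_codons = 5L) {
  # one codon per distinct residue so nt-level identity matches aa-level
  # distinctness in fixtures
  codons <- c("TGT", "GCC", "AGC", "GGA", "ACA", "TAC", "GAG", "CAG", "CTG")
  combos <- expand.grid(rep(list(codons), len_codons),
                        stringsAsFactors = FALSE)
  out <- do.call(paste0, combos)
  stopifnot(n <= length(out))
  out[seq_len(n)]
}
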