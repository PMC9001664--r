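# Per-cell chain assembly, chain-detection statistics, clonotype calling
# and expanded-clone detection.

#' Group productive contigs into per-cell chain sets
#'
#' Keeps productive TRA/TRB contigs with at least one UMI (and, by default,
#' the high-confidence flag set where the column exists), and groups them by
#' barcode. Within each cell and locus, contigs are sorted by UMI count
#' descending with ties broken by `contig_id`, so the first contig per locus
#' is the representative chain used for clonotyping.
#'
#' @param contigs A contig data frame ([read_contig_table()]).
#' @param require_high_confidence Drop contigs with `high_confidence = FALSE`.
#'   Whether low-confidence contigs were part of published repertoires is
#'   rarely stated; the default excludes them.
#' @return A list of class `cell_chains` with elements:
#'   `contigs` — the retained contigs with `rank_in_cell` (1 = representative)
#'   per (barcode, chain); `cells` — one row per chain-bearing barcode with
#'   `n_tra`, `n_trb` and the representative CDR3/V/J fields per locus;
#'   `n_multi_tra`, `n_multi_trb` — counts of multi-chain cells.
#' @export
build_cell_chains <- function(contigs, require_high_confidence = TRUE) {
  ctg <- as.data.frame(as_contig_records(contigs))
  keep <- ctg$chain %in% c("TRA", "TRB") &
    !is.na(ctg$productive) & ctg$productive &
    ctg$umis >= 1L
  if (require_high_confidence && "high_confidence" %in% names(ctg))
    keep <- keep & !is.na(ctg$high_confidence) & ctg$high_confidence
  ctg <- ctg[keep, , drop = FALSE]

  if (nrow(ctg)) {
    ord <- order(ctg$barcode, ctg$chain, -ctg$umis, ctg$contig_id,
                 method = "radix")
    ctg <- ctg[ord, , drop = FALSE]
    grp <- paste(ctg$barcode, ctg$chain)
    ctg$rank_in_cell <- stats::ave(seq_len(nrow(ctg)), grp,
                                   FUN = seq_along)
  } else {
    ctg$rank_in_cell <- integer(0)
  }
  rownames(ctg) <- NULL

  rep1 <- ctg[ctg$rank_in_cell == 1L, , drop = FALSE]
  barcodes <- sort(unique(ctg$barcode))
  n_tra <- table(factor(ctg$barcode[ctg$chain == "TRA"], levels = barcodes))
  n_trb <- table(factor(ctg$barcode[ctg$chain == "TRB"], levels = barcodes))
  cells <- data.frame(barcode = barcodes,
                      n_tra = as.integer(n_tra),
                      n_trb = as.integer(n_trb),
                      stringsAsFactors = FALSE)
  for (locus in c("TRA", "TRB")) {
    r <- rep1[rep1$chain == locus, , drop = FALSE]
    idx <- match(cells$barcode, r$barcode)
    pre <- if (locus == "TRA") "tra" else "trb"
    cells[[paste0(pre, "_cdr3_aa")]] <- r$cdr3_aa[idx]
    cells[[paste0(pre, "_cdr3_nt")]] <- r$cdr3_nt[idx]
    cells[[paste0(pre, "_v")]] <- r$v_gene[idx]
    cells[[paste0(pre, "_j")]] <- r$j_gene[idx]
    cells[[paste0(pre, "_umis")]] <- r$umis[idx]
  }

  structure(list(contigs = ctg, cells = cells,
                 n_multi_tra = sum(cells$n_tra > 1L),
                 n_multi_trb = sum(cells$n_trb > 1L)),
            class = "cell_chains")
}

#' @export
print.cell_chains <- function(x, ...) {
  cat(sprintf(
    "cell_chains: %d cell(s); %d multi-alpha, %d multi-beta\n",
    nrow(x$cells), x$n_multi_tra, x$n_multi_trb))
  invisible(x)
}

#' Per-sample chain-detection fractions
#'
#' Computes, against the total number of sequenced cells, the fractions of
#' cells with at least one productive alpha chain, at least one productive
#' beta chain, exactly one of each, and a full alpha/beta pair. These are the
#' standard QC fractions for single-cell V(D)J libraries (typical published
#' medians: ~61% for alpha, ~95% for beta).
#'
#' @param cells A `cell_chains` object.
#' @param n_total_cells Total sequenced cells in the sample (the denominator;
#'   must be at least the number of chain-bearing cells).
#' @return A one-row data frame with `f_ge1_alpha`, `f_ge1_beta`,
#'   `f_exactly1_alpha`, `f_exactly1_beta`, `f_paired`, `n_cells`.
#' @export
chain_detection_summary <- function(cells, n_total_cells) {
  n_total_cells <- stop_if_not_scalar_count(n_total_cells, "n_total_cells", 1L)
  cc <- cells$cells
  if (n_total_cells < nrow(cc))
    stop("n_total_cells (", n_total_cells, ") smaller than number of ",
         "chain-bearing cells (", nrow(cc), ")", call. = FALSE)
  data.frame(
    f_ge1_alpha = sum(cc$n_tra >= 1L) / n_total_cells,
    f_ge1_beta = sum(cc$n_trb >= 1L) / n_total_cells,
    f_exactly1_alpha = sum(cc$n_tra == 1L) / n_total_cells,
    f_exactly1_beta = sum(cc$n_trb == 1L) / n_total_cells,
    f_paired = sum(cc$n_tra >= 1L & cc$n_trb >= 1L) / n_total_cells,
    n_cells = n_total_cells
  )
}

.key_schemes <- c("nt_paired", "aa_paired", "nt_paired_vj", "beta_nt_only")

#' Call clonotypes from per-cell chains
#'
#' Assigns each cell at most one clonotype key. Under the paired schemes a
#' cell must carry both a productive alpha and beta chain; the representative
#' chain per locus is the highest-UMI contig. Cells lacking a required chain
#' are unkeyed and excluded from the frequency denominator. The default
#' scheme, `nt_paired`, keys on the paired alpha+beta nucleotide CDR3 — the
#' strictest reading of "identical TCR alpha and beta chains".
#'
#' @param cells A `cell_chains` object.
#' @param key_scheme One of `"nt_paired"`, `"aa_paired"`, `"nt_paired_vj"`
#'   (adds V/J gene names of both chains), `"beta_nt_only"`.
#' @param sample_id Optional sample label stored on the result.
#' @param subject_id Optional subject label stored on the result (used by
#'   [match_clones()] to refuse cross-subject comparisons).
#' @return A `clonotype_table`: list with `clones` (key, component CDR3/gene
#'   fields, `size`, `frequency`; sorted by size descending, key ascending),
#'   `cell_assignments` (barcode to key), `n_keyed_cells`, `key_scheme`,
#'   `sample_id`, `subject_id`.
#' @export
call_clonotypes <- function(cells, key_scheme = "nt_paired",
                            sample_id = NA_character_,
                            subject_id = NA_character_) {
  if (!key_scheme %in% .key_schemes)
    stop("unknown key_scheme: ", key_scheme, "; valid schemes: ",
         paste(.key_schemes, collapse = ", "), call. = FALSE)
  cc <- cells$cells

  keyed <- switch(key_scheme,
    nt_paired = ,
    aa_paired = ,
    nt_paired_vj = !is.na(cc$tra_cdr3_nt) & !is.na(cc$trb_cdr3_nt),
    beta_nt_only = !is.na(cc$trb_cdr3_nt)
  )
  cc <- cc[keyed, , drop = FALSE]
  key <- switch(key_scheme,
    nt_paired = paste(cc$tra_cdr3_nt, cc$trb_cdr3_nt, sep = "|"),
    aa_paired = paste(cc$tra_cdr3_aa, cc$trb_cdr3_aa, sep = "|"),
    nt_paired_vj = paste(cc$tra_cdr3_nt, cc$trb_cdr3_nt,
                         cc$tra_v, cc$tra_j, cc$trb_v, cc$trb_j, sep = "|"),
    beta_nt_only = cc$trb_cdr3_nt
  )

  n_keyed <- nrow(cc)
  if (n_keyed) {
    first <- !duplicated(key)
    clones <- data.frame(
      key = key[first],
      tra_cdr3_nt = cc$tra_cdr3_nt[first],
      tra_cdr3_aa = cc$tra_cdr3_aa[first],
      trb_cdr3_nt = cc$trb_cdr3_nt[first],
      trb_cdr3_aa = cc$trb_cdr3_aa[first],
      tra_v = cc$tra_v[first], tra_j = cc$tra_j[first],
      trb_v = cc$trb_v[first], trb_j = cc$trb_j[first],
      stringsAsFactors = FALSE
    )
    sz <- table(key)
    clones$size <- as.integer(sz[clones$key])
    clones$frequency <- clones$size / n_keyed
    clones <- clones[order(-clones$size, clones$key, method = "radix"), ,
                     drop = FALSE]
    rownames(clones) <- NULL
  } else {
    clones <- data.frame(key = character(0), tra_cdr3_nt = character(0),
                         tra_cdr3_aa = character(0), trb_cdr3_nt = character(0),
                         trb_cdr3_aa = character(0), tra_v = character(0),
                         tra_j = character(0), trb_v = character(0),
                         trb_j = character(0), size = integer(0),
                         frequency = numeric(0), stringsAsFactors = FALSE)
  }

  structure(list(clones = clones,
                 cell_assignments = data.frame(barcode = cc$barcode, key = key,
                                               stringsAsFactors = FALSE),
                 n_keyed_cells = n_keyed,
                 key_scheme = key_scheme,
                 sample_id = sample_id,
                 subject_id = subject_id),
            class = "clonotype_table")
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf("clonotype_table [%s]%s: %d clonotype(s) over %d keyed cell(s)\n",
              x$key_scheme,
              if (is.na(x$sample_id)) "" else paste0(" ", x$sample_id),
              nrow(x$clones), x$n_keyed_cells))
  if (nrow(x$clones)) {
    top <- head(x$clones[, c("key", "size", "frequency")], 5L)
    top$key <- ifelse(nchar(top$key) > 40, paste0(substr(top$key, 1, 37), "..."),
                      top$key)
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' Expanded clones: clonotypes with at least `min_cells` member cells
#'
#' The operational definition of an expanded clone in clonality studies of
#' T cell malignancies is a clonotype carried by at least 10 cells.
#'
#' @param table A `clonotype_table`.
#' @param min_cells Minimum clone size (default 10).
#' @return Character vector of expanded clonotype keys (possibly empty),
#'   in the table's order.
#' @export
call_expanded <- function(table, min_cells = 10L) {
  min_cells <- stop_if_not_scalar_count(min_cells, "min_cells", 2L)
  table$clones$key[table$clones$size >= min_cells]
}

#' Cumulative frequency of the k largest clones
#'
#' @param table A `clonotype_table` with at least one clone.
#' @param k Number of top clones to sum (default 3, the conventional
#'   "top-3 fraction" of clonality reports).
#' @return The summed frequency of the `k` largest clones (ties broken by
#'   key order), a proportion in (0, 1].
#' @export
top_k_fraction <- function(table, k = 3L) {
  k <- stop_if_not_scalar_count(k, "k", 1L)
  cl <- table$clones
  if (nrow(cl) == 0L) stop("empty clonotype table", call. = FALSE)
  # clones are already sorted by size desc, key asc
  sum(cl$frequency[seq_len(min(k, nrow(cl)))])
}
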