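# GLIPH-style CDR3 convergence groups: pooling top beta CDR3s, resampling
# k-mer enrichment against a reference repertoire, graph construction from
# shared motifs and near-identity, and the CMVpp65 motif Fisher test.

# drop the conserved flanks (first 3 / last 2 residues) before k-mer work;
# motifs there reflect germline C...F framing, not antigen contact
trim_cdr3 <- function(x) {
  n <- nchar(x)
  ifelse(n > 5L, substr(x, 4L, n - 2L), "")
}

#' Pool the top beta-chain CDR3s across samples
#'
#' Takes the union of each sample's `n` largest beta CDR3 amino-acid
#' sequences by cell count (ties broken by sequence order) and tabulates
#' per-sample cell counts for every pooled sequence. Published convergence
#' analyses typically pool the top 500 combined beta CDR3s.
#'
#' @param tables List of `clonotype_table`s.
#' @param n Top sequences per sample (default 500).
#' @return Data frame with `cdr3_aa`, `total_cells`, and one count column per
#'   sample id, sorted by `total_cells` descending then sequence.
#' @export
pool_top_cdr3 <- function(tables, n = 500L) {
  n <- stop_if_not_scalar_count(n, "n", 1L)
  if (inherits(tables, "clonotype_table")) tables <- list(tables)
  ids <- vapply(tables, function(t) t$sample_id, character(1))
  if (anyNA(ids)) ids <- paste0("sample_", seq_along(tables))

  # per-sample cell counts per beta CDR3 aa
  per_sample <- lapply(tables, function(tb) {
    cl <- tb$clones[!is.na(tb$clones$trb_cdr3_aa), , drop = FALSE]
    agg <- tapply(cl$size, cl$trb_cdr3_aa, sum)
    data.frame(cdr3_aa = names(agg), cells = as.integer(agg),
               stringsAsFactors = FALSE)
  })
  pooled_seqs <- unique(unlist(lapply(per_sample, function(d) {
    d <- d[order(-d$cells, d$cdr3_aa, method = "radix"), , drop = FALSE]
    head(d$cdr3_aa, n)
  }), use.names = FALSE))
  if (!length(pooled_seqs))
    return(data.frame(cdr3_aa = character(0), total_cells = integer(0)))

  out <- data.frame(cdr3_aa = pooled_seqs, stringsAsFactors = FALSE)
  for (i in seq_along(per_sample)) {
    idx <- match(out$cdr3_aa, per_sample[[i]]$cdr3_aa)
    cnt <- per_sample[[i]]$cells[idx]
    cnt[is.na(cnt)] <- 0L
    out[[ids[i]]] <- cnt
  }
  out$total_cells <- as.integer(rowSums(out[, ids, drop = FALSE]))
  out <- out[c("cdr3_aa", "total_cells", ids)]
  out <- out[order(-out$total_cells, out$cdr3_aa, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a motif-free reference CDR3 repertoire
#'
#' Draws CDR3 amino-acid sequences from the same model the simulator uses
#' ("C" + i.i.d. interior + "F", Gaussian length) with no planted motifs.
#' Serves as the naive background for k-mer enrichment when no user reference
#' file is supplied; this is a synthetic stand-in, not a curated naive
#' repertoire.
#'
#' @param n Number of sequences.
#' @param seed RNG seed.
#' @param length_mean,length_sd,length_range CDR3 length model (residues).
#' @return Character vector of CDR3 amino-acid sequences.
#' @export
make_reference_repertoire <- function(n = 10000L, seed = 20260101L,
                                      length_mean = 14, length_sd = 1.5,
                                      length_range = c(8L, 22L)) {
  with_local_seed(seed, {
    len <- pmin(pmax(round(rnorm(n, length_mean, length_sd)),
                     length_range[1]), length_range[2])
    vapply(len, function(L) {
      paste0("C", paste(sample(.aa20, L - 2L, replace = TRUE), collapse = ""),
             "F")
    }, character(1))
  })
}

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.kmers_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Enriched CDR3 k-mers relative to a reference repertoire
#'
#' Extracts contiguous k-mers (k in `k_set`) from flank-trimmed sample CDR3s
#' and reports those whose per-sequence frequency exceeds `fold_min` times
#' the reference frequency and whose resampling tail probability is at most
#' `p_max`. The tail probability counts, over `n_resample` size-matched
#' draws of sequences from the reference (with replacement), how often the
#' draw contains at least as many motif-bearing sequences as observed, with
#' an add-one estimator so p is never zero. Sequences whose trimmed form is
#' shorter than k are skipped for that k.
#'
#' @param cdr3s Character vector of CDR3 amino-acid sequences (distinct
#'   sequences; a pooled table's `cdr3_aa` column).
#' @param reference Character vector of reference CDR3s (untrimmed).
#' @param k_set Motif lengths (default 2:4).
#' @param fold_min Minimum observed/reference frequency ratio (default 10).
#' @param p_max Resampling p-value cutoff (default 0.001).
#' @param n_resample Resampling rounds (default 1000).
#' @param min_obs Minimum number of sample sequences carrying the motif
#'   (default 2): a motif seen in a single sequence cannot link sequences
#'   into a group, and singleton novelties would otherwise dominate the
#'   hit list.
#' @param seed RNG seed for the resampling.
#' @return Data frame of class `motif_hits` with `motif`, `k`,
#'   `observed_count`, `reference_rate`, `fold`, `p_resample`, sorted by
#'   `p_resample` then fold descending then motif; attribute `n_tested` gives
#'   the number of candidate motifs examined before filtering.
#' @export
enriched_kmers <- function(cdr3s, reference, k_set = c(2L, 3L, 4L),
                           fold_min = 10, p_max = 0.001,
                           n_resample = 1000L, min_obs = 2L, seed = 1L) {
  if (!length(reference)) stop("reference repertoire is empty", call. = FALSE)
  cdr3s <- unique(cdr3s)
  samp <- trim_cdr3(cdr3s)
  ref <- trim_cdr3(reference)
  n_samp <- length(samp)
  n_ref <- length(ref)

  res <- list()
  n_tested <- 0L
  for (k in sort(unique(as.integer(k_set)))) {
    usable <- nchar(samp) >= k
    if (sum(!usable))
      message(sprintf("enriched_kmers: %d sequence(s) shorter than k=%d skipped",
                      sum(!usable), k))
    if (!any(usable)) next
    km <- lapply(samp[usable], .kmers_of, k = k)
    counts <- table(unlist(km, use.names = FALSE))
    n_tested <- n_tested + length(counts)
    motifs <- names(counts)
    obs <- as.integer(counts)
    ref_count <- vapply(motifs, function(m)
      sum(grepl(m, ref, fixed = TRUE)), integer(1))
    ref_rate <- ref_count / n_ref
    obs_rate <- obs / n_samp
    fold <- ifelse(ref_rate > 0, obs_rate / ref_rate, Inf)
    cand <- which(fold >= fold_min & obs >= min_obs)
    if (!length(cand)) next

    # null motif counts in size-matched reference draws, shared across motifs
    inc <- vapply(motifs[cand], function(m) grepl(m, ref, fixed = TRUE),
                  logical(n_ref))
    inc <- matrix(as.numeric(inc), nrow = n_ref)
    exceed <- integer(length(cand))
    with_local_seed(seed + k, {
      for (r in seq_len(n_resample)) {
        idx <- sample.int(n_ref, n_samp, replace = TRUE)
        null_counts <- colSums(inc[idx, , drop = FALSE])
        exceed <- exceed + (null_counts >= obs[cand])
      }
    })
    p <- (1 + exceed) / (n_resample + 1)
    res[[as.character(k)]] <- data.frame(
      motif = motifs[cand], k = k, observed_count = obs[cand],
      reference_rate = ref_rate[cand], fold = fold[cand], p_resample = p,
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(motif = character(0), k = integer(0),
               observed_count = integer(0), reference_rate = numeric(0),
               fold = numeric(0), p_resample = numeric(0))
  out <- out[out$p_resample <= p_max, , drop = FALSE]
  out <- out[order(out$p_resample, -out$fold, out$motif, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_tested = n_tested, class = c("motif_hits", "data.frame"))
}

.hamming1_edges <- function(seqs) {
  # equal-length pairs at Hamming distance <= 1
  from <- character(0); to <- character(0)
  for (L in unique(nchar(seqs))) {
    grp <- seqs[nchar(seqs) == L]
    m <- length(grp)
    if (m < 2L) next
    chars <- matrix(unlist(strsplit(grp, "")), nrow = m, byrow = TRUE)
    for (i in seq_len(m - 1L)) {
      mism <- rowSums(chars[(i + 1L):m, , drop = FALSE] !=
                        matrix(chars[i, ], m - i, L, byrow = TRUE))
      hit <- which(mism <= 1L)
      if (length(hit)) {
        from <- c(from, rep(grp[i], length(hit)))
        to <- c(to, grp[i + hit])
      }
    }
  }
  data.frame(from = from, to = to, evidence = rep("hamming1", length(from)),
             stringsAsFactors = FALSE)
}

#' Build convergence groups (TCR specificity groups) from pooled CDR3s
#'
#' Constructs a graph on distinct pooled CDR3s with an edge whenever two
#' sequences share an enriched motif (within the flank-trimmed region) or
#' are of equal length at Hamming distance at most 1. Connected components
#' with more than `min_members` distinct sequences become convergence groups
#' (CRGs), named `CRG_` plus their most abundant member sequence and sorted
#' by total member cells descending.
#'
#' @param pooled Output of [pool_top_cdr3()].
#' @param motifs A `motif_hits` data frame ([enriched_kmers()]).
#' @param min_members Strict lower bound on distinct member sequences
#'   (default 5: components need more than five members, the conventional
#'   reporting cutoff; set `strict = FALSE` to include exactly-five groups).
#' @param strict If `TRUE` (default) require `> min_members` members.
#' @return List of class `crg_set`; each element has `name`, `members`,
#'   `n_members`, `member_cells`, `sample_counts`, `top5_contribution`
#'   and `edges` (with per-edge evidence).
#' @export
build_crgs <- function(pooled, motifs, min_members = 5L, strict = TRUE) {
  if (!nrow(pooled)) return(structure(list(), class = "crg_set"))
  seqs <- pooled$cdr3_aa
  trimmed <- trim_cdr3(seqs)

  edges <- .hamming1_edges(seqs)
  if (nrow(motifs)) {
    for (i in seq_len(nrow(motifs))) {
      hit <- seqs[grepl(motifs$motif[i], trimmed, fixed = TRUE)]
      if (length(hit) >= 2L) {
        pairs <- utils::combn(sort(hit), 2L)
        edges <- rbind(edges, data.frame(
          from = pairs[1L, ], to = pairs[2L, ],
          evidence = paste0("motif:", motifs$motif[i]),
          stringsAsFactors = FALSE))
      }
    }
  }

  # union-find over sequences
  parent <- seq_along(seqs)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(edges)) {
    ef <- match(edges$from, seqs)
    et <- match(edges$to, seqs)
    for (e in seq_len(nrow(edges))) {
      ri <- find(ef[e]); rj <- find(et[e])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_along(seqs), find, integer(1))

  sample_cols <- setdiff(names(pooled), c("cdr3_aa", "total_cells"))
  groups <- list()
  for (cid in unique(comp)) {
    members_idx <- which(comp == cid)
    nm <- length(members_idx)
    big_enough <- if (strict) nm > min_members else nm >= min_members
    if (!big_enough) next
    sub <- pooled[members_idx, , drop = FALSE]
    top <- sub$cdr3_aa[order(-sub$total_cells, sub$cdr3_aa,
                             method = "radix")][1L]
    counts <- if (length(sample_cols))
      colSums(sub[, sample_cols, drop = FALSE]) else numeric(0)
    in_grp <- edges$from %in% sub$cdr3_aa & edges$to %in% sub$cdr3_aa
    groups[[length(groups) + 1L]] <- list(
      name = paste0("CRG_", top),
      members = sort(sub$cdr3_aa),
      n_members = nm,
      member_cells = sum(sub$total_cells),
      sample_counts = counts,
      top5_contribution = .top5_contribution(counts),
      edges = edges[in_grp, , drop = FALSE]
    )
  }
  ord <- order(-vapply(groups, function(g) g$member_cells, numeric(1)),
               vapply(groups, function(g) g$name, character(1)),
               method = "radix")
  structure(groups[ord], class = "crg_set")
}

.top5_contribution <- function(counts) {
  tot <- sum(counts)
  if (!length(counts) || tot == 0) return(NA_real_)
  sum(sort(as.numeric(counts), decreasing = TRUE)[seq_len(min(5L, length(counts)))]) / tot
}

#' @export
print.crg_set <- function(x, ...) {
  cat(sprintf("crg_set: %d convergence group(s)\n", length(x)))
  for (g in head(x, 10L))
    cat(sprintf("  %s: %d sequences, %d cells, top-5 sample contribution %.2f\n",
                g$name, g$n_members, g$member_cells, g$top5_contribution))
  invisible(x)
}

#' Per-sample contribution of a convergence group
#'
#' Proportion of a group's member cells contributed by its five largest
#' contributing samples, optionally restricted to a subset of samples
#' (e.g. pre-treatment visits only).
#'
#' @param group One element of a `crg_set`.
#' @param samples Optional character vector of sample ids to restrict to.
#' @return List with `top5_contribution` and `per_sample` (a sorted data
#'   frame of cell counts and proportions).
#' @export
crg_contribution <- function(group, samples = NULL) {
  counts <- group$sample_counts
  if (!is.null(samples)) counts <- counts[names(counts) %in% samples]
  if (!length(counts) || sum(counts) == 0)
    stop("no member cells in the selected samples", call. = FALSE)
  per <- data.frame(sample_id = names(counts), cells = as.integer(counts),
                    proportion = as.numeric(counts) / sum(counts),
                    stringsAsFactors = FALSE)
  per <- per[order(-per$cells, per$sample_id, method = "radix"), , drop = FALSE]
  rownames(per) <- NULL
  list(top5_contribution = .top5_contribution(counts), per_sample = per)
}

#' Fisher test for motif enrichment in expanded clones of CMV+ subjects
#'
#' Scans clone beta CDR3s (full, untrimmed sequence — the published motif
#' panel includes 2-mers that trimming could remove) for a panel of motifs
#' and tests, with a two-sided Fisher exact test, whether motif-bearing
#' clones are over-represented among expanded clones of CMV-seropositive
#' subjects relative to all other clones. The default panel is the five
#' CMVpp65-associated motifs TGT, ATN, FQ, SSA, QTG.
#'
#' @param clones Data frame with columns `cdr3_aa`, `expanded` (logical) and
#'   `cmv_positive` (logical).
#' @param motifs Character vector of amino-acid motifs.
#' @return List with `table` (2x2: group x motif status), `p_value`,
#'   `odds_ratio`.
#' @export
motif_scan_fisher <- function(clones,
                              motifs = c("TGT", "ATN", "FQ", "SSA", "QTG")) {
  stopifnot(all(c("cdr3_aa", "expanded", "cmv_positive") %in% names(clones)))
  has_motif <- Reduce(`|`, lapply(motifs, function(m)
    grepl(m, clones$cdr3_aa, fixed = TRUE)))
  grp <- clones$expanded & clones$cmv_positive
  tab <- matrix(c(sum(grp & has_motif), sum(grp & !has_motif),
                  sum(!grp & has_motif), sum(!grp & !has_motif)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(group = c("expanded_cmv_pos", "other"),
                                motif = c("motif", "no_motif")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    empty <- c(names(which(rowSums(tab) == 0L)), names(which(colSums(tab) == 0L)))
    stop("degenerate margin: no clones in ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  list(table = tab, p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}
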