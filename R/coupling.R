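# Coupling between clonal structure and a per-cell transcriptome embedding:
# Damerau-Levenshtein CDR3 distances, permutation coherence tests,
# sequence-vs-embedding distance correlation, and kNN batch-mixing entropy.

#' Damerau-Levenshtein distance between CDR3 amino-acid strings
#'
#' The optimal-string-alignment (OSA) variant: substitutions, insertions,
#' deletions and adjacent transpositions each cost 1, and a transposed pair
#' is not edited again. OSA is the common choice for CDR3 dissimilarity;
#' note it can violate the triangle inequality. Vectorized over pairs.
#'
#' @param a,b Character vectors of equal length (or one of length 1,
#'   recycled).
#' @return Integer vector of distances; 0 iff the strings are equal.
#' @export
damerau_levenshtein <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b)) {
    if (length(a) == 1L) a <- rep(a, length(b))
    else if (length(b) == 1L) b <- rep(b, length(a))
    else stop("a and b must have equal length (or length 1)", call. = FALSE)
  }
  osa_distance_cpp(a, b)
}

.embed_matrix <- function(embedding) {
  dims <- grep("^dim_", names(embedding), value = TRUE)
  if (length(dims) < 2L)
    stop("embedding needs >= 2 coordinate columns named dim_1, dim_2, ...",
         call. = FALSE)
  m <- as.matrix(embedding[dims])
  if (!all(is.finite(m))) stop("non-finite embedding coordinates", call. = FALSE)
  keys <- cell_key(embedding$sample_id, embedding$barcode)
  if (anyDuplicated(keys))
    stop("duplicate (sample_id, barcode) keys in embedding", call. = FALSE)
  rownames(m) <- keys
  m
}

.mean_pairwise_dist <- function(m) mean(dist(m))

#' Permutation test of transcriptional coherence of a cell group
#'
#' Tests whether cells in a group (a clonotype or a convergence group) sit
#' closer together in the embedding than random cells do. The observed
#' statistic is the mean pairwise Euclidean distance among the group's
#' cells; the null distribution is the same statistic over `n_perm` random
#' equal-sized cell subsets drawn without replacement from the whole
#' embedding. The one-sided p-value for coherence (observed smaller than
#' null) uses the add-one estimator p = (1 + #\{null <= observed\}) /
#' (n_perm + 1), so it is never zero and is valid under the null.
#'
#' @param embedding Embedding data frame (`barcode`, `sample_id`,
#'   `dim_1..dim_k`, `batch`).
#' @param group_cells Data frame with `sample_id` and `barcode` columns, or a
#'   character vector of keys formed as `paste(sample_id, barcode)` rows of
#'   the embedding; at least 3 cells.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param alternative `"coherent"` (one-sided, default) or `"two.sided"`.
#' @return List with `n_cells`, `observed`, `null_mean`, `null_sd`,
#'   `n_perm`, `p_value`, `seed`.
#' @export
group_coherence <- function(embedding, group_cells, n_perm = 1000L, seed = 1L,
                            alternative = c("coherent", "two.sided")) {
  alternative <- match.arg(alternative)
  m <- .embed_matrix(embedding)
  keys <- if (is.data.frame(group_cells))
    cell_key(group_cells$sample_id, group_cells$barcode) else group_cells
  keys <- unique(keys)
  missing <- setdiff(keys, rownames(m))
  if (length(missing))
    stop("group cell(s) missing from embedding: ",
         paste(gsub("\r", "/", head(missing, 5L)), collapse = ", "),
         call. = FALSE)
  g <- length(keys)
  if (g < 3L) stop("group must contain >= 3 cells", call. = FALSE)

  observed <- .mean_pairwise_dist(m[keys, , drop = FALSE])
  null <- numeric(n_perm)
  with_local_seed(seed, {
    for (i in seq_len(n_perm)) {
      idx <- sample.int(nrow(m), g)
      null[i] <- .mean_pairwise_dist(m[idx, , drop = FALSE])
    }
  })
  p_low <- (1 + sum(null <= observed)) / (n_perm + 1)
  p <- if (alternative == "coherent") p_low else {
    p_high <- (1 + sum(null >= observed)) / (n_perm + 1)
    min(1, 2 * min(p_low, p_high))
  }
  list(n_cells = g, observed = observed, null_mean = mean(null),
       null_sd = sd(null), n_perm = n_perm, p_value = p, seed = seed)
}

#' Correlation between CDR3 dissimilarity and embedding distance
#'
#' On a seeded random sample of cell pairs, correlates the
#' Damerau-Levenshtein distance between the cells' CDR3s with their
#' Euclidean distance in the embedding. A positive correlation indicates
#' that clonally related cells are also transcriptionally similar.
#'
#' @param embedding Embedding data frame.
#' @param cells_with_cdr3 Data frame with `sample_id`, `barcode`, `cdr3_aa`.
#' @param n_pairs Number of random cell pairs (default 50000).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param seed RNG seed.
#' @return List with `estimate`, `p_value`, `n_pairs`, `method`, `seed`.
#' @export
seq_embed_correlation <- function(embedding, cells_with_cdr3,
                                  n_pairs = 50000L,
                                  method = c("spearman", "pearson"),
                                  seed = 1L) {
  method <- match.arg(method)
  m <- .embed_matrix(embedding)
  cc <- cells_with_cdr3[!is.na(cells_with_cdr3$cdr3_aa), , drop = FALSE]
  keys <- cell_key(cc$sample_id, cc$barcode)
  keep <- keys %in% rownames(m)
  cc <- cc[keep, , drop = FALSE]
  keys <- keys[keep]
  if (length(unique(cc$cdr3_aa)) < 2L)
    stop("all CDR3 sequences identical; correlation undefined", call. = FALSE)
  n <- nrow(cc)
  coords <- m[keys, , drop = FALSE]

  with_local_seed(seed, {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n, n_pairs, replace = TRUE)
  })
  ok <- i != j
  i <- i[ok]; j <- j[ok]
  seq_d <- damerau_levenshtein(cc$cdr3_aa[i], cc$cdr3_aa[j])
  emb_d <- sqrt(rowSums((coords[i, , drop = FALSE] -
                           coords[j, , drop = FALSE])^2))
  ct <- suppressWarnings(cor.test(seq_d, emb_d, method = method,
                                  exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n_pairs = length(i), method = method, seed = seed)
}

#' k-nearest-neighbour batch-mixing entropy
#'
#' For each cell, the Shannon entropy of the batch-label composition of its
#' `k_neighbors` nearest Euclidean neighbours, normalized by log of the
#' number of batches so the score lies in \[0, 1\]. Values near 1 indicate
#' well-mixed batches (successful integration); values near 0 indicate
#' batch-segregated neighbourhoods.
#'
#' @param embedding Embedding data frame with a `batch` column and >= 2
#'   batch labels.
#' @param k_neighbors Neighbourhood size (default 30).
#' @return List with `mean_entropy` and `per_cell` (a numeric vector in
#'   embedding row order).
#' @export
mixing_entropy <- function(embedding, k_neighbors = 30L) {
  k_neighbors <- stop_if_not_scalar_count(k_neighbors, "k_neighbors", 1L)
  m <- .embed_matrix(embedding)
  batch <- as.character(embedding$batch)
  n <- nrow(m)
  if (n < k_neighbors + 1L)
    stop("need at least k_neighbors + 1 cells", call. = FALSE)
  levels <- sort(unique(batch))
  if (length(levels) < 2L)
    stop("mixing entropy undefined with a single batch", call. = FALSE)
  logK <- log(length(levels))
  batch_i <- match(batch, levels)

  per_cell <- numeric(n)
  # chunked neighbour search keeps memory bounded on large embeddings
  chunk <- max(1L, floor(2e7 / n))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(rowSums(m[idx, , drop = FALSE]^2), rowSums(m^2), `+`) -
      2 * m[idx, , drop = FALSE] %*% t(m)
    for (r in seq_along(idx)) {
      o <- order(d2[r, ])
      nb <- setdiff(o, idx[r])[seq_len(k_neighbors)]
      tab <- tabulate(batch_i[nb], nbins = length(levels))
      p <- tab[tab > 0] / k_neighbors
      per_cell[idx[r]] <- -sum(p * log(p)) / logK
    }
  }
  list(mean_entropy = mean(per_cell), per_cell = per_cell)
}
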