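# Clonality and diversity statistics: Gini index, Shannon entropy,
# CDR3 spectratype, and log-log CCDF power-law fits of clone sizes.

#' Gini index of clone sizes
#'
#' G = sum_ij |x_i - x_j| / (2 n^2 xbar), computed through the sorted
#' O(n log n) identity. G is 0 for a perfectly even repertoire and tends to 1
#' under extreme clonal dominance; it is invariant to rescaling the sizes.
#'
#' @param sizes Positive clone sizes (need not be sorted).
#' @param small_sample_correction Multiply by n/(n-1) (off by default; most
#'   repertoire reports use the uncorrected index).
#' @return Gini index in \[0, 1).
#' @export
gini_index <- function(sizes, small_sample_correction = FALSE) {
  if (length(sizes) == 0L) stop("empty size vector", call. = FALSE)
  if (any(!is.finite(sizes) | sizes <= 0))
    stop("all sizes must be positive", call. = FALSE)
  x <- sort(as.numeric(sizes))
  n <- length(x)
  g <- (2 * sum(seq_len(n) * x)) / (n * sum(x)) - (n + 1) / n
  if (small_sample_correction && n > 1L) g <- g * n / (n - 1)
  g
}

#' Shannon entropy of the clone-frequency distribution
#'
#' H = -sum p_i log_base(p_i) with p_i = x_i / sum(x). H is 0 for a single
#' clone and log_base(n) for n equally sized clones. Base 2 (bits) is the
#' default; natural log is available since published repertoire entropies do
#' not always state the base (between-group orderings are base-invariant).
#'
#' @param sizes Positive clone sizes.
#' @param base 2 or `exp(1)`.
#' @return Entropy in \[0, log_base(n)\].
#' @export
shannon_entropy <- function(sizes, base = 2) {
  if (length(sizes) == 0L) stop("empty size vector", call. = FALSE)
  if (any(!is.finite(sizes) | sizes <= 0))
    stop("all sizes must be positive", call. = FALSE)
  p <- sizes / sum(sizes)
  -sum(p * log(p)) / log(base)
}

#' CDR3 length spectratype
#'
#' Length histogram of the representative-chain CDR3 amino-acid sequence over
#' cells carrying the locus, normalized to frequencies within each subset.
#'
#' @param cells A `cell_chains` object.
#' @param locus `"TRA"` or `"TRB"`.
#' @param subset_labels Optional per-cell labels (same order as
#'   `cells$cells`), e.g. CD4/CD8; one histogram per label.
#' @return Data frame with `subset`, `length`, `count`, `frequency`, sorted
#'   by subset then length.
#' @export
spectratype <- function(cells, locus = c("TRB", "TRA"), subset_labels = NULL) {
  locus <- match.arg(locus)
  cc <- cells$cells
  col <- if (locus == "TRA") "tra_cdr3_aa" else "trb_cdr3_aa"
  aa <- cc[[col]]
  subset <- if (is.null(subset_labels)) rep("all", nrow(cc)) else {
    if (length(subset_labels) != nrow(cc))
      stop("subset_labels must have one label per cell", call. = FALSE)
    as.character(subset_labels)
  }
  keep <- !is.na(aa)
  if (!any(keep)) {
    warning("no cells carry a productive ", locus, " CDR3", call. = FALSE)
    return(data.frame(subset = character(0), length = integer(0),
                      count = integer(0), frequency = numeric(0)))
  }
  len <- nchar(aa[keep])
  subset <- subset[keep]
  tab <- as.data.frame(table(subset = subset, length = len),
                       stringsAsFactors = FALSE)
  tab$length <- as.integer(tab$length)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  names(tab)[names(tab) == "Freq"] <- "count"
  tot <- tapply(tab$count, tab$subset, sum)
  tab$frequency <- tab$count / as.numeric(tot[tab$subset])
  tab <- tab[order(tab$subset, tab$length), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Log-log complementary CDF of clone sizes
#'
#' For each distinct clone size x, the point (log10 x, log10 P(X >= x)),
#' where P is taken over clones. This is the standard diagnostic for
#' power-law structure: a straight line of slope -gamma indicates
#' P(X >= x) ~ x^-gamma.
#'
#' @param sizes Positive clone sizes.
#' @return Data frame with `size`, `ccdf`, `log10_size`, `log10_ccdf`,
#'   sizes ascending (so `log10_ccdf` is non-increasing).
#' @export
clone_size_ccdf <- function(sizes) {
  if (length(sizes) == 0L) stop("empty size vector", call. = FALSE)
  x <- sort(unique(as.numeric(sizes)))
  n <- length(sizes)
  ccdf <- vapply(x, function(v) sum(sizes >= v) / n, numeric(1))
  data.frame(size = x, ccdf = ccdf,
             log10_size = log10(x), log10_ccdf = log10(ccdf))
}

#' Power-law slope of the clone-size CCDF
#'
#' Ordinary least squares on the log-log CCDF points (the fit drawn through
#' published clone-size plots), restricted to sizes at or above `min_size`.
#' The slope estimates -gamma for P(X >= x) ~ x^-gamma.
#'
#' @param sizes Positive clone sizes.
#' @param min_size Smallest clone size entering the fit.
#' @return List with `slope` (expected negative) and `r2`.
#' @export
powerlaw_slope <- function(sizes, min_size = 1L) {
  pts <- clone_size_ccdf(sizes)
  pts <- pts[pts$size >= min_size, , drop = FALSE]
  if (nrow(pts) < 3L)
    stop("need >= 3 distinct clone sizes >= min_size (have ", nrow(pts),
         "); lower min_size or skip this sample", call. = FALSE)
  fit <- lm(log10_ccdf ~ log10_size, data = pts)
  # collinear inputs are a legitimate case here; summary.lm warns on them
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(coef(fit)[2L]), r2 = r2)
}

#' Per-sample diversity metrics table
#'
#' Convenience wrapper computing the full clonality panel from one or more
#' clonotype tables: Gini index, Shannon entropy, clone and cell counts,
#' top-3 fraction, and the power-law CCDF fit (NA where fewer than 3 distinct
#' clone sizes exist).
#'
#' @param tables A `clonotype_table` or list of them.
#' @param base Log base for the entropy.
#' @param min_size Passed to [powerlaw_slope()].
#' @return Data frame with one row per sample, ordered as given.
#' @export
diversity_metrics <- function(tables, base = 2, min_size = 1L) {
  if (inherits(tables, "clonotype_table")) tables <- list(tables)
  rows <- lapply(tables, function(tb) {
    sizes <- tb$clones$size
    pl <- tryCatch(powerlaw_slope(sizes, min_size),
                   error = function(e) list(slope = NA_real_, r2 = NA_real_))
    data.frame(
      sample_id = tb$sample_id,
      gini = gini_index(sizes),
      shannon = shannon_entropy(sizes, base),
      n_clones = nrow(tb$clones),
      n_cells = tb$n_keyed_cells,
      top3_fraction = top_k_fraction(tb, 3L),
      powerlaw_slope = pl$slope,
      powerlaw_r2 = pl$r2,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
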