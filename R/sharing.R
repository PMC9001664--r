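# Cross-sample clonotype sharing and longitudinal clone dynamics.

.identity_key <- function(table, identity) {
  cl <- table$clones
  scheme <- table$key_scheme
  if (identity == "nt") {
    if (scheme == "beta_nt_only") cl$trb_cdr3_nt
    else paste(cl$tra_cdr3_nt, cl$trb_cdr3_nt, sep = "|")
  } else {
    if (scheme == "beta_nt_only") cl$trb_cdr3_aa
    else paste(cl$tra_cdr3_aa, cl$trb_cdr3_aa, sep = "|")
  }
}

.check_compatible <- function(a, b) {
  pa <- a$key_scheme == "beta_nt_only"
  pb <- b$key_scheme == "beta_nt_only"
  if (pa != pb)
    stop("incompatible key schemes: ", a$key_scheme, " vs ", b$key_scheme,
         call. = FALSE)
}

#' Number of clonotypes shared between two samples
#'
#' Counts distinct clonotype keys present in both samples at the stated
#' identity level. The default, nucleotide identity, is the strictest
#' criterion for calling a public clone.
#'
#' @param a,b `clonotype_table`s built under compatible key schemes (both
#'   paired, or both beta-only).
#' @param identity `"nt"` or `"aa"`.
#' @return Integer count of shared clonotypes.
#' @export
shared_clonotypes <- function(a, b, identity = c("nt", "aa")) {
  identity <- match.arg(identity)
  .check_compatible(a, b)
  length(intersect(unique(.identity_key(a, identity)),
                   unique(.identity_key(b, identity))))
}

#' Pairwise clonotype-sharing matrix
#'
#' Pairwise shared-clonotype counts across samples, either over all clones or
#' restricted to each sample's top-n clones by size (ties broken by key order
#' for determinism). The diagonal holds each sample's own clone count under
#' the mode.
#'
#' @param tables List of `clonotype_table`s (>= 2).
#' @param mode `"all_clones"` or `"top_n"`.
#' @param n Clones per sample under `top_n` (default 200, the conventional
#'   top-200 comparison).
#' @param identity `"nt"` or `"aa"`.
#' @return A symmetric integer matrix with sample ids as dimnames and
#'   attributes `mode`, `n`, `identity`.
#' @export
sharing_matrix <- function(tables, mode = c("all_clones", "top_n"), n = 200L,
                           identity = c("nt", "aa")) {
  mode <- match.arg(mode)
  identity <- match.arg(identity)
  if (length(tables) < 2L) stop("need >= 2 samples", call. = FALSE)
  n <- stop_if_not_scalar_count(n, "n", 1L)
  ids <- vapply(tables, function(t) t$sample_id, character(1))
  if (anyNA(ids)) ids <- paste0("sample_", seq_along(tables))

  keysets <- lapply(tables, function(tb) {
    cl <- tb$clones
    keys <- .identity_key(tb, identity)
    if (mode == "top_n") {
      ord <- order(-cl$size, cl$key, method = "radix")
      keys <- keys[ord][seq_len(min(n, length(keys)))]
    }
    unique(keys)
  })

  m <- matrix(0L, length(tables), length(tables), dimnames = list(ids, ids))
  for (i in seq_along(tables)) {
    m[i, i] <- length(keysets[[i]])
    if (i < length(tables)) for (j in seq((i + 1L), length(tables))) {
      s <- length(intersect(keysets[[i]], keysets[[j]]))
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  structure(m, mode = mode, n = if (mode == "top_n") n else NA_integer_,
            identity = identity)
}

#' Match clones between a subject's pre- and post-treatment samples
#'
#' Outer join of two clonotype tables on the clone key. Each matched clone is
#' classified by the relative change of its frequency (each table's own
#' keyed-cell denominator): increased if it grew by more than 20%, decreased
#' if it shrank by more than 20%, unchanged within the closed +-20% band.
#' Clones absent at one timepoint are emergent (post only) or lost (pre
#' only). Frequencies rather than raw sizes are compared so that differing
#' cell yields between visits do not masquerade as expansion; raw sizes are
#' still reported because published size-change ranges are cell-count deltas.
#'
#' @param pre,post `clonotype_table`s for the same subject (checked via their
#'   `subject_id` when both are set).
#' @param threshold Relative-change threshold (default 0.20).
#' @return Data frame with `subject_id`, `key`, `size_pre`, `size_post`,
#'   `freq_pre`, `freq_post`, `rel_change`, `class`, sorted by key.
#' @export
match_clones <- function(pre, post, threshold = 0.20) {
  if (!is.na(pre$subject_id) && !is.na(post$subject_id) &&
      pre$subject_id != post$subject_id)
    stop("subject mismatch: ", pre$subject_id, " vs ", post$subject_id,
         call. = FALSE)
  if (pre$key_scheme != post$key_scheme)
    stop("incompatible key schemes: ", pre$key_scheme, " vs ",
         post$key_scheme, call. = FALSE)
  keys <- sort(union(pre$clones$key, post$clones$key), method = "radix")
  ia <- match(keys, pre$clones$key)
  ib <- match(keys, post$clones$key)
  size_pre <- ifelse(is.na(ia), 0L, pre$clones$size[ia])
  size_post <- ifelse(is.na(ib), 0L, post$clones$size[ib])
  freq_pre <- ifelse(is.na(ia), 0, pre$clones$frequency[ia])
  freq_post <- ifelse(is.na(ib), 0, post$clones$frequency[ib])
  rel <- ifelse(freq_pre > 0, (freq_post - freq_pre) / freq_pre, NA_real_)
  class <- ifelse(size_pre == 0L, "emergent",
           ifelse(size_post == 0L, "lost",
           ifelse(rel > threshold, "increased",
           ifelse(rel < -threshold, "decreased", "unchanged"))))
  data.frame(
    subject_id = if (!is.na(pre$subject_id)) pre$subject_id else
      post$subject_id,
    key = keys, size_pre = size_pre, size_post = size_post,
    freq_pre = freq_pre, freq_post = freq_post, rel_change = rel,
    class = class, stringsAsFactors = FALSE
  )
}

#' Summarize clone dynamics
#'
#' Counts increased / unchanged / decreased clones and, per class, the range
#' of absolute cell-count changes. By default restricted to clones expanded
#' (>= `min_expanded` cells) at either timepoint, matching the usual focus on
#' expanded clones; emergent and lost clones are tallied separately and never
#' enter the three proportional-change classes.
#'
#' @param records Output of [match_clones()] (rows from one or more subjects
#'   may be concatenated).
#' @param restrict_to `"expanded_either"` or `"all"`.
#' @param min_expanded Expansion threshold in cells (default 10).
#' @return List with `counts` (named: increased, unchanged, decreased),
#'   `size_change_range` (per-class min/max of |size_post - size_pre|),
#'   `n_emergent`, `n_lost`, `n_records_considered`.
#' @export
dynamics_summary <- function(records,
                             restrict_to = c("expanded_either", "all"),
                             min_expanded = 10L) {
  restrict_to <- match.arg(restrict_to)
  min_expanded <- stop_if_not_scalar_count(min_expanded, "min_expanded", 2L)
  r <- records
  if (restrict_to == "expanded_either")
    r <- r[r$size_pre >= min_expanded | r$size_post >= min_expanded, ,
           drop = FALSE]
  classes <- c("increased", "unchanged", "decreased")
  counts <- vapply(classes, function(cl) sum(r$class == cl), integer(1))
  delta <- abs(r$size_post - r$size_pre)
  rng <- lapply(classes, function(cl) {
    d <- delta[r$class == cl]
    if (length(d)) c(min = min(d), max = max(d)) else c(min = NA, max = NA)
  })
  names(rng) <- classes
  list(counts = counts,
       size_change_range = rng,
       n_emergent = sum(r$class == "emergent"),
       n_lost = sum(r$class == "lost"),
       n_records_considered = nrow(r))
}
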