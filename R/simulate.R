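# Synthetic cohort generator. Emits paired-chain contig tables in the 10x
# dialect with power-law clone sizes, per-cell chain dropout, planted CDR3
# motifs, clone-correlated embeddings and paired timepoints, together with
# the ground truth that recovery tests compare against.

.trav <- sprintf("TRAV%d", 1:20)
.traj <- sprintf("TRAJ%d", 1:30)
.trbv <- sprintf("TRBV%d-1", 1:25)
.trbj <- sprintf("TRBJ%d-%d", rep(1:2, each = 4), rep(1:4, 2))

#' Simulation configuration
#'
#' Assembles and validates the parameter set for the synthetic cohort
#' generator. Defaults mirror a typical single-cell TCR study: clone sizes
#' with complementary-CDF exponent 1.5, per-cell detection of a productive
#' alpha chain in 61% and beta chain in 95% of cells (the published medians
#' for these libraries), 10%/5% multi-alpha/multi-beta cells, CDR3 lengths
#' Normal(14, 1.5) clipped to 8-22 residues, and subject-private clones
#' (zero cross-subject sharing unless raised).
#'
#' @param n_subjects Number of subjects.
#' @param groups Per-subject cohort labels (`"patient"`/`"healthy"`); default
#'   first half patient, second half healthy.
#' @param cmv_status Per-subject `"positive"`/`"negative"`; default
#'   alternating.
#' @param clones_per_subject Clones per subject repertoire.
#' @param ccdf_exponent Power-law exponent gamma: P(size >= x) ~ x^-gamma.
#' @param max_clone_size Truncation of the clone-size law.
#' @param cross_subject_overlap Probability a clone is copied from a
#'   previously generated subject.
#' @param p_alpha_detect,p_beta_detect Per-cell probability of recovering at
#'   least one productive chain at the locus.
#' @param p_multi_alpha,p_multi_beta Probability a detected cell carries a
#'   secondary productive chain at the locus.
#' @param p_nonproductive Per-cell probability of an extra nonproductive
#'   contig.
#' @param cdr3_length_mean,cdr3_length_sd,cdr3_length_range CDR3 amino-acid
#'   length model.
#' @param planted_motifs List of `list(motif =, n_cdr3 =, stratum =)` with
#'   stratum `"top"` (largest clones) or `"random"`.
#' @param dynamics List controlling the second timepoint: class mixture
#'   `p_increased`, `p_unchanged`, `p_decreased`, `p_lost`; fold ranges
#'   `fold_increased`, `fold_unchanged`, `fold_decreased`; `emergent_rate`.
#' @param sigma_between,sigma_within,n_dims Embedding model: clone centers
#'   Normal(0, sigma_between^2 I), cells Normal(center, sigma_within^2 I).
#'   `sigma_between = 0` is the null mode with no clone-embedding coupling.
#' @param seed Mandatory RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 6L,
                       groups = NULL,
                       cmv_status = NULL,
                       clones_per_subject = 300L,
                       ccdf_exponent = 1.5,
                       max_clone_size = 3000L,
                       cross_subject_overlap = 0,
                       p_alpha_detect = 0.61,
                       p_beta_detect = 0.95,
                       p_multi_alpha = 0.10,
                       p_multi_beta = 0.05,
                       p_nonproductive = 0.03,
                       cdr3_length_mean = 14,
                       cdr3_length_sd = 1.5,
                       cdr3_length_range = c(8L, 22L),
                       planted_motifs = list(),
                       dynamics = list(),
                       sigma_between = 5,
                       sigma_within = 1,
                       n_dims = 2L,
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  n_subjects <- stop_if_not_scalar_count(n_subjects, "n_subjects", 1L)
  if (is.null(groups))
    groups <- rep(c("patient", "healthy"),
                  c(ceiling(n_subjects / 2), floor(n_subjects / 2)))
  if (is.null(cmv_status))
    cmv_status <- rep(c("positive", "negative"), length.out = n_subjects)
  stopifnot(length(groups) == n_subjects, length(cmv_status) == n_subjects)
  probs <- c(p_alpha_detect, p_beta_detect, p_multi_alpha, p_multi_beta,
             p_nonproductive, cross_subject_overlap)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]",
                                       call. = FALSE)
  if (ccdf_exponent <= 0) stop("ccdf_exponent must be > 0", call. = FALSE)
  dyn <- utils::modifyList(list(
    p_increased = 0.3, p_unchanged = 0.3, p_decreased = 0.3, p_lost = 0.1,
    fold_increased = c(1.5, 3), fold_unchanged = c(0.9, 1.1),
    fold_decreased = c(0.2, 0.7), emergent_rate = 0.05), dynamics)
  if (abs(dyn$p_increased + dyn$p_unchanged + dyn$p_decreased +
          dyn$p_lost - 1) > 1e-9)
    stop("dynamics class probabilities must sum to 1", call. = FALSE)
  for (pm in planted_motifs) {
    # motif must fit inside the flank-trimmed region of the longest CDR3;
    # planted clones draw lengths conditioned on fitting
    if (nchar(pm$motif) > cdr3_length_range[2] - 5L)
      stop("motif ", pm$motif, " longer than the longest CDR3 interior",
           call. = FALSE)
  }
  structure(list(
    n_subjects = n_subjects, groups = groups, cmv_status = cmv_status,
    clones_per_subject = as.integer(clones_per_subject),
    ccdf_exponent = ccdf_exponent,
    max_clone_size = as.integer(max_clone_size),
    cross_subject_overlap = cross_subject_overlap,
    p_alpha_detect = p_alpha_detect, p_beta_detect = p_beta_detect,
    p_multi_alpha = p_multi_alpha, p_multi_beta = p_multi_beta,
    p_nonproductive = p_nonproductive,
    cdr3_length_mean = cdr3_length_mean, cdr3_length_sd = cdr3_length_sd,
    cdr3_length_range = as.integer(cdr3_length_range),
    planted_motifs = planted_motifs, dynamics = dyn,
    sigma_between = sigma_between, sigma_within = sigma_within,
    n_dims = as.integer(n_dims), seed = as.integer(seed)
  ), class = "sim_config")
}

# sizes with exact discrete CCDF P(X >= x) = x^-gamma: floor of a Pareto(1)
.draw_clone_sizes <- function(n, gamma, max_size) {
  pmin(floor(runif(n)^(-1 / gamma)), max_size)
}

.random_cdr3 <- function(n, config, min_len = NULL) {
  lo <- max(config$cdr3_length_range[1], min_len %||% 0L)
  len <- pmin(pmax(round(rnorm(n, config$cdr3_length_mean,
                               config$cdr3_length_sd)),
                   lo), config$cdr3_length_range[2])
  vapply(len, function(L)
    paste0("C", paste(sample(.aa20, L - 2L, replace = TRUE), collapse = ""),
           "F"),
    character(1))
}

.fresh_cdr3 <- function(config, used, min_len = NULL) {
  repeat {
    s <- .random_cdr3(1L, config, min_len)
    if (!s %in% used) return(s)
  }
}

# place motif at a random offset inside the trimmed region (positions
# 4 .. L-2) so flank trimming cannot remove it
.plant_motif <- function(cdr3, motif) {
  L <- nchar(cdr3)
  k <- nchar(motif)
  lo <- 4L
  hi <- L - 2L - k + 1L
  off <- if (hi > lo) sample(lo:hi, 1L) else lo
  paste0(substr(cdr3, 1L, off - 1L), motif, substr(cdr3, off + k, L))
}

# cells + 10x contig rows for one sample given its clone table and sizes
.emit_sample <- function(clones, sizes, sample_id, config) {
  keep <- sizes > 0L
  clones <- clones[keep, , drop = FALSE]
  sizes <- sizes[keep]
  n_cells <- sum(sizes)
  if (n_cells == 0L) {
    return(list(
      cells = data.frame(sample_id = character(0), barcode = character(0),
                         clone_id = character(0), alpha_detected = logical(0),
                         beta_detected = logical(0)),
      contigs = .empty_tenx()))
  }
  clone_of <- rep(seq_len(nrow(clones)), sizes)
  barcode <- sprintf("%s_cell%06d", sample_id, seq_len(n_cells))
  a_det <- runif(n_cells) < config$p_alpha_detect
  b_det <- runif(n_cells) < config$p_beta_detect
  a_multi <- a_det & runif(n_cells) < config$p_multi_alpha
  b_multi <- b_det & runif(n_cells) < config$p_multi_beta
  nonprod <- runif(n_cells) < config$p_nonproductive

  rows <- list()
  add <- function(cell_idx, chain, v, d, j, cgene, aa, nt, umis, prod) {
    if (!length(cell_idx)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      barcode = barcode[cell_idx], chain = chain,
      v_gene = v, d_gene = d, j_gene = j, c_gene = cgene,
      cdr3 = aa, cdr3_nt = nt, umis = umis, reads = umis * 15L,
      productive = prod, stringsAsFactors = FALSE)
  }
  ci <- clone_of
  idx <- which(a_det)
  add(idx, "TRA", clones$a_v[ci[idx]], NA_character_, clones$a_j[ci[idx]],
      "TRAC", clones$a_aa[ci[idx]], clones$a_nt[ci[idx]],
      3L + rpois(length(idx), 8), "True")
  idx <- which(a_multi)
  add(idx, "TRA", clones$a2_v[ci[idx]], NA_character_, clones$a2_j[ci[idx]],
      "TRAC", clones$a2_aa[ci[idx]], clones$a2_nt[ci[idx]],
      sample(1:2, length(idx), replace = TRUE), "True")
  idx <- which(b_det)
  add(idx, "TRB", clones$b_v[ci[idx]], "TRBD1", clones$b_j[ci[idx]],
      "TRBC1", clones$b_aa[ci[idx]], clones$b_nt[ci[idx]],
      3L + rpois(length(idx), 8), "True")
  idx <- which(b_multi)
  add(idx, "TRB", clones$b2_v[ci[idx]], "TRBD1", clones$b2_j[ci[idx]],
      "TRBC1", clones$b2_aa[ci[idx]], clones$b2_nt[ci[idx]],
      sample(1:2, length(idx), replace = TRUE), "True")
  idx <- which(nonprod)
  add(idx, "TRB", "TRBV1-1", "TRBD1", "TRBJ1-1", "TRBC1",
      NA_character_, NA_character_, 1L, "False")

  if (!length(rows))
    return(list(cells = data.frame(sample_id = sample_id, barcode = barcode,
                                   clone_id = clones$clone_id[clone_of],
                                   alpha_detected = a_det,
                                   beta_detected = b_det,
                                   stringsAsFactors = FALSE),
                contigs = .empty_tenx()))
  ctg <- do.call(rbind, rows)
  ctg <- ctg[order(ctg$barcode, ctg$chain, -ctg$umis, method = "radix"), ,
             drop = FALSE]
  ctg$contig_id <- paste0(ctg$barcode, "_contig_",
                          stats::ave(seq_len(nrow(ctg)), ctg$barcode,
                                     FUN = seq_along))
  ctg <- data.frame(
    barcode = ctg$barcode, is_cell = "True", contig_id = ctg$contig_id,
    high_confidence = "True",
    length = nchar(ifelse(is.na(ctg$cdr3_nt), "", ctg$cdr3_nt)) + 300L,
    chain = ctg$chain, v_gene = ctg$v_gene, d_gene = ctg$d_gene,
    j_gene = ctg$j_gene, c_gene = ctg$c_gene, full_length = "True",
    productive = ctg$productive, cdr3 = ctg$cdr3, cdr3_nt = ctg$cdr3_nt,
    reads = ctg$reads, umis = ctg$umis, stringsAsFactors = FALSE)
  rownames(ctg) <- NULL

  list(cells = data.frame(sample_id = sample_id, barcode = barcode,
                          clone_id = clones$clone_id[clone_of],
                          alpha_detected = a_det, beta_detected = b_det,
                          stringsAsFactors = FALSE),
       contigs = ctg)
}

.empty_tenx <- function() {
  data.frame(barcode = character(0), is_cell = character(0),
             contig_id = character(0), high_confidence = character(0),
             length = integer(0), chain = character(0),
             v_gene = character(0), d_gene = character(0),
             j_gene = character(0), c_gene = character(0),
             full_length = character(0), productive = character(0),
             cdr3 = character(0), cdr3_nt = character(0),
             reads = integer(0), umis = integer(0), stringsAsFactors = FALSE)
}

#' Generate a synthetic single-timepoint cohort
#'
#' Draws per-subject clonal repertoires with the configured power-law
#' clone-size law, builds paired alpha/beta CDR3 sequences (nucleotide
#' sequences back-translated codon-wise from the amino acids), plants the
#' configured motifs, and emits per-sample contig tables in the 10x dialect
#' after applying per-cell chain dropout and multi-chain rates. All
#' randomness is governed by `config$seed`; regeneration with the same
#' config is bit-identical.
#'
#' @param config A [sim_config()].
#' @return A list of class `tcr_sim`: `contigs` (named list of 10x-dialect
#'   data frames), `sample_sheet`, and `truth` (`clones`, `cells`, `samples`,
#'   `config`).
#' @export
generate_repertoire <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    subjects <- sprintf("S%02d", seq_len(config$n_subjects))
    used_b <- character(0)
    all_clones <- list()
    for (si in seq_along(subjects)) {
      n <- config$clones_per_subject
      sizes <- .draw_clone_sizes(n, config$ccdf_exponent,
                                 config$max_clone_size)
      cl <- data.frame(
        clone_id = sprintf("%s_clone%04d", subjects[si], seq_len(n)),
        subject_id = subjects[si], size_pre = as.integer(sizes),
        shared_from = NA_character_, stringsAsFactors = FALSE)
      copy_idx <- if (si > 1L && config$cross_subject_overlap > 0)
        which(runif(n) < config$cross_subject_overlap) else integer(0)
      a_aa <- .random_cdr3(n, config)
      b_aa <- vapply(seq_len(n), function(i) {
        s <- .fresh_cdr3(config, used_b)
        used_b <<- c(used_b, s)
        s
      }, character(1))
      cl$a_aa <- a_aa
      cl$b_aa <- b_aa
      cl$a_v <- sample(.trav, n, replace = TRUE)
      cl$a_j <- sample(.traj, n, replace = TRUE)
      cl$b_v <- sample(.trbv, n, replace = TRUE)
      cl$b_j <- sample(.trbj, n, replace = TRUE)
      # secondary chains for multi-chain cells
      cl$a2_aa <- .random_cdr3(n, config)
      cl$a2_v <- sample(.trav, n, replace = TRUE)
      cl$a2_j <- sample(.traj, n, replace = TRUE)
      cl$b2_aa <- .random_cdr3(n, config)
      cl$b2_v <- sample(.trbv, n, replace = TRUE)
      cl$b2_j <- sample(.trbj, n, replace = TRUE)
      if (length(copy_idx)) {
        donor_pool <- do.call(rbind, all_clones)
        # distinct donors so one subject never carries two clones with the
        # same receptor (clonotyping would merge them and break truth)
        copy_idx <- copy_idx[seq_len(min(length(copy_idx),
                                         nrow(donor_pool)))]
        src <- sample.int(nrow(donor_pool), length(copy_idx))
        fields <- c("a_aa", "b_aa", "a_v", "a_j", "b_v", "b_j",
                    "a2_aa", "a2_v", "a2_j", "b2_aa", "b2_v", "b2_j")
        cl[copy_idx, fields] <- donor_pool[src, fields]
        cl$shared_from[copy_idx] <- donor_pool$clone_id[src]
      }
      all_clones[[si]] <- cl
    }
    clones <- do.call(rbind, all_clones)

    clones$planted_motif <- NA_character_
    fresh <- is.na(clones$shared_from)
    for (pm in config$planted_motifs) {
      free <- which(fresh & is.na(clones$planted_motif))
      pick <- if (identical(pm$stratum %||% "top", "top")) {
        free[order(-clones$size_pre[free], clones$clone_id[free],
                   method = "radix")][seq_len(pm$n_cdr3)]
      } else {
        sample(free, pm$n_cdr3)
      }
      for (i in pick) {
        repeat {
          s <- .plant_motif(.fresh_cdr3(config, used_b,
                                        nchar(pm$motif) + 5L), pm$motif)
          if (!s %in% used_b) break
        }
        used_b <- c(used_b, s)
        clones$b_aa[i] <- s
        clones$planted_motif[i] <- pm$motif
      }
    }

    for (f in c("a_aa", "b_aa", "a2_aa", "b2_aa"))
      clones[[sub("aa", "nt", f)]] <- backtranslate_cdr3(clones[[f]])

    samples <- data.frame(
      sample_id = paste0(subjects, "_pre"), subject_id = subjects,
      timepoint = "pre", group = config$groups,
      cmv_status = config$cmv_status, responder = "na",
      stringsAsFactors = FALSE)

    contigs <- list()
    cells <- list()
    for (si in seq_along(subjects)) {
      cl <- clones[clones$subject_id == subjects[si], , drop = FALSE]
      em <- .emit_sample(cl, cl$size_pre, samples$sample_id[si], config)
      contigs[[samples$sample_id[si]]] <- em$contigs
      cells[[si]] <- em$cells
    }
    cells <- do.call(rbind, cells)
    samples$n_cells <- as.integer(table(factor(cells$sample_id,
                                               levels = samples$sample_id)))

    structure(list(contigs = contigs, sample_sheet = samples,
                   truth = list(clones = clones, cells = cells,
                                samples = samples, config = config)),
              class = "tcr_sim")
  })
}

#' Add a post-treatment timepoint to a synthetic cohort
#'
#' Draws a dynamics class per existing clone of each treated subject from
#' the configured mixture, applies a uniform fold change from the class's
#' range to the true clone size (increased x1.5-3, unchanged x0.9-1.1,
#' decreased x0.2-0.7 by default; lost clones drop to zero), injects
#' emergent clones at the configured rate, and emits the post-visit contig
#' tables under the same dropout model. The recorded `class_true` is the
#' classification of the true frequency change under the +-20% rule, which
#' is what a dropout-free pipeline run must reproduce; `class_drawn` keeps
#' the sampled mixture component.
#'
#' @param sim A `tcr_sim` from [generate_repertoire()].
#' @param subjects Subjects receiving a post visit (default: the `patient`
#'   group, or all subjects if there are no patients).
#' @return The extended `tcr_sim` with post samples appended and truth
#'   columns `size_post`, `class_drawn`, `class_true`.
#' @export
generate_timepoints <- function(sim, subjects = NULL) {
  stopifnot(inherits(sim, "tcr_sim"))
  config <- sim$truth$config
  dyn <- config$dynamics
  if (is.null(subjects)) {
    subjects <- sim$sample_sheet$subject_id[sim$sample_sheet$group == "patient"]
    if (!length(subjects)) subjects <- sim$sample_sheet$subject_id
  }
  with_local_seed(config$seed + 1L, {
    clones <- sim$truth$clones
    clones$size_post <- NA_integer_
    clones$class_drawn <- NA_character_
    new_clones <- list()
    for (sub in subjects) {
      idx <- which(clones$subject_id == sub)
      cls <- sample(c("increased", "unchanged", "decreased", "lost"),
                    length(idx), replace = TRUE,
                    prob = c(dyn$p_increased, dyn$p_unchanged,
                             dyn$p_decreased, dyn$p_lost))
      fold <- numeric(length(idx))
      for (cn in c("increased", "unchanged", "decreased")) {
        w <- cls == cn
        rng <- dyn[[paste0("fold_", cn)]]
        fold[w] <- runif(sum(w), rng[1], rng[2])
      }
      post <- as.integer(round(clones$size_pre[idx] * fold))
      post[cls == "lost"] <- 0L
      # a surviving clone keeps at least one cell; class bookkeeping stays
      # consistent because class_true is recomputed from realized sizes
      post[cls != "lost" & post < 1L] <- 1L
      clones$size_post[idx] <- post
      clones$class_drawn[idx] <- cls

      n_em <- as.integer(round(dyn$emergent_rate * length(idx)))
      if (n_em > 0L) {
        em_sizes <- .draw_clone_sizes(n_em, config$ccdf_exponent,
                                      config$max_clone_size)
        used_b <- clones$b_aa
        cl <- data.frame(
          clone_id = sprintf("%s_emclone%04d", sub, seq_len(n_em)),
          subject_id = sub, size_pre = 0L, shared_from = NA_character_,
          stringsAsFactors = FALSE)
        cl$a_aa <- .random_cdr3(n_em, config)
        cl$b_aa <- vapply(seq_len(n_em), function(i) {
          s <- .fresh_cdr3(config, used_b); used_b <<- c(used_b, s); s
        }, character(1))
        cl$a_v <- sample(.trav, n_em, replace = TRUE)
        cl$a_j <- sample(.traj, n_em, replace = TRUE)
        cl$b_v <- sample(.trbv, n_em, replace = TRUE)
        cl$b_j <- sample(.trbj, n_em, replace = TRUE)
        cl$a2_aa <- .random_cdr3(n_em, config)
        cl$a2_v <- sample(.trav, n_em, replace = TRUE)
        cl$a2_j <- sample(.traj, n_em, replace = TRUE)
        cl$b2_aa <- .random_cdr3(n_em, config)
        cl$b2_v <- sample(.trbv, n_em, replace = TRUE)
        cl$b2_j <- sample(.trbj, n_em, replace = TRUE)
        cl$planted_motif <- NA_character_
        for (f in c("a_aa", "b_aa", "a2_aa", "b2_aa"))
          cl[[sub("aa", "nt", f)]] <- backtranslate_cdr3(cl[[f]])
        cl$size_post <- as.integer(em_sizes)
        cl$class_drawn <- "emergent"
        new_clones[[length(new_clones) + 1L]] <- cl
      }
    }
    if (length(new_clones))
      clones <- rbind(clones, do.call(rbind, new_clones)[names(clones)])

    # truth classification of the realized frequency change, +-20% rule
    clones$class_true <- NA_character_
    for (sub in subjects) {
      idx <- which(clones$subject_id == sub)
      sp <- clones$size_pre[idx]
      so <- clones$size_post[idx]
      fp <- sp / sum(sp)
      fo <- so / sum(so)
      rel <- ifelse(fp > 0, (fo - fp) / fp, NA_real_)
      clones$class_true[idx] <-
        ifelse(sp == 0L, "emergent",
        ifelse(so == 0L, "lost",
        ifelse(rel > 0.20, "increased",
        ifelse(rel < -0.20, "decreased", "unchanged"))))
    }

    post_sheet <- sim$sample_sheet[sim$sample_sheet$subject_id %in% subjects &
                                     sim$sample_sheet$timepoint == "pre", ,
                                   drop = FALSE]
    post_sheet$sample_id <- paste0(post_sheet$subject_id, "_post")
    post_sheet$timepoint <- "post"

    contigs <- sim$contigs
    cells <- list(sim$truth$cells)
    for (i in seq_len(nrow(post_sheet))) {
      sub <- post_sheet$subject_id[i]
      cl <- clones[clones$subject_id == sub, , drop = FALSE]
      em <- .emit_sample(cl, cl$size_post, post_sheet$sample_id[i],
                         sim$truth$config)
      contigs[[post_sheet$sample_id[i]]] <- em$contigs
      cells[[length(cells) + 1L]] <- em$cells
    }
    cells <- do.call(rbind, cells)
    sheet <- rbind(sim$sample_sheet,
                   cbind(post_sheet[setdiff(names(post_sheet), "n_cells")],
                         n_cells = NA_integer_))
    sheet$n_cells <- as.integer(table(factor(cells$sample_id,
                                             levels = sheet$sample_id)))

    structure(list(contigs = contigs, sample_sheet = sheet,
                   truth = list(clones = clones, cells = cells,
                                samples = sheet, config = config)),
              class = "tcr_sim")
  })
}

#' Generate a clone-correlated cell embedding for a synthetic cohort
#'
#' Each clone receives a center drawn from Normal(0, sigma_between^2 I) and
#' each cell scatters around its clone's center with Normal(0,
#' sigma_within^2 I) noise; batch labels are the sample ids. With
#' `sigma_between = 0` (null mode) the embedding carries no clonal signal,
#' which is the regime used to calibrate the permutation tests.
#'
#' @param sim A `tcr_sim`.
#' @param sigma_between,sigma_within,n_dims Override the config values.
#' @param seed RNG seed (default `config$seed + 2`).
#' @return Embedding data frame: `barcode`, `sample_id`, `dim_1..dim_k`,
#'   `batch`, one row per sequenced cell.
#' @export
generate_embedding <- function(sim, sigma_between = NULL, sigma_within = NULL,
                               n_dims = NULL, seed = NULL) {
  stopifnot(inherits(sim, "tcr_sim"))
  config <- sim$truth$config
  sb <- sigma_between %||% config$sigma_between
  sw <- sigma_within %||% config$sigma_within
  k <- n_dims %||% config$n_dims
  seed <- seed %||% (config$seed + 2L)
  cells <- sim$truth$cells
  clone_ids <- unique(sim$truth$clones$clone_id)
  with_local_seed(seed, {
    centers <- matrix(rnorm(length(clone_ids) * k, 0, sb),
                      nrow = length(clone_ids),
                      dimnames = list(clone_ids, NULL))
    ci <- match(cells$clone_id, clone_ids)
    coords <- centers[ci, , drop = FALSE] +
      matrix(rnorm(nrow(cells) * k, 0, sw), ncol = k)
    out <- data.frame(barcode = cells$barcode, sample_id = cells$sample_id,
                      stringsAsFactors = FALSE)
    for (j in seq_len(k)) out[[paste0("dim_", j)]] <- coords[, j]
    out$batch <- cells$sample_id
    out
  })
}

#' Write a synthetic cohort to disk
#'
#' Emits per-sample `"<sample_id>.csv"` contig tables (10x dialect),
#' `sample_sheet.csv`, optionally `embedding.tsv`, and the truth tables
#' under `truth/`. Deterministic: the same `tcr_sim` writes byte-identical
#' files.
#'
#' @param sim A `tcr_sim`.
#' @param dir Output directory (created if needed).
#' @param embedding Optional embedding data frame to include.
#' @return Invisibly, `dir`.
#' @export
write_sim <- function(sim, dir, embedding = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  for (s in names(sim$contigs))
    write.csv(sim$contigs[[s]], file.path(dir, paste0(s, ".csv")),
              row.names = FALSE, quote = FALSE, na = "")
  write.csv(sim$sample_sheet, file.path(dir, "sample_sheet.csv"),
            row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(embedding))
    write_table(embedding, file.path(dir, "embedding.tsv"))
  write_table(sim$truth$clones, file.path(dir, "truth", "clones.tsv"))
  write_table(sim$truth$cells, file.path(dir, "truth", "cells.tsv"))
  invisible(dir)
}

#' @export
print.tcr_sim <- function(x, ...) {
  cat(sprintf("tcr_sim: %d sample(s), %d clone(s), %d cell(s) (seed %d)\n",
              length(x$contigs), nrow(x$truth$clones), nrow(x$truth$cells),
              x$truth$config$seed))
  invisible(x)
}

#' Clonotype tables for every sample of a cohort or simulation
#'
#' Runs [build_cell_chains()] and [call_clonotypes()] on each sample and
#' returns the tables as a named list, carrying sample and subject labels.
#'
#' @param x A `tcr_cohort` or `tcr_sim`.
#' @param key_scheme Passed to [call_clonotypes()].
#' @param require_high_confidence Passed to [build_cell_chains()].
#' @return Named list of `clonotype_table`s.
#' @export
clonotype_tables <- function(x, key_scheme = "nt_paired",
                             require_high_confidence = TRUE) {
  sheet <- if (inherits(x, "tcr_sim")) x$sample_sheet else x$samples
  out <- lapply(seq_len(nrow(sheet)), function(i) {
    sid <- sheet$sample_id[i]
    cc <- build_cell_chains(x$contigs[[sid]], require_high_confidence)
    call_clonotypes(cc, key_scheme, sample_id = sid,
                    subject_id = sheet$subject_id[i])
  })
  setNames(out, sheet$sample_id)
}
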