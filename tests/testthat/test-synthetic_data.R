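# The synthetic cohort generator: determinism, marginal fidelity at modest
# sizes, and exact truth recovery on dropout-free cohorts.

dropout_free <- function(...) {
  sim_config(p_alpha_detect = 1, p_beta_detect = 1, p_multi_alpha = 0,
             p_multi_beta = 0, p_nonproductive = 0, ...)
}

test_that("generation is bit-reproducible given the seed, and files are
           byte-identical", {
  cfg <- sim_config(n_subjects = 2, clones_per_subject = 60, seed = 7)
  s1 <- generate_repertoire(cfg)
  s2 <- generate_repertoire(cfg)
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$truth$clones, s2$truth$clones)
  d1 <- tempfile(); d2 <- tempfile()
  write_sim(s1, d1); write_sim(s2, d2)
  f <- paste0(s1$sample_sheet$sample_id[1], ".csv")
  expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                   readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  # a different seed changes the draw
  s3 <- generate_repertoire(sim_config(n_subjects = 2,
                                       clones_per_subject = 60, seed = 8))
  expect_false(identical(s1$truth$clones$b_aa, s3$truth$clones$b_aa))
})

test_that("nucleotide CDR3s translate back to the amino-acid truth and
           lengths respect the model's clip range", {
  cfg <- sim_config(n_subjects = 2, clones_per_subject = 80, seed = 12)
  sim <- generate_repertoire(cfg)
  cl <- sim$truth$clones
  expect_equal(translate_cdr3(cl$b_nt), cl$b_aa)
  expect_equal(translate_cdr3(cl$a_nt), cl$a_aa)
  expect_true(all(nchar(cl$b_aa) >= 8 & nchar(cl$b_aa) <= 22))
  expect_true(all(startsWith(cl$b_aa, "C") & endsWith(cl$b_aa, "F")))
  expect_true(all(cl$size_pre >= 1L))
})

test_that("planted CDR3 lengths concentrate near the configured mean", {
  cfg <- sim_config(n_subjects = 1, clones_per_subject = 5000, seed = 4,
                    groups = "patient", cmv_status = "positive")
  sim <- generate_repertoire(cfg)
  expect_lt(abs(mean(nchar(sim$truth$clones$b_aa)) - 14), 0.2)
})

test_that("chain detection fractions track the dropout configuration", {
  cfg <- sim_config(n_subjects = 1, clones_per_subject = 2000, seed = 9,
                    groups = "patient", cmv_status = "positive")
  sim <- generate_repertoire(cfg)
  sid <- sim$sample_sheet$sample_id[1]
  cc <- build_cell_chains(sim$contigs[[sid]])
  n_total <- sim$sample_sheet$n_cells[1]
  s <- chain_detection_summary(cc, n_total)
  expect_lt(abs(s$f_ge1_alpha - 0.61), 0.04)
  expect_lt(abs(s$f_ge1_beta - 0.95), 0.04)
  expect_lt(s$f_exactly1_alpha, s$f_ge1_alpha)  # multi-alpha cells exist
})

test_that("dropout-free cohorts reproduce truth exactly: clone sizes,
           expanded set, private sharing", {
  cfg <- dropout_free(n_subjects = 3, clones_per_subject = 120, seed = 21)
  sim <- generate_repertoire(cfg)
  tabs <- clonotype_tables(sim)
  truth <- sim$truth$clones
  for (i in seq_along(tabs)) {
    sub <- sim$sample_sheet$subject_id[i]
    tcl <- truth[truth$subject_id == sub, ]
    expect_equal(tabs[[i]]$n_keyed_cells, sum(tcl$size_pre))
    truth_key <- paste(tcl$a_nt, tcl$b_nt, sep = "|")
    got <- tabs[[i]]$clones
    expect_setequal(got$key, truth_key)
    expect_equal(got$size[match(truth_key, got$key)], tcl$size_pre)
    # expanded set equals ground truth at the 10-cell threshold
    expect_setequal(call_expanded(tabs[[i]]), truth_key[tcl$size_pre >= 10])
  }
  m <- sharing_matrix(tabs, "all_clones")
  expect_true(all(m[upper.tri(m)] == 0L))  # clones are subject-private
})

test_that("cross-subject overlap plants shared clones that the sharing
           matrix recovers", {
  cfg <- dropout_free(n_subjects = 2, clones_per_subject = 150, seed = 33,
                      cross_subject_overlap = 0.1)
  sim <- generate_repertoire(cfg)
  truth <- sim$truth$clones
  n_shared_truth <- sum(!is.na(truth$shared_from))
  expect_gt(n_shared_truth, 0L)
  tabs <- clonotype_tables(sim)
  m <- sharing_matrix(tabs, "all_clones")
  shared_keys <- intersect(
    paste(truth$a_nt, truth$b_nt, sep = "|")[truth$subject_id == "S01"],
    paste(truth$a_nt, truth$b_nt, sep = "|")[truth$subject_id == "S02"])
  expect_equal(m[1, 2], length(shared_keys))
})

test_that("timepoint dynamics on dropout-free cohorts match the recorded
           truth classes exactly", {
  cfg <- dropout_free(n_subjects = 2, clones_per_subject = 150, seed = 14,
                      groups = c("patient", "patient"),
                      dynamics = list(emergent_rate = 0.05))
  sim <- generate_timepoints(generate_repertoire(cfg))
  tabs <- clonotype_tables(sim)
  truth <- sim$truth$clones
  for (sub in c("S01", "S02")) {
    rec <- match_clones(tabs[[paste0(sub, "_pre")]],
                        tabs[[paste0(sub, "_post")]])
    tcl <- truth[truth$subject_id == sub, ]
    truth_key <- paste(tcl$a_nt, tcl$b_nt, sep = "|")
    idx <- match(rec$key, truth_key)
    expect_false(anyNA(idx))
    expect_equal(rec$class, tcl$class_true[idx])
    expect_equal(rec$size_pre, tcl$size_pre[idx])
    expect_equal(rec$size_post, tcl$size_post[idx])
  }
})

test_that("an all-unchanged fold mixture yields no proportional-change
           calls, and zero emergent rate yields no emergent records", {
  cfg <- dropout_free(n_subjects = 1, clones_per_subject = 200, seed = 6,
                      groups = "patient", cmv_status = "positive",
                      dynamics = list(p_increased = 0, p_unchanged = 1,
                                      p_decreased = 0, p_lost = 0,
                                      emergent_rate = 0))
  sim <- generate_timepoints(generate_repertoire(cfg))
  tabs <- clonotype_tables(sim)
  rec <- match_clones(tabs[["S01_pre"]], tabs[["S01_post"]])
  expect_equal(sum(rec$class %in% c("increased", "decreased")), 0L)
  expect_equal(sum(rec$class == "emergent"), 0L)
  s <- dynamics_summary(rec)
  expect_equal(unname(s$counts[c("increased", "decreased")]), c(0L, 0L))
})

test_that("planted motifs land in the trimmed region of designated top
           clones and are recovered as a convergence group", {
  cfg <- dropout_free(
    n_subjects = 3, clones_per_subject = 100, seed = 19,
    planted_motifs = list(list(motif = "WQVR", n_cdr3 = 7, stratum = "top")))
  sim <- generate_repertoire(cfg)
  truth <- sim$truth$clones
  planted <- truth[!is.na(truth$planted_motif), ]
  expect_equal(nrow(planted), 7L)
  trimmed <- substr(planted$b_aa, 4, nchar(planted$b_aa) - 2)
  expect_true(all(grepl("WQVR", trimmed, fixed = TRUE)))

  tabs <- clonotype_tables(sim)
  pooled <- pool_top_cdr3(tabs, 500)
  ref <- make_reference_repertoire(3000, seed = 77)
  hits <- suppressMessages(enriched_kmers(pooled$cdr3_aa, ref,
                                          n_resample = 1000, seed = 3))
  crgs <- build_crgs(pooled, hits)
  recovered <- any(vapply(crgs, function(g) all(planted$b_aa %in% g$members),
                          logical(1)))
  expect_true(recovered)
})

test_that("the embedding couples clones to space unless run in null mode", {
  cfg <- dropout_free(n_subjects = 1, clones_per_subject = 60, seed = 25,
                      groups = "patient", cmv_status = "positive",
                      sigma_between = 10, sigma_within = 1)
  sim <- generate_repertoire(cfg)
  emb <- generate_embedding(sim)
  expect_equal(nrow(emb), nrow(sim$truth$cells))
  tabs <- clonotype_tables(sim)
  big <- call_expanded(tabs[[1]], 10L)
  if (length(big)) {
    cells <- tabs[[1]]$cell_assignments
    grp <- data.frame(sample_id = sim$sample_sheet$sample_id[1],
                      barcode = cells$barcode[cells$key == big[1]])
    res <- group_coherence(emb, grp, n_perm = 199, seed = 8)
    expect_equal(res$p_value, 1 / 200)
  }
  # null mode: expanded-clone cells are no closer than random cells
  emb0 <- generate_embedding(sim, sigma_between = 0)
  cells <- tabs[[1]]$cell_assignments
  grp <- data.frame(sample_id = sim$sample_sheet$sample_id[1],
                    barcode = cells$barcode[cells$key ==
                                              tabs[[1]]$clones$key[1]])
  res0 <- group_coherence(emb0, grp, n_perm = 199, seed = 8)
  expect_gt(res0$p_value, 0.01)
})

test_that("multi-chain and nonproductive rates surface in the emitted
           contig tables", {
  cfg <- sim_config(n_subjects = 1, clones_per_subject = 800, seed = 41,
                    groups = "patient", cmv_status = "positive",
                    p_multi_alpha = 0.2, p_nonproductive = 0.1)
  sim <- generate_repertoire(cfg)
  ctg <- sim$contigs[[1]]
  expect_true(any(ctg$productive == "False"))
  cc <- build_cell_chains(ctg)
  expect_gt(cc$n_multi_tra, 0L)
  # representative chain is always the primary (higher-UMI) rearrangement
  tab <- call_clonotypes(cc, "nt_paired")
  truth_keys <- paste(sim$truth$clones$a_nt, sim$truth$clones$b_nt, sep = "|")
  expect_true(all(tab$clones$key %in% truth_keys))
})
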