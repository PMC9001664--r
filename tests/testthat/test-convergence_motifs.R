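# CDR3 pooling, k-mer enrichment, convergence-group construction and the
# motif Fisher test.

test_that("pooling unions each sample's top-n beta CDR3s with conserved
           per-sample counts", {
  nts <- nt_pool(6)
  a <- make_beta_table(nts[1:3], c(5L, 3L, 2L), "sA")
  b <- make_beta_table(nts[3:5], c(4L, 2L, 1L), "sB")
  pooled <- pool_top_cdr3(list(a, b), n = 3)
  expect_equal(nrow(pooled), 5L)  # 1 shared of 6
  expect_equal(pooled$total_cells, pooled$sA + pooled$sB)
  shared_aa <- translate_cdr3(nts[3])
  row <- pooled[pooled$cdr3_aa == shared_aa, ]
  expect_equal(row$sA, 2L)
  expect_equal(row$sB, 4L)
  # n larger than the repertoire pools everything
  expect_equal(nrow(pool_top_cdr3(list(a, b), n = 100)), 5L)
  # top-n truncation keeps the largest clones
  p1 <- pool_top_cdr3(list(a), n = 2)
  expect_equal(nrow(p1), 2L)
  expect_equal(sort(p1$cdr3_aa), sort(translate_cdr3(nts[1:2])))
})

test_that("planted k-mers are enriched against a motif-free reference and
           short sequences are skipped", {
  set.seed(21)
  ref <- make_reference_repertoire(4000, seed = 99)
  # 40 of 500 sample sequences carry PGTN in the trimmed region
  carriers <- vapply(1:40, function(i)
    paste0("CASS", "PGTN", random_aa_string(5), "FF"), character(1))
  bystanders <- ref[sample(length(ref), 460)]
  hits <- suppressMessages(
    enriched_kmers(c(carriers, bystanders), ref, k_set = 4L,
                   n_resample = 1000, seed = 31))
  expect_true("PGTN" %in% hits$motif)
  row <- hits[hits$motif == "PGTN", , drop = FALSE]
  expect_gte(row$observed_count, 40L)
  expect_lte(row$p_resample, 0.001)

  # trimmed length below k is skipped with a log message
  expect_message(
    enriched_kmers(c("CASSLLGF", "CPGTF"), ref, k_set = 4L, n_resample = 10,
                   seed = 1),
    "skipped")
  expect_error(enriched_kmers("CASSF", character(0)), "empty")
})

test_that("resampling p-values are deterministic given the seed", {
  ref <- make_reference_repertoire(1000, seed = 5)
  samp <- c(replicate(6, paste0("CAS", "WQV", random_aa_string(6), "F")),
            ref[1:100])
  h1 <- suppressMessages(enriched_kmers(samp, ref, k_set = 3L,
                                        n_resample = 200, seed = 77))
  h2 <- suppressMessages(enriched_kmers(samp, ref, k_set = 3L,
                                        n_resample = 200, seed = 77))
  expect_identical(as.data.frame(h1), as.data.frame(h2))
})

make_pooled <- function(seqs, cells = NULL, sample = "sA") {
  out <- data.frame(cdr3_aa = seqs,
                    total_cells = cells %||% rep(1L, length(seqs)),
                    stringsAsFactors = FALSE)
  out[[sample]] <- out$total_cells
  out
}

fake_hits <- function(motifs) {
  n <- length(motifs)
  data.frame(motif = motifs, k = nchar(motifs),
             observed_count = rep_len(99L, n),
             reference_rate = rep_len(0, n), fold = rep_len(Inf, n),
             p_resample = rep_len(1e-3, n), stringsAsFactors = FALSE)
}

test_that("convergence groups are connected components above the strict
           size cutoff", {
  carriers <- paste0("CASS", "PGTN", c("AAA", "CCC", "DDD", "EEE", "GGG",
                                       "HHH", "III"), "FF")
  singleton <- "CWWWWWWWWWWF"
  pooled <- make_pooled(c(carriers, singleton))
  crgs <- build_crgs(pooled, fake_hits("PGTN"))
  expect_length(crgs, 1L)
  expect_setequal(crgs[[1]]$members, carriers)
  expect_false(singleton %in% crgs[[1]]$members)

  # near-identity star with no motif: base plus five single-substitution
  # variants form one component of 6
  base <- "CASSAAAAAF"
  variants <- vapply(c("W", "Y", "H", "K", "R"), function(ch) {
    s <- base; substr(s, 5, 5) <- ch; s
  }, character(1), USE.NAMES = FALSE)
  crg2 <- build_crgs(make_pooled(c(base, variants)), fake_hits(character(0)))
  expect_length(crg2, 1L)
  expect_equal(crg2[[1]]$n_members, 6L)
  expect_true(all(crg2[[1]]$edges$evidence == "hamming1"))

  # exactly five members is excluded under the strict reading
  five <- paste0("CASS", "PGTN", c("AAA", "CCC", "DDD", "EEE", "GGG"), "FF")
  expect_length(build_crgs(make_pooled(five), fake_hits("PGTN")), 0L)
  expect_length(build_crgs(make_pooled(five), fake_hits("PGTN"),
                           strict = FALSE), 1L)
})

test_that("groups are named by their most abundant member, disjoint, and
           input-order invariant", {
  seqs <- paste0("CASS", "PGTN", c("AAA", "CCC", "DDD", "EEE", "GGG", "HHH"),
                 "FF")
  pooled <- make_pooled(seqs, cells = c(5L, 40L, 3L, 2L, 1L, 1L))
  crgs <- build_crgs(pooled, fake_hits("PGTN"))
  expect_equal(crgs[[1]]$name, paste0("CRG_", seqs[2]))

  set.seed(3)
  shuffled <- pooled[sample(nrow(pooled)), ]
  crgs2 <- build_crgs(shuffled, fake_hits("PGTN"))
  expect_equal(crgs2[[1]]$name, crgs[[1]]$name)
  expect_equal(crgs2[[1]]$members, crgs[[1]]$members)

  # each pooled sequence belongs to at most one group
  all_members <- unlist(lapply(crgs, `[[`, "members"))
  expect_false(anyDuplicated(all_members) > 0)
})

test_that("top-5 sample contribution follows its definition", {
  g <- list(name = "CRG_X", members = "CASSXF", n_members = 1L,
            member_cells = 100L,
            sample_counts = c(s1 = 50, s2 = 30, s3 = 20))
  expect_equal(crg_contribution(g)$top5_contribution, 1)
  g$sample_counts <- setNames(rep(10, 10), paste0("s", 1:10))
  expect_equal(crg_contribution(g)$top5_contribution, 0.5)
  g$sample_counts <- c(s1 = 73, s2 = 9, s3 = 6, s4 = 5, s5 = 4, s6 = 3)
  expect_equal(crg_contribution(g)$top5_contribution, 0.97)
  expect_equal(crg_contribution(g, samples = c("s1", "s2"))$top5_contribution,
               1)
  expect_equal(crg_contribution(g)$per_sample$sample_id[1], "s1")
})

test_that("the motif Fisher test matches hypergeometric enumeration and
           scans untrimmed sequences", {
  clones <- data.frame(
    cdr3_aa = c(rep("CASSATNYGYTF", 8), rep("CASSLLGGYTF", 2),
                rep("CATGTWF", 3), rep("CASSLWGNEQFF", 7)),
    expanded = rep(c(TRUE, FALSE), c(10, 10)),
    cmv_positive = rep(c(TRUE, FALSE), c(10, 10)),
    stringsAsFactors = FALSE)
  res <- motif_scan_fisher(clones, motifs = c("ATN", "TGT"))
  expect_equal(unname(res$table[1, ]), c(8L, 2L))
  expect_equal(unname(res$table[2, ]), c(3L, 7L))
  expect_equal(res$p_value, fisher_oracle(res$table), tolerance = 1e-12)
  expect_equal(res$p_value,
               fisher.test(matrix(c(8, 2, 3, 7), 2, byrow = TRUE))$p.value)

  # an all-motif (or all-motif-free) column is refused as degenerate
  degen <- data.frame(cdr3_aa = c("CFQAAAAF", "CFQGGGGF"),
                      expanded = c(TRUE, FALSE),
                      cmv_positive = c(TRUE, FALSE))
  expect_error(motif_scan_fisher(degen, motifs = "FQ"), "degenerate")
  # 2-mer FQ is matched on the full sequence including the C/F flanks,
  # where trimming would have removed it
  clones3 <- data.frame(cdr3_aa = c("CFQAAAAF", "CAAAAAAF", "CFQGGGGF",
                                    "CGGGGGGF"),
                        expanded = c(TRUE, FALSE, TRUE, FALSE),
                        cmv_positive = c(TRUE, FALSE, FALSE, TRUE))
  res3 <- motif_scan_fisher(clones3, motifs = "FQ")
  expect_equal(unname(res3$table["expanded_cmv_pos", "motif"]), 1L)
  expect_equal(unname(res3$table["other", "motif"]), 1L)
})
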