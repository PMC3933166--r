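test_that("singleton masking corrects private SNPs and protects shared ones", {
  # one clone with a private A->G; two clones sharing a G elsewhere
  aln <- seq_tbl(paste0("c", 1:5),
                 c("AATT", "AATT", "GATT", "AAGT", "AAGT"))
  out <- mask_singletons(aln)
  expect_equal(out$alignment$seq[3], "AATT")          # singleton masked
  expect_equal(out$alignment$seq[4:5], c("AAGT", "AAGT"))  # shared kept
  expect_equal(nrow(out$mask_report), 1)
  expect_equal(out$mask_report$clone_id, "c3")
  expect_equal(out$mask_report$original, "G")
  expect_equal(out$mask_report$replacement, "A")
})

test_that("masking in a 2-clone set is skipped with a warning", {
  aln <- seq_tbl(c("c1", "c2"), c("AATT", "GATT"))
  expect_warning(out <- mask_singletons(aln), "reciprocal singleton")
  expect_true(out$skipped)
  expect_equal(out$alignment$seq, aln$seq)
  expect_equal(nrow(out$mask_report), 0)
})

test_that("masking never alters residues shared by two or more clones", {
  set.seed(71)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    base <- rand_seq(40)
    seqs <- vapply(seq_len(n), function(j) mutate_k(base, sample(0:3, 1)), "")
    aln <- seq_tbl(paste0("c", seq_len(n)), seqs)
    out <- mask_singletons(aln)
    m0 <- do.call(rbind, strsplit(aln$seq, ""))
    m1 <- do.call(rbind, strsplit(out$alignment$seq, ""))
    for (k in seq_len(ncol(m0))) {
      shared <- names(which(table(m0[, k]) >= 2))
      changed <- which(m0[, k] != m1[, k])
      expect_false(any(m0[changed, k] %in% shared))
    }
  }
})

test_that("unsupported polymorphism patterns (e.g. chimeras) are discarded", {
  # two templates differing at two sites + one recombinant of the two
  t1 <- "AAAATTTT"
  t2 <- "GAAATTTC"
  chimera <- "GAAATTTT"  # t2 start, t1 end
  aln <- seq_tbl(paste0("c", 1:5), c(t1, t1, t2, t2, chimera))
  out <- discard_unsupported(aln)
  expect_equal(out$discards$clone_id, "c5")
  expect_equal(nrow(out$retained), 4)
  # oracle by pattern enumeration over polymorphic columns
  mat <- do.call(rbind, strsplit(aln$seq, ""))
  poly <- apply(mat, 2, function(col) length(unique(col)) > 1)
  pat <- apply(mat[, poly, drop = FALSE], 1, paste, collapse = "")
  expect_equal(sum(pat == pat[5]), 1)  # the chimera's pattern is unique

  pairs <- seq_tbl(paste0("p", 1:4), c(t1, t1, t2, t2))
  expect_equal(nrow(discard_unsupported(pairs)$discards), 0)
  trio <- seq_tbl(paste0("q", 1:3), c(t1, t1, t2))
  expect_equal(discard_unsupported(trio)$discards$clone_id, "q3")
})

test_that("clustering emits >=2-clone variants at the identity threshold", {
  set.seed(13)
  t1 <- rand_seq(60)
  t2 <- mutate_k(t1, 6)  # 90% identity between the pairs
  aln <- seq_tbl(paste0("c", 1:4), c(t1, t1, t2, t2))
  calls <- cluster_variants(aln, threshold_pct = 95, region = "C")
  expect_equal(nrow(calls), 2)
  expect_setequal(calls$consensus, c(t1, t2))
  expect_true(all(calls$n_support == 2))
  # a singleton cluster emits no variant
  aln2 <- seq_tbl(paste0("c", 1:3), c(t1, t1, t2))
  calls2 <- cluster_variants(aln2, threshold_pct = 95)
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$n_support, 2)
  expect_error(cluster_variants(aln, threshold_pct = 40), "50, 100")
  expect_error(cluster_variants(aln, threshold_pct = 101), "50, 100")
})

test_that("minimum locus count is the ceiling of variants over ploidy", {
  expect_equal(min_loci(7, 2), 4)
  expect_equal(min_loci(2), 1)
  expect_equal(min_loci(6), 3)
  expect_equal(min_loci(0), 0)
  expect_equal(min_loci(5, 3), 2)
  expect_error(min_loci(3, 0), "ploidy")
  expect_error(min_loci(-1), "n_variants")
})

test_that("full diagnosis recovers simulated templates and is order-stable", {
  set.seed(29)
  tpl <- make_templates(4, 200, 0.06)
  p <- sim_params(pcr_error_rate = 5e-4, clones_per_template = 6)
  cl <- simulate_clones(tpl, p, seed = 4)
  dg <- diagnose_variants(cl$clones)
  expect_equal(nrow(dg$variants), 4)
  expect_setequal(dg$variants$consensus, tpl$seq)
  expect_equal(dg$min_loci, 2)
  # every masked cell is a true injected PCR error
  if (nrow(dg$mask_report) > 0) {
    truth_keys <- paste(cl$truth$errors$clone_id, cl$truth$errors$position)
    mask_keys <- paste(dg$mask_report$clone_id, dg$mask_report$column)
    expect_true(all(mask_keys %in% truth_keys))
  }
  # clone order permutation does not change the call set
  perm <- sample(nrow(cl$clones))
  dg2 <- diagnose_variants(cl$clones[perm, ])
  expect_setequal(dg2$variants$consensus, dg$variants$consensus)
  expect_equal(dg2$min_loci, dg$min_loci)
})

test_that("degenerate clone sets warn instead of failing", {
  ident <- clone_set(paste0("c", 1:4), rep("ACGTACGTACGT", 4))
  dg <- diagnose_variants(ident)
  expect_equal(nrow(dg$variants), 1)
  expect_equal(dg$min_loci, 1)
  set.seed(99)
  singles <- clone_set(paste0("s", 1:3),
                       c(rand_seq(40), rand_seq(40), rand_seq(40)))
  # unrelated clones: everything is discarded or unclustered
  dg2 <- suppressWarnings(diagnose_variants(singles))
  expect_equal(nrow(dg2$variants), 0)
  expect_equal(dg2$min_loci, 0)
  one <- clone_set("c1", "ACGTACGT")
  expect_warning(dg3 <- diagnose_variants(one), "fewer than 2")
  expect_equal(dg3$min_loci, 0)
  expect_equal(glance(dg3)$n_variants, 0)
})

test_that("zero PCR error rate leaves the mask report empty", {
  set.seed(8)
  tpl <- make_templates(3, 150, 0.06)
  p <- sim_params(pcr_error_rate = 0, clones_per_template = 5)
  cl <- simulate_clones(tpl, p, seed = 2)
  dg <- diagnose_variants(cl$clones)
  expect_equal(nrow(dg$mask_report), 0)
  expect_equal(nrow(cl$truth$errors), 0)
})
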