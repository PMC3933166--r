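test_that("percent identity follows the configured gap policy", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 100)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 75)
  expect_equal(pairwise_identity("AC-T", "ACGT"), 100)
  expect_equal(pairwise_identity("AC-T", "ACGT", "gap_mismatch"), 75)
  expect_warning(v <- pairwise_identity("--", "AA"), "undefined")
  expect_true(is.na(v))
  expect_error(pairwise_identity("ACG", "AC"), "equal")
})

test_that("identity matrix is symmetric, unit-diagonal, order-invariant", {
  set.seed(19)
  x <- seq_tbl(paste0("s", 1:5),
               vapply(1:5, function(i) mutate_k(strrep("ACGTT", 8), i), ""))
  m <- identity_matrix(x)
  expect_true(isSymmetric(unclass(m)))
  expect_equal(unname(diag(m)), rep(100, 5))
  expect_true(all(m >= 0 & m <= 100))
  perm <- c(3, 1, 5, 2, 4)
  m2 <- identity_matrix(x[perm, ])
  expect_equal(unclass(m2), unclass(m)[perm, perm], ignore_attr = TRUE)
  expect_equal(mean_offdiag(m2), mean_offdiag(m))
  expect_equal(nrow(tidy(m)), 20)  # all ordered off-diagonal pairs
})

test_that("majority consensus wins each column and flags ties", {
  x <- seq_tbl(paste0("s", 1:3), rep("ACGTAC", 3))
  expect_equal(consensus_seq(x)$seq, "ACGTAC")
  # 11 G vs 9 A in one column
  y <- seq_tbl(paste0("r", 1:20),
               c(rep("AGT", 11), rep("AAT", 9)))
  expect_equal(consensus_seq(y)$seq, "AGT")
  # tie broken alphabetically and flagged
  z <- seq_tbl(c("a", "b"), c("AGT", "ACT"))
  cz <- consensus_seq(z)
  expect_equal(cz$seq, "ACT")
  expect_equal(attr(cz, "ties")$column, 2L)
  # gap-majority columns are dropped
  w <- seq_tbl(paste0("w", 1:3), c("A-T", "A-T", "AGT"))
  cw <- consensus_seq(w)
  expect_equal(cw$seq, "AT")
  expect_equal(attr(cw, "dropped_columns"), 2L)
})

test_that("consensus is column-wise majority-optimal", {
  set.seed(83)
  x <- seq_tbl(paste0("s", 1:9),
               vapply(1:9, function(i) mutate_k(strrep("GATTACA", 6), 6), ""))
  cons <- consensus_seq(x)$seq
  mat <- do.call(rbind, strsplit(x$seq, ""))
  cc <- strsplit(cons, "")[[1]]
  for (k in seq_along(cc)) {
    tab <- table(mat[, k])
    expect_equal(unname(tab[cc[k]]), max(tab))
  }
  # consensus mean identity to rows >= every row's mean identity
  with_cons <- dplyr::bind_rows(x, seq_tbl("cons", cons))
  m <- identity_matrix(with_cons)
  prm <- per_row_mean(m)
  expect_gte(prm$mean_identity[prm$id == "cons"] + 1e-9,
             max(prm$mean_identity[prm$id != "cons"]))
})

test_that("positional profile recovers a planted conserved block", {
  set.seed(47)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- rand_seq(200, alphabet = aa20)
  others <- vapply(1:3, function(i) {
    ch <- strsplit(ref, "")[[1]]
    pos <- sample(51:200, round(0.2 * 150))  # block 1..50 untouched
    for (p in pos) ch[p] <- sample(setdiff(aa20, ch[p]), 1)
    paste(ch, collapse = "")
  }, "")
  x <- seq_tbl(c("ref", paste0("o", 1:3)), c(ref, others), alphabet = "aa")
  domains <- tibble::tibble(start = c(0L, 50L), end = c(50L, 200L),
                            label = c("block", "background"))
  prof <- positional_profile(x, "ref", domains)
  expect_true(all(prof$frac_identical >= 0 & prof$frac_identical <= 1))
  rm_ <- region_means(prof)
  expect_equal(rm_$mean_identity_pct[rm_$label == "block"], 100)
  expect_lt(abs(rm_$mean_identity_pct[rm_$label == "background"] - 80), 5)
  expect_error(positional_profile(x, "ref",
                                  tibble::tibble(start = 0, end = 300,
                                                 label = "too_long")),
               "outside")
  expect_error(positional_profile(x, "nope"), "not present")
  ident <- seq_tbl(c("a", "b", "c"), rep("MASK", 3), alphabet = "aa")
  p2 <- positional_profile(ident, "a",
                           tibble::tibble(start = 0, end = 4, label = "all"))
  expect_equal(region_means(p2)$mean_identity_pct, 100)
})

test_that("composition and codon usage satisfy their normalizations", {
  comp <- aa_composition("AAAG")
  expect_equal(comp$percent[comp$residue == "A"], 75)
  expect_equal(sum(comp$percent), 100)
  set.seed(3)
  comp2 <- aa_composition(translate_seq(rand_cds(200)))
  expect_equal(sum(comp2$percent), 100)

  cu <- codon_usage("GCAGCTGCCGCG")
  expect_equal(cu$fraction, rep(0.25, 4))
  expect_equal(gcw_fraction(cu), 0.5)
  cu2 <- codon_usage(rand_cds(300))
  sums <- dplyr::summarise(dplyr::group_by(cu2, amino_acid),
                           s = sum(fraction))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_warning(cu3 <- codon_usage("ATGTAAGCT"), "internal stop")
  no_ala <- codon_usage("ATGAAG")
  expect_warning(g <- gcw_fraction(no_ala), "undefined")
  expect_true(is.na(g))
})

test_that("positional codon table flags shared and divergent codon columns", {
  x <- seq_tbl(paste0("r", 1:4),
               c("ATGGCTGGT", "ATGGCAGGT", "ATGGCTGGT", "ATGGCGGGT"))
  pt <- positional_codon_table(x)
  expect_equal(pt$summary$uniform, c(TRUE, FALSE, TRUE))
  expect_equal(pt$summary$codon[1], "ATG")
  expect_equal(pt$summary$codon[3], "GGT")
  expect_true(is.na(pt$summary$codon[2]))
  broken <- seq_tbl(c("a", "b"), c("AT-GCT", "ATGGCT"))
  expect_error(positional_codon_table(broken), "frame-breaking")
})

test_that("region divergence orders regions by mean p-distance", {
  set.seed(61)
  base <- rand_seq(120)
  low <- seq_tbl(paste0("l", 1:4),
                 vapply(1:4, function(i) mutate_k(base, 2), ""))
  high <- seq_tbl(paste0("h", 1:4),
                  vapply(1:4, function(i) mutate_k(base, 24), ""))
  same <- seq_tbl(paste0("s", 1:3), rep(base, 3))
  rd <- region_divergence(list(identical = same, repeats = low,
                               terminal = high))
  expect_equal(rd$mean_p_distance[rd$region == "identical"], 0)
  expect_equal(rd$region, c("identical", "repeats", "terminal"))
})

test_that("the shipped repeat-domain annotation drives region means", {
  path <- system.file("extdata", "acsp1_repeat_domains.tsv",
                      package = "spidrhom")
  domains <- read_domains(path)
  expect_equal(domains$label, c("helix_rich", "unstructured",
                                "major_helical"))
  expect_equal(domains$end[1], 150)
  set.seed(91)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref <- rand_seq(199, alphabet = aa20)
  homolog <- function() {
    ch <- strsplit(ref, "")[[1]]
    for (p in sample(151:199, 20)) ch[p] <- sample(setdiff(aa20, ch[p]), 1)
    paste(ch, collapse = "")
  }
  x <- seq_tbl(c("ref", "a", "b"), c(ref, homolog(), homolog()),
               alphabet = "aa")
  prof <- positional_profile(x, "ref", domains)
  rm_ <- region_means(prof)
  expect_equal(rm_$mean_identity_pct[rm_$label == "helix_rich"], 100)
  expect_lt(rm_$mean_identity_pct[rm_$label == "unstructured"], 75)
})
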