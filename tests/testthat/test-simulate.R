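test_that("simulated genes have the requested architecture and are seeded", {
  p <- sim_params(repeat_len_nt = 150, n_repeats = 6, n_term_len = 90,
                  c_term_len = 60, flank_len_nt = 30)
  g <- simulate_gene(p, seed = 12)
  expect_equal(nchar(g$orf), 90 + 6 * 150 + 60)
  expect_equal(substr(g$orf, 1, 3), "ATG")
  expect_true(substr(g$orf, nchar(g$orf) - 2, nchar(g$orf)) %in%
                c("TAA", "TAG", "TGA"))
  expect_equal(sum(grepl("^R", g$truth$model$region)), 6)
  # repeat units are exact copies at generation zero
  m <- g$truth$model
  rr <- m[grepl("^R", m$region), ]
  units <- substring(g$orf, rr$start + 1, rr$end)
  expect_equal(length(unique(units)), 1L)
  # the ORF embedded in the flanks is discoverable
  iv <- find_longest_orf(g$gene)
  expect_equal(iv$start, g$truth$orf_interval$start)
  expect_equal(iv$end, g$truth$orf_interval$end)
  # determinism
  g2 <- simulate_gene(p, seed = 12)
  expect_identical(g2$gene$seq, g$gene$seq)
  g3 <- simulate_gene(p, seed = 13)
  expect_false(identical(g3$gene$seq, g$gene$seq))
  # no internal stops in frame
  aa <- translate_seq(g$orf)
  expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  expect_error(sim_params(repeat_len_nt = 100), "multiple of 3")
  expect_error(sim_params(pcr_error_rate = 2), "\\[0, 1\\]")
})

test_that("zero mutation leaves evolved loci identical to the ancestor", {
  p <- sim_params(repeat_len_nt = 120, n_repeats = 4, n_term_len = 90,
                  c_term_len = 60, flank_len_nt = 0, n_loci = 2,
                  mutation_rate = 0, conversion_events = 0,
                  n_generations = 50)
  g <- simulate_gene(p, seed = 1)
  e <- evolve_loci(g, p, seed = 2)
  expect_equal(nrow(e$genomes), 4)  # 2 loci x diploid
  expect_true(all(e$genomes$seq == g$orf))
})

test_that("gene conversion homogenizes repeats (sign test across seeds)", {
  p0 <- sim_params(repeat_len_nt = 120, n_repeats = 6, n_term_len = 90,
                   c_term_len = 60, flank_len_nt = 0, n_loci = 1,
                   ploidy = 1, mutation_rate = 1e-3, n_generations = 100)
  rep_ident <- function(orf, model) {
    rr <- model[grepl("^R", model$region), ]
    units <- substring(orf, rr$start + 1, rr$end)
    mean_offdiag(identity_matrix(seq_tbl(paste0("u", seq_along(units)),
                                         units)))
  }
  wins <- 0
  n_seeds <- 15
  for (s in seq_len(n_seeds)) {
    g <- simulate_gene(p0, seed = s)
    pc <- p0
    pc$conversion_events <- 5
    pn <- p0
    pn$conversion_events <- 0
    with_conv <- rep_ident(evolve_loci(g, pc, seed = s + 500)$genomes$seq[1],
                           g$truth$model)
    without <- rep_ident(evolve_loci(g, pn, seed = s + 900)$genomes$seq[1],
                         g$truth$model)
    wins <- wins + (with_conv > without)
  }
  p_val <- stats::binom.test(wins, n_seeds, alternative = "greater")$p.value
  expect_lt(p_val, 0.01)
})

test_that("a terminal mutation-rate multiplier makes terminals more divergent", {
  p <- sim_params(repeat_len_nt = 120, n_repeats = 6, n_term_len = 90,
                  c_term_len = 60, flank_len_nt = 0, n_loci = 2, ploidy = 2,
                  mutation_rate = 1e-3, n_generations = 100,
                  terminal_rate_multiplier = 5)
  hits <- 0
  for (s in 1:15) {
    g <- simulate_gene(p, seed = s)
    e <- evolve_loci(g, p, seed = s + 77)
    m <- g$truth$model
    rr <- m[grepl("^R", m$region), ]
    nt <- substring(e$genomes$seq, 1, m$end[m$region == "n_term"])
    rp <- substring(e$genomes$seq, rr$start[1] + 1, rr$end[nrow(rr)])
    dv <- function(ss) 1 - mean_offdiag(
      identity_matrix(seq_tbl(paste0("s", seq_along(ss)), ss))) / 100
    hits <- hits + (dv(nt) > dv(rp))
  }
  expect_gte(hits, 14)  # >= 95% of seeds (allowing one stochastic miss)
})

test_that("PCR errors are Binomial per clone and fully recorded", {
  set.seed(2)
  tpl <- tibble::tibble(template_id = "t1", region = "C",
                        seq = rand_seq(400))
  p <- sim_params(pcr_error_rate = 5e-3, clones_per_template = 10)
  counts <- integer(0)
  for (s in 1:30) {
    cl <- simulate_clones(tpl, p, seed = s)
    # every recorded error is a real template/clone difference
    for (k in seq_len(nrow(cl$truth$errors))) {
      e <- cl$truth$errors[k, ]
      clone <- cl$clones$seq[cl$clones$clone_id == e$clone_id]
      expect_equal(substr(clone, e$position, e$position), e$observed)
      expect_equal(substr(tpl$seq, e$position, e$position), e$original)
    }
    counts <- c(counts, vapply(cl$clones$clone_id, function(id) {
      sum(cl$truth$errors$clone_id == id)
    }, 0L))
  }
  expected <- 5e-3 * 400
  se <- sqrt(5e-3 * 400 * (1 - 5e-3)) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
  # error rate zero -> clones identical to the template
  p0 <- sim_params(pcr_error_rate = 0, clones_per_template = 4)
  cl0 <- simulate_clones(tpl, p0, seed = 1)
  expect_true(all(cl0$clones$seq == tpl$seq))
  # determinism
  clA <- simulate_clones(tpl, p, seed = 9)
  clB <- simulate_clones(tpl, p, seed = 9)
  expect_identical(clA$clones, clB$clones)
})

test_that("the end-to-end synthetic study recovers its own truth", {
  p <- sim_params(repeat_len_nt = 120, n_repeats = 5, n_term_len = 90,
                  c_term_len = 60, flank_len_nt = 30, n_loci = 3,
                  mutation_rate = 5e-4, terminal_rate_multiplier = 8,
                  n_generations = 200, pcr_error_rate = 5e-4,
                  clones_per_template = 6)
  st <- simulate_study(p, seed = 3, region = "C")
  expect_equal(st$truth$true_loci, 3)
  expect_gte(nrow(st$templates), 1)
  dg <- suppressWarnings(diagnose_variants(st$clones))
  expect_lte(dg$min_loci, 3)
  # template recovery is exact whenever the templates are mutually
  # separable at the 95% clustering threshold
  separable <- nrow(st$templates) < 2 || {
    im <- identity_matrix(seq_tbl(st$templates$template_id,
                                  st$templates$seq))
    max(im[upper.tri(im)]) < 94.8
  }
  if (separable) {
    expect_setequal(dg$variants$consensus, st$templates$seq)
  }
})
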