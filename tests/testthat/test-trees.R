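test_that("three-taxon NJ solves the three-point equations exactly", {
  d <- matrix(c(0, 3, 5,
                3, 0, 6,
                5, 6, 0), 3, 3, dimnames = list(c("A", "B", "C"),
                                                c("A", "B", "C")))
  tr <- nj_tree(d)
  # closed form: a = (dAB + dAC - dBC)/2, etc.
  pl <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(unname(pl["A"]), (3 + 5 - 6) / 2)
  expect_equal(unname(pl["B"]), (3 + 6 - 5) / 2)
  expect_equal(unname(pl["C"]), (5 + 6 - 3) / 2)
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3 taxa")
  d2 <- d
  d2[1, 2] <- 4
  expect_error(nj_tree(d2), "symmetric")
})

test_that("NJ recovers additive five-taxon trees exactly", {
  set.seed(7)
  tr <- ape::rtree(5, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.1, 1)
  d <- ape::cophenetic.phylo(tr)
  rec <- nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(rec)), 0,
               ignore_attr = TRUE)
  drec <- ape::cophenetic.phylo(rec)
  expect_equal(drec[rownames(d), colnames(d)], d, tolerance = 1e-8)
})

test_that("midpoint rooting splits the longest path in half", {
  tr <- ape::read.tree(text = "(A:1,B:3);")
  rooted <- midpoint_root(tr)
  depths <- ape::node.depth.edgelength(rooted)
  expect_equal(unname(depths[1:2]), c(2, 2))
  # symmetric quartet roots on the central edge
  q <- ape::read.tree(text = "((A:1,B:1):0.5,(C:1,D:1):0.5);")
  rq <- midpoint_root(ape::unroot(q))
  dq <- ape::node.depth.edgelength(rq)
  expect_equal(max(dq[1:4]), min(dq[1:4]))
  # random additive trees: midpoint minimizes the deepest leaf
  set.seed(3)
  for (i in 1:10) {
    t0 <- ape::rtree(6, rooted = FALSE)
    t0$edge.length <- runif(length(t0$edge.length), 0.1, 2)
    rt <- midpoint_root(t0)
    deepest <- max(ape::node.depth.edgelength(rt)[1:6])
    d <- ape::cophenetic.phylo(t0)
    expect_equal(deepest, max(d) / 2, tolerance = 1e-8)
  }
})

test_that("monophyly matches a bipartition-enumeration oracle", {
  set.seed(15)
  tr <- ape::rtree(7, rooted = FALSE)
  tips <- tr$tip.label
  expect_true(is_monophyletic(tr, tips[1]))
  expect_true(is_monophyletic(tr, tips))
  expect_error(is_monophyletic(tr, "nope"), "unknown leaf")
  # oracle: enumerate the bipartition induced by each internal edge
  biparts <- ape::prop.part(tr)
  bip_sets <- lapply(biparts, function(ix) sort(tips[ix]))
  all_sets <- c(bip_sets, lapply(bip_sets, function(s) sort(setdiff(tips, s))))
  for (i in 1:20) {
    sub <- sort(sample(tips, sample(2:5, 1)))
    oracle <- any(vapply(all_sets, identical, TRUE, y = sub))
    expect_equal(is_monophyletic(tr, sub), oracle)
  }
})

test_that("bootstrap supports are seeded, reproducible and informative", {
  set.seed(4)
  base <- rand_seq(200)
  ga <- mutate_k(base, 60)
  aln <- seq_tbl(paste0("s", 1:4),
                 c(mutate_k(base, 2), mutate_k(base, 2),
                   mutate_k(ga, 2), mutate_k(ga, 2)))
  bt <- bootstrap_support(aln, n_reps = 100, seed = 7)
  bt2 <- bootstrap_support(aln, n_reps = 100, seed = 7)
  expect_identical(bt$node.label, bt2$node.label)
  # the deep split between the two diverged pairs is near-certain
  expect_true(is_monophyletic(bt, c("s1", "s2")))
  expect_gte(max(bt$node.label, na.rm = TRUE), 0.99)
  expect_error(bootstrap_support(aln[1:2, ], 10, 1), ">= 3")
  short <- seq_tbl(paste0("t", 1:3), rep("A", 3))
  expect_error(bootstrap_support(short, 10, 1), "2 columns")
})

test_that("newick output round-trips through read and write", {
  set.seed(9)
  tr <- ape::rtree(6)
  tr$node.label <- c("", "0.98", "0.75", "1.00", "0.50")
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- read_newick(path)
  expect_equal(back$tip.label, tr$tip.label)
  expect_equal(back$edge, tr$edge)
  expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-8)
  path2 <- tempfile(fileext = ".nwk")
  write_newick(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("species-specific repeat clusters group in the NJ tree", {
  set.seed(25)
  p <- sim_params(repeat_len_nt = 120, n_repeats = 5, n_term_len = 90,
                  c_term_len = 60, flank_len_nt = 0, n_loci = 1, ploidy = 1,
                  mutation_rate = 5e-4, n_generations = 60,
                  conversion_events = 2)
  anc <- simulate_gene(p, seed = 1)
  units_of <- function(orf) {
    m <- anc$truth$model
    rr <- m[grepl("^R", m$region), ]
    substring(orf, rr$start + 1, rr$end)
  }
  # two species evolved independently from the ancestor for a long time
  spA <- evolve_loci(anc, p, seed = 11)$genomes$seq[1]
  pB <- p
  pB$n_generations <- 400
  spB <- evolve_loci(anc, pB, seed = 22)$genomes$seq[1]
  aln <- seq_tbl(c(paste0("A_R", 1:5), paste0("B_R", 1:5)),
                 c(units_of(spA), units_of(spB)))
  tr <- nj_tree(p_distance_matrix(aln))
  expect_true(is_monophyletic(tr, paste0("A_R", 1:5)))
  expect_true(is_monophyletic(tr, paste0("B_R", 1:5)))
})
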