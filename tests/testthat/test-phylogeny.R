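test_that("distance matrices follow the p-distance and Poisson formulas", {
  blk <- aligned_block(c(a = "AAAA", b = "AAAT", c = "AAAA"))
  Dp <- distance_matrix(blk, model = "p-distance")
  expect_equal(Dp["a", "b"], 0.25)
  expect_equal(Dp["a", "c"], 0)
  expect_equal(Dp, t(Dp))
  expect_equal(diag(Dp), setNames(rep(0, 3), c("a", "b", "c")))
  Dpois <- distance_matrix(blk, model = "poisson")
  expect_equal(Dpois["a", "b"], -log(0.75))

  # pairwise deletion of gap columns
  gapped <- aligned_block(c(a = "AA-A", b = "AATA", c = "CCCC"))
  expect_equal(distance_matrix(gapped, model = "p-distance")["a", "b"], 0)

  sat <- aligned_block(c(a = "AAAA", b = "CCCC", c = "AAAA"))
  expect_error(distance_matrix(sat, model = "poisson"), "saturated")
  expect_equal(distance_matrix(sat, model = "p-distance")["a", "b"], 1)
})

test_that("NJ recovers the worked additive 4-taxon case exactly", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  # four-point condition sanity: AB + CD <= max of the other two sums
  expect_true(D["A", "B"] + D["C", "D"] <=
                max(D["A", "C"] + D["B", "D"], D["A", "D"] + D["B", "C"]))
  tr <- nj_tree(D)
  cd <- cophenetic(tr)[rownames(D), colnames(D)]
  expect_equal(cd, D, tolerance = 1e-12)
  # the AB|CD split is present
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  expect_equal(attr(tr, "negative_clamped"), 0L)
})

test_that("3 taxa resolve to the closed-form star lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(len, c(a = 1, b = 2, c = 3))
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ is consistent on random additive matrices (n <= 12)", {
  set.seed(20)
  for (k in 1:25) {
    n <- sample(4:12, 1)
    inst <- random_additive(n)
    tr <- nj_tree(inst$D)
    cd <- cophenetic(tr)[rownames(inst$D), colnames(inst$D)]
    expect_lt(max(abs(cd - inst$D)), 1e-9)
    expect_equal(phangorn::RF.dist(ape::unroot(inst$tree), tr), 0)
  }
})

test_that("NJ agrees with the reference implementation on random matrices", {
  set.seed(30)
  for (k in 1:10) {
    n <- sample(5:10, 1)
    M <- matrix(runif(n * n, 0.2, 2), n, n)
    D <- (M + t(M)) / 2
    diag(D) <- 0
    dimnames(D) <- list(letters[1:n], letters[1:n])
    expect_equal(phangorn::RF.dist(nj_tree(D), ape::nj(D)), 0)
  }
})

test_that("NJ equals exhaustive least-squares search on 5-taxon additive inputs", {
  set.seed(40)
  for (k in 1:20) {
    inst <- random_additive(5)
    tr <- nj_tree(inst$D)
    best <- ls_best_topology(inst$D)
    expect_lt(best$ssq, 1e-12)
    expect_equal(phangorn::RF.dist(tr, best$tree), 0)
  }
})

test_that("bootstrap on duplicated identical columns gives full support", {
  pat <- c(a = "AC", b = "AC", c = "CG", d = "CG", e = "GT", f = "GT")
  blk <- aligned_block(setNames(strrep(pat, 15), names(pat)))
  tr <- bootstrap_support(blk, replicates = 50, seed = 5, model = "p-distance")
  expect_true(all(tr$node.label == 100))
  expect_equal(attr(tr, "failed_replicates"), 0L)
})

test_that("a planted deep split earns high bootstrap support at 500 replicates", {
  set.seed(8)
  groupA <- paste(rep("A", 30), collapse = "")
  groupB <- paste(rep("C", 30), collapse = "")
  noise <- function() paste(sample(AA <- c("A", "C", "G", "T"), 40, TRUE),
                            collapse = "")
  seqs <- c(
    setNames(paste0(groupA, replicate(4, noise())), paste0("x", 1:4)),
    setNames(paste0(groupB, replicate(4, noise())), paste0("y", 1:4)))
  blk <- aligned_block(seqs)
  tr <- bootstrap_support(blk, replicates = 500, seed = 13, model = "p-distance")
  expect_gte(support_of_split(tr, paste0("x", 1:4)), 95)
})

test_that("zero replicates yield an unsupported, flagged tree", {
  blk <- aligned_block(c(a = "AAAA", b = "AATT", c = "CCTT", d = "CCGG"))
  tr <- bootstrap_support(blk, replicates = 0, seed = 1, model = "p-distance")
  expect_true(all(is.na(tr$node.label)))
  expect_equal(attr(tr, "bootstrap_replicates"), 0L)
})

test_that("subclass clades are monophyletic on planted typical-gene alignments", {
  sim <- simulate_genome(sim_config(seed = 12, n_background_genes = 40))
  calls <- classify_nlr(sim$genes, sim$domain_hits, sim$ref_hits)
  typ <- calls[calls$typical, ]
  aln <- nbs_alignment(typ, sim$proteins, sim$domain_hits)
  tr <- nj_tree(distance_matrix(aln))
  comp <- clade_composition(tr, calls)
  expect_equal(sort(comp$subclass), c("CNL", "RNL", "TNL"))
  expect_true(all(comp$monophyletic))
  expect_equal(sum(comp$n_tips), nrow(typ))
  # single-subclass input trivially forms one clade
  one <- clade_composition(tr, transform(calls, subclass = "CNL"))
  expect_true(one$monophyletic)
})
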