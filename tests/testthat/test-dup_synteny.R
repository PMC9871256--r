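test_that("homology graph hygiene: self-hits, reciprocal dedup, top-n", {
  h <- data.frame(
    query_id = c("A", "B", "A", rep("Q", 8)),
    subject_id = c("B", "A", "A", sprintf("S%d", 1:8)),
    pct_identity = 90, ali_length = 300, mismatches = 10, gap_open = 0,
    q_start = 1, q_end = 300, s_start = 1, s_end = 300,
    e_value = c(1e-30, 1e-28, 0, 10^-(20:13)),
    bit_score = 500, self = FALSE, stringsAsFactors = FALSE)
  p <- build_homology_graph(h)
  expect_equal(p[p$gene_a == "A", c("gene_a", "gene_b")],
               data.frame(gene_a = "A", gene_b = "B"))
  expect_equal(sum(p$gene_a == "A" & p$gene_b == "B"), 1L)  # dedup
  expect_false(any(p$gene_a == p$gene_b))                   # no self
  # 8 subjects for one query -> the 5 best by E-value are kept
  qs <- p[p$gene_a == "Q" | p$gene_b == "Q", ]
  expect_equal(nrow(qs), 5L)
  expect_setequal(setdiff(unlist(qs[1:2]), "Q"), sprintf("S%d", 1:5))
})

test_that("chain_anchors reproduces the worked diagonal, gap and inverted cases", {
  # perfect diagonal of 5: one block, score 5*50 with zero gap penalty
  out <- chain_anchors(anchors_from_ranks(1:5, 1:5), min_anchors = 5)
  expect_equal(nrow(out$blocks), 1L)
  expect_equal(out$blocks$n_anchors, 5L)
  expect_equal(out$blocks$chain_score, 250)
  expect_equal(out$blocks$orientation, "same")

  # breaking the run beyond max_rank_gap leaves only 4 chainable: no block
  out2 <- chain_anchors(anchors_from_ranks(c(1:4, 40), c(1:4, 5)),
                        min_anchors = 5, max_rank_gap = 25)
  expect_equal(nrow(out2$blocks), 0L)

  # inverted run is chained with orientation recorded
  out3 <- chain_anchors(anchors_from_ranks(1:5, 9:5), min_anchors = 5)
  expect_equal(nrow(out3$blocks), 1L)
  expect_equal(out3$blocks$orientation, "inverted")
  expect_equal(out3$blocks$chain_score, 250)

  expect_error(chain_anchors(anchors_from_ranks(1:5, 1:5), min_anchors = 1),
               "at least 2")
})

test_that("chain_anchors equals exhaustive monotone-subset search", {
  set.seed(101)
  for (k in 1:40) {
    n <- sample(6:11, 1)
    ra <- sample.int(30, n)
    rb <- sample.int(30, n)
    mina <- sample(3:5, 1)
    out <- chain_anchors(anchors_from_ranks(ra, rb), min_anchors = mina)
    got <- if (nrow(out$blocks)) max(out$blocks$chain_score) else -Inf
    want <- oracle_best_chain(ra, rb, min_anchors = mina)
    expect_equal(got, want, info = sprintf("instance %d", k))
  }
})

test_that("duplicate classification follows the stated priority", {
  # ten genes in rank order on chr3, one on chr9
  ranks <- data.frame(gene_id = sprintf("g%02d", 1:13),
                      chromosome = c(rep("chr3", 12), "chr9"),
                      rank = c(1:12, 1), stringsAsFactors = FALSE)
  pairs <- data.frame(gene_a = c("g07", "g02", "g01", "g05"),
                      gene_b = c("g08", "g07", "g13", "g12"),
                      stringsAsFactors = FALSE)
  lab <- classify_duplicates(ranks$gene_id, pairs, NULL, ranks)
  lv <- setNames(lab$label, lab$gene_id)
  expect_equal(unname(lv["g07"]), "tandem")      # rank gap 1 beats gap 5 to g02
  expect_equal(unname(lv["g08"]), "tandem")
  expect_equal(unname(lv["g02"]), "proximal")    # gap 5 <= 10
  expect_equal(unname(lv["g01"]), "dispersed")   # homolog on another chromosome
  expect_equal(unname(lv["g05"]), "proximal")    # gap 7 <= 10
  expect_equal(unname(lv["g03"]), "singleton_no_homolog")
  # block membership outranks everything
  blk <- list(anchors = data.frame(gene_a = "g07", gene_b = "g13"))
  lab2 <- classify_duplicates(ranks$gene_id, pairs, blk, ranks)
  expect_equal(lab2$label[lab2$gene_id == "g07"], "segmental")
  # labels are independent of pair row order and partition the gene set
  lab3 <- classify_duplicates(ranks$gene_id, pairs[sample(4), ], NULL, ranks)
  expect_equal(lab3, lab)
  expect_equal(nrow(lab), 13L)
  expect_false(anyNA(lab$label))
})

test_that("planted duplication types and blocks are recovered exactly", {
  sim <- simulate_genome(sim_config(seed = 6, n_background_genes = 60))
  calls <- classify_nlr(sim$genes, sim$domain_hits, sim$ref_hits)
  pairs <- build_homology_graph(sim$homology)
  ranks <- compute_gene_ranks(sim$genes)
  blocks <- chain_anchors(make_anchors(pairs, ranks))
  lab <- classify_duplicates(calls$gene_id, pairs, blocks, ranks)
  tr <- sim$truth$nlr
  expect_equal(setNames(lab$label, lab$gene_id)[tr$gene_id],
               setNames(tr$dup_label, tr$gene_id))
  expect_equal(unname(table(lab$label)["tandem"]), 16L)
  expect_equal(unname(table(lab$label)["segmental"]), 12L)

  sp <- syntenic_pairs(blocks, calls$gene_id)
  expect_equal(nrow(sp$pairs), 6L)
  st <- sim$truth$syntenic_nlr_pairs
  expect_setequal(paste(pmin(sp$pairs$gene_a, sp$pairs$gene_b),
                        pmax(sp$pairs$gene_a, sp$pairs$gene_b)),
                  paste(pmin(st$gene_src, st$gene_tgt),
                        pmax(st$gene_src, st$gene_tgt)))
  expect_equal(syntenic_pairs(chain_anchors(make_anchors(pairs[0, ], ranks)),
                              calls$gene_id)$pairs |> nrow(), 0L)
})

test_that("cross-species chaining recovers conserved runs and rejects shuffles", {
  ra <- data.frame(gene_id = sprintf("a%02d", 1:30), chromosome = "A1",
                   rank = 1:30, stringsAsFactors = FALSE)
  rb <- data.frame(gene_id = sprintf("b%02d", 1:30), chromosome = "B1",
                   rank = 1:30, stringsAsFactors = FALSE)
  orth <- data.frame(gene_a = sprintf("a%02d", 10:15),
                     gene_b = sprintf("b%02d", 3:8), stringsAsFactors = FALSE)
  out <- cross_species_synteny(orth, ra, rb)
  expect_equal(nrow(out$blocks), 1L)
  expect_equal(out$blocks$n_anchors, 6L)
  expect_equal(nrow(out$anchors), 6L)

  # a fixed shuffle of the partner order (no monotone run of 5) leaves no block
  shuf <- orth
  shuf$gene_b <- sprintf("b%02d", c(14, 22, 3, 27, 8, 18))
  out2 <- cross_species_synteny(shuf, ra, rb)
  expect_equal(nrow(out2$blocks), 0L)
})

test_that("self-comparison reproduces intra-species blocks", {
  sim <- simulate_genome(sim_config(seed = 6, n_background_genes = 60))
  pairs <- build_homology_graph(sim$homology)
  ranks <- compute_gene_ranks(sim$genes)
  intra <- chain_anchors(make_anchors(pairs, ranks))
  self <- cross_species_synteny(pairs, ranks, ranks)
  expect_equal(nrow(self$blocks), nrow(intra$blocks))
  expect_equal(sort(self$anchors$gene_a), sort(intra$anchors$gene_a))
})
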