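test_that("NBS candidate filter keeps E <= 1e-4 via the best hit per protein", {
  h <- rbind(mk_hits("keep", "NB-ARC", ev = 1e-5),
             mk_hits("drop", "NB-ARC", ev = 2e-4),
             mk_hits("best", "NB-ARC", ev = 1e-3),
             mk_hits("best", "NB-ARC", ev = 1e-6))
  expect_equal(filter_nbs_candidates(h), c("best", "keep"))
  # boundary: exactly 1e-4 is retained (inclusive cutoff)
  expect_equal(filter_nbs_candidates(mk_hits("b", "NB-ARC", ev = 1e-4)), "b")
  # only hmm-source NBS rows count
  expect_equal(filter_nbs_candidates(mk_hits("c", "NB-ARC", ev = 1e-9, source = "cdd")),
               character(0))
  # monotone in e_max
  loose <- filter_nbs_candidates(h, e_max = 1)
  expect_true(all(filter_nbs_candidates(h) %in% loose))
})

test_that("homology screen eliminates candidates without reference support", {
  rh <- data.frame(query_id = c("a", "b"), subject_id = c("AtCNL001", "AtTNL002"),
                   e_value = c(1e-20, 1e-3), stringsAsFactors = FALSE)
  expect_equal(homology_screen(c("a", "b", "c"), rh), "a")
  expect_equal(homology_screen(c("a", "b", "c"), rh, e_max = 1), c("a", "b"))
  expect_error(homology_screen("a", rh[0, ]), "non-empty reference")
})

test_that("subclass assignment follows domain priority and homology fallback", {
  tnl <- rbind(mk_hits("p", "TIR"), mk_hits("p", "NB-ARC"), mk_hits("p", "LRR_8"))
  expect_equal(assign_subclass(tnl)$subclass, "TNL")
  rnl <- rbind(mk_hits("p", "RPW8"), mk_hits("p", "NB-ARC"), mk_hits("p", "LRR_8"))
  expect_equal(assign_subclass(rnl)$subclass, "RNL")
  # RPW8 beats TIR and CC when several N-terminal domains are present
  multi <- rbind(rnl, mk_hits("p", "TIR"))
  s <- assign_subclass(multi)
  expect_equal(s$subclass, "RNL")
  expect_true(s$multi_nterm)
  # bare NBS: fallback decides; with no fallback, low-confidence CNL
  bare <- mk_hits("p", "NB-ARC")
  expect_equal(assign_subclass(bare, fallback = "CNL")$subclass, "CNL")
  nofb <- assign_subclass(bare)
  expect_equal(nofb$subclass, "CNL")
  expect_true(nofb$low_confidence)
  expect_error(assign_subclass(mk_hits("p", "TIR")), "NBS")
})

test_that("architecture codes record present parts in N-to-C order", {
  cn <- rbind(mk_hits("p", "RX-CC_like"), mk_hits("p", "NB-ARC"))
  expect_equal(architecture_code(cn, "CNL"), list(code = "CN", typical = FALSE))
  nl <- rbind(mk_hits("p", "NB-ARC"), mk_hits("p", "LRR_8"))
  expect_equal(architecture_code(nl, "TNL")$code, "NL")
  rnl <- rbind(mk_hits("p", "RPW8"), mk_hits("p", "NB-ARC"), mk_hits("p", "LRR_8"))
  expect_equal(architecture_code(rnl, "RNL"), list(code = "RNL", typical = TRUE))
  expect_equal(architecture_code(mk_hits("p", "NB-ARC"), "CNL")$code, "N")
})

test_that("integrated domains need E < 1e-5 and near-complete model coverage", {
  h <- rbind(mk_hits("p", "PLN03210", ev = 1e-8, source = "cdd"),
             mk_hits("p", "PPP1R42", ev = 1e-4, source = "cdd"),
             mk_hits("p", "CDC6", ev = 1e-9, source = "cdd", coverage = 0.5),
             mk_hits("p", "PLN03210", ev = 1e-7, source = "cdd"),
             mk_hits("p", "NB-ARC", ev = 1e-40))
  expect_equal(retain_integrated_domains(h), "PLN03210")  # deduplicated
  expect_equal(retain_integrated_domains(mk_hits("p", "PLN03210", ev = 1e-5,
                                                 source = "cdd")),
               character(0))  # strict bound
})

test_that("aliases are serial genome-wide with positional ordering and tiebreaks", {
  calls <- data.frame(
    gene_id = c("z", "y", "x", "w", "v", "u"),
    chromosome = c("chr2", "chr1", "chr1", "chr1", "chr1", "chr1"),
    start = c(50L, 100L, 200L, 300L, 400L, 400L),
    stringsAsFactors = FALSE)
  out <- assign_aliases(calls)
  expect_equal(out$alias, c("Mru1c1", "Mru1c2", "Mru1c3", "Mru1c4", "Mru1c5",
                            "Mru2c6"))
  # 5th NLR genome-wide on chr1 -> Mru1c5; same-start ties by gene_id
  expect_equal(out$gene_id[4:5], c("u", "v"))
  # order of input rows does not matter
  expect_equal(assign_aliases(calls[sample(6), ])$alias, out$alias)
})

test_that("classification summary partitions the call set", {
  sim <- simulate_genome(sim_config(seed = 3, n_background_genes = 40))
  calls <- classify_nlr(sim$genes, sim$domain_hits, sim$ref_hits)
  tb <- classification_summary(calls)
  expect_equal(sum(tb$count), nrow(calls))
  expect_equal(attr(tb, "total"), nrow(calls))
  tr <- sim$truth$nlr
  planted <- as.data.frame(table(subclass = tr$subclass, code = tr$code),
                           stringsAsFactors = FALSE)
  planted <- planted[planted$Freq > 0, ]
  planted <- planted[order(planted$subclass, planted$code), ]
  expect_equal(tb$count, planted$Freq)
  empty <- classification_summary(calls[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("classification is deterministic and recovers planted architectures", {
  sim <- simulate_genome(sim_config(seed = 5, n_background_genes = 60))
  calls <- classify_nlr(sim$genes, sim$domain_hits, sim$ref_hits)
  # row-order invariance of the evidence tables
  perm <- sim$domain_hits[sample(nrow(sim$domain_hits)), ]
  calls2 <- classify_nlr(sim$genes, perm, sim$ref_hits[sample(nrow(sim$ref_hits)), ])
  expect_equal(calls2$alias, calls$alias)
  expect_equal(calls2$code, calls$code)
  tr <- sim$truth$nlr
  m <- match(tr$gene_id, calls$gene_id)
  expect_false(anyNA(m))
  expect_equal(calls$subclass[m], tr$subclass)
  expect_equal(calls$code[m], tr$code)
  expect_equal(calls$typical[m], tr$typical)
  # integrated domains recovered where planted
  has_id <- nzchar(tr$integrated)
  expect_equal(vapply(calls$integrated[m[has_id]], paste, character(1)),
               tr$integrated[has_id])
  # decoys never enter the call set
  expect_false(any(sim$truth$decoys %in% calls$gene_id))
})
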