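test_that("chromosome counts partition the call set in natural order", {
  calls <- mk_calls(c(rep("chr2", 5), rep("chr10", 3), rep("chr1", 10)),
                    start = 1:18 * 1000, end = 1:18 * 1000 + 500)
  cc <- chromosome_counts(calls)
  expect_equal(names(cc), c("chr1", "chr2", "chr10"))
  expect_equal(unname(cc), c(10L, 5L, 3L))
  expect_equal(sum(cc), nrow(calls))
  expect_equal(length(chromosome_counts(calls[0, ])), 0L)
})

test_that("sliding density counts midpoints per window with conservation", {
  calls <- mk_calls("chr1", start = c(99000, 500000), end = c(101000, 502000))
  tr <- sliding_density(calls, chr_lengths = c(chr1 = 750000))
  # gene midpoint 100000 is counted by the first window [1, 250000)
  expect_equal(tr$count[tr$window_start == 1][1], 1L)
  # a window covering neither midpoint (100000 and 501000) counts zero
  expect_equal(sum(tr$count[tr$window_start == 150001]), 0L)
  # step == window gives non-overlapping bins that conserve the gene count
  bins <- sliding_density(calls, chr_lengths = c(chr1 = 750000),
                          window = 250000, step = 250000)
  expect_equal(sum(bins$count), 2L)
  # genes with midpoints more than a window apart never share a window
  both <- sliding_density(calls, chr_lengths = c(chr1 = 750000))
  expect_true(all(both$count <= 1L))
  expect_error(sliding_density(calls, window = 10, step = 100), "window >= step")
})

test_that("cluster detection follows the strict <250 kb intergenic rule", {
  calls <- mk_calls("chr1", start = c(100000, 200000, 600000),
                    end = c(110000, 210000, 610000))
  out <- detect_clusters(calls)
  expect_equal(nrow(out$clusters), 1L)
  expect_equal(out$clusters$n, 2L)
  expect_equal(out$clusters$members[[1]], c("g01", "g02"))
  expect_equal(out$singletons, "g03")

  # gap of exactly 250,000 bp does NOT join genes
  boundary <- mk_calls("chr1", start = c(100000, 360000), end = c(110000, 370000))
  expect_equal(nrow(detect_clusters(boundary)$clusters), 0L)
  just_under <- mk_calls("chr1", start = c(100000, 359999), end = c(110000, 370000))
  expect_equal(nrow(detect_clusters(just_under)$clusters), 1L)

  # overlapping genes (gap 0) always cluster
  over <- mk_calls("chr1", start = c(100, 150), end = c(200, 220))
  expect_equal(detect_clusters(over)$clusters$n, 2L)
})

test_that("clustering is idempotent, monotone in max_gap, and a partition", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 30
    calls <- mk_calls(sample(paste0("chr", 1:3), n, TRUE),
                      start = sort(sample.int(5e6, n)), end = 0)
    calls$end <- calls$start + sample(2000:8000, n, TRUE)
    out <- detect_clusters(calls)
    members <- unlist(out$clusters$members)
    expect_equal(sort(c(members, out$singletons)), sort(calls$alias))
    expect_equal(anyDuplicated(c(members, out$singletons)), 0L)
    # components never increase when max_gap grows
    comp <- function(mg) {
      o <- detect_clusters(calls, max_gap = mg)
      nrow(o$clusters) + length(o$singletons)
    }
    gaps <- c(1e4, 1e5, 2.5e5, 1e6)
    expect_true(all(diff(vapply(gaps, comp, numeric(1))) <= 0))
    # idempotence: the partition's units (cluster spans + singletons) are
    # mutually separated, so re-clustering them merges nothing
    spans <- out$clusters
    sing <- calls[calls$alias %in% out$singletons, c("alias", "chromosome",
                                                     "start", "end")]
    units <- rbind(data.frame(alias = spans$cluster_id,
                              chromosome = spans$chromosome,
                              start = spans$start, end = spans$end,
                              stringsAsFactors = FALSE), sing)
    again <- detect_clusters(units)
    expect_equal(nrow(again$clusters), 0L)
    expect_equal(sort(again$singletons), sort(units$alias))
  }
})

test_that("planted clusters are recovered exactly, including the 7-gene cluster", {
  sim <- simulate_genome(sim_config(seed = 2, n_background_genes = 60))
  calls <- classify_nlr(sim$genes, sim$domain_hits, sim$ref_hits)
  out <- detect_clusters(calls)
  tr <- sim$truth
  expect_equal(nrow(out$clusters), nrow(tr$clusters))
  expect_equal(sort(out$clusters$n), sort(tr$clusters$n))
  expect_equal(max(out$clusters$n), 7L)
  alias2gene <- setNames(calls$gene_id, calls$alias)
  det <- lapply(out$clusters$members, function(a) sort(unname(alias2gene[a])))
  want <- lapply(split(tr$nlr$gene_id[!is.na(tr$nlr$cluster)],
                       tr$nlr$cluster[!is.na(tr$nlr$cluster)]), sort)
  for (s in want)
    expect_true(any(vapply(det, identical, logical(1), y = s)))
})

test_that("cluster summary statistics are internally consistent", {
  calls <- mk_calls("chr1", start = c(1e5, 2e5), end = c(1.1e5, 2.1e5))
  s <- cluster_summary(detect_clusters(calls))
  expect_equal(s$mean_cluster_size, 2)
  expect_equal(s$clustered$pct, 100.0)
  expect_equal(s$singleton$count, 0L)
  # percentages recompute from stored counts and complement each other
  sim <- simulate_genome(sim_config(seed = 2, n_background_genes = 60))
  calls2 <- classify_nlr(sim$genes, sim$domain_hits, sim$ref_hits)
  s2 <- cluster_summary(detect_clusters(calls2), total = nrow(calls2))
  expect_equal(s2$clustered$count + s2$singleton$count, nrow(calls2))
  expect_lt(abs(s2$clustered$pct + s2$singleton$pct - 100), 0.11)
})
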