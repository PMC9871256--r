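# Independent oracles and small fixture builders used across the suite.

# Exhaustive monotone-chain search: best score over ALL anchor subsets that
# form a valid chain (per-link rank gaps in (0, max_rank_gap], second axis
# monotone increasing or decreasing) with at least min_anchors anchors.
# Ranks are assumed distinct on each axis.
oracle_best_chain <- function(ra, rb, min_anchors, max_rank_gap = 25,
                              gap_penalty = -1, match_score = 50) {
  n <- length(ra)
  best <- -Inf
  bits <- bitwShiftL(1L, 0:(n - 1L))
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, bits) != 0L)
    if (length(idx) < min_anchors) next
    o <- order(ra[idx])
    s <- idx[o]
    dra <- diff(ra[s]); drb <- diff(rb[s])
    ok_f <- all(dra > 0 & dra <= max_rank_gap) &&
      all(drb > 0 & drb <= max_rank_gap)
    ok_r <- all(dra > 0 & dra <= max_rank_gap) &&
      all(-drb > 0 & -drb <= max_rank_gap)
    if (!ok_f && !ok_r) next
    sc <- length(s) * match_score + gap_penalty * sum(dra + abs(drb) - 2)
    if (sc > best) best <- sc
  }
  best
}

# Wrap a rank-pair instance as a chain_anchors() input on one context.
anchors_from_ranks <- function(ra, rb) {
  data.frame(gene_a = sprintf("a%02d", seq_along(ra)),
             gene_b = sprintf("b%02d", seq_along(rb)),
             chr_a = "c1", chr_b = "c2", rank_a = ra, rank_b = rb,
             score = 50, stringsAsFactors = FALSE)
}

# Exhaustive least-squares topology search for small taxon sets: fit branch
# lengths of every unrooted topology by ordinary least squares on the
# path-incidence system and return the minimum-SSQ tree.
ls_best_topology <- function(D) {
  taxa <- rownames(D)
  n <- length(taxa)
  tops <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  prs <- t(combn(n, 2))
  dvec <- D[prs]
  best <- NULL; best_ss <- Inf
  for (ti in seq_along(tops)) {
    tp <- tops[[ti]]  # [[ re-attaches the shared tip labels of a multiPhylo
    key <- paste(pmin(tp$edge[, 1], tp$edge[, 2]),
                 pmax(tp$edge[, 1], tp$edge[, 2]))
    A <- matrix(0, nrow(prs), nrow(tp$edge))
    for (k in seq_len(nrow(prs))) {
      pth <- ape::nodepath(tp, prs[k, 1], prs[k, 2])
      ek <- paste(pmin(pth[-length(pth)], pth[-1]),
                  pmax(pth[-length(pth)], pth[-1]))
      A[k, match(ek, key)] <- 1
    }
    x <- qr.coef(qr(A), dvec)
    ss <- sum((A %*% x - dvec)^2)
    if (ss < best_ss - 1e-12) { best_ss <- ss; best <- tp }
  }
  list(tree = best, ssq = best_ss)
}

# Random additive instance: unrooted random topology with positive branch
# lengths and its exact path-distance matrix.
random_additive <- function(n) {
  tp <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
  D <- cophenetic(tp)
  D <- D[sort(rownames(D)), sort(rownames(D))]
  list(tree = tp, D = D)
}

# Bootstrap support of a specific tip bipartition (by tip labels), using
# the node.label/prop.part alignment of ape trees.
support_of_split <- function(tree, tips) {
  idx <- sort(match(tips, tree$tip.label))
  comp <- sort(setdiff(seq_along(tree$tip.label), idx))
  splits <- ape::prop.part(tree)
  for (i in seq_along(splits)) {
    s <- sort(splits[[i]])
    if (identical(s, idx) || identical(s, comp)) return(tree$node.label[i])
  }
  NA_real_
}

# Minimal in-memory domain-hit builder.
mk_hits <- function(protein, domain, s = 1L, e = 100L, ev = 1e-40,
                    source = "hmm", coverage = 1) {
  as_domain_hits(data.frame(protein_id = protein, domain_name = domain,
                            ali_start = s, ali_end = e, e_value = ev,
                            coverage = coverage, source = source,
                            stringsAsFactors = FALSE))
}

# Minimal positioned call table for clustering tests.
mk_calls <- function(chromosome, start, end, alias = NULL) {
  data.frame(alias = alias %||% sprintf("g%02d", seq_along(start)),
             gene_id = sprintf("id%02d", seq_along(start)),
             chromosome = chromosome, start = start, end = end,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
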