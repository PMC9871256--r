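## Homology post-processing, rank-space collinearity chaining, duplicate-type
## classification and syntenic pairing.  Chaining follows the MCScanX recipe:
## anchors are homologous gene pairs in positional-rank space, chained by
## dynamic programming with a match reward and per-rank gap penalty.

#' Clean an all-vs-all homology table into a unique pair list
#'
#' MCScanX-like input hygiene: self-hits are removed, per query only the
#' `top_n` best non-self subjects (by E-value) are kept, and reciprocal
#' hits are collapsed into one unordered pair.
#'
#' @param hits homology-hit table ([read_homology_hits()] layout).
#' @param e_max inclusive E-value cutoff (default 1e-5).
#' @param top_n subjects kept per query (default 5).
#' @return data.frame with `gene_a`, `gene_b` (lexicographically ordered
#'   within each pair), `e_value` (best over directions), `bit_score`.
#' @export
build_homology_graph <- function(hits, e_max = 1e-5, top_n = 5L) {
  h <- hits[hits$query_id != hits$subject_id & hits$e_value <= e_max, , drop = FALSE]
  if (nrow(h) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      e_value = numeric(0), bit_score = numeric(0)))
  h <- h[order(h$query_id, h$e_value, -h$bit_score, h$subject_id), , drop = FALSE]
  h <- h[!duplicated(h[c("query_id", "subject_id")]), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(h)), h$query_id),
                        function(i) head(i, top_n)), use.names = FALSE)
  h <- h[sort(keep), , drop = FALSE]
  a <- pmin(h$query_id, h$subject_id)
  b <- pmax(h$query_id, h$subject_id)
  p <- data.frame(gene_a = a, gene_b = b, e_value = h$e_value,
                  bit_score = h$bit_score, stringsAsFactors = FALSE)
  p <- p[order(p$gene_a, p$gene_b, p$e_value), , drop = FALSE]
  p <- p[!duplicated(p[c("gene_a", "gene_b")]), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Positional gene ranks per chromosome
#'
#' Ranks are 1-based positions of genes along each chromosome, ordered by
#' start (ties broken by gene_id).  MCScanX semantics rank the whole
#' annotation; pass a subset of `genes` for a family-only rank space.
#'
#' @param genes `gene_models` table (or any data.frame with `gene_id`,
#'   `chromosome`, `start`).
#' @return data.frame with `gene_id`, `chromosome`, `rank`.
#' @export
compute_gene_ranks <- function(genes) {
  ord <- order(chrom_order_key(genes$chromosome), genes$start, genes$gene_id)
  g <- genes[ord, c("gene_id", "chromosome"), drop = FALSE]
  g$rank <- stats::ave(seq_len(nrow(g)), g$chromosome, FUN = seq_along)
  rownames(g) <- NULL
  g
}

#' Build collinearity anchors from homologous pairs
#'
#' Joins a pair list with one (intra-species) or two (cross-species) rank
#' tables.  Pairs with an unranked side are dropped.  Each anchor is
#' normalized so that `chr_a` sorts before `chr_b` (and `rank_a <= rank_b`
#' within a chromosome).
#'
#' @param pairs pair list from [build_homology_graph()].
#' @param ranks_a rank table for the `gene_a` side.
#' @param ranks_b rank table for the `gene_b` side (defaults to `ranks_a`).
#' @return data.frame with `gene_a`, `gene_b`, `chr_a`, `chr_b`, `rank_a`,
#'   `rank_b`, `score`.
#' @export
make_anchors <- function(pairs, ranks_a, ranks_b = ranks_a) {
  ia <- match(pairs$gene_a, ranks_a$gene_id)
  ib <- match(pairs$gene_b, ranks_b$gene_id)
  ok <- !is.na(ia) & !is.na(ib)
  an <- data.frame(
    gene_a = pairs$gene_a[ok], gene_b = pairs$gene_b[ok],
    chr_a = ranks_a$chromosome[ia[ok]], chr_b = ranks_b$chromosome[ib[ok]],
    rank_a = ranks_a$rank[ia[ok]], rank_b = ranks_b$rank[ib[ok]],
    score = if ("bit_score" %in% names(pairs)) pairs$bit_score[ok] else 50,
    stringsAsFactors = FALSE
  )
  cross_species <- !identical(ranks_a, ranks_b)
  if (!cross_species) {
    swap <- chrom_order_key(an$chr_a) > chrom_order_key(an$chr_b) |
      (an$chr_a == an$chr_b & an$rank_a > an$rank_b)
    an[swap, c("gene_a", "gene_b", "chr_a", "chr_b", "rank_a", "rank_b")] <-
      an[swap, c("gene_b", "gene_a", "chr_b", "chr_a", "rank_b", "rank_a")]
  }
  an[order(an$chr_a, an$chr_b, an$rank_a, an$rank_b, an$gene_a), , drop = FALSE]
}

# DP over one orientation; rank_b already negated for inverted chains.
# State is (end anchor, chain length) so the min_anchors constraint is
# solved exactly: v[j, l] = best score of an l-anchor chain ending at j.
# Returns the best chain (indices into the anchor subset) with length >=
# min_anchors, or NULL.
chain_dp_once <- function(ra, rb, min_anchors, max_rank_gap,
                          gap_penalty, match_score) {
  n <- length(ra)
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]
  v <- matrix(-Inf, n, n)
  back <- matrix(0L, n, n)
  v[, 1] <- match_score
  for (j in seq_len(n)) {
    if (j == 1L) next
    for (i in seq_len(j - 1L)) {
      dra <- ra[j] - ra[i]
      drb <- rb[j] - rb[i]
      if (dra <= 0 || dra > max_rank_gap) next
      if (drb <= 0 || drb > max_rank_gap) next
      inc <- match_score + gap_penalty * (dra + drb - 2)
      for (l in 2:j) {
        if (!is.finite(v[i, l - 1L])) next
        cand <- v[i, l - 1L] + inc
        if (cand > v[j, l] + 1e-12) { v[j, l] <- cand; back[j, l] <- i }
      }
    }
  }
  sub <- v[, min_anchors:n, drop = FALSE]
  if (!any(is.finite(sub))) return(NULL)
  best <- which(v == max(sub) & col(v) >= min_anchors, arr.ind = TRUE)
  best <- best[order(best[, 2], best[, 1]), , drop = FALSE]  # deterministic
  j <- best[1, 1]; l <- best[1, 2]
  sc <- v[j, l]
  chain <- integer(0)
  while (j > 0L) { chain <- c(j, chain); j <- back[j, l]; l <- l - 1L }
  list(idx = ord[chain], score = sc)
}

#' Chain anchors into collinear (syntenic) blocks
#'
#' Dynamic programming per chromosome-pair context: a chain extends from
#' anchor i to anchor j when both rank gaps are positive (monotone, same or
#' inverted direction for the second axis), at most `max_rank_gap`, scoring
#' `match_score` per anchor plus `gap_penalty * (d_rank_a + |d_rank_b| - 2)`
#' per link.  Blocks are extracted greedily by descending chain score;
#' anchors of accepted blocks are removed before further chains are sought,
#' so each anchor belongs to at most one block.
#'
#' @param anchors anchor table from [make_anchors()].
#' @param min_anchors minimum anchors per block (default 5; must be >= 2).
#' @param max_rank_gap maximum rank gap between chained anchors (default 25).
#' @param gap_penalty per-rank gap penalty (default -1).
#' @param match_score per-anchor reward (default 50).
#' @return list with `blocks` (data.frame `block_id`, `chr_a`, `chr_b`,
#'   `n_anchors`, `chain_score`, `orientation`) and `anchors` (the block
#'   member anchors with a `block_id` column).
#' @export
chain_anchors <- function(anchors, min_anchors = 5L, max_rank_gap = 25L,
                          gap_penalty = -1, match_score = 50) {
  stop_if_not(min_anchors >= 2L, "min_anchors must be at least 2")
  blocks <- list(); members <- list()
  if (nrow(anchors) > 0) {
    ctx <- paste(anchors$chr_a, anchors$chr_b, sep = "\r")
    for (cx in unique(ctx)) {
      an <- anchors[ctx == cx, , drop = FALSE]
      repeat {
        if (nrow(an) < min_anchors) break
        fwd <- chain_dp_once(an$rank_a, an$rank_b, min_anchors,
                             max_rank_gap, gap_penalty, match_score)
        rev <- chain_dp_once(an$rank_a, -an$rank_b, min_anchors,
                             max_rank_gap, gap_penalty, match_score)
        sc_f <- if (is.null(fwd)) -Inf else fwd$score
        sc_r <- if (is.null(rev)) -Inf else rev$score
        if (!is.finite(sc_f) && !is.finite(sc_r)) break
        use_fwd <- sc_f >= sc_r
        best <- if (use_fwd) fwd else rev
        m <- an[best$idx, , drop = FALSE]
        blocks[[length(blocks) + 1L]] <- data.frame(
          chr_a = m$chr_a[1], chr_b = m$chr_b[1], n_anchors = nrow(m),
          chain_score = if (use_fwd) sc_f else sc_r,
          orientation = if (use_fwd) "same" else "inverted",
          stringsAsFactors = FALSE)
        members[[length(blocks)]] <- m
        an <- an[-best$idx, , drop = FALSE]
      }
    }
  }
  if (!length(blocks)) {
    return(list(
      blocks = data.frame(block_id = character(0), chr_a = character(0),
                          chr_b = character(0), n_anchors = integer(0),
                          chain_score = numeric(0), orientation = character(0)),
      anchors = data.frame(block_id = character(0), gene_a = character(0),
                           gene_b = character(0), chr_a = character(0),
                           chr_b = character(0), rank_a = integer(0),
                           rank_b = integer(0))))
  }
  bl <- do.call(rbind, blocks)
  ord <- order(-bl$chain_score, bl$chr_a, bl$chr_b)
  bl <- bl[ord, , drop = FALSE]
  members <- members[ord]
  bl$block_id <- sprintf("B%03d", seq_len(nrow(bl)))
  for (i in seq_along(members)) members[[i]]$block_id <- bl$block_id[i]
  an <- do.call(rbind, members)
  rownames(bl) <- rownames(an) <- NULL
  list(blocks = bl[c("block_id", "chr_a", "chr_b", "n_anchors",
                     "chain_score", "orientation")],
       anchors = an[c("block_id", "gene_a", "gene_b", "chr_a", "chr_b",
                      "rank_a", "rank_b")])
}

#' Classify duplicate types for a gene set
#'
#' MCScanX-style priority per gene: (1) `segmental` when the gene is an
#' anchor inside any collinear block; (2) `tandem` when it has a homolog at
#' the adjacent rank (rank gap 1) on the same chromosome; (3) `proximal`
#' when a same-chromosome homolog lies within `proximal_window` ranks;
#' (4) `dispersed` for any other homolog; (5) `singleton_no_homolog`
#' otherwise.  Each gene receives exactly one label.
#'
#' @param genes character vector of gene IDs to label.
#' @param pairs pair list from [build_homology_graph()].
#' @param blocks result of [chain_anchors()] (or NULL for no blocks).
#' @param ranks rank table from [compute_gene_ranks()].
#' @param proximal_window maximum rank gap for `proximal` (default 10).
#' @return data.frame with `gene_id`, `label`.
#' @export
classify_duplicates <- function(genes, pairs, blocks, ranks,
                                proximal_window = 10L) {
  seg <- if (!is.null(blocks) && nrow(blocks$anchors))
    unique(c(blocks$anchors$gene_a, blocks$anchors$gene_b)) else character(0)
  rk <- setNames(ranks$rank, ranks$gene_id)
  ch <- setNames(ranks$chromosome, ranks$gene_id)
  nbr <- split(c(pairs$gene_b, pairs$gene_a), c(pairs$gene_a, pairs$gene_b))
  label <- vapply(genes, function(g) {
    if (g %in% seg) return("segmental")
    h <- unique(nbr[[g]])
    if (is.null(h) || !length(h)) return("singleton_no_homolog")
    same <- h[!is.na(ch[h]) & ch[h] == ch[[g]]]
    if (length(same)) {
      dr <- abs(rk[same] - rk[[g]])
      if (any(dr == 1L)) return("tandem")
      if (any(dr <= proximal_window)) return("proximal")
    }
    "dispersed"
  }, character(1))
  data.frame(gene_id = genes, label = unname(label), stringsAsFactors = FALSE)
}

#' Family gene pairs on syntenic blocks
#'
#' Restricts block anchors to pairs where both genes belong to the family
#' call set; a gene may appear in several pairs (one per block partner).
#'
#' @param blocks result of [chain_anchors()].
#' @param family_ids character vector of family gene IDs.
#' @return list with `pairs` (data.frame `gene_a`, `gene_b`, `block_id`,
#'   `chr_a`, `chr_b`) and `by_chromosome_pair` (counts per chromosome
#'   pair).
#' @export
syntenic_pairs <- function(blocks, family_ids) {
  an <- blocks$anchors
  keep <- an$gene_a %in% family_ids & an$gene_b %in% family_ids
  p <- an[keep, c("gene_a", "gene_b", "block_id", "chr_a", "chr_b"), drop = FALSE]
  rownames(p) <- NULL
  cnt <- if (nrow(p)) table(paste(p$chr_a, p$chr_b, sep = "~")) else table(character(0))
  list(pairs = p, by_chromosome_pair = cnt)
}

#' Cross-species collinearity
#'
#' Identical chaining contract to [chain_anchors()], with positional ranks
#' computed within each species independently.
#'
#' @param pairs homologous pairs, `gene_a` from species A, `gene_b` from
#'   species B.
#' @param ranks_a,ranks_b per-species rank tables ([compute_gene_ranks()]).
#' @param ... chaining parameters passed to [chain_anchors()].
#' @return as [chain_anchors()].
#' @export
cross_species_synteny <- function(pairs, ranks_a, ranks_b, ...) {
  an <- make_anchors(pairs, ranks_a, ranks_b)
  chain_anchors(an, ...)
}
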