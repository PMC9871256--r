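## Chromosomal distribution, sliding-window density, and the physical
## cluster/singleton partition under the <250 kb intergenic-distance rule.

#' Gene counts per chromosome
#'
#' @param calls `nlr_calls` table (any data.frame with `chromosome`).
#' @return named integer vector in natural chromosome order; counts sum to
#'   the number of calls.
#' @export
chromosome_counts <- function(calls) {
  if (nrow(calls) == 0L) return(setNames(integer(0), character(0)))
  lev <- unique(calls$chromosome[order(chrom_order_key(calls$chromosome))])
  tab <- table(factor(calls$chromosome, levels = lev))
  setNames(as.integer(tab), names(tab))
}

#' Sliding-window gene density along chromosomes
#'
#' For each window start (1, 1+step, ...) the count of genes whose midpoint
#' lies in `[start, start + window)`.  Track length per chromosome is
#' `ceiling((chrlen - window + 1) / step)`, with a minimum of one window.
#'
#' @param calls positioned call table (`chromosome`, `start`, `end`).
#' @param chr_lengths named numeric vector of chromosome lengths (bp); when
#'   NULL, the maximum gene end per chromosome is used.
#' @param window window size in bp (default 250000).
#' @param step step size in bp (default 1000).
#' @return data.frame with `chromosome`, `window_start`, `window_end`,
#'   `count` (1-based inclusive window coordinates).
#' @export
sliding_density <- function(calls, chr_lengths = NULL,
                            window = 250000L, step = 1000L) {
  stop_if_not(step >= 1 && window >= step, "need window >= step >= 1")
  out <- list()
  for (chr in unique(calls$chromosome)) {
    g <- calls[calls$chromosome == chr, , drop = FALSE]
    len <- if (!is.null(chr_lengths)) chr_lengths[[chr]] else max(g$end)
    nwin <- max(1L, as.integer(ceiling((len - window + 1) / step)))
    ws <- 1 + step * (seq_len(nwin) - 1)
    mid <- sort(floor((g$start + g$end) / 2))
    cnt <- findInterval(ws + window - 1, mid) - findInterval(ws - 1, mid)
    out[[chr]] <- data.frame(chromosome = chr, window_start = ws,
                             window_end = ws + window - 1, count = cnt,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res))
    res <- data.frame(chromosome = character(0), window_start = numeric(0),
                      window_end = numeric(0), count = integer(0))
  res
}

#' Partition a call set into physical clusters and singletons
#'
#' Single-linkage chaining along each chromosome: consecutive family genes
#' join one cluster when the intergenic gap `max(0, next_start - prev_end)`
#' is strictly below `max_gap`.  Genes joined to no neighbour are
#' singletons; clusters have at least two members.
#'
#' @param calls positioned call table with `alias`, `chromosome`, `start`,
#'   `end`.
#' @param max_gap distance threshold in bp, exclusive (default 250000:
#'   genes exactly 250 kb apart are NOT clustered).
#' @return list with `clusters` (data.frame `cluster_id`, `chromosome`,
#'   `start`, `end`, `n`, list-column `members` of aliases ordered by
#'   start) and `singletons` (character vector of aliases).
#' @export
detect_clusters <- function(calls, max_gap = 250000) {
  clusters <- list()
  singletons <- character(0)
  chroms <- unique(calls$chromosome[order(chrom_order_key(calls$chromosome))])
  for (chr in chroms) {
    g <- calls[calls$chromosome == chr, , drop = FALSE]
    g <- g[order(g$start, g$alias), , drop = FALSE]
    if (nrow(g) == 0L) next
    gap <- pmax(0, g$start[-1] - g$end[-nrow(g)])
    grp <- cumsum(c(1L, as.integer(!(gap < max_gap))))
    for (k in unique(grp)) {
      m <- g[grp == k, , drop = FALSE]
      if (nrow(m) >= 2L) {
        clusters[[length(clusters) + 1L]] <- data.frame(
          chromosome = chr, start = min(m$start), end = max(m$end),
          n = nrow(m), stringsAsFactors = FALSE)
        clusters[[length(clusters)]]$members <- list(m$alias)
      } else {
        singletons <- c(singletons, m$alias)
      }
    }
  }
  cl <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(chromosome = character(0), start = integer(0),
               end = integer(0), n = integer(0),
               members = I(list()), stringsAsFactors = FALSE)
  cl$cluster_id <- if (nrow(cl)) sprintf("CL%03d", seq_len(nrow(cl))) else character(0)
  cl <- cl[c("cluster_id", "chromosome", "start", "end", "n", "members")]
  list(clusters = cl, singletons = singletons)
}

#' Summary statistics of the cluster/singleton partition
#'
#' @param clustering result of [detect_clusters()].
#' @param total total number of family genes (defaults to clustered +
#'   singleton count).
#' @return list with `n_clusters`, `clustered` and `singleton` (count +
#'   pct of all genes), `size_histogram`, `pct_two_gene` (share of 2-gene
#'   clusters among clusters), `clusters_per_chromosome`,
#'   `mean_cluster_size`.
#' @export
cluster_summary <- function(clustering, total = NULL) {
  cl <- clustering$clusters
  n_clustered <- sum(cl$n)
  n_single <- length(clustering$singletons)
  if (is.null(total)) total <- n_clustered + n_single
  stop_if_not(total >= n_clustered + n_single, "total smaller than partition")
  hist <- table(cl$n)
  list(
    n_clusters = nrow(cl),
    clustered = list(count = n_clustered,
                     pct = if (total > 0) percent(n_clustered, total) else NA_real_),
    singleton = list(count = n_single,
                     pct = if (total > 0) percent(n_single, total) else NA_real_),
    size_histogram = hist,
    pct_two_gene = if (nrow(cl) > 0) percent(sum(cl$n == 2L), nrow(cl)) else NA_real_,
    clusters_per_chromosome = if (nrow(cl)) table(cl$chromosome) else table(character(0)),
    mean_cluster_size = if (nrow(cl) > 0) mean(cl$n) else NA_real_
  )
}
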