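## Orchestration and the paper-style summary arithmetic: every reported
## percentage keeps its integer numerator and denominator so it can be
## recomputed exactly.

#' Rounded percentage with stored provenance
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` places.
#' When the one-decimal result would print below 1.0, the precision is
#' promoted to two decimals (so 2/338 prints 0.59, not 0.6).
#'
#' @param num integer numerator, `0 <= num <= den`.
#' @param den positive integer denominator.
#' @param decimals decimal places (default 1).
#' @return the rounded percentage as a plain number.
#' @export
percent <- function(num, den, decimals = 1L) {
  stop_if_not(length(den) == 1 && den > 0, "percent: denominator must be positive")
  stop_if_not(num >= 0 && num <= den, "percent: need 0 <= numerator <= denominator")
  p <- 100 * num / den
  r <- round_half_up(p, decimals)
  if (decimals == 1L && r < 1.0) r <- round_half_up(p, 2L)
  r
}

pct_record <- function(num, den) {
  list(num = as.integer(num), den = as.integer(den), pct = percent(num, den))
}

#' Run the full NLR analysis pipeline
#'
#' Executes the stages in dependency order: classification, then motifs,
#' clusters, duplication/synteny, phylogeny and the expression screen, and
#' assembles a consolidated summary report.  All inputs are in-memory
#' objects as produced by the readers in this package (or by
#' [simulate_genome()]).
#'
#' @param genes `gene_models` annotation.
#' @param proteins named [Biostrings::AAStringSet] of protein sequences.
#' @param domain_hits combined domain-hit table.
#' @param ref_hits homology hits against a reference NLR set.
#' @param homology all-vs-all homology hits ([read_homology_hits()] layout).
#' @param fpkm optional FPKM matrix; when NULL the expression section is
#'   marked absent.
#' @param groups sample-to-group table (required with `fpkm`).
#' @param group_r,group_s resistant / susceptible group names.
#' @param rank_space `"all"` (whole annotation, MCScanX semantics, default)
#'   or `"nlr"` (family-only ranks).
#' @param max_gap cluster distance rule in bp (default 250000, strict).
#' @param min_fold expression fold threshold (default 1.5).
#' @param bootstrap_reps bootstrap replicates for the typical-gene tree
#'   (default 500; 0 skips supports).
#' @param seed seed for the bootstrap resampling (default 1).
#' @param motif_models motif library (default [motif_library()]).
#' @param ... further arguments to [classify_nlr()].
#' @return list of class `nlr_report` with elements `calls`,
#'   `classification`, `motifs`, `motif_summary`, `clusters`,
#'   `cluster_summary`, `chromosome_counts`, `duplication`, `blocks`,
#'   `syntenic`, `tree`, `clades`, `expression`, and `summary` (named
#'   percentage records with numerator/denominator provenance).
#' @export
run_all <- function(genes, proteins, domain_hits, ref_hits, homology,
                    fpkm = NULL, groups = NULL,
                    group_r = "resistant", group_s = "susceptible",
                    rank_space = c("all", "nlr"), max_gap = 250000,
                    min_fold = 1.5, bootstrap_reps = 500L, seed = 1L,
                    motif_models = motif_library(), ...) {
  rank_space <- match.arg(rank_space)

  calls <- classify_nlr(genes, domain_hits, ref_hits, ...)
  cls <- classification_summary(calls)

  motifs <- presence_matrix(calls, proteins, models = motif_models,
                            domain_hits = domain_hits)
  msum <- motif_summary(motifs)

  clst <- detect_clusters(calls, max_gap = max_gap)
  csum <- cluster_summary(clst, total = nrow(calls))
  chrom <- chromosome_counts(calls)

  pairs <- build_homology_graph(homology)
  ranks <- if (rank_space == "all") compute_gene_ranks(genes)
           else compute_gene_ranks(calls)
  anchors <- make_anchors(pairs, ranks)
  blocks <- chain_anchors(anchors)
  dup <- classify_duplicates(calls$gene_id, pairs, blocks, ranks)
  dup$alias <- calls$alias[match(dup$gene_id, calls$gene_id)]
  synt <- syntenic_pairs(blocks, calls$gene_id)

  tree <- NULL; clades <- NULL
  typ <- calls[calls$typical, , drop = FALSE]
  if (nrow(typ) >= 4) {
    aln <- nbs_alignment(typ, proteins, domain_hits)
    tree <- if (bootstrap_reps > 0)
      bootstrap_support(aln, replicates = bootstrap_reps, seed = seed)
    else nj_tree(distance_matrix(aln))
    clades <- clade_composition(tree, calls)
  }

  expression <- NULL
  if (!is.null(fpkm)) {
    stop_if_not(!is.null(groups), "expression screen needs a groups table")
    fam <- fpkm[intersect(calls$gene_id, rownames(fpkm)), , drop = FALSE]
    expression <- fold_screen(fam, groups, group_r, group_s, min_fold = min_fold)
    expression$alias <- calls$alias[match(expression$gene_id, calls$gene_id)]
  }

  n <- nrow(calls)
  summary <- list(n_nlr = n)
  if (n > 0) {
    summary$typical <- pct_record(sum(calls$typical), n)
    summary$clustered <- pct_record(csum$clustered$count, n)
    summary$singleton <- pct_record(csum$singleton$count, n)
    summary$all_motifs <- pct_record(msum$all_required$count, n)
    for (lab in c("tandem", "proximal", "dispersed", "segmental"))
      summary[[lab]] <- pct_record(sum(dup$label == lab), n)
    if (!is.null(expression)) {
      summary$expressed <- pct_record(sum(expression$expressed), n)
      summary$flagged <- pct_record(sum(expression$flagged), n)
    }
  }
  structure(list(calls = calls, classification = cls, motifs = motifs,
                 motif_summary = msum, clusters = clst, cluster_summary = csum,
                 chromosome_counts = chrom, duplication = dup, blocks = blocks,
                 syntenic = synt, tree = tree, clades = clades,
                 expression = expression, summary = summary,
                 params = list(rank_space = rank_space, max_gap = max_gap,
                               min_fold = min_fold,
                               bootstrap_reps = bootstrap_reps, seed = seed)),
            class = "nlr_report")
}

#' Extract an NBS-region alignment for a call set
#'
#' Cuts each protein to its best NBS domain hit.  This supports the common
#' family-tree practice of comparing the conserved NB-ARC region; it
#' requires the cut regions to be of equal length (as for domain models of
#' fixed span or pre-aligned inputs) and errors otherwise, in which case a
#' pre-aligned FASTA should be supplied to [aligned_block()] directly.
#'
#' @param calls `nlr_calls` subset to align.
#' @param proteins named [Biostrings::AAStringSet].
#' @param domain_hits domain-hit table with NBS rows.
#' @return an `aligned_block` over the call aliases.
#' @export
nbs_alignment <- function(calls, proteins, domain_hits) {
  nb <- domain_hits[domain_hits$domain_label == "NBS", , drop = FALSE]
  nb <- nb[order(nb$e_value), , drop = FALSE]
  nb <- nb[!duplicated(nb$protein_id), , drop = FALSE]
  seqs <- if (methods::is(proteins, "XStringSet"))
    setNames(as.character(proteins), names(proteins)) else proteins
  rows <- vapply(seq_len(nrow(calls)), function(i) {
    g <- calls$gene_id[i]
    k <- match(g, nb$protein_id)
    stop_if_not(!is.na(k), "no NBS hit for %s", g)
    substr(seqs[[g]], nb$ali_start[k], nb$ali_end[k])
  }, character(1))
  stop_if_not(length(unique(nchar(rows))) == 1L,
              "NBS regions have unequal lengths; supply a pre-aligned block")
  aligned_block(setNames(rows, calls$alias))
}

#' @export
print.nlr_report <- function(x, ...) {
  s <- x$summary
  cat("NLR pipeline report\n")
  cat(sprintf("  calls: %d (%s typical, %.1f%%)\n", s$n_nlr,
              if (is.null(s$typical)) "0" else s$typical$num,
              if (is.null(s$typical)) 0 else s$typical$pct))
  cat(sprintf("  clusters: %d containing %d genes (%.1f%%); %d singletons\n",
              x$cluster_summary$n_clusters, x$cluster_summary$clustered$count,
              x$cluster_summary$clustered$pct %||% NA,
              x$cluster_summary$singleton$count))
  if (!is.null(s$tandem))
    cat(sprintf("  duplication: tandem %.1f%%, proximal %.1f%%, dispersed %.1f%%, segmental %.1f%%\n",
                s$tandem$pct, s$proximal$pct, s$dispersed$pct, s$segmental$pct))
  cat(sprintf("  syntenic family pairs: %d in %d blocks\n",
              nrow(x$syntenic$pairs), nrow(x$blocks$blocks)))
  if (!is.null(x$expression))
    cat(sprintf("  expression: %d expressed, %d flagged (fold >= %.2g)\n",
                sum(x$expression$expressed), sum(x$expression$flagged),
                x$params$min_fold))
  else cat("  expression: section absent (no FPKM input)\n")
  invisible(x)
}
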