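## Distance computation from an amino-acid alignment, Saitou-Nei
## neighbor-joining, column-resampling bootstrap, and clade composition.
## The NJ agglomeration is implemented here (deterministic tie-breaks by
## taxon label); ape supplies the phylo container and Newick I/O.

#' Build an aligned block from gapped sequences
#'
#' @param seqs named character vector (or [Biostrings::AAStringSet]) of
#'   equal-length gapped amino-acid rows.
#' @return list of class `aligned_block` with `taxa` and `rows`.
#' @export
aligned_block <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  stop_if_not(length(unique(nchar(seqs))) == 1L, "alignment rows differ in length")
  stop_if_not(!is.null(names(seqs)) && !anyDuplicated(names(seqs)),
              "alignment needs unique taxon names")
  structure(list(taxa = names(seqs), rows = unname(toupper(seqs))),
            class = "aligned_block")
}

#' Pairwise distance matrix from an aligned block
#'
#' Gap columns are removed pairwise (pairwise deletion; `complete = TRUE`
#' removes every column containing a gap anywhere first).  The p-distance
#' is mismatches over compared sites; the Poisson correction is
#' `-ln(1 - p)` and errors on saturated pairs (`p >= 1`).
#'
#' @param block an `aligned_block`.
#' @param model `"poisson"` (default, the usual protein NJ correction) or
#'   `"p-distance"`.
#' @param complete use complete deletion instead of pairwise deletion.
#' @return symmetric numeric matrix with zero diagonal, dimnames = taxa.
#' @export
distance_matrix <- function(block, model = c("poisson", "p-distance"),
                            complete = FALSE) {
  model <- match.arg(model)
  m <- do.call(rbind, strsplit(block$rows, ""))
  rownames(m) <- block$taxa
  gap <- m == "-" | m == "."
  if (complete) {
    keep <- colSums(gap) == 0L
    m <- m[, keep, drop = FALSE]
    gap <- gap[, keep, drop = FALSE]
  }
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(block$taxa, block$taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !gap[i, ] & !gap[j, ]
    stop_if_not(any(ok), "taxa %s and %s share no compared sites",
                block$taxa[i], block$taxa[j])
    p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    d <- if (model == "poisson") {
      stop_if_not(p < 1, "saturated distance (p >= 1) between %s and %s under the Poisson model",
                  block$taxa[i], block$taxa[j])
      -log(1 - p)
    } else p
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion
#' `Q(i,j) = (m-2) d(i,j) - r_i - r_j`.  Ties in Q are broken
#' deterministically by the (lexicographically smallest) pair of
#' representative taxon labels.  Negative branch-length estimates are
#' clamped to zero; the number of clamped edges is recorded in the
#' `"negative_clamped"` attribute.
#'
#' @param D symmetric distance matrix with taxon dimnames, >= 3 taxa.
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  stop_if_not(is.matrix(D) && nrow(D) == ncol(D) && nrow(D) >= 3,
              "D must be a square matrix with at least 3 taxa")
  stop_if_not(max(abs(D - t(D))) < 1e-8, "D must be symmetric")
  labels <- rownames(D)
  d <- D
  frag <- labels                 # newick fragment per active node
  rep_lab <- labels              # representative label for tie-breaks
  clamped <- 0L
  fmt <- function(x) sprintf("%.15g", x)
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(rep_lab[cand[, 1]], rep_lab[cand[, 2]]),
                 pmax(rep_lab[cand[, 1]], rep_lab[cand[, 2]]), sep = "\r")
    pick <- cand[order(key)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    li <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { clamped <- clamped + 1L; li <- 0 }
    if (lj < 0) { clamped <- clamped + 1L; lj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    newlab <- min(rep_lab[i], rep_lab[j])
    dk <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    rep_lab <- c(rep_lab[keep], newlab)
    d <- d2
  }
  # resolve the final three nodes around one internal vertex
  l1 <- 0.5 * (d[1, 2] + d[1, 3] - d[2, 3])
  l2 <- 0.5 * (d[1, 2] + d[2, 3] - d[1, 3])
  l3 <- 0.5 * (d[1, 3] + d[2, 3] - d[1, 2])
  ls <- c(l1, l2, l3)
  clamped <- clamped + sum(ls < 0)
  ls <- pmax(ls, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(ls[1]),
                 frag[2], fmt(ls[2]), frag[3], fmt(ls[3]))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_clamped") <- clamped
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `replicates` times; a
#' bipartition's support is the percentage of replicate NJ trees containing
#' it.  Supports are attached as internal-node labels.  Replicates whose
#' resampled columns yield a saturated Poisson distance are skipped and
#' counted in the `"failed_replicates"` attribute.
#'
#' @param block an `aligned_block` (>= 4 taxa for meaningful supports).
#' @param replicates number of bootstrap replicates (default 500;
#'   `replicates = 0` returns the tree with NA supports, flagged).
#' @param seed required random seed, stored in the output metadata.
#' @param model distance model, see [distance_matrix()].
#' @return the original NJ tree with `node.label` percentage supports and
#'   attributes `bootstrap_replicates`, `bootstrap_seed`,
#'   `failed_replicates`.
#' @export
bootstrap_support <- function(block, replicates = 500L, seed,
                              model = c("poisson", "p-distance")) {
  model <- match.arg(model)
  stop_if_not(!missing(seed), "bootstrap_support requires an explicit seed")
  tree <- nj_tree(distance_matrix(block, model = model))
  attr(tree, "bootstrap_replicates") <- replicates
  attr(tree, "bootstrap_seed") <- seed
  if (replicates == 0L) {
    tree$node.label <- rep(NA_real_, tree$Nnode)
    attr(tree, "failed_replicates") <- 0L
    return(tree)
  }
  nc <- nchar(block$rows[1])
  set.seed(seed)
  reps <- vector("list", replicates)
  failed <- 0L
  chars <- do.call(rbind, strsplit(block$rows, ""))
  for (b in seq_len(replicates)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    rb <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
    blk <- aligned_block(setNames(rb, block$taxa))
    reps[[b]] <- tryCatch(nj_tree(distance_matrix(blk, model = model)),
                          error = function(e) NULL)
    if (is.null(reps[[b]])) failed <- failed + 1L
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- round(100 * counts / length(reps), 1)
  attr(tree, "failed_replicates") <- failed
  tree
}

#' Clade composition of a tree with respect to subclass labels
#'
#' For each subclass, reports its members and whether they form a
#' monophyletic group in the unrooted sense (their tip set, or its
#' complement, is a split of the tree).
#'
#' @param tree an [ape::phylo] tree whose tips are call aliases.
#' @param calls `nlr_calls` table with `alias` and `subclass`.
#' @return data.frame with `subclass`, `n_tips`, `monophyletic`, plus a
#'   `members` list-column.
#' @export
clade_composition <- function(tree, calls) {
  sub <- setNames(calls$subclass, calls$alias)
  stop_if_not(all(tree$tip.label %in% names(sub)),
              "tree tips missing from the call table")
  splits <- ape::prop.part(tree)
  split_keys <- vapply(splits, function(s) paste(sort(s), collapse = ","), character(1))
  n <- length(tree$tip.label)
  out <- lapply(sort(unique(sub[tree$tip.label])), function(cl) {
    tips <- which(sub[tree$tip.label] == cl)
    comp <- setdiff(seq_len(n), tips)
    mono <- length(tips) <= 1L || length(comp) <= 1L ||
      paste(sort(tips), collapse = ",") %in% split_keys ||
      paste(sort(comp), collapse = ",") %in% split_keys
    r <- data.frame(subclass = cl, n_tips = length(tips), monophyletic = mono,
                    stringsAsFactors = FALSE)
    r$members <- list(tree$tip.label[tips])
    r
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
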