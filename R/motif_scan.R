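## Presence/absence calling of the conserved NB-ARC motifs with simple
## consensus-derived position-specific score matrices (PSSMs).  This replaces
## de-novo discovery: the motif set is a shipped, user-replaceable library.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Build a PSSM from a consensus string
#'
#' Consensus positions score `match` for the consensus residue and
#' `mismatch` otherwise; wildcard positions (`x`) score `wildcard`
#' uniformly, so substitutions there never change the score.  Residues
#' outside the 20-letter alphabet score like mismatches.
#'
#' @param consensus amino-acid consensus with `x` wildcards.
#' @param match,mismatch,wildcard per-position scores.
#' @return numeric matrix, one row per consensus position, 21 columns
#'   (20 residues + `other`).
#' @export
consensus_pssm <- function(consensus, match = 2, mismatch = -1, wildcard = 1) {
  res <- strsplit(toupper(consensus), "")[[1]]
  m <- matrix(mismatch, nrow = length(res), ncol = 21,
              dimnames = list(NULL, c(AA20, "other")))
  for (i in seq_along(res)) {
    if (res[i] == "X") m[i, ] <- wildcard
    else m[i, res[i]] <- match
  }
  m
}

#' Load a motif library
#'
#' Reads the shipped NB-ARC motif consensus table (or a user replacement)
#' and attaches consensus PSSMs.  The library lists motifs in N-to-C order
#' along the NBS domain; `required` marks the motifs counted in presence
#' summaries.
#'
#' @param path optional path to a replacement TSV with columns `name`,
#'   `consensus`, `required`, `threshold`.
#' @return list of motif models, each a list with `name`, `consensus`,
#'   `required`, `threshold`, `pssm`, `max_score`.
#' @export
motif_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "nbs_motifs.tsv", package = "nlratlas")
  tb <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stop_if_not(all(c("name", "consensus", "required", "threshold") %in% names(tb)),
              "motif library must have columns name, consensus, required, threshold")
  stop_if_not(all(tb$threshold > 0 & tb$threshold <= 1),
              "motif thresholds must lie in (0, 1]")
  models <- lapply(seq_len(nrow(tb)), function(i) {
    pssm <- consensus_pssm(tb$consensus[i])
    list(name = tb$name[i], consensus = tb$consensus[i],
         required = as.logical(tb$required[i]), threshold = tb$threshold[i],
         pssm = pssm, max_score = sum(apply(pssm, 1, max)))
  })
  names(models) <- tb$name
  models
}

#' Scan one protein sequence for a motif
#'
#' Slides the motif PSSM over the sequence (optionally restricted to the
#' NBS hit interval +/- `flank` residues) and reports the best-scoring
#' window.  Presence requires `best_score >= threshold * max_score`.
#'
#' @param sequence amino-acid string.
#' @param model one element of [motif_library()].
#' @param region optional integer `c(start, end)` (1-based, inclusive)
#'   restricting the scan, e.g. the NBS domain hit.
#' @param flank residues added on both sides of `region` (default 30).
#' @return list with `best_score`, `position` (window start in the full
#'   sequence, NA when no window fits), `present`, `max_score`.
#' @export
scan_motif <- function(sequence, model, region = NULL, flank = 30L) {
  L <- nrow(model$pssm)
  chars <- strsplit(toupper(sequence), "")[[1]]
  lo <- 1L; hi <- length(chars)
  if (!is.null(region)) {
    lo <- max(1L, as.integer(region[1]) - flank)
    hi <- min(hi, as.integer(region[2]) + flank)
  }
  n <- hi - lo + 1L
  if (n < L)
    return(list(best_score = -Inf, position = NA_integer_, present = FALSE,
                max_score = model$max_score))
  idx <- match(chars[lo:hi], AA20)
  idx[is.na(idx)] <- 21L
  # column-wise accumulation over all windows at once
  starts <- seq_len(n - L + 1L)
  scores <- numeric(length(starts))
  for (k in seq_len(L))
    scores <- scores + unname(model$pssm[k, idx[starts + k - 1L]])
  best <- which.max(scores)
  list(best_score = scores[best],
       position = lo + starts[best] - 1L,
       present = scores[best] >= model$threshold * model$max_score,
       max_score = model$max_score)
}

#' Motif presence matrix for a call set
#'
#' Scans every protein of a call set against every motif model.  When a
#' domain-hit table is supplied, scans are restricted to the protein's best
#' NBS hit interval +/- 30 residues.
#'
#' @param calls NLR call table (needs `gene_id` and `alias` columns); any
#'   data.frame with those columns works.
#' @param proteins named [Biostrings::AAStringSet] (or named character
#'   vector) covering all call gene IDs.
#' @param models motif library from [motif_library()].
#' @param domain_hits optional domain-hit table used to locate the NBS
#'   domain per protein.
#' @return data.frame with `alias`, `gene_id`, one logical presence column
#'   per motif, and integer `n_required`; attribute `required` names the
#'   counted motifs, attribute `scores` holds the best-score matrix.
#' @export
presence_matrix <- function(calls, proteins, models = motif_library(),
                            domain_hits = NULL) {
  req <- names(models)[vapply(models, `[[`, logical(1), "required")]
  if (nrow(calls) == 0L) {
    out <- data.frame(alias = character(0), gene_id = character(0))
    for (nm in names(models)) out[[nm]] <- logical(0)
    out$n_required <- integer(0)
    attr(out, "required") <- req
    return(out)
  }
  seqs <- if (methods::is(proteins, "XStringSet")) {
    setNames(as.character(proteins), names(proteins))
  } else proteins
  stop_if_not(all(calls$gene_id %in% names(seqs)),
              "proteins missing for some calls")
  nbs_region <- NULL
  if (!is.null(domain_hits)) {
    nb <- domain_hits[domain_hits$domain_label == "NBS", , drop = FALSE]
    nb <- nb[order(nb$e_value), , drop = FALSE]
    nb <- nb[!duplicated(nb$protein_id), , drop = FALSE]
    nbs_region <- setNames(Map(c, nb$ali_start, nb$ali_end), nb$protein_id)
  }
  pres <- matrix(FALSE, nrow(calls), length(models),
                 dimnames = list(NULL, names(models)))
  scr <- matrix(-Inf, nrow(calls), length(models),
                dimnames = list(NULL, names(models)))
  for (i in seq_len(nrow(calls))) {
    s <- seqs[[calls$gene_id[i]]]
    reg <- if (!is.null(nbs_region)) nbs_region[[calls$gene_id[i]]] else NULL
    for (j in seq_along(models)) {
      sc <- scan_motif(s, models[[j]], region = reg)
      pres[i, j] <- sc$present
      scr[i, j] <- sc$best_score
    }
  }
  out <- data.frame(alias = calls$alias, gene_id = calls$gene_id,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pres))
  out$n_required <- as.integer(rowSums(pres[, req, drop = FALSE]))
  attr(out, "required") <- req
  attr(out, "scores") <- scr
  out
}

#' Summary statistics for a motif presence table
#'
#' Reports, over the counted (required) motifs: the per-motif presence
#' percentage, the number and percentage of proteins with all counted
#' motifs, and with none of them.
#'
#' @param table output of [presence_matrix()].
#' @return list with `n`, `per_motif` (data.frame name/count/pct),
#'   `all_required` and `zero_required` (each count + pct).
#' @export
motif_summary <- function(table) {
  req <- attr(table, "required")
  n <- nrow(table)
  per <- data.frame(
    motif = req,
    count = vapply(req, function(m) sum(table[[m]]), integer(1)),
    stringsAsFactors = FALSE
  )
  per$pct <- if (n > 0) vapply(per$count, percent, numeric(1), den = n) else NA_real_
  all_req <- sum(table$n_required == length(req))
  zero_req <- sum(table$n_required == 0L)
  list(
    n = n,
    per_motif = per,
    all_required = list(count = all_req,
                        pct = if (n > 0) percent(all_req, n) else NA_real_),
    zero_required = list(count = zero_req,
                         pct = if (n > 0) percent(zero_req, n) else NA_real_)
  )
}
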