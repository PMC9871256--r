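## From raw domain/homology evidence to the NLR call set: E-value filter,
## reference-homology screen, subclass + architecture-code assignment,
## integrated-domain retention, and serial alias naming.

#' Filter NBS candidates by HMM E-value
#'
#' A protein is retained when its best (smallest) NBS domain E-value from
#' the HMM scan is at or below `e_max` (the classical 1e-4 cutoff for the
#' NB-ARC profile search).
#'
#' @param hits domain-hit table ([as_domain_hits()] layout).
#' @param e_max maximum E-value, inclusive.
#' @return sorted character vector of retained protein IDs.
#' @export
filter_nbs_candidates <- function(hits, e_max = 1e-4) {
  nb <- hits[hits$domain_label == "NBS" & hits$source == "hmm", , drop = FALSE]
  if (nrow(nb) == 0L) return(character(0))
  best <- tapply(nb$e_value, nb$protein_id, min)
  sort(names(best)[best <= e_max])
}

#' Screen candidates by homology to a reference NLR set
#'
#' Candidates with no hit against the reference NLR proteins at
#' `E <= e_max` are eliminated (the Arabidopsis-style elimination step).
#'
#' @param candidates character vector of protein IDs.
#' @param ref_hits homology-hit table (candidate vs reference NLRs,
#'   [read_homology_hits()] layout).
#' @param e_max maximum E-value, inclusive.
#' @return sorted subset of `candidates` with reference support.
#' @export
homology_screen <- function(candidates, ref_hits, e_max = 1e-5) {
  stop_if_not(!is.null(ref_hits) && nrow(ref_hits) > 0,
              "homology screen needs a non-empty reference hit table")
  keep <- unique(ref_hits$query_id[ref_hits$e_value <= e_max])
  sort(intersect(candidates, keep))
}

#' Best reference subclass per candidate
#'
#' Convenience fallback extractor: for each query, the subclass of its
#' best-E-value reference subject, inferred from a `CNL`/`TNL`/`RNL` token
#' in the subject name (e.g. `AtTNL_012`).
#'
#' @param ref_hits homology-hit table against a reference NLR set.
#' @return named character vector (query -> subclass), queries with no
#'   parseable subject omitted.
#' @export
reference_subclass <- function(ref_hits) {
  rh <- ref_hits[order(ref_hits$e_value, ref_hits$subject_id), , drop = FALSE]
  rh <- rh[!duplicated(rh$query_id), , drop = FALSE]
  m <- regmatches(rh$subject_id, regexpr("CNL|TNL|RNL", rh$subject_id))
  ok <- lengths(regmatches(rh$subject_id, gregexpr("CNL|TNL|RNL", rh$subject_id))) > 0
  setNames(m, rh$query_id[ok])
}

#' Assign the NLR subclass from domain evidence
#'
#' Domain-scan evidence always wins: RPW8 present -> RNL, else TIR -> TNL,
#' else CC -> CNL.  Only when no N-terminal domain was detected does the
#' homology `fallback` subclass apply; with neither, the call defaults to
#' CNL and is flagged low-confidence.
#'
#' @param hits domain hits for one protein.
#' @param fallback optional subclass (`"CNL"`, `"TNL"`, `"RNL"`) from the
#'   best reference homolog.
#' @return list with `subclass`, `low_confidence`, `multi_nterm` (TRUE when
#'   more than one N-terminal domain type was present).
#' @export
assign_subclass <- function(hits, fallback = NULL) {
  lab <- unique(hits$domain_label)
  stop_if_not("NBS" %in% lab, "assign_subclass requires NBS evidence")
  nterm <- intersect(c("RPW8", "TIR", "CC"), lab)
  if (length(nterm) > 0) {
    sub <- c(RPW8 = "RNL", TIR = "TNL", CC = "CNL")[[nterm[1]]]
    return(list(subclass = sub, low_confidence = FALSE,
                multi_nterm = length(nterm) > 1))
  }
  if (!is.null(fallback) && !is.na(fallback)) {
    stop_if_not(fallback %in% c("CNL", "TNL", "RNL"),
                "fallback subclass must be CNL, TNL or RNL")
    return(list(subclass = fallback, low_confidence = FALSE, multi_nterm = FALSE))
  }
  list(subclass = "CNL", low_confidence = TRUE, multi_nterm = FALSE)
}

#' Derive the domain architecture code
#'
#' Concatenates the present parts in N-to-C order: a leading `C`/`T`/`R`
#' when the subclass-defining N-terminal domain was detected, always `N`
#' (every NLR carries an NBS hit), and a trailing `L` when an LRR was
#' detected.  The typical flag marks three-part codes (`CNL`, `TNL`, `RNL`).
#'
#' @param hits domain hits for one protein.
#' @param subclass assigned subclass (determines the leading letter).
#' @return list with `code` and `typical`.
#' @export
architecture_code <- function(hits, subclass) {
  lab <- unique(hits$domain_label)
  stop_if_not("NBS" %in% lab, "architecture_code requires NBS evidence")
  lead_domain <- c(CNL = "CC", TNL = "TIR", RNL = "RPW8")[[subclass]]
  code <- paste0(
    if (lead_domain %in% lab) substr(subclass, 1, 1) else "",
    "N",
    if ("LRR" %in% lab) "L" else ""
  )
  list(code = code, typical = nchar(code) == 3L)
}

#' Retain integrated (non-canonical) domains
#'
#' Extra domains fused into NLR proteins (e.g. PLN03210) are kept when the
#' hit is confident (`E < e_max`, strict) and covers the domain model
#' nearly completely.
#'
#' @param hits domain hits for one protein.
#' @param e_max strict E-value bound (default 1e-5).
#' @param min_coverage minimum fraction of the domain model covered
#'   (default 0.9).
#' @return sorted character vector of unique retained domain names.
#' @export
retain_integrated_domains <- function(hits, e_max = 1e-5, min_coverage = 0.9) {
  oth <- hits[hits$domain_label == "OTHER" &
                hits$e_value < e_max &
                hits$coverage >= min_coverage, , drop = FALSE]
  sort(unique(oth$domain_name))
}

#' Assign serial aliases to an NLR call set
#'
#' Genes are sorted by (chromosome in natural order, start, gene_id) and
#' numbered 1..N genome-wide; the alias is
#' `"Mru" + chromosome number + "c" + serial` (e.g. the 5th NLR genome-wide,
#' sitting on chromosome 1, becomes `Mru1c5`).
#'
#' @param calls call table with `gene_id`, `chromosome`, `start`.
#' @param prefix alias prefix (default `"Mru"`).
#' @return `calls` reordered by genomic position with an `alias` column.
#' @export
assign_aliases <- function(calls, prefix = "Mru") {
  ord <- order(chrom_order_key(calls$chromosome), calls$start, calls$gene_id)
  calls <- calls[ord, , drop = FALSE]
  calls$alias <- sprintf("%s%sc%d", prefix, chrom_number(calls$chromosome),
                         seq_len(nrow(calls)))
  rownames(calls) <- NULL
  calls
}

#' Build the full NLR call set from evidence tables
#'
#' Chains the identification steps: NBS E-value filter, reference-homology
#' screen, per-protein subclass + architecture code + integrated domains,
#' gene-coordinate join, and alias assignment.
#'
#' @param genes `gene_models` annotation.
#' @param domain_hits combined domain-hit table (HMM + CDD sources).
#' @param ref_hits homology hits against a reference NLR protein set.
#' @param e_nbs inclusive NBS HMM E-value cutoff (default 1e-4).
#' @param e_screen inclusive homology-screen E-value cutoff (default 1e-5).
#' @param e_id strict integrated-domain E-value cutoff (default 1e-5).
#' @param id_coverage minimum integrated-domain model coverage (default 0.9).
#' @param alias_prefix alias prefix (default `"Mru"`).
#' @return data.frame of class `nlr_calls`: one row per NLR gene with
#'   `gene_id`, `alias`, `chromosome`, `strand`, `start`, `end`, `subclass`,
#'   `code`, `typical`, `low_confidence`, `multi_nterm` and list-column
#'   `integrated`.
#' @export
classify_nlr <- function(genes, domain_hits, ref_hits,
                         e_nbs = 1e-4, e_screen = 1e-5,
                         e_id = 1e-5, id_coverage = 0.9,
                         alias_prefix = "Mru") {
  cand <- filter_nbs_candidates(domain_hits, e_max = e_nbs)
  kept <- homology_screen(cand, ref_hits, e_max = e_screen)
  fb <- reference_subclass(ref_hits)
  rows <- lapply(kept, function(p) {
    h <- domain_hits[domain_hits$protein_id == p, , drop = FALSE]
    sub <- assign_subclass(h, fallback = fb[p][[1]])
    arc <- architecture_code(h, sub$subclass)
    gi <- match(p, genes$gene_id)
    stop_if_not(!is.na(gi), "candidate %s not present in the annotation", p)
    data.frame(gene_id = p, chromosome = genes$chromosome[gi],
               strand = genes$strand[gi], start = genes$start[gi],
               end = genes$end[gi], subclass = sub$subclass, code = arc$code,
               typical = arc$typical, low_confidence = sub$low_confidence,
               multi_nterm = sub$multi_nterm, stringsAsFactors = FALSE)
  })
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), chromosome = character(0),
               strand = character(0), start = integer(0), end = integer(0),
               subclass = character(0), code = character(0),
               typical = logical(0), low_confidence = logical(0),
               multi_nterm = logical(0), stringsAsFactors = FALSE)
  calls$integrated <- lapply(calls$gene_id, function(p)
    retain_integrated_domains(domain_hits[domain_hits$protein_id == p, , drop = FALSE],
                              e_max = e_id, min_coverage = id_coverage))
  calls <- assign_aliases(calls, prefix = alias_prefix)
  class(calls) <- c("nlr_calls", "data.frame")
  calls
}

#' Count calls per subclass and architecture code
#'
#' @param calls `nlr_calls` table.
#' @return data.frame with `subclass`, `code`, `count` plus attributes
#'   `total` and `typical` (typical count per subclass).
#' @export
classification_summary <- function(calls) {
  if (nrow(calls) == 0L) {
    out <- data.frame(subclass = character(0), code = character(0),
                      count = integer(0))
    attr(out, "total") <- 0L
    return(out)
  }
  tb <- as.data.frame(table(subclass = calls$subclass, code = calls$code),
                      stringsAsFactors = FALSE)
  tb <- tb[tb$Freq > 0, , drop = FALSE]
  names(tb)[3] <- "count"
  tb <- tb[order(tb$subclass, tb$code), , drop = FALSE]
  rownames(tb) <- NULL
  attr(tb, "total") <- nrow(calls)
  attr(tb, "typical") <- tapply(calls$typical, calls$subclass, sum)
  tb
}
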