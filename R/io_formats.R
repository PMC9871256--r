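## Readers/writers for the external formats the pipeline touches.
## Coordinates are GFF3 1-based inclusive everywhere internally; the only
## 0-based half-open output is the cluster BED written at export time.

#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `CDS` features into a gene-model table.  CDS features
#' are attached to their parent gene either directly (`Parent=<gene>`) or
#' through one mRNA level (`CDS -> mRNA -> gene`).
#'
#' @param path path to a GFF3 file.
#' @return a `data.frame` of class `gene_models` with columns `gene_id`,
#'   `chromosome`, `strand`, `start`, `end` and a list-column `cds_parts`
#'   (two-column integer matrix `start`,`end` per gene, sorted in genomic
#'   order, possibly zero rows).  Rows are ordered by (chromosome, start,
#'   gene_id); coordinates are 1-based inclusive.
#' @export
read_gff3 <- function(path) {
  stop_if_not(file.exists(path), "GFF3 file not found: %s", path)
  raw <- readLines(path, warn = FALSE)
  body <- raw[!grepl("^\\s*(#|$)", raw)]
  if (length(body) == 0L) {
    warning("GFF3 file has no feature lines: ", path)
    return(empty_gene_models())
  }
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(!grepl("^\\s*(#|$)", raw))[which(nf != 9L)[1L]]
    stop(sprintf("malformed GFF3 line %d in %s: expected 9 tab-separated fields, found %d",
                 bad, path, nf[nf != 9L][1L]), call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)

  is_gene <- typ == "gene"
  ids <- as.character(md$ID)
  genes <- data.frame(
    gene_id    = ids[is_gene],
    chromosome = as.character(GenomicRanges::seqnames(gr))[is_gene],
    strand     = as.character(GenomicRanges::strand(gr))[is_gene],
    start      = GenomicRanges::start(gr)[is_gene],
    end        = GenomicRanges::end(gr)[is_gene],
    stringsAsFactors = FALSE
  )
  stop_if_not(!anyDuplicated(genes$gene_id), "duplicated gene IDs in %s", path)

  # map feature ID -> parent gene (one mRNA level supported)
  mrna_parent <- ids[typ == "mRNA"]
  names(mrna_parent) <- ids[typ == "mRNA"]
  mrna2gene <- vapply(which(typ == "mRNA"), function(i) {
    p <- unlist(md$Parent[i])
    if (length(p)) p[1L] else NA_character_
  }, character(1))
  names(mrna2gene) <- ids[typ == "mRNA"]

  cds_idx <- which(typ == "CDS")
  cds_gene <- vapply(cds_idx, function(i) {
    p <- unlist(md$Parent[i])
    if (!length(p)) return(NA_character_)
    p <- p[1L]
    if (p %in% genes$gene_id) p
    else if (p %in% names(mrna2gene)) mrna2gene[[p]]
    else NA_character_
  }, character(1))
  if (anyNA(cds_gene)) stop("CDS feature with unresolvable Parent in ", path, call. = FALSE)

  cds_parts <- rep(list(empty_cds()), nrow(genes))
  names(cds_parts) <- genes$gene_id
  for (g in unique(cds_gene)) {
    i <- cds_idx[cds_gene == g]
    m <- cbind(start = GenomicRanges::start(gr)[i], end = GenomicRanges::end(gr)[i])
    m <- m[order(m[, "start"]), , drop = FALSE]
    gi <- match(g, genes$gene_id)
    if (m[1, "start"] < genes$start[gi] || m[nrow(m), "end"] > genes$end[gi])
      stop(sprintf("CDS of gene %s extends outside the gene span", g), call. = FALSE)
    if (nrow(m) > 1 && any(m[-1, "start"] <= m[-nrow(m), "end"]))
      stop(sprintf("overlapping CDS parts for gene %s", g), call. = FALSE)
    cds_parts[[gi]] <- m
  }
  genes$cds_parts <- unname(cds_parts)
  ord <- order(chrom_order_key(genes$chromosome), genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  class(genes) <- c("gene_models", "data.frame")
  genes
}

empty_cds <- function() cbind(start = integer(0), end = integer(0))

empty_gene_models <- function() {
  g <- data.frame(gene_id = character(0), chromosome = character(0),
                  strand = character(0), start = integer(0), end = integer(0),
                  stringsAsFactors = FALSE)
  g$cds_parts <- list()
  class(g) <- c("gene_models", "data.frame")
  g
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()]: emits one `gene` feature per row plus its CDS
#' parts (with `Parent` set to the gene), 1-based inclusive.
#'
#' @param genes a `gene_models` data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    writeLines(sprintf("%s\tnlratlas\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chromosome[i], genes$start[i], genes$end[i],
                       genes$strand[i], genes$gene_id[i]), con)
    cp <- genes$cds_parts[[i]]
    if (!is.null(cp) && nrow(cp)) {
      writeLines(sprintf("%s\tnlratlas\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                         genes$chromosome[i], cp[, "start"], cp[, "end"],
                         genes$strand[i], genes$gene_id[i]), con)
    }
  }
  invisible(path)
}

#' Translate the CDS of gene models against a genome
#'
#' CDS parts are concatenated in transcription order (minus-strand genes are
#' reverse-complemented) and translated with the standard genetic code.  A
#' trailing incomplete codon is dropped with a warning.
#'
#' @param genes a `gene_models` data.frame with non-empty `cds_parts`.
#' @param genome a [Biostrings::DNAStringSet] named by chromosome.
#' @return an [Biostrings::AAStringSet] named by `gene_id`.
#' @export
translate_cds <- function(genes, genome) {
  seqs <- vapply(seq_len(nrow(genes)), function(i) {
    cp <- genes$cds_parts[[i]]
    stop_if_not(nrow(cp) > 0, "gene %s has no CDS parts", genes$gene_id[i])
    chr <- genome[[genes$chromosome[i]]]
    s <- paste(vapply(seq_len(nrow(cp)),
                      function(k) as.character(Biostrings::subseq(chr, cp[k, "start"], cp[k, "end"])),
                      character(1)), collapse = "")
    if (genes$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    if (nchar(s) %% 3 != 0) {
      warning("gene ", genes$gene_id[i], ": trailing incomplete codon dropped")
      s <- substr(s, 1, nchar(s) - nchar(s) %% 3)
    }
    s
  }, character(1))
  aa <- Biostrings::translate(Biostrings::DNAStringSet(seqs), no.init.codon = TRUE)
  names(aa) <- genes$gene_id
  aa
}

## ---- domain-hit tables -----------------------------------------------------

#' Shipped domain-label normalization table
#'
#' Maps the model names emitted by HMM/CDD scans (e.g. `NB-ARC`,
#' `RX-CC_like`, `TIR_2`) onto the five canonical NLR part labels.  The
#' table ships as a plain TSV in `extdata` and can be replaced or extended
#' by the user.
#'
#' @param path optional path to a replacement table (columns `pattern`,
#'   `label`; `pattern` is a case-insensitive regular expression).
#' @return data.frame with columns `pattern`, `label`.
#' @export
domain_alias_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "domain_aliases.tsv", package = "nlratlas")
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Normalize raw domain names to canonical labels
#'
#' @param names character vector of raw domain/model names.
#' @param aliases alias table from [domain_alias_table()].
#' @return character vector over `NBS`, `TIR`, `CC`, `RPW8`, `LRR`, `OTHER`.
#' @export
normalize_domain_label <- function(names, aliases = domain_alias_table()) {
  out <- rep("OTHER", length(names))
  for (i in seq_len(nrow(aliases))) {
    hit <- grepl(aliases$pattern[i], names, ignore.case = TRUE) & out == "OTHER"
    out[hit] <- aliases$label[i]
  }
  out
}

#' Read a HMMER/CDD-style tabular domain-hit file
#'
#' Expects a header line and tab-separated columns `protein_id`, `domain`,
#' `ali_start`, `ali_end`, `e_value` and optionally `coverage` (fraction of
#' the domain model covered by the alignment; assumed 1 when absent).
#'
#' @param path path to the TSV.
#' @param source provenance of the hits: `"hmm"`, `"cdd"` or `"homology"`.
#' @param aliases domain-label normalization table.
#' @return data.frame with columns `protein_id`, `domain_label` (canonical),
#'   `domain_name` (raw), `ali_start`, `ali_end`, `e_value`, `coverage`,
#'   `source`.
#' @export
read_domain_hits <- function(path, source = c("hmm", "cdd", "homology"),
                             aliases = domain_alias_table()) {
  source <- match.arg(source)
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "domain", "ali_start", "ali_end", "e_value")
  stop_if_not(all(need %in% names(d)),
              "domain-hit table %s lacks columns: %s", path,
              paste(setdiff(need, names(d)), collapse = ", "))
  if (!"coverage" %in% names(d)) d$coverage <- 1
  as_domain_hits(data.frame(
    protein_id = as.character(d$protein_id),
    domain_name = as.character(d$domain),
    ali_start = as.integer(d$ali_start),
    ali_end = as.integer(d$ali_end),
    e_value = as.numeric(d$e_value),
    coverage = as.numeric(d$coverage),
    source = source,
    stringsAsFactors = FALSE
  ), aliases = aliases)
}

#' Validate and label an in-memory domain-hit table
#' @param d data.frame with `protein_id`, `domain_name`, `ali_start`,
#'   `ali_end`, `e_value`, optional `coverage`, `source`.
#' @param aliases domain-label normalization table.
#' @return validated data.frame with `domain_label` added.
#' @export
as_domain_hits <- function(d, aliases = domain_alias_table()) {
  if (!"coverage" %in% names(d)) d$coverage <- 1
  if (!"source" %in% names(d)) d$source <- "hmm"
  stop_if_not(all(d$ali_start >= 1) && all(d$ali_end >= d$ali_start),
              "domain hit with invalid alignment coordinates")
  stop_if_not(all(d$e_value >= 0), "domain hit with negative E-value")
  d$domain_label <- normalize_domain_label(d$domain_name, aliases)
  d[c("protein_id", "domain_label", "domain_name", "ali_start", "ali_end",
      "e_value", "coverage", "source")]
}

#' Read BLAST tabular (outfmt 6) homology hits
#'
#' Standard 12-column headerless BLAST output.  Self-hits are kept but
#' flagged in the `self` column.
#'
#' @param path path to the tabular file.
#' @return data.frame with the 12 outfmt-6 columns (named `query_id`,
#'   `subject_id`, `pct_identity`, `ali_length`, `mismatches`, `gap_open`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `e_value`, `bit_score`) plus
#'   logical `self`.
#' @export
read_homology_hits <- function(path) {
  cols <- c("query_id", "subject_id", "pct_identity", "ali_length",
            "mismatches", "gap_open", "q_start", "q_end", "s_start", "s_end",
            "e_value", "bit_score")
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stop_if_not(ncol(d) == 12L, "expected 12 tab-separated columns in %s, found %d",
              path, ncol(d))
  names(d) <- cols
  stop_if_not(all(d$e_value >= 0), "homology hit with negative E-value")
  stop_if_not(all(d$pct_identity >= 0 & d$pct_identity <= 100),
              "percent identity outside [0,100] in %s", path)
  d$self <- d$query_id == d$subject_id
  d
}

#' Read an FPKM expression matrix
#'
#' Tab-separated, header line with sample names, first column `gene_id`.
#'
#' @param path path to the TSV.
#' @return numeric matrix (genes x samples) with dimnames.
#' @export
read_fpkm <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stop_if_not(names(d)[1] == "gene_id", "first column of %s must be gene_id", path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  stop_if_not(!anyDuplicated(rownames(m)) && !anyDuplicated(colnames(m)),
              "duplicated gene or sample labels in %s", path)
  stop_if_not(all(m >= 0), "negative FPKM values in %s", path)
  m
}

#' Read a sample-to-group mapping
#' @param path TSV with columns `sample_id`, `group`.
#' @return data.frame with `sample_id`, `group`.
#' @export
read_groups <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stop_if_not(all(c("sample_id", "group") %in% names(d)),
              "%s must have columns sample_id and group", path)
  d
}

## ---- writers ---------------------------------------------------------------

#' Write a phylogenetic tree to Newick
#'
#' Branch lengths are kept; bootstrap supports (if present as
#' `tree$node.label`) become internal-node labels.
#'
#' @param tree an [ape::phylo] tree with at least 2 leaves.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stop_if_not(inherits(tree, "phylo"), "tree must be a phylo object")
  stop_if_not(length(tree$tip.label) >= 2, "tree must have at least 2 leaves")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write synteny blocks as a Circos-style link file
#'
#' One anchor pair per line: `chrA startA endA chrB startB endB block_id`
#' (tab-separated, with header).  Gene coordinates are looked up from the
#' annotation.
#'
#' @param blocks result of [chain_anchors()] (list with `blocks`, `anchors`).
#' @param genes `gene_models` annotation covering all anchor genes.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_links <- function(blocks, genes, path) {
  an <- blocks$anchors
  hdr <- "chr_a\tstart_a\tend_a\tchr_b\tstart_b\tend_b\tblock_id"
  if (is.null(an) || nrow(an) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  ia <- match(an$gene_a, genes$gene_id)
  ib <- match(an$gene_b, genes$gene_id)
  stop_if_not(!anyNA(ia) && !anyNA(ib), "anchor gene missing from annotation")
  writeLines(c(hdr, sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s",
                            genes$chromosome[ia], genes$start[ia], genes$end[ia],
                            genes$chromosome[ib], genes$start[ib], genes$end[ib],
                            an$block_id)), path)
  invisible(path)
}

#' Write gene clusters as BED
#'
#' The only 0-based half-open output: internal 1-based inclusive spans are
#' converted at write time (`start-1`, `end`).
#'
#' @param clusters result of [detect_clusters()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_clusters_bed <- function(clusters, path) {
  cl <- clusters$clusters
  if (nrow(cl) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d", cl$chromosome, cl$start - 1L, cl$end,
                     cl$cluster_id, cl$n), path)
  invisible(path)
}

#' Write a set of report tables as round-trippable TSVs
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(tables, dir) {
  stop_if_not(is.list(tables) && length(names(tables)) == length(tables),
              "tables must be a named list")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    tb <- tables[[nm]]
    tb <- tb[!vapply(tb, is.list, logical(1))]  # drop list-columns
    write.table(tb, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
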