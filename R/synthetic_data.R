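## Synthetic genomes with planted ground truth.  The generator emits every
## input the pipeline consumes (gene models, protein sequences, domain-hit
## tables, reference and all-vs-all homology hits, FPKM matrix) plus a truth
## manifest, so each stage can be scored exactly.  NLR proteins are
## concatenations of domain blocks; the NBS block is assembled from the
## shipped motif-library consensus in canonical order with subclass-specific
## linker variation.

## ---- fixed sequence blocks -------------------------------------------------

.SIM_CC   <- "MADALVSAVLEQLASIIREEAKLLGGVHDDVQFIKDELESMQAFLKDA"
.SIM_TIR  <- "MAYDVFLSFRGEDTRKTFTSHLYAALDRKGIYTFIDDEELRRGDEISPALLKAIEESRIAIIVFSKNYASSTWCLDELVKIMEC"
.SIM_RPW8 <- "MGEIIGGALVSEAIGVLLDRLASPEFLNFIRGKKLDEKLLKKLKTTLLS"
.SIM_LRR  <- paste(rep("LPELGNLKSLQYLDLSGNKLTGSIP", 6), collapse = "")
.SIM_LINKER <- "AQDVSKEWVEKI"   # inter-motif linker template, mutable

## ---- configuration ---------------------------------------------------------

#' Simulation configuration
#'
#' The defaults define the package's reference study conditions: a compact
#' eight-chromosome genome of about 500 genes with 60 planted NLRs whose
#' architectures, clusters, duplication roles, syntenic runs and expression
#' folds are known.
#'
#' @param seed mandatory integer seed; every random draw derives from it.
#' @param n_background_genes background (non-NLR) gene count (default 440).
#' @param chr_length maximum chromosome length in bp (default 6e6); the
#'   layout errors if a chromosome cannot fit.
#' @param plan planted-NLR plan, see [default_nlr_plan()].
#' @param spurious_hit_rate spurious homology rows added, as a fraction of
#'   the true homology rows (default 0).
#' @param protein_divergence per-gene linker mutation rate from the
#'   subclass scaffold (default 0.05).
#' @param copy_divergence extra linker divergence of a duplicate from its
#'   family founder (default 0.03).
#' @param expression_noise_sd multiplicative log-normal noise sd on FPKM
#'   (default 0.1).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, n_background_genes = 440L, chr_length = 6e6,
                       plan = default_nlr_plan(), spurious_hit_rate = 0,
                       protein_divergence = 0.05, copy_divergence = 0.03,
                       expression_noise_sd = 0.1) {
  stop_if_not(!missing(seed) && length(seed) == 1 && is.finite(seed),
              "sim_config requires a seed")
  structure(list(seed = as.integer(seed),
                 n_background_genes = as.integer(n_background_genes),
                 chr_length = chr_length, plan = plan,
                 spurious_hit_rate = spurious_hit_rate,
                 protein_divergence = protein_divergence,
                 copy_divergence = copy_divergence,
                 expression_noise_sd = expression_noise_sd),
            class = "sim_config")
}

#' Default planted-NLR plan
#'
#' Sixty NLR genes across eight chromosomes: 15 physical clusters (sizes 2
#' to 7) and 20 singletons; 16 tandem, 8 proximal, 10 dispersed and 12
#' segmental duplicates (two collinear runs of six genes each) plus 14
#' genes without homologs; subclass mix 35 CNL / 21 TNL / 4 RNL with
#' typical and atypical architecture codes; a handful of integrated
#' domains, planted motif corruptions, and expression classes (2.5-fold
#' induction, absent-in-susceptible, silent, flat).
#'
#' @return list with `nlr` (per-gene table), `islands` (physical layout
#'   units), `seg_runs`, `dup_pairs`.
#' @export
default_nlr_plan <- function() {
  nlr <- read.delim(text = "id\tsubclass\tcode\tintegrated\tmotif_corrupt\texpr_class
N01\tRNL\tRNL\tPLN03210\t\tup
N02\tRNL\tRNL\tPLN03210\t\tflat
N03\tCNL\tCNL\t\t\tup
N04\tCNL\tCNL\t\t\tflat
N05\tCNL\tN\t\t\tabsent_s
N06\tCNL\tCNL\t\t\tup
N07\tCNL\tCNL\t\t\tflat
N08\tTNL\tNL\t\t\tsilent
N09\tCNL\tCNL\t\t\tflat
N10\tTNL\tTNL\tPLN03150\t\tup
N11\tTNL\tTNL\t\t\tflat
N12\tCNL\tNL\t\t\tup
N13\tCNL\tNL\t\t\tflat
N14\tCNL\tCN\t\tkinase-2\tflat
N15\tTNL\tN\t\tP-loop,kinase-2,RNBS-C,GLPL,RNBS-D,MHDV\tsilent
N16\tCNL\tNL\t\tGLPL\tflat
N17\tCNL\tCN\t\t\tflat
N18\tCNL\tCN\t\t\tflat
N19\tTNL\tTNL\t\t\tup
N20\tCNL\tCNL\t\t\tflat
N21\tCNL\tCN\t\t\tflat
N22\tTNL\tTNL\t\t\tup
N23\tTNL\tTNL\t\t\tflat
N24\tTNL\tNL\t\t\tabsent_s
N25\tCNL\tCNL\t\t\tflat
N26\tTNL\tTN\t\t\tflat
N27\tTNL\tTN\t\t\tup
N28\tTNL\tTN\t\t\tflat
N29\tCNL\tN\t\t\tflat
N30\tCNL\tCNL\tCDC6\t\tsilent
N31\tCNL\tN\t\t\tflat
N32\tCNL\tCNL\t\t\tup
N33\tTNL\tTNL\t\t\tflat
N34\tCNL\tNL\t\t\tflat
N35\tCNL\tCNL\t\t\tflat
N36\tCNL\tCNL\t\t\tflat
N37\tTNL\tTNL\t\t\tup
N38\tTNL\tTNL\t\t\tflat
N39\tCNL\tCNL\t\t\tflat
N40\tTNL\tTNL\t\t\tflat
N41\tCNL\tNL\t\t\tflat
N42\tCNL\tCNL\t\t\tup
N43\tCNL\tCNL\t\t\tflat
N44\tTNL\tNL\t\t\tflat
N45\tCNL\tCN\t\t\tup
N46\tCNL\tNL\t\t\tsilent
N47\tTNL\tTNL\t\t\tabsent_s
N48\tCNL\tCNL\t\t\tflat
N49\tCNL\tCN\t\t\tflat
N50\tTNL\tTNL\t\t\tup
N51\tTNL\tTNL\t\t\tflat
N52\tCNL\tCNL\t\t\tflat
N53\tCNL\tN\t\t\tflat
N54\tTNL\tTNL\t\t\tflat
N55\tCNL\tCN\t\t\tflat
N56\tTNL\tTNL\t\t\tsilent
N57\tRNL\tRNL\t\t\tup
N58\tRNL\tRNL\t\t\tflat
N59\tCNL\tCN\t\tMHDV\tabsent_s
N60\tCNL\tCNL\t\t\tflat", stringsAsFactors = FALSE)

  island <- function(id, chr, slots) list(id = id, chr = chr, slots = slots)
  islands <- list(
    island("I01", "chr1", c("N01", "N02")),
    island("I02", "chr1", c("N03", "B", "B", "B", "N04", "N05")),
    island("I03", "chr2", c("N06", "N07")),
    island("I04", "chr2", "N08"),
    island("I05", "chr2", "N09"),
    island("I06", "chr3", c("N10", "N11", "B", "N12", "B", "B", "B",
                            "N13", "N14", "N15", "N16")),
    island("I07", "chr3", c("N17", "N18")),
    island("I08", "chr3", c("N19", "B", "N20", "B", "N21", "B")),
    island("I09", "chr4", c("N22", "B", "B", "N23")),
    island("I10", "chr4", "N24"),
    island("I11", "chr4", "N25"),
    island("I12", "chr4", "N26"),
    island("I13", "chr5", c("N27", "N28")),
    island("I14", "chr5", "N29"),
    island("I15", "chr5", "N30"),
    island("I16", "chr5", "N31"),
    island("I17", "chr6", c("N32", "B", "N33", "B", "N34", "B")),
    island("I18", "chr6", c("N35", "N36")),
    island("I19", "chr6", "N37"),
    island("I20", "chr6", "N38"),
    island("I21", "chr7", c("N39", "B", "N40", "B", "N41", "B")),
    island("I22", "chr7", c("N42", "B", "B", "N43")),
    island("I23", "chr7", "N44"),
    island("I24", "chr7", "N45"),
    island("I25", "chr7", "N46"),
    island("I26", "chr8", c("N47", "B", "N48", "B", "N49", "B")),
    island("I27", "chr8", c("N50", "N51")),
    island("I28", "chr8", "N52"),
    island("I29", "chr8", "N53"),
    island("I30", "chr8", "N54"),
    island("I31", "chr8", "N55"),
    island("I32", "chr8", "N56"),
    island("I33", "chr8", c("N57", "N58")),
    island("I34", "chr8", "N59"),
    island("I35", "chr8", "N60")
  )
  seg_runs <- list(list(run = "S1", src = "I17", tgt = "I21"),
                   list(run = "S2", src = "I08", tgt = "I26"))
  dup_pairs <- data.frame(
    a = c("N01", "N06", "N10", "N17", "N27", "N35", "N50", "N57",
          "N03", "N12", "N22", "N42",
          "N24", "N25", "N29", "N37", "N45"),
    b = c("N02", "N07", "N11", "N18", "N28", "N36", "N51", "N58",
          "N04", "N13", "N23", "N43",
          "N44", "N52", "N53", "N54", "N55"),
    role = c(rep("tandem", 8), rep("proximal", 4), rep("dispersed", 5)),
    stringsAsFactors = FALSE
  )
  list(nlr = nlr, islands = islands, seg_runs = seg_runs,
       dup_pairs = dup_pairs)
}

## ---- sequence assembly -----------------------------------------------------

rand_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# NBS scaffold per subclass: motif consensus blocks (wildcards resolved to
# 'A') joined by linkers whose every third position carries the subclass
# letter; returns the string and the motif block offsets.
nbs_scaffold <- function(subclass, models) {
  letter <- c(CNL = "C", TNL = "T", RNL = "R")[[subclass]]
  linker <- strsplit(.SIM_LINKER, "")[[1]]
  linker[seq(1, length(linker), by = 3)] <- letter
  linker <- paste(linker, collapse = "")
  parts <- character(0); offsets <- list(); pos <- 0L
  linker_pos <- integer(0)
  add <- function(s, mutable) {
    parts <<- c(parts, s)
    if (mutable) linker_pos <<- c(linker_pos, pos + seq_len(nchar(s)))
    pos <<- pos + nchar(s)
  }
  add(linker, TRUE)
  for (nm in names(models)) {
    block <- gsub("x", "A", models[[nm]]$consensus, ignore.case = FALSE)
    offsets[[nm]] <- c(pos + 1L, pos + nchar(block))
    add(block, FALSE)
    add(linker, TRUE)
  }
  list(seq = paste(parts, collapse = ""), motif_offsets = offsets,
       linker_pos = linker_pos)
}

mutate_positions <- function(seq, positions, rate) {
  if (rate <= 0 || !length(positions)) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- positions[runif(length(positions)) < rate]
  if (length(hit))
    chars[hit] <- sample(AA20, length(hit), replace = TRUE)
  paste(chars, collapse = "")
}

## ---- the generator ---------------------------------------------------------

#' Simulate a genome with planted NLR truth
#'
#' Produces, deterministically from the seed, all pipeline inputs: a gene
#' annotation, protein sequences, HMM/CDD-style domain hits (including
#' filter decoys), reference-NLR homology hits, an all-vs-all homology
#' table (true duplicate relationships plus optional spurious rows), an
#' FPKM matrix with a resistant and a susceptible group of three
#' replicates, and a truth manifest covering every planted gene.
#'
#' @param config a [sim_config()].
#' @return list of class `nlr_sim` with `genes`, `proteins`, `domain_hits`,
#'   `ref_hits`, `homology`, `fpkm`, `groups`, `truth`, `config`.
#' @export
simulate_genome <- function(config) {
  stop_if_not(inherits(config, "sim_config"), "config must come from sim_config()")
  set.seed(config$seed)
  plan <- config$plan
  models <- motif_library()
  req <- names(models)[vapply(models, `[[`, logical(1), "required")]

  ## -- layout ----------------------------------------------------------------
  chroms <- sort(unique(vapply(plan$islands, `[[`, character(1), "chr")))
  isl_by_chr <- split(plan$islands, vapply(plan$islands, `[[`, character(1), "chr"))
  n_bg_in_islands <- sum(vapply(plan$islands, function(i) sum(i$slots == "B"), integer(1)))
  n_free_bg <- config$n_background_genes - n_bg_in_islands
  stop_if_not(n_free_bg >= 0, "n_background_genes smaller than the plan's island spacers")
  bg_share <- diff(round(seq(0, n_free_bg, length.out = length(chroms) + 1L)))

  rows <- list(); counter <- 0L
  plant2gene <- character(0)
  island_members <- list()  # island id -> gene ids (NLR only)
  slot_gene <- list()       # island id -> gene id per slot (all slots)
  for (ci in seq_along(chroms)) {
    chr <- chroms[ci]
    isl <- isl_by_chr[[chr]]
    nruns <- length(isl) + 1L
    runs <- diff(round(seq(0, bg_share[ci], length.out = nruns + 1L)))
    cursor <- 50000 + round(runif(1, 0, 10000))
    last_nlr_end <- -Inf
    put_gene <- function(is_nlr, plant = NA_character_) {
      counter <<- counter + 1L
      len <- round(runif(1, 2000, 5000))
      start <- cursor
      end <- start + len - 1L
      cursor <<- end + round(runif(1, 1000, 5000))
      gid <- sprintf("MruG%05d", counter)
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = gid, chromosome = chr,
        strand = sample(c("+", "-"), 1), start = start, end = end,
        stringsAsFactors = FALSE)
      if (is_nlr) { plant2gene[plant] <<- gid; last_nlr_end <<- end }
      gid
    }
    for (k in seq_len(nruns)) {
      for (b in seq_len(runs[k])) put_gene(FALSE)
      if (k <= length(isl)) {
        if (is.finite(last_nlr_end))
          cursor <- max(cursor, last_nlr_end + 300000 + round(runif(1, 0, 200000)))
        ids <- character(length(isl[[k]]$slots))
        for (s in seq_along(isl[[k]]$slots)) {
          tok <- isl[[k]]$slots[s]
          ids[s] <- put_gene(tok != "B", plant = if (tok != "B") tok else NA)
        }
        slot_gene[[isl[[k]]$id]] <- ids
        island_members[[isl[[k]]$id]] <- ids[isl[[k]]$slots != "B"]
      }
    }
    stop_if_not(cursor <= config$chr_length,
                "infeasible layout: %s needs %d bp but chr_length is %g",
                chr, cursor, config$chr_length)
  }
  genes <- do.call(rbind, rows)
  genes$cds_parts <- lapply(seq_len(nrow(genes)), function(i)
    cbind(start = genes$start[i], end = genes$end[i]))
  ord <- order(chrom_order_key(genes$chromosome), genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  class(genes) <- c("gene_models", "data.frame")

  nlr <- plan$nlr
  nlr$gene_id <- plant2gene[nlr$id]
  stop_if_not(!anyNA(nlr$gene_id), "plan NLRs not all placed")
  gene_chr <- setNames(genes$chromosome, genes$gene_id)
  nlr$chromosome <- gene_chr[nlr$gene_id]

  ## -- proteins + domain evidence -------------------------------------------
  # family founders: tandem/proximal/dispersed pairs share a founder; the
  # two islands of a segmental run are slot-wise copies.
  founder_of <- setNames(nlr$id, nlr$id)
  for (i in seq_len(nrow(plan$dup_pairs)))
    founder_of[plan$dup_pairs$b[i]] <- plan$dup_pairs$a[i]
  gene2plant <- setNames(nlr$id, nlr$gene_id)
  for (run in plan$seg_runs) {
    src <- slot_gene[[run$src]]; tgt <- slot_gene[[run$tgt]]
    for (s in seq_along(src)) {
      ps <- gene2plant[src[s]]; pt <- gene2plant[tgt[s]]
      if (!is.na(ps) && !is.na(pt)) founder_of[pt] <- ps
    }
  }

  scaffolds <- lapply(setNames(c("CNL", "TNL", "RNL"), c("CNL", "TNL", "RNL")),
                      nbs_scaffold, models = models)
  founder_nbs <- list()
  proteins <- character(0)
  dom_rows <- list()
  truth_motifs_absent <- setNames(vector("list", nrow(nlr)), nlr$id)

  nlr_order <- order(nlr$id)
  # founders first so copies can derive from them
  for (pass in 1:2) for (i in nlr_order) {
    id <- nlr$id[i]
    is_founder <- founder_of[[id]] == id
    if ((pass == 1) != is_founder) next
    sc <- scaffolds[[nlr$subclass[i]]]
    nbs <- if (is_founder) {
      mutate_positions(sc$seq, sc$linker_pos, config$protein_divergence)
    } else {
      mutate_positions(founder_nbs[[founder_of[[id]]]], sc$linker_pos,
                       config$copy_divergence)
    }
    if (is_founder) founder_nbs[[id]] <- nbs
    corrupt <- if (nzchar(nlr$motif_corrupt[i]))
      strsplit(nlr$motif_corrupt[i], ",")[[1]] else character(0)
    if (length(corrupt)) {
      chars <- strsplit(nbs, "")[[1]]
      for (m in corrupt) {
        off <- sc$motif_offsets[[m]]
        chars[off[1]:off[2]] <- sample(AA20, off[2] - off[1] + 1L, replace = TRUE)
      }
      nbs <- paste(chars, collapse = "")
    }
    truth_motifs_absent[[id]] <- intersect(corrupt, req)

    code <- nlr$code[i]
    lead <- substr(code, 1, 1) %in% c("C", "T", "R")
    has_lrr <- substr(code, nchar(code), nchar(code)) == "L"
    nterm <- if (!lead) "" else switch(nlr$subclass[i], CNL = .SIM_CC,
                                       TNL = .SIM_TIR, RNL = .SIM_RPW8)
    lrr <- if (has_lrr) .SIM_LRR else ""
    idom <- if (nzchar(nlr$integrated[i])) rand_aa(0) else ""  # block added below
    prot <- paste0(nterm, nbs, lrr)
    nbs_start <- nchar(nterm) + 1L
    nbs_end <- nchar(nterm) + nchar(nbs)
    gid <- nlr$gene_id[i]
    add_hit <- function(domain, s, e, ev, src, cov = 1) {
      dom_rows[[length(dom_rows) + 1L]] <<- data.frame(
        protein_id = gid, domain_name = domain, ali_start = s, ali_end = e,
        e_value = ev, coverage = cov, source = src, stringsAsFactors = FALSE)
    }
    add_hit("NB-ARC", nbs_start, nbs_end, 10^-runif(1, 40, 80), "hmm")
    if (lead) {
      dn <- switch(nlr$subclass[i], CNL = "RX-CC_like", TNL = "TIR", RNL = "RPW8")
      add_hit(dn, 1L, nchar(nterm), 10^-runif(1, 10, 30), "cdd")
    }
    if (has_lrr)
      add_hit("LRR_8", nbs_end + 1L, nbs_end + nchar(lrr), 10^-runif(1, 8, 20), "cdd")
    if (nzchar(nlr$integrated[i])) {
      block <- rand_aa(30)
      s <- nchar(prot) + 1L
      prot <- paste0(prot, block)
      add_hit(nlr$integrated[i], s, s + 29L, 1e-8, "cdd", cov = 1)
    }
    proteins[gid] <- prot
  }

  # background proteins
  bg_ids <- setdiff(genes$gene_id, nlr$gene_id)
  for (gid in bg_ids) proteins[gid] <- rand_aa(round(runif(1, 200, 400)))
  proteins <- proteins[genes$gene_id]

  # filter decoys: weak/unsupported NBS hits on background genes
  decoys <- head(bg_ids, 3L)
  dec_e <- c(2e-4, 3e-4, 5e-5)
  for (k in seq_along(decoys))
    dom_rows[[length(dom_rows) + 1L]] <- data.frame(
      protein_id = decoys[k], domain_name = "NB-ARC", ali_start = 10L,
      ali_end = 250L, e_value = dec_e[k], coverage = 1, source = "hmm",
      stringsAsFactors = FALSE)
  domain_hits <- as_domain_hits(do.call(rbind, dom_rows))

  ## -- reference homology (subclass-bearing subjects) ------------------------
  fam_idx <- as.integer(factor(founder_of[nlr$id]))
  ref_hits <- data.frame(
    query_id = nlr$gene_id,
    subject_id = sprintf("At%s%03d", nlr$subclass, fam_idx),
    pct_identity = round(runif(nrow(nlr), 55, 75), 1),
    ali_length = nchar(proteins[nlr$gene_id]),
    mismatches = 0L, gap_open = 0L, q_start = 1L,
    q_end = nchar(proteins[nlr$gene_id]), s_start = 1L,
    s_end = nchar(proteins[nlr$gene_id]),
    e_value = 10^-runif(nrow(nlr), 40, 90),
    bit_score = round(runif(nrow(nlr), 200, 600), 1),
    stringsAsFactors = FALSE)
  ref_hits$self <- FALSE
  # decoy 3 passes the NBS filter but gets no reference support

  ## -- all-vs-all homology ---------------------------------------------------
  true_pairs <- list()
  for (i in seq_len(nrow(plan$dup_pairs)))
    true_pairs[[length(true_pairs) + 1L]] <-
      c(plant2gene[plan$dup_pairs$a[i]], plant2gene[plan$dup_pairs$b[i]])
  seg_pair_tab <- list()
  for (run in plan$seg_runs) {
    src <- slot_gene[[run$src]]; tgt <- slot_gene[[run$tgt]]
    for (s in seq_along(src)) {
      true_pairs[[length(true_pairs) + 1L]] <- c(src[s], tgt[s])
      seg_pair_tab[[length(seg_pair_tab) + 1L]] <- data.frame(
        run = run$run, gene_src = src[s], gene_tgt = tgt[s],
        is_nlr = src[s] %in% nlr$gene_id, stringsAsFactors = FALSE)
    }
  }
  seg_pairs <- do.call(rbind, seg_pair_tab)

  hom_row <- function(q, s) {
    lq <- nchar(proteins[[q]])
    ident <- round(runif(1, 85, 98), 1)
    data.frame(query_id = q, subject_id = s, pct_identity = ident,
               ali_length = lq, mismatches = round(lq * (1 - ident / 100)),
               gap_open = 0L, q_start = 1L, q_end = lq, s_start = 1L,
               s_end = nchar(proteins[[s]]),
               e_value = 10^-runif(1, 60, 120),
               bit_score = round(2 * lq * ident / 100, 1),
               stringsAsFactors = FALSE)
  }
  hom <- list()
  for (p in true_pairs) {
    hom[[length(hom) + 1L]] <- hom_row(p[1], p[2])
    hom[[length(hom) + 1L]] <- hom_row(p[2], p[1])
  }
  for (gid in nlr$gene_id) {   # self-hits, flagged downstream
    r <- hom_row(gid, gid); r$pct_identity <- 100; r$mismatches <- 0L
    hom[[length(hom) + 1L]] <- r
  }
  n_true_rows <- 2L * length(true_pairs)
  n_spur <- round(config$spurious_hit_rate * n_true_rows)
  spurious <- character(0)
  if (n_spur > 0) {
    for (k in seq_len(n_spur)) {
      pr <- sample(genes$gene_id, 2L)
      r <- hom_row(pr[1], pr[2])
      r$pct_identity <- round(runif(1, 30, 45), 1)
      r$e_value <- 10^-runif(1, 6, 10)
      hom[[length(hom) + 1L]] <- r
      spurious <- c(spurious, paste(pr, collapse = "~"))
    }
  }
  homology <- do.call(rbind, hom)
  homology$self <- homology$query_id == homology$subject_id

  ## -- expression ------------------------------------------------------------
  samples <- c("R1", "R2", "R3", "S1", "S2", "S3")
  groups <- data.frame(sample_id = samples,
                       group = rep(c("resistant", "susceptible"), each = 3L),
                       stringsAsFactors = FALSE)
  fpkm <- matrix(0, nrow(genes), 6L, dimnames = list(genes$gene_id, samples))
  noise <- function(mu, n) round(mu * exp(rnorm(n, 0, config$expression_noise_sd)), 3)
  for (gid in bg_ids) fpkm[gid, ] <- noise(10^runif(1, 0, 1.5), 6L)
  true_fold <- setNames(rep(1, nrow(nlr)), nlr$id)
  for (i in seq_len(nrow(nlr))) {
    gid <- nlr$gene_id[i]
    base <- 10^runif(1, 0.3, 1.3)
    fpkm[gid, ] <- switch(nlr$expr_class[i],
      flat = noise(base, 6L),
      up = c(noise(base * 2.5, 3L), noise(base, 3L)),
      absent_s = c(noise(base, 3L), 0, 0, 0),
      silent = rep(0, 6L))
    true_fold[nlr$id[i]] <- switch(nlr$expr_class[i], flat = 1, up = 2.5,
                                   absent_s = Inf, silent = 1)
  }

  ## -- truth manifest --------------------------------------------------------
  cluster_of <- setNames(rep(NA_character_, nrow(nlr)), nlr$id)
  for (isl in plan$islands) {
    mem <- island_members[[isl$id]]
    if (length(mem) >= 2L) cluster_of[gene2plant[mem]] <- isl$id
  }
  dup_label <- setNames(rep("singleton_no_homolog", nrow(nlr)), nlr$id)
  seg_nlr <- gene2plant[c(seg_pairs$gene_src[seg_pairs$is_nlr],
                          seg_pairs$gene_tgt[seg_pairs$is_nlr])]
  dup_label[seg_nlr] <- "segmental"
  for (i in seq_len(nrow(plan$dup_pairs))) {
    dup_label[plan$dup_pairs$a[i]] <- plan$dup_pairs$role[i]
    dup_label[plan$dup_pairs$b[i]] <- plan$dup_pairs$role[i]
  }
  truth_nlr <- data.frame(
    plant_id = nlr$id, gene_id = nlr$gene_id, chromosome = nlr$chromosome,
    subclass = nlr$subclass, code = nlr$code,
    typical = nlr$code %in% c("CNL", "TNL", "RNL"),
    cluster = unname(cluster_of[nlr$id]),
    dup_label = unname(dup_label[nlr$id]),
    integrated = nlr$integrated,
    expr_class = nlr$expr_class, true_fold = unname(true_fold[nlr$id]),
    expressed = nlr$expr_class != "silent",
    stringsAsFactors = FALSE)
  truth_nlr$motifs_absent <- unname(truth_motifs_absent[nlr$id])

  truth_clusters <- do.call(rbind, lapply(plan$islands, function(isl) {
    mem <- island_members[[isl$id]]
    if (length(mem) < 2L) return(NULL)
    data.frame(cluster = isl$id, chromosome = isl$chr, n = length(mem),
               stringsAsFactors = FALSE)
  }))
  synt_truth <- seg_pairs[seg_pairs$is_nlr, c("run", "gene_src", "gene_tgt")]

  structure(list(
    genes = genes, proteins = Biostrings::AAStringSet(proteins),
    domain_hits = domain_hits, ref_hits = ref_hits, homology = homology,
    fpkm = fpkm, groups = groups,
    truth = list(nlr = truth_nlr, clusters = truth_clusters,
                 seg_pairs = seg_pairs, syntenic_nlr_pairs = synt_truth,
                 decoys = decoys, n_spurious_hits = n_spur,
                 spurious = spurious),
    config = config), class = "nlr_sim")
}

#' Write a simulated genome to pipeline input files
#'
#' Emits GFF3, protein FASTA, HMM and CDD domain-hit TSVs, reference and
#' all-vs-all homology tables (BLAST outfmt-6), FPKM and group TSVs, and
#' the truth manifest as JSON.
#'
#' @param sim an `nlr_sim` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- c(gff = file.path(dir, "annotation.gff3"),
         faa = file.path(dir, "proteins.faa"),
         hmm = file.path(dir, "domain_hits_hmm.tsv"),
         cdd = file.path(dir, "domain_hits_cdd.tsv"),
         ref = file.path(dir, "ref_hits.tsv"),
         hom = file.path(dir, "homology.tsv"),
         fpkm = file.path(dir, "fpkm.tsv"),
         groups = file.path(dir, "groups.tsv"),
         truth = file.path(dir, "truth.json"))
  write_gff3(sim$genes, p[["gff"]])
  Biostrings::writeXStringSet(sim$proteins, p[["faa"]])
  dh <- sim$domain_hits
  for (src in c("hmm", "cdd")) {
    d <- dh[dh$source == src, c("protein_id", "domain_name", "ali_start",
                                "ali_end", "e_value", "coverage")]
    names(d)[2] <- "domain"
    write.table(d, p[[src]], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ofmt6 <- function(d, path)
    write.table(d[setdiff(names(d), "self")], path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  ofmt6(sim$ref_hits, p[["ref"]])
  ofmt6(sim$homology, p[["hom"]])
  write.table(data.frame(gene_id = rownames(sim$fpkm), sim$fpkm,
                         check.names = FALSE),
              p[["fpkm"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$groups, p[["groups"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- sim$truth
  truth$nlr$motifs_absent <- vapply(truth$nlr$motifs_absent, paste,
                                    character(1), collapse = ",")
  jsonlite::write_json(truth, p[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(p)
}

#' Run the full pipeline on a simulated genome and score each stage
#'
#' Simulates a genome from `config`, runs [run_all()] on its outputs, and
#' scores every stage against the truth manifest: exact identification of
#' the planted set, subclass/architecture recovery, motif-presence
#' recovery, recovery of the planted cluster partition, duplication-label
#' accuracy, collinear-block and syntenic-pair recovery, expression-screen
#' sensitivity, and subclass monophyly on the typical-gene tree.
#'
#' @param config a [sim_config()].
#' @param bootstrap_reps bootstrap replicates for the tree stage (default
#'   0: topology only).
#' @return list with `scores` (named recovery rates in `[0,1]`, plus
#'   counts), `report` (the `nlr_report`), `sim`.
#' @export
end_to_end_recovery <- function(config, bootstrap_reps = 0L) {
  sim <- simulate_genome(config)
  report <- run_all(sim$genes, sim$proteins, sim$domain_hits, sim$ref_hits,
                    sim$homology, fpkm = sim$fpkm, groups = sim$groups,
                    group_r = "resistant", group_s = "susceptible",
                    bootstrap_reps = bootstrap_reps, seed = config$seed)
  tr <- sim$truth$nlr
  calls <- report$calls
  id_exact <- setequal(calls$gene_id, tr$gene_id)

  m <- match(tr$gene_id, calls$gene_id)
  class_ok <- !is.na(m) & calls$subclass[m] == tr$subclass & calls$code[m] == tr$code

  req <- attr(report$motifs, "required")
  mm <- match(tr$gene_id, report$motifs$gene_id)
  motif_ok <- vapply(seq_len(nrow(tr)), function(i) {
    if (is.na(mm[i])) return(FALSE)
    want <- setdiff(req, tr$motifs_absent[[i]])
    got <- req[as.logical(report$motifs[mm[i], req])]
    setequal(want, got)
  }, logical(1))

  # clusters: truth clusters exactly recovered as member sets (by gene id)
  alias2gene <- setNames(calls$gene_id, calls$alias)
  det_sets <- lapply(report$clusters$clusters$members,
                     function(a) sort(unname(alias2gene[a])))
  tr_sets <- lapply(split(tr$gene_id[!is.na(tr$cluster)],
                          tr$cluster[!is.na(tr$cluster)]), sort)
  cl_ok <- vapply(tr_sets, function(s)
    any(vapply(det_sets, identical, logical(1), y = s)), logical(1))
  singles_truth <- sort(tr$gene_id[is.na(tr$cluster)])
  singles_det <- sort(unname(alias2gene[report$clusters$singletons]))
  partition_exact <- all(cl_ok) && identical(singles_truth, singles_det) &&
    length(det_sets) == length(tr_sets)

  dm <- match(tr$gene_id, report$duplication$gene_id)
  dup_ok <- !is.na(dm) & report$duplication$label[dm] == tr$dup_label

  st <- sim$truth$syntenic_nlr_pairs
  det_pairs <- paste(pmin(report$syntenic$pairs$gene_a, report$syntenic$pairs$gene_b),
                     pmax(report$syntenic$pairs$gene_a, report$syntenic$pairs$gene_b))
  tr_pairs <- paste(pmin(st$gene_src, st$gene_tgt), pmax(st$gene_src, st$gene_tgt))
  synt_ok <- tr_pairs %in% det_pairs
  block_ok <- vapply(split(seq_len(nrow(st)), st$run), function(i)
    all(synt_ok[i]), logical(1))

  expr <- report$expression
  em <- match(tr$gene_id, expr$gene_id)
  up_truth <- tr$expr_class %in% c("up", "absent_s")
  sens <- if (any(up_truth)) mean(expr$flagged[em[up_truth]]) else NA_real_
  spec <- if (any(!up_truth)) mean(!expr$flagged[em[!up_truth]]) else NA_real_
  expressed_ok <- mean(expr$expressed[em] == tr$expressed)

  mono <- if (!is.null(report$clades)) all(report$clades$monophyletic) else NA

  list(scores = list(
    identification_exact = id_exact,
    n_called = nrow(calls), n_planted = nrow(tr),
    classification = mean(class_ok),
    motifs = mean(motif_ok),
    cluster_recovery = mean(cl_ok),
    partition_exact = partition_exact,
    duplication = mean(dup_ok),
    block_recovery = mean(block_ok),
    syntenic_pair_recovery = mean(synt_ok),
    expression_sensitivity = sens,
    expression_specificity = spec,
    expressed_agreement = expressed_ok,
    subclasses_monophyletic = mono,
    n_spurious_hits = sim$truth$n_spurious_hits),
    report = report, sim = sim)
}
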