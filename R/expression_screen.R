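## Resistant-vs-susceptible FPKM screen: expressed-gene calling, fold-change
## flagging with pseudocount, absent-in-one-variety class, heatmap export.

#' Call expressed genes from an FPKM matrix
#'
#' A gene is expressed when its FPKM exceeds `min_fpkm` in at least
#' `min_samples` samples.
#'
#' @param fpkm numeric gene x sample matrix.
#' @param min_fpkm strict FPKM threshold (default 0).
#' @param min_samples minimum qualifying samples (default 1).
#' @return named logical vector per gene.
#' @export
call_expressed <- function(fpkm, min_fpkm = 0, min_samples = 1L) {
  setNames(rowSums(fpkm > min_fpkm) >= min_samples, rownames(fpkm))
}

#' Fold-change screen between two sample groups
#'
#' Group means are taken over the biological replicates of each group; the
#' fold change is `(mean_r + pseudocount) / (mean_s + pseudocount)` and a
#' gene is flagged when `fold >= min_fold` (boundary inclusive).  When one
#' group mean is zero and the other positive, `absent_in` records the
#' silent group.
#'
#' @param fpkm numeric gene x sample matrix.
#' @param groups data.frame `sample_id`, `group` covering the columns.
#' @param group_r,group_s resistant and susceptible group names.
#' @param min_fold flagging threshold (default 1.5).
#' @param pseudocount added to both means (default 0.01) so zero
#'   denominators stay finite.
#' @return data.frame with `gene_id`, `mean_r`, `mean_s`, `fold_change`,
#'   `flagged`, `expressed`, `absent_in` (NA, or the silent group name).
#' @export
fold_screen <- function(fpkm, groups, group_r, group_s,
                        min_fold = 1.5, pseudocount = 0.01) {
  stop_if_not(all(c(group_r, group_s) %in% groups$group),
              "groups table lacks %s or %s", group_r, group_s)
  sr <- groups$sample_id[groups$group == group_r]
  ss <- groups$sample_id[groups$group == group_s]
  stop_if_not(all(c(sr, ss) %in% colnames(fpkm)),
              "FPKM matrix lacks samples of the requested groups")
  mr <- rowMeans(fpkm[, sr, drop = FALSE])
  ms <- rowMeans(fpkm[, ss, drop = FALSE])
  fold <- (mr + pseudocount) / (ms + pseudocount)
  absent <- ifelse(mr == 0 & ms > 0, group_r,
                   ifelse(ms == 0 & mr > 0, group_s, NA_character_))
  data.frame(gene_id = rownames(fpkm), mean_r = mr, mean_s = ms,
             fold_change = fold, flagged = fold >= min_fold,
             expressed = call_expressed(fpkm[, c(sr, ss), drop = FALSE]),
             absent_in = absent, row.names = NULL, stringsAsFactors = FALSE)
}

#' Heatmap-ready transformed expression matrix
#'
#' Rows are ordered by descending fold change; values are `log2(FPKM + 1)`
#' or row z-scores (constant rows map to 0 under `zscore-rows`).
#'
#' @param records result of [fold_screen()].
#' @param fpkm the FPKM matrix the records were computed from.
#' @param transform `"log2p1"` (default) or `"zscore-rows"`.
#' @param flagged_only restrict to flagged genes (default TRUE, matching
#'   the usual differential heatmap).
#' @return numeric matrix, rows in descending fold-change order.
#' @export
heatmap_export <- function(records, fpkm,
                           transform = c("log2p1", "zscore-rows"),
                           flagged_only = TRUE) {
  transform <- match.arg(transform)
  r <- records[order(-records$fold_change, records$gene_id), , drop = FALSE]
  if (flagged_only) r <- r[r$flagged, , drop = FALSE]
  m <- fpkm[r$gene_id, , drop = FALSE]
  if (transform == "log2p1") return(log2(m + 1))
  t(apply(m, 1, function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
}
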