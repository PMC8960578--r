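# Methylation-expression correlation within cis TSS windows, and the join
# against an external eQTM (expression quantitative trait methylation) table.

#' Correlate DMC methylation with expression of genes in a cis window
#'
#' For each DMC, every gene whose TSS lies within `window_bp` of the CpG in
#' either direction (closed window: a TSS at exactly `window_bp` is
#' included) is tested: the Spearman rank correlation (average-rank tie
#' handling) between the per-sample methylation proportion and the gene's
#' expression is computed across the samples, pooling cases and controls,
#' over samples where both measurements are observed. Pairs with fewer than
#' `min_samples` complete observations are skipped with a reason.
#'
#' @param dmcs GRanges of DMCs (e.g. from [callDMCs()]).
#' @param me the [MethylExperiment-class] of the same fraction.
#' @param expression genes x samples matrix (RPKM-normalised); sample ids
#'   must be resolvable against the methylation samples.
#' @param models a [GeneModelSet-class] supplying TSS positions.
#' @param window_bp cis window half-width in bp (default 250000).
#' @param report_abs_rho |rho| threshold for the `flagged` column
#'   (default 0.5).
#' @param min_samples minimum complete pairs (default 10).
#' @return data.frame with columns `chrom`, `pos`, `gene_id`, `gene_name`,
#'   `rho`, `n_samples`, `window_distance`, `flagged`; skipped pairs are in
#'   `attr(x, "skipped")` with a `reason`.
#' @export
correlateExpression <- function(dmcs, me, expression, models,
                                window_bp = 250000L, report_abs_rho = 0.5,
                                min_samples = 10L) {
  if (!all(colnames(expression) %in% colnames(me)))
    stop("expression samples must be a subset of the methylation samples")
  shared <- intersect(colnames(me), colnames(expression))
  lv <- methLevels(me)
  key <- paste(as.character(seqnames(rowRanges(me))), start(rowRanges(me)))
  tss <- tssPositions(models)
  tss_chr <- as.character(seqnames(tss))
  out <- list(); skipped <- list()
  for (i in seq_along(dmcs)) {
    chrom <- as.character(seqnames(dmcs))[i]
    pos <- start(dmcs)[i]
    row <- match(paste(chrom, pos), key)
    if (is.na(row)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        chrom = chrom, pos = pos, gene_id = NA_character_,
        reason = "site_not_in_matrix")
      next
    }
    cand <- which(tss_chr == chrom & abs(start(tss) - pos) <= window_bp)
    for (g in cand) {
      gid <- tss$gene_id[g]
      if (!gid %in% rownames(expression)) next
      x <- lv[row, shared]
      y <- expression[gid, shared]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_samples) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          chrom = chrom, pos = pos, gene_id = gid,
          reason = "too_few_complete_pairs")
        next
      }
      rho <- cor(x[ok], y[ok], method = "spearman")
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, pos = pos, gene_id = gid,
        gene_name = tss$gene_name[g], rho = rho, n_samples = sum(ok),
        window_distance = start(tss)[g] - pos,
        flagged = abs(rho) > report_abs_rho)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), gene_id = character(),
               gene_name = character(), rho = numeric(),
               n_samples = integer(), window_distance = integer(),
               flagged = logical())
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(chrom = character(), pos = integer(), gene_id = character(),
               reason = character())
  res
}

#' Join DMCs against an external cis-eQTM table
#'
#' Exact-position inner join of DMC coordinates against a user-supplied
#' table of known expression quantitative trait methylation effects (for
#' example an export from a blood eQTM database). When the input carries
#' in-cohort correlations (`rho` column from [correlateExpression()]), the
#' sign of the external effect is compared with the in-cohort sign for the
#' matching gene.
#'
#' @param dmcs GRanges of DMCs, or a data.frame with `chrom` and `pos`
#'   (optionally `gene_id`/`gene` and `rho` for the concordance flag).
#' @param eqtm data.frame with columns `chrom`, `pos` (hg19-style 1-based),
#'   `gene`, `effect` (signed external effect or correlation).
#' @return data.frame of joined rows with `concordant_sign` (`NA` when no
#'   in-cohort rho is available for that gene).
#' @export
joinEQTM <- function(dmcs, eqtm) {
  req <- c("chrom", "pos", "gene", "effect")
  if (!all(req %in% colnames(eqtm)))
    stop("eQTM table needs columns: ", paste(req, collapse = ", "))
  if (anyNA(eqtm$pos)) stop("unparseable position in eQTM table")
  if (is(dmcs, "GRanges")) {
    d <- data.frame(chrom = as.character(seqnames(dmcs)),
                    pos = start(dmcs))
    if (!is.null(dmcs$rho)) d$rho <- dmcs$rho
    if (!is.null(dmcs$gene_id)) d$gene <- dmcs$gene_id
  } else {
    d <- as.data.frame(dmcs)
    if ("gene_id" %in% names(d)) d$gene <- d$gene_id
  }
  j <- merge(d, eqtm, by = c("chrom", "pos"),
             suffixes = c("_cohort", ""))
  if (!nrow(j)) {
    j$concordant_sign <- logical(0)
    return(j)
  }
  j$concordant_sign <- NA
  if ("rho" %in% names(j)) {
    same_gene <- if ("gene_cohort" %in% names(j))
      j$gene_cohort == j$gene else TRUE
    j$concordant_sign <- ifelse(same_gene & !is.na(j$rho),
                                sign(j$rho) == sign(j$effect), NA)
  }
  j[order(j$chrom, j$pos), , drop = FALSE]
}
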