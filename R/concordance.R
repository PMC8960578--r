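# Concordance between RRBS and an orthogonal per-site methylation assay
# (pyrosequencing-style proportions) on a validation subset of samples.

#' RRBS vs pyrosequencing concordance per site
#'
#' For each validated site, compares the two assays over their shared
#' samples: the Pearson correlation of the per-sample methylation
#' proportions (with the raw p-value from the correlation t-test, BH
#' adjusted across validated sites), and whether the case-control mean
#' difference points in the same direction in both assays. Group means are
#' unweighted means of per-sample proportions within the validation subset
#' (pyrosequencing has no read-count denominator, so the assay-symmetric
#' definition is used on both sides). Concordance is defined only when both
#' assays give a nonzero difference; a site with zero variance in either
#' vector gets an undefined correlation and is flagged.
#'
#' @param me the [MethylExperiment-class] supplying the RRBS proportions
#'   and the sample sheet (group labels).
#' @param pyro data.frame with columns `chrom`, `pos`, `sample_id`,
#'   `proportion` (e.g. from [simulatePyroReplicates()]).
#' @param min_samples minimum shared samples per site (default 3; below
#'   this the correlation t-test is undefined).
#' @return data.frame with one row per site: `chrom`, `pos`, `n_samples`,
#'   `rrbs_diff`, `pyro_diff`, `concordant_direction`, `pearson_r`,
#'   `p_value`, `q_value`, `status` (`ok`, `too_few_samples`,
#'   `zero_variance`).
#' @export
pyroConcordance <- function(me, pyro, min_samples = 3L) {
  stopifnot(is(me, "MethylExperiment"))
  req <- c("chrom", "pos", "sample_id", "proportion")
  if (!all(req %in% colnames(pyro)))
    stop("pyro table needs columns: ", paste(req, collapse = ", "))
  lv <- methLevels(me)
  key <- paste(as.character(seqnames(rowRanges(me))), start(rowRanges(me)))
  grp <- setNames(me$group, colnames(me))
  rows <- lapply(split(pyro, paste(pyro$chrom, pyro$pos)), function(d) {
    row <- match(paste(d$chrom[1], d$pos[1]), key)
    if (is.na(row)) stop("pyro site absent from the methylation matrix: ",
                         d$chrom[1], ":", d$pos[1])
    sm <- intersect(d$sample_id, colnames(me))
    x <- lv[row, sm]
    y <- setNames(d$proportion, d$sample_id)[sm]
    ok <- !is.na(x) & !is.na(y)
    base <- data.frame(chrom = d$chrom[1], pos = d$pos[1],
                       n_samples = sum(ok), rrbs_diff = NA_real_,
                       pyro_diff = NA_real_, concordant_direction = NA,
                       pearson_r = NA_real_, p_value = NA_real_)
    if (sum(ok) < min_samples) { base$status <- "too_few_samples"; return(base) }
    x <- x[ok]; y <- y[ok]; g <- grp[names(x)]
    base$rrbs_diff <- mean(x[g == "case"]) - mean(x[g == "control"])
    base$pyro_diff <- mean(y[g == "case"]) - mean(y[g == "control"])
    if (base$rrbs_diff != 0 && base$pyro_diff != 0)
      base$concordant_direction <- sign(base$rrbs_diff) ==
        sign(base$pyro_diff)
    if (sd(x) == 0 || sd(y) == 0) { base$status <- "zero_variance"; return(base) }
    ct <- cor.test(x, y, method = "pearson")
    base$pearson_r <- unname(ct$estimate)
    base$p_value <- ct$p.value
    base$status <- "ok"
    base
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out$q_value <- bhAdjust(out$p_value)
  out
}
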