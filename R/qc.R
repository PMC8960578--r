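# Site/sample quality filtering and exploratory QC ahead of testing.

#' Filtering thresholds for [filterSites()]
#'
#' @param min_coverage minimum read coverage for a cell to count as observed
#'   at filtering (default 10).
#' @param min_fraction_per_group proportion of case samples AND of control
#'   samples in which a site must reach `min_coverage` (default 0.5).
#' @param max_coverage_quantile upper trim quantile; cells with coverage
#'   above this quantile of all observed cells are masked (default 0.999,
#'   guarding against PCR-duplicated pile-ups).
#' @return list of class `filter_config`.
#' @export
filterConfig <- function(min_coverage = 10L, min_fraction_per_group = 0.5,
                         max_coverage_quantile = 0.999) {
  stopifnot(min_coverage >= 1,
            min_fraction_per_group > 0, min_fraction_per_group <= 1,
            max_coverage_quantile > 0, max_coverage_quantile <= 1)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_fraction_per_group = min_fraction_per_group,
                 max_coverage_quantile = max_coverage_quantile),
            class = "filter_config")
}

#' Coverage-filter the sites of a MethylExperiment
#'
#' Masks cells whose coverage exceeds the upper trim quantile, then retains
#' sites that reach `min_coverage` in at least `min_fraction_per_group` of
#' the case samples and of the control samples. The absolute trim threshold
#' is stored in the object metadata and reused when an already-filtered
#' object is filtered again with the same configuration, so filtering is
#' idempotent. A filter report (sites/cells in and out) is attached to the
#' metadata as well.
#'
#' @param me a [MethylExperiment-class].
#' @param cfg a [filterConfig()].
#' @return The filtered [MethylExperiment-class]; surviving counts are
#'   unaltered. Errors if no site survives.
#' @export
filterSites <- function(me, cfg = filterConfig()) {
  stopifnot(is(me, "MethylExperiment"))
  m <- methCounts(me); n <- totalCounts(me)
  prior <- metadata(me)$filter
  threshold <- if (!is.null(prior) && identical(prior$config, cfg))
    prior$threshold
  else as.numeric(quantile(n[!is.na(n)], cfg$max_coverage_quantile,
                           type = 7))
  mask <- !is.na(n) & n > threshold
  m[mask] <- NA_integer_
  n[mask] <- NA_integer_
  grp <- me$group
  ok <- !is.na(n) & n >= cfg$min_coverage
  frac_case <- rowMeans(ok[, grp == "case", drop = FALSE])
  frac_ctrl <- rowMeans(ok[, grp == "control", drop = FALSE])
  keep <- frac_case >= cfg$min_fraction_per_group &
    frac_ctrl >= cfg$min_fraction_per_group
  report <- list(sites_in = nrow(me), sites_out = sum(keep),
                 cells_trimmed = sum(mask), threshold = threshold)
  if (!any(keep))
    stop("filter removes every site (", nrow(me), " in); threshold=",
         cfg$min_coverage, " in >=", cfg$min_fraction_per_group,
         " of each group")
  out <- me[keep, ]
  assay(out, "meth") <- m[keep, , drop = FALSE]
  assay(out, "total") <- n[keep, , drop = FALSE]
  metadata(out)$filter <- list(config = cfg, threshold = threshold,
                               report = report)
  out
}

#' Principal component analysis of sample methylation profiles
#'
#' Computes standard PCA of the per-sample methylation-proportion vectors
#' over sites observed (coverage > 0) in every sample. Intended for outlier
#' inspection; no sample is excluded automatically.
#'
#' @param me a [MethylExperiment-class] with at least 3 samples.
#' @return list with `coordinates` (data.frame: sample_id, PC1, PC2) and
#'   `explained_variance` (ratios over all components, summing to <= 1).
#' @export
samplePCA <- function(me) {
  stopifnot(is(me, "MethylExperiment"))
  if (ncol(me) < 3) stop("PCA needs at least 3 samples")
  lv <- methLevels(me)
  complete <- rowSums(is.na(lv)) == 0
  if (sum(complete) < 3) stop("fewer than 3 sites observed in all samples")
  x <- t(lv[complete, , drop = FALSE])
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  co <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  if (ncol(co) < 2) co <- cbind(co, PC2 = 0)
  list(coordinates = data.frame(sample_id = colnames(me),
                                PC1 = co[, 1], PC2 = co[, 2],
                                row.names = NULL),
       explained_variance = ev)
}
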