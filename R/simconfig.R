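#' SimConfig: parameters of the synthetic matched-pair RRBS cohort
#'
#' Encapsulates the study conditions emulated by [simulateCohort()]: a
#' prospective cohort of matched case-control pairs, each individual sampled
#' longitudinally in several purified cell fractions, with seroconversion of
#' the cases inside a stated age window. See [simConfig()] for the defaults.
#'
#' @slot n_pairs number of case-control pairs.
#' @slot fractions cell-fraction labels.
#' @slot time_points_months sampling ages (months), shared by all individuals.
#' @slot seroconversion_window_months c(min, max) age at which cases
#'   seroconvert; drawn uniformly per case.
#' @slot coverage_mean,coverage_dispersion negative-binomial mean and size of
#'   per-site, per-sample read coverage.
#' @slot baseline_alpha,baseline_beta beta parameters of the background
#'   per-site methylation level.
#' @slot site_overdispersion beta-binomial intra-site correlation rho in (0,1).
#' @slot n_sites total CpG count (background plus injected).
#' @slot dmr_specs list of injected effects; each element is a list with
#'   `chrom`, `span_bp`, `n_cpgs`, `delta` and `pre_seroconversion_only`.
#' @slot expr_link_specs list of CpG-gene expression links; each element has
#'   `dmr` (index into `dmr_specs`) or `site` (background site index),
#'   optionally `member` (CpG within the DMR), plus `gene` and `rho`
#'   (target Spearman correlation).
#' @slot missing_rate probability a site is unobserved in a sample.
#' @slot seed master RNG seed; all draws derive from it.
#' @aliases SimConfig
#' @export
setClass("SimConfig",
         representation(n_pairs = "integer", fractions = "character",
                        time_points_months = "numeric",
                        seroconversion_window_months = "numeric",
                        coverage_mean = "numeric",
                        coverage_dispersion = "numeric",
                        baseline_alpha = "numeric", baseline_beta = "numeric",
                        site_overdispersion = "numeric", n_sites = "integer",
                        dmr_specs = "list", expr_link_specs = "list",
                        missing_rate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@n_pairs < 2L) msg <- c(msg, "n_pairs must be >= 2")
  if (!length(object@fractions)) msg <- c(msg, "at least one fraction")
  if (length(object@seroconversion_window_months) != 2L ||
      diff(object@seroconversion_window_months) < 0)
    msg <- c(msg, "seroconversion window must be c(min, max)")
  if (object@coverage_mean <= 0 || object@coverage_dispersion <= 0)
    msg <- c(msg, "coverage parameters must be positive")
  if (object@site_overdispersion <= 0 || object@site_overdispersion >= 1)
    msg <- c(msg, "site_overdispersion must lie in (0,1)")
  if (object@missing_rate < 0 || object@missing_rate >= 1)
    msg <- c(msg, "missing_rate must lie in [0,1)")
  ncpg <- 0L
  for (sp in object@dmr_specs) {
    if (!all(c("chrom", "span_bp", "n_cpgs", "delta") %in% names(sp)))
      msg <- c(msg, "each dmr_spec needs chrom, span_bp, n_cpgs, delta")
    else {
      if (abs(sp$delta) > 0.9)
        msg <- c(msg, "injected |delta| must be <= 0.9 so that the shifted
                 methylation level stays inside the clamp range")
      if (abs(sp$delta) > 1) msg <- c(msg, "delta must lie in [-1,1]")
      ncpg <- ncpg + sp$n_cpgs
    }
  }
  if (ncpg > object@n_sites)
    msg <- c(msg, "n_sites must be >= total injected CpGs")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-cohort configuration
#'
#' Defaults are the emulated study conditions: seven matched case-control
#' pairs, three cell fractions, five sampling ages between 12 and 36 months,
#' case seroconversion uniform between 13 and 24 months, heavy-tailed RRBS
#' coverage (negative binomial, mean 30, size 4), a mildly bimodal background
#' methylation baseline, beta-binomial overdispersion rho = 0.05, 5%
#' missing cells, and a handful of injected differentially methylated
#' regions with |delta| between 0.15 and 0.55 (one pre-seroconversion-only)
#' plus CpG-gene expression links at |rho| around 0.5-0.7.
#'
#' @param n_pairs,fractions,time_points_months,seroconversion_window_months
#'   cohort design; see [SimConfig-class].
#' @param coverage_mean,coverage_dispersion negative-binomial coverage model.
#' @param baseline_alpha,baseline_beta background methylation beta prior.
#' @param site_overdispersion beta-binomial intra-site correlation in (0,1).
#' @param n_sites total number of CpG sites.
#' @param dmr_specs,expr_link_specs injected effects and expression links;
#'   see [SimConfig-class]. `list()` gives a null cohort.
#' @param missing_rate per-cell missingness probability.
#' @param seed master seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(n_sites = 200L, dmr_specs = list(), seed = 7L)
#' sim <- simulateCohort(cfg)
#' sim$matrices$CD4
#' @export
simConfig <- function(n_pairs = 7L,
                      fractions = c("CD4", "CD8", "DN"),
                      time_points_months = c(12, 18, 24, 30, 36),
                      seroconversion_window_months = c(13, 24),
                      coverage_mean = 30, coverage_dispersion = 4,
                      baseline_alpha = 0.6, baseline_beta = 0.6,
                      site_overdispersion = 0.05, n_sites = 2000L,
                      dmr_specs = defaultDmrSpecs(),
                      expr_link_specs = defaultExprLinks(),
                      missing_rate = 0.05, seed = 1L) {
  if (missing(expr_link_specs)) {
    # keep only default links whose anchor DMR exists in dmr_specs
    expr_link_specs <- Filter(function(sp)
      is.null(sp$dmr) || sp$dmr <= length(dmr_specs), expr_link_specs)
  }
  new("SimConfig", n_pairs = as.integer(n_pairs), fractions = fractions,
      time_points_months = time_points_months,
      seroconversion_window_months = seroconversion_window_months,
      coverage_mean = coverage_mean,
      coverage_dispersion = coverage_dispersion,
      baseline_alpha = baseline_alpha, baseline_beta = baseline_beta,
      site_overdispersion = site_overdispersion,
      n_sites = as.integer(n_sites), dmr_specs = dmr_specs,
      expr_link_specs = expr_link_specs, missing_rate = missing_rate,
      seed = as.integer(seed))
}

#' Default injected differentially methylated regions
#'
#' Five effects spanning the magnitudes reported for top-ranked DMCs
#' (|delta| 0.15-0.55): three multi-CpG hyper/hypomethylated regions, one
#' single stand-alone CpG, and one pre-seroconversion-only region.
#' @return list of DMR specs for [simConfig()].
#' @export
defaultDmrSpecs <- function() {
  list(
    list(chrom = "chr1", span_bp = 1500L, n_cpgs = 5L, delta = 0.40,
         pre_seroconversion_only = FALSE),
    list(chrom = "chr1", span_bp = 800L, n_cpgs = 3L, delta = -0.25,
         pre_seroconversion_only = FALSE),
    list(chrom = "chr2", span_bp = 1200L, n_cpgs = 4L, delta = 0.55,
         pre_seroconversion_only = FALSE),
    list(chrom = "chr2", span_bp = 1000L, n_cpgs = 4L, delta = 0.40,
         pre_seroconversion_only = TRUE),
    list(chrom = "chr3", span_bp = 1L, n_cpgs = 1L, delta = -0.15,
         pre_seroconversion_only = FALSE))
}

#' Default CpG-gene expression links
#'
#' Four links at target |Spearman rho| 0.5-0.7, anchored on injected CpGs.
#' @return list of link specs for [simConfig()].
#' @export
defaultExprLinks <- function() {
  list(
    list(dmr = 1L, member = 1L, gene = "GLNK1", rho = 0.62),
    list(dmr = 2L, member = 1L, gene = "GLNK2", rho = -0.59),
    list(dmr = 3L, member = 2L, gene = "GLNK3", rho = 0.65),
    list(dmr = 4L, member = 1L, gene = "GLNK4", rho = -0.54))
}
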