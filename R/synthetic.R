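# Synthetic matched-pair longitudinal RRBS cohort with known ground truth.
# The generator emulates the statistical structure of the study design:
# matched case-control pairs sampled longitudinally in purified cell
# fractions, beta-binomial methylation counts over negative-binomial
# coverage, injected differentially methylated sites/regions, and expression
# values linked to designated CpGs through a rank-preserving Gaussian copula.

# deterministic 31-bit sub-seed per named stream; a fresh stream per
# (fraction, sample) keeps existing samples invariant when samples are added
.deriveSeed <- function(master, key) {
  h <- 0
  for (ch in utf8ToInt(paste0(master, "|", key)))
    h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

.clampProb <- function(p, lo = 0.02, hi = 0.98) pmin(pmax(p, lo), hi)

# site layout: background grid plus injected DMR CpGs, sorted by (chrom,pos)
.siteLayout <- function(config) {
  specs <- config@dmr_specs
  inj <- list()
  for (d in seq_along(specs)) {
    sp <- specs[[d]]
    n <- sp$n_cpgs
    start <- 40000000L + (d - 1L) * 1000000L
    pos <- if (n == 1L) start else
      start + as.integer(round(seq(0, sp$span_bp, length.out = n)))
    inj[[d]] <- data.frame(chrom = sp$chrom, pos = pos, delta = sp$delta,
                           pre_sc_only = isTRUE(sp$pre_seroconversion_only),
                           dmr_id = d)
  }
  inj <- if (length(inj)) do.call(rbind, inj) else
    data.frame(chrom = character(), pos = integer(), delta = numeric(),
               pre_sc_only = logical(), dmr_id = integer())
  n_bg <- config@n_sites - nrow(inj)
  chroms <- c("chr1", "chr2", "chr3")
  bg <- data.frame(
    chrom = chroms[(seq_len(n_bg) - 1L) %% 3L + 1L],
    pos = 1000000L + ((seq_len(n_bg) - 1L) %/% 3L) * 3000L,
    delta = 0, pre_sc_only = FALSE, dmr_id = NA_integer_)
  sites <- rbind(bg, inj)
  sites[order(sites$chrom, sites$pos), , drop = FALSE]
}

.buildSheet <- function(config) {
  rows <- list()
  for (i in seq_len(config@n_pairs)) {
    set.seed(.deriveSeed(config@seed, paste0("sc_age_", i)))
    sc <- runif(1, config@seroconversion_window_months[1],
                config@seroconversion_window_months[2])
    for (grp in c("case", "control")) {
      ind <- sprintf("%s%02d", ifelse(grp == "case", "case", "ctrl"), i)
      for (fr in config@fractions) for (t in config@time_points_months) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_m%02d", ind, fr, t),
          individual_id = ind, pair_id = sprintf("P%02d", i), group = grp,
          fraction = fr, age_months = t,
          seroconversion_age_months = if (grp == "case") sc else NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a matched-pair longitudinal RRBS cohort
#'
#' Generates per-fraction [MethylExperiment-class] count matrices, a sample
#' sheet, toy gene models and a ground-truth manifest. Coverage is drawn per
#' site and sample from a negative binomial; per-sample methylation counts
#' are beta-binomial around a per-site baseline; case samples at injected
#' sites have their methylation level shifted by its configured `delta` (clamped
#' to \[0.02, 0.98\]), either at all time points or only before that case's
#' seroconversion when `pre_seroconversion_only` is set. Missing cells are
#' masked independently. All draws derive from the config seed through one
#' named RNG stream per (fraction, sample), so a fixed seed reproduces the
#' cohort exactly.
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @return A list with elements `matrices` (named list of
#'   [MethylExperiment-class], one per fraction), `sheet` (sample sheet
#'   data.frame), `models` ([GeneModelSet-class] toy gene models), `truth`
#'   (list with `sites`: injected positions with true deltas;
#'   `links`: CpG-gene expression links with target rho), and `config`.
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  layout <- .siteLayout(config)
  sheet <- .buildSheet(config)
  rho <- config@site_overdispersion
  s <- (1 - rho) / rho
  inj <- !is.na(layout$dmr_id)

  matrices <- list()
  for (fr in config@fractions) {
    set.seed(.deriveSeed(config@seed, paste0("baseline_", fr)))
    p0 <- .clampProb(rbeta(nrow(layout), config@baseline_alpha,
                           config@baseline_beta))
    # injected-site baselines leave room for the shift inside [0.05, 0.95]
    if (any(inj)) {
      d <- layout$delta[inj]
      lo <- ifelse(d > 0, 0.05, 0.05 - d)
      hi <- ifelse(d > 0, 0.95 - d, 0.95)
      p0[inj] <- lo + runif(sum(inj)) * (hi - lo)
    }
    sub <- sheet[sheet$fraction == fr, , drop = FALSE]
    meth <- total <- matrix(NA_integer_, nrow(layout), nrow(sub))
    colnames(meth) <- colnames(total) <- sub$sample_id
    for (j in seq_len(nrow(sub))) {
      set.seed(.deriveSeed(config@seed,
                           paste0("counts_", fr, "_", sub$sample_id[j])))
      cov <- rnbinom(nrow(layout), size = config@coverage_dispersion,
                     mu = config@coverage_mean)
      p <- p0
      if (sub$group[j] == "case" && any(inj)) {
        on <- inj & (!layout$pre_sc_only |
                       sub$age_months[j] < sub$seroconversion_age_months[j])
        p[on] <- .clampProb(p0[on] + layout$delta[on])
      }
      theta <- rbeta(nrow(layout), p * s, (1 - p) * s)
      m <- rbinom(nrow(layout), cov, theta)
      miss <- runif(nrow(layout)) < config@missing_rate
      m[miss] <- NA_integer_
      cov[miss] <- NA_integer_
      meth[, j] <- m
      total[, j] <- cov
    }
    matrices[[fr]] <- MethylExperiment(meth, total,
                                       layout[, c("chrom", "pos")], sub)
  }

  truth_sites <- layout[inj, c("chrom", "pos", "delta", "pre_sc_only",
                               "dmr_id")]
  rownames(truth_sites) <- NULL
  models <- toyGeneModels(config)
  links <- .resolveLinks(config, layout)
  if (nrow(links)) {
    tss <- tssPositions(models)
    for (k in seq_len(nrow(links))) {
      g <- which(tss$gene_id == links$gene[k])
      if (!length(g)) stop("expression link gene not in gene models: ",
                           links$gene[k])
      if (as.character(seqnames(tss)[g]) != links$chrom[k] ||
          abs(start(tss)[g] - links$pos[k]) > 250000)
        stop("linked gene TSS is not within 250 kb of its CpG: ",
             links$gene[k])
    }
  }
  list(matrices = matrices, sheet = sheet, models = models,
       truth = list(sites = truth_sites, links = links), config = config)
}

.resolveLinks <- function(config, layout) {
  out <- list()
  for (k in seq_along(config@expr_link_specs)) {
    sp <- config@expr_link_specs[[k]]
    if (!is.null(sp$dmr)) {
      member <- if (is.null(sp$member)) 1L else sp$member
      idx <- which(layout$dmr_id == sp$dmr)
      if (member > length(idx)) stop("expr link member out of range")
      idx <- idx[member]
    } else if (!is.null(sp$site)) {
      bg <- which(is.na(layout$dmr_id))
      if (sp$site > length(bg)) stop("expr link site index out of range")
      idx <- bg[sp$site]
    } else stop("expr link spec needs 'dmr' or 'site'")
    out[[k]] <- data.frame(chrom = layout$chrom[idx], pos = layout$pos[idx],
                           gene = sp$gene, rho = sp$rho)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), gene = character(),
               rho = numeric())
}

#' Deterministic toy gene models spanning the simulated CpG space
#'
#' Builds a small gene set with known TSSs and exon/intron structure:
#' one gene whose promoter covers the first CpG of each injected region, one
#' gene per expression link with its TSS a few kb from the linked CpG, a grid
#' of background genes, and one deliberately distant gene (300 kb from the
#' first linked CpG) that cis-window queries must exclude.
#'
#' @param config a [SimConfig-class].
#' @return A [GeneModelSet-class]; no randomness is involved.
#' @export
toyGeneModels <- function(config) {
  layout <- .siteLayout(config)
  links <- .resolveLinks(config, layout)
  rows <- list(); exon_rows <- list()
  addGene <- function(id, name, chrom, tss, strand) {
    span <- if (strand == "+") c(tss, tss + 4999L) else c(tss - 4999L, tss)
    off <- c(0L, 1800L, 4600L)
    ex <- if (strand == "+") IRanges(span[1] + off, width = 400L) else
      IRanges(span[2] - off - 399L, width = 400L)
    ex <- restrict(ex, span[1], span[2])
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = span[1], end = span[2], strand = strand,
      gene_id = id, gene_name = name)
    exon_rows[[id]] <<- data.frame(chrom = chrom, start = start(ex),
                                   end = end(ex), strand = strand)
  }
  for (d in seq_along(config@dmr_specs)) {
    first <- layout[which(layout$dmr_id == d)[1L], ]
    addGene(sprintf("GDMR%d", d), sprintf("GDMR%d", d), first$chrom,
            as.integer(first$pos + 200L), "+")
  }
  if (nrow(links)) for (k in seq_len(nrow(links))) {
    addGene(links$gene[k], links$gene[k], links$chrom[k],
            as.integer(links$pos[k] + 5000L + 1370L * k),
            if (k %% 2L) "+" else "-")
  }
  for (j in 1:12) {
    chrom <- c("chr1", "chr2", "chr3")[(j - 1L) %% 3L + 1L]
    addGene(sprintf("GBG%02d", j), sprintf("GBG%02d", j), chrom,
            1000500L + (j - 1L) * 97000L, if (j %% 2L) "+" else "-")
  }
  if (nrow(links))
    addGene("GFAR", "GFAR", links$chrom[1L],
            as.integer(links$pos[1L] + 300000L), "+")
  df <- do.call(rbind, rows)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                gene_id = df$gene_id, gene_name = df$gene_name)
  gr <- sort(gr)
  exons <- lapply(exon_rows, function(d)
    GRanges(d$chrom, IRanges(d$start, d$end), strand = d$strand,
            seqinfo = seqinfo(gr)))
  GeneModelSet(gr, GRangesList(exons)[gr$gene_id])
}

#' Simulate RPKM-style expression linked to methylation
#'
#' For each linked CpG-gene pair the expression of the samples of that CpG's
#' fraction is generated through a rank-preserving latent Gaussian copula on
#' the observed per-sample methylation proportion: the latent correlation is
#' calibrated (Moran's finite-n mean under a Gaussian copula) so the
#' realised Spearman correlation targets the configured `rho` (exactly
#' monotone, hence rho = +/-1, when |rho| = 1). Unlinked
#' genes (and other fractions' samples) are independent log-normal noise.
#'
#' @param sim result of [simulateCohort()].
#' @param config the same [SimConfig-class] used for the cohort.
#' @return A genes x samples numeric matrix (all samples of all fractions).
#' @export
simulateExpression <- function(sim, config = sim$config) {
  models <- sim$models
  gene_ids <- geneRanges(models)$gene_id
  samples <- sim$sheet$sample_id
  set.seed(.deriveSeed(config@seed, "expr_base"))
  base <- exp(rnorm(length(gene_ids), mean = 2, sd = 0.8))
  names(base) <- gene_ids
  expr <- matrix(NA_real_, length(gene_ids), length(samples),
                 dimnames = list(gene_ids, samples))
  for (fr in config@fractions) {
    cols <- sim$sheet$sample_id[sim$sheet$fraction == fr]
    set.seed(.deriveSeed(config@seed, paste0("expr_", fr)))
    expr[, cols] <- base * matrix(rlnorm(length(gene_ids) * length(cols),
                                         0, 0.5),
                                  length(gene_ids), length(cols))
    links <- sim$truth$links
    if (!nrow(links)) next
    me <- sim$matrices[[fr]]
    lv <- methLevels(me)
    key <- paste(as.character(seqnames(rowRanges(me))), start(rowRanges(me)))
    for (k in seq_len(nrow(links))) {
      if (!links$gene[k] %in% gene_ids)
        stop("unknown gene in expression link: ", links$gene[k])
      i <- match(paste(links$chrom[k], links$pos[k]), key)
      if (is.na(i)) stop("unknown CpG in expression link: ",
                         links$chrom[k], ":", links$pos[k])
      x <- lv[i, cols]
      x[is.na(x)] <- median(x, na.rm = TRUE)
      n <- length(x)
      z <- qnorm((rank(x, ties.method = "average") - 0.5) / n)
      # latent correlation calibrated so that the expected sample Spearman
      # at this n equals the target (Moran's finite-n mean for a Gaussian
      # copula); falls back to exact monotone coupling at |rho| = 1
      moran <- function(r) 6 / (pi * (n + 1)) *
        (asin(r) + (n - 2) * asin(r / 2))
      target <- min(abs(links$rho[k]), 1)
      rl <- if (target >= 1 || target >= moran(1)) 1 else if (target == 0) 0
      else uniroot(function(r) moran(r) - target, c(0, 1),
                   tol = 1e-10)$root
      eps <- rnorm(n)
      latent <- rl * z + sqrt(max(0, 1 - rl^2)) * eps
      if (links$rho[k] < 0) latent <- -latent
      expr[links$gene[k], cols] <- base[links$gene[k]] * exp(0.6 * latent)
    }
  }
  expr
}

#' Simulate pyrosequencing-style replicate measurements
#'
#' For the selected case-control pairs, one sample per individual (the
#' median time point; the first observed one if that cell is missing) is
#' re-measured at each requested site: the RRBS methylation proportion plus
#' independent Gaussian noise, truncated to \[0, 1\]. With `noise_sd = 0`
#' the pyro proportions equal the RRBS proportions exactly.
#'
#' @param sim result of [simulateCohort()].
#' @param sites data.frame with columns `chrom`, `pos` (sites to validate).
#' @param n_pairs_selected number of pairs to assay (2 individuals each).
#' @param noise_sd standard deviation of the measurement noise.
#' @param fraction which cell fraction is assayed.
#' @return data.frame with columns `chrom`, `pos`, `sample_id`, `proportion`.
#' @export
simulatePyroReplicates <- function(sim, sites, n_pairs_selected = 3L,
                                   noise_sd = 0.05,
                                   fraction = sim$config@fractions[1L]) {
  config <- sim$config
  if (n_pairs_selected > config@n_pairs)
    stop("n_pairs_selected exceeds the available pairs")
  me <- sim$matrices[[fraction]]
  lv <- methLevels(me)
  key <- paste(as.character(seqnames(rowRanges(me))), start(rowRanges(me)))
  idx <- match(paste(sites$chrom, sites$pos), key)
  if (anyNA(idx)) stop("site not present in the methylation matrix: ",
                       paste(sites$chrom[is.na(idx)], sites$pos[is.na(idx)],
                             sep = ":", collapse = ", "))
  cd <- as.data.frame(colData(me))
  pairs <- sort(unique(cd$pair_id))[seq_len(n_pairs_selected)]
  cd <- cd[cd$pair_id %in% pairs, , drop = FALSE]
  tps <- sort(unique(cd$age_months))
  med_tp <- tps[ceiling(length(tps) / 2)]
  chosen <- vapply(split(cd, cd$individual_id), function(d) {
    d <- d[order(d$age_months), , drop = FALSE]
    pick <- d$sample_id[d$age_months == med_tp]
    if (length(pick)) pick[1L] else d$sample_id[1L]
  }, character(1))
  set.seed(.deriveSeed(config@seed, paste0("pyro_", fraction)))
  out <- list()
  for (r in seq_along(idx)) {
    for (sm in chosen) {
      prop <- unname(lv[idx[r], sm])
      if (is.na(prop)) {
        obs <- lv[idx[r], cd$sample_id[cd$individual_id ==
                                         cd$individual_id[cd$sample_id == sm]]]
        prop <- unname(obs[!is.na(obs)][1L])
      }
      meas <- if (noise_sd == 0) prop else
        min(max(prop + rnorm(1, 0, noise_sd), 0), 1)
      out[[length(out) + 1L]] <- data.frame(
        chrom = sites$chrom[r], pos = sites$pos[r], sample_id = sm,
        proportion = meas)
    }
  }
  do.call(rbind, out)
}

#' Write a simulated cohort to disk in standard formats
#'
#' Emits one Bismark-coverage-style TSV per sample (under `coverage/`), the
#' sample sheet CSV, the toy gene models as GTF, enhancer intervals as BED6,
#' toy gene sets as GMT, the ground-truth manifest as JSON and, when given,
#' the expression matrix as TSV. Output is a pure function of the simulated
#' objects, so a fixed seed gives byte-identical files.
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @param expression optional matrix from [simulateExpression()].
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(sim, dir, expression = NULL) {
  dir.create(file.path(dir, "coverage"), recursive = TRUE,
             showWarnings = FALSE)
  for (fr in names(sim$matrices)) {
    me <- sim$matrices[[fr]]
    rr <- rowRanges(me)
    m <- methCounts(me); n <- totalCounts(me)
    for (j in seq_len(ncol(me))) {
      ok <- !is.na(n[, j])
      df <- data.frame(chrom = as.character(seqnames(rr))[ok],
                       pos = start(rr)[ok], n_meth = m[ok, j],
                       n_total = n[ok, j])
      writeBismarkCoverage(df, file.path(dir, "coverage",
                                         paste0(colnames(me)[j], ".cov")))
    }
  }
  writeSampleSheet(sim$sheet, file.path(dir, "sample_sheet.csv"))
  writeGeneModels(sim$models, file.path(dir, "genes.gtf"))
  enh <- .toyEnhancers(sim)
  rtracklayer::export(enh, file.path(dir, "enhancers.bed"), format = "BED")
  writeGmt(.toyGeneSets(sim), file.path(dir, "gene_sets.gmt"))
  if (!is.null(expression))
    writeExpressionMatrix(expression, file.path(dir, "expression.tsv"))
  truth <- sim$truth
  jsonlite::write_json(list(sites = truth$sites, links = truth$links),
                       file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}

# enhancer intervals over a subset of the injected regions (odd dmr ids)
.toyEnhancers <- function(sim) {
  st <- sim$truth$sites
  ids <- unique(st$dmr_id)
  ids <- ids[ids %% 2L == 1L]
  if (!length(ids)) return(GRanges())
  rows <- do.call(rbind, lapply(ids, function(d) {
    s <- st[st$dmr_id == d, ]
    data.frame(chrom = s$chrom[1], start = min(s$pos) - 200L,
               end = max(s$pos) + 200L, name = sprintf("ENH%d", d))
  }))
  sort(GRanges(rows$chrom, IRanges(rows$start, rows$end), name = rows$name,
               score = 0L))
}

# toy gene sets: one set collecting the injected-region and linked genes
# (over-represented among DMC genes by construction) plus background sets
.toyGeneSets <- function(sim) {
  g <- geneRanges(sim$models)$gene_id
  linked <- g[startsWith(g, "GDMR") | startsWith(g, "GLNK")]
  bg <- g[startsWith(g, "GBG")]
  list(SET_INJECTED = linked,
       SET_BG_ODD = bg[seq_along(bg) %% 2L == 1L],
       SET_BG_EVEN = bg[seq_along(bg) %% 2L == 0L])
}
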