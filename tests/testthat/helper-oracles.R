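# Independent brute-force oracles and small fixture builders shared by the
# test files. Each oracle is written from the definition, independently of
# the package implementation it checks.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# Benjamini-Hochberg step-up from the definition: find the largest k with
# p_(k) <= k*q/m, reject all smaller; q_i = min over j>=rank(i) of m*p_(j)/j
bhStepUpOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# one-sided over-representation p: hypergeometric tail sum from choose()
hyperTailOracle <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Spearman rho as rank-then-Pearson with average ranks
spearmanOracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exhaustive chain partition for DMR merging: split sorted DMCs at every
# point where the chromosome changes, the adjacent gap exceeds max_gap, or
# the delta sign flips; chains of >= 2 are DMRs
chainPartitionOracle <- function(chrom, pos, delta, max_gap = 2000) {
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]; delta <- delta[o]
  n <- length(pos)
  if (n == 0) return(list(chains = list()))
  breaks <- c(FALSE, vapply(2:max(n, 2), function(i) {
    if (i > n) return(FALSE)
    chrom[i] != chrom[i - 1] || pos[i] - pos[i - 1] > max_gap ||
      sign(delta[i]) != sign(delta[i - 1]) || sign(delta[i]) == 0
  }, logical(1))[seq_len(max(0, n - 1))])
  id <- cumsum(breaks) + 1
  list(chains = split(seq_len(n), id), order = o,
       chrom = chrom, pos = pos, delta = delta)
}

# small MethylExperiment straight from count matrices
makeToyME <- function(meth, total, n_pairs = ncol(meth) / 2,
                      chrom = "chr1", pos = NULL,
                      group = NULL, pair = NULL, fraction = "CD4",
                      age = NULL, sc_age = NULL) {
  ns <- ncol(meth)
  if (is.null(pos)) pos <- seq_len(nrow(meth)) * 1000L
  if (is.null(group)) group <- rep(c("case", "control"), each = ns / 2)
  if (is.null(pair)) pair <- rep(sprintf("P%02d", seq_len(n_pairs)),
                                 length.out = ns)
  if (is.null(age)) age <- rep(12, ns)
  sheet <- data.frame(
    sample_id = sprintf("s%02d", seq_len(ns)),
    individual_id = paste0(substr(group, 1, 2), pair),
    pair_id = pair, group = group, fraction = fraction, age_months = age,
    seroconversion_age_months = if (is.null(sc_age)) {
      ifelse(group == "case", 30, NA_real_)
    } else sc_age)
  colnames(meth) <- colnames(total) <- sheet$sample_id
  MethylExperiment(meth, total,
                   data.frame(chrom = chrom, pos = pos), sheet)
}

# balanced paired longitudinal toy cohort with beta-binomial noise
makePairedME <- function(n_sites = 50, n_pairs = 4, n_tp = 3, coverage = 30,
                         p0 = NULL, delta = 0, rho = 0.05, seed = 1) {
  set.seed(seed)
  if (is.null(p0)) p0 <- runif(n_sites, 0.2, 0.8)
  sheet <- expand.grid(pair = seq_len(n_pairs), group = c("case", "control"),
                       tp = seq_len(n_tp))
  ns <- nrow(sheet)
  s <- (1 - rho) / rho
  meth <- total <- matrix(NA_integer_, n_sites, ns)
  for (j in seq_len(ns)) {
    p <- if (sheet$group[j] == "case") pmin(pmax(p0 + delta, 0.02), 0.98)
    else p0
    cv <- rpois(n_sites, coverage)
    th <- rbeta(n_sites, p * s, (1 - p) * s)
    meth[, j] <- rbinom(n_sites, cv, th)
    total[, j] <- cv
  }
  makeToyME(meth, total, n_pairs = n_pairs,
            group = as.character(sheet$group),
            pair = sprintf("P%02d", sheet$pair),
            age = sheet$tp * 6 + 6)
}

# minimal gene models built by hand
makeToyModels <- function(df) {
  # df: gene_id, chrom, tss, strand; span 2 kb downstream of TSS
  g <- GRanges(df$chrom,
               IRanges(ifelse(df$strand == "+", df$tss, df$tss - 1999L),
                       ifelse(df$strand == "+", df$tss + 1999L, df$tss)),
               strand = df$strand,
               gene_id = df$gene_id, gene_name = df$gene_id)
  GeneModelSet(sort(g))
}

grKey <- function(gr) paste(as.character(seqnames(gr)), start(gr))
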