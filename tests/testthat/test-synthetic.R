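# The synthetic cohort generator: determinism, ground-truth bookkeeping,
# null behaviour, expression links and pyrosequencing replicates.

test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- simConfig(n_sites = 120L, fractions = "CD4", seed = 9L)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(methCounts(a$matrices$CD4), methCounts(b$matrices$CD4))
  expect_identical(totalCounts(a$matrices$CD4), totalCounts(b$matrices$CD4))
  expect_identical(a$sheet, b$sheet)
  expect_identical(a$truth, b$truth)
})

test_that("ground truth lists exactly the injected positions and deltas", {
  cfg <- simConfig(n_sites = 100L, fractions = "CD4",
                   dmr_specs = list(list(chrom = "chr1", span_bp = 1200L,
                                         n_cpgs = 5L, delta = 0.4,
                                         pre_seroconversion_only = FALSE)),
                   expr_link_specs = list(), seed = 3L)
  sim <- simulateCohort(cfg)
  expect_equal(nrow(sim$truth$sites), 5L)
  expect_true(all(sim$truth$sites$delta == 0.4))
  # every manifest position exists in the emitted matrix
  me <- sim$matrices$CD4
  expect_true(all(paste(sim$truth$sites$chrom, sim$truth$sites$pos) %in%
                    grKey(rowRanges(me))))
})

test_that("counts never exceed coverage and missingness obeys the rate", {
  cfg <- simConfig(n_sites = 400L, fractions = "CD4", missing_rate = 0.1,
                   seed = 5L)
  me <- simulateCohort(cfg)$matrices$CD4
  m <- methCounts(me); n <- totalCounts(me)
  expect_true(all(m[!is.na(m)] <= n[!is.na(n)]))
  expect_identical(is.na(m), is.na(n))
  expect_gt(mean(is.na(n)), 0.07)
  expect_lt(mean(is.na(n)), 0.13)
})

test_that("a null cohort shows no systematic group difference", {
  # pooled case-control |delta| stays small at every site over seeds
  worst <- vapply(1:8, function(sd) {
    cfg <- simConfig(n_sites = 100L, fractions = "CD4", missing_rate = 0,
                     coverage_mean = 30, dmr_specs = list(),
                     expr_link_specs = list(), seed = as.integer(400 + sd))
    me <- simulateCohort(cfg)$matrices$CD4
    expect_true(all(!is.na(totalCounts(me))))
    max(abs(methpairs:::.deltaVector(me)))
  }, numeric(1))
  expect_true(all(worst < 0.15))
})

test_that("expression links reach their target Spearman correlation", {
  # |rho| = 1 is exact (monotone transform); rho = 0.6 is recovered on
  # average; unlinked genes stay near zero
  cfg1 <- simConfig(n_sites = 60L, fractions = "CD4",
                    dmr_specs = defaultDmrSpecs()[1],
                    expr_link_specs = list(list(dmr = 1L, member = 1L,
                                                gene = "GLNK1", rho = 1)),
                    missing_rate = 0, seed = 21L)
  sim1 <- simulateCohort(cfg1)
  ex1 <- simulateExpression(sim1)
  me <- sim1$matrices$CD4
  link <- sim1$truth$links
  x <- methLevels(me)[match(paste(link$chrom, link$pos),
                            grKey(rowRanges(me))), colnames(me)]
  y <- ex1[link$gene, colnames(me)]
  expect_equal(cor(x, y, method = "spearman"), 1)

  rhos <- vapply(1:10, function(sd) {
    cfg <- simConfig(n_sites = 60L, fractions = "CD4",
                     time_points_months = c(12, 24), n_pairs = 7L,
                     dmr_specs = defaultDmrSpecs()[1],
                     expr_link_specs = list(list(dmr = 1L, member = 1L,
                                                 gene = "GLNK1", rho = 0.6)),
                     missing_rate = 0, seed = as.integer(500 + sd))
    sim <- simulateCohort(cfg)
    ex <- simulateExpression(sim)
    me <- sim$matrices$CD4
    link <- sim$truth$links
    x <- methLevels(me)[match(paste(link$chrom, link$pos),
                              grKey(rowRanges(me))), colnames(me)]
    cor(x, ex[link$gene, colnames(me)], method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0.45)
  expect_lt(mean(rhos), 0.75)

  # unlinked gene: null correlation at n = 28 samples stays below 0.4
  nulls <- vapply(1:10, function(sd) {
    cfg <- simConfig(n_sites = 60L, fractions = "CD4",
                     time_points_months = c(12, 24),
                     dmr_specs = defaultDmrSpecs()[1],
                     expr_link_specs = list(), missing_rate = 0,
                     seed = as.integer(600 + sd))
    sim <- simulateCohort(cfg)
    ex <- simulateExpression(sim)
    me <- sim$matrices$CD4
    x <- methLevels(me)[1, colnames(me)]
    cor(x, ex["GBG01", colnames(me)], method = "spearman")
  }, numeric(1))
  expect_gte(mean(abs(nulls) < 0.4), 0.9)
})

test_that("pyro replicates reproduce RRBS proportions at zero noise", {
  cfg <- simConfig(n_sites = 60L, fractions = "CD4", missing_rate = 0,
                   dmr_specs = list(), expr_link_specs = list(), seed = 31L)
  sim <- simulateCohort(cfg)
  me <- sim$matrices$CD4
  sites <- data.frame(chrom = "chr1", pos = start(rowRanges(me))[1:2])
  pyro <- simulatePyroReplicates(sim, sites, n_pairs_selected = 3L,
                                 noise_sd = 0)
  # three pairs -> six measurement rows per site
  expect_equal(nrow(pyro), 12L)
  expect_equal(sum(pyro$pos == sites$pos[1]), 6L)
  lv <- methLevels(me)
  for (r in seq_len(nrow(pyro))) {
    i <- match(paste(pyro$chrom[r], pyro$pos[r]), grKey(rowRanges(me)))
    expect_equal(pyro$proportion[r], unname(lv[i, pyro$sample_id[r]]))
  }
  expect_error(simulatePyroReplicates(sim, sites, n_pairs_selected = 20L),
               "exceeds")
  expect_error(simulatePyroReplicates(sim, data.frame(chrom = "chrZ",
                                                      pos = 1L)),
               "not present")
})

test_that("toy gene models give each linked gene exactly one TSS", {
  cfg <- simConfig(n_sites = 200L, seed = 2L)
  models <- toyGeneModels(cfg)
  tss <- tssPositions(models)
  for (sp in cfg@expr_link_specs)
    expect_equal(sum(tss$gene_id == sp$gene), 1L)
  # the deliberately distant gene sits 300 kb from the first linked CpG
  sim <- simulateCohort(cfg)
  far <- tss[tss$gene_id == "GFAR"]
  expect_equal(start(far) - sim$truth$links$pos[1], 300000L)
})

test_that("cohort files are written deterministically", {
  cfg <- simConfig(n_sites = 50L, fractions = "CD4", seed = 77L)
  sim <- simulateCohort(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeCohort(sim, d1)
  writeCohort(sim, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) > 5)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})
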