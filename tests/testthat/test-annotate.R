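# Region annotation: promoter/exon/intron/intergenic precedence, nearest
# gene by TSS distance, enhancer containment, DMR region distribution.

twoGeneModels <- function() {
  # GA: plus strand, TSS 10000, exons at [10000,10399] and [11600,11999]
  # GB: minus strand, TSS 30000
  g <- GRanges(c("chr1", "chr1"), IRanges(c(10000L, 28001L),
                                          c(11999L, 30000L)),
               strand = c("+", "-"),
               gene_id = c("GA", "GB"), gene_name = c("GA", "GB"))
  ex <- GRangesList(
    GA = GRanges("chr1", IRanges(c(10000L, 11600L), c(10399L, 11999L)),
                 strand = "+"),
    GB = GRanges("chr1", IRanges(29800L, 30000L), strand = "-"))
  GeneModelSet(g, ex)
}

test_that("the promoter window and precedence order are respected", {
  models <- twoGeneModels()
  # upstream of the plus-strand TSS, within 1 kb -> promoter
  a <- annotateSites(data.frame(chrom = "chr1", pos = 9500L), models)
  expect_equal(a$region, "promoter")
  expect_equal(a$nearest_gene, "GA")
  # inside an exon beyond the promoter window -> exon
  b <- annotateSites(data.frame(chrom = "chr1", pos = 11700L), models)
  expect_equal(b$region, "exon")
  # inside the gene span, outside exons and promoter -> intron
  cc <- annotateSites(data.frame(chrom = "chr1", pos = 11400L), models)
  expect_equal(cc$region, "intron")
  # far from everything -> intergenic
  d <- annotateSites(data.frame(chrom = "chr1", pos = 500000L), models)
  expect_equal(d$region, "intergenic")
})

test_that("promoter beats the intron of an overlapping second gene", {
  g <- GRanges(c("chr1", "chr1"), IRanges(c(10000L, 5000L),
                                          c(11999L, 20000L)),
               strand = c("+", "+"),
               gene_id = c("GA", "GHOST"), gene_name = c("GA", "GHOST"))
  ex <- GRangesList(GA = GRanges("chr1", IRanges(10000L, 10399L),
                                 strand = "+"),
                    GHOST = GRanges("chr1", IRanges(5000L, 5100L),
                                    strand = "+"))
  models <- GeneModelSet(g, ex)
  a <- annotateSites(data.frame(chrom = "chr1", pos = 9500L), models)
  expect_equal(a$region, "promoter")
})

test_that("minus-strand promoters sit downstream of the span end", {
  models <- twoGeneModels()
  a <- annotateSites(data.frame(chrom = "chr1", pos = 30800L), models)
  expect_equal(a$region, "promoter")
  expect_equal(a$nearest_gene, "GB")
  # signed distance is negative upstream in reading direction
  expect_equal(a$distance_to_tss, -800L)
})

test_that("nearest-gene ties break lexicographically by gene id", {
  g <- GRanges(c("chr1", "chr1"), IRanges(c(1000L, 3000L),
                                          c(1999L, 3999L)),
               strand = c("+", "+"),
               gene_id = c("ZZ", "AA"), gene_name = c("ZZ", "AA"))
  models <- GeneModelSet(g)
  # equidistant from both TSSs (1000 bp each)
  a <- annotateSites(data.frame(chrom = "chr1", pos = 2000L), models)
  expect_equal(a$nearest_gene, "AA")
})

test_that("unknown chromosomes fall back to intergenic with a warning", {
  models <- twoGeneModels()
  expect_warning(
    a <- annotateSites(data.frame(chrom = "chr9", pos = 100L), models),
    "absent")
  expect_equal(a$region, "intergenic")
  expect_true(is.na(a$nearest_gene))
})

test_that("enhancer hits are interval containment", {
  models <- twoGeneModels()
  enh <- GRanges("chr1", IRanges(9400L, 9600L), name = "E1")
  a <- annotateSites(data.frame(chrom = "chr1", pos = c(9500L, 9700L)),
                     models, enhancers = enh)
  expect_equal(a$enhancer_hit, c(TRUE, FALSE))
  expect_equal(a$enhancer_id, c("E1", NA))
})

test_that("a promoter-overlapping CpG annotates to the expected gene", {
  # synthetic gene-model fixture placing an ARRDC2-like promoter at the
  # validated CpG coordinate chr19:18118304
  g <- GRanges("chr19", IRanges(18118000L, 18125000L), strand = "+",
               gene_id = "ARRDC2", gene_name = "ARRDC2")
  models <- GeneModelSet(g)
  a <- annotateSites(data.frame(chrom = "chr19", pos = 18118304L), models)
  expect_equal(a$region, "promoter")
  expect_equal(a$nearest_gene, "ARRDC2")
})

test_that("region distribution uses DMR midpoints and sums to one", {
  models <- twoGeneModels()
  dmrs <- GRanges("chr1", IRanges(c(9400L, 11300L, 490000L, 495000L),
                                  c(9600L, 11500L, 492000L, 497000L)))
  rd <- regionDistribution(dmrs, models)
  expect_equal(sum(rd), 1)
  expect_equal(unname(rd["promoter"]), 0.25)
  expect_equal(unname(rd["intron"]), 0.25)
  expect_equal(unname(rd["intergenic"]), 0.5)
  expect_error(regionDistribution(GRanges(), models), "empty")
  # proportions sum to one on fuzzed inputs
  set.seed(5)
  for (i in 1:10) {
    pos <- sort(sample(1:600000, 6))
    fz <- GRanges("chr1", IRanges(pos, pos + 100L))
    expect_equal(sum(regionDistribution(fz, models)), 1)
  }
})
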