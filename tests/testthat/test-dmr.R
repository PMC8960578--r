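# DMR merging (2 kb chaining with consistent direction) and the
# member-sharing overlap rule.

dmcGR <- function(chrom, pos, delta) {
  GRanges(chrom, IRanges(pos, width = 1L), delta = delta)
}

test_that("the 2 kb chaining rule merges and separates as specified", {
  dmcs <- dmcGR("chr1", c(100L, 1500L, 4000L), c(0.3, 0.2, 0.25))
  out <- mergeDMRs(dmcs, max_gap = 2000L)
  expect_equal(length(out$dmrs), 1L)
  expect_equal(start(out$dmrs), 100L)
  expect_equal(end(out$dmrs), 1500L)
  expect_equal(out$dmrs$n_members, 2L)
  expect_equal(start(out$standalone), 4000L)
})

test_that("a sign flip closes the chain", {
  dmcs <- dmcGR("chr1", c(100L, 500L), c(0.3, -0.3))
  out <- mergeDMRs(dmcs)
  expect_equal(length(out$dmrs), 0L)
  expect_equal(length(out$standalone), 2L)
})

test_that("empty input gives empty outputs", {
  out <- mergeDMRs(GRanges())
  expect_equal(length(out$dmrs), 0L)
  expect_equal(length(out$standalone), 0L)
})

test_that("max_gap = 0 makes every distinct position stand-alone", {
  dmcs <- dmcGR("chr1", c(100L, 200L, 300L), rep(0.2, 3))
  out <- mergeDMRs(dmcs, max_gap = 0L)
  expect_equal(length(out$dmrs), 0L)
  expect_equal(length(out$standalone), 3L)
})

test_that("merging equals the exhaustive chain-partition oracle on fuzzed
          layouts and partitions every DMC exactly once", {
  set.seed(42)
  for (rep in 1:150) {
    n <- sample(1:25, 1)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    pos <- sample(1:20000, n)
    delta <- round(runif(n, -0.5, 0.5), 2)
    delta[delta == 0] <- 0.1
    dmcs <- dmcGR(chrom, pos, delta)
    out <- mergeDMRs(dmcs, max_gap = 2000L)
    oracle <- chainPartitionOracle(chrom, pos, delta, max_gap = 2000L)
    sizes <- sort(unname(lengths(oracle$chains)))
    got <- sort(c(out$dmrs$n_members, rep(1L, length(out$standalone))))
    expect_equal(got, as.integer(sizes))
    # spans of multi-member chains match
    ospans <- lapply(Filter(function(i) length(i) >= 2, oracle$chains),
                     function(i) c(oracle$chrom[i[1]],
                                   min(oracle$pos[i]), max(oracle$pos[i])))
    gspans <- lapply(seq_along(out$dmrs), function(i)
      c(as.character(seqnames(out$dmrs))[i], start(out$dmrs)[i],
        end(out$dmrs)[i]))
    expect_setequal(vapply(ospans, paste, character(1), collapse = ":"),
                    vapply(gspans, paste, character(1), collapse = ":"))
    # partition: every DMC in exactly one DMR or stand-alone
    n_assigned <- sum(out$dmrs$n_members) + length(out$standalone)
    expect_equal(n_assigned, n)
  }
})

test_that("merging is invariant to input order", {
  set.seed(7)
  dmcs <- dmcGR("chr1", sample(1:10000, 10), runif(10, 0.1, 0.5))
  a <- mergeDMRs(dmcs)
  b <- mergeDMRs(dmcs[sample(10)])
  expect_identical(as.data.frame(a$dmrs), as.data.frame(b$dmrs))
})

test_that("member gaps within a DMR never exceed the threshold", {
  set.seed(21)
  dmcs <- dmcGR("chr1", sort(sample(1:30000, 40)), runif(40, 0.05, 0.3))
  out <- mergeDMRs(dmcs, max_gap = 2000L)
  for (i in seq_along(out$dmrs)) {
    mp <- sort(unlist(out$dmrs$member_pos[i]))
    if (length(mp) > 1) expect_true(all(diff(mp) <= 2000L))
  }
})

test_that("overlap counts DMRs sharing a member position, not just spans", {
  mk <- function(members, delta = 0.3) {
    gr <- GRanges("chr1", IRanges(min(members), max(members)),
                  n_members = length(members), direction = "hyper",
                  mean_delta = delta,
                  member_pos = IntegerList(members))
    gr
  }
  # identical DMR in two sets -> shared
  ov <- dmrOverlap(list(A = mk(c(100L, 800L)), B = mk(c(100L, 800L))))
  expect_equal(ov$cells$n[ov$cells$signature == "A+B"], 1L)
  # overlapping spans, disjoint members -> not shared
  ov2 <- dmrOverlap(list(A = mk(c(100L, 800L)), B = mk(c(300L, 600L))))
  expect_true(!"A+B" %in% ov2$cells$signature)
  expect_equal(sum(ov2$cells$n), 2L)
  # three sets sharing one member position -> triple cell of one
  ov3 <- dmrOverlap(list(A = mk(c(100L, 800L)), B = mk(c(100L, 1900L)),
                         C = mk(c(100L, 500L))))
  expect_equal(ov3$cells$n[ov3$cells$signature == "A+B+C"], 1L)
})

test_that("overlap cells are label-symmetric and obey inclusion-exclusion", {
  mk <- function(members) GRanges("chr1",
                                  IRanges(min(members), max(members)),
                                  n_members = length(members),
                                  direction = "hyper", mean_delta = 0.2,
                                  member_pos = IntegerList(members))
  sets <- list(A = c(mk(c(100L, 700L)), mk(c(5000L, 5600L))),
               B = c(mk(c(700L, 1200L)), mk(c(9000L, 9400L))),
               C = mk(c(5000L, 5300L)))
  ov <- dmrOverlap(sets)
  ov_perm <- dmrOverlap(sets[c("C", "A", "B")])
  expect_equal(sort(paste(ov$cells$signature, ov$cells$n)),
               sort(paste(ov_perm$cells$signature, ov_perm$cells$n)))
  # clusters containing each label sum over the label's Venn cells
  for (lab in names(sets)) {
    in_cells <- sum(ov$cells$n[vapply(strsplit(ov$cells$signature, "\\+"),
                                      function(s) lab %in% s, logical(1))])
    expect_lte(in_cells, length(sets[[lab]]))
    expect_gte(in_cells, 1L)
  }
  # pairwise counts equal cells summed over signatures containing the pair
  pc <- ov$pair_counts
  for (r in seq_len(nrow(pc))) {
    expect_equal(pc$n[r], sum(ov$cells$n[
      vapply(strsplit(ov$cells$signature, "\\+"),
             function(s) all(c(pc$label_a[r], pc$label_b[r]) %in% s),
             logical(1))]))
  }
})
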