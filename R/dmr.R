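# Merge called DMCs into differentially methylated regions (DMRs) and
# compute cross-fraction / cross-scope overlaps by the member-sharing rule.

#' Merge DMCs into DMRs by greedy chaining
#'
#' Walks the called DMCs left to right per chromosome: a DMC joins the
#' current chain iff it lies on the same chromosome, its gap to the previous
#' member (or to the chain start, with `gap_from = "first"`) is at most
#' `max_gap` bp, and its methylation difference has the same sign
#' ("consistent methylation pattern"). A sign flip closes the chain. Chains
#' of two or more DMCs become DMRs; singleton chains are stand-alone DMCs.
#'
#' @param dmcs a [GenomicRanges::GRanges] of DMCs with mcols `delta` (from
#'   [callDMCs()]); unsorted input is sorted first.
#' @param max_gap maximum gap in bp between consecutive members
#'   (default 2000).
#' @param gap_from `"previous"` measures the gap to the previous member
#'   (default); `"first"` anchors it at the chain's first member.
#' @return list with `dmrs` (GRanges spanning first to last member, mcols
#'   `n_members`, `direction`, `mean_delta` and `member_pos`, an
#'   [IRanges::IntegerList] of member positions) and `standalone` (GRanges
#'   of the singleton DMCs). Every input DMC appears in exactly one of the
#'   two.
#' @export
mergeDMRs <- function(dmcs, max_gap = 2000L, gap_from = c("previous",
                                                          "first")) {
  gap_from <- match.arg(gap_from)
  if (!length(dmcs))
    return(list(dmrs = GRanges(), standalone = GRanges()))
  o <- order(as.factor(seqnames(dmcs)), start(dmcs))
  dmcs <- dmcs[o]
  chrom <- as.character(seqnames(dmcs))
  pos <- start(dmcs)
  sgn <- sign(dmcs$delta)
  chain_id <- integer(length(dmcs))
  cur <- 1L
  chain_id[1L] <- cur
  for (i in seq_along(dmcs)[-1L]) {
    anchor <- if (gap_from == "previous") pos[i - 1L] else
      pos[match(cur, chain_id)]
    if (chrom[i] == chrom[i - 1L] && pos[i] - anchor <= max_gap &&
        sgn[i] == sgn[i - 1L] && sgn[i] != 0) {
      chain_id[i] <- cur
    } else {
      cur <- cur + 1L
      chain_id[i] <- cur
    }
  }
  sizes <- table(chain_id)
  dmr_chains <- as.integer(names(sizes)[sizes >= 2L])
  standalone <- dmcs[chain_id %in% as.integer(names(sizes)[sizes == 1L])]
  dmrs <- GRanges()
  if (length(dmr_chains)) {
    idxs <- lapply(dmr_chains, function(cc) which(chain_id == cc))
    first <- vapply(idxs, `[`, integer(1), 1L)
    last <- vapply(idxs, function(i) i[length(i)], integer(1))
    dmrs <- GRanges(chrom[first], IRanges(pos[first], pos[last]))
    mcols(dmrs) <- DataFrame(
      n_members = lengths(idxs),
      direction = ifelse(sgn[first] > 0, "hyper", "hypo"),
      mean_delta = vapply(idxs, function(i) mean(dmcs$delta[i]), numeric(1)),
      member_pos = IntegerList(lapply(idxs, function(i) pos[i])))
  }
  list(dmrs = dmrs, standalone = standalone)
}

#' Cross-set DMR overlap by the member-sharing rule
#'
#' A DMR of one set matches another set iff at least one of its member DMC
#' positions is a member position of some DMR in the other set; overlapping
#' spans with disjoint members do not count. Matching DMRs across sets are
#' linked into clusters (connected components of the sharing graph); each
#' cluster contributes one count to the Venn cell of the label signature it
#' spans.
#'
#' @param dmr_sets named list, one element per label (fraction or scope),
#'   each the `dmrs` GRanges from [mergeDMRs()].
#' @return list with `set_counts` (DMRs per label), `cells` (data.frame:
#'   `signature` such as `"CD4+CD8"`, `n`), and `pair_counts` (data.frame of
#'   pairwise shared-cluster counts, i.e. clusters containing both labels).
#' @export
dmrOverlap <- function(dmr_sets) {
  stopifnot(is.list(dmr_sets), !is.null(names(dmr_sets)))
  labels <- names(dmr_sets)
  nodes <- list()
  for (lab in labels) {
    set <- dmr_sets[[lab]]
    for (i in seq_along(set))
      nodes[[length(nodes) + 1L]] <- list(
        label = lab,
        members = paste0(as.character(seqnames(set))[i], ":",
                         unlist(set$member_pos[i])))
  }
  n <- length(nodes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    pos_index <- list()
    for (i in seq_len(n)) for (k in nodes[[i]]$members)
      pos_index[[k]] <- c(pos_index[[k]], i)
    for (grp in pos_index) if (length(grp) > 1L) {
      r <- find(grp[1L])
      for (j in grp[-1L]) parent[find(j)] <- r
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  sig <- vapply(split(seq_len(n), comp), function(idx)
    paste(sort(unique(vapply(nodes[idx], `[[`, character(1), "label"))),
          collapse = "+"),
    character(1))
  cells <- as.data.frame(table(signature = sig), stringsAsFactors = FALSE)
  names(cells)[2] <- "n"
  pair_counts <- data.frame(label_a = character(), label_b = character(),
                            n = integer())
  if (length(labels) > 1L) {
    combs <- utils::combn(sort(labels), 2)
    pair_counts <- data.frame(
      label_a = combs[1, ], label_b = combs[2, ],
      n = apply(combs, 2, function(ab) {
        sum(vapply(strsplit(sig, "\\+"), function(s)
          all(ab %in% s), logical(1)))
      }))
  }
  list(set_counts = vapply(dmr_sets, length, integer(1)),
       cells = cells, pair_counts = pair_counts)
}
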