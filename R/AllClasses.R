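#' MethylExperiment: per-CpG methylation counts for one or more cell fractions
#'
#' A thin extension of [SummarizedExperiment::RangedSummarizedExperiment-class]
#' holding two integer assays, `meth` (methylated read counts) and `total`
#' (total read coverage), with one row per CpG site (width-1 ranges, 1-based
#' plus-strand cytosine positions) and one column per sample. `NA` cells mark
#' sites unobserved in a sample; zero-coverage cells are kept distinct from
#' missing cells at read time (both are removed by [filterSites()]).
#'
#' The column data is the sample sheet: `sample_id`, `individual_id`,
#' `pair_id`, `group` (`case`/`control`), `fraction`, `age_months` and
#' `seroconversion_age_months` (`NA` for controls).
#'
#' @aliases MethylExperiment
#' @export
setClass("MethylExperiment", contains = "RangedSummarizedExperiment")

setValidity("MethylExperiment", function(object) {
  msg <- character()
  if (!all(c("meth", "total") %in% assayNames(object)))
    msg <- c(msg, "assays 'meth' and 'total' are required")
  else {
    m <- assay(object, "meth"); n <- assay(object, "total")
    if (!identical(dim(m), dim(n)))
      msg <- c(msg, "'meth' and 'total' dimensions differ")
    if (!identical(is.na(m), is.na(n)))
      msg <- c(msg, "'meth' and 'total' must share one missingness pattern")
    ok <- !is.na(m)
    if (any(m[ok] < 0) || any(n[ok] < 0) || any(m[ok] > n[ok]))
      msg <- c(msg, "counts must satisfy 0 <= meth <= total")
  }
  if (length(object) && any(width(rowRanges(object)) != 1L))
    msg <- c(msg, "row ranges must be width-1 CpG positions")
  if (is.unsorted(order(as.factor(seqnames(rowRanges(object))),
                        start(rowRanges(object)))))
    msg <- c(msg, "sites must be sorted by (chrom, pos)")
  req <- c("sample_id", "individual_id", "pair_id", "group", "fraction",
           "age_months")
  if (!all(req %in% colnames(colData(object))))
    msg <- c(msg, paste("sample sheet columns missing:",
                        paste(setdiff(req, colnames(colData(object))),
                              collapse = ", ")))
  else if (!all(object$group %in% c("case", "control")))
    msg <- c(msg, "group must be 'case' or 'control'")
  if (length(msg)) msg else TRUE
})

#' Construct a MethylExperiment
#'
#' @param meth,total integer matrices (sites x samples) of methylated and
#'   total read counts; `NA` marks missing cells (same pattern in both).
#' @param sites a [GenomicRanges::GRanges] of width-1 CpG positions, or a
#'   data.frame with columns `chrom` and `pos` (1-based).
#' @param sampleSheet a data.frame/DataFrame of per-sample metadata with
#'   columns `sample_id`, `individual_id`, `pair_id`, `group`, `fraction`,
#'   `age_months` and optionally `seroconversion_age_months`.
#' @return A [MethylExperiment-class] with sites sorted by (chrom, pos).
#' @export
MethylExperiment <- function(meth, total, sites, sampleSheet) {
  if (is.data.frame(sites))
    sites <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
  sampleSheet <- validateSampleSheet(sampleSheet, require_pairs = FALSE)
  storage.mode(meth) <- "integer"
  storage.mode(total) <- "integer"
  o <- order(as.factor(seqnames(sites)), start(sites))
  se <- SummarizedExperiment(
    assays = list(meth = meth[o, , drop = FALSE],
                  total = total[o, , drop = FALSE]),
    rowRanges = sites[o],
    colData = sampleSheet)
  colnames(se) <- sampleSheet$sample_id
  new("MethylExperiment", se)
}

#' Validate a sample sheet
#'
#' Checks column presence, group labels, and (optionally) that every pair id
#' carries exactly one case and one control individual.
#'
#' @param sheet data.frame or DataFrame.
#' @param require_pairs enforce the one-case/one-control-per-pair invariant.
#' @return The sheet as a [S4Vectors::DataFrame] with `sample_id` row names.
#' @export
validateSampleSheet <- function(sheet, require_pairs = TRUE) {
  sheet <- as(sheet, "DataFrame")
  req <- c("sample_id", "individual_id", "pair_id", "group", "fraction",
           "age_months")
  miss <- setdiff(req, colnames(sheet))
  if (length(miss))
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  if (!all(sheet$group %in% c("case", "control")))
    stop("group must be 'case' or 'control'")
  if (!"seroconversion_age_months" %in% colnames(sheet))
    sheet$seroconversion_age_months <- NA_real_
  if (require_pairs) {
    ind <- unique(as.data.frame(sheet[, c("pair_id", "group",
                                          "individual_id")]))
    tab <- table(ind$pair_id, ind$group)
    if (!all(tab == 1L))
      stop("each pair_id must have exactly one case and one control ",
           "individual")
  }
  rownames(sheet) <- NULL
  sheet
}

#' @describeIn MethylExperiment methylated-count assay
#' @param object,x a `MethylExperiment`
#' @export
methCounts <- function(object) assay(object, "meth")

#' @describeIn MethylExperiment total-coverage assay
#' @export
totalCounts <- function(object) assay(object, "total")

#' @describeIn MethylExperiment per-cell methylation proportions
#'   (meth/total; `NA` where missing or zero coverage)
#' @export
methLevels <- function(object) {
  m <- assay(object, "meth"); n <- assay(object, "total")
  p <- m / n
  p[!is.na(n) & n == 0L] <- NA_real_
  p
}

#' @describeIn MethylExperiment the sample sheet (column data)
#' @export
sampleSheet <- function(object) colData(object)

setMethod("show", "MethylExperiment", function(object) {
  cat("MethylExperiment:", nrow(object), "CpG sites x", ncol(object),
      "samples\n")
  cat("  fractions:", paste(unique(object$fraction), collapse = ", "), "\n")
  cat("  groups: ", sum(object$group == "case"), "case /",
      sum(object$group == "control"), "control samples;",
      length(unique(object$pair_id)), "pairs\n")
  obs <- !is.na(assay(object, "total"))
  cat(sprintf("  observed cells: %.1f%%\n", 100 * mean(obs)))
  invisible(NULL)
})

#' GeneModelSet: gene structures for annotation and cis windows
#'
#' Holds gene spans (with strand, id and name) and per-gene exon intervals.
#' The transcription start site (TSS) is the strand-aware span end: span
#' start for plus-strand genes, span end for minus-strand genes.
#'
#' @aliases GeneModelSet
#' @export
setClass("GeneModelSet",
         representation(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModelSet", function(object) {
  msg <- character()
  if (!all(c("gene_id", "gene_name") %in% colnames(mcols(object@genes))))
    msg <- c(msg, "genes need mcols 'gene_id' and 'gene_name'")
  if (any(duplicated(object@genes$gene_id)))
    msg <- c(msg, "duplicated gene_id")
  if (!all(names(object@exons) %in% object@genes$gene_id))
    msg <- c(msg, "exon list names must be gene ids")
  if (any(as.character(strand(object@genes)) == "*"))
    msg <- c(msg, "gene strand must be + or -")
  for (g in names(object@exons)) {
    span <- object@genes[object@genes$gene_id == g]
    ex <- object@exons[[g]]
    if (length(ex) && (any(start(ex) < start(span)) ||
                       any(end(ex) > end(span)))) {
      msg <- c(msg, paste0("exons of ", g, " exceed the gene span"))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModelSet
#' @param genes GRanges of gene spans with mcols `gene_id`, `gene_name` and
#'   explicit strand.
#' @param exons GRangesList of exon intervals, named by gene id.
#' @return A [GeneModelSet-class].
#' @export
GeneModelSet <- function(genes, exons = GRangesList()) {
  if (!length(exons)) {
    exons <- GRangesList(setNames(lapply(seq_along(genes),
                                         function(i) genes[i]),
                                  genes$gene_id))
  }
  new("GeneModelSet", genes = genes, exons = exons)
}

#' @describeIn GeneModelSet gene spans
#' @param object a `GeneModelSet`
#' @export
geneRanges <- function(object) object@genes

#' @describeIn GeneModelSet exon intervals per gene
#' @export
exonRanges <- function(object) object@exons

#' @describeIn GeneModelSet strand-aware TSS positions (width-1 GRanges,
#'   mcols carry gene id/name)
#' @export
tssPositions <- function(object) {
  g <- object@genes
  tss <- ifelse(as.character(strand(g)) == "+", start(g), end(g))
  out <- GRanges(seqnames(g), IRanges(tss, width = 1L), strand = strand(g))
  mcols(out) <- mcols(g)
  out
}

#' @describeIn GeneModelSet promoter windows around each TSS
#' @param upstream,downstream window half-widths in bp (default 1000/1000)
#' @export
promoterRegions <- function(object, upstream = 1000L, downstream = 1000L) {
  tss <- tssPositions(object)
  plus <- as.character(strand(tss)) == "+"
  st <- ifelse(plus, start(tss) - upstream, start(tss) - downstream)
  en <- ifelse(plus, start(tss) + downstream, start(tss) + upstream)
  out <- GRanges(seqnames(tss), IRanges(pmax(st, 1L), en), strand = strand(tss))
  mcols(out) <- mcols(tss)
  out
}

#' @describeIn GeneModelSet intron intervals (gene span minus exons)
#' @export
intronRanges <- function(object) {
  g <- object@genes
  out <- lapply(seq_along(g), function(i) {
    ex <- object@exons[[g$gene_id[i]]]
    GenomicRanges::setdiff(g[i], ex, ignore.strand = TRUE)
  })
  GRangesList(setNames(out, g$gene_id))
}

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet:", length(object@genes), "genes on",
      length(unique(as.character(seqnames(object@genes)))), "chromosomes\n")
  invisible(NULL)
})
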