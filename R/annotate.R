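# Genomic-feature annotation of DMCs/DMRs: promoter > exon > intron >
# intergenic precedence, nearest gene by TSS distance, enhancer overlap.

#' Annotate genomic positions against gene models
#'
#' Each position gets a region label with the fixed precedence
#' promoter > exon > intron > intergenic: promoter if inside any gene's
#' promoter window, else exon if inside any exon, else intron if inside any
#' transcript span, else intergenic. The nearest gene minimises the absolute
#' distance to a TSS (ties broken lexicographically by gene id, making the
#' result independent of gene-model input order); the signed TSS distance is
#' positive downstream of the TSS in the gene's reading direction. Enhancer
#' hits are interval containment in the optional enhancer set.
#'
#' @param sites a [GenomicRanges::GRanges] of width-1 positions (e.g. from
#'   [callDMCs()]) or a data.frame with `chrom` and `pos`.
#' @param models a [GeneModelSet-class].
#' @param enhancers optional [GenomicRanges::GRanges] of enhancer intervals
#'   (e.g. from [readBedIntervals()]); a `name` mcol is used as enhancer id.
#' @param promoter_up,promoter_down promoter window around the TSS in bp
#'   (default 1000/1000).
#' @return data.frame with columns `chrom`, `pos`, `region`, `nearest_gene`,
#'   `nearest_gene_name`, `distance_to_tss`, `enhancer_hit`, `enhancer_id`.
#' @export
annotateSites <- function(sites, models, enhancers = NULL,
                          promoter_up = 1000L, promoter_down = 1000L) {
  if (is.data.frame(sites))
    sites <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
  if (!length(geneRanges(models))) stop("empty gene models")
  genes <- geneRanges(models)
  tss <- tssPositions(models)
  prom <- promoterRegions(models, promoter_up, promoter_down)
  ex_all <- unlist(exonRanges(models), use.names = FALSE)
  known_chroms <- unique(as.character(seqnames(genes)))

  ov <- function(a, b) suppressWarnings(overlapsAny(a, b,
                                                    ignore.strand = TRUE))
  in_prom <- ov(sites, prom)
  in_exon <- ov(sites, ex_all)
  in_gene <- ov(sites, genes)
  region <- ifelse(in_prom, "promoter",
                   ifelse(in_exon, "exon",
                          ifelse(in_gene, "intron", "intergenic")))

  n <- length(sites)
  nearest_gene <- rep(NA_character_, n)
  nearest_name <- rep(NA_character_, n)
  dist_tss <- rep(NA_integer_, n)
  site_chr <- as.character(seqnames(sites))
  unknown <- !(site_chr %in% known_chroms)
  if (any(unknown)) {
    warning(sum(unknown), " position(s) on chromosome(s) absent from the ",
            "gene models: annotated intergenic with no nearest gene")
    region[unknown] <- "intergenic"
  }
  tss_chr <- as.character(seqnames(tss))
  tss_pos <- start(tss)
  tss_minus <- as.character(strand(tss)) == "-"
  ord <- order(tss$gene_id)
  for (i in which(!unknown)) {
    cand <- which(tss_chr == site_chr[i])
    if (!length(cand)) { region[i] <- "intergenic"; next }
    d <- abs(start(sites)[i] - tss_pos[cand])
    best <- cand[d == min(d)]
    if (length(best) > 1L) best <- best[order(tss$gene_id[best])][1L]
    nearest_gene[i] <- tss$gene_id[best]
    nearest_name[i] <- tss$gene_name[best]
    raw <- start(sites)[i] - tss_pos[best]
    dist_tss[i] <- if (tss_minus[best]) -raw else raw
  }

  enh_hit <- rep(FALSE, n)
  enh_id <- rep(NA_character_, n)
  if (!is.null(enhancers) && length(enhancers)) {
    hits <- suppressWarnings(findOverlaps(sites, enhancers,
                                          ignore.strand = TRUE))
    enh_hit[queryHits(hits)] <- TRUE
    ids <- if ("name" %in% colnames(mcols(enhancers)))
      enhancers$name else as.character(seq_along(enhancers))
    enh_id[queryHits(hits)] <- ids[subjectHits(hits)]
  }
  data.frame(chrom = site_chr, pos = start(sites), region = region,
             nearest_gene = nearest_gene, nearest_gene_name = nearest_name,
             distance_to_tss = dist_tss, enhancer_hit = enh_hit,
             enhancer_id = enh_id)
}

#' Distribution of DMRs over genomic regions
#'
#' Each DMR is represented by the midpoint of its span (a symmetric choice)
#' and annotated with [annotateSites()]; the proportions over the four
#' region labels sum to 1.
#'
#' @param dmrs GRanges of DMRs (from [mergeDMRs()]); must be non-empty.
#' @param models a [GeneModelSet-class].
#' @param ... passed to [annotateSites()].
#' @return named numeric over `promoter`, `exon`, `intron`, `intergenic`.
#' @export
regionDistribution <- function(dmrs, models, ...) {
  if (!length(dmrs)) stop("empty DMR list")
  mid <- GRanges(seqnames(dmrs),
                 IRanges((start(dmrs) + end(dmrs)) %/% 2L, width = 1L))
  ann <- annotateSites(mid, models, ...)
  labels <- c("promoter", "exon", "intron", "intergenic")
  props <- table(factor(ann$region, levels = labels)) / length(dmrs)
  setNames(as.numeric(props), labels)
}
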