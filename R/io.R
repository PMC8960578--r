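# Readers and writers for the on-disk formats: Bismark-coverage-style TSV,
# sample sheet CSV, GTF gene models, BED intervals, GMT gene sets and TSV
# expression matrices. Internal coordinates are 1-based inclusive (matching
# printed hg19 positions); BED input/output converts from/to the half-open
# 0-based convention through rtracklayer.

#' Read a Bismark-coverage-style TSV of per-CpG counts
#'
#' Expects six tab-separated columns with no header: chromosome, start, end,
#' methylation percentage, methylated count, unmethylated count; positions
#' are 1-based with start = end at the CpG cytosine. The recomputed
#' percentage is checked against column 4 (warning beyond 0.5 percentage
#' points). Zero-coverage rows are retained (they are removed later by the
#' coverage filter). CpG sites are destranded by default: a record at
#' position pos+1 immediately following a record at pos (the minus-strand
#' cytosine of the same CpG) is merged into the plus-strand position.
#'
#' @param path file path.
#' @param destrand merge pos+1 records into an existing pos record.
#' @return data.frame with columns `chrom`, `pos`, `n_meth`, `n_total`.
#' @export
readBismarkCoverage <- function(path, destrand = TRUE) {
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE,
               colClasses = c("character", "integer", "integer", "numeric",
                              "integer", "integer"),
               col.names = c("chrom", "start", "end", "pct", "n_meth",
                             "n_unmeth")),
    error = function(e) stop("malformed coverage file '", path, "': ",
                             conditionMessage(e)))
  if (!nrow(raw))
    return(data.frame(chrom = character(), pos = integer(),
                      n_meth = integer(), n_total = integer()))
  bad <- which(is.na(raw$start) | is.na(raw$n_meth) | is.na(raw$n_unmeth) |
                 raw$n_meth < 0 | raw$n_unmeth < 0 | raw$start < 1)
  if (length(bad))
    stop("malformed coverage row(s) in '", path, "' at line(s) ",
         paste(head(bad, 5), collapse = ", "))
  df <- data.frame(chrom = raw$chrom, pos = raw$start,
                   n_meth = raw$n_meth,
                   n_total = raw$n_meth + raw$n_unmeth)
  pct <- ifelse(df$n_total > 0, 100 * df$n_meth / df$n_total, 0)
  off <- abs(pct - raw$pct) > 0.5
  if (any(off))
    warning(sum(off), " row(s) in '", path,
            "' have a methylation percentage off by more than 0.5")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  if (destrand && nrow(df) > 1L) {
    keep_into <- rep(NA_integer_, nrow(df))
    last_kept <- 1L
    keep_into[1L] <- 1L
    for (i in 2L:nrow(df)) {
      if (df$chrom[i] == df$chrom[last_kept] &&
          df$pos[i] == df$pos[last_kept] + 1L) {
        keep_into[i] <- last_kept
      } else {
        keep_into[i] <- i
        last_kept <- i
      }
    }
    if (any(keep_into != seq_len(nrow(df)))) {
      df <- data.frame(
        chrom = df$chrom[unique(keep_into)],
        pos = df$pos[unique(keep_into)],
        n_meth = as.integer(tapply(df$n_meth, keep_into, sum)
                            [as.character(unique(keep_into))]),
        n_total = as.integer(tapply(df$n_total, keep_into, sum)
                             [as.character(unique(keep_into))]))
    }
  }
  rownames(df) <- NULL
  df
}

#' Write per-CpG counts in Bismark coverage format
#' @param df data.frame with `chrom`, `pos`, `n_meth`, `n_total`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBismarkCoverage <- function(df, path) {
  pct <- ifelse(df$n_total > 0, 100 * df$n_meth / df$n_total, 0)
  out <- data.frame(df$chrom, df$pos, df$pos, sprintf("%.6g", pct),
                    df$n_meth, df$n_total - df$n_meth)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Assemble per-sample coverage files into a MethylExperiment
#'
#' Takes the union of sites across samples of one cell fraction; cells for
#' sites absent from a sample's file are missing (`NA`).
#'
#' @param files named character vector mapping `sample_id` to file path.
#' @param sheet sample sheet (see [validateSampleSheet()]).
#' @param fraction fraction label; all sheet samples of this fraction must
#'   have a file.
#' @param destrand passed to [readBismarkCoverage()].
#' @return A [MethylExperiment-class] for the fraction.
#' @export
assembleMethylExperiment <- function(files, sheet, fraction,
                                     destrand = TRUE) {
  sheet <- validateSampleSheet(sheet, require_pairs = FALSE)
  sub <- sheet[sheet$fraction == fraction, , drop = FALSE]
  if (!nrow(sub)) stop("no samples of fraction '", fraction,
                       "' in the sample sheet")
  unknown <- setdiff(names(files), sheet$sample_id)
  if (length(unknown))
    stop("file(s) for sample(s) not in the sample sheet: ",
         paste(unknown, collapse = ", "))
  missing_files <- setdiff(sub$sample_id, names(files))
  if (length(missing_files))
    stop("no coverage file for sample(s): ",
         paste(missing_files, collapse = ", "))
  per <- lapply(sub$sample_id, function(sm) {
    df <- readBismarkCoverage(files[[sm]], destrand = destrand)
    if (anyDuplicated(paste(df$chrom, df$pos)))
      stop("duplicate (chrom,pos) in file of sample ", sm)
    if (!nrow(df)) warning("empty coverage file for sample ", sm)
    df
  })
  names(per) <- sub$sample_id
  all_sites <- unique(do.call(rbind, lapply(per, function(d)
    d[, c("chrom", "pos")])))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), ,
                         drop = FALSE]
  key <- paste(all_sites$chrom, all_sites$pos)
  meth <- total <- matrix(NA_integer_, nrow(all_sites), nrow(sub),
                          dimnames = list(NULL, sub$sample_id))
  for (sm in sub$sample_id) {
    d <- per[[sm]]
    i <- match(paste(d$chrom, d$pos), key)
    meth[i, sm] <- d$n_meth
    total[i, sm] <- d$n_total
  }
  MethylExperiment(meth, total, all_sites, sub)
}

#' Read / write the sample sheet CSV
#' @param path file path.
#' @return [readSampleSheet()]: a validated data.frame.
#' @export
readSampleSheet <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE,
                   stringsAsFactors = FALSE)
  as.data.frame(validateSampleSheet(df, require_pairs = FALSE))
}

#' @rdname readSampleSheet
#' @param sheet sample sheet data.frame.
#' @export
writeSampleSheet <- function(sheet, path) {
  write.table(as.data.frame(sheet), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Uses `gene` and `exon` features; genes lacking explicit `gene` rows are
#' reconstructed from the span of their exons. The TSS of a minus-strand
#' gene is the span end.
#'
#' @param path GTF file.
#' @return A [GeneModelSet-class].
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!"gene_id" %in% colnames(mcols(gr)))
    stop("GTF lacks gene_id attributes")
  if (!"gene_name" %in% colnames(mcols(gr)))
    gr$gene_name <- gr$gene_id
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  if (!length(genes)) {
    spl <- split(exons, exons$gene_id)
    genes <- unlist(range(spl, ignore.strand = FALSE))
    genes$gene_id <- names(genes)
    nm <- vapply(spl, function(x) x$gene_name[1], character(1))
    genes$gene_name <- nm[genes$gene_id]
    names(genes) <- NULL
  }
  g <- GRanges(seqnames(genes), ranges(genes), strand = strand(genes),
               gene_id = genes$gene_id, gene_name = genes$gene_name)
  g <- sort(g)
  ex <- lapply(g$gene_id, function(id) {
    e <- exons[exons$gene_id == id]
    granges(sort(e))
  })
  names(ex) <- g$gene_id
  empty <- !lengths(ex)
  for (id in g$gene_id[empty]) ex[[id]] <- granges(g[g$gene_id == id])
  GeneModelSet(g, GRangesList(ex))
}

#' Write gene models as GTF (gene and exon features)
#' @param models a [GeneModelSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  g <- geneRanges(models)
  lines <- character()
  for (i in seq_along(g)) {
    id <- g$gene_id[i]
    attr_g <- sprintf('gene_id "%s"; gene_name "%s";', id, g$gene_name[i])
    lines <- c(lines, paste(as.character(seqnames(g))[i], "toy", "gene",
                            start(g)[i], end(g)[i], ".",
                            as.character(strand(g))[i], ".", attr_g,
                            sep = "\t"))
    ex <- exonRanges(models)[[id]]
    for (j in seq_along(ex)) {
      attr_e <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_name "%s";',
                        id, id, g$gene_name[i])
      lines <- c(lines, paste(as.character(seqnames(ex))[j], "toy", "exon",
                              start(ex)[j], end(ex)[j], ".",
                              as.character(strand(ex))[j], ".", attr_e,
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read BED intervals as 1-based inclusive GRanges
#'
#' BED is half-open and 0-based; the returned GRanges is 1-based inclusive,
#' so a BED line `chr1 99 200` becomes `chr1:100-200`.
#'
#' @param path BED file (BED3/BED6/BED12).
#' @return A [GenomicRanges::GRanges].
#' @export
readBedIntervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(start(gr) < 1)) stop("coordinate underflow in BED file")
  gr
}

#' Read a GMT gene-set file
#' @param path GMT file (term, description, genes...; tab-separated).
#' @return Named list of character vectors of gene ids.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1],
                       character(1))
  out
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a genes x samples expression matrix (TSV, RPKM-normalised)
#' @param path TSV file with gene ids in the first column and sample ids as
#'   header.
#' @return [readExpressionMatrix()]: a numeric matrix.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                   check.names = FALSE)
  m <- as.matrix(df)
  if (any(m < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  m
}

#' @rdname readExpressionMatrix
#' @param mat numeric matrix, genes x samples.
#' @export
writeExpressionMatrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
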