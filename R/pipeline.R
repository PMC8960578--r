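# End-to-end orchestration: filter -> DMC (per fraction x scope) -> DMR ->
# overlap -> annotate -> correlate -> enrich -> concordance, with a run
# manifest and deterministic TSV outputs.

#' Assemble a pipeline configuration
#'
#' @param coverage_files named character vector `sample_id` -> coverage
#'   file path, or `NULL` when `matrices` supplies in-memory data.
#' @param sample_sheet data.frame or path of the sample sheet CSV.
#' @param gtf path of the gene-model GTF, or a [GeneModelSet-class].
#' @param matrices optional named list of [MethylExperiment-class] per
#'   fraction (takes precedence over `coverage_files`).
#' @param enhancers optional BED path or GRanges.
#' @param expression optional expression TSV path or matrix.
#' @param gmt optional GMT path or named list of gene sets.
#' @param eqtm optional eQTM table path (TSV with chrom, pos, gene, effect)
#'   or data.frame.
#' @param pyro optional pyro-proportion table (TSV/data.frame: chrom, pos,
#'   sample_id, proportion) with a `fraction` attribute, or `NULL`.
#' @param out_dir output directory.
#' @param filter a [filterConfig()].
#' @param scopes analysis scopes to run.
#' @param fdr,min_delta DMC thresholds (defaults 0.1/0.1).
#' @param max_gap DMR merging gap (default 2000).
#' @param window_bp,min_abs_rho cis-correlation window and reporting cut.
#' @param enrich_fdr enrichment FDR threshold (default 0.05).
#' @param seed master seed recorded in the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipelineConfig <- function(coverage_files = NULL, sample_sheet, gtf,
                           matrices = NULL, enhancers = NULL,
                           expression = NULL, gmt = NULL, eqtm = NULL,
                           pyro = NULL, out_dir,
                           filter = filterConfig(),
                           scopes = c("all_longitudinal",
                                      "pre_seroconversion"),
                           fdr = 0.1, min_delta = 0.1, max_gap = 2000L,
                           window_bp = 250000L, min_abs_rho = 0.5,
                           enrich_fdr = 0.05, seed = 1L) {
  stopifnot(fdr > 0, fdr <= 1, min_delta >= 0, min_delta <= 1,
            max_gap >= 0, window_bp > 0, min_abs_rho >= 0,
            enrich_fdr > 0, enrich_fdr <= 1)
  for (p in c(coverage_files,
              Filter(is.character, list(sample_sheet, gtf, enhancers,
                                        expression, gmt, eqtm, pyro))))
    if (is.character(p) && length(p) == 1 && !file.exists(p))
      stop("input file does not exist: ", p)
  structure(list(coverage_files = coverage_files,
                 sample_sheet = sample_sheet, gtf = gtf,
                 matrices = matrices, enhancers = enhancers,
                 expression = expression, gmt = gmt, eqtm = eqtm,
                 pyro = pyro, out_dir = out_dir, filter = filter,
                 scopes = scopes, fdr = fdr, min_delta = min_delta,
                 max_gap = max_gap, window_bp = window_bp,
                 min_abs_rho = min_abs_rho, enrich_fdr = enrich_fdr,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# stable hash of the run configuration (file paths and thresholds)
.configHash <- function(config) {
  # the hash covers analytic inputs and thresholds, not the output location
  strip <- config[!(names(config) %in% c("matrices", "out_dir"))]
  strip <- lapply(strip, function(x)
    if (is.character(x) || is.numeric(x) || is.logical(x) || is.list(x)) x
    else class(x))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(strip, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

# TSV writer with a schema header comment; output depends only on `df`
.writeStageTable <- function(df, path, stage, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# stage: %s", stage),
               sprintf("# config_hash: %s", hash),
               sprintf("# columns: %s", paste(colnames(df),
                                              collapse = ", "))), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.grangesToDf <- function(gr) {
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
                   end = end(gr))
  md <- as.data.frame(mcols(gr))
  for (j in colnames(md)) if (is(md[[j]], "list") || is.list(md[[j]]))
    md[[j]] <- vapply(md[[j]], function(v) paste(unlist(v), collapse = ";"),
                      character(1))
  cbind(df, md)
}

#' Run the full differential-methylation pipeline
#'
#' Executes, per cell fraction and analysis scope: site filtering, per-CpG
#' beta-binomial testing and DMC calling, DMR merging, genomic annotation,
#' optional cis expression correlation, optional gene-set enrichment, and
#' optional pyrosequencing concordance; then cross-fraction and
#' all-vs-pre-seroconversion DMR overlaps. All stage outputs are TSV files
#' under `out_dir` with a manifest JSON (config hash, package version, row
#' counts per stage). Output is a pure function of (inputs, config, seed);
#' any stage failure aborts with the stage name, keeping the outputs of the
#' completed stages on disk.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, a list with per-fraction/scope results (`dmcs`,
#'   `dmrs`, `standalone`, `annotation`, `correlations`, `enrichment`,
#'   `concordance`), `overlaps`, and the `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .configHash(config)
  manifest <- list(config_hash = hash, seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("methpairs")),
                   stages = list())
  results <- list(fractions = list())
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e) fail(name, e))
    manifest$stages[[name]] <<- TRUE
    r
  }

  sheet <- stage("read_sheet", {
    if (is.character(config$sample_sheet))
      readSampleSheet(config$sample_sheet) else
        as.data.frame(config$sample_sheet)
  })
  models <- stage("read_models", {
    if (is.character(config$gtf)) readGeneModels(config$gtf) else config$gtf
  })
  enhancers <- if (is.null(config$enhancers)) NULL else
    stage("read_enhancers", {
      if (is.character(config$enhancers))
        readBedIntervals(config$enhancers) else config$enhancers
    })
  expression <- if (is.null(config$expression)) NULL else
    stage("read_expression", {
      if (is.character(config$expression))
        readExpressionMatrix(config$expression) else config$expression
    })
  gene_sets <- if (is.null(config$gmt)) NULL else
    stage("read_gmt", {
      if (is.character(config$gmt)) readGmt(config$gmt) else config$gmt
    })

  fractions <- unique(sheet$fraction)
  dmr_sets_by_scope <- list()
  for (fr in fractions) {
    me <- stage(paste0("assemble_", fr), {
      if (!is.null(config$matrices)) config$matrices[[fr]] else
        assembleMethylExperiment(config$coverage_files, sheet, fr)
    })
    mef <- stage(paste0("filter_", fr), filterSites(me, config$filter))
    for (sc in config$scopes) {
      tag <- paste0(fr, "_", sub("_longitudinal", "", sc))
      dmcs <- stage(paste0("dmc_", tag),
                    callDMCs(mef, scope = sc, fdr = config$fdr,
                             min_delta = config$min_delta))
      merged <- stage(paste0("dmr_", tag),
                      mergeDMRs(dmcs, max_gap = config$max_gap))
      ann <- stage(paste0("annotate_", tag), {
        if (length(dmcs))
          annotateSites(dmcs, models, enhancers = enhancers) else NULL
      })
      corr <- NULL
      if (!is.null(expression))
        corr <- stage(paste0("correlate_", tag), {
          ex <- expression[, colnames(expression) %in% colnames(mef),
                           drop = FALSE]
          if (!ncol(ex))
            stop("no expression samples match the methylation samples of ",
                 "fraction ", fr)
          correlateExpression(dmcs, mef, ex, models,
                              window_bp = config$window_bp,
                              report_abs_rho = config$min_abs_rho)
        })
      enr <- NULL
      if (!is.null(gene_sets) && length(dmcs) && !is.null(ann))
        enr <- stage(paste0("enrich_", tag), {
          all_ann <- annotateSites(attr(dmcs, "all_sites"), models)
          background <- unique(stats::na.omit(all_ann$nearest_gene))
          query <- unique(stats::na.omit(ann$nearest_gene))
          if (!is.null(corr) && nrow(corr))
            query <- union(query, corr$gene_id[corr$flagged])
          query <- intersect(query, background)
          fisherEnrichment(query, background, gene_sets,
                           fdr_threshold = config$enrich_fdr)
        })
      dmr_sets_by_scope[[sc]][[fr]] <- merged$dmrs
      results$fractions[[tag]] <- list(
        fraction = fr, scope = sc, dmcs = dmcs, dmrs = merged$dmrs,
        standalone = merged$standalone, annotation = ann,
        correlations = corr, enrichment = enr)
      if (length(dmcs))
        .writeStageTable(cbind(.grangesToDf(dmcs),
                               if (!is.null(ann))
                                 ann[, c("region", "nearest_gene")] else
                                   NULL),
                         file.path(config$out_dir,
                                   paste0("dmc_", tag, ".tsv")),
                         paste0("dmc_", tag), hash)
      if (length(merged$dmrs))
        .writeStageTable(.grangesToDf(merged$dmrs),
                         file.path(config$out_dir,
                                   paste0("dmr_", tag, ".tsv")),
                         paste0("dmr_", tag), hash)
      if (!is.null(corr) && nrow(corr))
        .writeStageTable(corr, file.path(config$out_dir,
                                         paste0("corr_", tag, ".tsv")),
                         paste0("corr_", tag), hash)
      if (!is.null(enr))
        .writeStageTable(enr, file.path(config$out_dir,
                                        paste0("enrich_", tag, ".tsv")),
                         paste0("enrich_", tag), hash)
      manifest$stages[[paste0("counts_", tag)]] <- list(
        dmcs = length(dmcs), dmrs = length(merged$dmrs),
        standalone = length(merged$standalone))
    }
  }

  results$overlaps <- list()
  for (sc in names(dmr_sets_by_scope))
    if (length(dmr_sets_by_scope[[sc]]) > 1)
      results$overlaps[[sc]] <- stage(paste0("overlap_", sc),
                                      dmrOverlap(dmr_sets_by_scope[[sc]]))
  if (length(config$scopes) > 1)
    for (fr in fractions) {
      sets <- lapply(config$scopes, function(sc)
        dmr_sets_by_scope[[sc]][[fr]])
      names(sets) <- config$scopes
      results$overlaps[[paste0("scopes_", fr)]] <-
        stage(paste0("overlap_scopes_", fr), dmrOverlap(sets))
    }
  for (nm in names(results$overlaps))
    .writeStageTable(results$overlaps[[nm]]$cells,
                     file.path(config$out_dir,
                               paste0("overlap_", nm, ".tsv")),
                     paste0("overlap_", nm), hash)

  if (!is.null(config$pyro)) {
    pyro <- if (is.character(config$pyro))
      read.table(config$pyro, sep = "\t", header = TRUE) else config$pyro
    fr <- attr(config$pyro, "fraction")
    if (is.null(fr)) fr <- fractions[1]
    me <- if (!is.null(config$matrices)) config$matrices[[fr]] else
      assembleMethylExperiment(config$coverage_files, sheet, fr)
    results$concordance <- stage("concordance", pyroConcordance(me, pyro))
    .writeStageTable(results$concordance,
                     file.path(config$out_dir, "concordance.tsv"),
                     "concordance", hash)
  }

  eqtm <- if (is.null(config$eqtm)) NULL else
    stage("eqtm_join", {
      tab <- if (is.character(config$eqtm))
        read.table(config$eqtm, sep = "\t", header = TRUE) else config$eqtm
      first <- results$fractions[[1]]
      joinEQTM(first$dmcs, tab)
    })
  if (!is.null(eqtm)) results$eqtm <- eqtm

  results$manifest <- manifest
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Human-readable summary of a pipeline run
#'
#' @param results the list returned by [runPipeline()].
#' @return character vector of report lines, invisibly; also printed.
#' @export
reportSummary <- function(results) {
  lines <- c("methpairs pipeline summary",
             paste0("config hash: ", results$manifest$config_hash))
  for (nm in names(results$fractions)) {
    r <- results$fractions[[nm]]
    lines <- c(lines, sprintf(
      "%s [%s]: %d DMCs, %d DMRs, %d stand-alone DMCs",
      r$fraction, r$scope, length(r$dmcs), length(r$dmrs),
      length(r$standalone)))
    if (!is.null(r$enrichment)) {
      hit <- r$enrichment[r$enrichment$enriched, , drop = FALSE]
      if (nrow(hit))
        lines <- c(lines, sprintf("  enriched terms: %s",
                                  paste(hit$term, collapse = ", ")))
    }
    if (!is.null(r$correlations) && nrow(r$correlations)) {
      fl <- r$correlations[r$correlations$flagged, , drop = FALSE]
      lines <- c(lines, sprintf("  |rho|>threshold CpG-gene pairs: %d",
                                nrow(fl)))
    }
  }
  for (nm in names(results$overlaps)) {
    ov <- results$overlaps[[nm]]
    lines <- c(lines, sprintf("overlap %s: %s", nm,
                              paste(sprintf("%s=%d", ov$cells$signature,
                                            ov$cells$n), collapse = ", ")))
  }
  if (!is.null(results$concordance)) {
    cc <- results$concordance
    lines <- c(lines, sprintf(
      "concordance: %d/%d sites with concordant direction",
      sum(cc$concordant_direction, na.rm = TRUE),
      sum(!is.na(cc$concordant_direction))))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
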