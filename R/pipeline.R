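#' Pipeline configuration
#'
#' Assembles and validates the tunable parameters of the per-case and
#' cohort analysis. Defaults: 5 mm PTV margin, rCBV inclusion-zone cutoff
#' ratio 1.75, distance-band cuts at 20 and 30 mm with inside-CTV voxels
#' counted in the first band, and a 0.05 significance level.
#'
#' @param ptv_margin_mm positive CTV-to-PTV margin in mm.
#' @param iz_threshold_ratio positive rCBV cutoff ratio.
#' @param distance_cuts_mm strictly increasing positive pair (mm).
#' @param include_inside_in_bands count inside-CTV voxels (distance 0) in
#'   the first band.
#' @param alpha significance / normality-gate level in (0, 1).
#' @param crop_to_brain_mask intersect target volumes with a brain mask
#'   (off by default: the analysis hull deliberately extends beyond
#'   anatomical boundaries).
#' @param brain_mask_path optional brain-mask NIfTI used when cropping.
#' @param seed optional integer seed (used by the simulate entry point).
#' @return A validated configuration list.
#' @export
pipelineConfig <- function(ptv_margin_mm = 5,
                           iz_threshold_ratio = 1.75,
                           distance_cuts_mm = c(20, 30),
                           include_inside_in_bands = TRUE,
                           alpha = 0.05,
                           crop_to_brain_mask = FALSE,
                           brain_mask_path = NULL,
                           seed = NULL) {
  stopifnot(ptv_margin_mm > 0, iz_threshold_ratio > 0,
            length(distance_cuts_mm) == 2L,
            all(distance_cuts_mm > 0),
            distance_cuts_mm[1] < distance_cuts_mm[2],
            alpha > 0, alpha < 1)
  cfg <- list(ptv_margin_mm = ptv_margin_mm,
              iz_threshold_ratio = iz_threshold_ratio,
              distance_cuts_mm = distance_cuts_mm,
              include_inside_in_bands = include_inside_in_bands,
              alpha = alpha,
              crop_to_brain_mask = crop_to_brain_mask,
              brain_mask_path = brain_mask_path,
              seed = seed)
  class(cfg) <- "PipelineConfig"
  cfg
}

readCaseDir <- function(dir, row, withBrainMask = NULL) {
  cavity <- readLabelVolume(file.path(dir, "cavity.nii.gz"),
                            labelMap = c(cavity = 1L))
  enhancing <- readLabelVolume(file.path(dir, "enhancing.nii.gz"),
                               labelMap = c(enhancing = 1L))
  cbv <- NULL; reference <- NULL
  if (file.exists(file.path(dir, "cbv.nii.gz")) &&
      file.exists(file.path(dir, "reference.nii.gz"))) {
    cbv <- readScalarVolume(file.path(dir, "cbv.nii.gz"))
    reference <- readLabelVolume(file.path(dir, "reference.nii.gz"),
                                 labelMap = c(reference = 1L))
  }
  PatientCase(caseId = row$case_id, cavity = cavity,
              enhancing = enhancing, cbv = cbv, reference = reference,
              group = row$group, mgmt = row$mgmt, tert = row$tert,
              subtype = row$subtype, ttf = row$ttf,
              progressed = as.logical(row$progressed),
              pfsMonths = row$pfs_months)
}

#' Run the full study pipeline on a prepared input directory
#'
#' Expects `cohort.csv` at the root of `inputDir` and one sub-directory
#' per case (named by `case_id`) holding `cavity.nii.gz`,
#' `enhancing.nii.gz`, and optionally `cbv.nii.gz` + `reference.nii.gz`.
#' Produces, under `outputDir`: `region_counts.csv` (validated per-case
#' region and band counts, joined with covariates), `comparisons.csv`
#' (two-group tests over the six regions and the band percentages),
#' `subgroup_comparisons.csv` (MGMT / TERT / subtype strata, inside and
#' outside the CTV), `survival.csv`, `report.md`, `config.resolved.yaml`,
#' and a structured `pipeline.log`. CSV outputs are deterministic for
#' fixed inputs and configuration.
#'
#' @param inputDir study directory as above.
#' @param outputDir output directory (created if needed).
#' @param config a [pipelineConfig()].
#' @param skipBad skip cases that fail validation (logged with reasons)
#'   instead of aborting (default `FALSE`).
#' @return Invisibly, a list with the tables written
#'   (`regionCounts`, `comparisons`, `subgroupComparisons`, `survival`,
#'   `skipped`).
#' @export
runPipeline <- function(inputDir, outputDir, config = pipelineConfig(),
                        skipBad = FALSE) {
  if (!dir.exists(inputDir)) stop("input directory not found: ", inputDir)
  cohortPath <- file.path(inputDir, "cohort.csv")
  if (!file.exists(cohortPath))
    stop("malformed layout: missing ", cohortPath)
  records <- readCohortTable(cohortPath)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outputDir, "pipeline.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon), add = TRUE)
  logLine <- function(...) {
    writeLines(paste(..., sep = "\t"), logCon)
  }
  logLine("case_id", "stage", "seconds", "outcome")

  rows <- list(); skipped <- character()
  for (i in seq_len(nrow(records))) {
    row <- records[i, ]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      case <- readCaseDir(file.path(inputDir, row$case_id), row)
      out <- summarizeCase(case, config = config)
      if (out$outside_ctv == 0)
        logLine(row$case_id, "classify", "", "note: empty out-of-CTV set")
      if (out$iz_inside_ctv + out$iz_outside_ctv == 0 &&
          !is.null(case@cbv))
        logLine(row$case_id, "classify", "", "note: empty inclusion zone")
      out
    }, error = function(e) e)
    dt <- sprintf("%.2f", proc.time()[["elapsed"]] - t0)
    if (inherits(res, "error")) {
      logLine(row$case_id, "case", dt,
              paste0("failed: ", conditionMessage(res)))
      if (!skipBad)
        stop("case '", row$case_id, "' failed: ", conditionMessage(res),
             " (use skipBad = TRUE to skip)")
      skipped <- c(skipped, row$case_id)
    } else {
      logLine(row$case_id, "case", dt, "ok")
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) stop("no cases were successfully processed")
  counts <- do.call(rbind, rows)
  validateRegionCounts(counts,
                       bandsIncludeInside = config$include_inside_in_bands)
  kept <- records[match(counts$case_id, records$case_id), ]
  regionCounts <- cbind(counts, kept[, c("group", "mgmt", "tert", "subtype",
                                         "ttf", "progressed",
                                         "pfs_months")])
  utils::write.csv(regionCounts,
                   file.path(outputDir, "region_counts.csv"),
                   row.names = FALSE)

  # band percentages per case (share of counted voxels per band)
  bandTotal <- regionCounts$band_le_2cm + regionCounts$band_2_3cm +
    regionCounts$band_gt_3cm
  safeTotal <- ifelse(bandTotal == 0, 1, bandTotal)
  regionCounts$pct_le_2cm <- 100 * regionCounts$band_le_2cm / safeTotal
  regionCounts$pct_2_3cm <- 100 * regionCounts$band_2_3cm / safeTotal
  regionCounts$pct_gt_3cm <- 100 * regionCounts$band_gt_3cm / safeTotal

  compRegions <- c(.regionCols,
                   c("pct_le_2cm", "pct_2_3cm", "pct_gt_3cm"))
  comparisons <- compareAllRegions(regionCounts, regions = compRegions,
                                   alpha = config$alpha)
  utils::write.csv(comparisons, file.path(outputDir, "comparisons.csv"),
                   row.names = FALSE)

  strata <- list(mgmt = c("methylated", "unmethylated"),
                 tert = c("mutant", "nonmutant"),
                 subtype = c("RTK_I", "RTK_II", "MES"))
  sub <- list()
  for (sf in names(strata))
    for (lv in strata[[sf]])
      for (region in c("inside_ctv", "outside_ctv")) {
        r <- tryCatch(
          subgroupCompare(regionCounts, region, sf, lv,
                          alpha = config$alpha),
          error = function(e) e)
        if (inherits(r, "error")) {
          logLine("-", paste0("subgroup:", sf, "=", lv, ":", region), "",
                  paste0("skipped: ", conditionMessage(r)))
        } else {
          sub[[length(sub) + 1L]] <- r
        }
      }
  subgroupComparisons <- if (length(sub)) do.call(rbind, sub) else
    data.frame()
  utils::write.csv(subgroupComparisons,
                   file.path(outputDir, "subgroup_comparisons.csv"),
                   row.names = FALSE)

  surv <- survivalSummary(kept)
  survDf <- surv$groups
  survDf$logrank_p <- surv$logrank_p
  utils::write.csv(survDf, file.path(outputDir, "survival.csv"),
                   row.names = FALSE)

  writeReport(file.path(outputDir, "report.md"), regionCounts, comparisons,
              subgroupComparisons, survDf, kept, config)
  resolved <- config
  resolved$distance_cuts_mm <- as.list(resolved$distance_cuts_mm)
  yaml::write_yaml(unclass(resolved),
                   file.path(outputDir, "config.resolved.yaml"))
  logLine("-", "pipeline", "", sprintf("done: %d cases, %d skipped",
                                       nrow(counts), length(skipped)))
  invisible(list(regionCounts = regionCounts, comparisons = comparisons,
                 subgroupComparisons = subgroupComparisons,
                 survival = survDf, skipped = skipped))
}

mdTable <- function(df, digits = 3) {
  if (!nrow(df)) return("_(empty)_")
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "NA",
                              formatC(x, digits = digits, format = "g"))
    else as.character(x)
  }
  body <- apply(as.data.frame(lapply(df, fmt)), 1, paste, collapse = " | ")
  paste(c(paste(names(df), collapse = " | "),
          paste(rep("---", ncol(df)), collapse = " | "),
          body), collapse = "\n")
}

writeReport <- function(path, regionCounts, comparisons,
                        subgroupComparisons, survDf, records, config) {
  catComps <- list()
  for (v in c("mgmt", "tert", "subtype", "ttf")) {
    r <- tryCatch(compareCategorical(records, v), error = function(e) NULL)
    if (!is.null(r)) catComps[[length(catComps) + 1L]] <- r
  }
  catDf <- if (length(catComps)) do.call(rbind, catComps) else data.frame()
  lines <- c(
    "# Progression-pattern analysis report",
    "",
    sprintf("Cases analysed: %d (%s)", nrow(regionCounts),
            paste(sprintf("%s n=%d", names(table(regionCounts$group)),
                          as.integer(table(regionCounts$group))),
                  collapse = ", ")),
    sprintf("PTV margin: %g mm; IZ threshold ratio: %g; band cuts: %s mm",
            config$ptv_margin_mm, config$iz_threshold_ratio,
            paste(config$distance_cuts_mm, collapse = ", ")),
    "",
    "## Cohort characteristics (categorical comparisons)",
    "",
    mdTable(catDf),
    "",
    "## Region comparisons between groups",
    "",
    mdTable(comparisons),
    "",
    "## Subgroup comparisons",
    "",
    mdTable(subgroupComparisons),
    "",
    "## Progression-free survival",
    "",
    mdTable(survDf))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a synthetic study directory
#'
#' Generates a complete synthetic study with [makeCohort()] and writes it
#' in the layout [runPipeline()] consumes. `spec` may be a [cohortSpec()]
#' object or the path to a YAML file of `cohortSpec` arguments (with
#' `grid: {shape: [...], spacing_mm: [...]}`).
#'
#' @param spec a [cohortSpec()] or YAML path.
#' @param outputDir directory to write the study to.
#' @param config a [pipelineConfig()] (used for the emitted ground truth).
#' @return Invisibly, the [makeCohort()] result.
#' @export
simulateStudy <- function(spec, outputDir, config = pipelineConfig()) {
  if (is.character(spec)) spec <- cohortSpecFromYaml(spec)
  stopifnot(inherits(spec, "CohortSpec"))
  res <- makeCohort(spec, outputDir = outputDir, config = config)
  invisible(res)
}

#' Read a cohort specification from YAML
#'
#' @param path YAML file whose keys are [cohortSpec()] arguments; the grid
#'   is given as `grid: {shape: [...], spacing_mm: [...]}` and named lists
#'   (burdens, effects, frequencies, PFS model) as YAML maps.
#' @return A `CohortSpec`.
#' @export
cohortSpecFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$grid))
    args$grid <- GridSpec(unlist(y$grid$shape),
                          spacingMm = unlist(y$grid$spacing_mm))
  scalar <- intersect(names(y),
                      c("transitionOffsetMm", "maxComponentRadiusMm",
                        "seed"))
  for (k in scalar) args[[k]] <- y[[k]]
  vecs <- intersect(names(y),
                    c("nPerGroup", "cavityRadiusRangeMm",
                      "activeFractionRange", "outsideOffsetRangeMm",
                      "censorRangeMonths"))
  for (k in vecs) args[[k]] <- unlist(y[[k]])
  maps <- intersect(names(y), c("burdenLognormal", "groupEffect",
                                "covariateFreqs", "pfsModel"))
  for (k in maps) args[[k]] <- lapply(y[[k]], unlist)
  do.call(cohortSpec, args)
}
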