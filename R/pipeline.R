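#' Read and validate a pipeline configuration
#'
#' Configurations are plain named lists (or YAML files mapping to them).
#' Recognized keys, all optional unless noted:
#' \describe{
#'   \item{simulate}{list of \code{\link{simParams}} arguments; presence
#'     switches the pipeline to synthetic input.}
#'   \item{paths}{list with \code{families}, \code{pedigree},
#'     \code{interviews} when reading field-format files instead.}
#'   \item{models}{labels among A..F to fit, default \code{c("A","F")}.}
#'   \item{nPerm}{permutations for significance (0 disables), default 0.}
#'   \item{nullLevels}{default all three levels.}
#'   \item{nRealizations}{null ensemble size, default 200.}
#'   \item{lags}{lag grid, default 1:60; \code{pooledLags} default 1:3.}
#'   \item{kinThreshold}{close-kin boundary, default 0.25.}
#'   \item{nAGQ}{mixed-model accuracy, default 1.}
#'   \item{seed}{master seed, default 1.}
#'   \item{outDir}{output directory (required by the run functions).}
#'   \item{figures}{write pdf figures, default TRUE.}
#' }
#'
#' @param config a named list or the path of a YAML file.
#' @return normalized config list.
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("simulate", "paths", "models", "nPerm", "nullLevels",
             "nRealizations", "lags", "pooledLags", "kinThreshold",
             "nAGQ", "seed", "outDir", "figures", "nDays")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  dflt <- list(models = c("A", "F"), nPerm = 0L,
               nullLevels = c("homogeneous", "kin_heterogeneous",
                              "full_heterogeneous"),
               nRealizations = 200L, lags = 1:60, pooledLags = 1:3,
               kinThreshold = 0.25, nAGQ = 1L, seed = 1L, figures = TRUE)
  for (k in names(dflt)) if (is.null(config[[k]])) config[[k]] <- dflt[[k]]
  if (is.null(config$simulate) && is.null(config$paths))
    config$simulate <- list()
  config
}

.log <- function(...) message("[dyadRecip] ", ...)

#' Simulate a study and write its files
#'
#' Generates a synthetic village, events and interviews under the config's
#' \code{simulate} parameters and writes them in the field file formats
#' (families CSV, pedigree TSV, interviews CSV, reconciled events CSV),
#' the ground truth as JSON, and a manifest recording the seeds.
#'
#' @param config see \code{\link{pipelineConfig}}; \code{outDir} required.
#' @return invisibly, the list of written paths.
#' @export
runSimulate <- function(config) {
  config <- pipelineConfig(config)
  stopifnot(!is.null(config$outDir))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  args <- config$simulate
  if (is.null(args$seed)) args$seed <- config$seed
  params <- do.call(simParams, args)
  .log("simulating study (seed ", params@seed, ")")
  study <- simulateStudy(params)
  p <- function(f) file.path(config$outDir, f)
  writeVillage(study$village, p("families.csv"), p("pedigree.tsv"))
  writeInterviews(study$interviews, p("interviews.csv"))
  writeEvents(study$events, p("events.csv"))
  exportPanel(study$panel, p("panel.csv.gz"))
  truth <- study$truth
  jsonlite::write_json(
    list(weights = truth$weights, rho = truth$rho, window = truth$window,
         classes = truth$classes, seed = truth$seed),
    p("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(created = as.character(Sys.time()),
                   seed = params@seed,
                   params = lapply(slotNames(params), function(s)
                     slot(params, s)) |> setNames(slotNames(params)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  .log("wrote ", config$outDir)
  invisible(list(families = p("families.csv"), pedigree = p("pedigree.tsv"),
                 interviews = p("interviews.csv"), events = p("events.csv"),
                 panel = p("panel.csv.gz"),
                 groundTruth = p("ground_truth.json")))
}

.loadInputs <- function(config) {
  if (!is.null(config$paths)) {
    v <- readVillage(config$paths$families, config$paths$pedigree,
                     nDays = if (is.null(config$nDays)) 112L else
                       config$nDays)
    iv <- readInterviews(config$paths$interviews, v)
    ev <- reconcileReports(iv, seed = config$seed)
    list(village = v, interviews = iv, events = ev,
         panel = buildPanel(v, iv, ev))
  } else {
    args <- config$simulate
    if (is.null(args$seed)) args$seed <- config$seed
    simulateStudy(do.call(simParams, args))
  }
}

#' Run the full analysis pipeline
#'
#' Builds (or simulates) the panel, computes summary statistics, fits the
#' requested regression ladder, estimates reciprocity curves for every
#' null level and kin class, and writes a structured report (JSON +
#' tables + optional figures) into \code{outDir}.  Every stochastic stage
#' derives its seed from the config seed; a stage failure halts with a
#' stage-named error and earlier outputs are preserved.
#'
#' @param config see \code{\link{pipelineConfig}}.
#' @return invisibly, a list with all computed objects.
#' @export
runFull <- function(config) {
  config <- pipelineConfig(config)
  stopifnot(!is.null(config$outDir))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$outDir, f)
  stage <- function(name, expr) {
    .log("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  inputs <- stage("build", .loadInputs(config))
  village <- inputs$village; panel <- inputs$panel
  relmat <- stage("kinship", familyRelatedness(village))
  distmat <- stage("distance", familyDistances(village))
  sums <- stage("summarize", panelSummaries(panel))
  write.csv(sums$perFamily, p("family_rates.csv"), row.names = FALSE)
  write.csv(sums$perDyad, p("dyad_rates.csv"), row.names = FALSE)
  writeFamilyMatrix(relmat, p("relatedness.csv"))
  writeFamilyMatrix(distmat, p("distance.csv"))
  fits <- list(); vexp <- list()
  if (length(config$models)) {
    tab <- stage("design", assembleDesign(panel, village, relmat, distmat))
    specs <- standardSpecs(config$models)
    fits <- stage("regress", lapply(specs, function(s) {
      if (config$nPerm > 0)
        permutationSignificance(tab, s, nPerm = config$nPerm,
                                seed = config$seed, nAGQ = config$nAGQ)
      else fitHierLogistic(tab, s, nAGQ = config$nAGQ)
    }))
    writeLines(renderFitTable(fits), p("regression.txt"))
    if (all(c("B", "F") %in% names(fits)))
      vexp$dyad_full_vs_B <- varianceExplained(fits$B, fits$F, "dyad")
  }
  curves <- stage("reciprocity", {
    out <- list()
    for (lv in config$nullLevels) {
      null <- fitNull(panel, relmat, level = lv)
      ens <- sampleNull(null, observable(panel),
                        nRealizations = config$nRealizations,
                        seed = config$seed + 17L)
      for (cl in c("all", "close_kin", "not_close_kin")) {
        cv <- tryCatch(
          classCurve(panel, ens, relmat, classLabel = cl,
                     lags = config$lags, pooledLags = config$pooledLags,
                     kinThreshold = config$kinThreshold),
          error = function(e) NULL)   # empty class on small inputs
        if (!is.null(cv)) out[[paste(lv, cl, sep = ".")]] <- cv
      }
    }
    out
  })
  if (length(curves)) writeCurves(curves, p("reciprocity_curves.csv"))
  if (isTRUE(config$figures) && length(curves)) {
    grDevices::pdf(p("reciprocity_curves.pdf"), width = 7, height = 9)
    on.exit(grDevices::dev.off(), add = TRUE)
    op <- graphics::par(mfrow = c(min(3, length(curves)), 1),
                        mar = c(4, 4, 2, 1))
    for (cv in curves[grepl("\\.all$", names(curves))]) plotCurve(cv)
    graphics::par(op)
  }
  report <- list(
    seed = config$seed,
    summary = list(
      events = sums$overall$events, riskDays = sums$overall$riskDays,
      hostingRatePct = 100 * sums$overall$rate,
      dyadsWithEvent = sums$dyadsWithEvent,
      fracDyadsWithEventPct = 100 * sums$fracDyadsWithEvent,
      varHostRate = sums$varHostRate, varAttendRate = sums$varAttendRate),
    kinship = local({
      r <- relmat[upper.tri(relmat)]
      list(meanRelatedness = mean(r),
           pctClose = 100 * mean(r >= config$kinThreshold),
           pctDistant = 100 * mean(r > 0 & r < config$kinThreshold),
           pctUnrelated = 100 * mean(r == 0))
    }),
    models = lapply(fits, function(f) list(
      beta = as.list(f@beta), expBeta = as.list(f@expBeta),
      varComponents = as.list(f@varComponents), aic = f@aic,
      converged = f@converged,
      permP = if (length(f@permP)) as.list(f@permP) else NULL)),
    varianceExplained = vexp,
    reciprocity = lapply(curves, function(cv) as.list(pooledStat(cv))))
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  .log("report written to ", p("report.json"))
  invisible(list(config = config, inputs = inputs, relmat = relmat,
                 distmat = distmat, summaries = sums, fits = fits,
                 varianceExplained = vexp, curves = curves,
                 report = report))
}
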