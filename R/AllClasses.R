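#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats rbinom rpois runif rnorm quantile sd var setNames
#'   as.formula binomial glm coef AIC model.matrix na.omit complete.cases
#' @importFrom utils read.csv write.csv read.delim write.table
#' @importFrom graphics plot polygon lines points abline par
#' @importFrom grDevices adjustcolor pdf dev.off
NULL

#' Village: families, members and pedigree over a fixed study window
#'
#' A \code{Village} bundles the static social context of a study: the nuclear
#' families (with household coordinates, head ages and sizes), the pedigree
#' linking all individuals, and the number of calendar days in the study
#' window.  Days are 0-based indices from study start; weeks are consecutive
#' 7-day blocks (\code{floor(day / 7)}).
#'
#' @slot families data.frame with columns \code{family_id}, \code{size},
#'   \code{head_age1}, \code{head_age2} (NA if a single head), \code{lat},
#'   \code{lon}.
#' @slot pedigree data.frame with columns \code{individual_id},
#'   \code{father_id}, \code{mother_id} (NA for founders), \code{sex}
#'   (1 male / 2 female), \code{family_id}.  Every individual belongs to
#'   exactly one family; parent links must be acyclic.
#' @slot nDays integer, number of study days.
#'
#' @export
setClass("Village",
  slots = c(families = "data.frame", pedigree = "data.frame",
            nDays = "integer"))

setValidity("Village", function(object) {
  fam <- object@families
  ped <- object@pedigree
  msg <- character()
  needF <- c("family_id", "size", "head_age1", "head_age2", "lat", "lon")
  if (!all(needF %in% names(fam)))
    msg <- c(msg, paste("families lacks columns:",
                        paste(setdiff(needF, names(fam)), collapse = ", ")))
  needP <- c("individual_id", "father_id", "mother_id", "sex", "family_id")
  if (!all(needP %in% names(ped)))
    msg <- c(msg, paste("pedigree lacks columns:",
                        paste(setdiff(needP, names(ped)), collapse = ", ")))
  if (length(msg)) return(msg)
  if (nrow(fam) < 1L) msg <- c(msg, "no families")
  if (anyDuplicated(fam$family_id))
    msg <- c(msg, "duplicate family ids")
  if (anyDuplicated(ped$individual_id))
    msg <- c(msg, "duplicate individual ids")
  if (!all(ped$family_id %in% fam$family_id))
    msg <- c(msg, "pedigree references unknown families")
  cnt <- table(factor(ped$family_id, levels = fam$family_id))
  if (any(cnt == 0L))
    msg <- c(msg, paste("empty families:",
                        paste(names(cnt)[cnt == 0L], collapse = ", ")))
  if (any(fam$lat < -90 | fam$lat > 90, na.rm = TRUE))
    msg <- c(msg, "latitude outside [-90, 90]")
  if (any(fam$lon < -180 | fam$lon > 180, na.rm = TRUE))
    msg <- c(msg, "longitude outside [-180, 180]")
  if (length(object@nDays) != 1L || is.na(object@nDays) || object@nDays < 1L)
    msg <- c(msg, "nDays must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a Village
#'
#' @param families data.frame, see \linkS4class{Village}.
#' @param pedigree data.frame, see \linkS4class{Village}.
#' @param nDays number of study days.
#' @return A validated \linkS4class{Village}.
#' @examples
#' fam <- data.frame(family_id = c("F1", "F2"), size = c(1L, 1L),
#'                   head_age1 = c(40, 35), head_age2 = NA_real_,
#'                   lat = c(-14.90, -14.91), lon = c(-66.30, -66.31))
#' ped <- data.frame(individual_id = c("A", "B"), father_id = NA,
#'                   mother_id = NA, sex = c(1L, 2L),
#'                   family_id = c("F1", "F2"))
#' Village(fam, ped, nDays = 14)
#' @export
Village <- function(families, pedigree, nDays) {
  families$family_id <- as.character(families$family_id)
  pedigree$individual_id <- as.character(pedigree$individual_id)
  pedigree$father_id <- as.character(pedigree$father_id)
  pedigree$mother_id <- as.character(pedigree$mother_id)
  pedigree$family_id <- as.character(pedigree$family_id)
  new("Village", families = families, pedigree = pedigree,
      nDays = as.integer(nDays))
}

#' EventPanel: hosting and observability indicators over dyads and days
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment}.  Rows are all
#' ordered family pairs (host, guest) with host != guest; columns are study
#' days.  Three binary assays:
#' \describe{
#'   \item{\code{h}}{1 if the host family was recorded hosting the guest
#'     family on that day.}
#'   \item{\code{o}}{1 if the event was potentially observable, i.e. an
#'     interview of either family covered the day ("risk day").}
#'   \item{\code{guestOnly}}{1 if the day was covered only by interviews of
#'     the potential guest, never the host (flags differential
#'     under-reporting).}
#' }
#' The invariant \code{h <= o} holds elementwise: a recorded event implies
#' coverage.  \code{rowData} carries \code{host} and \code{guest} ids;
#' \code{colData} carries \code{day} (0-based) and \code{week}.
#'
#' @export
setClass("EventPanel", contains = "SummarizedExperiment")

setValidity("EventPanel", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("h", "o", "guestOnly") %in% an))
    return("assays h, o and guestOnly are required")
  h <- SummarizedExperiment::assay(object, "h")
  o <- SummarizedExperiment::assay(object, "o")
  g <- SummarizedExperiment::assay(object, "guestOnly")
  if (!all(h %in% c(0L, 1L)) || !all(o %in% c(0L, 1L)) ||
      !all(g %in% c(0L, 1L)))
    msg <- c(msg, "assays must be binary")
  else if (any(h > o))
    msg <- c(msg, "h > o somewhere: an event on an uncovered dyad-day")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("host", "guest") %in% names(rd)))
    msg <- c(msg, "rowData needs host and guest")
  else if (any(rd$host == rd$guest))
    msg <- c(msg, "self-pairs are not allowed")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("day", "week") %in% names(cd)))
    msg <- c(msg, "colData needs day and week")
  if (length(msg)) msg else TRUE
})

#' Construct an EventPanel from binary matrices
#'
#' @param h,o,guestOnly binary matrices (ordered dyads x days).
#' @param host,guest character vectors of family ids per row.
#' @param days integer vector of 0-based day indices per column.
#' @return An \linkS4class{EventPanel}.
#' @export
EventPanel <- function(h, o, guestOnly = NULL, host, guest, days) {
  storage.mode(h) <- "integer"
  storage.mode(o) <- "integer"
  if (is.null(guestOnly)) guestOnly <- matrix(0L, nrow(h), ncol(h))
  storage.mode(guestOnly) <- "integer"
  rn <- paste(host, guest, sep = "->")
  dimnames(h) <- dimnames(o) <- dimnames(guestOnly) <-
    list(rn, paste0("d", days))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(h = h, o = o, guestOnly = guestOnly),
    rowData = S4Vectors::DataFrame(host = host, guest = guest),
    colData = S4Vectors::DataFrame(day = as.integer(days),
                                   week = as.integer(days %/% 7L)))
  new("EventPanel", se)
}

#' Fitted multi-level logistic model of daily hosting
#'
#' Returned by \code{\link{fitHierLogistic}}.  Holds fixed-effect estimates
#' on the log-odds scale with their odds ratios, variances of the crossed
#' random intercepts (host, guest, dyad), the model AIC, and (once
#' \code{\link{permutationSignificance}} has been run) permutation p-values.
#'
#' @slot beta named numeric, fixed-effect log-odds estimates.
#' @slot expBeta named numeric, \code{exp(beta)} odds ratios.
#' @slot varComponents named numeric, random-intercept variances.
#' @slot aic numeric(1).
#' @slot permP named numeric, permutation p-values (empty until computed).
#' @slot converged logical(1); FALSE flags a dubious fit.
#' @slot messages character, optimizer diagnostics for non-converged fits.
#' @slot spec the \linkS4class{ModelSpec} that was fitted.
#' @slot nobs integer(1), rows used.
#' @slot fit the underlying fitted model object (glmerMod or glm).
#' @export
setClass("HierFit",
  slots = c(beta = "numeric", expBeta = "numeric",
            varComponents = "numeric", aic = "numeric", permP = "numeric",
            converged = "logical", messages = "character", spec = "ANY",
            nobs = "integer", fit = "ANY"))

setValidity("HierFit", function(object) {
  msg <- character()
  if (any(object@varComponents < 0)) msg <- c(msg, "negative variance")
  if (length(object@beta) &&
      any(abs(object@expBeta - exp(object@beta)) > 1e-8))
    msg <- c(msg, "expBeta != exp(beta)")
  if (length(msg)) msg else TRUE
})

#' Model specification for the hierarchical hosting regression
#'
#' @slot fixed character vector of fixed-term names among
#'   \code{"weeks"}, \code{"guestOnly"}, \code{"hostAge"}, \code{"hostAge2"},
#'   \code{"guestAge"}, \code{"hostSize"}, \code{"guestSize"},
#'   \code{"logDist"}, \code{"relatedness"}, \code{"recipRate"},
#'   \code{"recipXkin"}.  The intercept is always included.
#' @slot random character subset of \code{c("host", "guest", "dyad")}.
#' @slot label optional human-readable label.
#' @export
setClass("ModelSpec",
  slots = c(fixed = "character", random = "character", label = "character"))

.specTerms <- c("weeks", "guestOnly", "hostAge", "hostAge2", "guestAge",
                "hostSize", "guestSize", "logDist", "relatedness",
                "recipRate", "recipXkin")

setValidity("ModelSpec", function(object) {
  msg <- character()
  bad <- setdiff(object@fixed, .specTerms)
  if (length(bad))
    msg <- c(msg, paste("unknown fixed terms:", paste(bad, collapse = ", ")))
  if (!all(object@random %in% c("host", "guest", "dyad")))
    msg <- c(msg, "random terms must be among host, guest, dyad")
  if ("dyad" %in% object@random &&
      !all(c("host", "guest") %in% c("host", "guest")))
    msg <- c(msg, "dyad term requires host and guest identifiers")
  if (length(msg)) msg else TRUE
})

#' @param fixed,random,label see \linkS4class{ModelSpec}.
#' @rdname ModelSpec-class
#' @export
modelSpec <- function(fixed = character(), random = c("host", "guest", "dyad"),
                      label = "") {
  new("ModelSpec", fixed = fixed, random = random, label = label)
}

#' Stationary null model for the hosting process
#'
#' One level of the null hierarchy fitted by \code{\link{fitNull}}.  Encodes
#' a per-(dyad, day) Bernoulli hosting probability built from the level's
#' preserved margins -- one rate per host (\code{homogeneous}), one rate per
#' host and kin stratum (\code{kin_heterogeneous}), or one rate per ordered
#' pair (\code{full_heterogeneous}) -- modulated by fitted weekly seasonal
#' multipliers and a guest-only reporting factor.  Sampling a realization
#' draws every observable dyad-day independently (the mechanisms are
#' time-independent: no conditional-action term).
#'
#' @slot level character(1).
#' @slot prob matrix (dyads x days) of Bernoulli probabilities, aligned with
#'   the panel the model was fitted to.
#' @slot rate named numeric, the level's base rates (per host, per
#'   host:stratum, or per ordered pair).
#' @slot weekMult numeric, one multiplier per week (mean 1 over observed
#'   exposure).
#' @slot guestOnlyFactor numeric(1), fitted ratio of reporting rates on
#'   guest-only vs host-covered risk days.
#' @slot host,guest character, row alignment (same as the source panel).
#' @slot strata numeric, rounded mean relatedness per row (kin level only).
#' @export
setClass("NullModel",
  slots = c(level = "character", prob = "matrix", rate = "numeric",
            weekMult = "numeric", guestOnlyFactor = "numeric",
            host = "character", guest = "character", strata = "numeric"))

setValidity("NullModel", function(object) {
  msg <- character()
  if (!object@level %in% c("homogeneous", "kin_heterogeneous",
                           "full_heterogeneous"))
    msg <- c(msg, "unknown null level")
  if (any(object@prob < 0 | object@prob > 1))
    msg <- c(msg, "probabilities outside [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Ensemble of null-model realizations
#'
#' Compact storage of simulated hosting panels: each realization is a
#' two-column matrix of (row index, column index) event cells on the same
#' dyad x day grid as the source panel.  All realizations share the true
#' observation mask.
#'
#' @slot events list of integer matrices, one per realization.
#' @slot dim integer(2), the panel dimensions.
#' @slot level character(1), the generating null level.
#' @slot seed integer(1).
#' @export
setClass("NullEnsemble",
  slots = c(events = "list", dim = "integer", level = "character",
            seed = "integer"))

#' Class-averaged conditional-action reciprocity curve
#'
#' Observed class-averaged, null-renormalized reciprocity ratio per lag,
#' with Monte-Carlo one- and two-sigma bands and upper-tail p-values from a
#' null ensemble, plus the pooled short-lag (default lags 1-3) statistic.
#'
#' @slot table data.frame with columns \code{lag}, \code{observed},
#'   \code{nullMean}, \code{lo1}, \code{hi1}, \code{lo2}, \code{hi2},
#'   \code{p}, \code{nPairs}.
#' @slot pooled data.frame (one row) with the pooled statistic and p-value.
#' @slot classLabel one of \code{"all"}, \code{"close_kin"},
#'   \code{"not_close_kin"}.
#' @slot nullLevel the null hierarchy level used for renormalization.
#' @slot nRealizations integer(1).
#' @slot nDropped integer(1), pairs dropped for undefined null means.
#' @export
setClass("ReciprocityCurve",
  slots = c(table = "data.frame", pooled = "data.frame",
            classLabel = "character", nullLevel = "character",
            nRealizations = "integer", nDropped = "integer"))

setValidity("ReciprocityCurve", function(object) {
  tb <- object@table
  msg <- character()
  ok <- stats::complete.cases(tb[, c("lo1", "hi1", "lo2", "hi2")])
  if (any(tb$lo1[ok] < tb$lo2[ok]) || any(tb$hi1[ok] > tb$hi2[ok]))
    msg <- c(msg, "one-sigma band must nest inside two-sigma band")
  p <- c(tb$p, object@pooled$p)
  p <- p[!is.na(p)]
  if (any(p <= 0 | p > 1)) msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic village-and-events generator
#'
#' Defaults describe the emulated study community: 35 nuclear families
#' (~200 people) observed for 112 days (16 weeks), interviewed about twice a
#' week about the two preceding days, with guest under-reporting, kin- and
#' distance-structured guest preferences, heterogeneous host propensities, a
#' seasonal activity profile, and a short-timescale conditional reciprocity
#' kernel acting among non-close-kin dyads.  See the package vignette for
#' the rationale behind each default.
#'
#' @slot nFamilies,nDays integer counts.
#' @slot baseHostRate daily probability that a family at the modal head age
#'   throws a party, before seasonal modulation.
#' @slot ageEffect numeric(2): linear and quadratic log-scale coefficients
#'   on (head age - 50) for the hosting propensity.
#' @slot sigmaHost SD of the lognormal family-specific hosting propensity
#'   (hosting is far more idiosyncratic than attendance in communities of
#'   this kind).
#' @slot partySizeMean mean number of guest families per party (sizes are
#'   1 + Poisson(partySizeMean - 1), truncated below the village size).
#' @slot betaDist,betaKin guest-preference weights on log-km distance and
#'   mean relatedness.
#' @slot sigmaDyad SD of the lognormal dyad-specific preference effect.
#' @slot recipStrength multiplicative boost (rho >= 0) on the guest weight
#'   of j for host i when j hosted i within the last \code{recipWindow}
#'   days; \code{recipStrength = 1} switches the mechanism off.
#' @slot recipWindow integer days.
#' @slot recipClasses which kin classes the kernel applies to:
#'   \code{"not_close"}, \code{"close"} or \code{"all"}.
#' @slot interviewRate expected interviews per family per week.
#' @slot guestReportProb probability a guest family reports an attended
#'   event at a covering interview (hosts always report).
#' @slot seasonal numeric weekly multipliers (recycled/truncated to the
#'   number of weeks) or length 0 for the built-in profile.
#' @slot seed integer master seed; substreams for village, events and
#'   interviews are derived from it.
#' @export
setClass("SimParams",
  slots = c(nFamilies = "integer", nDays = "integer",
            baseHostRate = "numeric", ageEffect = "numeric",
            sigmaHost = "numeric",
            partySizeMean = "numeric", betaDist = "numeric",
            betaKin = "numeric", sigmaDyad = "numeric",
            recipStrength = "numeric", recipWindow = "integer",
            recipClasses = "character", interviewRate = "numeric",
            guestReportProb = "numeric", seasonal = "numeric",
            seed = "integer"))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@nFamilies < 2L) msg <- c(msg, "need at least 2 families")
  if (object@baseHostRate < 0 || object@baseHostRate > 1)
    msg <- c(msg, "baseHostRate must be a probability")
  if (object@guestReportProb < 0 || object@guestReportProb > 1)
    msg <- c(msg, "guestReportProb must be a probability")
  if (object@recipStrength < 0) msg <- c(msg, "recipStrength must be >= 0")
  if (object@recipWindow < 1L) msg <- c(msg, "recipWindow must be >= 1")
  if (!object@recipClasses %in% c("not_close", "close", "all"))
    msg <- c(msg, "recipClasses must be not_close, close or all")
  if (length(msg)) msg else TRUE
})

#' @param nFamilies,nDays,baseHostRate,ageEffect,partySizeMean,betaDist
#'   see \linkS4class{SimParams}.
#' @param betaKin,sigmaDyad,recipStrength,recipWindow,recipClasses see
#'   \linkS4class{SimParams}.
#' @param interviewRate,guestReportProb,seasonal,seed see
#'   \linkS4class{SimParams}.
#' @rdname SimParams-class
#' @export
simParams <- function(nFamilies = 35L, nDays = 112L,
                      baseHostRate = 0.16, ageEffect = c(0, -0.0012),
                      sigmaHost = 0.9,
                      partySizeMean = 2.5, betaDist = -1.05, betaKin = 3,
                      sigmaDyad = 1.5, recipStrength = 3, recipWindow = 3L,
                      recipClasses = "not_close", interviewRate = 2,
                      guestReportProb = 0.38, seasonal = numeric(),
                      seed = 1L) {
  new("SimParams", nFamilies = as.integer(nFamilies),
      nDays = as.integer(nDays), baseHostRate = baseHostRate,
      ageEffect = ageEffect, sigmaHost = sigmaHost, partySizeMean = partySizeMean,
      betaDist = betaDist, betaKin = betaKin, sigmaDyad = sigmaDyad,
      recipStrength = recipStrength, recipWindow = as.integer(recipWindow),
      recipClasses = recipClasses, interviewRate = interviewRate,
      guestReportProb = guestReportProb, seasonal = seasonal,
      seed = as.integer(seed))
}
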