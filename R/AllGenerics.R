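#' @rdname Village-class
#' @param x,object a \linkS4class{Village}.
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))

#' @rdname Village-class
#' @export
setGeneric("nFamilies", function(x) standardGeneric("nFamilies"))

#' @rdname Village-class
#' @export
setGeneric("nDays", function(x) standardGeneric("nDays"))

#' @rdname Village-class
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' @rdname Village-class
#' @export
setGeneric("families", function(x) standardGeneric("families"))

#' @rdname EventPanel-class
#' @param x,object an \linkS4class{EventPanel}.
#' @export
setGeneric("hostings", function(x) standardGeneric("hostings"))

#' @rdname EventPanel-class
#' @export
setGeneric("observable", function(x) standardGeneric("observable"))

#' @rdname EventPanel-class
#' @export
setGeneric("guestOnly", function(x) standardGeneric("guestOnly"))

#' @rdname EventPanel-class
#' @export
setGeneric("hostIds", function(x) standardGeneric("hostIds"))

#' @rdname EventPanel-class
#' @export
setGeneric("guestIds", function(x) standardGeneric("guestIds"))

#' Variance components, coefficients and odds ratios of a fit
#'
#' Accessors for \linkS4class{HierFit}.
#' @param x a \linkS4class{HierFit}.
#' @return named numeric vectors.
#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))

#' @rdname varComponents
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))

#' @rdname varComponents
#' @export
setGeneric("oddsRatios", function(x) standardGeneric("oddsRatios"))

#' @rdname varComponents
#' @export
setGeneric("permP", function(x) standardGeneric("permP"))

setMethod("familyIds", "Village", function(x) x@families$family_id)
setMethod("nFamilies", "Village", function(x) nrow(x@families))
setMethod("nDays", "Village", function(x) x@nDays)
setMethod("pedigree", "Village", function(x) x@pedigree)
setMethod("families", "Village", function(x) x@families)

#' Members of one family
#' @param x a \linkS4class{Village}.
#' @param family a family id.
#' @return character vector of individual ids.
#' @export
memberIds <- function(x, family) {
  x@pedigree$individual_id[x@pedigree$family_id == family]
}

#' Week index of each study day
#' @param x a \linkS4class{Village}.
#' @return integer vector of length \code{nDays(x)} with 0-based weeks.
#' @export
weekIndex <- function(x) as.integer((seq_len(nDays(x)) - 1L) %/% 7L)

#' @export
setMethod("show", "Village", function(object) {
  cat("Village:", nFamilies(object), "families,",
      nrow(object@pedigree), "individuals,",
      object@nDays, "study days\n")
})

setMethod("hostings", "EventPanel",
  function(x) SummarizedExperiment::assay(x, "h"))
setMethod("observable", "EventPanel",
  function(x) SummarizedExperiment::assay(x, "o"))
setMethod("guestOnly", "EventPanel",
  function(x) SummarizedExperiment::assay(x, "guestOnly"))
setMethod("hostIds", "EventPanel",
  function(x) SummarizedExperiment::rowData(x)$host)
setMethod("guestIds", "EventPanel",
  function(x) SummarizedExperiment::rowData(x)$guest)

#' @export
setMethod("show", "EventPanel", function(object) {
  h <- hostings(object); o <- observable(object)
  cat("EventPanel:", nrow(object), "ordered dyads x", ncol(object),
      "days\n  ", sum(h), "hosting events on", sum(o),
      sprintf("risk days (rate %.3f%%)\n", 100 * sum(h) / max(1, sum(o))))
})

#' Row index of an ordered dyad in a panel
#' @param panel an \linkS4class{EventPanel}.
#' @param host,guest family ids.
#' @return integer row index.
#' @export
pairIndex <- function(panel, host, guest) {
  i <- which(hostIds(panel) == host & guestIds(panel) == guest)
  if (length(i) != 1L)
    stop("no unique row for dyad ", host, " -> ", guest)
  i
}

setMethod("varComponents", "HierFit", function(x) x@varComponents)
setMethod("fixedEffects", "HierFit", function(x) x@beta)
setMethod("oddsRatios", "HierFit", function(x) x@expBeta)
setMethod("permP", "HierFit", function(x) x@permP)

#' @export
setMethod("show", "HierFit", function(object) {
  cat("HierFit", if (nchar(object@spec@label))
    paste0("[", object@spec@label, "]") else "",
    "on", object@nobs, "risk days; AIC =", round(object@aic, 1), "\n")
  if (!object@converged)
    cat("  ** convergence flagged:", paste(object@messages, collapse = "; "),
        "\n")
  if (length(object@varComponents)) {
    cat("  Random-effect variances:\n")
    print(round(object@varComponents, 3))
  }
  cat("  Fixed effects (log-odds / odds ratio):\n")
  tab <- data.frame(beta = round(object@beta, 3),
                    expBeta = round(object@expBeta, 3))
  if (length(object@permP))
    tab$p <- round(object@permP[rownames(tab)], 4)
  print(tab)
})

#' @export
setMethod("show", "NullModel", function(object) {
  cat("NullModel (", object@level, "): ", nrow(object@prob), " dyads x ",
      ncol(object@prob), " days; guest-only reporting factor ",
      round(object@guestOnlyFactor, 3), "\n", sep = "")
})

#' @export
setMethod("show", "NullEnsemble", function(object) {
  cat("NullEnsemble:", length(object@events), "realizations of a",
      object@dim[1], "x", object@dim[2], object@level, "null\n")
})

#' @export
setMethod("show", "ReciprocityCurve", function(object) {
  cat("ReciprocityCurve [", object@classLabel, " vs ", object@nullLevel,
      " null, ", object@nRealizations, " realizations]\n", sep = "")
  if (nrow(object@pooled))
    cat(sprintf("  pooled (lags %s): R = %.3g (null mean %.3g), p = %.4g, %d pairs\n",
                object@pooled$lags, object@pooled$observed,
                object@pooled$nullMean, object@pooled$p,
                object@pooled$nPairs))
  cat("  per-lag table:", nrow(object@table), "lags\n")
})

#' Tidy per-lag table of a reciprocity curve
#' @param x a \linkS4class{ReciprocityCurve}.
#' @return data.frame with class and null-level columns prepended.
#' @export
curveTable <- function(x) {
  cbind(class = x@classLabel, null_level = x@nullLevel, x@table,
        stringsAsFactors = FALSE)
}

#' @rdname ReciprocityCurve-class
#' @param x a \linkS4class{ReciprocityCurve}.
#' @export
pooledStat <- function(x) x@pooled
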