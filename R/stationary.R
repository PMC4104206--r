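#' Assemble the risk-day observation table
#'
#' One row per (host, guest, day) cell with o = 1 -- a day on which the
#' pair was at risk of an observed hosting -- with the binary outcome h and
#' all model covariates: week index, guest-only coverage flag, host/guest
#' mean head age (and its square) and family size, log household distance
#' (km, floored at 10 m before the log), mean relatedness, the reciprocal
#' hosting rate (mean daily rate at which the guest hosted the host over
#' the whole sample: events / risk days, 0 when the reverse dyad was never
#' observable), and the kin class.
#'
#' @param panel an \linkS4class{EventPanel}.
#' @param village the matching \linkS4class{Village}.
#' @param relmat,distmat family relatedness and distance matrices.
#' @return data.frame with one row per risk day.
#' @export
assembleDesign <- function(panel, village, relmat, distmat) {
  o <- observable(panel)
  h <- hostings(panel)
  g <- guestOnly(panel)
  host <- hostIds(panel); guest <- guestIds(panel)
  fam <- families(village)
  mi <- match(host, fam$family_id); mj <- match(guest, fam$family_id)
  if (anyNA(mi) || anyNA(mj)) stop("panel references unknown families")
  age <- rowMeans(cbind(fam$head_age1, fam$head_age2), na.rm = TRUE)
  if (anyNA(age))
    stop("missing head ages for family ",
         paste(fam$family_id[is.na(age)], collapse = ", "))
  if (anyNA(fam$lat) || anyNA(fam$lon))
    stop("missing coordinates for family ",
         paste(fam$family_id[is.na(fam$lat) | is.na(fam$lon)],
               collapse = ", "))
  ri <- match(host, rownames(relmat)); rj <- match(guest, colnames(relmat))
  rel <- relmat[cbind(ri, rj)]
  dist <- distmat[cbind(match(host, rownames(distmat)),
                        match(guest, colnames(distmat)))]
  # reciprocal rate: mean daily rate the guest hosted the host
  rev <- match(paste(guest, host), paste(host, guest))
  revRate <- ifelse(rowSums(o)[rev] > 0,
                    rowSums(h)[rev] / rowSums(o)[rev], 0)
  cells <- which(o == 1L)
  rc <- arrayInd(cells, dim(o))
  p <- rc[, 1]; d <- rc[, 2]
  week <- SummarizedExperiment::colData(panel)$week
  df <- data.frame(
    h = as.integer(h[cells]),
    host = host[p], guest = guest[p],
    dyad = paste(host, guest, sep = "->")[p],
    day = SummarizedExperiment::colData(panel)$day[d],
    week = factor(week[d]),
    guestOnly = as.integer(g[cells]),
    hostAge = age[mi][p], hostAge2 = age[mi][p]^2,
    guestAge = age[mj][p],
    hostSize = fam$size[mi][p], guestSize = fam$size[mj][p],
    logDist = log(pmax(dist, 0.01))[p],
    relatedness = rel[p],
    recipRate = revRate[p],
    kinClass = kinClass(rel)[p],
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

.specFormula <- function(spec) {
  map <- c(weeks = "week", guestOnly = "guestOnly", hostAge = "hostAge",
           hostAge2 = "hostAge2", guestAge = "guestAge",
           hostSize = "hostSize", guestSize = "guestSize",
           logDist = "logDist", relatedness = "relatedness",
           recipRate = "recipRate", recipXkin = "relatedness:recipRate")
  fx <- unname(map[spec@fixed])
  re <- c(host = "(1 | host)", guest = "(1 | guest)",
          dyad = "(1 | dyad)")[spec@random]
  rhs <- paste(c("1", fx, unname(re)), collapse = " + ")
  as.formula(paste("h ~", rhs))
}

.nParams <- function(spec) length(spec@fixed) + length(spec@random)

#' Fit the multi-level logistic hosting model
#'
#' Logistic regression of the daily hosting outcome on the spec's fixed
#' terms with crossed random intercepts for host, guest and dyad identity,
#' fitted with \code{lme4::glmer} (plain \code{glm} when the spec has no
#' random terms).  All specs fitted on identical rows with the same
#' \code{nAGQ} yield comparable AICs.  Non-convergence is flagged on the
#' returned object (with the optimizer's diagnostics), never silently
#' ignored; a degenerate outcome (all 0 or all 1) is flagged the same way.
#'
#' @param table risk-day table from \code{\link{assembleDesign}}.
#' @param spec a \linkS4class{ModelSpec}.
#' @param nAGQ integrated-likelihood accuracy passed to \code{glmer}
#'   (0 = fast penalized-likelihood step, 1 = Laplace, the default).
#' @return a \linkS4class{HierFit}.
#' @export
fitHierLogistic <- function(table, spec, nAGQ = 1L) {
  stopifnot(is(spec, "ModelSpec"))
  stopifnot(all(table$h %in% 0:1))
  degenerate <- length(unique(table$h)) < 2L
  fml <- .specFormula(spec)
  msgs <- character(0)
  if (length(spec@random)) {
    fit <- withCallingHandlers(
      lme4::glmer(fml, data = table, family = binomial(),
                  nAGQ = if (length(spec@random) > 1L) min(nAGQ, 1L) else nAGQ,
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    beta <- lme4::fixef(fit)
    vc <- lme4::VarCorr(fit)
    varComp <- vapply(vc, function(v) as.numeric(v[1, 1]), 0)
    conv <- length(fit@optinfo$conv$lme4$messages) == 0L &&
      fit@optinfo$conv$opt == 0
    msgs <- c(msgs, unlist(fit@optinfo$conv$lme4$messages))
  } else {
    fit <- withCallingHandlers(
      glm(fml, data = table, family = binomial()),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    beta <- coef(fit)
    varComp <- setNames(numeric(0), character(0))
    conv <- fit$converged
  }
  if (degenerate) {
    conv <- FALSE
    msgs <- c(msgs, "degenerate outcome: no variation in h")
  }
  new("HierFit", beta = beta, expBeta = exp(beta), varComponents = varComp,
      aic = AIC(fit), permP = setNames(numeric(0), character(0)),
      converged = conv, messages = unique(msgs), spec = spec,
      nobs = nrow(table), fit = fit)
}

#' Proportion of a variance component explained by added predictors
#'
#' \code{1 - Var_component(model) / Var_component(baseline)}, reported as
#' a percentage rounded to the nearest integer.  Both fits must share rows
#' and differ only in fixed terms; alternatively two plain variance values
#' may be supplied.
#'
#' @param baseline a \linkS4class{HierFit} or a single variance value.
#' @param model a \linkS4class{HierFit} or a single variance value.
#' @param component which random component to compare (ignored for plain
#'   numbers), default \code{"dyad"}.
#' @return percentage (integer-valued numeric).
#' @examples
#' varianceExplained(2.817, 1.166)   # 59
#' @export
varianceExplained <- function(baseline, model, component = "dyad") {
  pick <- function(x) {
    if (is(x, "HierFit")) {
      if (!component %in% names(varComponents(x)))
        stop("fit has no '", component, "' variance component")
      varComponents(x)[[component]]
    } else as.numeric(x)
  }
  if (is(baseline, "HierFit") && is(model, "HierFit")) {
    if (baseline@nobs != model@nobs)
      stop("fits do not share rows")
  }
  vb <- pick(baseline); vm <- pick(model)
  if (vb <= 0) stop("baseline variance must be positive")
  round(100 * (1 - vm / vb))
}

#' AIC model selection over candidate specifications
#'
#' Fits every candidate on the same table and returns the one minimizing
#' AIC; ties are broken toward fewer parameters.  Candidates that fail or
#' do not converge are excluded with a warning.
#'
#' @param table risk-day table.
#' @param specs list of \linkS4class{ModelSpec} candidates.
#' @param nAGQ passed through to \code{\link{fitHierLogistic}}.
#' @return list with \code{best} (the winning \linkS4class{HierFit}),
#'   \code{spec}, and \code{aicTable} (label, params, AIC, converged).
#' @export
aicSelect <- function(table, specs, nAGQ = 1L) {
  stopifnot(length(specs) >= 1L)
  fits <- lapply(specs, function(s)
    tryCatch(fitHierLogistic(table, s, nAGQ = nAGQ), error = function(e) e))
  ok <- vapply(fits, function(f) is(f, "HierFit") && f@converged, TRUE)
  if (!all(ok))
    warning(sum(!ok), " candidate(s) excluded (failed or non-convergent)")
  if (!any(ok)) stop("no candidate converged")
  aics <- vapply(fits, function(f)
    if (is(f, "HierFit")) f@aic else NA_real_, 0)
  npar <- vapply(specs, .nParams, 0L)
  cand <- which(ok)
  best <- cand[order(aics[cand], npar[cand])][1]
  labels <- vapply(seq_along(specs), function(k) {
    l <- specs[[k]]@label
    if (nchar(l)) l else paste0("spec", k)
  }, "")
  list(best = fits[[best]], spec = specs[[best]],
       aicTable = data.frame(label = labels, params = npar, aic = aics,
                             converged = ok))
}

#' Permutation significance for fixed effects and variance components
#'
#' Shuffles the hosting outcome across all observation rows, refits the
#' spec, and compares: for each fixed effect the absolute estimate, for
#' each variance component the estimate itself, against the permutation
#' distribution.  P-values use the add-one estimator
#' \code{(1 + #permuted >= observed) / (nPerm + 1)}.
#'
#' @param table risk-day table.
#' @param spec a \linkS4class{ModelSpec}.
#' @param nPerm number of permutations (>= 99).
#' @param seed integer seed.
#' @param nAGQ passed to the fitter.
#' @return a \linkS4class{HierFit} (the observed fit) whose \code{permP}
#'   slot holds p-values named after the estimates; variance-component
#'   entries are prefixed \code{"var_"}.
#' @export
permutationSignificance <- function(table, spec, nPerm = 199L, seed = 1L,
                                    nAGQ = 1L) {
  stopifnot(nPerm >= 99L)
  obs <- fitHierLogistic(table, spec, nAGQ = nAGQ)
  varStat <- function(f) {
    v <- f@varComponents
    if (length(v)) names(v) <- paste0("var_", names(v))
    v
  }
  obsStat <- c(abs(obs@beta), varStat(obs))
  geCount <- setNames(numeric(length(obsStat)), names(obsStat))
  nUsed <- 0L
  set.seed(seed)
  for (b in seq_len(nPerm)) {
    perm <- table
    perm$h <- sample(table$h)
    pf <- tryCatch(fitHierLogistic(perm, spec, nAGQ = nAGQ),
                   error = function(e) NULL)
    if (is.null(pf)) next
    stat <- c(abs(pf@beta), varStat(pf))
    common <- intersect(names(stat), names(obsStat))
    geCount[common] <- geCount[common] +
      (stat[common] >= obsStat[common])
    nUsed <- nUsed + 1L
  }
  obs@permP <- (1 + geCount) / (nUsed + 1)
  obs
}

#' The standard ladder of model specifications
#'
#' The fixed-effect builds used in the stationary analysis: a baseline
#' with week and reporting controls (A); family-level host/guest age and
#' size terms (B); dyadic distance (C), kinship (D), both (E); and the
#' full model adding the reciprocal hosting rate and its interaction with
#' kinship (F).  All carry crossed host, guest and dyad random intercepts.
#'
#' @param which subset of labels to return.
#' @return named list of \linkS4class{ModelSpec}.
#' @export
standardSpecs <- function(which = c("A", "B", "C", "D", "E", "F")) {
  base <- c("weeks", "guestOnly")
  fams <- c("hostAge", "hostAge2", "guestAge", "hostSize", "guestSize")
  all <- list(
    A = modelSpec(base, label = "A: controls"),
    B = modelSpec(c(base, fams), label = "B: + family traits"),
    C = modelSpec(c(base, fams, "logDist"), label = "C: + distance"),
    D = modelSpec(c(base, fams, "relatedness"), label = "D: + kinship"),
    E = modelSpec(c(base, fams, "logDist", "relatedness"),
                  label = "E: + distance + kinship"),
    F = modelSpec(c(base, fams, "logDist", "relatedness", "recipRate",
                    "recipXkin"), label = "F: + reciprocity"))
  all[which]
}

#' Table-1-style text rendering of a set of fits
#' @param fits named list of \linkS4class{HierFit}.
#' @return character vector of report lines.
#' @export
renderFitTable <- function(fits) {
  lines <- character(0)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    lines <- c(lines, sprintf("Model %s (%s)", nm, f@spec@label))
    if (length(f@varComponents)) {
      lines <- c(lines, "  Var(alpha):")
      for (v in names(f@varComponents)) {
        p <- f@permP[paste0("var_", v)]
        lines <- c(lines, sprintf("    %-6s %8.3f%s", v,
                                  f@varComponents[[v]],
                                  ifelse(length(p) && !is.na(p),
                                         sprintf("  p=%.4g", p), "")))
      }
    }
    lines <- c(lines, "  beta / exp(beta):")
    for (b in names(f@beta)) {
      p <- f@permP[b]
      lines <- c(lines, sprintf("    %-24s %8.3f %8.3f%s", b, f@beta[[b]],
                                f@expBeta[[b]],
                                ifelse(length(p) && !is.na(p),
                                       sprintf("  p=%.4g", p), "")))
    }
    lines <- c(lines, sprintf("  AIC: %.1f", f@aic), "")
  }
  lines
}
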