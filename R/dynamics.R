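#' Windowed pair counts at each lag
#'
#' For an ordered pair (i, j) and lag \eqn{\Delta t}, the four sums over day
#' pairs \eqn{t' - t = \Delta t}:
#' \eqn{N_{hh} = \sum h_{ij}(t) h_{ji}(t')},
#' \eqn{N_{oo} = \sum o_{ij}(t) o_{ji}(t')},
#' \eqn{N_{ho} = \sum h_{ij}(t) o_{ji}(t')},
#' \eqn{N_{oh} = \sum o_{ij}(t) h_{ji}(t')}.
#' These correct the conditional-probability estimate for observational
#' windowing: only jointly observable day pairs enter the denominators.
#'
#' @param panel an \linkS4class{EventPanel}.
#' @param host,guest family ids of the ordered pair (host != guest).
#' @param lags positive integer lags (days).
#' @return data.frame with columns lag, Nhh, Noo, Nho, Noh.
#' @export
pairCounts <- function(panel, host, guest, lags = 1:60) {
  stopifnot(host != guest, all(lags >= 1))
  i <- pairIndex(panel, host, guest)
  j <- pairIndex(panel, guest, host)
  h <- hostings(panel); o <- observable(panel)
  cnt <- .lagCounts(h[i, ], h[j, ], o[i, ], o[j, ], lags)
  data.frame(lag = lags, Nhh = cnt$hh, Noo = cnt$oo, Nho = cnt$ho,
             Noh = cnt$oh)
}

.lagCounts <- function(hij, hji, oij, oji, lags) {
  T <- length(hij)
  f <- function(a, b, d) if (d >= T) 0 else
    sum(a[seq_len(T - d)] * b[seq_len(T - d) + d])
  list(hh = vapply(lags, function(d) f(hij, hji, d), 0),
       oo = vapply(lags, function(d) f(oij, oji, d), 0),
       ho = vapply(lags, function(d) f(hij, oji, d), 0),
       oh = vapply(lags, function(d) f(oij, hji, d), 0))
}

# Vectorized pair counts for many ordered pairs at once.
# H, O: dyads x days matrices; idx, rev: row indices of (i,j) and (j,i).
# Returns list of nPairs x nLags matrices hh, oo, ho, oh.
.lagCountsMany <- function(H, O, idx, rev, lags) {
  T <- ncol(H)
  n <- length(idx)
  out <- list(hh = matrix(0, n, length(lags)),
              oo = matrix(0, n, length(lags)),
              ho = matrix(0, n, length(lags)),
              oh = matrix(0, n, length(lags)))
  Hi <- H[idx, , drop = FALSE]; Hj <- H[rev, , drop = FALSE]
  Oi <- O[idx, , drop = FALSE]; Oj <- O[rev, , drop = FALSE]
  for (k in seq_along(lags)) {
    d <- lags[k]
    if (d >= T) next
    a <- seq_len(T - d); b <- a + d
    out$hh[, k] <- rowSums(Hi[, a, drop = FALSE] * Hj[, b, drop = FALSE])
    out$oo[, k] <- rowSums(Oi[, a, drop = FALSE] * Oj[, b, drop = FALSE])
    out$ho[, k] <- rowSums(Hi[, a, drop = FALSE] * Oj[, b, drop = FALSE])
    out$oh[, k] <- rowSums(Oi[, a, drop = FALSE] * Hj[, b, drop = FALSE])
  }
  out
}

#' Windowing-corrected reciprocity ratio from pair counts
#'
#' The maximum-likelihood estimate of the ratio of the conditional
#' probability P("j hosts i" at t + lag | "i hosts j" at t) to the base
#' rate P("j hosts i"), corrected for the observation window:
#' \deqn{\hat R = \frac{N_{hh} \, N_{oo}}{N_{ho} \, N_{oh}}.}
#' Undefined (NA) when \eqn{N_{ho} = 0} or \eqn{N_{oh} = 0}; never coerced
#' to 0 or infinity.
#'
#' @param counts data.frame from \code{\link{pairCounts}} (or any frame
#'   with columns Nhh, Noo, Nho, Noh).
#' @return numeric vector of \eqn{\hat R} per row.
#' @examples
#' rhat(data.frame(Nhh = 2, Noo = 100, Nho = 10, Noh = 10))   # 2
#' @export
rhat <- function(counts) {
  ifelse(counts$Nho > 0 & counts$Noh > 0,
         counts$Nhh * counts$Noo / (counts$Nho * counts$Noh),
         NA_real_)
}

#' Pooled short-lag reciprocity ratio
#'
#' Sums the four windowed counts over the pooled lags (default 1-3 days)
#' before forming the ratio -- the maximum-likelihood estimate of the
#' pooled conditional probability, preferred over averaging per-lag ratios
#' which are frequently undefined at realistic sparsity.
#'
#' @param counts data.frame from \code{\link{pairCounts}} covering the lags
#'   to pool.
#' @param lags lags to pool, default 1:3.
#' @return single pooled \eqn{\hat R} (NA when undefined).
#' @export
pooledRhat <- function(counts, lags = 1:3) {
  cc <- counts[counts$lag %in% lags, , drop = FALSE]
  s <- as.data.frame(t(colSums(cc[, c("Nhh", "Noo", "Nho", "Noh")])))
  rhat(s)
}

.kinStratum <- function(r, digits = 3) round(r, digits)

#' Fit one level of the stationary null hierarchy
#'
#' Estimates, by observed count ratios restricted to observable cells, the
#' margins a null level preserves: the guest-only reporting factor (ratio
#' of event rates on guest-only-covered vs host-covered risk days), weekly
#' seasonal multipliers (weekly event-rate fractions, normalized to unit
#' exposure-weighted mean), and the level's base rates -- per host
#' (\code{homogeneous}), per host and kin stratum with mean relatedness
#' rounded to \code{kinDigits} decimals (\code{kin_heterogeneous}), or per
#' ordered pair (\code{full_heterogeneous}).  Rates are maximum-likelihood
#' under the thinning model: events divided by exposure, where the exposure
#' of an observable cell is its weekly multiplier times the reporting
#' factor when only the guest's interviews covered it.
#'
#' @param panel an \linkS4class{EventPanel}.
#' @param relmat family relatedness matrix (needed for the kin level).
#' @param level \code{"homogeneous"}, \code{"kin_heterogeneous"} or
#'   \code{"full_heterogeneous"}.
#' @param kinDigits rounding used to group "the same mean r" into strata.
#' @return a \linkS4class{NullModel}.
#' @export
fitNull <- function(panel, relmat = NULL,
                    level = c("homogeneous", "kin_heterogeneous",
                              "full_heterogeneous"),
                    kinDigits = 3) {
  level <- match.arg(level)
  h <- hostings(panel); o <- observable(panel); gOnly <- guestOnly(panel)
  host <- hostIds(panel); guest <- guestIds(panel)
  week <- SummarizedExperiment::colData(panel)$week
  # guest-only reporting factor
  hc <- o == 1L & gOnly == 0L
  go <- o == 1L & gOnly == 1L
  rateHC <- if (sum(hc)) sum(h[hc]) / sum(hc) else 0
  rateGO <- if (sum(go)) sum(h[go]) / sum(go) else 0
  gFac <- if (rateHC > 0 && sum(go) > 0) min(1, rateGO / rateHC) else 1
  # weekly multipliers from weekly event fractions over observable cells
  wk <- sort(unique(week))
  oW <- vapply(wk, function(w) sum(o[, week == w]), 0)
  hW <- vapply(wk, function(w) sum(h[, week == w]), 0)
  overall <- sum(h) / max(1, sum(o))
  m <- ifelse(oW > 0 & overall > 0, (hW / pmax(1, oW)) / overall, 1)
  # normalize to exposure-weighted mean one so total rate is preserved
  if (sum(oW) > 0 && sum(m * oW) > 0) m <- m * sum(oW) / sum(m * oW)
  weekMult <- setNames(m, paste0("w", wk))
  # per-cell exposure (0 off the observation mask)
  expo <- o * m[match(week, wk)][col(o)] *
    ifelse(gOnly == 1L, gFac, 1)
  strata <- rep(NA_real_, nrow(panel))
  if (level == "homogeneous") {
    unit <- host
  } else if (level == "kin_heterogeneous") {
    if (is.null(relmat)) stop("kin_heterogeneous level needs relmat")
    r <- relmat[cbind(match(host, rownames(relmat)),
                      match(guest, colnames(relmat)))]
    strata <- .kinStratum(r, kinDigits)
    unit <- paste(host, strata, sep = "|")
  } else {
    unit <- paste(host, guest, sep = "->")
  }
  evU <- tapply(rowSums(h), unit, sum)
  exU <- tapply(rowSums(expo), unit, sum)
  q <- ifelse(exU > 0, evU / exU, 0)
  qRow <- as.numeric(q[match(unit, names(q))])
  prob <- qRow * expo / pmax(o, 1e-300)
  prob[o == 0L] <- qRow[row(prob)[o == 0L]] *
    (m[match(week, wk)][col(prob)])[o == 0L]
  prob <- pmin(pmax(prob, 0), 1)
  dimnames(prob) <- dimnames(h)
  new("NullModel", level = level, prob = prob,
      rate = setNames(as.numeric(q), names(q)), weekMult = weekMult,
      guestOnlyFactor = gFac, host = host, guest = guest, strata = strata)
}

#' Sample i.i.d. realizations of a null model
#'
#' Draws each observable dyad-day independently from the null's Bernoulli
#' probability (which already folds in the seasonal multipliers and the
#' guest-only reporting factor), windowed by the supplied observation mask
#' -- normally the true mask of the panel the null was fitted to.
#'
#' @param null a \linkS4class{NullModel}.
#' @param mask binary observability matrix (same shape as the fitted
#'   panel); cells with 0 can never contain a simulated event.
#' @param nRealizations ensemble size (>= 100 recommended for inference).
#' @param seed integer seed.
#' @return a \linkS4class{NullEnsemble}.
#' @export
sampleNull <- function(null, mask, nRealizations = 1000L, seed = 1L) {
  stopifnot(all(dim(mask) == dim(null@prob)))
  set.seed(seed)
  p <- null@prob * (mask == 1L)
  cells <- which(p > 0)
  pv <- p[cells]
  ev <- vector("list", nRealizations)
  dm <- dim(p)
  for (k in seq_len(nRealizations)) {
    on <- cells[stats::runif(length(pv)) < pv]
    ev[[k]] <- arrayInd(on, dm)
  }
  new("NullEnsemble", events = ev, dim = as.integer(dm), level = null@level,
      seed = as.integer(seed))
}

#' Dense hosting matrix of one null realization
#' @param ensemble a \linkS4class{NullEnsemble}.
#' @param k realization index.
#' @return binary integer matrix.
#' @export
nullRealization <- function(ensemble, k) {
  H <- matrix(0L, ensemble@dim[1], ensemble@dim[2])
  H[ensemble@events[[k]]] <- 1L
  H
}

#' Ordered pairs with observed reciprocity
#'
#' Membership rule for class averaging: events observed in both directions
#' (N("i hosts j") > 0 and N("j hosts i") > 0) and the pair jointly
#' observable at some lag in the grid.
#' @param panel an \linkS4class{EventPanel}.
#' @param lags lag grid.
#' @return integer matrix with columns \code{idx} and \code{rev} (row
#'   indices of the ordered pair and its reverse).
#' @keywords internal
.reciprocalPairs <- function(panel, lags) {
  h <- hostings(panel); o <- observable(panel)
  host <- hostIds(panel); guest <- guestIds(panel)
  rev <- match(paste(guest, host), paste(host, guest))
  evFwd <- rowSums(h)
  both <- evFwd > 0 & evFwd[rev] > 0
  cand <- which(both)
  if (!length(cand)) return(cbind(idx = integer(0), rev = integer(0)))
  oo <- .lagCountsMany(h, o, cand, rev[cand], lags)$oo
  keep <- rowSums(oo) > 0
  cbind(idx = cand[keep], rev = rev[cand][keep])
}

#' Class-averaged, null-renormalized reciprocity curve
#'
#' Implements the class average
#' \deqn{\hat R(\Delta t) = \left\langle \hat R_{ij}(\Delta t) /
#'   \langle \hat R_{ij}(\Delta t) \rangle_{null}
#'   \right\rangle_{ij \in C}}
#' over ordered pairs with observed reciprocity in class C, where the inner
#' average runs over the realizations of a null ensemble.  Bands are the
#' one- and two-sigma quantile envelopes of the identical statistic
#' computed on each null realization; p-values are one-sided upper-tail
#' fractions with the add-one estimator.  A pooled statistic over
#' \code{pooledLags} (counts summed before the ratio) is reported
#' alongside.  Pairs whose null mean is undefined at every realization are
#' dropped with a message.
#'
#' @param panel the observed \linkS4class{EventPanel}.
#' @param ensemble a \linkS4class{NullEnsemble} sampled on the panel's
#'   observation mask.
#' @param relmat family relatedness matrix.
#' @param classLabel \code{"all"}, \code{"close_kin"} or
#'   \code{"not_close_kin"} (binary split at \code{kinThreshold}).
#' @param lags lag grid in days (same-day lag 0 is excluded by design:
#'   same-day mutual hosting is ill-ordered).
#' @param pooledLags lags pooled into the short-timescale statistic.
#' @param kinThreshold close-kin boundary on mean relatedness.
#' @return a \linkS4class{ReciprocityCurve}.
#' @export
classCurve <- function(panel, ensemble, relmat,
                       classLabel = c("all", "close_kin", "not_close_kin"),
                       lags = 1:60, pooledLags = 1:3, kinThreshold = 0.25) {
  classLabel <- match.arg(classLabel)
  stopifnot(all(lags >= 1))
  pairs <- .reciprocalPairs(panel, lags)
  host <- hostIds(panel); guest <- guestIds(panel)
  if (nrow(pairs)) {
    r <- relmat[cbind(match(host[pairs[, "idx"]], rownames(relmat)),
                      match(guest[pairs[, "idx"]], colnames(relmat)))]
    keep <- switch(classLabel,
                   all = rep(TRUE, nrow(pairs)),
                   close_kin = r >= kinThreshold,
                   not_close_kin = r < kinThreshold)
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (!nrow(pairs))
    stop("empty class: no pairs with observed reciprocity in '",
         classLabel, "'")
  idx <- pairs[, "idx"]; rev <- pairs[, "rev"]
  h <- hostings(panel); o <- observable(panel)
  nP <- length(idx); nL <- length(lags); nK <- length(ensemble@events)
  pool <- match(pooledLags, lags)
  stopifnot(!anyNA(pool))
  obsCnt <- .lagCountsMany(h, o, idx, rev, lags)
  ratio <- function(cnt, cols) {
    hh <- rowSums(cnt$hh[, cols, drop = FALSE])
    oo <- rowSums(cnt$oo[, cols, drop = FALSE])
    ho <- rowSums(cnt$ho[, cols, drop = FALSE])
    oh <- rowSums(cnt$oh[, cols, drop = FALSE])
    ifelse(ho > 0 & oh > 0, hh * oo / (ho * oh), NA_real_)
  }
  obsR <- vapply(seq_len(nL), function(k) ratio(obsCnt, k), numeric(nP))
  obsR <- matrix(obsR, nP, nL)
  obsPool <- ratio(obsCnt, pool)
  nullR <- array(NA_real_, c(nP, nL, nK))
  nullPool <- matrix(NA_real_, nP, nK)
  for (k in seq_len(nK)) {
    H <- nullRealization(ensemble, k)
    cnt <- .lagCountsMany(H, o, idx, rev, lags)
    nullR[, , k] <- vapply(seq_len(nL), function(l) ratio(cnt, l),
                           numeric(nP))
    nullPool[, k] <- ratio(cnt, pool)
  }
  nullMeanLag <- apply(nullR, c(1, 2), function(v) mean(v, na.rm = TRUE))
  nullMeanPool <- rowMeans(nullPool, na.rm = TRUE)
  dropped <- sum(!is.finite(nullMeanPool) | nullMeanPool == 0)
  if (dropped)
    message(dropped, " pair(s) dropped from the pooled class average ",
            "(undefined or zero null mean)")
  classAvg <- function(vals, means) {
    ok <- is.finite(vals) & is.finite(means) & means > 0
    if (!any(ok)) return(NA_real_)
    mean(vals[ok] / means[ok])
  }
  obsStat <- vapply(seq_len(nL), function(l)
    classAvg(obsR[, l], nullMeanLag[, l]), 0)
  nullStat <- matrix(NA_real_, nK, nL)
  for (k in seq_len(nK))
    nullStat[k, ] <- vapply(seq_len(nL), function(l)
      classAvg(nullR[, l, k], nullMeanLag[, l]), 0)
  qs <- function(x, p) if (all(is.na(x))) NA_real_ else
    quantile(x, p, na.rm = TRUE, names = FALSE)
  pUp <- function(obs, nulls) {
    if (!is.finite(obs)) return(NA_real_)
    n <- sum(is.finite(nulls))
    if (n == 0) return(NA_real_)
    (1 + sum(nulls[is.finite(nulls)] >= obs)) / (n + 1)
  }
  tab <- data.frame(
    lag = lags, observed = obsStat,
    nullMean = vapply(seq_len(nL), function(l)
      mean(nullStat[, l], na.rm = TRUE), 0),
    lo1 = vapply(seq_len(nL), function(l) qs(nullStat[, l], 0.158655), 0),
    hi1 = vapply(seq_len(nL), function(l) qs(nullStat[, l], 0.841345), 0),
    lo2 = vapply(seq_len(nL), function(l) qs(nullStat[, l], 0.022750), 0),
    hi2 = vapply(seq_len(nL), function(l) qs(nullStat[, l], 0.977250), 0),
    p = vapply(seq_len(nL), function(l) pUp(obsStat[l], nullStat[, l]), 0),
    nPairs = vapply(seq_len(nL), function(l)
      sum(is.finite(obsR[, l]) & is.finite(nullMeanLag[, l]) &
            nullMeanLag[, l] > 0), 0L))
  obsPoolStat <- classAvg(obsPool, nullMeanPool)
  nullPoolStat <- vapply(seq_len(nK), function(k)
    classAvg(nullPool[, k], nullMeanPool), 0)
  pooled <- data.frame(
    lags = paste(range(pooledLags), collapse = "-"),
    observed = obsPoolStat,
    nullMean = mean(nullPoolStat, na.rm = TRUE),
    lo2 = qs(nullPoolStat, 0.022750), hi2 = qs(nullPoolStat, 0.977250),
    p = pUp(obsPoolStat, nullPoolStat),
    nPairs = sum(is.finite(obsPool) & is.finite(nullMeanPool) &
                   nullMeanPool > 0))
  new("ReciprocityCurve", table = tab, pooled = pooled,
      classLabel = classLabel, nullLevel = ensemble@level,
      nRealizations = as.integer(nK), nDropped = as.integer(dropped))
}

#' Export reciprocity curves as a tidy CSV
#' @param curves list of \linkS4class{ReciprocityCurve} objects.
#' @param path output file.
#' @export
writeCurves <- function(curves, path) {
  tab <- do.call(rbind, lapply(curves, curveTable))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Plot a reciprocity curve against its null bands
#'
#' Observed class-averaged ratio per lag over the one/two-sigma null
#' envelopes, on a log scale.
#' @param curve a \linkS4class{ReciprocityCurve}.
#' @param main title (defaults to class and null level).
#' @export
plotCurve <- function(curve, main = NULL) {
  tb <- curve@table
  ok <- is.finite(tb$observed)
  if (is.null(main))
    main <- paste0(curve@classLabel, " vs ", curve@nullLevel, " null")
  ylim <- range(c(tb$observed[ok], tb$lo2, tb$hi2), na.rm = TRUE)
  ylim[1] <- max(ylim[1], 1e-2)
  plot(tb$lag, pmax(tb$observed, 1e-2), type = "n", log = "y",
       xlab = expression(Delta * t ~ "(days)"),
       ylab = expression(hat(R)(Delta * t)), ylim = ylim, main = main)
  polygon(c(tb$lag, base::rev(tb$lag)), pmax(c(tb$lo2, base::rev(tb$hi2)), 1e-2),
          col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
  polygon(c(tb$lag, base::rev(tb$lag)), pmax(c(tb$lo1, base::rev(tb$hi1)), 1e-2),
          col = grDevices::adjustcolor("steelblue", 0.45), border = NA)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  graphics::lines(tb$lag[ok], pmax(tb$observed[ok], 1e-2), lwd = 1.5)
  graphics::points(tb$lag[ok], pmax(tb$observed[ok], 1e-2), pch = 16,
                   cex = 0.5)
  invisible(NULL)
}
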