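#' Built-in seasonal activity profile
#'
#' Piecewise-constant weekly multipliers over a 16-week window: an active
#' early season, a mid-season lull, then a second active period, mirroring
#' the shape of typical field seasons with harvest and field-clearing
#' phases.  Normalized to mean 1.
#' @param nWeeks number of weeks.
#' @return numeric vector of length \code{nWeeks}.
#' @export
defaultSeasonal <- function(nWeeks = 16L) {
  base <- c(rep(1.4, 5), rep(0.55, 3), rep(1.15, 6), rep(0.9, 2))
  s <- rep(base, length.out = nWeeks)
  s / mean(s)
}

.substream <- function(seed, k) (as.integer(seed) * 7L + k) %% 2147483629L

#' Generate a synthetic village
#'
#' Builds a kin-structured village of nuclear families spanning at least
#' three generations: founder couples, descendant families formed by
#' marrying children off (within the village or to in-marrying founders),
#' and their own children.  Household locations follow a kin-clustered
#' spatial mixture -- descendant households settle near their parental
#' households with noise, with occasional relocation -- calibrated so that
#' relatedness explains on the order of a fifth of the variance in
#' log household distance.  Head ages fall in 18-75 and family sizes in
#' 1-10.
#'
#' @param nFamilies number of nuclear families (>= 2).
#' @param seed integer seed; the same seed reproduces the same village.
#' @param nDays study-window length stored on the village.
#' @param meanChildren mean number of resident children per family.
#' @return a \linkS4class{Village}.
#' @examples
#' v <- makeVillage(8, seed = 42, nDays = 28)
#' nFamilies(v)
#' @export
makeVillage <- function(nFamilies = 35L, seed = 1L, nDays = 112L,
                        meanChildren = 4.8) {
  stopifnot(nFamilies >= 2L)
  set.seed(.substream(seed, 1L))
  nFounder <- max(2L, ceiling(nFamilies / 2.6))
  famId <- function(k) sprintf("F%02d", k)
  nextInd <- 0L
  newInd <- function() {
    nextInd <<- nextInd + 1L
    sprintf("I%03d", nextInd)
  }
  ped <- data.frame(individual_id = character(), father_id = character(),
                    mother_id = character(), sex = integer(),
                    family_id = character(), stringsAsFactors = FALSE)
  addInd <- function(id, f, m, sex, fam) {
    ped[nrow(ped) + 1L, ] <<- list(id, f, m, sex, fam)
  }
  # children of each family not yet married off: id, sex, generation
  pool <- data.frame(id = character(), sex = integer(), fam = character(),
                     gen = integer(), stringsAsFactors = FALSE)
  famGen <- integer(nFamilies)
  famLoc <- matrix(NA_real_, nFamilies, 2)   # km offsets (x, y)
  famHeads <- vector("list", nFamilies)
  parentsOf <- vector("list", nFamilies)     # family indices of the couple's
                                             # natal families (for locations)
  spawnChildren <- function(k, father, mother, gen) {
    nKids <- min(8L, rpois(1, meanChildren))
    for (c in seq_len(nKids)) {
      id <- newInd()
      sex <- sample(1:2, 1)
      addInd(id, father, mother, sex, famId(k))
      pool[nrow(pool) + 1L, ] <<- list(id, sex, famId(k), gen + 1L)
    }
  }
  for (k in seq_len(nFounder)) {
    if (k > nFamilies) break
    fa <- newInd(); mo <- newInd()
    addInd(fa, NA, NA, 1L, famId(k))
    addInd(mo, NA, NA, 2L, famId(k))
    famGen[k] <- 0L
    famHeads[[k]] <- c(fa, mo)
    parentsOf[[k]] <- integer(0)
    spawnChildren(k, fa, mo, 0L)
  }
  if (nFamilies > nFounder) for (k in (nFounder + 1L):nFamilies) {
    # marry a pooled child; spouse from another family's pool or in-marrying
    if (nrow(pool) == 0L) {
      # no marriageable children left: seed a fresh founder couple
      fa <- newInd(); mo <- newInd()
      addInd(fa, NA, NA, 1L, famId(k))
      addInd(mo, NA, NA, 2L, famId(k))
      famGen[k] <- 0L
      famHeads[[k]] <- c(fa, mo)
      parentsOf[[k]] <- integer(0)
      spawnChildren(k, fa, mo, 0L)
      next
    }
    a <- sample(seq_len(nrow(pool)), 1)
    aInfo <- pool[a, ]
    spouseCand <- which(pool$fam != aInfo$fam & pool$sex != aInfo$sex)
    natal <- match(aInfo$fam, famId(seq_len(nFamilies)))
    if (length(spouseCand) && runif(1) < 0.5) {
      b <- if (length(spouseCand) == 1L) spouseCand else sample(spouseCand, 1)
      bInfo <- pool[b, ]
      natalB <- match(bInfo$fam, famId(seq_len(nFamilies)))
      pool <- pool[-c(a, b), , drop = FALSE]
    } else {
      pool <- pool[-a, , drop = FALSE]
      bid <- newInd()
      bInfo <- data.frame(id = bid, sex = ifelse(aInfo$sex == 1L, 2L, 1L),
                          fam = NA_character_,
                          gen = aInfo$gen, stringsAsFactors = FALSE)
      addInd(bid, NA, NA, bInfo$sex, famId(k))   # in-marrying founder
      natalB <- NA_integer_
    }
    # move both spouses into the new family
    ped$family_id[ped$individual_id == aInfo$id] <- famId(k)
    if (!is.na(bInfo$fam[1]))
      ped$family_id[ped$individual_id == bInfo$id] <- famId(k)
    gen <- max(aInfo$gen, bInfo$gen)
    famGen[k] <- gen
    famHeads[[k]] <- c(aInfo$id, bInfo$id)
    parentsOf[[k]] <- stats::na.omit(c(natal, natalB))
    father <- if (aInfo$sex == 1L) aInfo$id else bInfo$id
    mother <- if (aInfo$sex == 1L) bInfo$id else aInfo$id
    spawnChildren(k, father, mother, gen)
  }
  # guard: families emptied by marriage would be invalid; parents stay put,
  # so every family keeps its couple
  # locations: founders uniform over the village extent, descendants near
  # the mean of their natal households with noise; occasional relocation
  extent <- 3.0    # village spans ~3 km
  sigmaNear <- 0.10
  for (k in seq_len(nFamilies)) {
    par <- parentsOf[[k]]
    if (!length(par) || runif(1) < 0.1) {
      famLoc[k, ] <- runif(2, 0, extent)
    } else {
      anchor <- colMeans(famLoc[par, , drop = FALSE])
      famLoc[k, ] <- anchor + rnorm(2, 0, sigmaNear)
    }
  }
  lat0 <- -14.90; lon0 <- -66.30
  lat <- lat0 + famLoc[, 2] / 111.19
  lon <- lon0 + famLoc[, 1] / (111.19 * cos(lat0 * pi / 180))
  ageAt <- function(gen) {
    lo <- c(55, 36, 20, 18)[min(gen + 1L, 4L)]
    hi <- c(75, 58, 42, 34)[min(gen + 1L, 4L)]
    runif(1, lo, hi)
  }
  head1 <- vapply(seq_len(nFamilies), function(k) ageAt(famGen[k]), 0)
  head2 <- vapply(seq_len(nFamilies), function(k)
    max(18, min(75, head1[k] + rnorm(1, 0, 4))), 0)
  cnt <- table(factor(ped$family_id, levels = famId(seq_len(nFamilies))))
  fam <- data.frame(family_id = famId(seq_len(nFamilies)),
                    size = as.integer(cnt),
                    head_age1 = round(head1, 1),
                    head_age2 = round(head2, 1),
                    lat = round(lat, 6), lon = round(lon, 6),
                    stringsAsFactors = FALSE)
  Village(fam, ped, nDays)
}

#' Simulate hosting events with known ground truth
#'
#' Each day, every family throws a party with probability
#' \code{baseHostRate} times its idiosyncratic propensity, an age
#' multiplier (log-quadratic in mean head age, peaking at 50) and the
#' weekly seasonal multiplier.  Guest families are drawn without
#' replacement, with weight
#' \eqn{\exp(\beta_{dist} \log d_{ij} + \beta_{kin} r_{ij} +
#' \epsilon_{ij})}, where \eqn{\epsilon_{ij}} is a fixed seeded dyad
#' effect.  The conditional-action kernel is a hazard multiplier on the
#' directed return event: while a debt is outstanding (j hosted i within
#' the previous \code{recipWindow} days and the dyad belongs to
#' \code{recipClasses}), family i additionally hosts j with probability
#' \code{(recipStrength - 1)} times the baseline dyadic hazard
#' \eqn{p^0_{ij}(t)} (party probability times the first-order inclusion
#' probability of j), so the conditional probability of the return event
#' is multiplied by approximately \code{recipStrength} and both the
#' hosting and the guest-choice margins respond.  With
#' \code{recipStrength = 1} the process is exactly i.i.d. across days
#' given the stationary preferences.
#'
#' @param village a \linkS4class{Village}.
#' @param params a \linkS4class{SimParams}.
#' @return list with \code{events} (data.frame host, guest, day) and
#'   \code{truth} (list: weight matrix, per-day host party probabilities,
#'   dyad effects, rho, window, classes, seed).
#' @export
simulateEvents <- function(village, params) {
  stopifnot(is(params, "SimParams"))
  set.seed(.substream(params@seed, 2L))
  fids <- familyIds(village)
  nF <- length(fids)
  nT <- nDays(village)
  if (1 + (params@partySizeMean - 1) * 3 >= nF)
    warning("party sizes may saturate the village")
  R <- familyRelatedness(village)
  D <- familyDistances(village)
  eps <- matrix(rnorm(nF * nF, 0, params@sigmaDyad), nF, nF)
  W <- exp(params@betaDist * log(pmax(D, 0.01)) + params@betaKin *
             ifelse(is.na(R), 0, R) + eps)
  diag(W) <- 0
  dimnames(W) <- list(fids, fids)
  age <- rowMeans(cbind(families(village)$head_age1,
                        families(village)$head_age2), na.rm = TRUE)
  ageMult <- exp(params@ageEffect[1] * (age - 50) +
                 params@ageEffect[2] * (age - 50)^2)
  hostProp <- exp(rnorm(nF, -params@sigmaHost^2 / 2, params@sigmaHost))
  nW <- ceiling(nT / 7)
  seas <- if (length(params@seasonal))
    rep(params@seasonal, length.out = nW) else defaultSeasonal(nW)
  week <- (seq_len(nT) - 1L) %/% 7L + 1L
  pHost <- outer(params@baseHostRate * ageMult * hostProp, seas[week])
  pHost <- pmin(pHost, 1)
  rho <- params@recipStrength
  w <- params@recipWindow
  close <- !is.na(R) & R >= 0.25
  eligible <- switch(params@recipClasses,
                     close = close,
                     not_close = !close & !diag(TRUE, nF),
                     all = !diag(TRUE, nF))
  diag(eligible) <- FALSE
  lastHosted <- matrix(-Inf, nF, nF)   # [i, j]: last day j hosted i
  # baseline dyadic hazard of "i hosts j": party probability times the
  # first-order inclusion probability of guest j
  incl0 <- params@partySizeMean * W / pmax(rowSums(W), 1e-300)
  incl0[incl0 > 1] <- 1
  host <- integer(0); guest <- integer(0); day <- integer(0)
  for (t in seq_len(nT)) {
    # debts[i, j]: j hosted i within the last w days and the kernel applies
    debts <- (t - 1 - lastHosted) <= w & eligible
    for (i in seq_len(nF)) {
      todays <- integer(0)
      if (runif(1) < pHost[i, t]) {
        size <- min(nF - 1L,
                    1L + rpois(1, max(0, params@partySizeMean - 1)))
        todays <- sample(seq_len(nF), size, prob = W[i, ])
      }
      if (rho != 1 && any(debts[i, ])) {
        # return-hosting channel: extra hazard (rho - 1) * p0 per debt
        owed <- which(debts[i, ])
        p0 <- pHost[i, t] * incl0[i, owed]
        extra <- owed[runif(length(owed)) < (rho - 1) * p0]
        todays <- union(todays, extra)
      }
      if (!length(todays)) next
      host <- c(host, rep(i, length(todays)))
      guest <- c(guest, todays)
      day <- c(day, rep(t - 1L, length(todays)))
      lastHosted[cbind(todays, i)] <- t - 1L
    }
  }
  events <- data.frame(host = fids[host], guest = fids[guest],
                       day = as.integer(day))
  events <- events[order(events$host, events$guest, events$day), ]
  rownames(events) <- NULL
  truth <- list(weights = W, hostProb = pHost, dyadEffects = eps,
                rho = rho, window = w, classes = params@recipClasses,
                eligible = eligible, seed = params@seed)
  list(events = events, truth = truth)
}

#' Stationary dyadic hosting probabilities implied by ground truth
#'
#' Monte-Carlo estimate (exact when parties always have one guest) of
#' P("i hosts j" on a day), i.e. the party probability times the guest's
#' inclusion probability, averaged over days, with the reciprocity kernel
#' switched off.
#' @param truth ground-truth list from \code{\link{simulateEvents}}.
#' @param params the \linkS4class{SimParams} used.
#' @param nMC Monte-Carlo draws per host.
#' @return matrix of daily probabilities P("i hosts j").
#' @export
truePreferences <- function(truth, params, nMC = 4000L) {
  W <- truth$weights
  nF <- nrow(W)
  pBar <- rowMeans(truth$hostProb)
  incl <- matrix(0, nF, nF, dimnames = dimnames(W))
  lambda <- max(0, params@partySizeMean - 1)
  for (i in seq_len(nF)) {
    wt <- W[i, ]
    if (lambda == 0) {
      incl[i, ] <- wt / sum(wt)
    } else {
      set.seed(.substream(params@seed, 100L + i))
      acc <- numeric(nF)
      for (m in seq_len(nMC)) {
        size <- min(nF - 1L, 1L + rpois(1, lambda))
        g <- sample(seq_len(nF), size, prob = wt)
        acc[g] <- acc[g] + 1
      }
      incl[i, ] <- acc / nMC
    }
  }
  pBar * incl
}

#' Simulate the interview observer
#'
#' Each family receives interviews on random weekdays at the configured
#' weekly rate; an interview covers the two preceding days.  Hosts report
#' their own hostings on covered days with certainty, guests report
#' attended events with probability \code{guestReportProb} per covering
#' interview, emulating guest under-reporting.
#'
#' @param events true event data.frame from \code{\link{simulateEvents}}.
#' @param village a \linkS4class{Village}.
#' @param params a \linkS4class{SimParams}.
#' @return interview records data.frame as read by
#'   \code{\link{readInterviews}}.
#' @export
simulateInterviews <- function(events, village, params) {
  set.seed(.substream(params@seed, 3L))
  fids <- familyIds(village)
  nT <- nDays(village)
  nW <- ceiling(nT / 7)
  rows <- list()
  for (f in fids) {
    idays <- integer(0)
    for (wk in seq_len(nW) - 1L) {
      k <- rpois(1, params@interviewRate)
      if (k == 0L) next
      daysInWeek <- (wk * 7L):min(wk * 7L + 6L, nT - 1L)
      k <- min(k, length(daysInWeek))
      idays <- c(idays, sort(sample(daysInWeek, k)))
    }
    for (d in idays) {
      cov <- coveredDays(d, nT)
      hosted <- events[events$host == f & events$day %in% cov, ,
                       drop = FALSE]
      attended <- events[events$guest == f & events$day %in% cov, ,
                         drop = FALSE]
      if (nrow(attended))
        attended <- attended[runif(nrow(attended)) < params@guestReportProb,
                             , drop = FALSE]
      n <- nrow(hosted) + nrow(attended)
      if (n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          reporter_family = f, interview_day = d, role = NA_character_,
          partner_family = NA_character_, event_day = NA_integer_)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          reporter_family = f, interview_day = d,
          role = c(rep("host", nrow(hosted)), rep("guest", nrow(attended))),
          partner_family = c(hosted$guest, attended$host),
          event_day = c(hosted$day, attended$day))
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reporter_family = character(), interview_day = integer(),
               role = character(), partner_family = character(),
               event_day = integer())
  validateInterviews(df, village)
}

#' One-call synthetic study
#'
#' Convenience wrapper: village, true events, interviews, reconciliation
#' and panel in one step.
#' @param params a \linkS4class{SimParams}.
#' @return list with village, trueEvents, truth, interviews, events
#'   (reconciled) and panel.
#' @export
simulateStudy <- function(params = simParams()) {
  village <- makeVillage(params@nFamilies, seed = params@seed,
                         nDays = params@nDays)
  sim <- simulateEvents(village, params)
  interviews <- simulateInterviews(sim$events, village, params)
  events <- reconcileReports(interviews, seed = .substream(params@seed, 4L))
  panel <- buildPanel(village, interviews, events)
  list(village = village, trueEvents = sim$events, truth = sim$truth,
       interviews = interviews, events = events, panel = panel)
}
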