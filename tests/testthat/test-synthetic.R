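# Ground-truth generator: structure, determinism, observation model.

test_that("generated villages are valid, sized and three-generational", {
  v <- makeVillage(35, seed = 1, nDays = 112)
  expect_true(validObject(v))
  expect_equal(nFamilies(v), 35)
  expect_equal(nrow(familyRelatedness(v)), 35)
  fam <- families(v)
  expect_true(all(fam$size >= 1 & fam$size <= 10))
  expect_true(all(fam$head_age1 >= 18 & fam$head_age1 <= 75))
  ped <- pedigree(v)
  # at least one individual with a known grandparent (>= 3 generations)
  gp <- ped$father_id[match(ped$father_id, ped$individual_id)]
  expect_true(any(!is.na(gp)))
  expect_equal(sum(upper.tri(familyRelatedness(v))), 595)
})

test_that("two-founder villages are unrelated and regeneration is exact", {
  v2 <- makeVillage(2, seed = 4, nDays = 7)
  R <- familyRelatedness(v2)
  expect_equal(R[1, 2], 0)
  va <- makeVillage(9, seed = 21, nDays = 14)
  vb <- makeVillage(9, seed = 21, nDays = 14)
  expect_equal(families(va), families(vb))
  expect_equal(pedigree(va), pedigree(vb))
  vc <- makeVillage(9, seed = 22, nDays = 14)
  expect_false(identical(families(va), families(vc)))
})

test_that("event simulation is seeded, bounded and switchable", {
  v <- makeVillage(8, seed = 2, nDays = 28)
  p <- simParams(nFamilies = 8, nDays = 28, seed = 2)
  s1 <- simulateEvents(v, p)
  s2 <- simulateEvents(v, p)
  expect_identical(s1$events, s2$events)
  expect_true(all(s1$events$host != s1$events$guest))
  expect_true(all(s1$events$day >= 0 & s1$events$day < 28))
  # no hosting propensity, no events
  p0 <- simParams(nFamilies = 8, nDays = 28, baseHostRate = 0, seed = 2)
  expect_equal(nrow(simulateEvents(v, p0)$events), 0L)
})

test_that("with no conditional kernel the process has no lag correlation", {
  # rho = 1: daily hosting is i.i.d. given preferences, so the mean
  # per-dyad lag-1 autocorrelation sits at zero within sampling error
  p <- simParams(nFamilies = 12, nDays = 400, recipStrength = 1,
                 sigmaHost = 0.3, seed = 6)
  v <- makeVillage(12, seed = 6, nDays = 400)
  ev <- simulateEvents(v, p)$events
  fids <- familyIds(v)
  ac <- c()
  for (i in fids) for (j in fids) {
    if (i == j) next
    x <- integer(400)
    x[ev$day[ev$host == i & ev$guest == j] + 1L] <- 1L
    if (sum(x) < 5) next
    ac <- c(ac, suppressWarnings(cor(x[-400], x[-1])))
  }
  ac <- ac[is.finite(ac)]
  expect_gt(length(ac), 30)
  expect_lt(abs(mean(ac)), 3 * sd(ac) / sqrt(length(ac)) + 0.01)
})

test_that("empirical dyadic rates converge to the ground-truth preferences", {
  # long single-guest simulation: inclusion probabilities are exact
  p <- simParams(nFamilies = 8, nDays = 5000, partySizeMean = 1,
                 recipStrength = 1, seasonal = 1, sigmaHost = 0.5,
                 baseHostRate = 0.1, seed = 13)
  v <- makeVillage(8, seed = 13, nDays = 5000)
  sim <- simulateEvents(v, p)
  P <- truePreferences(sim$truth, p)
  fids <- familyIds(v)
  emp <- matrix(0, 8, 8, dimnames = list(fids, fids))
  tab <- table(factor(sim$events$host, fids), factor(sim$events$guest, fids))
  emp[] <- tab / 5000
  off <- row(P) != col(P)
  tol <- 3 * sqrt(P * (1 - P) / 5000)
  expect_true(all(abs(emp[off] - P[off]) <= tol[off] + 1e-12))
})

test_that("the interview observer under-reports guests at the set rate", {
  p <- simParams(nFamilies = 15, nDays = 112, guestReportProb = 0.38,
                 seed = 8)
  v <- makeVillage(15, seed = 8, nDays = 112)
  sim <- simulateEvents(v, p)
  iv <- simulateInterviews(sim$events, v, p)
  # guest-role reports / guest-covered true attendances ~ 0.38: count per
  # (event, interview) exposure directly
  exposures <- 0L; reported <- 0L
  ivSet <- unique(iv[, c("reporter_family", "interview_day")])
  for (k in seq_len(nrow(ivSet))) {
    f <- ivSet$reporter_family[k]
    cov <- coveredDays(ivSet$interview_day[k], 112L)
    att <- sim$events[sim$events$guest == f & sim$events$day %in% cov, ]
    exposures <- exposures + nrow(att)
    if (nrow(att)) {
      rep <- iv[iv$reporter_family == f &
                  iv$interview_day == ivSet$interview_day[k] &
                  !is.na(iv$role) & iv$role == "guest", ]
      reported <- reported + nrow(rep)
    }
  }
  expect_gt(exposures, 100)
  phat <- reported / exposures
  expect_lt(abs(phat - 0.38), 3 * sqrt(0.38 * 0.62 / exposures))
  # no interviews at all: an empty record set and an all-zero panel
  p0 <- simParams(nFamilies = 15, nDays = 112, interviewRate = 0, seed = 8)
  iv0 <- simulateInterviews(sim$events, v, p0)
  expect_equal(nrow(iv0), 0L)
  panel0 <- buildPanel(v, iv0, iv0[0, 1:3] |>
                         setNames(c("host", "guest", "day")))
  expect_equal(sum(observable(panel0)), 0)
})

test_that("lossless observation recovers the true events exactly", {
  p <- simParams(nFamilies = 6, nDays = 28, guestReportProb = 1,
                 interviewRate = 7, seed = 10)
  v <- makeVillage(6, seed = 10, nDays = 28)
  sim <- simulateEvents(v, p)
  iv <- simulateInterviews(sim$events, v, p)
  panel <- buildPanel(v, iv, reconcileReports(iv, seed = 1))
  covered <- observable(panel)
  fids <- familyIds(v)
  key <- paste(hostIds(panel), guestIds(panel))
  for (k in seq_len(nrow(sim$events))) {
    ri <- match(paste(sim$events$host[k], sim$events$guest[k]), key)
    if (covered[ri, sim$events$day[k] + 1L] == 1L)
      expect_equal(hostings(panel)[ri, sim$events$day[k] + 1L], 1L)
  }
  # and no spurious events appear
  expect_lte(sum(hostings(panel)), nrow(sim$events))
})

test_that("simulated panels always satisfy h <= o", {
  for (s in 1:3) {
    st <- simulateStudy(simParams(nFamilies = 10, nDays = 56, seed = s))
    expect_true(all(hostings(st$panel) <= observable(st$panel)))
    expect_true(validObject(st$panel))
  }
})

test_that("the injected kernel raises short-lag returns where it acts", {
  # direct generator property: under rho = 3 among non-close kin, the
  # fraction of true events that are returns (the reverse event occurred
  # within the 3 preceding days) rises relative to rho = 1, and only for
  # the class the kernel targets; the full detection experiment lives in
  # the acceptance suite
  returnFrac <- function(ev, R) {
    isReturn <- vapply(seq_len(nrow(ev)), function(k) {
      any(ev$host == ev$guest[k] & ev$guest == ev$host[k] &
            ev$day >= ev$day[k] - 3 & ev$day < ev$day[k])
    }, TRUE)
    r <- R[cbind(ev$host, ev$guest)]
    notClose <- is.na(r) | r < 0.25
    mean(isReturn[notClose])
  }
  fr1 <- c(); fr3 <- c()
  for (s in 1:2) {
    v <- makeVillage(35, seed = s, nDays = 112)
    R <- familyRelatedness(v)
    e1 <- simulateEvents(v, simParams(seed = s, recipStrength = 1))$events
    e3 <- simulateEvents(v, simParams(seed = s, recipStrength = 3))$events
    fr1 <- c(fr1, returnFrac(e1, R))
    fr3 <- c(fr3, returnFrac(e3, R))
  }
  expect_gt(mean(fr3), mean(fr1) * 1.5)
})
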