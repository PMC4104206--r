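# Risk-day design assembly, hierarchical fits, AIC selection, permutation.

makeSmallStudy <- function(seed = 5, nFamilies = 10, nDays = 42, ...) {
  st <- simulateStudy(simParams(nFamilies = nFamilies, nDays = nDays,
                                seed = seed, ...))
  st$relmat <- familyRelatedness(st$village)
  st$distmat <- familyDistances(st$village)
  st
}

test_that("design rows are exactly the observable cells with features", {
  st <- makeSmallStudy()
  tab <- assembleDesign(st$panel, st$village, st$relmat, st$distmat)
  expect_equal(nrow(tab), sum(observable(st$panel)))
  expect_equal(sum(tab$h), sum(hostings(st$panel)))
  # spot-check one row's features against first principles
  k <- which(tab$h == 1)[1]
  fam <- families(st$village)
  i <- match(tab$host[k], fam$family_id); j <- match(tab$guest[k],
                                                    fam$family_id)
  expect_equal(tab$logDist[k],
               log(max(sphericalDistance(fam$lat[i], fam$lon[i],
                                         fam$lat[j], fam$lon[j]), 0.01)))
  expect_equal(tab$relatedness[k], st$relmat[tab$host[k], tab$guest[k]])
  expect_equal(tab$hostAge[k],
               mean(c(fam$head_age1[i], fam$head_age2[i]), na.rm = TRUE))
  expect_equal(tab$hostAge2[k], tab$hostAge[k]^2)
  # reciprocal rate equals reverse-dyad events over reverse-dyad risk days
  ri <- pairIndex(st$panel, tab$guest[k], tab$host[k])
  expect_equal(tab$recipRate[k],
               sum(hostings(st$panel)[ri, ]) /
                 sum(observable(st$panel)[ri, ]))
  # empty panel gives an empty table
  v <- tinyVillage()
  rec0 <- validateInterviews(fullCoverageInterviews(v)[0, ], v)
  p0 <- buildPanel(v, rec0, data.frame(host = character(),
                                       guest = character(),
                                       day = integer()))
  expect_equal(nrow(assembleDesign(p0, v, familyRelatedness(v),
                                   familyDistances(v))), 0L)
})

test_that("design row counts match brute-force enumeration on a toy study", {
  v <- makeVillage(4, seed = 30, nDays = 6)
  fids <- familyIds(v)
  rec <- validateInterviews(data.frame(
    reporter_family = c("F01", "F02", "F03"),
    interview_day = c(2L, 3L, 5L),
    role = NA_character_, partner_family = NA_character_,
    event_day = NA_integer_), v)
  panel <- buildPanel(v, rec, data.frame(host = character(),
                                         guest = character(),
                                         day = integer()))
  tab <- assembleDesign(panel, v, familyRelatedness(v), familyDistances(v))
  # brute force: enumerate (i, j, t), count coverage by either party
  expect_equal(nrow(tab), bruteRiskDays(v, rec))
  got <- sort(paste(tab$host, tab$guest, tab$day))
  want <- character(0)
  for (i in fids) for (j in fids) for (t in 0:5) {
    if (i == j) next
    cov <- function(f) any(vapply(
      rec$interview_day[rec$reporter_family == f],
      function(d) t %in% coveredDays(d, 6L), TRUE))
    if (cov(i) || cov(j)) want <- c(want, paste(i, j, t))
  }
  expect_equal(got, sort(want))
})

test_that("the glm path agrees with a direct glm fit and flags degeneracy", {
  set.seed(31)
  n <- 500
  tab <- data.frame(h = rbinom(n, 1, 0.15), guestOnly = rbinom(n, 1, 0.4),
                    week = factor(rep(0:1, length.out = n)))
  spec <- modelSpec(c("weeks", "guestOnly"), random = character())
  f <- fitHierLogistic(tab, spec)
  ref <- glm(h ~ week + guestOnly, data = tab, family = binomial())
  expect_equal(fixedEffects(f), coef(ref))
  expect_equal(f@aic, AIC(ref))
  expect_equal(oddsRatios(f), exp(coef(ref)))
  expect_true(f@converged)
  # degenerate outcome is flagged, not silent
  tab$h <- 0L
  fd <- fitHierLogistic(tab, spec)
  expect_false(fd@converged)
  expect_match(paste(fd@messages, collapse = " "), "degenerate")
})

test_that("crossed random intercepts recover an injected dyad variance", {
  # dyad-effect world on a realistic observation mask, single seed here
  # (the multi-seed recovery experiment is in the acceptance suite)
  st <- makeSmallStudy(seed = 41, nFamilies = 12, nDays = 56)
  o <- observable(st$panel)
  cells <- which(o == 1L)
  rc <- arrayInd(cells, dim(o))
  set.seed(41)
  alpha <- rnorm(nrow(o), 0, sqrt(2.5))
  tab <- data.frame(h = rbinom(length(cells), 1,
                               plogis(-4 + alpha[rc[, 1]])),
                    dyad = rownames(o)[rc[, 1]])
  f <- fitHierLogistic(tab, modelSpec(character(), random = "dyad"))
  expect_true(f@converged)
  expect_lt(abs(varComponents(f)["dyad"] - 2.5) / 2.5, 0.6)
  expect_equal(unname(oddsRatios(f)), unname(exp(fixedEffects(f))))
})

test_that("guest under-reporting surfaces as an odds ratio below one", {
  st <- makeSmallStudy(seed = 12, nFamilies = 15, nDays = 84,
                       guestReportProb = 0.38)
  tab <- assembleDesign(st$panel, st$village, st$relmat, st$distmat)
  f <- fitHierLogistic(tab, standardSpecs("A")$A, nAGQ = 0)
  expect_lt(oddsRatios(f)["guestOnly"], 1)
})

test_that("variance-explained accounting is exact arithmetic", {
  expect_equal(varianceExplained(2.817, 1.166), 59)
  expect_equal(varianceExplained(2.817, 2.817), 0)
  expect_error(varianceExplained(0, 1), "positive")
})

test_that("AIC selection prefers true age structure and breaks ties small", {
  # outcome driven by a quadratic host-age effect on a real design
  st <- makeSmallStudy(seed = 17, nFamilies = 14, nDays = 70)
  tab <- assembleDesign(st$panel, st$village, st$relmat, st$distmat)
  set.seed(17)
  eta <- -4.5 + 0.28 * (tab$hostAge - 30) - 0.006 * (tab$hostAge - 30)^2
  tab$h <- rbinom(nrow(tab), 1, plogis(eta))
  cand <- list(
    modelSpec("guestOnly", random = character(), label = "controls"),
    modelSpec(c("guestOnly", "hostAge", "hostAge2"), random = character(),
              label = "ages"))
  sel <- aicSelect(tab, cand)
  expect_equal(sel$spec@label, "ages")
  expect_equal(nrow(sel$aicTable), 2)
  # single candidate comes straight back
  one <- aicSelect(tab, cand[1])
  expect_equal(one$spec@label, "controls")
  # the AIC table matches independent refits
  refit <- vapply(cand, function(s) fitHierLogistic(tab, s)@aic, 0)
  expect_equal(sel$aicTable$aic, refit)
})

test_that("permutation p-values respect the add-one floor and find effects", {
  set.seed(23)
  n <- 700
  tab <- data.frame(logDist = rnorm(n))
  tab$h <- rbinom(n, 1, 0.12)                    # no real effect
  spec <- modelSpec("logDist", random = character())
  f0 <- permutationSignificance(tab, spec, nPerm = 99, seed = 1)
  expect_true(all(permP(f0) >= 1 / 100))
  expect_true(all(permP(f0) <= 1))
  # determinism
  f0b <- permutationSignificance(tab, spec, nPerm = 99, seed = 1)
  expect_identical(permP(f0), permP(f0b))
  # a strong injected effect is detected at the resolution limit
  tab$h <- rbinom(n, 1, plogis(-2 + 1.5 * tab$logDist))
  f1 <- permutationSignificance(tab, spec, nPerm = 199, seed = 2)
  expect_lte(permP(f1)["logDist"], 0.01)
})
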