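# Windowed pair counts, the reciprocity ratio, the null hierarchy.

test_that("pair counts match hand enumeration and saturate when h == o", {
  # full observation, 10 days, lag 1: nine adjacent day pairs
  p <- toyPanel(hij = rep(0L, 10), hji = rep(0L, 10))
  cnt <- pairCounts(p, "A", "B", lags = 1)
  expect_equal(cnt$Noo, 9)
  expect_equal(cnt$Nhh, 0)
  # explicit 4-day fixture, counted by hand:
  # h_AB = 1 0 1 0 ; h_BA = 0 1 0 0 ; o_AB = 1 1 1 1 ; o_BA = 1 1 1 0
  p2 <- toyPanel(hij = c(1L, 0L, 1L, 0L), hji = c(0L, 1L, 0L, 0L),
                 oij = c(1L, 1L, 1L, 1L), oji = c(1L, 1L, 1L, 0L))
  c2 <- pairCounts(p2, "A", "B", lags = 1:2)
  # lag 1: pairs (t, t+1) in {(1,2),(2,3),(3,4)}
  expect_equal(c2[c2$lag == 1, c("Nhh", "Noo", "Nho", "Noh")],
               data.frame(Nhh = 1, Noo = 2, Nho = 1, Noh = 1),
               ignore_attr = TRUE)
  # lag 2: pairs {(1,3),(2,4)}
  expect_equal(c2[c2$lag == 2, c("Nhh", "Noo", "Nho", "Noh")],
               data.frame(Nhh = 0, Noo = 1, Nho = 1, Noh = 0),
               ignore_attr = TRUE)
  # saturation: h == o collapses all four counts
  p3 <- toyPanel(hij = c(1L, 0L, 1L), hji = c(0L, 1L, 1L),
                 oij = c(1L, 0L, 1L), oji = c(0L, 1L, 1L))
  c3 <- pairCounts(p3, "A", "B", lags = 1:2)
  expect_equal(c3$Nhh, c3$Noo)
  expect_equal(c3$Nho, c3$Noo)
  expect_equal(c3$Noh, c3$Noo)
  # count inequalities hold everywhere
  expect_true(all(c2$Nhh <= pmin(c2$Nho, c2$Noh)))
  expect_true(all(pmax(c2$Nho, c2$Noh) <= c2$Noo))
})

test_that("the reciprocity ratio follows its closed form and flags NA", {
  expect_equal(rhat(data.frame(Nhh = 2, Noo = 100, Nho = 10, Noh = 10)), 2)
  expect_true(is.na(rhat(data.frame(Nhh = 0, Noo = 5, Nho = 0, Noh = 2))))
  expect_true(is.na(rhat(data.frame(Nhh = 0, Noo = 5, Nho = 2, Noh = 0))))
  expect_equal(rhat(data.frame(Nhh = 0, Noo = 5, Nho = 2, Noh = 2)), 0)
})

test_that("independent coin-flip hosting gives a ratio near one", {
  set.seed(55)
  T <- 6000
  p <- toyPanel(hij = rbinom(T, 1, 0.25), hji = rbinom(T, 1, 0.3))
  r <- rhat(pairCounts(p, "A", "B", lags = 1))
  expect_lt(abs(r - 1), 0.1)
})

test_that("pooling sums counts before the ratio", {
  cnt <- data.frame(lag = 1:3, Nhh = c(2, 2, 2), Noo = c(50, 50, 50),
                    Nho = c(10, 10, 10), Noh = c(8, 8, 8))
  expect_equal(pooledRhat(cnt), rhat(cnt[1, ]))
  # all-zero numerators with open windows pool to zero
  cnt$Nhh <- 0
  expect_equal(pooledRhat(cnt), 0)
  # pooled equals brute-force pooling on a toy panel
  set.seed(77)
  oij <- rbinom(12, 1, 0.8); oji <- rbinom(12, 1, 0.8)
  p <- toyPanel(hij = rbinom(12, 1, 0.4) * oij,
                hji = rbinom(12, 1, 0.4) * oji, oij = oij, oji = oji)
  cc <- pairCounts(p, "A", "B", lags = 1:3)
  s <- colSums(cc[, c("Nhh", "Noo", "Nho", "Noh")])
  manual <- if (s["Nho"] > 0 && s["Noh"] > 0)
    s[["Nhh"]] * s[["Noo"]] / (s[["Nho"]] * s[["Noh"]]) else NA_real_
  expect_equal(pooledRhat(cc), manual)
})

test_that("the estimator equals brute-force conditional counting", {
  # exhaustive sweep: every h configuration on a 4-day fully observed pair
  for (code in 0:255) {
    bits <- as.integer(intToBits(code))[1:8]
    p <- toyPanel(hij = bits[1:4], hji = bits[5:8])
    for (lag in 1:2) {
      cnt <- pairCounts(p, "A", "B", lags = lag)
      expect_equal(rhat(cnt),
                   bruteRhat(bits[1:4], bits[5:8], rep(1L, 4), rep(1L, 4),
                             lag))
    }
  }
  # random panels up to 6 days with irregular observation windows
  set.seed(66)
  for (rep in 1:300) {
    T <- sample(3:6, 1)
    oij <- rbinom(T, 1, 0.7); oji <- rbinom(T, 1, 0.7)
    hij <- rbinom(T, 1, 0.5) * oij; hji <- rbinom(T, 1, 0.5) * oji
    p <- toyPanel(hij, hji, oij, oji)
    lag <- sample(1:3, 1)
    expect_equal(rhat(pairCounts(p, "A", "B", lags = lag)),
                 bruteRhat(hij, hji, oij, oji, lag))
  }
})

test_that("null fitting preserves the margins each level declares", {
  st <- simulateStudy(simParams(nFamilies = 8, nDays = 56, seed = 31))
  R <- familyRelatedness(st$village)
  h <- hostings(st$panel); o <- observable(st$panel)
  host <- hostIds(st$panel)
  for (lv in c("homogeneous", "kin_heterogeneous", "full_heterogeneous")) {
    null <- fitNull(st$panel, R, lv)
    # expected events under the null on the observed mask reproduce the
    # observed per-host totals (whole-sample margin preservation), and the
    # finer levels nest: they preserve every coarser margin too
    # exact up to the clamp of per-cell probabilities at one
    expEv <- rowSums(null@prob * o)
    perHost <- tapply(expEv, host, sum)
    obsHost <- tapply(rowSums(h), host, sum)
    expect_lt(max(abs(perHost - obsHost) / pmax(obsHost, 1)), 0.02)
    if (lv == "full_heterogeneous")
      expect_lt(max(abs(rowSums(null@prob * o) - rowSums(h)) /
                      pmax(rowSums(h), 1)), 0.02)
    if (lv == "kin_heterogeneous") {
      strat <- paste(host, null@strata)
      expect_lt(max(abs(tapply(expEv, strat, sum) -
                          tapply(rowSums(h), strat, sum)) /
                      pmax(tapply(rowSums(h), strat, sum), 1)), 0.02)
    }
  }
  expect_error(fitNull(st$panel, R, "bogus"))
})

test_that("single-stratum hosts collapse the kin level to the homogeneous", {
  # village of founders: every dyad has r = 0, one stratum per host
  v <- makeVillage(2, seed = 9, nDays = 20)
  fids <- familyIds(v)
  rec <- validateInterviews(fullCoverageInterviews(v), v)
  ev <- data.frame(host = fids[c(1, 1, 2)], guest = fids[c(2, 2, 1)],
                   day = c(1L, 5L, 9L))
  ev <- unique(ev)
  panel <- buildPanel(v, rec, ev)
  R <- familyRelatedness(v)
  nh <- fitNull(panel, R, "homogeneous")
  nk <- fitNull(panel, R, "kin_heterogeneous")
  expect_equal(nh@prob, nk@prob, tolerance = 1e-12)
})

test_that("a monopolist host is assigned its observed party rate", {
  # family A hosts a party of size 2 every single day, fully observed
  v <- makeVillage(4, seed = 9, nDays = 14)
  fids <- familyIds(v)
  rec <- validateInterviews(fullCoverageInterviews(v), v)
  ev <- expand.grid(guest = fids[2:3], day = 0:13,
                    stringsAsFactors = FALSE)
  ev$host <- fids[1]
  panel <- buildPanel(v, rec, ev[, c("host", "guest", "day")])
  null <- fitNull(panel, familyRelatedness(v), "full_heterogeneous")
  # implied party probability for A is 1 and party size mass sits at 2
  pA <- null@prob[hostIds(panel) == fids[1], ]
  expect_equal(sort(unique(round(rowMeans(pA), 10))), c(0, 1))
  expect_equal(mean(colSums(pA)), 2)
})

test_that("null sampling matches its probabilities and respects the mask", {
  st <- simulateStudy(simParams(nFamilies = 8, nDays = 56, seed = 33))
  R <- familyRelatedness(st$village)
  null <- fitNull(st$panel, R, "full_heterogeneous")
  o <- observable(st$panel)
  ens <- sampleNull(null, o, nRealizations = 200, seed = 5)
  expect_length(ens@events, 200)
  counts <- vapply(seq_len(200), function(k) nrow(ens@events[[k]]), 0L)
  expEv <- sum(null@prob * o)
  sdEv <- sqrt(sum(null@prob * o * (1 - null@prob * o)))
  expect_lt(abs(mean(counts) - expEv), 3 * sdEv / sqrt(200))
  # all sampled cells lie on the mask
  H <- nullRealization(ens, 1)
  expect_true(all(H <= o))
  # a dead mask yields empty realizations
  ens0 <- sampleNull(null, o * 0L, nRealizations = 3, seed = 5)
  expect_true(all(vapply(ens0@events, nrow, 0L) == 0L))
})

test_that("class curves renormalize cleanly and handle sparse classes", {
  st <- simulateStudy(simParams(nFamilies = 12, nDays = 84, seed = 35))
  R <- familyRelatedness(st$village)
  null <- fitNull(st$panel, R, "full_heterogeneous")
  ens <- sampleNull(null, observable(st$panel), 60, seed = 7)
  cv <- suppressMessages(classCurve(st$panel, ens, R, "all", lags = 1:5))
  tb <- curveTable(cv)
  expect_equal(nrow(tb), 5)
  expect_true(all(tb$p > 0 & tb$p <= 1, na.rm = TRUE))
  expect_true(all(tb$lo2 <= tb$lo1 & tb$hi1 <= tb$hi2, na.rm = TRUE))
  expect_true(is.finite(pooledStat(cv)$observed))
  # a class with no qualifying pairs errors with its name
  Rzero <- R; Rzero[] <- 0; diag(Rzero) <- NA
  expect_error(
    suppressMessages(classCurve(st$panel, ens, Rzero, "close_kin",
                                lags = 1:5)),
    "close_kin")
  # a single-pair class with undefined lags reports NA without crashing
  v <- tinyVillage(nDays = 10L)
  rec <- validateInterviews(fullCoverageInterviews(v), v)
  ev <- data.frame(host = c("F1", "F2"), guest = c("F2", "F1"),
                   day = c(0L, 9L))
  panel <- buildPanel(v, rec, ev)
  Rt <- familyRelatedness(v)
  nullt <- fitNull(panel, Rt, "homogeneous")
  enst <- sampleNull(nullt, observable(panel), 30, seed = 2)
  cvt <- suppressMessages(classCurve(panel, enst, Rt, "all", lags = 1:3))
  expect_true(all(is.na(curveTable(cvt)$observed) |
                    is.finite(curveTable(cvt)$observed)))
})

test_that("analyzing data generated by a null yields a calibrated curve", {
  # one-seed spot check (the three-level calibration experiment at study
  # scale runs in the acceptance suite)
  st <- simulateStudy(simParams(nFamilies = 12, nDays = 84, seed = 36,
                                recipStrength = 1))
  R <- familyRelatedness(st$village)
  null <- fitNull(st$panel, R, "full_heterogeneous")
  ens <- sampleNull(null, observable(st$panel), 150, seed = 8)
  cv <- suppressMessages(classCurve(st$panel, ens, R, "all", lags = 1:3))
  ps <- pooledStat(cv)
  expect_gt(ps$p, 0.02)    # not spuriously significant
  expect_lt(abs(ps$observed - ps$nullMean),
            3 * (ps$hi2 - ps$lo2) / 4 + 0.5)
})
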