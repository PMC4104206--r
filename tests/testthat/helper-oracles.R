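# Independent oracles used across the suite.  These deliberately take the
# slow, literal route (explicit loops, direct counting, Monte-Carlo) so
# they share no code with the implementation they check.

# Gene-dropping Monte-Carlo estimate of the kinship coefficient phi(a, b):
# founders carry unique alleles, each child inherits one random allele per
# parent, and phi is the probability that one random allele of a is
# identical by descent to one random allele of b.
geneDropPhi <- function(ped, a, b, nReps = 20000, seed = 99) {
  set.seed(seed)
  ids <- ped$individual_id
  fa <- match(ped$father_id, ids)
  mo <- match(ped$mother_id, ids)
  # order parents before children
  ord <- integer(0)
  placed <- logical(length(ids))
  while (length(ord) < length(ids)) {
    ready <- which(!placed & (is.na(fa) | placed[fa]) &
                     (is.na(mo) | placed[mo]))
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  ia <- match(a, ids); ib <- match(b, ids)
  hits <- 0
  for (r in seq_len(nReps)) {
    al1 <- integer(length(ids)); al2 <- integer(length(ids))
    nextAllele <- 0L
    for (k in ord) {
      if (is.na(fa[k])) {
        al1[k] <- (nextAllele <- nextAllele + 1L)
      } else {
        al1[k] <- if (runif(1) < 0.5) al1[fa[k]] else al2[fa[k]]
      }
      if (is.na(mo[k])) {
        al2[k] <- (nextAllele <- nextAllele + 1L)
      } else {
        al2[k] <- if (runif(1) < 0.5) al1[mo[k]] else al2[mo[k]]
      }
    }
    pick <- function(i) if (runif(1) < 0.5) al1[i] else al2[i]
    hits <- hits + (pick(ia) == pick(ib))
  }
  hits / nReps
}

# Direct conditional-probability computation of the reciprocity ratio by
# explicit looping over day pairs: P(h_ji at t+d | h_ij at t) / P(h_ji),
# each probability estimated by counting over the jointly observable
# window.
bruteRhat <- function(hij, hji, oij, oji, lag) {
  T <- length(hij)
  nCond <- 0; nCondHit <- 0; nBase <- 0; nBaseHit <- 0
  for (t in seq_len(T)) {
    tp <- t + lag
    if (tp > T) next
    # conditional probability: j hosts i at t+lag given i hosted j at t,
    # counted over days where the return event was observable
    if (hij[t] == 1 && oji[tp] == 1) {
      nCond <- nCond + 1
      if (hji[tp] == 1) nCondHit <- nCondHit + 1
    }
    # base rate of "j hosts i", counted over jointly observable day pairs
    if (oij[t] == 1 && oji[tp] == 1) nBase <- nBase + 1
    if (oij[t] == 1 && hji[tp] == 1) nBaseHit <- nBaseHit + 1
  }
  if (nCond == 0 || nBaseHit == 0 || nBase == 0) return(NA_real_)
  (nCondHit / nCond) / (nBaseHit / nBase)
}

# Exhaustive count of observable (i, j, t) cells from first principles.
bruteRiskDays <- function(village, records) {
  fids <- familyIds(village)
  total <- 0L
  covers <- function(f, t) {
    iv <- records[records$reporter_family == f, , drop = FALSE]
    any(vapply(unique(iv$interview_day), function(d)
      t %in% coveredDays(d, nDays(village)), TRUE))
  }
  for (i in fids) for (j in fids) {
    if (i == j) next
    for (t in seq_len(nDays(village)) - 1L)
      if (covers(i, t) || covers(j, t)) total <- total + 1L
  }
  total
}

# A tiny hand-buildable panel: supply explicit h/o (and optionally
# guest-only) bit matrices for a two-family village.
toyPanel <- function(hij, hji, oij = NULL, oji = NULL, gij = NULL,
                     gji = NULL) {
  T <- length(hij)
  if (is.null(oij)) oij <- rep(1L, T)
  if (is.null(oji)) oji <- rep(1L, T)
  h <- rbind(hij, hji)
  o <- rbind(oij, oji)
  g <- rbind(if (is.null(gij)) rep(0L, T) else gij,
             if (is.null(gji)) rep(0L, T) else gji)
  EventPanel(h, o, g, host = c("A", "B"), guest = c("B", "A"),
             days = 0:(T - 1L))
}
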