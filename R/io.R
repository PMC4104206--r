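#' Read a village from families and pedigree files
#'
#' The families file is a CSV with header
#' \code{family_id,member_ids,head_ages,size,lat,lon}, where
#' \code{member_ids} and \code{head_ages} are \code{;}-separated.  The
#' pedigree file is a PED-like headerless TSV with columns family_id,
#' individual_id, father_id, mother_id, sex, using \code{0} for a missing
#' parent.  Parents referenced but not listed are treated as founders with
#' a warning.
#'
#' @param familiesPath,pedigreePath input files.
#' @param nDays study-window length in days (not stored in the files).
#' @return a validated \linkS4class{Village}.
#' @export
readVillage <- function(familiesPath, pedigreePath, nDays = 112L) {
  stopifnot(file.exists(familiesPath), file.exists(pedigreePath))
  fam <- read.csv(familiesPath, colClasses = "character")
  if (nrow(fam) == 0L) stop("empty family file: zero families listed")
  if (anyDuplicated(fam$family_id))
    stop("duplicate family ids: ",
         paste(unique(fam$family_id[duplicated(fam$family_id)]),
               collapse = ", "))
  ages <- strsplit(fam$head_ages, ";", fixed = TRUE)
  if (!all(lengths(ages) %in% 1:2))
    stop("head_ages must hold 1 or 2 values per family")
  ped <- read.delim(pedigreePath, header = FALSE, colClasses = "character",
                    col.names = c("family_id", "individual_id", "father_id",
                                  "mother_id", "sex"))
  if (anyDuplicated(ped$individual_id))
    stop("duplicate individual ids: ",
         paste(unique(ped$individual_id[duplicated(ped$individual_id)]),
               collapse = ", "))
  ped$father_id[ped$father_id == "0"] <- NA
  ped$mother_id[ped$mother_id == "0"] <- NA
  unknown <- setdiff(stats::na.omit(c(ped$father_id, ped$mother_id)),
                     ped$individual_id)
  if (length(unknown))
    warning("parents not in pedigree treated as founders: ",
            paste(unknown, collapse = ", "))
  .pedigreeOrder(ped)   # errors on cycles
  members <- strsplit(fam$member_ids, ";", fixed = TRUE)
  declared <- as.integer(fam$size)
  if (!identical(declared, lengths(members)))
    stop("size must equal the number of member_ids")
  # membership declared in the families file must match the pedigree
  for (k in seq_len(nrow(fam))) {
    inPed <- ped$individual_id[ped$family_id == fam$family_id[k]]
    if (!setequal(inPed, members[[k]]))
      stop("family ", fam$family_id[k],
           ": member_ids disagree with pedigree membership")
  }
  famDf <- data.frame(
    family_id = fam$family_id,
    size = declared,
    head_age1 = vapply(ages, function(a) as.numeric(a[1]), 0),
    head_age2 = vapply(ages, function(a)
      if (length(a) > 1) as.numeric(a[2]) else NA_real_, 0),
    lat = as.numeric(fam$lat), lon = as.numeric(fam$lon),
    stringsAsFactors = FALSE)
  ped$sex <- as.integer(ped$sex)
  ped <- ped[, c("individual_id", "father_id", "mother_id", "sex",
                 "family_id")]
  Village(famDf, ped, nDays)
}

#' Write a village in the format read by \code{readVillage}
#' @param village a \linkS4class{Village}.
#' @param familiesPath,pedigreePath output files.
#' @export
writeVillage <- function(village, familiesPath, pedigreePath) {
  fam <- families(village)
  ped <- pedigree(village)
  mem <- vapply(fam$family_id, function(f)
    paste(memberIds(village, f), collapse = ";"), "")
  ha <- ifelse(is.na(fam$head_age2), as.character(fam$head_age1),
               paste(fam$head_age1, fam$head_age2, sep = ";"))
  out <- data.frame(family_id = fam$family_id, member_ids = mem,
                    head_ages = ha, size = fam$size,
                    lat = fam$lat, lon = fam$lon)
  write.csv(out, familiesPath, row.names = FALSE, quote = FALSE)
  pedOut <- data.frame(fam = ped$family_id, id = ped$individual_id,
                       father = ifelse(is.na(ped$father_id), "0",
                                       ped$father_id),
                       mother = ifelse(is.na(ped$mother_id), "0",
                                       ped$mother_id),
                       sex = ped$sex)
  write.table(pedOut, pedigreePath, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(c(familiesPath, pedigreePath))
}

#' Covered days of an interview
#'
#' An interview on day d covers exactly the two preceding days,
#' {d-2, d-1}, clipped to the study window.
#' @param interviewDay integer day index.
#' @param nDays study length.
#' @return integer vector of covered day indices.
#' @export
coveredDays <- function(interviewDay, nDays) {
  d <- c(interviewDay - 2L, interviewDay - 1L)
  d[d >= 0L & d < nDays]
}

#' Read interview records
#'
#' CSV with header
#' \code{reporter_family,interview_day,role,partner_family,event_day}; one
#' row per reported event, and rows with empty role/partner recording an
#' interview at which no events were reported.
#'
#' @param path CSV file.
#' @param village a \linkS4class{Village}; partner families must exist in
#'   it and reported event days must fall within the interview's covered
#'   days.
#' @return data.frame of records sorted by interview day (an empty file
#'   yields a zero-row data.frame).
#' @export
readInterviews <- function(path, village) {
  stopifnot(file.exists(path))
  df <- read.csv(path, colClasses = c("character", "integer", "character",
                                      "character", "integer"))
  validateInterviews(df, village)
}

#' Validate and normalize an interview table
#' @param df data.frame in the \code{readInterviews} layout.
#' @param village a \linkS4class{Village}.
#' @return the sorted, validated data.frame.
#' @export
validateInterviews <- function(df, village) {
  need <- c("reporter_family", "interview_day", "role", "partner_family",
            "event_day")
  stopifnot(all(need %in% names(df)))
  if (nrow(df) == 0L) return(df[, need])
  df$role[is.na(df$role) | df$role == ""] <- NA
  df$partner_family[is.na(df$partner_family) |
                      df$partner_family == ""] <- NA
  if (any(!is.na(df$role) & is.na(df$partner_family)))
    stop("reported events must name a partner family")
  fids <- familyIds(village)
  bad <- setdiff(stats::na.omit(unique(c(df$reporter_family,
                                         df$partner_family))), fids)
  if (length(bad))
    stop("unknown family id in interviews: ", paste(bad, collapse = ", "))
  if (!all(is.na(df$role) | df$role %in% c("host", "guest")))
    stop("role must be host, guest or empty")
  has <- which(!is.na(df$role))
  for (k in has) {
    cov <- coveredDays(df$interview_day[k], nDays(village))
    if (!df$event_day[k] %in% cov)
      stop("row ", k, ": event day ", df$event_day[k],
           " outside the days covered by an interview on day ",
           df$interview_day[k])
  }
  df <- df[order(df$interview_day, df$reporter_family, df$role,
                 df$partner_family, df$event_day), need]
  rownames(df) <- NULL
  df
}

#' @rdname readInterviews
#' @param records interview data.frame.
#' @export
writeInterviews <- function(records, path) {
  out <- records
  out$role[is.na(out$role)] <- ""
  out$partner_family[is.na(out$partner_family)] <- ""
  out$event_day[is.na(out$event_day)] <- ""
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reconcile host and guest reports into a single event list
#'
#' A dyad-day counts as an event if either party reported it (positive
#' reports win over silence).  When the host and the guest of the same
#' unordered pair report the same apparent event under divergent dates --
#' a host-only report and a guest-only report of complementary roles at
#' most two days apart, with no confirmed counterpart on either date --
#' exactly one of the two dates is kept, chosen uniformly at random under
#' \code{seed}.  Identical duplicate reports merge silently.
#'
#' @param records validated interview data.frame.
#' @param seed integer seed for the divergent-date tie-breaks.
#' @return data.frame with columns \code{host}, \code{guest}, \code{day},
#'   deduplicated and sorted.
#' @export
reconcileReports <- function(records, seed = 1L) {
  empty <- data.frame(host = character(), guest = character(),
                      day = integer())
  if (nrow(records) == 0L) return(empty)
  rep <- records[!is.na(records$role), , drop = FALSE]
  if (nrow(rep) == 0L) return(empty)
  host <- ifelse(rep$role == "host", rep$reporter_family,
                 rep$partner_family)
  guest <- ifelse(rep$role == "host", rep$partner_family,
                  rep$reporter_family)
  cand <- unique(data.frame(host = host, guest = guest, day = rep$event_day,
                            source = rep$role, stringsAsFactors = FALSE))
  key <- function(d) paste(d$host, d$guest, d$day)
  hostK <- key(cand[cand$source == "host", ])
  guestK <- key(cand[cand$source == "guest", ])
  ev <- unique(cand[, c("host", "guest", "day")])
  ev <- ev[order(ev$host, ev$guest, ev$day), ]
  # divergent-date candidates: single-sourced reports of the same ordered
  # pair with complementary roles and dates <= 2 days apart
  hostOnly <- cand[cand$source == "host" & !key(cand) %in% guestK, ]
  guestOnly <- cand[cand$source == "guest" & !key(cand) %in% hostK, ]
  hostOnly <- hostOnly[order(hostOnly$host, hostOnly$guest, hostOnly$day), ]
  guestOnly <- guestOnly[order(guestOnly$host, guestOnly$guest,
                               guestOnly$day), ]
  drop <- character(0)
  if (nrow(hostOnly) && nrow(guestOnly)) {
    set.seed(seed)
    usedG <- logical(nrow(guestOnly))
    for (k in seq_len(nrow(hostOnly))) {
      m <- which(!usedG &
                 guestOnly$host == hostOnly$host[k] &
                 guestOnly$guest == hostOnly$guest[k] &
                 guestOnly$day != hostOnly$day[k] &
                 abs(guestOnly$day - hostOnly$day[k]) <= 2L)
      if (!length(m)) next
      m <- m[1L]
      usedG[m] <- TRUE
      loser <- if (runif(1) < 0.5) guestOnly[m, ] else hostOnly[k, ]
      drop <- c(drop, paste(loser$host, loser$guest, loser$day))
    }
  }
  ev <- ev[!key(ev) %in% drop, ]
  rownames(ev) <- NULL
  ev
}

#' @rdname reconcileReports
#' @param events event data.frame (host, guest, day).
#' @param path output CSV.
#' @export
writeEvents <- function(events, path) {
  write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname reconcileReports
#' @export
readEvents <- function(path) {
  read.csv(path, colClasses = c("character", "character", "integer"))
}

#' Build the hosting/observability panel
#'
#' For every ordered family pair (i, j) and day t: \code{o = 1} iff some
#' interview by i or j covered t; \code{h = 1} iff a reconciled event
#' (i, j, t) exists; \code{guestOnly = 1} iff t was covered by an interview
#' of the potential guest j but by none of the potential host i.  An event
#' on an uncovered dyad-day violates \code{h <= o} and is an error.
#'
#' @param village a \linkS4class{Village}.
#' @param records validated interview data.frame.
#' @param events reconciled events from \code{\link{reconcileReports}}.
#' @return an \linkS4class{EventPanel}.
#' @export
buildPanel <- function(village, records, events) {
  fids <- familyIds(village)
  nF <- length(fids)
  nT <- nDays(village)
  # per-family coverage from the union of its interviews
  cov <- matrix(FALSE, nF, nT, dimnames = list(fids, NULL))
  if (nrow(records)) {
    iv <- unique(records[, c("reporter_family", "interview_day")])
    for (k in seq_len(nrow(iv))) {
      d <- coveredDays(iv$interview_day[k], nT)
      cov[iv$reporter_family[k], d + 1L] <- TRUE
    }
  }
  hostIdx <- rep(seq_len(nF), each = nF)
  guestIdx <- rep(seq_len(nF), times = nF)
  keep <- hostIdx != guestIdx
  hostIdx <- hostIdx[keep]; guestIdx <- guestIdx[keep]
  o <- (cov[hostIdx, , drop = FALSE] | cov[guestIdx, , drop = FALSE]) * 1L
  g <- (cov[guestIdx, , drop = FALSE] & !cov[hostIdx, , drop = FALSE]) * 1L
  h <- matrix(0L, length(hostIdx), nT)
  if (nrow(events)) {
    ri <- match(paste(events$host, events$guest),
                paste(fids[hostIdx], fids[guestIdx]))
    if (anyNA(ri)) stop("event references unknown dyad")
    bad <- o[cbind(ri, events$day + 1L)] == 0L
    if (any(bad))
      stop("event on an uncovered dyad-day (h <= o violated): ",
           paste(paste(events$host, events$guest, events$day)[bad][1:min(3, sum(bad))],
                 collapse = "; "))
    h[cbind(ri, events$day + 1L)] <- 1L
  }
  EventPanel(h, o, g, host = fids[hostIdx], guest = fids[guestIdx],
             days = 0:(nT - 1L))
}

#' Export a panel in long tabular form
#'
#' Writes one row per dyad-day with columns i, j, t, h, o, guest_only,
#' gzip-compressed when the path ends in \code{.gz}.
#' @param panel an \linkS4class{EventPanel}.
#' @param path output file.
#' @param observableOnly drop cells with o = 0 (default TRUE).
#' @export
exportPanel <- function(panel, path, observableOnly = TRUE) {
  h <- hostings(panel); o <- observable(panel); g <- guestOnly(panel)
  idx <- if (observableOnly) which(o == 1L) else seq_along(o)
  rc <- arrayInd(idx, dim(o))
  df <- data.frame(i = hostIds(panel)[rc[, 1]],
                   j = guestIds(panel)[rc[, 1]],
                   t = SummarizedExperiment::colData(panel)$day[rc[, 2]],
                   h = h[idx], o = o[idx], guest_only = g[idx])
  df <- df[order(df$i, df$j, df$t), ]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summary rates of a hosting panel
#'
#' Rates are events per risk day at each aggregation level; units with zero
#' risk days get NA.  Also reports the variance across families of the
#' hosting and attendance rates, and the fraction of directed dyads with at
#' least one observed event.
#'
#' @param panel an \linkS4class{EventPanel}.
#' @return list with elements \code{overall} (events, riskDays, rate),
#'   \code{perFamily}, \code{perDyad}, \code{varHostRate},
#'   \code{varAttendRate}, \code{dyadsWithEvent},
#'   \code{fracDyadsWithEvent}.
#' @export
panelSummaries <- function(panel) {
  h <- hostings(panel); o <- observable(panel)
  host <- hostIds(panel); guest <- guestIds(panel)
  fids <- sort(unique(c(host, guest)))
  rateOf <- function(e, n) ifelse(n > 0, e / n, NA_real_)
  hostEv <- tapply(rowSums(h), host, sum)[fids]
  hostRk <- tapply(rowSums(o), host, sum)[fids]
  attEv <- tapply(rowSums(h), guest, sum)[fids]
  attRk <- tapply(rowSums(o), guest, sum)[fids]
  perFamily <- data.frame(
    family = fids,
    hostEvents = as.integer(hostEv), hostRiskDays = as.integer(hostRk),
    hostRate = rateOf(hostEv, hostRk),
    attendEvents = as.integer(attEv), attendRiskDays = as.integer(attRk),
    attendRate = rateOf(attEv, attRk), row.names = NULL)
  perDyad <- data.frame(host = host, guest = guest,
                        events = as.integer(rowSums(h)),
                        riskDays = as.integer(rowSums(o)),
                        rate = rateOf(rowSums(h), rowSums(o)))
  nEv <- sum(h); nRk <- sum(o)
  list(overall = data.frame(events = nEv, riskDays = nRk,
                            rate = rateOf(nEv, nRk)),
       perFamily = perFamily,
       perDyad = perDyad,
       varHostRate = var(perFamily$hostRate, na.rm = TRUE),
       varAttendRate = var(perFamily$attendRate, na.rm = TRUE),
       dyadsWithEvent = sum(perDyad$events > 0),
       fracDyadsWithEvent = sum(perDyad$events > 0) / nrow(perDyad))
}
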