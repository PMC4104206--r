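# Shared hand-built fixtures (all constructed in code).

# Four families:
#   F1 founder couple (A, B) with children C, D (C stays in F1)
#   F2 = C's child household: C married in-marrying founder E, child G
#   F3 = D's household: D married in-marrying founder Fq, child Hh
#   F4 unrelated founder couple (X, Y)
# So F2-F3 heads are full siblings; F4 unrelated to everyone.
tinyVillage <- function(nDays = 10L) {
  ped <- data.frame(
    individual_id = c("A", "B", "C0", "D0", "E0", "G0", "F0", "H0",
                      "X", "Y"),
    father_id = c(NA, NA, "A", "A", NA, "C0", NA, "D0", NA, NA),
    mother_id = c(NA, NA, "B", "B", NA, "E0", NA, "F0", NA, NA),
    sex = c(1L, 2L, 1L, 2L, 2L, 1L, 1L, 2L, 1L, 2L),
    family_id = c("F1", "F1", "F2", "F3", "F2", "F2", "F3", "F3",
                  "F4", "F4"),
    stringsAsFactors = FALSE)
  fam <- data.frame(
    family_id = c("F1", "F2", "F3", "F4"),
    size = c(2L, 3L, 3L, 2L),
    head_age1 = c(62, 35, 33, 58),
    head_age2 = c(60, 33, 31, 55),
    lat = c(-14.900, -14.901, -14.905, -14.930),
    lon = c(-66.300, -66.302, -66.299, -66.330),
    stringsAsFactors = FALSE)
  Village(fam, ped, nDays)
}

# Interviews giving full coverage of every day for every family: one
# interview two days after each covered pair of days.
fullCoverageInterviews <- function(village) {
  fids <- familyIds(village)
  nT <- nDays(village)
  idays <- unique(pmin(nT - 1L + 2L, seq(2L, nT + 1L, by = 2L)))
  # interviews on days 2, 4, ... cover {0,1}, {2,3}, ...; allow interview
  # day indices beyond the window end so the last days are covered too
  df <- expand.grid(reporter_family = fids, interview_day = idays,
                    stringsAsFactors = FALSE)
  df$role <- NA_character_
  df$partner_family <- NA_character_
  df$event_day <- NA_integer_
  df
}
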