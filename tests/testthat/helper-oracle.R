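# Independent brute-force staging oracle, written against the guideline
# table directly (logical stage masks rather than set intersection) so it
# shares no code path with the package engine.

oracle_stage <- function(vmax, mpg, ava, calcified) {
  if (is.na(vmax) && is.na(mpg) && is.na(ava)) {
    return(list(stage = "indeterminate", concordant = FALSE,
                flags = "insufficient_data"))
  }
  ok <- rep(TRUE, 5)  # normal, sclerosis, mild, moderate, severe
  if (!is.na(vmax)) {
    ok <- ok & c(vmax < 2, vmax < 2,
                 vmax >= 2 && vmax < 3, vmax >= 3 && vmax < 4, vmax >= 4)
  }
  if (!is.na(mpg)) {
    ok <- ok & c(mpg < 20, mpg < 20, mpg < 20,
                 mpg >= 20 && mpg < 40, mpg >= 40)
  }
  if (!is.na(ava)) {
    ok <- ok & c(ava > 1.5, ava > 1.5, ava > 1.5,
                 ava > 1 && ava <= 1.5, ava <= 1)
  }
  stages <- c("normal", "sclerosis", "mild", "moderate", "severe")

  # discordance flags, straight from the definitions
  flags <- character()
  n_avail <- sum(!is.na(c(vmax, mpg, ava)))
  band_v <- if (is.na(vmax)) NA else
    c("low", "mild", "moderate", "severe")[findInterval(vmax, c(0, 2, 3, 4))]
  band_g <- if (is.na(mpg)) NA else
    c("mild", "moderate", "severe")[findInterval(mpg, c(0, 20, 40))]
  if (n_avail >= 2 && !is.na(band_v) && !is.na(band_g)) {
    pair <- sort(c(band_v, band_g))
    if (identical(pair, c("mild", "moderate"))) flags <- c(flags, "mild_to_moderate")
    if (identical(pair, c("moderate", "severe"))) flags <- c(flags, "moderate_to_severe")
  }
  if (n_avail >= 2 && !is.na(ava) && ava < 1 &&
      (!is.na(vmax) || !is.na(mpg))) {
    sev_v <- !is.na(vmax) && vmax >= 4
    sev_g <- !is.na(mpg) && mpg >= 40
    if (!sev_v && !sev_g) flags <- c(flags, "lflg_severe_pattern")
  }
  flags <- sort(unique(flags))

  if (!any(ok)) {
    # disagreement: ceiling = most severe single-parameter band
    tops <- c(
      if (!is.na(vmax)) which(c(vmax < 2, vmax < 2, vmax >= 2 && vmax < 3,
                                vmax >= 3 && vmax < 4, vmax >= 4)),
      if (!is.na(mpg)) max(which(c(mpg < 20, mpg < 20, mpg < 20,
                                   mpg >= 20 && mpg < 40, mpg >= 40))),
      if (!is.na(ava)) max(which(c(ava > 1.5, ava > 1.5, ava > 1.5,
                                   ava > 1 && ava <= 1.5, ava <= 1))))
    return(list(stage = stages[max(tops)], concordant = FALSE, flags = flags))
  }
  top <- max(which(ok))
  if (top >= 3) {
    return(list(stage = stages[top], concordant = length(flags) == 0,
                flags = flags))
  }
  # sub-2 m/s band: split by calcification
  if (is.na(calcified)) {
    return(list(stage = "normal", concordant = FALSE,
                flags = sort(unique(c(flags, "insufficient_data")))))
  }
  list(stage = if (calcified) "sclerosis" else "normal",
       concordant = length(flags) == 0, flags = flags)
}
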