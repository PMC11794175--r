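# Guideline staging engine: severity bands, discordance / low-flow-low-gradient
# detection, continuity-equation AVA and simplified-Bernoulli pressure.

AS_STAGES <- c("normal", "sclerosis", "mild", "moderate", "severe")

#' Stage ordinal
#'
#' Integer position of an AS stage on the severity ladder, 0 (normal) to
#' 4 (severe).
#'
#' @param stage Character vector of stage names.
#' @return Integer vector in 0..4.
#' @export
stage_ordinal <- function(stage) {
  i <- match(stage, AS_STAGES)
  if (anyNA(i)) stop("unknown stage: ", paste(stage[is.na(i)], collapse = ", "))
  i - 1L
}

#' AS measurement set
#'
#' Container for the conventional AS parameters. Any field may be `NA`
#' ("unavailable"); the staging engine works with whatever is present.
#'
#' @param vmax Peak aortic-jet velocity (m/s).
#' @param mpg Mean transvalvular pressure gradient (mmHg).
#' @param ava Aortic valve area (cm^2).
#' @param av_vti Aortic-valve velocity-time integral (cm).
#' @param lvot_vti LVOT velocity-time integral (cm).
#' @param lvot_diameter LVOT diameter (cm).
#' @param calcified Logical; aortic-valve calcification present.
#' @return An object of class `as_measurements`.
#' @export
as_measurements <- function(vmax = NA_real_, mpg = NA_real_, ava = NA_real_,
                            av_vti = NA_real_, lvot_vti = NA_real_,
                            lvot_diameter = NA_real_, calcified = NA) {
  num <- list(vmax = vmax, mpg = mpg, ava = ava, av_vti = av_vti,
              lvot_vti = lvot_vti, lvot_diameter = lvot_diameter)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (length(v) != 1L) stop(nm, " must be a scalar")
    if (!is.na(v) && v < 0) stop(nm, " must be >= 0, got ", v)
  }
  if (!is.na(ava) && ava <= 0) stop("ava must be > 0 when available")
  structure(c(num, list(calcified = as.logical(calcified))),
            class = "as_measurements")
}

#' @export
print.as_measurements <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else format(v)
  cat("AS measurements: Vmax", fmt(x$vmax), "m/s | mPG", fmt(x$mpg),
      "mmHg | AVA", fmt(x$ava), "cm2 | calcified", fmt(x$calcified), "\n")
  invisible(x)
}

# Compatible-stage sets. Table-1 bands are half-open on the printed gaps
# (Vmax [2,3), [3,4); mPG [20,40)); severe bounds inclusive as printed
# (Vmax >= 4, mPG >= 40, AVA <= 1). mPG and AVA have no band of their own
# below mild, so their lowest band is compatible with normal..mild.
stage_set_vmax <- function(v) {
  if (v < 2) c("normal", "sclerosis")
  else if (v < 3) "mild"
  else if (v < 4) "moderate"
  else "severe"
}
stage_set_mpg <- function(g) {
  if (g < 20) c("normal", "sclerosis", "mild")
  else if (g < 40) "moderate"
  else "severe"
}
stage_set_ava <- function(a) {
  if (a > 1.5) c("normal", "sclerosis", "mild")
  else if (a > 1) "moderate"
  else "severe"
}

# Single-band label used for discordance bookkeeping (most severe stage the
# parameter is compatible with, collapsing normal/sclerosis into "mild" floor
# for mPG/AVA per Table 1's printed bands).
band_label <- function(set) set[length(set)]

#' Severity band of a single parameter
#'
#' @param value Parameter value.
#' @param parameter One of `"vmax"`, `"mpg"`, `"ava"`.
#' @return The most severe stage compatible with the value (the band label
#'   used for discordance comparison).
#' @export
severity_band <- function(value, parameter = c("vmax", "mpg", "ava")) {
  parameter <- match.arg(parameter)
  set <- switch(parameter,
                vmax = stage_set_vmax(value),
                mpg = stage_set_mpg(value),
                ava = stage_set_ava(value))
  band_label(set)
}

#' Stage AS from a measurement set
#'
#' Bins every available parameter into its Table-1 severity band and returns
#' the stage on which all of them agree. `Vmax < 2` m/s splits into normal
#' versus sclerosis by the calcification flag. When the available bands
#' disagree the engine does not force a stage: it reports the most severe
#' compatible band as a ceiling, sets `concordant = FALSE` and raises the
#' matching discordance flags (see [detect_discordance()]).
#'
#' @param m An [as_measurements()] object.
#' @return An object of class `as_stage` with fields `stage` (one of the five
#'   stages or `"indeterminate"`), `concordant` (logical) and `flags`
#'   (character vector).
#' @export
stage_from_measurements <- function(m) {
  stopifnot(inherits(m, "as_measurements"))
  avail <- !vapply(m[c("vmax", "mpg", "ava")], is.na, logical(1))
  if (!any(avail)) {
    return(as_stage("indeterminate", FALSE, "insufficient_data"))
  }
  sets <- list()
  if (avail[["vmax"]]) sets$vmax <- stage_set_vmax(m$vmax)
  if (avail[["mpg"]])  sets$mpg  <- stage_set_mpg(m$mpg)
  if (avail[["ava"]])  sets$ava  <- stage_set_ava(m$ava)
  common <- Reduce(intersect, sets)

  flags <- detect_discordance(m)
  pick_normal_sclerosis <- function(compatible) {
    # split the sub-2 m/s band by calcification; unknown flag -> normal band
    # reported with an insufficient_data flag
    if (is.na(m$calcified)) {
      return(as_stage("normal", FALSE, union(flags, "insufficient_data")))
    }
    st <- if (isTRUE(m$calcified)) "sclerosis" else "normal"
    if (!st %in% compatible) st <- compatible[1]
    as_stage(st, length(flags) == 0L, flags)
  }

  if (length(common) > 0L) {
    top <- common[which.max(stage_ordinal(common))]
    if (top %in% c("normal", "sclerosis") &&
        all(c("normal", "sclerosis") %in% common)) {
      return(pick_normal_sclerosis(common))
    }
    return(as_stage(top, length(flags) == 0L, flags))
  }
  # disagreement: report the most severe band as a ceiling, never concordant
  bands <- vapply(sets, band_label, character(1))
  ceiling_stage <- bands[which.max(stage_ordinal(bands))]
  as_stage(unname(ceiling_stage), FALSE, flags)
}

as_stage <- function(stage, concordant, flags = character()) {
  structure(list(stage = stage, concordant = concordant,
                 flags = sort(unique(flags))), class = "as_stage")
}

#' @export
print.as_stage <- function(x, ...) {
  cat("AS stage:", x$stage,
      if (x$concordant) "(concordant)" else "(not concordant)", "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Detect discordant severity classifications
#'
#' Flags the classical discordance patterns: Vmax and mPG falling one band
#' apart (`mild_to_moderate`, `moderate_to_severe`) and the low-flow
#' low-gradient severe pattern (`lflg_severe_pattern`): AVA < 1 cm^2 while
#' neither Vmax nor mPG reaches the severe band.
#'
#' @param m An [as_measurements()] object.
#' @return Character vector of flags (possibly empty). Fewer than two
#'   available parameters yields an empty set - there is nothing to compare.
#' @export
detect_discordance <- function(m) {
  stopifnot(inherits(m, "as_measurements"))
  avail <- !vapply(m[c("vmax", "mpg", "ava")], is.na, logical(1))
  if (sum(avail) < 2L) return(character())
  flags <- character()
  if (avail[["vmax"]] && avail[["mpg"]]) {
    pair <- c(severity_band(m$vmax, "vmax"), severity_band(m$mpg, "mpg"))
    if (setequal(pair, c("mild", "moderate"))) flags <- c(flags, "mild_to_moderate")
    if (setequal(pair, c("moderate", "severe"))) flags <- c(flags, "moderate_to_severe")
  }
  if (avail[["ava"]] && m$ava < 1) {
    vel_severe <- (avail[["vmax"]] && m$vmax >= 4) ||
      (avail[["mpg"]] && m$mpg >= 40)
    if (!vel_severe && (avail[["vmax"]] || avail[["mpg"]])) {
      flags <- c(flags, "lflg_severe_pattern")
    }
  }
  sort(unique(flags))
}

#' Continuity-equation aortic valve area
#'
#' `AVA = pi * (d_lvot / 2)^2 * vti_lvot / vti_av`, equating stroke volume
#' through the outflow tract and the valve.
#'
#' @param d_lvot LVOT diameter (cm).
#' @param vti_lvot LVOT velocity-time integral (cm).
#' @param vti_av Aortic-valve velocity-time integral (cm).
#' @return Valve area in cm^2.
#' @export
compute_ava_continuity <- function(d_lvot, vti_lvot, vti_av) {
  if (any(!is.finite(c(d_lvot, vti_lvot, vti_av))) ||
      any(c(d_lvot, vti_lvot, vti_av) <= 0)) {
    stop("continuity equation requires positive d_lvot, vti_lvot, vti_av")
  }
  pi * (d_lvot / 2)^2 * vti_lvot / vti_av
}

#' Simplified Bernoulli pressure gradient
#'
#' Instantaneous transvalvular gradient `4 v^2` in mmHg for a jet velocity in
#' m/s.
#'
#' @param v Velocity (m/s), non-negative.
#' @return Pressure gradient (mmHg).
#' @export
bernoulli_pressure <- function(v) {
  if (any(v < 0)) stop("velocity must be >= 0")
  4 * v^2
}

#' Batch staging of a measurements table
#'
#' Applies [stage_from_measurements()] row-wise to a data frame whose columns
#' follow the [as_measurements()] field names (missing values = unavailable).
#'
#' @param df Data frame with any of the columns `vmax`, `mpg`, `ava`,
#'   `calcified`.
#' @return `df` with columns `stage`, `concordant`, `flags` appended.
#' @export
stage_table <- function(df) {
  get <- function(nm, default) if (nm %in% names(df)) df[[nm]] else rep(default, nrow(df))
  res <- lapply(seq_len(nrow(df)), function(i) {
    m <- as_measurements(vmax = get("vmax", NA_real_)[i],
                         mpg = get("mpg", NA_real_)[i],
                         ava = get("ava", NA_real_)[i],
                         calcified = get("calcified", NA)[i])
    stage_from_measurements(m)
  })
  df$stage <- vapply(res, `[[`, character(1), "stage")
  df$concordant <- vapply(res, `[[`, logical(1), "concordant")
  df$flags <- vapply(res, function(s) paste(s$flags, collapse = ";"), character(1))
  df
}
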