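#' Limit of detection from method blanks
#'
#' LOD = mean of the blanks plus three times their (sample, n-1) standard
#' deviation, the convention used for fluorometric ammonium and the
#' autoanalyser nutrient channels.
#'
#' @param blanks Numeric vector of blank determinations (>= 2).
#' @return LOD in the units of the blanks.
#' @export
limit_of_detection <- function(blanks) {
  if (length(blanks) < 2) {
    stop("insufficient blanks: need at least 2", call. = FALSE)
  }
  mean(blanks) + 3 * stats::sd(blanks)
}

#' Default analytical detection limits (nmol L^-1)
#'
#' Phosphate 10, ammonium 24, nitrogen oxides 583, nitrite 33 nmol L^-1;
#' overridable wherever they are consumed.
#'
#' @return Named numeric vector.
#' @export
default_lods <- function() {
  c(Pi = 10, NH4 = 24, NOx = 583, NO2 = 33)
}

#' Derive organic phosphorus pools from total and inorganic phosphorus
#'
#' OP = TP - Pi and DOP = OP - POP. Negative derived pools (analytically
#' inconsistent rows, e.g. TP < Pi) are floored at zero and flagged rather
#' than propagated.
#'
#' @param sample data.frame with columns `TP` and `Pi` (nmol L^-1) and
#'   optionally `POP`; other columns pass through.
#' @return The input with columns `OP`, `DOP` (NA when POP absent) and
#'   logical flags `op_inconsistent`, `dop_inconsistent` added.
#' @export
derive_phosphorus_pools <- function(sample) {
  if (!all(c("TP", "Pi") %in% names(sample))) {
    stop("cannot derive pools: TP and Pi columns required", call. = FALSE)
  }
  op <- sample$TP - sample$Pi
  sample$op_inconsistent <- !is.na(op) & op < 0
  sample$OP <- pmax(op, 0)
  if ("POP" %in% names(sample)) {
    dop <- sample$OP - sample$POP
    sample$dop_inconsistent <- !is.na(dop) & dop < 0
    sample$DOP <- pmax(dop, 0)
  } else {
    sample$DOP <- NA_real_
    sample$dop_inconsistent <- NA
  }
  sample
}

#' Inorganic N:P ratio with detection-limit censoring
#'
#' N is nitrogen oxides plus ammonium; P is phosphate. When phosphate is
#' below its detection limit the ratio is reported censored (NA with the
#' `censored` flag set), never computed from a substituted value such as
#' LOD/2: with Pi below detection the ratio is unquantifiable, which is
#' itself the observation.
#'
#' @param nox,nh4,pi Concentrations (nmol L^-1); vectors recycle.
#' @param pi_censored Logical; TRUE where Pi is below its LOD. Defaults to
#'   `pi < pi_lod`.
#' @param pi_lod Phosphate LOD (default from [default_lods()]).
#' @return data.frame with columns `ratio` (NA where censored) and
#'   `censored`.
#' @export
n_to_p_ratio <- function(nox, nh4, pi, pi_censored = NULL,
                         pi_lod = default_lods()[["Pi"]]) {
  if (is.null(pi_censored)) pi_censored <- !is.na(pi) & pi < pi_lod
  pi_censored <- pi_censored | is.na(pi)
  ratio <- ifelse(pi_censored, NA_real_, (nox + nh4) / pi)
  data.frame(ratio = ratio, censored = pi_censored)
}

#' Nitrate from combined nitrogen oxides and nitrite
#'
#' NO3 = NOx - NO2, floored at zero (the difference of two measured
#' channels can go slightly negative near the detection limits).
#'
#' @param nox,no2 Concentrations, same units.
#' @return Nitrate concentration.
#' @export
no3_from_nox <- function(nox, no2) pmax(nox - no2, 0)

#' Calibrate a fluorescence sensor against extracted chlorophyll a
#'
#' Ordinary least-squares line converting relative fluorescence units into
#' ug L^-1 chlorophyll a, from paired discrete samples.
#'
#' @param rfu Relative fluorescence units (>= 3 values, non-constant).
#' @param chl Extracted chlorophyll a, ug L^-1, paired with `rfu`.
#' @return List of class `fluorescence_calibration`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
calibrate_fluorescence <- function(rfu, chl) {
  stopifnot(length(rfu) == length(chl))
  if (length(rfu) < 2) stop("need at least 2 calibration pairs", call. = FALSE)
  if (stats::sd(rfu) == 0) {
    stop("singular fit: fluorescence values are constant", call. = FALSE)
  }
  fit <- stats::lm(chl ~ rfu)
  # an exact calibration line is fine, not a pathology
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n = length(rfu)),
    class = "fluorescence_calibration"
  )
}

#' Apply a fluorescence calibration to a sensor profile
#'
#' @param calibration A [calibrate_fluorescence()] result.
#' @param rfu Relative fluorescence units.
#' @return Chlorophyll a in ug L^-1.
#' @export
apply_calibration <- function(calibration, rfu) {
  stopifnot(inherits(calibration, "fluorescence_calibration"))
  calibration$intercept + calibration$slope * rfu
}

#' Flag the deep chlorophyll maximum in a calibrated profile
#'
#' The DCM is taken as the contiguous depth region where chlorophyll a
#' exceeds a threshold (default 0.35 ug L^-1).
#'
#' @param chl Chlorophyll a, ug L^-1, ordered by depth.
#' @param threshold ug L^-1.
#' @return Logical vector marking the DCM region (all FALSE when the
#'   threshold is never exceeded).
#' @export
dcm_region <- function(chl, threshold = 0.35) {
  above <- !is.na(chl) & chl > threshold
  if (!any(above)) return(rep(FALSE, length(chl)))
  # contiguous block containing the maximum
  peak <- which.max(ifelse(is.na(chl), -Inf, chl))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  i <- which(runs$values & starts <= peak & peak <= ends)
  out <- rep(FALSE, length(chl))
  if (length(i)) out[starts[i]:ends[i]] <- TRUE
  out
}

#' Read a nutrient table with "<LOD" censoring
#'
#' Accepts TSV/CSV with one row per station/depth. Cells equal to
#' `"<LOD"` (case-insensitive, optionally `"<value"`) are parsed as
#' censored: the numeric column gets NA and a companion
#' `<analyte>_censored` logical column records the flag.
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.csv` -> comma, else tab).
#' @param analytes Columns to treat as (possibly censored) concentrations.
#' @return data.frame with numeric analyte columns and `_censored` flags.
#' @export
read_nutrient_table <- function(path,
                                analytes = c("NOx", "NO2", "NH4", "Pi",
                                             "TP", "POP", "POC", "PON")) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  for (a in intersect(analytes, names(raw))) {
    v <- trimws(raw[[a]])
    cens <- grepl("^<", v) | toupper(v) %in% c("<LOD", "BDL")
    num <- suppressWarnings(as.numeric(v))
    num[cens] <- NA_real_
    raw[[a]] <- num
    raw[[paste0(a, "_censored")]] <- cens | is.na(num)
  }
  for (a in setdiff(names(raw), c(analytes, paste0(analytes, "_censored")))) {
    num <- suppressWarnings(as.numeric(raw[[a]]))
    if (!all(is.na(num))) raw[[a]] <- num
  }
  raw
}
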