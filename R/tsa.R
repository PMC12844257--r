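# Thermal shift assay (differential scanning fluorimetry) analysis.
#
# Each well's fluorescence-vs-temperature melt curve is reduced to a
# melting temperature Tm, either as the maximum of the smoothed first
# derivative or as the midpoint of a fitted two-state Boltzmann sigmoid
#   F(T) = base + amp / (1 + exp((Tm - T)/slope)).
# Per plate, the thermal shift of a compound well is
#   dTm = Tm(compound) - Tm(reference),
# with the reference taken as the median Tm of that plate's usable
# control wells. A compound is a primary hit when
#   |dTm| >= MED(dTm) + 3 * RSD(dTm)   and   |dTm| >= 0.5 degC,
# where MED and RSD are the median and a robust standard deviation
# (scaled median absolute deviation, 1.4826 * MAD) of the plate's sample
# shifts, controls excluded. The 0.5 degC floor keeps plates with very
# tight null distributions from flagging negligible shifts. The sign of
# dTm classifies positive (stabilizing) vs negative (destabilizing)
# shifters.

#' Construct a melt curve
#'
#' @param temperatures ascending temperature grid in degC (>= 20 points).
#' @param fluorescence fluorescence values, same length, no missing values.
#' @param plate_id,well,compound_id identifiers; use
#'   `compound_id = "control"` and `role = "control"` for reference wells.
#' @param concentration screening concentration in uM.
#' @param role `"sample"` or `"control"`.
#' @return object of class `melt_curve`.
#' @export
melt_curve <- function(temperatures, fluorescence, plate_id = "P1", well = "A1",
                       compound_id = "cpd", concentration = NA_real_,
                       role = c("sample", "control")) {
  role <- match.arg(role)
  temperatures <- as.numeric(temperatures)
  fluorescence <- as.numeric(fluorescence)
  if (length(temperatures) < 20L)
    stop("input error: melt curve needs at least 20 temperature points",
         call. = FALSE)
  if (length(fluorescence) != length(temperatures))
    stop("temperature and fluorescence lengths differ", call. = FALSE)
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperatures must be strictly increasing", call. = FALSE)
  if (anyNA(fluorescence)) stop("missing fluorescence values", call. = FALSE)
  structure(list(plate_id = plate_id, well = well, compound_id = compound_id,
                 concentration = concentration, role = role,
                 temperatures = temperatures, fluorescence = fluorescence),
            class = "melt_curve")
}

# noise level of a curve: scaled MAD of residuals around the smooth trend
.curve_noise <- function(f, s) 1.4826 * stats::median(abs(f - s))

#' Extract the melting temperature from a melt curve
#'
#' @param curve a `melt_curve`.
#' @param method `"derivative"` (default): Tm is the maximum of dF/dT on a
#'   Savitzky-Golay smoothed curve, refined by parabolic interpolation of
#'   the peak; or `"boltzmann"`: Tm is the midpoint parameter of a fitted
#'   two-state sigmoid.
#' @param window,poly_order Savitzky-Golay filter window (points, odd) and
#'   polynomial order for the derivative method. The default window of 11
#'   points (5.5 degC on a 0.5 degC grid) keeps the derivative peak stable
#'   under realistic fluorescence noise; narrower windows track sharper
#'   transitions but amplify noise.
#' @return object of class `tm_result`: `tm` (degC), `method`, `quality`
#'   (signal-to-noise of the transition amplitude), `usable`. Curves with
#'   no discernible transition, or whose derivative peak sits on the grid
#'   boundary, are flagged `usable = FALSE`.
#' @export
extract_tm <- function(curve, method = c("derivative", "boltzmann"),
                       window = 11L, poly_order = 3L) {
  stopifnot(inherits(curve, "melt_curve"))
  method <- match.arg(method)
  tt <- curve$temperatures; ff <- curve$fluorescence
  sm <- signal::sgolayfilt(ff, p = poly_order, n = window)
  noise <- .curve_noise(ff, sm)
  rise <- stats::quantile(sm, 0.95, names = FALSE) -
          stats::quantile(sm, 0.05, names = FALSE)
  quality <- if (noise > 0) rise / noise else ifelse(rise > 0, Inf, 0)
  bad <- function() structure(list(tm = NA_real_, method = method,
                                   quality = quality, usable = FALSE),
                              class = "tm_result")
  # no transition: amplitude indistinguishable from noise
  if (!(quality > 10)) return(bad())
  if (method == "derivative") {
    # Savitzky-Golay first-derivative filter on a (near-)uniform grid
    h <- stats::median(diff(tt))
    dfdt <- signal::sgolayfilt(ff, p = poly_order, n = window, m = 1L, ts = h)
    pk <- which.max(dfdt)
    if (pk <= 1L || pk >= length(dfdt)) return(bad())
    # parabolic refinement through the peak and its neighbours
    y0 <- dfdt[pk - 1L]; y1 <- dfdt[pk]; y2 <- dfdt[pk + 1L]
    denom <- y0 - 2 * y1 + y2
    delta <- if (denom < 0) 0.5 * (y0 - y2) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    tm <- tt[pk] + delta * h
  } else {
    base0 <- stats::quantile(sm, 0.05, names = FALSE)
    amp0 <- rise
    tm0 <- tt[which.min(abs(sm - (base0 + amp0 / 2)))]
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ff ~ base + amp / (1 + exp((tm - tt) / slope)),
        start = list(base = base0, amp = amp0, tm = tm0, slope = 1),
        data = data.frame(tt = tt, ff = ff),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(bad())
    cf <- stats::coef(fit)
    if (cf[["slope"]] <= 0 || cf[["amp"]] <= 0) return(bad())
    tm <- cf[["tm"]]
  }
  if (is.na(tm) || tm <= tt[1L] || tm >= tt[length(tt)]) return(bad())
  structure(list(tm = tm, method = method, quality = quality, usable = TRUE),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("<tm_result> tm=%.2f degC (%s), quality=%.1f, usable=%s\n",
              x$tm, x$method, x$quality, x$usable))
  invisible(x)
}

#' Robust location and scale of a plate's thermal shifts
#'
#' @param shifts numeric vector of per-compound shifts (degC), controls
#'   excluded; at least 4 values.
#' @param rsd_constant scale factor converting the MAD to a standard
#'   deviation equivalent; 1.4826 makes it consistent with the SD of a
#'   normal distribution.
#' @return list with `med` (median) and `rsd` (scaled MAD), both in degC.
#' @examples
#' robust_stats(c(1, 2, 3, 4, 100))  # med 3, rsd 1.4826
#' @export
robust_stats <- function(shifts, rsd_constant = 1.4826) {
  shifts <- as.numeric(shifts)
  shifts <- shifts[!is.na(shifts)]
  if (length(shifts) < 4L)
    stop("plate too sparse: robust statistics need at least 4 sample shifts",
         call. = FALSE)
  med <- stats::median(shifts)
  rsd <- stats::mad(shifts, constant = rsd_constant)
  list(med = med, rsd = rsd)
}

#' Per-plate thermal shifts relative to the control reference
#'
#' @param tm_table data frame with one row per well: columns `compound_id`,
#'   `role` (`"sample"`/`"control"`), `tm`, `usable` (as from
#'   [extract_tm()]), and optionally `plate_id`, `well`, `concentration`.
#' @return data frame of class `shift_table` with sample rows only,
#'   columns `compound_id`, `delta_tm`, plus a `reference_tm` attribute.
#'   Unusable wells are dropped and listed in the `excluded` attribute.
#' @export
compute_shifts <- function(tm_table) {
  tm_table <- as.data.frame(tm_table)
  stopifnot(all(c("compound_id", "role", "tm", "usable") %in% names(tm_table)))
  ctrl <- tm_table$role == "control" & tm_table$usable
  if (!any(ctrl)) stop("no usable control wells on the plate", call. = FALSE)
  ref <- stats::median(tm_table$tm[ctrl])
  smp <- tm_table[tm_table$role == "sample", , drop = FALSE]
  excluded <- smp$compound_id[!smp$usable]
  smp <- smp[smp$usable, , drop = FALSE]
  out <- data.frame(compound_id = smp$compound_id,
                    delta_tm = smp$tm - ref, stringsAsFactors = FALSE)
  if ("concentration" %in% names(smp)) out$concentration <- smp$concentration
  if ("plate_id" %in% names(smp)) out$plate_id <- smp$plate_id
  attr(out, "reference_tm") <- ref
  attr(out, "excluded") <- excluded
  class(out) <- c("shift_table", "data.frame")
  out
}

#' Call thermal-shift hits on one plate
#'
#' Applies the robust per-plate rule: a compound is a hit when its |dTm|
#' reaches both the adaptive threshold MED + k * RSD (computed over the
#' plate's sample shifts, controls never included) and the fixed minimum
#' shift floor.
#'
#' @param shift_table `shift_table` from [compute_shifts()] (or any data
#'   frame with `compound_id` and `delta_tm`).
#' @param k multiplier on the robust SD (default 3).
#' @param floor minimum |dTm| in degC for a meaningful interaction
#'   (default 0.5).
#' @param rsd_constant passed to [robust_stats()].
#' @param on_absolute compute MED/RSD on |shifts| instead of signed shifts
#'   (sensitivity analysis option; default `FALSE`, signed).
#' @return the table with added columns `hit` and `direction`
#'   (`"positive"`/`"negative"`), and attributes `med`, `rsd`, `threshold`.
#' @export
call_hits <- function(shift_table, k = 3, floor = 0.5, rsd_constant = 1.4826,
                      on_absolute = FALSE) {
  stopifnot(all(c("compound_id", "delta_tm") %in% names(shift_table)))
  d <- shift_table$delta_tm
  st <- robust_stats(if (on_absolute) abs(d) else d, rsd_constant = rsd_constant)
  thr <- st$med + k * st$rsd
  hit <- abs(d) >= thr & abs(d) >= floor
  out <- shift_table
  out$hit <- hit
  out$direction <- ifelse(d >= 0, "positive", "negative")
  attr(out, "med") <- st$med
  attr(out, "rsd") <- st$rsd
  attr(out, "threshold") <- max(thr, floor)
  class(out) <- unique(c("shift_table", class(out)))
  out
}

#' Analyse a long-format DSF plate table end to end
#'
#' Reduces every well to a Tm, computes shifts against the plate's control
#' reference, and calls hits per plate (and per screening concentration
#' when a `concentration_uM` column is present). A compound screened at
#' several concentrations is a primary hit if flagged at any of them.
#'
#' @param plates data frame (or CSV path) in long format with columns
#'   `plate`, `well`, `compound_id`, `role`, `temperature_C`,
#'   `fluorescence`, and optionally `concentration_uM`.
#' @param method,k,floor,rsd_constant passed to [extract_tm()] /
#'   [call_hits()].
#' @return list with `shifts` (combined shift table across plates),
#'   `hits` (per-compound summary with `hit_any`), and `plates`
#'   (per-plate reference Tm and thresholds).
#' @export
tsa_screen <- function(plates, method = "derivative", k = 3, floor = 0.5,
                       rsd_constant = 1.4826) {
  if (is.character(plates)) plates <- utils::read.csv(plates, stringsAsFactors = FALSE)
  need <- c("plate", "well", "compound_id", "role", "temperature_C", "fluorescence")
  stopifnot(all(need %in% names(plates)))
  has_conc <- "concentration_uM" %in% names(plates)
  key <- paste(plates$plate, plates$well, sep = "||")
  shift_list <- list(); plate_meta <- list()
  for (pid in unique(plates$plate)) {
    sub <- plates[plates$plate == pid, , drop = FALSE]
    wells <- unique(sub$well)
    rows <- lapply(wells, function(w) {
      ws <- sub[sub$well == w, , drop = FALSE]
      ws <- ws[order(ws$temperature_C), , drop = FALSE]
      mc <- melt_curve(ws$temperature_C, ws$fluorescence, plate_id = pid,
                       well = w, compound_id = ws$compound_id[1L],
                       concentration = if (has_conc) ws$concentration_uM[1L] else NA_real_,
                       role = ws$role[1L])
      tmres <- extract_tm(mc, method = method)
      data.frame(plate_id = pid, well = w, compound_id = mc$compound_id,
                 role = mc$role, concentration = mc$concentration,
                 tm = tmres$tm, usable = tmres$usable, stringsAsFactors = FALSE)
    })
    tm_table <- do.call(rbind, rows)
    shifts <- compute_shifts(tm_table)
    called <- call_hits(shifts, k = k, floor = floor, rsd_constant = rsd_constant)
    shift_list[[pid]] <- called
    plate_meta[[pid]] <- data.frame(
      plate_id = pid, reference_tm = attr(shifts, "reference_tm"),
      med = attr(called, "med"), rsd = attr(called, "rsd"),
      threshold = attr(called, "threshold"),
      n_excluded = length(attr(shifts, "excluded")), stringsAsFactors = FALSE)
  }
  shifts <- do.call(rbind, lapply(shift_list, as.data.frame))
  rownames(shifts) <- NULL
  agg <- stats::aggregate(hit ~ compound_id, data = shifts, FUN = any)
  names(agg)[2L] <- "hit_any"
  dirs <- stats::aggregate(delta_tm ~ compound_id, data = shifts,
                           FUN = function(v) v[which.max(abs(v))])
  names(dirs)[2L] <- "max_abs_delta_tm"
  hits <- merge(agg, dirs, by = "compound_id")
  hits$direction <- ifelse(hits$max_abs_delta_tm >= 0, "positive", "negative")
  list(shifts = shifts, hits = hits,
       plates = do.call(rbind, plate_meta))
}
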