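# Enzymatic dose-response confirmation.
#
# Esterase-activity kinetics (p-nitrophenyl acetate hydrolysis followed by
# absorbance) are reduced to initial rates, converted to percent
# inhibition against the no-inhibitor and background controls, and fitted
# with the four-parameter logistic (4PL)
#   y(x) = bottom + (top - bottom) / (1 + (IC50 / x)^hill),
# where y is percent inhibition and x the inhibitor concentration. IC50
# is optimized on the log scale for conditioning, with a small multistart
# over Hill slopes.

#' Geometric serial-dilution ladder
#'
#' @param top highest concentration (uM).
#' @param factor dilution factor between consecutive points (> 1).
#' @param points number of concentrations (>= 2).
#' @return numeric vector `top, top/factor, ..., top/factor^(points-1)`.
#' @examples
#' serial_dilution(200, 3, 10)  # 10-point 3-fold ladder down to ~0.01 uM
#' @export
serial_dilution <- function(top, factor, points) {
  if (!is.numeric(top) || length(top) != 1L || top <= 0)
    stop("top concentration must be a positive number", call. = FALSE)
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 1)
    stop("dilution factor must exceed 1", call. = FALSE)
  if (!is.numeric(points) || length(points) != 1L || points < 2)
    stop("a dilution series needs at least 2 points", call. = FALSE)
  top / factor^(seq_len(as.integer(points)) - 1L)
}

#' Initial rate of a kinetic trace
#'
#' Least-squares slope of absorbance vs time over the initial linear
#' window.
#'
#' @param times seconds, strictly increasing.
#' @param absorbance AU, same length.
#' @param window length of the initial window in seconds (default: whole
#'   trace).
#' @return slope in AU/s.
#' @export
initial_rate <- function(times, absorbance, window = Inf) {
  stopifnot(length(times) == length(absorbance))
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  keep <- times <= times[1L] + window
  if (sum(keep) < 3L)
    stop("initial-rate window holds fewer than 3 points", call. = FALSE)
  unname(stats::coef(stats::lm(absorbance[keep] ~ times[keep]))[2L])
}

#' Percent inhibition from initial rates
#'
#' @param rate_sample,rate_control,rate_background initial rates (AU/s) of
#'   the inhibited well, the no-inhibitor control, and the no-enzyme
#'   background. The control rate must exceed the background rate.
#' @param clamp clamp range for reported inhibition; values outside are
#'   clamped and flagged via the `"clamped"` attribute.
#' @return percent inhibition (0 = full activity, 100 = full inhibition).
#' @export
percent_inhibition <- function(rate_sample, rate_control, rate_background = 0,
                               clamp = c(-20, 120)) {
  if (any(rate_control <= rate_background))
    stop("control rate must exceed background rate", call. = FALSE)
  p <- 100 * (1 - (rate_sample - rate_background) / (rate_control - rate_background))
  clamped <- p < clamp[1L] | p > clamp[2L]
  p <- pmin(pmax(p, clamp[1L]), clamp[2L])
  attr(p, "clamped") <- clamped
  p
}

# 4PL response at concentration x
.fpl <- function(x, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (ic50 / x)^hill)
}

#' Assemble a dose-response table
#'
#' @param compound_id identifier.
#' @param concentration concentrations in uM (replicates repeat values).
#' @param inhibition percent inhibition per point.
#' @return data frame of class `dose_response`.
#' @export
dose_response <- function(compound_id, concentration, inhibition) {
  stopifnot(length(concentration) == length(inhibition))
  if (any(concentration <= 0)) stop("concentrations must be positive", call. = FALSE)
  structure(data.frame(compound_id = compound_id,
                       concentration = as.numeric(concentration),
                       inhibition = as.numeric(inhibition),
                       stringsAsFactors = FALSE),
            class = c("dose_response", "data.frame"))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Replicates are fitted as pooled points by default. The fit multistarts
#' over Hill slopes 0.5, 1 and 2 with IC50 parameterized as log10(IC50).
#' A fit is declared non-converged when the response shows no dose
#' dependence, the optimizer fails, or the fitted IC50 falls outside the
#' tested concentration range by more than a factor of 10 (guard band).
#'
#' @param dr `dose_response` data frame (one compound).
#' @param pool_replicates fit all points (`TRUE`, default) or per-dose
#'   means.
#' @return object of class `ic50_fit` with `ic50` (uM), `hill`, `top`,
#'   `bottom`, `converged`, `reason`, `ci95` (Wald 95% interval on IC50),
#'   `rmse` and the data.
#' @export
fit_ic50 <- function(dr, pool_replicates = TRUE) {
  stopifnot(inherits(dr, "data.frame"),
            all(c("concentration", "inhibition") %in% names(dr)))
  cid <- if ("compound_id" %in% names(dr)) dr$compound_id[1L] else "cpd"
  x <- dr$concentration; y <- dr$inhibition
  if (length(unique(x)) < 6L)
    stop("IC50 fitting needs at least 6 distinct concentrations", call. = FALSE)
  if (!pool_replicates) {
    m <- stats::aggregate(y, by = list(x = x), FUN = mean)
    y <- m[[2L]]; x <- m$x
  }
  out <- structure(list(compound_id = cid, ic50 = NA_real_, hill = NA_real_,
                        top = NA_real_, bottom = NA_real_, converged = FALSE,
                        reason = "", ci95 = c(NA_real_, NA_real_),
                        rmse = NA_real_, data = dr), class = "ic50_fit")
  my <- tapply(y, x, mean)
  if (diff(range(my)) < 15) {
    out$reason <- "no dose dependence"
    return(out)
  }
  dat <- data.frame(x = x, y = y)
  top0 <- max(my); bot0 <- min(my)
  # midpoint guess: concentration whose mean response is nearest half-effect
  half <- (top0 + bot0) / 2
  l50_0 <- log10(as.numeric(names(my))[which.min(abs(my - half))])
  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + (10^(l50 - log10(x)))^hill),
        data = dat,
        start = list(bottom = bot0, top = top0, l50 = l50_0, hill = h0),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) { out$reason <- "optimizer failed"; return(out) }
  cf <- stats::coef(best$fit)
  ic50 <- 10^cf[["l50"]]
  out$ic50 <- ic50; out$hill <- cf[["hill"]]
  out$top <- cf[["top"]]; out$bottom <- cf[["bottom"]]
  out$rmse <- sqrt(best$rss / length(y))
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit)))[["l50"]],
                 error = function(e) NA_real_)
  if (!is.na(se)) out$ci95 <- 10^(cf[["l50"]] + c(-1, 1) * 1.96 * se)
  guard <- c(min(x) / 10, max(x) * 10)
  if (ic50 < guard[1L] || ic50 > guard[2L]) {
    out$reason <- "IC50 outside tested range (extrapolation)"
    return(out)
  }
  if (out$hill <= 0) { out$reason <- "non-positive Hill slope"; return(out) }
  if (out$hill < 0.2 || out$hill > 5) {
    out$reason <- "implausible Hill slope"
    return(out)
  }
  if (out$top <= out$bottom) { out$reason <- "degenerate plateau ordering"; return(out) }
  out$converged <- TRUE
  out
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<ic50_fit %s> IC50 = %.3g uM [%.3g, %.3g], hill = %.2f, top = %.1f%%, bottom = %.1f%%\n",
                x$compound_id, x$ic50, x$ci95[1L], x$ci95[2L], x$hill, x$top, x$bottom))
  } else {
    cat(sprintf("<ic50_fit %s> not converged (%s)", x$compound_id, x$reason))
    if (!is.na(x$ic50)) cat(sprintf("; unguarded estimate %.3g uM", x$ic50))
    cat("\n")
  }
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(ic50 = object$ic50, hill = object$hill, top = object$top,
    bottom = object$bottom)
}

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$concentration else
    if (is.data.frame(newdata)) newdata$concentration else as.numeric(newdata)
  .fpl(x, object$bottom, object$top, object$ic50, object$hill)
}

#' Reduce a kinetics table to dose-response points and fit IC50s
#'
#' @param kinetics long-format data frame (or CSV path) with columns
#'   `well`, `compound_id`, `concentration_uM`, `role` (`"sample"`,
#'   `"no_inhibitor_control"`, `"background"`), `time_s`, `absorbance`.
#' @param window initial-rate window in seconds.
#' @param top_concentration reporting threshold: compounds whose response
#'   never reaches half-effect are reported as `IC50 > top_concentration`.
#' @return list with `doses` (per-well percent inhibition) and `fits`
#'   (named list of `ic50_fit` objects), plus a `summary` data frame.
#' @export
ic50_from_kinetics <- function(kinetics, window = Inf, top_concentration = NULL) {
  if (is.character(kinetics)) kinetics <- utils::read.csv(kinetics, stringsAsFactors = FALSE)
  need <- c("well", "compound_id", "concentration_uM", "role", "time_s", "absorbance")
  stopifnot(all(need %in% names(kinetics)))
  rate_of <- function(sub) {
    sub <- sub[order(sub$time_s), , drop = FALSE]
    initial_rate(sub$time_s, sub$absorbance, window = window)
  }
  wells <- unique(kinetics$well)
  per_well <- do.call(rbind, lapply(wells, function(w) {
    sub <- kinetics[kinetics$well == w, , drop = FALSE]
    data.frame(well = w, compound_id = sub$compound_id[1L],
               concentration = sub$concentration_uM[1L], role = sub$role[1L],
               rate = rate_of(sub), stringsAsFactors = FALSE)
  }))
  r_ctrl <- mean(per_well$rate[per_well$role == "no_inhibitor_control"])
  r_bg <- if (any(per_well$role == "background"))
    mean(per_well$rate[per_well$role == "background"]) else 0
  smp <- per_well[per_well$role == "sample", , drop = FALSE]
  smp$inhibition <- as.numeric(percent_inhibition(smp$rate, r_ctrl, r_bg))
  fits <- list(); rows <- list()
  for (cpd in unique(smp$compound_id)) {
    d <- smp[smp$compound_id == cpd, , drop = FALSE]
    dr <- dose_response(cpd, d$concentration, d$inhibition)
    f <- fit_ic50(dr)
    fits[[cpd]] <- f
    top_c <- if (is.null(top_concentration)) max(d$concentration) else top_concentration
    label <- if (f$converged) sprintf("%.3g", f$ic50) else sprintf("> %g", top_c)
    rows[[cpd]] <- data.frame(compound_id = cpd, ic50_uM = f$ic50,
                              hill = f$hill, converged = f$converged,
                              ic50_label = label, stringsAsFactors = FALSE)
  }
  list(doses = smp, fits = fits, summary = do.call(rbind, rows))
}
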