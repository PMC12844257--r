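# Synthetic-data generation.
#
# Every input the cascade consumes can be generated with known ground
# truth: building-block sets drawn from a programmatically decorated
# SMILES pool, Bernoulli synthesis outcomes with truncated-normal yields,
# two-state DSF melt plates with planted positive/negative shifters, and
# linear esterase kinetics whose rates follow a planted 4PL dose-response.
# All generators take an explicit seed and restore the caller's RNG state;
# the same seed always reproduces the same data.

# run expr under a local, fully specified RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Curated SMILES pool for synthetic building-block sets
#'
#' Builds, by combinatorial decoration of a handful of aromatic and
#' aliphatic scaffolds, three pools of valid single-site reactants:
#' organic azides, terminal alkynes bearing one primary sulfonamide, and
#' carboxylic acids. Each entry passes [validate_building_block()] for its
#' role.
#'
#' @return list with character vectors `azides`, `alkynes`, `acids`
#'   (canonical SMILES, deduplicated).
#' @export
smiles_pool <- function() {
  subs <- c("F", "Cl", "Br", "I", "C", "CC", "C(C)C", "OC", "O",
            "C(F)(F)F", "[N+](=O)[O-]", "N(C)C")
  ring <- function(attach) {
    c(sprintf("c1ccccc1%s", attach),                    # unsubstituted
      sprintf("c1cc(%s)ccc1%s", subs, attach),          # meta-like
      sprintf("c1ccc(%s)cc1%s", subs, attach))          # para-like
  }
  az_linkers <- c("N=[N+]=[N-]", "CN=[N+]=[N-]", "CCN=[N+]=[N-]",
                  "OCCN=[N+]=[N-]")
  azides <- c(unlist(lapply(az_linkers, ring)),
              paste0(c("CC", "CCC", "CCCC", "CC(C)", "C1CCCCC1",
                       "C1CCCC1C", "COCC"), "N=[N+]=[N-]"))
  ak_attach <- c("C#C", "CC#C", "OCC#C", "NC(=O)CC#C")   # read right-to-left
  sulf_ring <- function(attach) {
    c(sprintf("NS(=O)(=O)c1ccc(%s)cc1", attach),
      sprintf("NS(=O)(=O)c1ccc(%s)cc1%s", attach, subs),
      sprintf("NS(=O)(=O)c1cc(%s)ccc1%s", attach, subs))
  }
  alkynes <- c(unlist(lapply(ak_attach, sulf_ring)),
               c("C#CCS(N)(=O)=O", "C#CCCS(N)(=O)=O", "C#CCCCS(N)(=O)=O",
                 "C#CCNC(=O)CS(N)(=O)=O", "C#CCOCCS(N)(=O)=O"))
  ac_attach <- c("C(=O)O", "CC(=O)O", "CCC(=O)O", "OCC(=O)O", "C(C)C(=O)O")
  acids <- c(unlist(lapply(ac_attach, ring)),
             c("CC(=O)O", "CCC(=O)O", "CCCC(=O)O", "CC(C)C(=O)O",
               "C1CCCCC1C(=O)O", "C1CCCC1C(=O)O", "OC(=O)c1ccco1",
               "OC(=O)c1cccs1", "OC(=O)c1ccncc1", "OC(=O)c1cccnc1",
               "OC(=O)C1CC1", "OC(=O)CC1CCCCC1"))
  list(azides = unique(canonical_smiles(azides)),
       alkynes = unique(canonical_smiles(alkynes)),
       acids = unique(canonical_smiles(acids)))
}

#' Generate synthetic building-block sets
#'
#' Draws without replacement from [smiles_pool()] and validates every
#' block. Set labels follow the library-4 convention: azides "1", alkynes
#' "2" (the sulfonamide carriers), acids "3".
#'
#' @param n_azide,n_alkyne,n_acid set sizes.
#' @param seed RNG seed (mandatory).
#' @return list with `azides`, `alkynes`, `acids`: lists of
#'   `building_block` objects with indices 1..n.
#' @export
gen_building_blocks <- function(n_azide, n_alkyne, n_acid, seed) {
  stopifnot(n_azide >= 1L, n_alkyne >= 1L, n_acid >= 1L)
  pool <- smiles_pool()
  if (n_azide > length(pool$azides) || n_alkyne > length(pool$alkynes) ||
      n_acid > length(pool$acids))
    stop(sprintf("requested sizes (%d, %d, %d) exceed pool sizes (%d, %d, %d)",
                 n_azide, n_alkyne, n_acid, length(pool$azides),
                 length(pool$alkynes), length(pool$acids)), call. = FALSE)
  pick <- with_seed(seed, list(az = sample(pool$azides, n_azide),
                               ak = sample(pool$alkynes, n_alkyne),
                               ac = sample(pool$acids, n_acid)))
  mk <- function(smis, role, lab) {
    out <- vector("list", length(smis))
    for (q in seq_along(smis))
      out[[q]] <- validate_building_block(smis[q], role, lab, q)
    out
  }
  list(azides = mk(pick$az, "azide", "1"),
       alkynes = mk(pick$ak, "alkyne", "2"),
       acids = mk(pick$ac, "acid", "3"))
}

#' Generate synthetic synthesis outcomes
#'
#' Isolation is Bernoulli with probability `ssr_true`/100; isolated
#' members get yields from a normal distribution truncated to (0, 100].
#'
#' @param member_ids character vector of member ids.
#' @param ssr_true true synthesis success rate in percent.
#' @param yield_mean,yield_sd yield distribution in percent.
#' @param seed RNG seed.
#' @return `synthesis_outcomes` data frame.
#' @export
gen_outcomes <- function(member_ids, ssr_true = 75, yield_mean = 56,
                         yield_sd = 15, seed = 1L) {
  stopifnot(length(member_ids) >= 1L, ssr_true >= 0, ssr_true <= 100,
            yield_sd >= 0)
  with_seed(seed, {
    iso <- stats::runif(length(member_ids)) < ssr_true / 100
    yld <- rep(NA_real_, length(member_ids))
    for (q in which(iso)) {
      repeat {
        v <- stats::rnorm(1, yield_mean, yield_sd)
        if (v > 0 && v <= 100) { yld[q] <- v; break }
      }
    }
    synthesis_outcomes(member_ids, iso, yld)
  })
}

# two-state melt model with optional post-transition decay
.melt_model <- function(tt, tm, base, amp, slope, decay = 0) {
  f <- base + amp / (1 + exp((tm - tt) / slope))
  if (decay > 0) {
    post <- tt > tm
    f[post] <- base + (f[post] - base) * exp(-decay * (tt[post] - tm))
  }
  f
}

#' Generate a synthetic DSF plate
#'
#' Builds long-format melt curves for planted shifter compounds, null
#' compounds and control wells. Shifter wells melt at `tm0 + delta`; null
#' wells at `tm0` plus Gaussian jitter; controls at exactly `tm0` (before
#' noise). Fluorescence carries multiplicative Gaussian noise.
#'
#' @param n_null number of null (inactive) sample compounds.
#' @param shifters data frame with columns `count` and `delta` (degC),
#'   e.g. `data.frame(count = c(5, 10), delta = c(3, -2))`.
#' @param n_controls number of reference wells.
#' @param tm0 reference melting temperature (degC).
#' @param null_sd SD of the null compounds' true Tm jitter (degC).
#' @param base,amp,slope melt-curve baseline, amplitude and transition
#'   width (degC).
#' @param noise_frac multiplicative fluorescence noise, as a fraction of
#'   the amplitude.
#' @param decay optional post-transition decay rate (1/degC); 0 disables.
#' @param grid temperature grid (degC).
#' @param plate_id,concentration identifiers for the output table.
#' @param seed RNG seed.
#' @return long-format data frame (`plate`, `well`, `compound_id`, `role`,
#'   `concentration_uM`, `temperature_C`, `fluorescence`) with a
#'   `truth` attribute giving each compound's planted delta.
#' @export
gen_melt_plate <- function(n_null = 85, shifters = data.frame(count = c(5, 10),
                                                              delta = c(3, -2)),
                           n_controls = 8, tm0 = 55, null_sd = 0.15,
                           base = 0.1, amp = 1, slope = 1, noise_frac = 0.02,
                           decay = 0, grid = seq(25, 95, by = 0.5),
                           plate_id = "P1", concentration = 20, seed = 1L) {
  stopifnot(n_null >= 0, n_controls >= 1, null_sd >= 0, noise_frac >= 0)
  shifters <- as.data.frame(shifters)
  with_seed(seed, {
    deltas <- c(rep(shifters$delta, shifters$count), stats::rnorm(n_null, 0, null_sd))
    truth <- rep(c(rep(shifters$delta, shifters$count), rep(0, n_null)))
    n_smp <- length(deltas)
    cpd <- sprintf("cpd%03d", seq_len(n_smp))
    ids <- c(cpd, rep("control", n_controls))
    roles <- c(rep("sample", n_smp), rep("control", n_controls))
    tms <- c(tm0 + deltas, rep(tm0, n_controls))
    rows <- vector("list", length(ids))
    for (w in seq_along(ids)) {
      f <- .melt_model(grid, tms[w], base, amp, slope, decay)
      f <- f * (1 + stats::rnorm(length(grid), 0, noise_frac))
      rows[[w]] <- data.frame(plate = plate_id, well = sprintf("W%03d", w),
                              compound_id = ids[w], role = roles[w],
                              concentration_uM = concentration,
                              temperature_C = grid, fluorescence = f,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- data.frame(compound_id = cpd, true_delta = truth,
                                     stringsAsFactors = FALSE)
    out
  })
}

#' Generate a synthetic dose-response table
#'
#' Percent-inhibition points on a serial-dilution ladder, from a planted
#' 4PL with additive Gaussian noise.
#'
#' @param ic50,hill,top,bottom planted 4PL parameters (uM, unitless, %, %).
#' @param noise_sd additive noise on the percent-inhibition scale.
#' @param n_rep replicates per concentration.
#' @param top_conc,factor,points serial-dilution design.
#' @param compound_id identifier.
#' @param seed RNG seed.
#' @return `dose_response` data frame.
#' @export
gen_dose_response <- function(ic50 = 1, hill = 1, top = 100, bottom = 0,
                              noise_sd = 5, n_rep = 4, top_conc = 200,
                              factor = 3, points = 10,
                              compound_id = "cpd", seed = 1L) {
  conc <- rep(serial_dilution(top_conc, factor, points), each = n_rep)
  with_seed(seed, {
    y <- .fpl(conc, bottom, top, ic50, hill) + stats::rnorm(length(conc), 0, noise_sd)
    dose_response(compound_id, conc, y)
  })
}

#' Generate synthetic esterase kinetics for a dose-response experiment
#'
#' Linear absorbance traces whose slopes encode a planted 4PL: the
#' no-inhibitor control hydrolyses substrate at `rate_control`, background
#' wells at `rate_background`, and each sample well at the rate the 4PL
#' inhibition predicts, perturbed by Gaussian noise on the inhibition
#' scale.
#'
#' @inheritParams gen_dose_response
#' @param rate_control,rate_background control and background slopes
#'   (AU/s); the control rate must exceed the background.
#' @param noise_frac SD of the rate perturbation as a fraction of the
#'   control-background dynamic range (0.05 reproduces 5-point noise on
#'   the percent-inhibition scale).
#' @param n_ctrl control and background well count.
#' @param times sampling times in seconds.
#' @return long-format kinetics data frame (`well`, `compound_id`,
#'   `concentration_uM`, `role`, `time_s`, `absorbance`).
#' @export
gen_dose_kinetics <- function(ic50 = 1, hill = 1, top = 100, bottom = 0,
                              noise_frac = 0.05, n_rep = 4, top_conc = 200,
                              factor = 3, points = 10, rate_control = 2e-3,
                              rate_background = 2e-4, n_ctrl = 4,
                              times = seq(0, 300, by = 15),
                              compound_id = "cpd", seed = 1L) {
  if (rate_control <= rate_background)
    stop("generation error: control rate must exceed background rate",
         call. = FALSE)
  conc <- rep(serial_dilution(top_conc, factor, points), each = n_rep)
  span <- rate_control - rate_background
  with_seed(seed, {
    inh <- .fpl(conc, bottom, top, ic50, hill) / 100 +
      stats::rnorm(length(conc), 0, noise_frac)
    rates <- rate_background + span * (1 - inh)
    mk <- function(w, cpd, cc, role, rate) {
      a <- 0.05 + rate * times + stats::rnorm(length(times), 0, 1e-4)
      data.frame(well = w, compound_id = cpd, concentration_uM = cc,
                 role = role, time_s = times, absorbance = a,
                 stringsAsFactors = FALSE)
    }
    rows <- list()
    for (q in seq_along(conc))
      rows[[length(rows) + 1L]] <- mk(sprintf("S%03d", q), compound_id,
                                      conc[q], "sample", rates[q])
    for (q in seq_len(n_ctrl)) {
      rows[[length(rows) + 1L]] <- mk(sprintf("C%02d", q), "control", 0,
                                      "no_inhibitor_control", rate_control)
      rows[[length(rows) + 1L]] <- mk(sprintf("B%02d", q), "background", 0,
                                      "background", rate_background)
    }
    do.call(rbind, rows)
  })
}
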