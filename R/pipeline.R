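# End-to-end campaign orchestration.
#
# A flat YAML config (one section per stage) drives the cascade:
# simulate -> enumerate -> track -> tsa -> ic50 -> report. Stages run in
# order; a stage error short-circuits the rest and the partial report
# records the failure. All defaults are echoed into the report for
# provenance, and every stage logs one structured line.

.default_config <- function() {
  list(
    seed = 1L,
    workdir = ".",
    simulate = list(enabled = TRUE, n_azide = 8L, n_alkyne = 6L, n_acid = 8L,
                    n_planned = 60L, ssr_true = 75, yield_mean = 56,
                    yield_sd = 15, n_null = 85L,
                    shifter_counts = c(5L, 10L), shifter_deltas = c(3, -2),
                    n_controls = 8L, tm0 = 55, null_sd = 0.15,
                    melt_noise = 0.02, ic50_true = c(0.2, 1.1, 6.07, 8.74),
                    hill_true = 1, dose_noise = 0.05, n_rep = 4L),
    enumerate = list(building_blocks = "building_blocks.csv",
                     planned = "planned.csv", products = "products.sdf",
                     manifest = "manifest.csv", library_label = "4"),
    track = list(outcomes = "outcomes.csv"),
    tsa = list(plates = "plates.csv", k = 3, floor = 0.5,
               rsd_constant = 1.4826, method = "derivative"),
    ic50 = list(kinetics = "kinetics.csv", dilution_top = 200,
                dilution_factor = 3, dilution_points = 10L),
    report = list(path = "campaign_report.json")
  )
}

# deep-merge user config over defaults
.merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      .merge_config(base[[k]], user[[k]]) else user[[k]]
  }
  base
}

#' Load (or default) a pipeline configuration
#'
#' @param path YAML file with one section per stage; missing keys fall
#'   back to package defaults. `NULL` returns the defaults.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config error: file not found: ", path,
                                 call. = FALSE)
    cfg <- .merge_config(cfg, yaml::read_yaml(path))
  }
  if (cfg$tsa$k <= 0) stop("config error: tsa k must be positive", call. = FALSE)
  if (cfg$tsa$floor < 0) stop("config error: tsa floor must be >= 0", call. = FALSE)
  structure(cfg, class = c("pipeline_config", "list"))
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the whole screening cascade
#'
#' Executes enumerate -> track -> tsa -> ic50 and writes a machine-readable
#' campaign report. With `simulate.enabled`, all stage inputs are first
#' generated synthetically under the configured seed, so a full
#' deterministic campaign runs from a config file alone.
#'
#' @param config a `pipeline_config` (or path to a YAML config).
#' @return the campaign report (named list), invisibly also written to
#'   `report$path` as JSON.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- pipeline_config(config)
  wd <- config$workdir
  pth <- function(p) if (is.null(p) || grepl("^/", p)) p else file.path(wd, p)
  report <- list(config = unclass(config), stages = list())
  fail <- function(stage, e) {
    .log_stage(stage, "FAILED: ", conditionMessage(e))
    report$stages[[stage]] <<- list(status = "failed",
                                    error = conditionMessage(e))
    report
  }
  seed <- as.integer(config$seed)

  if (isTRUE(config$simulate$enabled)) {
    res <- tryCatch({
      s <- config$simulate
      .log_stage("simulate", sprintf("seed=%d sizes=(%d,%d,%d)", seed,
                                     s$n_azide, s$n_alkyne, s$n_acid))
      if (!dir.exists(wd)) dir.create(wd, recursive = TRUE)
      bb <- gen_building_blocks(s$n_azide, s$n_alkyne, s$n_acid, seed = seed)
      write_building_blocks(c(bb$azides, bb$alkynes, bb$acids),
                            pth(config$enumerate$building_blocks))
      full <- expand.grid(i = seq_len(s$n_azide), j = seq_len(s$n_alkyne),
                          k = seq_len(s$n_acid))
      n_pl <- min(s$n_planned, nrow(full))
      planned <- full[with_seed(seed + 1L, sample(nrow(full), n_pl)), ]
      utils::write.csv(planned, pth(config$enumerate$planned), row.names = FALSE)
      plate <- gen_melt_plate(n_null = s$n_null,
                              shifters = data.frame(count = s$shifter_counts,
                                                    delta = s$shifter_deltas),
                              n_controls = s$n_controls, tm0 = s$tm0,
                              null_sd = s$null_sd, noise_frac = s$melt_noise,
                              seed = seed + 2L)
      utils::write.csv(plate, pth(config$tsa$plates), row.names = FALSE)
      kin <- do.call(rbind, lapply(seq_along(s$ic50_true), function(q) {
        k <- gen_dose_kinetics(ic50 = s$ic50_true[q], hill = s$hill_true,
                               noise_frac = s$dose_noise, n_rep = s$n_rep,
                               top_conc = config$ic50$dilution_top,
                               factor = config$ic50$dilution_factor,
                               points = config$ic50$dilution_points,
                               compound_id = sprintf("hit%d", q),
                               seed = seed + 10L + q)
        k$well <- paste0("h", q, "_", k$well)
        k
      }))
      utils::write.csv(kin, pth(config$ic50$kinetics), row.names = FALSE)
      list(status = "ok",
           truth = list(ssr_true = s$ssr_true,
                        shifters = data.frame(count = s$shifter_counts,
                                              delta = s$shifter_deltas),
                        ic50_true = s$ic50_true))
    }, error = function(e) e)
    if (inherits(res, "error")) return(invisible(fail("simulate", res)))
    report$stages$simulate <- res
  }

  # enumerate
  res <- tryCatch({
    e <- config$enumerate
    for (f in c(e$building_blocks, e$planned))
      if (!file.exists(pth(f))) stop("config error: missing input ", f)
    blocks <- read_building_blocks(pth(e$building_blocks))
    roles <- vapply(blocks, `[[`, character(1), "role")
    planned <- utils::read.csv(pth(e$planned))
    design <- library_design(e$library_label,
                             blocks[roles == "azide"], blocks[roles == "alkyne"],
                             blocks[roles == "acid"],
                             sulfonamide_carrier = if (any(vapply(
                               blocks[roles == "alkyne"], `[[`, logical(1),
                               "carries_sulfonamide"))) "alkyne" else "azide",
                             planned = planned)
    members <- enumerate_library(design)
    write_products(members, pth(e$products), pth(e$manifest))
    .log_stage("enumerate", sprintf("planned=%d ok=%d failed=%d theoretical=%d",
                                    nrow(members), sum(members$status == "ok"),
                                    sum(members$status != "ok"),
                                    count_theoretical(design)))
    list(status = "ok", planned = nrow(members),
         enumerated = sum(members$status == "ok"),
         theoretical_space = count_theoretical(design),
         members = members)
  }, error = function(e) e)
  if (inherits(res, "error")) return(invisible(fail("enumerate", res)))
  report$stages$enumerate <- res[names(res) != "members"]
  members <- res$members
  if (nrow(members) == 0L) {
    .log_stage("enumerate", "no planned members; downstream stages skipped")
    report$stages$track <- report$stages$tsa <- report$stages$ic50 <-
      list(status = "skipped", reason = "empty library")
    .write_report(report, pth(config$report$path))
    return(invisible(report))
  }

  # track: synthesize outcomes if simulating, else read them
  res <- tryCatch({
    oc_path <- pth(config$track$outcomes)
    if (isTRUE(config$simulate$enabled) && !file.exists(oc_path)) {
      oc <- gen_outcomes(members$member_id[members$status == "ok"],
                         ssr_true = config$simulate$ssr_true,
                         yield_mean = config$simulate$yield_mean,
                         yield_sd = config$simulate$yield_sd,
                         seed = seed + 3L)
      utils::write.csv(oc, oc_path, row.names = FALSE)
    }
    if (!file.exists(oc_path)) stop("config error: missing input ", oc_path)
    oc <- read_outcomes(oc_path)
    rep4 <- library_report(oc, report$stages$enumerate$theoretical_space,
                           config$enumerate$library_label)
    .log_stage("track", sprintf("isolated=%d/%d ssr=%d%%", rep4$isolated_count,
                                rep4$planned_count, rep4$ssr_percent))
    list(status = "ok", report = unclass(rep4))
  }, error = function(e) e)
  if (inherits(res, "error")) return(invisible(fail("track", res)))
  report$stages$track <- res

  # tsa
  res <- tryCatch({
    tp <- config$tsa
    if (!file.exists(pth(tp$plates))) stop("config error: missing input ", tp$plates)
    scr <- tsa_screen(pth(tp$plates), method = tp$method, k = tp$k,
                      floor = tp$floor, rsd_constant = tp$rsd_constant)
    nhit <- sum(scr$hits$hit_any)
    .log_stage("tsa", sprintf("%d hits (%d positive, %d negative)", nhit,
                              sum(scr$hits$hit_any & scr$hits$direction == "positive"),
                              sum(scr$hits$hit_any & scr$hits$direction == "negative")))
    list(status = "ok",
         hits = scr$hits[scr$hits$hit_any, c("compound_id", "max_abs_delta_tm",
                                             "direction")],
         plates = scr$plates)
  }, error = function(e) e)
  if (inherits(res, "error")) return(invisible(fail("tsa", res)))
  report$stages$tsa <- res

  # ic50
  res <- tryCatch({
    ip <- config$ic50
    if (!file.exists(pth(ip$kinetics))) stop("config error: missing input ", ip$kinetics)
    conf <- ic50_from_kinetics(pth(ip$kinetics),
                               top_concentration = ip$dilution_top)
    .log_stage("ic50", sprintf("%d compounds fitted, %d converged",
                               nrow(conf$summary), sum(conf$summary$converged)))
    list(status = "ok", table = conf$summary)
  }, error = function(e) e)
  if (inherits(res, "error")) return(invisible(fail("ic50", res)))
  report$stages$ic50 <- res

  .write_report(report, pth(config$report$path))
  invisible(report)
}

.write_report <- function(report, path) {
  js <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows", force = TRUE)
  writeLines(js, path)
  .log_stage("report", "written to ", path)
}
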