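# Parallel-synthesis bookkeeping.
#
# The synthesis success rate (SSR) is the percentage of planned parallel
# experiments that delivered an isolated library member; the mean isolated
# yield is averaged over the members that were isolated AND had a yield
# reported (isolated members without a yield count toward SSR only).
# Printed percentages are rounded half away from zero, so 186/247 prints
# as 75% and 76/89 as 85%.

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build a synthesis-outcome table
#'
#' @param member_id character vector of member ids.
#' @param isolated logical vector: was the target isolated?
#' @param yield_percent numeric isolated yield in percent, `NA` when not
#'   reported. A yield may only be present for isolated members and must
#'   lie in (0, 100].
#' @return data frame of class `synthesis_outcomes`.
#' @export
synthesis_outcomes <- function(member_id, isolated, yield_percent = NA_real_) {
  stopifnot(length(member_id) == length(isolated))
  yield_percent <- rep_len(as.numeric(yield_percent), length(member_id))
  isolated <- as.logical(isolated)
  if (anyNA(isolated)) stop("isolated flags must be TRUE/FALSE", call. = FALSE)
  has_y <- !is.na(yield_percent)
  if (any(has_y & !isolated))
    stop("yield reported for a member that was not isolated", call. = FALSE)
  if (any(has_y & (yield_percent <= 0 | yield_percent > 100)))
    stop("yields must lie in (0, 100]", call. = FALSE)
  structure(data.frame(member_id = as.character(member_id), isolated = isolated,
                       yield_percent = yield_percent, stringsAsFactors = FALSE),
            class = c("synthesis_outcomes", "data.frame"))
}

#' Read synthesis outcomes from CSV
#' @param path CSV with columns `member_id`, `isolated`, `yield_percent`.
#' @return `synthesis_outcomes` data frame.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("member_id", "isolated", "yield_percent")
  if (!all(need %in% names(df)))
    stop("outcomes CSV must have columns: ", paste(need, collapse = ", "))
  synthesis_outcomes(df$member_id, df$isolated, df$yield_percent)
}

#' Synthesis success rate
#'
#' @param outcomes `synthesis_outcomes` data frame.
#' @param rounded return the nearest-integer percentage (default) or the
#'   exact value.
#' @return SSR in percent.
#' @examples
#' oc <- synthesis_outcomes(sprintf("m%d", 1:4), c(TRUE, TRUE, TRUE, FALSE))
#' compute_ssr(oc)  # 75
#' @export
compute_ssr <- function(outcomes, rounded = TRUE) {
  stopifnot(inherits(outcomes, "synthesis_outcomes"))
  if (nrow(outcomes) == 0L) stop("no synthesis outcomes", call. = FALSE)
  ssr <- 100 * sum(outcomes$isolated) / nrow(outcomes)
  if (rounded) round_half_up(ssr) else ssr
}

#' Mean isolated yield
#'
#' Arithmetic mean over isolated members with a reported yield.
#'
#' @inheritParams compute_ssr
#' @return mean yield in percent.
#' @export
mean_yield <- function(outcomes, rounded = TRUE) {
  stopifnot(inherits(outcomes, "synthesis_outcomes"))
  y <- outcomes$yield_percent[outcomes$isolated & !is.na(outcomes$yield_percent)]
  if (length(y) == 0L) stop("no isolated members with reported yields", call. = FALSE)
  m <- mean(y)
  if (rounded) round_half_up(m) else m
}

#' Per-library performance report
#'
#' @param outcomes `synthesis_outcomes` for one library.
#' @param theoretical_space size of the library's full combination space.
#' @param library_label label for printing.
#' @return object of class `library_report` with planned/isolated counts,
#'   rounded SSR and mean yield, and the theoretical space.
#' @export
library_report <- function(outcomes, theoretical_space, library_label = "") {
  stopifnot(inherits(outcomes, "synthesis_outcomes"))
  has_yield <- any(outcomes$isolated & !is.na(outcomes$yield_percent))
  structure(list(
    library_label = as.character(library_label),
    planned_count = nrow(outcomes),
    isolated_count = sum(outcomes$isolated),
    ssr_percent = compute_ssr(outcomes),
    ssr_exact = compute_ssr(outcomes, rounded = FALSE),
    mean_yield_percent = if (has_yield) mean_yield(outcomes) else NA_real_,
    theoretical_space = as.integer(theoretical_space),
    yield_basis = "isolated members with reported yields only"
  ), class = "library_report")
}

#' Pool several library reports into a campaign report
#'
#' Counts and theoretical spaces are summed; the pooled SSR is recomputed
#' from the summed counts (not averaged over libraries), so the result is
#' invariant under permutation of the inputs.
#'
#' @param reports list of `library_report` objects (or several reports as
#'   `...`).
#' @return a pooled `library_report`.
#' @export
combined_report <- function(reports, ...) {
  if (inherits(reports, "library_report")) reports <- c(list(reports), list(...))
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, logical(1), "library_report")))
  g <- function(f) vapply(reports, `[[`, numeric(1), f)
  planned <- as.integer(sum(g("planned_count")))
  isolated <- as.integer(sum(g("isolated_count")))
  my <- g("mean_yield_percent"); iso <- g("isolated_count")
  pooled_yield <- if (all(is.na(my))) NA_real_ else {
    w <- iso[!is.na(my)]
    round_half_up(sum(my[!is.na(my)] * w) / sum(w))
  }
  structure(list(
    library_label = paste(vapply(reports, `[[`, character(1), "library_label"),
                          collapse = "+"),
    planned_count = planned,
    isolated_count = isolated,
    ssr_percent = round_half_up(100 * isolated / planned),
    ssr_exact = 100 * isolated / planned,
    mean_yield_percent = pooled_yield,
    theoretical_space = as.integer(sum(vapply(reports, `[[`, numeric(1),
                                              "theoretical_space"))),
    yield_basis = "isolated members with reported yields only"
  ), class = "library_report")
}

#' @export
print.library_report <- function(x, ...) {
  cat(sprintf("<library_report %s>\n", x$library_label))
  cat(sprintf("  planned experiments : %d\n", x$planned_count))
  cat(sprintf("  isolated members    : %d\n", x$isolated_count))
  cat(sprintf("  synthesis success   : %.0f%% (exact %.2f%%)\n",
              x$ssr_percent, x$ssr_exact))
  if (!is.na(x$mean_yield_percent))
    cat(sprintf("  mean isolated yield : %.0f%% (%s)\n",
                x$mean_yield_percent, x$yield_basis))
  cat(sprintf("  theoretical space   : %d combinations\n", x$theoretical_space))
  invisible(x)
}

#' Serialize a report to JSON
#' @param report `library_report`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string, invisibly when written to file.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "library_report"))
  x <- unclass(report)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
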