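# Centile curves, the monthly reference table, and per-child screening.

#' Fitted centile table of erupted-tooth counts
#'
#' Evaluates the fitted distribution's quantiles on an age grid, producing
#' the monthly reference table: raw (unrounded) centile values and an
#' integer-rounded copy clamped to the dentition range \[0, 20\].  Any
#' response offset used at fitting time (zero-count handling) is removed
#' before reporting.
#'
#' @param model a fitted `bcx_gamlss` model.
#' @param ages age grid in months (default integer 12..36, intersected with
#'   the model's fitted range unless extrapolation is allowed).
#' @param levels centile levels in percent (default 5, 25, 50, 75, 95).
#' @param allow_extrapolation permit ages outside the fitted range.
#' @return an object of class `centile_table`: a list with `raw` and
#'   `rounded` data.frames (columns `age_months`, then `p<level>`), plus the
#'   levels and the model family.
#' @export
centile_table <- function(model, ages = 12:36, levels = c(5, 25, 50, 75, 95),
                          allow_extrapolation = FALSE) {
  stopifnot(inherits(model, "bcx_gamlss"),
            all(levels > 0), all(levels < 100), !is.unsorted(levels))
  p <- predict_params(model, ages, allow_extrapolation = allow_extrapolation)
  raw <- data.frame(age_months = ages)
  for (lev in levels) {
    raw[[paste0("p", lev)]] <-
      qbcx(lev / 100, model$family, p$mu, p$sigma, p$nu, p$tau) - model$offset
  }
  rounded <- raw
  for (lev in levels) {
    cn <- paste0("p", lev)
    rounded[[cn]] <- pmin(pmax(round(raw[[cn]]), 0L), 20L)
  }
  structure(list(raw = raw, rounded = rounded, levels = levels,
                 family = model$family),
            class = "centile_table")
}

#' @export
print.centile_table <- function(x, ...) {
  cat("Reference centiles (", x$family, " fit), counts rounded to [0, 20]\n",
      sep = "")
  print(x$rounded, row.names = FALSE)
  invisible(x)
}

#' Screen one child's tooth count against the fitted curve
#'
#' Computes the model centile of the observed count at the child's corrected
#' age, the corresponding z-score, and a screening flag using configurable
#' centile cut-offs.  Defaults follow the convention for growth curves:
#' below the 3rd centile `atypical_low`, 3rd-10th `watch`, above the 97th
#' `atypical_high`, otherwise `typical`.  Ages outside the model's validity
#' range yield an explicit `out_of_range` flag instead of a silent answer.
#'
#' @param model a fitted `bcx_gamlss` model.
#' @param corrected_age_months the child's corrected age.
#' @param count observed erupted-tooth count (0-20).
#' @param child_id optional identifier echoed in the result.
#' @param cutoffs named numeric vector `c(low, watch, high)` of centile
#'   cut-offs in percent.  The 5th-centile alternative is available as
#'   `cutoffs = assess_cutoffs("p5")`.
#' @return a one-row data.frame: `child_id`, `corrected_age_months`, `count`,
#'   `centile`, `z`, `flag`.
#' @export
assess_child <- function(model, corrected_age_months, count,
                         child_id = NA_character_,
                         cutoffs = assess_cutoffs()) {
  stopifnot(inherits(model, "bcx_gamlss"),
            length(corrected_age_months) == 1, length(count) == 1,
            count >= 0, count <= 20)
  out_of_range <- corrected_age_months < model$age_range[1] - 1e-9 ||
    corrected_age_months > model$age_range[2] + 1e-9
  p <- predict_params(model, corrected_age_months, allow_extrapolation = TRUE)
  yy <- count + model$offset
  if (yy <= 0) yy <- 0.5  # a zero count under an offset-free fit
  cent <- 100 * pbcx(yy, model$family, p$mu, p$sigma, p$nu, p$tau)
  z <- stats::qnorm(pmin(pmax(cent / 100, 1e-12), 1 - 1e-12))
  flag <- if (out_of_range) "out_of_range"
  else if (cent < cutoffs["low"]) "atypical_low"
  else if (cent < cutoffs["watch"]) "watch"
  else if (cent > cutoffs["high"]) "atypical_high"
  else "typical"
  data.frame(child_id = child_id,
             corrected_age_months = corrected_age_months,
             count = count, centile = cent, z = z, flag = flag)
}

#' Screen a whole cohort against the fitted curve
#'
#' Vectorized equivalent of [assess_child()] applied to every record.
#'
#' @inheritParams assess_child
#' @param cohort data.frame with `child_id`, `corrected_age_months`,
#'   `n_teeth`.
#' @return a data.frame with one assessment row per child.
#' @export
assess_cohort <- function(model, cohort, cutoffs = assess_cutoffs()) {
  stopifnot(inherits(model, "bcx_gamlss"),
            all(c("corrected_age_months", "n_teeth") %in% names(cohort)))
  age <- cohort$corrected_age_months
  count <- cohort$n_teeth
  p <- predict_params(model, age, allow_extrapolation = TRUE)
  yy <- count + model$offset
  yy[yy <= 0] <- 0.5
  cent <- 100 * pbcx(yy, model$family, p$mu, p$sigma, p$nu, p$tau)
  z <- stats::qnorm(pmin(pmax(cent / 100, 1e-12), 1 - 1e-12))
  out_of_range <- age < model$age_range[1] - 1e-9 |
    age > model$age_range[2] + 1e-9
  flag <- ifelse(out_of_range, "out_of_range",
          ifelse(cent < cutoffs["low"], "atypical_low",
          ifelse(cent < cutoffs["watch"], "watch",
          ifelse(cent > cutoffs["high"], "atypical_high", "typical"))))
  data.frame(child_id = if ("child_id" %in% names(cohort))
               as.character(cohort$child_id) else NA_character_,
             corrected_age_months = age, count = count,
             centile = cent, z = z, flag = flag)
}

#' Screening cut-off presets
#'
#' @param preset `"p3"` (3/10/97 convention, default) or `"p5"` (5/10/95).
#' @return named numeric vector `c(low, watch, high)`.
#' @export
assess_cutoffs <- function(preset = c("p3", "p5")) {
  preset <- match.arg(preset)
  switch(preset,
         p3 = c(low = 3, watch = 10, high = 97),
         p5 = c(low = 5, watch = 10, high = 95))
}

#' Write the reference chart and table to files
#'
#' Renders the centile curves (age on the abscissa, counts 0-20 on the
#' ordinate, one labelled curve per level) and writes the rounded reference
#' table as CSV.  Output is deterministic given identical inputs.
#'
#' @param model the fitted model (used for curve smoothness between table
#'   ages).
#' @param table a [centile_table()].
#' @param dir output directory (created if absent).
#' @param basename file basename, default `"reference"`.
#' @return invisibly, the paths written (`table`, `chart`).
#' @export
reference_report <- function(model, table, dir, basename = "reference") {
  stopifnot(inherits(table, "centile_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  table_path <- file.path(dir, paste0(basename, "_table.csv"))
  utils::write.csv(table$rounded, table_path, row.names = FALSE)

  ages_fine <- seq(min(table$raw$age_months), max(table$raw$age_months),
                   by = 0.1)
  fine <- centile_table(model, ages = ages_fine, levels = table$levels,
                        allow_extrapolation = TRUE)$raw
  long <- do.call(rbind, lapply(table$levels, function(lev) {
    data.frame(age = fine$age_months,
               count = pmin(pmax(fine[[paste0("p", lev)]], 0), 20),
               centile = paste0("P", lev))
  }))
  long$centile <- factor(long$centile, levels = paste0("P", table$levels))
  gp <- ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$count,
                                           colour = .data$centile)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 20)) +
    ggplot2::labs(x = "Corrected age (months)",
                  y = "Number of erupted deciduous teeth",
                  colour = "Centile",
                  title = "Reference centile curves") +
    ggplot2::theme_minimal()
  chart_path <- file.path(dir, paste0(basename, "_chart.svg"))
  grDevices::svg(chart_path, width = 7, height = 5)
  print(gp)
  grDevices::dev.off()
  invisible(list(table = table_path, chart = chart_path))
}
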