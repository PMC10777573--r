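# Cohort file I/O and descriptive statistics.

.TOOTH_COLS <- paste0("t", c(51:55, 61:65, 71:75, 81:85))

#' Write a cohort to CSV (with a metadata sidecar)
#'
#' Writes the cohort as plain CSV; generator metadata (seed, generator name)
#' carried in the data.frame's attributes is written to
#' `<path>.meta.json`.
#'
#' @param cohort a cohort data.frame.
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  meta <- list(n = nrow(cohort),
               seed = attr(cohort, "seed"),
               generator = attr(cohort, "generator"),
               columns = names(cohort))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' Load and validate a cohort CSV
#'
#' Reads child records, resolves columns through an optional mapping, and
#' validates every row: the count must be an integer in \[0, 20\], per-tooth
#' flags (when present) must sum to the count, and an age must be available.
#' Invalid rows are never silently dropped: they are returned (and optionally
#' written) as a reject table with one reason per row, and
#' `valid + rejected = input` is asserted.  Corrected age is computed from
#' gestational age when missing.
#'
#' @param path CSV file.
#' @param mapping optional named character vector mapping standard names
#'   (`child_id, sex, chron_age_months, ga_weeks, corrected_age_months,
#'   n_teeth`) to the file's column names.
#' @param reject_path optional path for the reject CSV.
#' @return the validated cohort data.frame, with the rejects in attribute
#'   `rejects`.
#' @export
load_cohort <- function(path, mapping = NULL, reject_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  std <- c("child_id", "sex", "chron_age_months", "ga_weeks",
           "corrected_age_months", "n_teeth")
  if (!is.null(mapping)) {
    unknown <- setdiff(unname(mapping), names(raw))
    if (length(unknown))
      stop("mapped columns not in file: ", paste(unknown, collapse = ", "),
           "; available: ", paste(names(raw), collapse = ", "),
           call. = FALSE)
    for (s in names(mapping)) names(raw)[names(raw) == mapping[[s]]] <- s
  }
  missing_core <- setdiff(c("n_teeth"), names(raw))
  if (length(missing_core))
    stop("required column(s) missing: ",
         paste(missing_core, collapse = ", "),
         "; available: ", paste(names(raw), collapse = ", "), call. = FALSE)
  if (!"corrected_age_months" %in% names(raw))
    raw$corrected_age_months <- NA_real_
  if (!"ga_weeks" %in% names(raw)) raw$ga_weeks <- NA_real_
  if (!"chron_age_months" %in% names(raw)) raw$chron_age_months <- NA_real_
  if (!"child_id" %in% names(raw))
    raw$child_id <- sprintf("R%06d", seq_len(nrow(raw)))

  # fill corrected age where derivable
  derivable <- is.na(raw$corrected_age_months) &
    !is.na(raw$chron_age_months) & !is.na(raw$ga_weeks) &
    raw$ga_weeks >= 22 & raw$ga_weeks <= 44 & raw$chron_age_months > 0
  raw$corrected_age_months[derivable] <-
    corrected_age(raw$chron_age_months[derivable], raw$ga_weeks[derivable])

  flags_present <- all(.TOOTH_COLS %in% names(raw))
  reason <- rep(NA_character_, nrow(raw))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- why
  }
  bad(!is.finite(raw$n_teeth), "missing count")
  bad(raw$n_teeth < 0 | raw$n_teeth > 20, "count out of range")
  bad(is.finite(raw$n_teeth) & raw$n_teeth != round(raw$n_teeth),
      "non-integer count")
  if (flags_present) {
    fsum <- rowSums(raw[.TOOTH_COLS])
    bad(is.finite(fsum) & is.finite(raw$n_teeth) & fsum != raw$n_teeth,
        "flag/count mismatch")
  }
  bad(!is.finite(raw$corrected_age_months), "missing age")
  bad(is.finite(raw$corrected_age_months) &
        (raw$corrected_age_months <= 0 | raw$corrected_age_months > 60),
      "age out of range")

  ok <- is.na(reason)
  cohort <- raw[ok, , drop = FALSE]
  rejects <- cbind(raw[!ok, , drop = FALSE],
                   reject_reason = reason[!ok])
  stopifnot(nrow(cohort) + nrow(rejects) == nrow(raw))  # no silent data loss
  if (!is.null(reject_path) && nrow(rejects) > 0)
    utils::write.csv(rejects, reject_path, row.names = FALSE)
  if (nrow(cohort) == 0)
    stop("no valid rows after validation (", nrow(rejects), " rejected)",
         call. = FALSE)
  rownames(cohort) <- NULL
  attr(cohort, "rejects") <- rejects
  cohort
}

#' Descriptive statistics of a cohort
#'
#' The descriptive surface of the analysis: per-tooth presence percentages by
#' sex with a two-proportion chi-square p-value per tooth (continuity
#' uncorrected, only when per-tooth flags are available), mean erupted-teeth
#' counts by sex with a two-sample t-test, and per-month five-number
#' summaries (boxplot statistics) of the count.
#'
#' @param cohort a validated cohort data.frame.
#' @return a list: `per_tooth` (or NULL), `means_by_sex` (or NULL when only
#'   one sex is present, with a notice), `by_month`.
#' @export
describe_cohort <- function(cohort) {
  stopifnot(nrow(cohort) >= 1)
  sexes <- unique(cohort$sex[!is.na(cohort$sex)])
  two_sexes <- length(sexes) == 2

  per_tooth <- NULL
  if (all(.TOOTH_COLS %in% names(cohort)) && two_sexes) {
    per_tooth <- do.call(rbind, lapply(.TOOTH_COLS, function(cn) {
      tab <- table(factor(cohort[[cn]], levels = c(1, 0)),
                   factor(cohort$sex, levels = sexes))
      pv <- tryCatch(
        stats::chisq.test(tab, correct = FALSE)$p.value,
        warning = function(w)
          suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
        error = function(e) NA_real_)
      pct <- 100 * prop.table(tab, margin = 2)[1, ]
      out <- data.frame(tooth_fdi = sub("^t", "", cn))
      for (s in sexes) out[[paste0("pct_", s)]] <- unname(pct[s])
      out$p_value <- pv
      out
    }))
  }

  means_by_sex <- NULL
  if (two_sexes) {
    tt <- stats::t.test(n_teeth ~ sex, data = cohort)
    agg <- tapply(cohort$n_teeth, cohort$sex, mean)
    means_by_sex <- data.frame(
      sex = names(agg), mean_n_teeth = unname(agg),
      n = as.vector(table(cohort$sex)[names(agg)]), row.names = NULL)
    attr(means_by_sex, "t_test_p") <- tt$p.value
  } else {
    message("single-sex cohort: sex comparisons omitted")
  }

  mo <- floor(cohort$corrected_age_months)
  by_month <- do.call(rbind, lapply(sort(unique(mo)), function(m) {
    v <- cohort$n_teeth[mo == m]
    fn <- stats::fivenum(v)
    data.frame(age_month = m, n = length(v), min = fn[1], q1 = fn[2],
               median = fn[3], q3 = fn[4], max = fn[5])
  }))
  list(per_tooth = per_tooth, means_by_sex = means_by_sex,
       by_month = by_month)
}
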