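#' Normalized dying-tumor fraction of one classified volume
#'
#' The headline readout: the volume of voxels where the live tumor stain and
#' annexin V-APC co-localize (class \code{dying}), divided by the total tumor
#' volume. The default denominator is all green-positive tumor tissue
#' (\code{live + dying + til_on_live}), which stays observable at every
#' timepoint despite green loss in fully dead tissue; the alternative
#' \code{"all_tumor"} additionally counts the \code{dead} class.
#'
#' @param classified a [classify_voxels()] result.
#' @param denominator \code{"green_tumor"} (default) or \code{"all_tumor"}.
#' @return one-row data.frame (a dying-fraction record): fragment_id,
#'   condition (NA until joined with a layout), time_h, dying_volume_um3,
#'   total_tumor_volume_um3, dying_fraction, denominator, qc_flags. A zero
#'   denominator yields an NA fraction flagged \code{empty_tumor_mask}, never
#'   a fabricated value.
#' @export
dying_fraction <- function(classified,
                           denominator = c("green_tumor", "all_tumor")) {
  stopifnot(inherits(classified, "classified_volume"))
  denominator <- match.arg(denominator)
  v <- classified$volumes_um3
  dying <- unname(v["dying"])
  total <- unname(v["live"] + v["dying"] + v["til_on_live"])
  if (denominator == "all_tumor") total <- total + unname(v["dead"])
  qc <- character(0)
  frac <- if (total > 0) dying / total else {
    qc <- c(qc, "empty_tumor_mask")
    NA_real_
  }
  data.frame(fragment_id = classified$fragment_id,
             condition = NA_character_,
             time_h = classified$time_h,
             dying_volume_um3 = dying,
             total_tumor_volume_um3 = total,
             dying_fraction = frac,
             denominator = denominator,
             qc_flags = paste(qc, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Per-condition dying-fraction trajectories
#'
#' Joins per-fragment records with the experiment layout and summarizes per
#' condition and timepoint. Gaps (expected fragment x timepoint combinations
#' without a record) are kept as NA rows flagged \code{missing_timepoint};
#' nothing is interpolated. The standard error is sd/sqrt(n) and is NA
#' (flagged \code{se_undefined}) for single-fragment groups.
#'
#' @param records data.frame of [dying_fraction()] rows.
#' @param layout an [load_layout()] result.
#' @return list with \code{fragments} (tidy fragment x time table) and
#'   \code{conditions} (condition x time: n, mean_fraction, se_fraction,
#'   qc_flags).
#' @export
dying_timeseries <- function(records, layout) {
  stopifnot(is.data.frame(records), inherits(layout, "experiment_layout"))
  unknown <- setdiff(records$fragment_id, layout$fragments$fragment_id)
  if (length(unknown))
    stop_config("record(s) reference fragment(s) absent from the layout: ",
                paste(unknown, collapse = ", "))

  grid <- expand.grid(fragment_id = layout$fragments$fragment_id,
                      time_h = layout$time_points,
                      stringsAsFactors = FALSE)
  grid <- merge(grid, layout$fragments, by = "fragment_id")
  keep <- setdiff(names(records), "condition")
  tab <- merge(grid, records[keep], by = c("fragment_id", "time_h"),
               all.x = TRUE, sort = FALSE)
  miss <- is.na(tab$dying_fraction) &
    (is.na(tab$qc_flags) | tab$qc_flags == "")
  tab$qc_flags[is.na(tab$qc_flags)] <- ""
  tab$qc_flags[miss] <- "missing_timepoint"
  tab <- tab[order(tab$condition, tab$fragment_id, tab$time_h), ]
  rownames(tab) <- NULL

  agg <- do.call(rbind, lapply(
    split(tab, list(tab$condition, tab$time_h), drop = TRUE),
    function(d) {
      x <- d$dying_fraction[!is.na(d$dying_fraction)]
      n <- length(x)
      data.frame(condition = d$condition[1], time_h = d$time_h[1],
                 n = n,
                 mean_fraction = if (n > 0) mean(x) else NA_real_,
                 se_fraction = std_error(x),
                 qc_flags = if (n < 2) "se_undefined" else "",
                 stringsAsFactors = FALSE)
    }))
  agg <- agg[order(agg$condition, agg$time_h), ]
  rownames(agg) <- NULL
  list(fragments = tab, conditions = agg)
}

#' Fold increase of a treated group over the control
#'
#' The field reports "x-fold increase" under two conventions; both are always
#' returned side by side: \code{relative_increase = (treated - control) /
#' control} and \code{ratio = treated / control}. (A treated mean of 13\%
#' over a control of 8\% is a 0.625 relative increase -- reported as a
#' "0.6-fold increase" -- while 25\% over 8\% is a 3.125 ratio, reported as
#' "approximately 3-fold".) A non-positive control mean yields NA values
#' flagged \code{control_zero}.
#'
#' @param treated_mean,control_mean group mean fractions (or percentages; the
#'   result is scale-invariant).
#' @param condition,time_h optional provenance columns.
#' @return one-row data.frame: condition, time_h, treated_mean, control_mean,
#'   relative_increase, ratio, qc_flags.
#' @export
fold_increase <- function(treated_mean, control_mean,
                          condition = NA_character_, time_h = NA_real_) {
  stopifnot(is_scalar_number(treated_mean) || is.na(treated_mean),
            is_scalar_number(control_mean) || is.na(control_mean))
  qc <- character(0)
  if (is.na(treated_mean) || is.na(control_mean)) {
    qc <- c(qc, "missing_mean"); rel <- NA_real_; ratio <- NA_real_
  } else if (control_mean <= 0) {
    qc <- c(qc, "control_zero"); rel <- NA_real_; ratio <- NA_real_
  } else {
    rel <- (treated_mean - control_mean) / control_mean
    ratio <- treated_mean / control_mean
  }
  data.frame(condition = condition, time_h = time_h,
             treated_mean = treated_mean, control_mean = control_mean,
             relative_increase = rel, ratio = ratio,
             qc_flags = paste(qc, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Fold-increase table across treated conditions and timepoints
#'
#' @param condition_summary the \code{conditions} table from
#'   [dying_timeseries()].
#' @param control_condition the reference condition (default isotype).
#' @param time_h timepoints to report; default all.
#' @return data.frame of [fold_increase()] rows (zero rows when there is no
#'   treated condition).
#' @export
fold_increase_table <- function(condition_summary,
                                control_condition = "isotype",
                                time_h = NULL) {
  stopifnot(is.data.frame(condition_summary))
  ctrl <- condition_summary[condition_summary$condition == control_condition, ]
  treated <- setdiff(unique(condition_summary$condition), control_condition)
  times <- time_h %||% sort(unique(condition_summary$time_h))
  rows <- list()
  for (cond in treated) for (t in times) {
    tm <- condition_summary$mean_fraction[
      condition_summary$condition == cond & condition_summary$time_h == t]
    cm <- ctrl$mean_fraction[ctrl$time_h == t]
    if (!length(tm) || !length(cm)) next
    rows[[length(rows) + 1L]] <- fold_increase(tm, cm, condition = cond,
                                               time_h = t)
  }
  if (!length(rows))
    return(data.frame(condition = character(0), time_h = numeric(0),
                      treated_mean = numeric(0), control_mean = numeric(0),
                      relative_increase = numeric(0), ratio = numeric(0),
                      qc_flags = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
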