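#' Select the number of synergies from a tVAF curve
#'
#' Dual-criterion rule: the number of synergies (NoS) is the smallest k such
#' that (1) tVAF(k) exceeds `tvaf_threshold` (strictly) AND (2) adding one
#' more synergy raises tVAF by at most `increment_threshold` percentage
#' points (criterion 2 is vacuously met at the last k). If no k satisfies
#' both, the largest candidate is returned with `criteria_met = FALSE`.
#'
#' @param curve a `"tvaf_curve"` or a numeric vector of tVAF values for
#'   k = 1, 2, ... (assumed non-decreasing).
#' @param tvaf_threshold tVAF threshold in percent (default 90).
#' @param increment_threshold maximum tolerated tVAF gain for one extra
#'   synergy, in percentage points (default 1).
#' @return List of class `"nos_result"`: `nos`, `tvaf_at_nos`,
#'   `criterion1_k` (smallest k with tVAF above threshold, NA if none),
#'   `criteria_met`, plus curve identifiers.
#' @export
select_nos <- function(curve, tvaf_threshold = 90, increment_threshold = 1) {
  if (inherits(curve, "tvaf_curve")) {
    tv <- curve$tvaf_by_k
    ks <- curve$k_range
    pid <- curve$participant_id
    tid <- curve$task_id
  } else {
    tv <- as.numeric(curve)
    ks <- seq_along(tv)
    pid <- NA
    tid <- NA
  }
  if (length(tv) == 0) stop("empty tVAF curve", call. = FALSE)

  c1 <- which(tv > tvaf_threshold)
  criterion1_k <- if (length(c1) > 0) ks[c1[1]] else NA_integer_
  nos <- NA_integer_
  for (i in seq_along(tv)) {
    ok1 <- tv[i] > tvaf_threshold
    ok2 <- i == length(tv) || (tv[i + 1] - tv[i]) <= increment_threshold
    if (ok1 && ok2) { nos <- ks[i]; break }
  }
  criteria_met <- !is.na(nos)
  if (!criteria_met) nos <- ks[length(ks)]

  structure(list(
    participant_id = pid, task_id = tid,
    nos = as.integer(nos),
    tvaf_at_nos = tv[match(nos, ks)],
    criterion1_k = criterion1_k,
    criteria_met = criteria_met
  ), class = "nos_result")
}

#' Study-wide number of synergies (NoSoA)
#'
#' The arithmetic mean of all per-participant, per-task NoS values, rounded
#' half-up to the nearest integer, so that every cross-participant and
#' cross-task comparison operates at a common rank.
#'
#' @param nos numeric vector of NoS values, a list of `"nos_result"`
#'   objects, or a data frame with a `nos` column.
#' @return Integer NoSoA.
#' @export
nosoa <- function(nos) {
  if (is.data.frame(nos)) nos <- nos$nos
  if (is.list(nos)) nos <- vapply(nos, function(x) as.numeric(x$nos), 0)
  if (length(nos) == 0) stop("no NoS values supplied", call. = FALSE)
  as.integer(floor(mean(nos) + 0.5))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values numeric vector with at least 2 entries and nonzero mean.
#' @return CoV as a ratio (not percent).
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("CoV needs at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CoV undefined for zero mean", call. = FALSE)
  sd(values) / m
}

#' Tabulate NoS and tVAF per participant and task
#'
#' Applies [select_nos()] to every curve, derives the study-wide NoSoA, and
#' reads the tVAF at NoS and at NoSoA off each curve.
#'
#' @param curves nested list: `curves[[participant]][[task]]` is a
#'   `"tvaf_curve"`.
#' @param tvaf_threshold,increment_threshold passed to [select_nos()].
#' @return List with `table` (data frame: participant, task, nos,
#'   tvaf_at_nos, tvaf_at_nosoa, criteria_met) and `nosoa`.
#' @export
nos_table <- function(curves, tvaf_threshold = 90, increment_threshold = 1) {
  rows <- list()
  sel <- list()
  for (p in names(curves)) {
    for (t in names(curves[[p]])) {
      s <- select_nos(curves[[p]][[t]], tvaf_threshold, increment_threshold)
      sel[[length(sel) + 1L]] <- list(p = p, t = t, s = s,
                                      curve = curves[[p]][[t]])
    }
  }
  k_all <- nosoa(lapply(sel, function(x) x$s))
  for (x in sel) {
    tv_at_nosoa <- x$curve$tvaf_by_k[match(k_all, x$curve$k_range)]
    rows[[length(rows) + 1L]] <- data.frame(
      participant = x$p, task = x$t, nos = x$s$nos,
      tvaf_at_nos = x$s$tvaf_at_nos,
      tvaf_at_nosoa = if (length(tv_at_nosoa) == 1) tv_at_nosoa else NA_real_,
      criteria_met = x$s$criteria_met,
      stringsAsFactors = FALSE
    )
  }
  list(table = do.call(rbind, rows), nosoa = k_all)
}

#' Per-task coefficient-of-variation summary
#'
#' Mirrors the usual inter-participant variability table: per task, the CoV,
#' mean and SD of NoS, tVAF at NoS and tVAF at NoSoA across participants.
#'
#' @param nos_tbl the `table` element of [nos_table()].
#' @return Data frame with one row per task and metric.
#' @export
cov_summary <- function(nos_tbl) {
  metrics <- c(nos = "nos", tvaf_at_nos = "tvaf_at_nos",
               tvaf_at_nosoa = "tvaf_at_nosoa")
  rows <- list()
  for (task in unique(nos_tbl$task)) {
    sub <- nos_tbl[nos_tbl$task == task, ]
    for (mi in names(metrics)) {
      v <- sub[[metrics[mi]]]
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, metric = mi,
        cov = coefficient_of_variation(v),
        mean = mean(v), sd = sd(v),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
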