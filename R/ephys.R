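#' Construct a current trace
#'
#' A uniformly sampled whole-cell current record. Sample `k` is taken at
#' time `(k - 1) / sample_rate` seconds, so the first sample sits at t = 0.
#'
#' @param samples Numeric vector of current values in pA (inward currents
#'   negative).
#' @param sample_rate Sampling rate in Hz (e.g. 50000).
#' @param step_onset Time of the voltage-step onset in seconds; must lie
#'   within the record.
#' @param capacitance Optional cell capacitance in pF (needed for current
#'   densities).
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(samples, sample_rate, step_onset, capacitance = NULL) {
  stopifnot(sample_rate > 0, length(samples) >= 2L)
  dur <- (length(samples) - 1) / sample_rate
  if (step_onset < 0 || step_onset > dur)
    stop("step_onset outside the record (0 to ", signif(dur, 4), " s)")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 step_onset = step_onset, capacitance = capacitance),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples @ %g kHz, step at %g ms%s\n",
              length(x$samples), x$sample_rate / 1000, x$step_onset * 1000,
              if (!is.null(x$capacitance)) sprintf(", C = %g pF", x$capacitance) else ""))
  invisible(x)
}

.trace_times <- function(t) (seq_along(t$samples) - 1) / t$sample_rate

#' Zero-subtract a trace against its pre-step baseline
#'
#' Subtracts the mean current of the `baseline_window` seconds immediately
#' preceding the voltage step, so the holding-level current reads zero.
#'
#' @param t A [current_trace()].
#' @param baseline_window Window length in seconds before the step onset
#'   (default 0.14 s).
#' @return The zero-subtracted `current_trace`.
#' @export
zero_subtract <- function(t, baseline_window = 0.14) {
  stopifnot(inherits(t, "current_trace"))
  if (baseline_window > t$step_onset + 1e-12)
    stop("baseline window (", baseline_window,
         " s) exceeds the pre-step record (", t$step_onset, " s)")
  tt <- .trace_times(t)
  idx <- tt >= (t$step_onset - baseline_window) & tt < t$step_onset
  if (!any(idx)) stop("no samples in the baseline window")
  t$samples <- t$samples - mean(t$samples[idx])
  t
}

# Indices of samples with t0 <= (time - step_onset) < t1 (half-open window
# aligned to sample times at or after t0).
.window_idx <- function(t, t0, t1) {
  rel <- .trace_times(t) - t$step_onset
  which(rel >= t0 - 1e-12 & rel < t1 - 1e-12)
}

#' Mean current density over a post-step window
#'
#' Arithmetic mean of the samples in the half-open window
#' `[t0, t1)` after the step onset, divided by the cell capacitance.
#'
#' @param t A [current_trace()] with `capacitance` set.
#' @param t0,t1 Window bounds in seconds after step onset (defaults 0.4 ms
#'   and 1.0 ms).
#' @return Mean current density in pA/pF.
#' @export
window_mean_density <- function(t, t0 = 0.4e-3, t1 = 1.0e-3) {
  stopifnot(inherits(t, "current_trace"), t1 > t0)
  if (is.null(t$capacitance)) stop("capacitance required for current density")
  idx <- .window_idx(t, t0, t1)
  if (length(idx) == 0L) stop("window contains no samples")
  mean(t$samples[idx]) / t$capacitance
}

#' Peak current density and peak time in a post-step window
#'
#' Extremum of the signed current in the half-open window (default
#' 0.4-8 ms after the step): the most negative sample for the inward
#' convention, the most positive for outward.
#'
#' @param t A [current_trace()] with `capacitance` set.
#' @param window Numeric length-2 window in seconds after step onset.
#' @param polarity `"inward"` (default) or `"outward"`.
#' @return A list with `density` (pA/pF), `time_ms` (ms after step onset)
#'   and `polarity`.
#' @export
peak_density_and_time <- function(t, window = c(0.4e-3, 8e-3),
                                  polarity = c("inward", "outward")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(t, "current_trace"))
  if (is.null(t$capacitance)) stop("capacitance required for current density")
  idx <- .window_idx(t, window[1], window[2])
  if (length(idx) == 0L) stop("window contains no samples")
  v <- t$samples[idx]
  k <- if (polarity == "inward") which.min(v) else which.max(v)
  list(density = v[k] / t$capacitance,
       time_ms = ((idx[k] - 1) / t$sample_rate - t$step_onset) * 1000,
       polarity = polarity)
}

#' Subtract two traces (drug-sensitive component)
#'
#' Samplewise `pre - post`, the standard way to isolate the drug-sensitive
#' current from total and drug-resistant records. Conservation holds
#' exactly: result + post == pre.
#'
#' @param pre_drug,post_drug Zero-subtracted [current_trace()] objects with
#'   identical length and sample rate.
#' @return A `current_trace` holding the difference.
#' @export
subtract_traces <- function(pre_drug, post_drug) {
  stopifnot(inherits(pre_drug, "current_trace"),
            inherits(post_drug, "current_trace"))
  if (length(pre_drug$samples) != length(post_drug$samples) ||
      pre_drug$sample_rate != post_drug$sample_rate)
    stop("traces must have identical length and sample rate")
  out <- pre_drug
  out$samples <- pre_drug$samples - post_drug$samples
  out
}

#' Percentage of action potentials remaining under drug
#'
#' `100 * ap_drug / ap_baseline`, rounded half away from zero to one
#' decimal. A zero baseline makes the metric undefined: such entries return
#' `NA` (flagged via the `"undefined"` attribute) and are excluded from
#' group averages downstream.
#'
#' @param ap_drug,ap_baseline Action-potential counts for the same stimulus
#'   train (drug and control).
#' @return Numeric vector of percentages (one decimal).
#' @export
remaining_ap_percent <- function(ap_drug, ap_baseline) {
  stopifnot(length(ap_drug) == length(ap_baseline),
            all(ap_drug >= 0), all(ap_baseline >= 0))
  undef <- ap_baseline == 0
  out <- ifelse(undef, NA_real_,
                round_half_up(100 * ap_drug / ap_baseline, 1))
  attr(out, "undefined") <- undef
  out
}

#' Percent change in rheobase
#'
#' `100 * (r_drug - r_baseline) / r_baseline`, one decimal, half away from
#' zero.
#'
#' @param r_drug,r_baseline Rheobase values in pA; baseline must be
#'   positive.
#' @return Numeric vector of percent changes.
#' @export
rheobase_change_percent <- function(r_drug, r_baseline) {
  if (any(r_baseline <= 0)) stop("baseline rheobase must be positive")
  round_half_up(100 * (r_drug - r_baseline) / r_baseline, 1)
}

.EPHYS_FREQS <- c("0.1", "1", "3", "10")
.EPHYS_AP_COLS <- paste0("aps_", .EPHYS_FREQS, "Hz")
.EPHYS_STIM <- c(`0.1` = 10, `1` = 120, `3` = 120, `10` = 120)

#' Read a per-cell excitability table
#'
#' CSV with one row per (cell, dose): columns `cell`, `dose` (the string
#' `"baseline"` or a concentration in uM), `rheobase_pA`, and AP counts
#' `aps_0.1Hz`, `aps_1Hz`, `aps_3Hz`, `aps_10Hz` for trains delivered at
#' 150% of baseline rheobase (10 steps at 0.1 Hz, up to 120 at the higher
#' frequencies).
#'
#' @param path CSV path.
#' @return A data.frame of class `ephys_cells`.
#' @export
read_ephys_cells <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(cell = "character", dose = "character"))
  need <- c("cell", "dose", "rheobase_pA", .EPHYS_AP_COLS)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ephys table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$rheobase_pA <= 0)) stop("rheobase must be positive")
  for (f in .EPHYS_FREQS) {
    col <- paste0("aps_", f, "Hz")
    if (any(df[[col]] < 0 | df[[col]] > .EPHYS_STIM[[f]]))
      stop("AP count exceeds stimulus count in column ", col)
  }
  class(df) <- c("ephys_cells", "data.frame")
  df
}

#' Per-cell percent metrics of an excitability table
#'
#' Expands an `ephys_cells` table into the derived percent columns:
#' rheobase percent change versus each cell's baseline row, and
#' remaining-AP percentages per stimulation frequency.
#'
#' @param cells An `ephys_cells` data.frame (see [read_ephys_cells()]).
#' @return A long data.frame with columns `cell`, `dose`, `metric`
#'   (`"rheobase_change"` or `"remaining_ap"`), `frequency_Hz` (NA for
#'   rheobase) and `percent` (one decimal; NA where undefined).
#' @export
ephys_percent_table <- function(cells) {
  stopifnot(all(c("cell", "dose", "rheobase_pA") %in% names(cells)))
  out <- list()
  for (cl in unique(cells$cell)) {
    sub <- cells[cells$cell == cl, , drop = FALSE]
    b <- sub[sub$dose == "baseline", , drop = FALSE]
    if (nrow(b) != 1L)
      stop("cell ", cl, " must have exactly one baseline row")
    for (r in seq_len(nrow(sub))) {
      out[[length(out) + 1L]] <- data.frame(
        cell = cl, dose = sub$dose[r], metric = "rheobase_change",
        frequency_Hz = NA_real_,
        percent = rheobase_change_percent(sub$rheobase_pA[r], b$rheobase_pA),
        stringsAsFactors = FALSE)
      for (f in .EPHYS_FREQS) {
        col <- paste0("aps_", f, "Hz")
        out[[length(out) + 1L]] <- data.frame(
          cell = cl, dose = sub$dose[r], metric = "remaining_ap",
          frequency_Hz = as.numeric(f),
          percent = as.numeric(remaining_ap_percent(sub[[col]][r], b[[col]])),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Group mean and SEM of per-cell percent metrics
#'
#' Summarizes an excitability table the way dose-effect tables are printed:
#' per (dose, frequency) group, the mean and standard error of the per-cell
#' one-decimal percentages (SEM = sample SD / sqrt(n)), both reported to one
#' decimal. Cells whose metric is undefined at a (dose, frequency) — zero
#' baseline APs — are excluded from that group. Groups of one cell report
#' the mean with an NA SEM. When `group_col` names a two-level column of
#' `cells`, an unpaired two-sided Student's t-test between the two groups is
#' added per row.
#'
#' @param cells An `ephys_cells` data.frame.
#' @param metric `"remaining_ap"` or `"rheobase_change"`.
#' @param group_col Optional name of a two-level grouping column (e.g.
#'   vehicle versus drug) for the t-test.
#' @return A data.frame with columns `dose`, `frequency_Hz` (remaining-AP
#'   only), `n`, `mean`, `sem`, and (with `group_col`) `t`, `df`, `p`.
#' @export
summarize_cells <- function(cells, metric = c("remaining_ap", "rheobase_change"),
                            group_col = NULL) {
  metric <- match.arg(metric)
  pct <- ephys_percent_table(cells)
  pct <- pct[pct$metric == metric, , drop = FALSE]
  if (!is.null(group_col)) {
    stopifnot(group_col %in% names(cells))
    pct$group <- cells[[group_col]][match(pct$cell, cells$cell)]
    if (length(unique(pct$group)) != 2L)
      stop("group_col must have exactly two levels")
  }
  keyvars <- if (metric == "remaining_ap") c("dose", "frequency_Hz") else "dose"
  keys <- unique(pct[keyvars])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    sel <- rep(TRUE, nrow(pct))
    for (v in keyvars) sel <- sel & (pct[[v]] %in% keys[[v]][k])
    vals <- pct$percent[sel]
    ok <- !is.na(vals)
    n <- sum(ok)
    row <- cbind(keys[k, , drop = FALSE],
                 data.frame(n = n,
                            mean = if (n) round_half_up(mean(vals[ok]), 1) else NA_real_,
                            sem = if (n > 1)
                              round_half_up(stats::sd(vals[ok]) / sqrt(n), 1)
                            else NA_real_))
    if (!is.null(group_col)) {
      g <- pct$group[sel][ok]
      v <- vals[ok]
      if (length(unique(g)) == 2L && all(table(g) >= 2L)) {
        tt <- stats::t.test(v ~ g, var.equal = FALSE)
        row$t <- unname(tt$statistic); row$df <- unname(tt$parameter)
        row$p <- tt$p.value
      } else {
        row$t <- NA_real_; row$df <- NA_real_; row$p <- NA_real_
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
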