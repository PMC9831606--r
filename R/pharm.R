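#' Fraction of current inhibited
#'
#' `1 - i_drug / i_control`, clipped to `[0, 1]`. Clipping (which can occur
#' with current run-up or run-down between control and drug) is flagged in
#' the `"clipped"` attribute.
#'
#' @param i_drug,i_control Current amplitudes with the same sign convention
#'   (inward currents negative). `i_control` must be non-zero.
#' @return Numeric vector of fractions in `[0, 1]` with a logical
#'   `"clipped"` attribute.
#' @export
fraction_inhibited <- function(i_drug, i_control) {
  if (any(i_control == 0)) stop("zero control current")
  if (any(sign(i_drug) * sign(i_control) < 0))
    stop("i_drug and i_control must share a sign convention")
  f <- 1 - i_drug / i_control
  clipped <- f < 0 | f > 1
  f <- pmin(1, pmax(0, f))
  attr(f, "clipped") <- clipped
  f
}

# Hill model with floor 0 and ceiling 1 in log-concentration space:
# f = [L]^h / (IC50^h + [L]^h) = plogis(h * (log [L] - log IC50)).
.hill <- function(conc, ic50, h) stats::plogis(h * (log(conc) - log(ic50)))

# Vectorized Levenberg-Marquardt refit of the 2-parameter Hill model on B
# datasets at once (rows of X = log concentration, Y = response). Parameters
# are la = log(IC50) and lh = log(h); closed-form 2x2 normal equations per
# row keep the whole sweep in matrix arithmetic. Used for the bootstrap,
# where thousands of warm-started refits are needed.
.hill_refit_batch <- function(X, Y, la0, lh0, fix_h = NULL,
                              max_iter = 60L, tol = 1e-10) {
  B <- nrow(X)
  la <- rep(la0, length.out = B)
  lh <- rep(if (is.null(fix_h)) lh0 else log(fix_h), length.out = B)
  lam <- rep(1e-3, B)
  sse_of <- function(la, lh) {
    mu <- stats::plogis(exp(lh) * (X - la))
    rowSums((Y - mu)^2)
  }
  sse <- sse_of(la, lh)
  lo_a <- min(X) - 12; hi_a <- max(X) + 12
  for (it in seq_len(max_iter)) {
    h <- exp(lh)
    mu <- stats::plogis(h * (X - la))
    r <- Y - mu
    w <- mu * (1 - mu)
    da <- -h * w                # d mu / d la
    db <- h * (X - la) * w      # d mu / d lh
    g1 <- rowSums(da * r); H11 <- rowSums(da * da)
    if (is.null(fix_h)) {
      g2 <- rowSums(db * r)
      H12 <- rowSums(da * db); H22 <- rowSums(db * db)
      h11 <- H11 * (1 + lam) + 1e-12
      h22 <- H22 * (1 + lam) + 1e-12
      det <- h11 * h22 - H12 * H12
      s1 <- (g1 * h22 - g2 * H12) / det
      s2 <- (g2 * h11 - g1 * H12) / det
    } else {
      s1 <- g1 / (H11 * (1 + lam) + 1e-12)
      s2 <- 0
    }
    la_t <- pmin(hi_a, pmax(lo_a, la + s1))
    lh_t <- pmin(log(50), pmax(log(1e-3), lh + s2))
    sse_t <- sse_of(la_t, lh_t)
    acc <- is.finite(sse_t) & sse_t <= sse
    la[acc] <- la_t[acc]; lh[acc] <- lh_t[acc]; sse[acc] <- sse_t[acc]
    lam[acc] <- pmax(1e-9, lam[acc] / 4)
    lam[!acc] <- pmin(1e9, lam[!acc] * 6)
    # stop once every row's proposed step is negligible (heavily damped rows
    # propose tiny steps, so this also covers stalled rows)
    if (max(abs(s1), abs(s2)) < tol) break
  }
  list(ic50 = exp(la), h = exp(lh), sse = sse)
}

# Rowwise standard error of la = log(IC50) from the Gauss-Newton covariance
# at the supplied parameters (2x2 normal equations in closed form).
.hill_se_batch <- function(X, Y, la, lh) {
  h <- exp(lh)
  mu <- stats::plogis(h * (X - la))
  r <- Y - mu
  w <- mu * (1 - mu)
  J1 <- -h * w
  J2 <- h * (X - la) * w
  H11 <- rowSums(J1 * J1); H12 <- rowSums(J1 * J2); H22 <- rowSums(J2 * J2)
  det <- H11 * H22 - H12 * H12
  s2 <- rowSums(r * r) / (ncol(X) - 2)
  sqrt(s2 * H22 / det)
}

#' Fit the Hill equation to concentration-response data
#'
#' Least-squares fit of `f([L]) = [L]^h / (IC50^h + [L]^h)` (floor 0,
#' ceiling 1, i.e. complete block at saturation) with the optimization done
#' in `log(IC50)` and `log(h)` space via [minpack.lm::nlsLM()]. The default
#' 95% confidence interval is a seeded case-resampling bootstrap-t
#' (studentized) interval on `log(IC50)`: the (concentration, response)
#' points are resampled with replacement, each resample is refit with a
#' vectorized Levenberg-Marquardt engine warm-started at the point estimate,
#' and the studentized pivot quantiles calibrate the interval. The
#' studentized flavour is the default because the plain percentile interval
#' measurably undercovers at typical per-peptide design sizes (about 15
#' points); the percentile interval and a Wald interval on `log(IC50)`
#' remain available for cross-checking.
#'
#' @param dr A data.frame with columns `concentration_nM` and
#'   `fraction_inhibited` (optionally `cell_id`), or a `dose_response`
#'   object from [gen_dose_response()].
#' @param fix_h Optional fixed Hill coefficient; when given, two distinct
#'   concentrations suffice (otherwise three are required, mirroring the
#'   usual per-cell acceptance criterion).
#' @param ci_method `"bootstrap"` (studentized, default), `"percentile"`,
#'   or `"wald"`.
#' @param B Number of bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap resampling (the caller's RNG state is
#'   left untouched).
#' @param free_top If TRUE, the ceiling is a free parameter in `(0, 1]`
#'   rather than fixed at 1 (for partial blockers).
#' @return An object of class `hill_fit`: list with `ic50` (nM), `h`,
#'   `ci95` (nM), `ci95_h`, `n_cells`, `n_points`, `sse`, `ci_method`,
#'   `converged`.
#' @export
fit_hill <- function(dr, fix_h = NULL,
                     ci_method = c("bootstrap", "percentile", "wald"),
                     B = 2000, seed = NULL, free_top = FALSE) {
  ci_method <- match.arg(ci_method)
  conc <- dr$concentration_nM
  y <- dr$fraction_inhibited
  stopifnot(length(conc) == length(y), length(conc) >= 2L)
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (any(y < 0 | y > 1)) stop("fractions must lie in [0, 1]")
  ndist <- length(unique(conc))
  if (is.null(fix_h) && ndist < 3L)
    stop("need at least 3 distinct concentrations (or fix_h with at least 2)")
  if (!is.null(fix_h) && ndist < 2L)
    stop("need at least 2 distinct concentrations")
  if (all(y == 0)) stop("all responses are zero: no inhibition to fit")
  x <- log(conc)
  # start log(IC50) where the response crosses 0.5
  o <- order(x)
  la0 <- tryCatch(stats::approx(y[o], x[o], xout = 0.5, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(la0)) la0 <- stats::median(x)
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch({
    if (free_top) {
      minpack.lm::nlsLM(y ~ stats::plogis(qt) * stats::plogis(exp(lh) * (x - la)),
                             data = dat,
                             start = list(la = la0, lh = 0, qt = 4),
                             control = minpack.lm::nls.lm.control(maxiter = 300))
    } else if (is.null(fix_h)) {
      minpack.lm::nlsLM(y ~ stats::plogis(exp(lh) * (x - la)), data = dat,
                        start = list(la = la0, lh = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 300))
    } else {
      minpack.lm::nlsLM(y ~ stats::plogis(fix_h * (x - la)), data = dat,
                        start = list(la = la0),
                        control = minpack.lm::nls.lm.control(maxiter = 300))
    }
  }, error = function(e)
    stop("Hill fit did not converge: ", conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  ic50 <- exp(cf[["la"]])
  h <- if (!is.null(fix_h)) fix_h else exp(cf[["lh"]])
  top <- if (free_top) stats::plogis(cf[["qt"]]) else 1
  n <- length(y)
  if (ci_method %in% c("bootstrap", "percentile")) {
    idx <- with_seed(seed,
                     matrix(sample.int(n, n * B, replace = TRUE), nrow = B))
    Xb <- matrix(x[idx], nrow = B)
    Yb <- matrix(y[idx], nrow = B)
    bb <- .hill_refit_batch(Xb, Yb, la0 = log(ic50), lh0 = log(h),
                            fix_h = fix_h)
    keep <- is.finite(bb$ic50)
    if (ci_method == "bootstrap") {
      la_hat <- log(ic50)
      se_hat <- .hill_se_batch(matrix(x, nrow = 1), matrix(y, nrow = 1),
                               la_hat, log(h))
      seb <- .hill_se_batch(Xb, Yb, log(bb$ic50), log(bb$h))
      tb <- (log(bb$ic50) - la_hat) / seb
      tb <- tb[is.finite(tb) & keep]
      qs <- unname(stats::quantile(tb, c(0.025, 0.975)))
      ci <- exp(c(la_hat - qs[2] * se_hat, la_hat - qs[1] * se_hat))
    } else {
      ci <- unname(stats::quantile(bb$ic50[keep], c(0.025, 0.975)))
    }
    ci_h <- unname(stats::quantile(bb$h[keep], c(0.025, 0.975)))
  } else {
    se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["la"]],
                   error = function(e) NA_real_)
    ci <- exp(log(ic50) + c(-1, 1) * stats::qnorm(0.975) * se)
    ci_h <- c(NA_real_, NA_real_)
  }
  # the interval always brackets the point estimate
  ci <- c(min(ci[1], ic50), max(ci[2], ic50))
  structure(list(ic50 = unname(ic50), h = unname(h), top = top,
                 ci95 = ci, ci95_h = ci_h,
                 n_cells = if (!is.null(dr$cell_id)) length(unique(dr$cell_id)) else NA_integer_,
                 n_points = n, sse = sum(stats::resid(fit)^2),
                 ci_method = ci_method,
                 B = if (ci_method == "wald") NA else B,
                 converged = TRUE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> IC50 = %.4g nM [%.4g, %.4g] (95%% %s), h = %.3g, n = %d point(s)\n",
              x$ic50, x$ci95[1], x$ci95[2], x$ci_method, x$h, x$n_points))
  invisible(x)
}

# Parse IC50 entries that may carry a ">" censoring prefix and thousands
# separators ("">150,000"" -> bound 150000).
.parse_ic50 <- function(x) {
  x <- trimws(as.character(x))
  censored <- startsWith(x, ">")
  val <- suppressWarnings(as.numeric(gsub("[>,  ]", "", x)))
  if (anyNA(val)) stop("unparsable IC50 value(s): ",
                       paste(x[is.na(val)], collapse = ", "))
  data.frame(value = val, censored = censored)
}

#' Subtype-selectivity fold matrix
#'
#' Fold selectivity of a peptide for the reference subtype versus each other
#' subtype: `floor(IC50_subtype / IC50_reference)` (truncation toward zero,
#' the convention that reproduces printed integer fold tables, e.g.
#' 382/3.8 -> 100). Censored entries (`">150000"`) propagate as censored
#' lower bounds on the fold.
#'
#' @param ic50s A data.frame with columns `subtype` and `ic50_nM` (numeric or
#'   character, `">"`-prefixed for censored lower bounds), or a named
#'   vector/list.
#' @param reference Reference subtype (must be present and uncensored).
#' @return An object of class `selectivity_matrix`: data.frame with columns
#'   `subtype`, `ic50_nM`, `censored`, `fold`, `fold_display`; attribute
#'   `reference`.
#' @export
selectivity_matrix <- function(ic50s, reference = "hNav1.7") {
  if (!is.data.frame(ic50s))
    ic50s <- data.frame(subtype = names(ic50s),
                        ic50_nM = unlist(ic50s, use.names = FALSE))
  stopifnot(all(c("subtype", "ic50_nM") %in% names(ic50s)))
  p <- .parse_ic50(ic50s$ic50_nM)
  ref_i <- match(reference, ic50s$subtype)
  if (is.na(ref_i)) stop("reference subtype '", reference, "' not present")
  if (p$censored[ref_i]) stop("reference subtype IC50 is censored")
  ref <- p$value[ref_i]
  # tiny epsilon so mathematically integer ratios are not floored down by
  # floating-point representation
  fold <- as.integer(floor(p$value / ref + 1e-9))
  out <- data.frame(subtype = ic50s$subtype, ic50_nM = p$value,
                    censored = p$censored, fold = fold,
                    fold_display = ifelse(p$censored, paste0(">", fold),
                                          as.character(fold)),
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- reference
  class(out) <- c("selectivity_matrix", "data.frame")
  out
}

#' Rank peptides by potency
#'
#' Ascending IC50 order with stable ties. Range entries such as
#' `"0.3-1.7"` are ordered by their midpoint (the printed range is kept for
#' display).
#'
#' @param potencies A data.frame with columns `peptide` and `ic50_nM`
#'   (numeric, or character allowing `"lo-hi"` ranges).
#' @return The input with a `rank` column, sorted by potency.
#' @export
rank_peptides <- function(potencies) {
  stopifnot(all(c("peptide", "ic50_nM") %in% names(potencies)))
  raw <- trimws(as.character(potencies$ic50_nM))
  key <- vapply(raw, function(v) {
    v <- gsub(",", "", gsub("–", "-", v))  # en-dash ranges
    parts <- suppressWarnings(as.numeric(strsplit(v, "-", fixed = TRUE)[[1]]))
    if (anyNA(parts)) stop("unparsable IC50 '", v, "'")
    mean(parts)
  }, 0)
  o <- order(key)  # stable: ties keep input order
  out <- potencies[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", setdiff(names(out), "rank"))]
}
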