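# Per-transcript mRNA half-life estimation from metabolic-labelling
# conversion time courses: SNP masking, per-3'UTR conversion-rate
# aggregation, exponential decay fitting with a goodness-of-fit filter, and
# half-life summaries.

#' Mask SNP positions from conversion counting
#'
#' Positions with coverage of at least `min_cov` and variant fraction of at
#' least `min_vaf` are treated as genomic variants and excluded from
#' conversion counting.
#'
#' @param positions data.frame with `coverage` and `variant_fraction`
#'   (plus any identifying columns).
#' @param min_cov inclusive coverage cutoff (default 10).
#' @param min_vaf inclusive variant-fraction cutoff (default 0.8).
#' @return `positions` with a logical `masked` column.
#' @export
mask_snps <- function(positions, min_cov = 10, min_vaf = 0.8) {
  positions$masked <- positions$coverage >= min_cov &
    positions$variant_fraction >= min_vaf
  positions
}

#' Per-transcript conversion rate from windowed counts
#'
#' The per-position rate is conversions divided by coverage; positions are
#' averaged within each window over its T positions, and window means are
#' averaged per 3'UTR.
#'
#' @param window_counts data.frame with `transcript`, `window`, `position`,
#'   `conversions`, `coverage` (one row per T position; masked positions
#'   should already be removed).
#' @return data.frame with `transcript` and `rate`; transcripts with no
#'   covered T position are dropped (reported via attribute `n_dropped`).
#' @export
conversion_rate_per_utr <- function(window_counts) {
  wc <- window_counts[window_counts$coverage > 0, , drop = FALSE]
  n_dropped <- length(setdiff(unique(window_counts$transcript),
                              unique(wc$transcript)))
  if (nrow(wc) == 0L) {
    out <- data.frame(transcript = character(0), rate = numeric(0))
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  wc$prate <- wc$conversions / wc$coverage
  per_win <- stats::aggregate(prate ~ transcript + window, data = wc, FUN = mean)
  per_tx <- stats::aggregate(prate ~ transcript, data = per_win, FUN = mean)
  names(per_tx)[2] <- "rate"
  attr(per_tx, "n_dropped") <- n_dropped
  per_tx
}

#' Fit an exponential decay model to a conversion time course
#'
#' The background (a scalar, e.g. the mean conversion rate of an unlabelled
#' control) is subtracted, negative values are floored at zero, the curve is
#' normalised so the t = 0 value is one, and y(t) = exp(-k t) is fitted by
#' nonlinear least squares initialised from the log-linear regression slope.
#' The half-life is ln(2)/k; the estimate is reliable when R-squared against
#' the fitted model exceeds `r2_min`. A two-parameter variant
#' y(t) = a exp(-k t) is available via `two_parameter`.
#'
#' @param times numeric vector of chase times in hours, starting at 0,
#'   strictly increasing.
#' @param rates conversion rates at `times`.
#' @param background scalar background conversion rate (default 0).
#' @param r2_min reliability threshold on R-squared (default 0.5; the filter
#'   keeps fits with R-squared strictly greater).
#' @param two_parameter fit amplitude as a free parameter (default FALSE).
#' @param transcript optional id carried through.
#' @return One-row data.frame: `transcript`, `k`, `t_half`, `r2`,
#'   `reliable`, `flag` ("" when clean).
#' @export
fit_decay <- function(times, rates, background = 0, r2_min = 0.5,
                      two_parameter = FALSE, transcript = NA_character_) {
  if (length(times) < 4L) stop("need at least 4 time points")
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("times must start at 0 and increase strictly")
  }
  y <- rates - background
  flag <- ""
  if (any(y < 0)) { y <- pmax(y, 0); flag <- "floored" }
  if (y[1] <= 0) {
    return(data.frame(transcript = transcript, k = NA_real_,
                      t_half = NA_real_, r2 = NA_real_, reliable = FALSE,
                      flag = "nonpositive_t0"))
  }
  yn <- y / y[1]
  pos <- yn > 0
  k0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(yn[pos]) ~ times[pos]))[2]
    max(-as.numeric(sl), 1e-4)
  } else 0.5
  df <- data.frame(t = times, y = yn)
  fit <- tryCatch({
    if (two_parameter) {
      minpack.lm::nlsLM(y ~ a * exp(-k * t), data = df,
                        start = list(a = 1, k = k0),
                        lower = c(a = 0, k = 0), control = list(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ exp(-k * t), data = df, start = list(k = k0),
                        lower = c(k = 0), control = list(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) {
    return(data.frame(transcript = transcript, k = NA_real_,
                      t_half = NA_real_, r2 = NA_real_, reliable = FALSE,
                      flag = "no_convergence"))
  }
  k <- stats::coef(fit)[["k"]]
  pred <- stats::fitted(fit)
  ss_res <- sum((yn - pred)^2)
  ss_tot <- sum((yn - mean(yn))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  data.frame(transcript = transcript, k = k,
             t_half = if (k > 0) log(2) / k else Inf,
             r2 = r2, reliable = is.finite(k) && k > 0 && r2 > r2_min,
             flag = flag)
}

#' Fit decay curves for a time-course table
#'
#' @param curves data.frame with `transcript`, `time_h`, `rate` (long form).
#' @inheritParams fit_decay
#' @return data.frame of per-transcript estimates (see [fit_decay()]).
#' @export
fit_decay_table <- function(curves, background = 0, r2_min = 0.5,
                            two_parameter = FALSE) {
  res <- lapply(split(curves, curves$transcript), function(cc) {
    cc <- cc[order(cc$time_h), ]
    fit_decay(cc$time_h, cc$rate, background = background, r2_min = r2_min,
              two_parameter = two_parameter, transcript = cc$transcript[1])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarise reliable half-lives: median and quartile categories
#'
#' Categories come from the empirical 25/50/75 percent quantiles of the
#' supplied reliable estimates (the activated-state printed cutoffs of the
#' source analyses are that distribution's own quartiles, not constants).
#'
#' @param estimates data.frame from [fit_decay_table()].
#' @return list with `median`, `quartiles` (the three cutoffs), `categories`
#'   (per-transcript factor with levels `Q1`..`Q4`), and `degenerate`
#'   (TRUE when the quartiles collapse).
#' @export
summarize_half_lives <- function(estimates) {
  rel <- estimates[estimates$reliable, , drop = FALSE]
  if (nrow(rel) == 0L) stop("no reliable half-life estimates")
  th <- rel$t_half
  qs <- stats::quantile(th, c(0.25, 0.5, 0.75), names = FALSE)
  degenerate <- length(unique(qs)) < 3L
  breaks <- unique(c(-Inf, qs, Inf))
  cats <- cut(th, breaks = breaks,
              labels = paste0("Q", seq_len(length(breaks) - 1L)))
  list(median = stats::median(th),
       quartiles = qs,
       categories = stats::setNames(cats, rel$transcript),
       degenerate = degenerate)
}
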