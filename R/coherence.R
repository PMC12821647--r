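#' Correlation and coherence between load measures
#'
#' Spearman rank correlations relate gaze metrics to NASA-TLX answers overall
#' and within each driving stage. Coherence is Lin's concordance correlation
#' coefficient (CCC) between (1) rank-coded stages and gaze metrics, (2)
#' rank-coded stages and TLX scales, and (3) gaze metrics and TLX scales,
#' pooling subject x stage observations within each stage pair. Because CCC
#' penalises location and scale disagreement, both vectors are min-max scaled
#' to `[0, 1]` within the compared pair before the coefficient is computed;
#' absolute values of significant components are aggregated as mean, min and
#' max.
#'
#' @name coherence-stats
NULL

#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (xbar - ybar)^2)` with population
#' (1/n) moments. Lies in `[-1, 1]` and equals 1 only for `y = x`.
#'
#' @param x,y numeric vectors of equal length >= 3 with finite values and
#'   non-zero variance in at least one of them.
#' @return the concordance coefficient.
#' @examples
#' lins_ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
lins_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) stop("CCC undefined: zero variances and equal means")
  2 * sxy / denom
}

# two-sided p for rho_c via Fisher z on atanh(ccc), se = 1/sqrt(n - 3)
ccc_p_value <- function(ccc, n) {
  if (n <= 3) return(NA_real_)
  z <- atanh(max(-1 + 1e-12, min(1 - 1e-12, ccc)))
  2 * stats::pnorm(-abs(z) * sqrt(n - 3))
}

rescale01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

correlation_band <- function(rho) {
  a <- abs(rho)
  ifelse(a < 0.3, "weak", ifelse(a <= 0.7, "moderate", "strong"))
}

#' Spearman correlations between gaze metrics and TLX scales, by stage
#'
#' One cell per (metric, scale, stage) plus pooled `Overall` rows; cells with
#' fewer than 4 paired observations are reported missing. Coefficients are
#' labelled `weak` (|rho| < 0.3), `moderate` (0.3-0.7) or `strong` (> 0.7).
#' No multiple-testing correction is applied by default (raw significance is
#' reported); set `p_adjust_method` to any [stats::p.adjust()] method to
#' correct across cells.
#'
#' @param stage_metrics long tibble: `participant`, `stage`, one column per
#'   gaze metric.
#' @param tlx tibble: `participant`, `stage`, six scales, `averaged_answer`.
#' @param metrics,scales column names to correlate; sensible defaults.
#' @param p_adjust_method optional [stats::p.adjust()] method, default "none".
#' @return tibble: `metric`, `scale`, `stage`, `n`, `rho`, `p`, `band`.
#' @export
spearman_by_stage <- function(stage_metrics, tlx,
                              metrics = c("fixation_duration", "saccade_velocity",
                                          "blink_number", "sge", "gte"),
                              scales = c("mental", "physical", "temporal",
                                         "performance", "effort", "frustration",
                                         "averaged_answer"),
                              p_adjust_method = "none") {
  joined <- dplyr::inner_join(stage_metrics, tlx, by = c("participant", "stage"))
  stages <- c(sort(unique(joined$stage)), "Overall")
  out <- list()
  for (st in stages) {
    d <- if (st == "Overall") joined else joined[joined$stage == st, ]
    for (ms in metrics) for (sc in scales) {
      x <- d[[ms]]; y <- d[[sc]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n >= 4) {
        ct <- suppressWarnings(
          stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
        rho <- unname(ct$estimate); p <- ct$p.value
      } else {
        rho <- NA_real_; p <- NA_real_
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        metric = ms, scale = sc, stage = st, n = n, rho = rho, p = p)
    }
  }
  res <- dplyr::bind_rows(out)
  res$p <- stats::p.adjust(res$p, method = p_adjust_method)
  res$band <- correlation_band(res$rho)
  res
}

#' Coherence analysis via Lin's CCC against rank-coded stages
#'
#' Within each stage pair the two stages are coded 0 (lower load) and 1
#' (higher load). Components are computed over pooled subject x stage
#' observations after min-max scaling, kept when their significance test
#' passes `alpha`, and their absolute values aggregated.
#'
#' @param stage_metrics,tlx as in [spearman_by_stage()]; QC-passed
#'   participants only.
#' @param alpha significance level for component inclusion, default 0.05.
#' @param metrics,scales component columns, as in [spearman_by_stage()].
#' @return tibble: `pairing` (stages_vs_gaze | stages_vs_tlx | gaze_vs_tlx),
#'   `pair`, `mean_abs`, `min_abs`, `max_abs`, `n_components` (aggregates are
#'   `NA` when no component is significant).
#' @export
coherence_analysis <- function(stage_metrics, tlx, alpha = 0.05,
                               metrics = c("fixation_duration", "saccade_velocity",
                                           "blink_number", "sge", "gte"),
                               scales = c("mental", "physical", "temporal",
                                          "performance", "effort", "frustration",
                                          "averaged_answer")) {
  pairs <- stage_pairs()
  joined <- dplyr::inner_join(stage_metrics, tlx, by = c("participant", "stage"))
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    d <- joined[joined$stage %in% c(pairs$stage_a[k], pairs$stage_b[k]), ]
    # keep subjects observed in both stages of the pair
    both <- names(which(table(d$participant) == 2))
    d <- d[d$participant %in% both, ]
    rank01 <- as.numeric(d$stage == pairs$higher_cl[k])
    comp <- function(x, y) {
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 4) return(NULL)
      cc <- tryCatch(lins_ccc(rescale01(x[ok]), rescale01(y[ok])),
                     error = function(e) NA_real_)
      if (!is.finite(cc)) return(NULL)
      c(ccc = cc, p = ccc_p_value(cc, sum(ok)))
    }
    collect <- function(pairing, xs, ys) {
      vals <- list()
      for (xn in xs) for (yn in ys) {
        x <- if (xn == ".rank") rank01 else d[[xn]]
        cm <- comp(x, d[[yn]])
        if (!is.null(cm)) vals[[length(vals) + 1L]] <- cm
      }
      m <- do.call(rbind, vals)
      sig <- if (is.null(m)) numeric(0) else abs(m[m[, "p"] < alpha, "ccc"])
      tibble::tibble(pairing = pairing, pair = pairs$pair[k],
                     mean_abs = if (length(sig)) mean(sig) else NA_real_,
                     min_abs = if (length(sig)) min(sig) else NA_real_,
                     max_abs = if (length(sig)) max(sig) else NA_real_,
                     n_components = length(sig))
    }
    out[[length(out) + 1L]] <- collect("stages_vs_gaze", ".rank", metrics)
    out[[length(out) + 1L]] <- collect("stages_vs_tlx", ".rank", scales)
    out[[length(out) + 1L]] <- collect("gaze_vs_tlx", metrics, scales)
  }
  dplyr::bind_rows(out)
}
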