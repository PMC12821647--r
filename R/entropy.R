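#' Gaze entropy measures
#'
#' Fixation centroids are discretised onto a fixed grid of 30 x 30 pixel
#' cells anchored at the plane origin (half-open cells, no re-centering), and
#' two Shannon measures are computed on the resulting bin sequence:
#'
#' * stationary gaze entropy (SGE), the entropy of the marginal bin
#'   distribution - how dispersed fixations are over the scene;
#' * gaze transition entropy (GTE), the conditional entropy of successive
#'   bin-to-bin transitions - how unpredictable the scan path is.
#'
#' Both are reported in bits (log base 2). Marginal shares are count based
#' (not duration weighted); GTE weights each source bin by its share among
#' transition sources (the first n-1 fixations), so rows and weights describe
#' the same sample.
#'
#' @name gaze-entropy
NULL

#' Discretise fixation centroids into grid bins
#'
#' @param u_px,v_px fixation centroid coordinates in pixels.
#' @param bin_px cell edge in pixels, default 30.
#' @return character vector of bin ids `"i:j"` with `i = floor(u/bin)`,
#'   `j = floor(v/bin)` (floor semantics also on negatives), order preserved.
#' @export
bin_fixations <- function(u_px, v_px, bin_px = 30) {
  stopifnot(length(u_px) == length(v_px), bin_px > 0)
  paste(floor(u_px / bin_px), floor(v_px / bin_px), sep = ":")
}

#' Stationary gaze entropy (bits)
#'
#' @param bins sequence of bin ids (any atomic type).
#' @return `-sum p_i log2 p_i` over the empirical bin shares; `NA` for an
#'   empty sequence (the window metric is then missing).
#' @export
stationary_gaze_entropy <- function(bins) {
  bins <- bins[!is.na(bins)]
  if (!length(bins)) return(NA_real_)
  p <- tabulate(factor(bins)) / length(bins)
  -sum(p * log2(p))
}

#' Gaze transition entropy (bits)
#'
#' Conditional entropy of the first-order transition table estimated from
#' successive fixation pairs: `-sum_i p_i sum_j p(j|i) log2 p(j|i)`, with
#' `p_i` the source shares over the first n-1 fixations.
#'
#' @param bins sequence of bin ids.
#' @return GTE in bits; `NA` when fewer than 2 fixations.
#' @export
gaze_transition_entropy <- function(bins) {
  bins <- bins[!is.na(bins)]
  n <- length(bins)
  if (n < 2) return(NA_real_)
  from <- bins[-n]
  to <- bins[-1]
  tab <- table(from, to)
  rs <- rowSums(tab)
  p_i <- rs / (n - 1)
  cond <- tab / rs
  h_rows <- -rowSums(ifelse(cond > 0, cond * log2(cond), 0))
  sum(p_i * h_rows)
}
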