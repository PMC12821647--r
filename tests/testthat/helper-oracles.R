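# Independent oracles and small constructors used across the suite.

# brute-force parametric ray-plane intersection: t = (D - n.o) / (n.d)
oracle_intersect <- function(origin, direction, plane) {
  denom <- sum(plane$normal * direction)
  if (abs(denom) < 1e-9) return(NULL)
  tt <- (plane$offset - sum(plane$normal * origin)) / denom
  p <- origin + tt * direction
  rel <- p - plane$point
  list(point = p, t = tt,
       u = sum(rel * plane$basis_u), v = sum(rel * plane$basis_v))
}

# unit gaze directions from cumulative horizontal angles (degrees)
dirs_from_angles <- function(deg) {
  a <- deg * pi / 180
  cbind(sin(a), 0, cos(a))
}

# fraction of truth events matched by a detection at IoU >= 0.5 on frame spans
iou_recovery <- function(truth, detected, min_iou = 0.5) {
  if (!nrow(truth)) return(NA_real_)
  if (!nrow(detected)) return(0)
  hits <- 0L
  for (i in seq_len(nrow(truth))) {
    s <- truth$start_frame[i]; e <- truth$end_frame[i]
    ov <- pmax(0, pmin(detected$end_frame, e) - pmax(detected$start_frame, s) + 1)
    un <- (detected$end_frame - detected$start_frame + 1) + (e - s + 1) - ov
    if (any(ov / un >= min_iou)) hits <- hits + 1L
  }
  hits / nrow(truth)
}

# brute-force conditional entropy of a bin sequence: enumerate observed
# pairs, compute each source's row entropy, weight by source share
oracle_gte <- function(bins) {
  n <- length(bins)
  pairs <- data.frame(from = bins[-n], to = bins[-1])
  total <- 0
  for (f in unique(pairs$from)) {
    succ <- pairs$to[pairs$from == f]
    p <- table(succ) / length(succ)
    h <- -sum(p * log2(p))
    total <- total + length(succ) / nrow(pairs) * h
  }
  total
}

# moment-form CCC oracle, written independently of lins_ccc
oracle_ccc <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / n
  sx2 <- sum((x - mean(x))^2) / n
  sy2 <- sum((y - mean(y))^2) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

# a minimal valid gaze-frame tibble looking straight ahead
flat_frames <- function(n, gaze_q = rep(1, n), valid = rep(1, n)) {
  tibble::tibble(
    t_s = (seq_len(n) - 1) / 60,
    head_x_cm = 0, head_y_cm = 0, head_z_cm = 0,
    headdir_x = 0, headdir_y = 0, headdir_z = 1,
    gazeorig_x_cm = 0, gazeorig_y_cm = 0, gazeorig_z_cm = 0,
    gazedir_x = 0, gazedir_y = 0, gazedir_z = 1,
    eyelid_open = 9, head_q = 1, gaze_q = gaze_q, valid = valid
  )
}

# small fast regime for event-level tests
test_regime <- function(stage = "HighwayDriving", ...) {
  args <- list(stage_label = stage, grid_size = 4, dispersion = 0.6,
               regularity_eps = 0.4, blink_rate = 12, dropout_rate = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(stage_regime, args)
}
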