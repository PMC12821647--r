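#' Expected-direction discriminative accuracy
#'
#' For each measure and each of the three stage pairs (HighwayDriving vs
#' HighwayNback, UrbanDriving vs UrbanNback, HighwayDriving vs UrbanDriving)
#' a subject counts as 1 when the within-subject difference between stage
#' means goes in the direction predicted by the cognitive-load model, and 0
#' otherwise (ties score 0 - the rule is binary). Accuracy is the count of
#' subjects matching the expectation divided by the number of subjects with
#' both values available.
#'
#' @name cl-discrimination
NULL

stage_pairs <- function() {
  tibble::tibble(
    pair = c("HighwayDriving_vs_HighwayNback",
             "UrbanDriving_vs_UrbanNback",
             "HighwayDriving_vs_UrbanDriving"),
    stage_a = c("HighwayDriving", "UrbanDriving", "HighwayDriving"),
    stage_b = c("HighwayNback", "UrbanNback", "UrbanDriving"),
    # rank coding for coherence: lower-CL stage = 0, higher = 1
    higher_cl = c("HighwayNback", "UrbanNback", "UrbanDriving")
  )
}

#' Default expected-direction table
#'
#' Directions follow the within-subject cognitive-load model (urban above
#' highway; N-Back stages above driving-only stages) and the distribution-
#' level findings for each gaze metric: fixation duration and blink number
#' are higher on the highway than in urban driving and rise with the N-Back
#' task; saccade velocity falls with load on either axis; SGE is higher in
#' urban driving and falls under the N-Back task; GTE is higher on the
#' highway, falls with the N-Back task on the highway but rises with it in
#' urban driving. TLX scales follow the load ordering directly, except the
#' raw performance scale, whose direction is reversed (better rated
#' performance under lower load). The table is configuration: rows may be
#' overridden or replaced wholesale in [run_config()].
#'
#' @return tibble with columns `measure`, `pair`, `higher` (the stage label
#'   expected to have the larger value). Every measure has exactly three pair
#'   entries.
#' @export
default_direction_table <- function() {
  hp <- "HighwayDriving_vs_HighwayNback"
  up <- "UrbanDriving_vs_UrbanNback"
  hu <- "HighwayDriving_vs_UrbanDriving"
  HD <- "HighwayDriving"; HN <- "HighwayNback"
  UD <- "UrbanDriving"; UN <- "UrbanNback"
  rows <- list(
    c("fixation_duration", hp, HN), c("fixation_duration", up, UN),
    c("fixation_duration", hu, HD),
    c("blink_number", hp, HN), c("blink_number", up, UN),
    c("blink_number", hu, HD),
    c("saccade_velocity", hp, HD), c("saccade_velocity", up, UD),
    c("saccade_velocity", hu, HD),
    c("sge", hp, HD), c("sge", up, UD), c("sge", hu, UD),
    c("gte", hp, HD), c("gte", up, UN), c("gte", hu, HD)
  )
  tlx_up <- c("mental", "physical", "temporal", "effort", "frustration",
              "averaged_answer")
  for (sc in tlx_up)
    rows <- c(rows, list(c(sc, hp, HN), c(sc, up, UN), c(sc, hu, UD)))
  rows <- c(rows, list(c("performance", hp, HD), c("performance", up, UD),
                       c("performance", hu, HD)))
  m <- do.call(rbind, rows)
  tibble::tibble(measure = m[, 1], pair = m[, 2], higher = m[, 3])
}

#' Pairwise expected-direction accuracy
#'
#' @param values_a,values_b per-subject stage means for the two stages,
#'   aligned by subject; pairs with a missing value are dropped from `N`.
#' @param higher either `"a"` or `"b"`: which stage is expected larger.
#' @return list: `n` (usable subjects), `n_expected`, `accuracy`.
#' @examples
#' pairwise_accuracy(c(2, 3, 1), c(1, 1, 5), higher = "a")$accuracy  # 2/3
#' @export
pairwise_accuracy <- function(values_a, values_b, higher = c("a", "b")) {
  higher <- match.arg(higher)
  stopifnot(length(values_a) == length(values_b))
  ok <- !is.na(values_a) & !is.na(values_b)
  a <- values_a[ok]; b <- values_b[ok]
  n <- length(a)
  if (n == 0) stop("no subjects with both stage values")
  hit <- if (higher == "a") a > b else b > a   # ties count 0
  list(n = n, n_expected = sum(hit), accuracy = sum(hit) / n)
}

#' Accuracy table across measures and stage pairs
#'
#' @param stage_values long tibble: `participant`, `stage`, one column per
#'   measure (gaze metrics and/or TLX scales).
#' @param direction_table a [default_direction_table()]-shaped tibble.
#' @param measures which measure columns to evaluate; defaults to every
#'   measure present in both `stage_values` and the direction table.
#' @return tibble: `measure`, `pair`, `n`, `n_expected`, `accuracy`, plus
#'   per-pair `Average` rows over the evaluated measures.
#' @export
accuracy_table <- function(stage_values, direction_table = default_direction_table(),
                           measures = NULL) {
  pairs <- stage_pairs()
  if (is.null(measures))
    measures <- intersect(unique(direction_table$measure), names(stage_values))
  out <- list()
  for (ms in measures) {
    wide <- tidyr::pivot_wider(stage_values[, c("participant", "stage", ms)],
                               names_from = "stage",
                               values_from = dplyr::all_of(ms))
    for (k in seq_len(nrow(pairs))) {
      dir <- direction_table$higher[direction_table$measure == ms &
                                      direction_table$pair == pairs$pair[k]]
      if (length(dir) != 1)
        stop("direction table has no entry for ", ms, " / ", pairs$pair[k])
      va <- wide[[pairs$stage_a[k]]]
      vb <- wide[[pairs$stage_b[k]]]
      acc <- pairwise_accuracy(va, vb,
                               higher = if (dir == pairs$stage_a[k]) "a" else "b")
      out[[length(out) + 1L]] <- tibble::tibble(
        measure = ms, pair = pairs$pair[k], n = acc$n,
        n_expected = acc$n_expected, accuracy = acc$accuracy)
    }
  }
  res <- dplyr::bind_rows(out)
  avg <- res |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(measure = "Average", n = max(.data$n),
                     n_expected = NA_integer_,
                     accuracy = mean(.data$accuracy), .groups = "drop")
  dplyr::bind_rows(res, avg[, names(res)])
}
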