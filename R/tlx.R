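#' Score the adjusted NASA-TLX
#'
#' Six scales (mental, physical, temporal, performance, effort, frustration)
#' answered on a signed nine-point Likert scale from -4 ("very low") to +4
#' ("very high"). The averaged answer inverts the performance scale by
#' negation - the natural mirror on a symmetric signed scale - so that higher
#' values consistently mean higher perceived load:
#' `averaged = mean(mental, physical, temporal, -performance, effort,
#' frustration)`.
#'
#' All arguments are vectorised (one element per questionnaire).
#'
#' @param mental,physical,temporal,performance,effort,frustration integer
#'   answers in `[-4, 4]`.
#' @return tibble with the six scales and `averaged_answer`.
#' @examples
#' score_tlx(2, 1, 2, 3, 2, 0)$averaged_answer  # 0.6667
#' @export
score_tlx <- function(mental, physical, temporal, performance, effort,
                      frustration) {
  scales <- list(mental = mental, physical = physical, temporal = temporal,
                 performance = performance, effort = effort,
                 frustration = frustration)
  n <- unique(lengths(scales))
  if (length(n) != 1) stop("all six scales must have equal length")
  for (nm in names(scales)) {
    x <- scales[[nm]]
    if (any(is.na(x))) stop("missing answer on scale '", nm, "'")
    if (any(x < -4 | x > 4)) stop("answers on scale '", nm, "' outside [-4, 4]")
    if (any(x != round(x))) stop("answers on scale '", nm, "' must be integers")
  }
  tibble::tibble(
    mental = as.integer(mental), physical = as.integer(physical),
    temporal = as.integer(temporal), performance = as.integer(performance),
    effort = as.integer(effort), frustration = as.integer(frustration),
    averaged_answer = (mental + physical + temporal - performance +
                         effort + frustration) / 6
  )
}
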