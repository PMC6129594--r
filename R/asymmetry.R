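#' Hemispheric asymmetry scores
#'
#' The asymmetry score of a network property X is
#' \deqn{AS(X) = 100 (X_R - X_L) / (X_R + X_L)}
#' a dimensionless laterality index in (-100, 100) for positive inputs.
#' Positive values indicate rightward asymmetry, negative values leftward
#' asymmetry. The score is invariant under common scaling of both
#' hemispheres and antisymmetric under hemisphere exchange.
#'
#' @name asymmetry
NULL

#' Asymmetry score of a left/right property pair
#'
#' Vectorized. When both values are zero the score is undefined and
#' returned as `NA` with a warning (downstream statistics use pairwise
#' deletion).
#'
#' @param x_right property value in the right hemisphere (nonnegative)
#' @param x_left property value in the left hemisphere (nonnegative)
#' @return `100 * (x_right - x_left) / (x_right + x_left)`
#' @export
asymmetry_score <- function(x_right, x_left) {
  if (any(x_right < 0, na.rm = TRUE) || any(x_left < 0, na.rm = TRUE))
    stop("asymmetry score requires nonnegative property values")
  s <- x_right + x_left
  zero <- !is.na(s) & s == 0
  if (any(zero))
    warning(sum(zero), " pair(s) with zero denominator; returning NA")
  out <- ifelse(zero, NA_real_, 100 * (x_right - x_left) / s)
  out
}

#' Per-subject asymmetry table for a cohort
#'
#' Pairs each subject's left and right hemispheric metrics (global metrics
#' by name; nodal efficiency by homotopic region, i.e. matching
#' parcellation position/abbreviation) and computes the asymmetry score of
#' each pair. Subjects missing either hemisphere for a metric are dropped
#' from that metric with a message.
#'
#' @param metrics long-format metric table from [cohort_metrics()]
#' @return data.frame with columns
#'   `subject_id`, `metric`, `x_left`, `x_right`, `AS`
#'   (`metric` is e.g. `"Eg"` or `"Enodal:ROL"`)
#' @export
cohort_asymmetry <- function(metrics) {
  stopifnot(all(c("subject_id", "hemisphere", "metric", "node", "value")
                %in% names(metrics)))
  key <- ifelse(is.na(metrics$node) | metrics$node == "",
                metrics$metric, paste0(metrics$metric, ":", metrics$node))
  left <- metrics[metrics$hemisphere == "L", ]
  right <- metrics[metrics$hemisphere == "R", ]
  kl <- key[metrics$hemisphere == "L"]
  kr <- key[metrics$hemisphere == "R"]
  idl <- paste(left$subject_id, kl, sep = "\r")
  idr <- paste(right$subject_id, kr, sep = "\r")
  common <- intersect(idl, idr)
  dropped <- length(unique(c(setdiff(idl, idr), setdiff(idr, idl))))
  if (dropped > 0)
    message(dropped, " subject-metric pair(s) missing a hemisphere; dropped")
  ml <- left[match(common, idl), ]
  mr <- right[match(common, idr), ]
  out <- data.frame(subject_id = ml$subject_id,
                    metric = kl[match(common, idl)],
                    x_left = ml$value, x_right = mr$value,
                    stringsAsFactors = FALSE)
  out$AS <- asymmetry_score(out$x_right, out$x_left)
  rownames(out) <- NULL
  out
}
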