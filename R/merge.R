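# Spatial filtering (merging) of repeated stimuli: single-linkage grouping at
# a geodesic radius; each group becomes one merged point with the spherical
# mean location and the mean or maximal response.

#' Merge repeated stimulation points
#'
#' Groups projected stimulation points by single linkage at a geodesic radius
#' and replaces each group by one merged point with the averaged location and
#' the averaged (or maximal) response. Groups with fewer repetitions than
#' `min_repetitions` are dropped, so that only locations stimulated often
#' enough contribute to the map.
#'
#' @param ab n x 2 matrix of projected angular coordinates.
#' @param h numeric vector of nonnegative responses (e.g. MEP amplitude, uV).
#' @param sph a [sphere()].
#' @param merge_radius geodesic linkage radius in mm (0 merges only coincident
#'   points).
#' @param merge_stat `"mean"` or `"max"` group response.
#' @param min_repetitions minimum group size kept.
#' @param ids optional point identifiers carried into `source_ids`.
#' @return data frame of class `merged_points` with columns `alpha`, `beta`,
#'   `h`, `repetitions` and a list column `source_ids`.
#' @export
merge_points <- function(ab, h, sph, merge_radius = 2,
                         merge_stat = c("mean", "max"),
                         min_repetitions = 1, ids = NULL) {
  merge_stat <- match.arg(merge_stat)
  ab <- as_angular(ab)
  h <- as.numeric(h)
  stopifnot(length(h) == nrow(ab))
  if (any(h < 0)) stop("responses must be nonnegative")
  if (merge_radius < 0) stop("merge_radius must be nonnegative")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(ab)))
  n <- nrow(ab)
  if (n == 0L) {
    out <- data.frame(alpha = numeric(0), beta = numeric(0), h = numeric(0),
                      repetitions = integer(0))
    out$source_ids <- list()
    class(out) <- c("merged_points", "data.frame")
    return(out)
  }
  dirs <- angular_to_direction(ab)
  if (n == 1L) {
    cl <- 1L
  } else {
    d <- geodesic_cross(dirs, dirs, sph$radius)
    cl <- stats::cutree(stats::hclust(stats::as.dist(d), method = "single"),
                        h = merge_radius)
  }
  groups <- split(seq_len(n), cl)
  loc <- t(vapply(groups, function(g) {
    normalize3(colMeans(dirs[g, , drop = FALSE]))
  }, numeric(3)))
  hg <- vapply(groups, function(g) {
    if (merge_stat == "mean") mean(h[g]) else max(h[g])
  }, numeric(1))
  reps <- lengths(groups)
  keep <- reps >= min_repetitions
  ab_m <- direction_to_angular(loc[keep, , drop = FALSE])
  out <- data.frame(alpha = ab_m[, 1], beta = ab_m[, 2],
                    h = unname(hg[keep]), repetitions = unname(reps[keep]))
  out$source_ids <- unname(lapply(groups[keep], function(g) ids[g]))
  class(out) <- c("merged_points", "data.frame")
  out
}
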