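# Kernel (abruptly changing response) map construction: the surface is the
# pointwise maximum of exponential kernels centered at the merged points,
# h_i * a^(r^2 / b^2), with r the geodesic distance. The parameter a is the
# portion of a single kernel's volume lying beyond radius b: b is the
# navigation accuracy in a (1 - a) share of stimuli (defaults a = 0.05,
# b = 2 mm).

#' Kernel weight at geodesic distance r
#'
#' The single-point kernel profile `a^(r^2/b^2)`, a Gaussian in disguise
#' (`exp(-r^2 ln(1/a)/b^2)`) parameterized so that exactly the fraction `a` of
#' its volume lies beyond radius `b`.
#'
#' @param r geodesic distance(s), mm.
#' @param a fraction in (0, 1).
#' @param b radius in mm.
#' @return kernel weight(s) in (0, 1].
#' @export
kernel_weight <- function(r, a = 0.05, b = 2) {
  if (a <= 0 || a >= 1) stop("kernel parameter a must lie in (0, 1)")
  if (b <= 0) stop("kernel parameter b must be positive")
  a^((r * r) / (b * b))
}

# kernel surface over the full lattice (vector of length nx*ny)
kernel_field <- function(merged, grid, a = 0.05, b = 2) {
  if (nrow(merged) == 0L) stop("kernel surface needs at least one merged point")
  ndirs <- lattice_directions(grid)
  mdirs <- angular_to_direction(cbind(merged$alpha, merged$beta))
  r <- geodesic_cross(ndirs, mdirs, grid$poi$sphere$radius)
  w <- kernel_weight(r, a, b)
  contrib <- sweep(w, 2, merged$h, "*")
  do.call(pmax, c(lapply(seq_len(ncol(contrib)), function(j) contrib[, j]), list(0)))
}
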