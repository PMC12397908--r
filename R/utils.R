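# Small internal geometry helpers shared across modules.

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a rotation of `angle` degrees about the
#' (normalised) `axis`, acting on row vectors as `x %*% R`.
#'
#' @param axis numeric length-3 axis direction (need not be unit length).
#' @param angle rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  # acting on row vectors: x %*% t(R) rotates like R %*% x
  t(R)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) v / vnorm(v)

# angle between two 3-vectors, degrees, numerically clamped
vec_angle <- function(u, v) {
  cth <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cth))) * 180 / pi
}

# run code with a temporary RNG state seeded from `seed`; restores the
# caller's stream afterwards so simulators do not perturb user sessions
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
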