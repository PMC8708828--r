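# small geometry helpers shared across modules

# rotation matrix for a right-handed rotation of `angle` radians about
# the (not necessarily unit) axis vector
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c_ + ux^2 * (1 - c_),      ux * uy * (1 - c_) - uz * s_, ux * uz * (1 - c_) + uy * s_,
    uy * ux * (1 - c_) + uz * s_, c_ + uy^2 * (1 - c_),      uy * uz * (1 - c_) - ux * s_,
    uz * ux * (1 - c_) - uy * s_, uz * uy * (1 - c_) + ux * s_, c_ + uz^2 * (1 - c_)),
    nrow = 3, byrow = TRUE)
}

rot_x <- function(angle) rotation_about_axis(c(1, 0, 0), angle)
rot_z <- function(angle) rotation_about_axis(c(0, 0, 1), angle)

# squared distance matrix between two coordinate sets (rows)
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
}

cross_dist <- function(a, b) sqrt(pmax(cross_dist2(a, b), 0))

mean_sd <- function(x) c(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0)
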