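# Minimal unit-quaternion toolbox used by the orientation module and the
# signal-level generator. Quaternions are length-4 numeric vectors
# (w, x, y, z); matrices of quaternions are n x 4. q maps body -> world:
# v_world = R(q) %*% v_body.

quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-12) abort_swayrisk("cannot normalize a zero quaternion")
  q / n
}

quat_multiply <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

# rotation matrix (body -> world) of a unit quaternion
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# exp map: rotation vector (rad, body frame) -> unit quaternion
quat_from_rotvec <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) {
    quat_normalize(c(1, v / 2))
  } else {
    c(cos(theta / 2), sin(theta / 2) * v / theta)
  }
}

# log map: unit quaternion -> rotation vector (rad)
quat_to_rotvec <- function(q) {
  if (q[1] < 0) q <- -q
  v <- q[2:4]
  s <- sqrt(sum(v^2))
  if (s < 1e-12) return(2 * v)
  2 * atan2(s, q[1]) * v / s
}

# shortest-arc quaternion rotating unit vector a onto unit vector b
quat_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    # 180 degrees: pick any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- c(a[2] * ax[3] - a[3] * ax[2],
              a[3] * ax[1] - a[1] * ax[3],
              a[1] * ax[2] - a[2] * ax[1])
    axis <- axis / sqrt(sum(axis^2))
    return(c(0, axis))
  }
  axis <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
  q <- c(1 + d, axis)
  quat_normalize(q)
}

# intrinsic x-y-z (Tait-Bryan) angles, degrees, from a body->world rotation.
# R = Rx(tx) %*% Ry(ty) %*% Rz(tz); ty positive for squat flexion.
rotmat_to_xyz_deg <- function(R) {
  ty <- asin(max(-1, min(1, R[1, 3])))
  if (abs(R[1, 3]) < 1 - 1e-9) {
    tx <- atan2(-R[2, 3], R[3, 3])
    tz <- atan2(-R[1, 2], R[1, 1])
  } else {
    tx <- atan2(R[2, 1], R[2, 2])
    tz <- 0
  }
  c(tx, ty, tz) * 180 / pi
}

rotation_about <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, 3, byrow = TRUE),
    y = matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, 3, byrow = TRUE),
    z = matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  )
}
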