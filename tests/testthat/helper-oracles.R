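# Independent oracles for rotation algebra: literal element-wise textbook
# matrices, composed by plain matrix multiplication. Kept separate from the
# package implementation on purpose.

oracle_rz <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0,
           sin(a),  cos(a), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}
oracle_rx <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0,       0,
           0, cos(a), -sin(a),
           0, sin(a),  cos(a)), 3, 3, byrow = TRUE)
}
oracle_ry <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a),  0, sin(a),
           0,       1, 0,
           -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}
oracle_zxz <- function(tdrot, tilt, narot)
  oracle_rz(narot) %*% oracle_rx(tilt) %*% oracle_rz(tdrot)
oracle_zyz <- function(rot, tilt, psi)
  oracle_rz(psi) %*% oracle_ry(tilt) %*% oracle_rz(rot)

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# smallest difference between two angles in degrees, modulo `period`
angle_diff <- function(a, b, period = 360) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

# small disc phantom for CTF-correction comparisons
disc_phantom <- function(n = 128, radius = 20) {
  xs <- matrix(0:(n - 1), n, n) - (n - 1) / 2
  (xs^2 + t(xs)^2 <= radius^2) * 1.0
}
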