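# Hexagonal-lattice primitives shared by the scaffold and molecular-graph
# modules.  Axial coordinates (q, r); the six fusion directions d = 0..5 step
# counter-clockwise, so direction d + 1 is direction d rotated by 60 degrees.

# axial unit steps for directions 0..5
.hex_axial <- matrix(
  c(1L, 0L,
    0L, 1L,
    -1L, 1L,
    -1L, 0L,
    0L, -1L,
    1L, -1L),
  ncol = 2, byrow = TRUE
)

# Distance between two axial cells (number of lattice steps).
.hex_distance <- function(a, b) {
  dq <- a[1] - b[1]
  dr <- a[2] - b[2]
  (abs(dq) + abs(dr) + abs(dq + dr)) / 2
}

# The 12 symmetries of the hexagonal lattice act on directions:
# s = 0..5  rotations  d -> (d + s) mod 6
# s = 6..11 reflections d -> (s - 6 - d) mod 6
.sym_direction <- function(d, s) {
  if (s <= 5L) (d + s) %% 6L else (s - 6L - d) %% 6L
}

# Cartesian centre of an axial cell for a hexagon with circumradius `side`
# (equal to the ring bond length).  Pointy-top convention: the neighbour in
# direction d lies at angle 60 d + 60 degrees.
.hex_center <- function(q, r, side = 1.4) {
  s3 <- sqrt(3) * side
  cbind(x = s3 * (0.5 * q - 0.5 * r),
        y = s3 * (sqrt(3) / 2) * (q + r))
}

# Cartesian position of corner c (0..5) of a cell; corner c sits at angle
# 60 c + 30 degrees from the centre.  The edge facing direction d joins
# corners d and d + 1.
.hex_corner <- function(center, c, side = 1.4) {
  th <- (60 * c + 30) * pi / 180
  cbind(x = center[, 1] + side * cos(th),
        y = center[, 2] + side * sin(th))
}
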