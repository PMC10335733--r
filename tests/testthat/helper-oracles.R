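# dense-sampling oracle: min over sampled points on segment a of the exact
# point-to-segment distance to b (vectorised, independent of the C++ path)
seg_dist_oracle <- function(a1, a2, b1, b2, n_samp = 2000) {
  tt <- seq(0, 1, length.out = n_samp)
  px <- a1[1] + tt * (a2[1] - a1[1])
  py <- a1[2] + tt * (a2[2] - a1[2])
  dx <- b2[1] - b1[1]; dy <- b2[2] - b1[2]
  l2 <- dx * dx + dy * dy
  s <- if (l2 == 0) rep(0, n_samp) else
    pmin(1, pmax(0, ((px - b1[1]) * dx + (py - b1[2]) * dy) / l2))
  qx <- b1[1] + s * dx; qy <- b1[2] + s * dy
  min(sqrt((px - qx)^2 + (py - qy)^2))
}

# pixel-counting oracle for the projected area of one capsule-shaped cell
capsule_pixel_area <- function(cc, px = 0.05) {
  h <- cc$ell / 2; r <- cc$radius
  gx <- seq(cc$x - h - r, cc$x + h + r, by = px)
  gy <- seq(cc$y - h - r, cc$y + h + r, by = px)
  g <- expand.grid(x = gx, y = gy)
  dx <- g$x - cc$x; dy <- g$y - cc$y
  ax <- cos(cc$theta); ay <- sin(cc$theta)
  tpar <- pmin(h, pmax(-h, dx * ax + dy * ay))
  d2 <- (dx - tpar * ax)^2 + (dy - tpar * ay)^2
  sum(d2 <= r^2) * px^2
}
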