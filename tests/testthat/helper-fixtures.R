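# Shared fixtures, all built in code.

# A flat height map at a given constant elevation.
flat_map <- function(n = 40L, spacing = 0.1, value = 0) {
  height_map(matrix(value, n, n), pixel_spacing = spacing)
}

# Height map sampling an exact plane z = a x + b y + c at cell centres.
plane_map <- function(n = 40L, spacing = 0.1, a = 0, b = 0, c = 0) {
  xs <- (seq_len(n) - 0.5) * spacing
  height_map(outer(xs, xs, function(y, x) a * x + b * y + c),
             pixel_spacing = spacing)
}

square_roi <- function(x0, y0, x1, y1, label = "background") {
  roi_polygon(c(x0, x1, x1, x0), c(y0, y0, y1, y1), label = label)
}

# Worked clinical example: five-visit series and background readings.
table1_absvol <- c(9.17, 11.76, 5.73, 0.73, 0.70)
table1_background <- c(0.44, 0.59, 0.73)

# Random simple polygon: jittered angles around a full circle keep every
# angular gap below pi, so the star construction is guaranteed simple.
random_polygon <- function(n_vertices = 12L) {
  step <- 2 * pi / n_vertices
  th <- (seq_len(n_vertices) - 1) * step + runif(n_vertices, -0.3, 0.3) * step
  r <- runif(n_vertices, 0.5, 3)
  roi_polygon(2 + r * cos(th), 2 + r * sin(th), label = "lesion")
}
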