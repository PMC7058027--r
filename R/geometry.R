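# Planar geometry helpers for ISH sections. Coordinates are micrometres,
# origin top-left, y increasing downward. Polygons are simple and closed
# implicitly (last vertex connects to first).

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ray-casting point-in-polygon, vectorized over query points.
# Points exactly on an edge may fall on either side; region polygons are
# expected to be separated by more than coordinate jitter.
.pointInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Shoelace area; positive for counter-clockwise vertex order in a y-down
# coordinate frame the sign flips, so take the absolute value.
.polygonArea <- function(vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1))
  abs(sum(vx[j] * vy - vx * vy[j])) / 2
}

# Conservative polygon-overlap screen: two regions are flagged when any
# vertex or the centroid of one lies strictly inside the other. This covers
# the rectangular atlas-style layouts used here; degenerate edge-crossing
# configurations without vertex containment are not detected.
.regionsOverlap <- function(regions) {
  nms <- unique(regions$region)
  if (length(nms) < 2) return(FALSE)
  polys <- lapply(nms, function(r) {
    sub <- regions[regions$region == r, ]
    sub <- sub[order(sub$vertex_index), ]
    list(x = sub$x_um, y = sub$y_um)
  })
  names(polys) <- nms
  for (a in seq_along(nms)) {
    for (b in seq_along(nms)) {
      if (a == b) next
      pa <- polys[[a]]; pb <- polys[[b]]
      qx <- c(pa$x, mean(pa$x)); qy <- c(pa$y, mean(pa$y))
      if (any(.pointInPolygon(qx, qy, pb$x, pb$y))) return(TRUE)
    }
  }
  FALSE
}

# Map points to the named region containing them ("outside" if none).
# Regions are non-overlapping, so the first hit is the only hit.
.regionOfPoints <- function(regions, px, py) {
  out <- rep("outside", length(px))
  for (r in unique(regions$region)) {
    sub <- regions[regions$region == r, ]
    sub <- sub[order(sub$vertex_index), ]
    todo <- out == "outside"
    if (!any(todo)) break
    hit <- .pointInPolygon(px[todo], py[todo], sub$x_um, sub$y_um)
    out[todo][hit] <- r
  }
  out
}

# Draw n points uniformly inside a polygon by rejection from its bbox.
.runifPolygon <- function(n, vx, vy) {
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 16L)
    cx <- runif(m, min(vx), max(vx))
    cy <- runif(m, min(vy), max(vy))
    keep <- .pointInPolygon(cx, cy, vx, vy)
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

# Evaluate an expression with a private RNG stream seeded from `seed`,
# restoring the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}
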