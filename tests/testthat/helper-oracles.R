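# Independent oracles used across the suite.

# Queue-based flood-fill component labeling, written independently of the
# package's labeler: scans row-major, grows one component at a time.
flood_fill_label <- function(img, connectivity = 4) {
  nr <- nrow(img); nc <- ncol(img)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  current <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (isTRUE(img[r0, c0] == 1L) && lab[r0, c0] == 0L) {
      current <- current + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- current
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in seq_len(nrow(offs))) {
          rr <- p[1] + offs[d, 1]; cc <- p[2] + offs[d, 2]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              isTRUE(img[rr, cc] == 1L) && lab[rr, cc] == 0L) {
            lab[rr, cc] <- current
            queue <- c(queue, list(c(rr, cc)))
          }
        }
      }
    }
  }
  lab
}

# Build a field_grid by hand from an arbitrary implicit function (mm
# coordinates), for meshes with closed-form volume.
synthetic_field_grid <- function(fun, domain, pitch) {
  fg <- field_on_grid("gyroid", domain, pitch = pitch, cell = 2.5)
  n <- dim(fg$values)
  Xm <- matrix(fg$axes[[1]], n[1], n[2])
  Ym <- matrix(fg$axes[[2]], n[1], n[2], byrow = TRUE)
  for (iz in seq_len(n[3])) {
    fg$values[, , iz] <- fun(Xm, Ym, fg$axes[[3]][iz])
  }
  fg$geometry <- "synthetic"
  fg
}

# Hand-built unit cube mesh: vertices at {0,1}^3, 12 outward-wound triangles.
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 7, 3), c(1, 5, 7),   # x = 0, outward -x
    c(2, 4, 8), c(2, 8, 6),   # x = 1, outward +x
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(3, 8, 4), c(3, 7, 8),   # y = 1
    c(1, 4, 2), c(1, 3, 4),   # z = 0
    c(5, 6, 8), c(5, 8, 7)    # z = 1
  )
  triangle_mesh(v, f)
}

# Random binary image with a fixed seed.
random_binary <- function(n, p = 0.4, seed) {
  set.seed(seed)
  matrix(as.integer(runif(n * n) < p), n, n)
}
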