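# Shared fixtures built in code. Phantoms are small so every file
# stays fast; anything expensive is cached per test run.

.fix <- new.env(parent = emptyenv())

straight_spec <- function(radius = 8, len = 160, grid = 96L) {
  phantomSpec(curve_kind = "straight", radius_mm = radius,
              length_mm = len, grid_shape = rep(grid, 3L),
              edge_softness_mm = 0)
}

straight_case <- function() {
  if (is.null(.fix$straight)) .fix$straight <- makePhantom(straight_spec())
  .fix$straight
}

tiny_case <- function() {
  if (is.null(.fix$tiny))
    .fix$tiny <- makePhantomDataset(1, phantomDistributionTiny(),
                                    seed = 77)[[1]]
  .fix$tiny
}

tiny_net <- function() {
  if (is.null(.fix$net))
    .fix$net <- createNetwork(networkConfig(
      stage_channels = c(2L, 3L, 4L, 5L, 6L), num_points = 8L,
      neighbors_k = 2L), seed = 5L)
  .fix$net
}

# independent point-to-polyline distance oracle: plain R loop over all
# point/segment pairs
oracle_point_polyline <- function(P, Q) {
  seg_d <- function(p, a, b) {
    d <- b - a
    qq <- sum(d^2)
    t <- if (qq > 0) sum((p - a) * d) / qq else 0
    t <- min(max(t, 0), 1)
    sqrt(sum((p - a - t * d)^2))
  }
  apply(P, 1, function(p) {
    min(vapply(seq_len(nrow(Q) - 1), function(j)
      seg_d(p, Q[j, ], Q[j + 1, ]), numeric(1)))
  })
}

# brute-force Chamfer oracle over all pairs
oracle_chamfer <- function(P, T, squared = FALSE) {
  f <- function(A, B) {
    sum(apply(A, 1, function(p) {
      d2 <- min(colSums((t(B) - p)^2))
      if (squared) d2 else sqrt(d2)
    }))
  }
  f(P, T) + f(T, P)
}

rand_polyline <- function(n, scale = 50) {
  p <- matrix(runif(3, 0, scale), 1, 3)
  for (i in seq_len(n - 1))
    p <- rbind(p, p[i, ] + runif(3, -8, 8) + c(4, 0, 0))
  p
}
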