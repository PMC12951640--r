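# Independent oracles used by the unit and property tests. These are
# deliberately written over different primitives than the package internals
# (zero-padded embedding for dilation, an explicit BFS queue for growth).

random_mask <- function(d, p = 0.3) {
  array(as.integer(runif(prod(d)) < p), dim = d)
}

# one-step 26-neighborhood binary dilation via a zero-padded embedding
oracle_dilate26 <- function(m) {
  d <- dim(m)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  acc <- array(0L, d)
  for (dx in 0:2) for (dy in 0:2) for (dz in 0:2) {
    acc <- acc + pad[dx + seq_len(d[1]), dy + seq_len(d[2]), dz + seq_len(d[3])]
  }
  array(as.integer(acc > 0L), dim = d)
}

# hysteresis growth as the fixpoint of dilate-and-intersect
oracle_growth_fixpoint <- function(m1, m2) {
  cur <- m1
  repeat {
    nxt <- array(as.integer(oracle_dilate26(cur) & m2), dim = dim(m2))
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# hysteresis growth by explicit breadth-first flood fill from the M1 seeds
oracle_growth_bfs <- function(m1, m2) {
  d <- dim(m2)
  out <- array(0L, d)
  queue <- which(m1 == 1L)
  out[queue] <- 1L
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    ijk <- arrayInd(v, d)
    for (o in seq_len(nrow(offs))) {
      n <- ijk + offs[o, ]
      if (any(n < 1L) || any(n > d)) next
      li <- n[1L] + d[1L] * (n[2L] - 1L) + d[1L] * d[2L] * (n[3L] - 1L)
      if (m2[li] == 1L && out[li] == 0L) {
        out[li] <- 1L
        queue <- c(queue, li)
      }
    }
  }
  out
}

# a small axis-aligned cuboid mask
cube_mask <- function(d, from, to) {
  m <- array(0L, d)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- 1L
  m
}
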