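# Independent oracles and small generators used across the suite.
# The morphology oracles evaluate the set definitions directly (brute-force
# double loops); reconstruction is iterated conditional dilation; 3D
# components are a plain-R breadth-first search. None of them share code with
# the package implementations they check.

rand_mask <- function(nr, nc, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

rand_se <- function(max_dim = 3L) {
  repeat {
    nr <- sample(max_dim, 1); nc <- sample(max_dim, 1)
    g <- matrix(stats::runif(nr * nc) < 0.6, nr, nc)
    if (any(g)) break
  }
  struct_el(g, anchor = c(sample(nr, 1), sample(nc, 1)))
}

# Dilation by direct enumeration of {c = a + b} (offsets relative to anchor)
oracle_dilate <- function(a, b) {
  out <- matrix(FALSE, nrow(a), ncol(a))
  aw <- which(a, arr.ind = TRUE)
  bw <- which(b$grid, arr.ind = TRUE)
  if (nrow(aw) == 0L) return(out)
  for (i in seq_len(nrow(aw))) {
    for (j in seq_len(nrow(bw))) {
      r <- aw[i, 1] + bw[j, 1] - b$anchor[1]
      c <- aw[i, 2] + bw[j, 2] - b$anchor[2]
      if (r >= 1 && r <= nrow(a) && c >= 1 && c <= ncol(a)) out[r, c] <- TRUE
    }
  }
  out
}

# Erosion by checking "c + b in A for every b" at every position
oracle_erode <- function(a, b) {
  out <- matrix(FALSE, nrow(a), ncol(a))
  bw <- which(b$grid, arr.ind = TRUE)
  for (r in seq_len(nrow(a))) {
    for (c in seq_len(ncol(a))) {
      ok <- TRUE
      for (j in seq_len(nrow(bw))) {
        rr <- r + bw[j, 1] - b$anchor[1]
        cc <- c + bw[j, 2] - b$anchor[2]
        if (rr < 1 || rr > nrow(a) || cc < 1 || cc > ncol(a) || !a[rr, cc]) {
          ok <- FALSE
          break
        }
      }
      if (ok) out[r, c] <- TRUE
    }
  }
  out
}

# Reconstruction as iterated conditional dilation of the marker inside the
# mask until stability (8-connectivity)
oracle_reconstruct <- function(marker, mask) {
  se8 <- struct_el(matrix(TRUE, 3, 3), anchor = c(2L, 2L))
  cur <- marker & mask
  repeat {
    nxt <- (oracle_dilate(cur, se8) | cur) & mask
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# 3D connected components by breadth-first search; returns an integer array
# labelled in first-voxel order, comparable to any labelling up to renaming
oracle_label3d <- function(g, connectivity = 26L) {
  d <- dim(g)
  off <- expand.grid(ds = -1:1, dr = -1:1, dc = -1:1)
  off <- off[!(off$ds == 0 & off$dr == 0 & off$dc == 0), ]
  if (connectivity == 6L) {
    off <- off[abs(off$ds) + abs(off$dr) + abs(off$dc) == 1, ]
  }
  lab <- array(0L, d)
  nxt <- 0L
  for (idx in which(g)) {
    if (lab[idx] != 0L) next
    nxt <- nxt + 1L
    queue <- idx
    lab[idx] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      s <- ((cur - 1L) %% d[1]) + 1L
      r <- (((cur - 1L) %/% d[1]) %% d[2]) + 1L
      c <- ((cur - 1L) %/% (d[1] * d[2])) + 1L
      for (k in seq_len(nrow(off))) {
        s2 <- s + off$ds[k]; r2 <- r + off$dr[k]; c2 <- c + off$dc[k]
        if (s2 < 1 || s2 > d[1] || r2 < 1 || r2 > d[2] ||
            c2 < 1 || c2 > d[3]) next
        j <- s2 + d[1] * (r2 - 1L) + d[1] * d[2] * (c2 - 1L)
        if (g[j] && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# canonical partition signature: voxels grouped by component, each component
# keyed by its smallest linear index
partition_of <- function(lab) {
  idx <- which(lab != 0L)
  split(idx, lab[idx])[order(vapply(split(idx, lab[idx]), min, 0))]
}

# Embed a mask in a frame of background so that identities over the infinite
# grid can be checked away from the frame border: pad must be at least the
# total structuring-element reach of the expression under test.
framed <- function(a, pad) {
  f <- matrix(FALSE, nrow(a) + 2 * pad, ncol(a) + 2 * pad)
  f[pad + seq_len(nrow(a)), pad + seq_len(ncol(a))] <- a
  f
}

interior <- function(f, pad, nr, nc) {
  f[pad + seq_len(nr), pad + seq_len(nc)]
}

# a small, fast phantom for unit tests (acceptance uses the defaults)
small_spec <- function(...) {
  phantom_spec(shape = c(20L, 64L, 64L), ...)
}
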