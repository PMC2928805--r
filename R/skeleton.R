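# Topological skeletonization (Zhang-Suen thinning) and reduction of the
# skeleton to its longest endpoint-to-endpoint geodesic path.

# Shift a 0/1 matrix by (dr, dc), zero-filling.
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen thinning of a logical mask to a 1-px-wide skeleton.
thin_mask <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours clockwise from north: P2..P9
      P2 <- shift_mat(m, 1, 0); P3 <- shift_mat(m, 1, -1)
      P4 <- shift_mat(m, 0, -1); P5 <- shift_mat(m, -1, -1)
      P6 <- shift_mat(m, -1, 0); P7 <- shift_mat(m, -1, 1)
      P8 <- shift_mat(m, 0, 1); P9 <- shift_mat(m, 1, 1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (sub == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# Reduce a skeleton to the ordered pixel path of its longest geodesic between
# endpoints. Returns an n x 2 matrix of (x, y) pixel-center coordinates,
# or raises a "coiled posture" condition if the skeleton has no endpoints.
skeleton_longest_path <- function(skel) {
  idx <- which(skel)
  if (length(idx) < 3) {
    frame_error("skeleton too small to trace", "nemaphene_midline_error")
  }
  H <- nrow(skel)
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  key <- function(rr, cc) (cc - 1L) * H + rr
  id_of <- integer(H * ncol(skel))
  id_of[idx] <- seq_along(idx)

  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  ef <- integer(0); et <- integer(0); ew <- numeric(0)
  deg <- integer(length(idx))
  for (k in seq_len(nrow(offs))) {
    rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= ncol(skel)
    ok[ok] <- skel[key(rr[ok], cc[ok])]
    deg <- deg + as.integer(ok)
    if (k <= 4) {  # each undirected edge once (offsets 5..8 mirror 1..4)
      from <- which(ok)
      to <- id_of[key(rr[from], cc[from])]
      ef <- c(ef, from); et <- c(et, to)
      ew <- c(ew, rep(sqrt(sum(offs[k, ]^2)), length(from)))
    }
  }
  ends <- which(deg == 1L)
  if (length(ends) == 0) {
    frame_error("coiled posture: skeleton has no endpoints",
                "nemaphene_coiled_error")
  }
  g <- igraph::graph_from_edgelist(cbind(ef, et), directed = FALSE)
  if (igraph::vcount(g) < length(idx)) {
    g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
  }
  igraph::E(g)$weight <- ew
  D <- igraph::distances(g, v = ends, to = ends)
  D[!is.finite(D)] <- -1
  best <- which(D == max(D), arr.ind = TRUE)[1, ]
  vp <- igraph::shortest_paths(g, from = ends[best[1]], to = ends[best[2]],
                               output = "vpath")$vpath[[1]]
  vi <- as.integer(vp)
  cbind(x = c[vi] - 0.5, y = r[vi] - 0.5)
}
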