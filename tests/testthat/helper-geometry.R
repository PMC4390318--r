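## shared geometry fixtures, built in code

disk_mask <- function(n, cy, cx, r) {
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  (ys - cy)^2 + (xs - cx)^2 <= r^2
}

bar_mask <- function(n, cy, x0, x1, width) {
  m <- matrix(FALSE, n, n)
  half <- floor(width / 2)
  m[(cy - half):(cy + half - (1 - width %% 2)), x0:x1] <- TRUE
  m
}

dumbbell_mask <- function(n = 101, r = 20, neck_half = 5,
                          c1 = c(51, 26), c2 = c(51, 76)) {
  m <- disk_mask(n, c1[1], c1[2], r) | disk_mask(n, c2[1], c2[2], r)
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  m | (ys >= c1[1] - neck_half & ys <= c1[1] + neck_half &
         xs >= c1[2] & xs <= c2[2])
}

psnr <- function(x, ref) 10 * log10(max(ref)^2 / mean((x - ref)^2))

## independent oracle: multi-source Dijkstra geodesic distance on the
## 8-neighbor grid graph restricted to a mask
geodesic_bfs_dist <- function(mask, sources) {
  n <- sum(mask)
  idx <- which(mask)
  pos <- match(seq_len(length(mask)), idx)  # full index -> compact
  nr <- nrow(mask); nc <- ncol(mask)
  dist <- rep(Inf, n)
  dist[pos[sources][!is.na(pos[sources])]] <- 0
  visited <- rep(FALSE, n)
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  w8 <- sqrt(offs$dy^2 + offs$dx^2)
  repeat {
    u <- which.min(ifelse(visited, Inf, dist))
    if (!length(u) || !is.finite(dist[u]) || all(visited)) break
    if (visited[u]) break
    visited[u] <- TRUE
    fi <- idx[u]
    ui <- (fi - 1) %% nr + 1; uj <- (fi - 1) %/% nr + 1
    for (k in seq_len(nrow(offs))) {
      vi <- ui + offs$dy[k]; vj <- uj + offs$dx[k]
      if (vi < 1 || vi > nr || vj < 1 || vj > nc) next
      if (!mask[vi, vj]) next
      v <- pos[vi + (vj - 1) * nr]
      if (dist[u] + w8[k] < dist[v]) dist[v] <- dist[u] + w8[k]
    }
  }
  out <- matrix(Inf, nr, nc)
  out[idx] <- dist
  out
}
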