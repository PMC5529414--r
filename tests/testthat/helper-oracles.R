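# Independent oracles used to validate the fast C++ implementations.

# 8-connected grayscale dilation by matrix shifts
dilate8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  out <- m
  for (dr in -1:1)
    for (dc in -1:1)
      out <- pmax(out, pad[(2:(H + 1)) + dr, (2:(W + 1)) + dc])
  out
}

# brute-force morphological reconstruction by iterative geodesic dilation
reconstruct_oracle <- function(marker, mask) {
  J <- marker
  repeat {
    J2 <- pmin(dilate8(J), mask)
    if (identical(J2, J)) return(J)
    J <- J2
  }
}

# brute-force regional maxima: flood each equal-valued plateau and check no
# 8-neighbour exceeds it
regmax_oracle <- function(img) {
  H <- nrow(img); W <- ncol(img)
  visited <- matrix(FALSE, H, W)
  out <- matrix(FALSE, H, W)
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  for (r0 in 1:H) for (c0 in 1:W) {
    if (visited[r0, c0]) next
    v <- img[r0, c0]
    queue <- list(c(r0, c0))
    visited[r0, c0] <- TRUE
    plateau <- list()
    ismax <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      plateau[[length(plateau) + 1L]] <- p
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb$dr[k]; c <- p[2] + nb$dc[k]
        if (r < 1 || r > H || c < 1 || c > W) next
        if (img[r, c] > v) ismax <- FALSE
        else if (img[r, c] == v && !visited[r, c]) {
          visited[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
    if (ismax) for (p in plateau) out[p[1], p[2]] <- TRUE
  }
  out
}

extended_maxima_oracle <- function(map, h) {
  hm <- if (h == 0) map else reconstruct_oracle(map - h, map)
  regmax_oracle(hm)
}

# maximum-cardinality one-to-one matching within radius d (assignment oracle)
match_cardinality_oracle <- function(auto, manual, d) {
  na <- nrow(auto); nm <- nrow(manual)
  if (na == 0L || nm == 0L) return(0L)
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("igraph needed for the matching oracle")
  dd <- sqrt(outer(auto$x, manual$x, "-")^2 + outer(auto$y, manual$y, "-")^2)
  edges <- which(dd <= d, arr.ind = TRUE)
  if (nrow(edges) == 0L) return(0L)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, na), rep(TRUE, nm)),
    edges = as.vector(t(cbind(edges[, 1L], na + edges[, 2L]))))
  igraph::max_bipartite_match(g)$matching_size
}

# naive explicit mirror-padding (half-sample symmetric) for the probmap test
mirror_pad_oracle <- function(m, half) {
  H <- nrow(m); W <- ncol(m)
  idx <- function(n) c(rev(seq_len(half)), 1:n, n:(n - half + 1L))
  m[idx(H), idx(W)]
}
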