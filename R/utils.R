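# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# (row, col) offsets of the Euclidean disc of radius r (in pixels).
disc_offsets <- function(radius) {
  r <- ceiling(radius)
  d <- expand.grid(dr = -r:r, dc = -r:r)
  d <- d[d$dr^2 + d$dc^2 <= radius^2, , drop = FALSE]
  as.matrix(d)
}

# Linear indices (column-major, 1-based) of the disc around a 1-based (row, col)
# centre, clipped to the image bounds.
neighborhood_indices <- function(center_rc, offsets, dim) {
  rr <- round(center_rc[1]) + offsets[, 1]
  cc <- round(center_rc[2]) + offsets[, 2]
  ok <- rr >= 1 & rr <= dim[1] & cc >= 1 & cc <= dim[2]
  (cc[ok] - 1L) * dim[1] + rr[ok]
}

# 8-connected labeling of a binary matrix. Returns an integer matrix with
# 0 = background and labels 1..n assigned in column-major first-pixel order.
label8 <- function(mask) {
  dm <- dim(mask)
  idx <- which(mask > 0)
  out <- matrix(0L, dm[1], dm[2])
  n <- length(idx)
  if (n == 0L) return(out)
  nr <- dm[1]
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  inmask <- logical(nr * dm[2]) # lookup: is pixel foreground
  inmask[idx] <- TRUE
  pos <- integer(nr * dm[2])    # pixel index -> vertex id
  pos[idx] <- seq_len(n)
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nrw <- row + off[1]; ncl <- col + off[2]
    ok <- nrw >= 1L & nrw <= nr & ncl >= 1L & ncl <= dm[2]
    nid <- (ncl[ok] - 1L) * nr + nrw[ok]
    hit <- inmask[nid]
    if (any(hit)) edges <- c(edges, rbind(pos[idx[ok]][hit], pos[nid][hit]))
  }
  g <- igraph::make_graph(edges = edges, n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel in column-major first-encounter order
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  out[idx] <- relab[memb]
  out
}

# For every pixel, the label of the nearest nonzero object in `labels` within
# Chebyshev distance `max_dist` (ties at equal distance -> lowest label), and
# that distance. Computed by iterated 3x3 max-dilation of a reversed label map.
nearest_label_map <- function(labels, max_dist) {
  k <- max(labels) + 1L
  rev_lab <- ifelse(labels > 0L, k - labels, 0L)
  assigned <- rev_lab
  dist <- ifelse(labels > 0L, 0L, NA_integer_)
  cur <- rev_lab
  if (max_dist >= 1L && k > 1L) {
    brush <- EBImage::makeBrush(3, "box")
    for (d in seq_len(max_dist)) {
      cur <- EBImage::dilate(cur, brush)
      newly <- which(assigned == 0L & cur > 0L)
      if (length(newly)) {
        assigned[newly] <- cur[newly]
        dist[newly] <- d
      }
    }
  }
  lab_near <- ifelse(assigned > 0L, k - assigned, NA_integer_)
  list(label = matrix(as.integer(lab_near), nrow(labels)),
       dist = matrix(as.integer(dist), nrow(labels)))
}
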