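# independent oracles, deliberately written with different mechanics than
# the package implementations they check

# Frustum-union volume by dense voxel counting: rasterizes every edge as an
# (unclamped-projection) truncated cone onto a fine grid and counts union
# voxels. Independent of the analytic frustum formula.
voxel_volume_oracle <- function(tree, voxel_nm = 20) {
  nd <- tree$nodes
  rmax <- max(nd$radius)
  lo <- c(min(nd$x), min(nd$y), min(nd$z)) - rmax - voxel_nm
  hi <- c(max(nd$x), max(nd$y), max(nd$z)) + rmax + voxel_nm
  dims <- as.integer(ceiling((hi - lo) / voxel_nm))
  occupied <- array(FALSE, dims)
  cc <- lapply(1:3, function(a) lo[a] + (seq_len(dims[a]) - 0.5) * voxel_nm)
  i <- match(tree$edges$from, nd$id)
  j <- match(tree$edges$to, nd$id)
  for (e in seq_along(i)) {
    p1 <- c(nd$x[i[e]], nd$y[i[e]], nd$z[i[e]])
    p2 <- c(nd$x[j[e]], nd$y[j[e]], nd$z[j[e]])
    r1 <- nd$radius[i[e]]; r2 <- nd$radius[j[e]]
    rp <- max(r1, r2)
    il <- pmax(1L, as.integer(floor((pmin(p1, p2) - rp - lo) / voxel_nm)))
    ih <- pmin(dims, as.integer(ceiling((pmax(p1, p2) + rp - lo) / voxel_nm)))
    grid <- expand.grid(x = cc[[1]][il[1]:ih[1]],
                        y = cc[[2]][il[2]:ih[2]],
                        z = cc[[3]][il[3]:ih[3]])
    w <- p2 - p1
    tt <- ((grid$x - p1[1]) * w[1] + (grid$y - p1[2]) * w[2] +
             (grid$z - p1[3]) * w[3]) / sum(w^2)
    dx <- grid$x - (p1[1] + tt * w[1])
    dy <- grid$y - (p1[2] + tt * w[2])
    dz <- grid$z - (p1[3] + tt * w[3])
    inside <- tt >= 0 & tt <= 1 &
      dx^2 + dy^2 + dz^2 <= (r1 + tt * (r2 - r1))^2
    if (!any(inside)) next
    sel <- expand.grid(i = il[1]:ih[1], j = il[2]:ih[2], k = il[3]:ih[3])
    sel <- sel[inside, ]
    occupied[cbind(sel$i, sel$j, sel$k)] <- TRUE
  }
  sum(occupied) * (voxel_nm / 1e3)^3 / 1e0  # um^3 (voxel_nm in nm -> um)
}

# Naive constrained dilation: per sweep, every labeled voxel proposes its
# label to each of its 26 neighbors; proposals are tallied per target voxel
# and applied only where a single label claims. Offset-by-offset index
# arithmetic, no separable filters.
naive_constrained_dilate <- function(arr, rounds) {
  d <- dim(arr)
  contested <- array(FALSE, d)
  for (s in seq_len(rounds)) {
    claim_lab <- array(0L, d)
    claim_multi <- array(FALSE, d)
    src <- which(arr > 0L)
    ai <- arrayInd(src, d)
    labs <- arr[src]
    for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
      if (ox == 0 && oy == 0 && oz == 0) next
      ti <- cbind(ai[, 1] + ox, ai[, 2] + oy, ai[, 3] + oz)
      ok <- ti[, 1] >= 1 & ti[, 1] <= d[1] &
        ti[, 2] >= 1 & ti[, 2] <= d[2] &
        ti[, 3] >= 1 & ti[, 3] <= d[3]
      if (!any(ok)) next
      tl <- ti[ok, 1] + d[1] * (ti[ok, 2] - 1L + d[2] * (ti[ok, 3] - 1L))
      ll <- labs[ok]
      bg <- arr[tl] == 0L & !contested[tl]
      tl <- tl[bg]; ll <- ll[bg]
      # first-claim vs conflicting-claim bookkeeping (order-independent:
      # conflicts detected against any differing label)
      prev <- claim_lab[tl]
      claim_multi[tl[prev != 0L & prev != ll]] <- TRUE
      claim_lab[tl[prev == 0L]] <- ll[prev == 0L]
    }
    take <- claim_lab != 0L & !claim_multi
    arr[take] <- claim_lab[take]
    contested[claim_multi] <- TRUE
  }
  list(arr = arr, contested = contested)
}
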