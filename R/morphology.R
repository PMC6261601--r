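# 3D binary/label morphology on dense arrays.
#
# All operations use the 3x3x3 cubic structuring element (26-neighborhood).
# A cube is separable for min/max filters, so dilation and erosion run as
# three axis-wise passes of three-way pmax/pmin instead of 27 shifts.
# Outside the array counts as background.

shift3 <- function(a, s, axis, fill) {
  d <- dim(a)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  src <- if (s > 0) 1:(n - s) else (1 - s):n
  dst <- if (s > 0) (1 + s):n else 1:(n + s)
  if (axis == 1L) out[dst, , ] <- a[src, , ]
  else if (axis == 2L) out[, dst, ] <- a[, src, ]
  else out[, , dst] <- a[, , src]
  out
}

max_filter3 <- function(a, fill) {
  for (ax in 1:3) {
    a <- pmax(a, shift3(a, 1L, ax, fill), shift3(a, -1L, ax, fill))
  }
  a
}

min_filter3 <- function(a, fill) {
  for (ax in 1:3) {
    a <- pmin(a, shift3(a, 1L, ax, fill), shift3(a, -1L, ax, fill))
  }
  a
}

# binary dilation / erosion by the 3^3 cube, `rounds` times
dilate_bin <- function(a, rounds = 1L) {
  for (r in seq_len(rounds)) a <- max_filter3(a, FALSE) > 0
  a
}

erode_bin <- function(a, rounds = 1L) {
  for (r in seq_len(rounds)) a <- min_filter3(a, TRUE) & TRUE
  a
}

# pmax/pmin drop dim on plain logicals; keep arrays numeric-logical safe
pmax <- function(...) {
  out <- base::pmax(...)
  dim(out) <- dim(..1)
  out
}
pmin <- function(...) {
  out <- base::pmin(...)
  dim(out) <- dim(..1)
  out
}

bbox_of <- function(mask, margin = 0L) {
  d <- dim(mask)
  w <- which(mask)
  if (!length(w)) return(NULL)
  w <- arrayInd(w, d)
  lo <- pmax.int(apply(w, 2, min) - margin, 1L)
  hi <- pmin.int(apply(w, 2, max) + margin, d)
  list(lo = lo, hi = hi)
}
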