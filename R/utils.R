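#' @include methods.R
NULL

# Resample a polyline at equal arc-length spacing.  Points at 0, step,
# 2*step, ...; the final input point is kept (last segment may be shorter).
# Output points lie exactly on the input polyline.
.resample_polyline <- function(points, step) {
    seg <- points[-1L, , drop = FALSE] - points[-nrow(points), , drop = FALSE]
    len <- sqrt(rowSums(seg^2))
    cum <- c(0, cumsum(len))
    total <- cum[length(cum)]
    s <- seq(0, total, by = step)
    if (total - s[length(s)] > 1e-9) s <- c(s, total)
    idx <- findInterval(s, cum, rightmost.closed = TRUE)
    idx[idx >= nrow(points)] <- nrow(points) - 1L
    frac <- (s - cum[idx]) / ifelse(len[idx] > 0, len[idx], 1)
    points[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
}

# TRUE for each world-mm point whose nearest voxel is inside the mask
.points_in_mask <- function(points, mask, affine) {
    v <- round(.world2voxel(affine, points))
    d <- dim(mask)
    ok <- v[, 1] >= 0 & v[, 1] < d[1] &
          v[, 2] >= 0 & v[, 2] < d[2] &
          v[, 3] >= 0 & v[, 3] < d[3]
    hit <- rep(FALSE, nrow(v))
    if (any(ok)) {
        lin <- 1L + v[ok, 1] + d[1] * (v[ok, 2] + d[2] * v[ok, 3])
        hit[ok] <- mask[lin]
    }
    hit
}

# does a fiber (point matrix) touch the mask?
.fiber_hits_mask <- function(points, mask, affine) {
    any(.points_in_mask(points, mask, affine))
}

# world coordinates of all voxel centers (n x 3, voxel-major order)
.voxel_centers <- function(dims, affine) {
    idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1L), j = 0:(dims[2] - 1L),
                                 k = 0:(dims[3] - 1L)))
    .voxel2world(affine, idx)
}
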