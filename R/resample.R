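#' Block down-sampling of a volume
#'
#' Down-samples by an integer factor using non-overlapping blocks, the
#' resolution-reduction step used before model calibration. Two modes are
#' provided: `"mean"` for intensity-like volumes and `"sum"` for cell-count
#' volumes, where the block sum conserves the total number of cells. Shapes
#' not divisible by the factor are zero-padded on the high-index side before
#' blocking; because padding carries zeros, sum-mode totals are unaffected.
#'
#' @param vol an [image_volume()].
#' @param factor positive integer block edge (1 is a no-op copy).
#' @param mode `"mean"` or `"sum"` block aggregation.
#' @return an `image_volume` with spacing multiplied by `factor`; the origin
#'   moves to the center of the first block.
#' @export
downsample_by_factor <- function(vol, factor, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  stopifnot(is_image_volume(vol))
  f <- as.integer(factor)
  if (is.na(f) || f <= 0L) stop("'factor' must be a positive integer")
  a <- vol$values
  d <- dim(a)
  dp <- as.integer(ceiling(d / f) * f)
  if (any(dp != d)) {
    b <- array(0, dp)
    b[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
    a <- b
  }
  nb <- dp %/% f
  dim(a) <- c(f, nb[1], f, nb[2], f, nb[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(f^3, prod(nb))
  out <- .colSums(a, f^3, prod(nb))
  if (mode == "mean") out <- out / f^3
  image_volume(array(out, nb),
               spacing = vol$spacing * f,
               origin = vol$origin + (f - 1) / 2 * vol$spacing)
}

# Majority-vote block down-sampling for integer label volumes; ties resolve
# to the largest label so tumor presence wins over background.
downsample_labels <- function(labels, factor) {
  f <- as.integer(factor)
  classes <- sort(unique(as.vector(labels)))
  counts <- lapply(classes, function(cl) {
    v <- image_volume(array(as.double(labels == cl), dim(labels)))
    downsample_by_factor(v, f, mode = "sum")$values
  })
  best <- array(classes[1], dim(counts[[1]]))
  bestn <- counts[[1]]
  for (j in seq_along(classes)[-1]) {
    take <- counts[[j]] >= bestn
    best[take] <- classes[j]
    bestn[take] <- counts[[j]][take]
  }
  array(as.integer(best), dim(bestn))
}

#' Trilinear resampling onto a target grid
#'
#' Interpolates `vol` at the voxel centers of `target`'s grid, the operation
#' used to bring lower-resolution sequences (diffusion-weighted, PET) onto
#' the contrast-enhanced grid. Points outside the source extent are filled
#' with 0. Trilinear interpolation is exact on constant and affine fields.
#'
#' @param vol source [image_volume()].
#' @param target `image_volume` supplying the output grid (its values are
#'   ignored).
#' @return `image_volume` on `target`'s grid.
#' @export
resample_to_grid <- function(vol, target) {
  stopifnot(is_image_volume(vol), is_image_volume(target))
  ds <- dim(vol$values); dt <- dim(target$values)
  lo_s <- vol$origin; hi_s <- vol$origin + (ds - 1) * vol$spacing
  lo_t <- target$origin; hi_t <- target$origin + (dt - 1) * target$spacing
  if (any(hi_t < lo_s) || any(lo_t > hi_s))
    stop("source and target grids have disjoint physical extents")

  # fractional (0-based) source indices of target voxel centers, per axis
  fidx <- lapply(1:3, function(ax) {
    coords <- lo_t[ax] + (seq_len(dt[ax]) - 1) * target$spacing[ax]
    (coords - lo_s[ax]) / vol$spacing[ax]
  })
  f1 <- array(fidx[[1]], dt)
  f2 <- array(rep(fidx[[2]], each = dt[1]), dt)
  f3 <- array(rep(fidx[[3]], each = dt[1] * dt[2]), dt)
  eps <- 1e-9
  inside <- f1 >= -eps & f1 <= ds[1] - 1 + eps &
            f2 >= -eps & f2 <= ds[2] - 1 + eps &
            f3 >= -eps & f3 <= ds[3] - 1 + eps
  clamp <- function(f, n) pmin(pmax(f, 0), n - 1)
  f1 <- clamp(f1, ds[1]); f2 <- clamp(f2, ds[2]); f3 <- clamp(f3, ds[3])
  i1 <- pmin(floor(f1), ds[1] - 2); i1[ds[1] == 1] <- 0
  i2 <- pmin(floor(f2), ds[2] - 2); i2[ds[2] == 1] <- 0
  i3 <- pmin(floor(f3), ds[3] - 2); i3[ds[3] == 1] <- 0
  w1 <- f1 - i1; w2 <- f2 - i2; w3 <- f3 - i3
  s <- vol$values
  gather <- function(a, b, c_) {
    ii <- pmin(i1 + a, ds[1] - 1) + 1
    jj <- pmin(i2 + b, ds[2] - 1) + 1
    kk <- pmin(i3 + c_, ds[3] - 1) + 1
    s[cbind(as.vector(ii), as.vector(jj), as.vector(kk))]
  }
  out <- (1 - w1) * (1 - w2) * (1 - w3) * gather(0, 0, 0) +
         w1 * (1 - w2) * (1 - w3) * gather(1, 0, 0) +
         (1 - w1) * w2 * (1 - w3) * gather(0, 1, 0) +
         (1 - w1) * (1 - w2) * w3 * gather(0, 0, 1) +
         w1 * w2 * (1 - w3) * gather(1, 1, 0) +
         w1 * (1 - w2) * w3 * gather(1, 0, 1) +
         (1 - w1) * w2 * w3 * gather(0, 1, 1) +
         w1 * w2 * w3 * gather(1, 1, 1)
  out <- array(out, dt)
  out[!inside] <- 0
  image_volume(out, target$spacing, target$origin)
}
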