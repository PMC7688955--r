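#' Construct an image volume
#'
#' `image_volume` is the universal carrier for every 3D scalar field in the
#' package: raw MR signals, ADC maps, drug-distribution maps, stress fields,
#' and tumor cellularity. It couples a 3D numeric array to a physical grid
#' defined by a voxel spacing and an origin, with a voxel-centered coordinate
#' convention: the physical position of voxel `(i, j, k)` (1-based indices)
#' is `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param values 3D numeric array; all values must be finite.
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in mm;
#'   strictly positive.
#' @param origin numeric length-3, physical position of the first voxel
#'   center in mm.
#' @return An object of class `image_volume`: a list with elements
#'   `values`, `spacing`, `origin`.
#' @examples
#' v <- image_volume(array(1, c(4, 4, 4)), spacing = c(2, 2, 2))
#' voxel_volume_mm3(v)
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  storage.mode(values) <- "double"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite numbers")
  if (any(!is.finite(values)))
    stop("'values' contains non-finite entries")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %d x %d x %d, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Test for the image_volume class
#' @param x object to test.
#' @return logical scalar.
#' @export
is_image_volume <- function(x) inherits(x, "image_volume")

#' Are two volumes defined on the same physical grid?
#'
#' Two volumes are grid-compatible iff their array shapes agree and their
#' spacings and origins agree within `tol` mm componentwise.
#'
#' @param a,b `image_volume` objects.
#' @param tol absolute tolerance in mm (default `1e-6`).
#' @return logical scalar.
#' @export
grid_compatible <- function(a, b, tol = 1e-6) {
  stopifnot(is_image_volume(a), is_image_volume(b))
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

#' Physical voxel volume in cubic millimetres
#' @param x an `image_volume`, or a numeric length-3 spacing.
#' @return voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(x) {
  sp <- if (is_image_volume(x)) x$spacing else as.numeric(x)
  stopifnot(length(sp) == 3L, all(sp > 0))
  prod(sp)
}

#' Build a volume on the same grid as a template
#' @param values 3D array (or scalar, recycled) of new values.
#' @param template `image_volume` supplying spacing and origin.
#' @return `image_volume`.
#' @export
volume_like <- function(values, template) {
  stopifnot(is_image_volume(template))
  if (length(values) == 1L)
    values <- array(values, dim(template$values))
  image_volume(values, template$spacing, template$origin)
}

# Shift a 3D array by one voxel along an axis, padding with `fill`.
# dir = +1 returns a[i+1] at slot i (look-ahead); dir = -1 the reverse.
shift3 <- function(a, axis, dir, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  n <- d[axis]
  if (n <= 1L) return(out)
  src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  dst <- src
  if (dir > 0) { dst[[axis]] <- 1:(n - 1L); src[[axis]] <- 2:n }
  else         { dst[[axis]] <- 2:n;        src[[axis]] <- 1:(n - 1L) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Binary dilation of a logical 3D array by `r` voxels (6-connected, r steps).
dilate_mask <- function(mask, r = 1L) {
  m <- mask
  for (s in seq_len(r)) {
    grown <- m
    for (ax in 1:3) for (dir in c(-1, 1))
      grown <- grown | (shift3(m, ax, dir, fill = FALSE) > 0)
    m <- grown
  }
  m
}
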