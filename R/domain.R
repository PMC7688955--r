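#' Breast domain: mask and tissue labels
#'
#' The spatial domain of the model: a boolean inside-breast mask and an
#' integer tissue label volume with 0 = outside, 1 = adipose,
#' 2 = fibroglandular, 3 = tumor. Labels must be nonzero exactly where the
#' mask is true, so the tumor region is necessarily inside the breast.
#'
#' @param mask logical 3D array, `TRUE` inside the breast.
#' @param tissue_labels integer 3D array of the same shape with values in
#'   `0:3`.
#' @return a `breast_domain` object.
#' @export
breast_domain <- function(mask, tissue_labels) {
  stopifnot(is.array(mask), is.array(tissue_labels),
            identical(dim(mask), dim(tissue_labels)))
  mask <- array(as.logical(mask), dim(mask))
  tissue_labels <- array(as.integer(tissue_labels), dim(tissue_labels))
  if (any(is.na(mask)) || any(is.na(tissue_labels)))
    stop("mask/labels contain NA")
  if (!all(tissue_labels %in% 0:3))
    stop("tissue labels must be in 0:3 (outside/adipose/fibroglandular/tumor)")
  if (any((tissue_labels != 0L) != mask))
    stop("tissue labels must be nonzero exactly where the mask is TRUE")
  structure(list(mask = mask, tissue_labels = tissue_labels),
            class = "breast_domain")
}

#' @export
print.breast_domain <- function(x, ...) {
  d <- dim(x$mask)
  n <- tabulate(x$tissue_labels + 1L, nbins = 4L)
  cat(sprintf("<breast_domain> %d x %d x %d; adipose %d, fibroglandular %d, tumor %d voxels\n",
              d[1], d[2], d[3], n[2], n[3], n[4]))
  invisible(x)
}

#' Tumor region of a breast domain
#' @param domain a [breast_domain()].
#' @return logical array, `TRUE` on tumor voxels.
#' @export
tumor_roi <- function(domain) {
  stopifnot(inherits(domain, "breast_domain"))
  domain$tissue_labels == 3L
}
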