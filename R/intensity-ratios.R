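#' Layered intensity image with named masks
#'
#' Container for the confocal-style quantifications: one or two named
#' intensity channels (numeric matrices, non-negative) plus named binary
#' masks of identical shape (e.g. `OS`, `IS`, `ONL`, `myoid`, `cell_1`).
#' Masks are supplied, not segmented — layer boundaries on real data are
#' drawn manually, and curved retina sections must be straightened before
#' the geometric myoid split applies.
#'
#' @param intensity a numeric matrix, or a named list of matrices (one
#'   per channel).
#' @param masks named list of logical matrices, same dimensions as the
#'   intensity raster(s).
#' @param pixel_size_um pixel size in micrometers (metadata only).
#' @return A `layer_image` list.
#' @export
layer_image <- function(intensity, masks = list(), pixel_size_um = NA_real_) {
  if (is.matrix(intensity)) intensity <- list(intensity = intensity)
  stopifnot(length(intensity) >= 1L,
            all(vapply(intensity, is.matrix, logical(1L))))
  dm <- dim(intensity[[1L]])
  for (ch in intensity) {
    if (!identical(dim(ch), dm)) stop("channel shapes differ",
                                      call. = FALSE)
    if (any(ch < 0)) stop("intensities must be non-negative",
                          call. = FALSE)
  }
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!identical(dim(m), dm))
      stop("mask '", nm, "' shape differs from intensity", call. = FALSE)
    masks[[nm]] <- as.logical(m) |> matrix(dm[1L], dm[2L])
  }
  if (all(c("IS", "myoid") %in% names(masks)) &&
      any(masks$myoid & !masks$IS))
    stop("myoid mask must be a subset of the IS mask", call. = FALSE)
  structure(list(intensity = intensity, masks = masks,
                 pixel_size_um = pixel_size_um), class = "layer_image")
}

check_shapes <- function(image, mask) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ", call. = FALSE)
}

#' Integrated density within a mask
#'
#' The exact sum of intensities over mask-true pixels; an empty mask has
#' integrated density 0. No background subtraction is applied by default
#' anywhere in this module (see `background`).
#'
#' @param image numeric intensity matrix.
#' @param mask logical matrix, same shape.
#' @param background optional constant offset subtracted per pixel before
#'   summing (default 0).
#' @return Scalar integrated density.
#' @export
integrated_density <- function(image, mask, background = 0) {
  check_shapes(image, mask)
  sum(image[mask] - background)
}

#' Mean intensity within a non-empty mask
#'
#' @inheritParams integrated_density
#' @return Scalar mean of in-mask intensities.
#' @export
mean_intensity <- function(image, mask) {
  check_shapes(image, mask)
  n <- sum(mask)
  if (n == 0L) stop("mask is empty", call. = FALSE)
  sum(image[mask]) / n
}

#' Surface-label to expression ratio for one cell
#'
#' Ratio of the surface label's (e.g. ALFA tag) mean intensity to the
#' expression reporter's (e.g. GFP) mean intensity over one cell mask —
#' the per-cell surface-expression readout. Invariant to common positive
#' rescaling of both channels.
#'
#' @param alfa,gfp intensity matrices for the two channels.
#' @param cell_mask logical matrix selecting the cell, non-empty.
#' @param region_id,group identifiers carried into the result row.
#' @return One-row data.frame: `region_id`, `kind = "alfa_gfp"`, `value`,
#'   `group`.
#' @export
alfa_gfp_ratio <- function(alfa, gfp, cell_mask, region_id = "cell",
                           group = "unlabeled") {
  g <- mean_intensity(gfp, cell_mask)
  if (g == 0) stop("GFP mean intensity is zero in cell mask",
                   call. = FALSE)
  ratio_row(region_id, "alfa_gfp", mean_intensity(alfa, cell_mask) / g,
            group)
}

ratio_row <- function(region_id, kind, value, group) {
  data.frame(region_id = region_id, kind = kind, value = value,
             group = group, stringsAsFactors = FALSE)
}

#' Proximal (myoid-side) half of an inner-segment mask
#'
#' Splits an already-straightened IS mask at the midpoint of its extent
#' along the declared layer-normal axis and returns the proximal half as
#' a mask (always a subset of the input). The midpoint is
#' `(min + max) / 2` of the mask's occupied indices along the axis;
#' pixels strictly on the proximal side of it are returned, which for a
#' rectangular strip of even depth yields exactly half the rows.
#'
#' @param is_mask non-empty logical matrix for the IS layer.
#' @param axis `"row"` if the layer normal runs along rows (strata are
#'   horizontal bands), `"col"` otherwise.
#' @param proximal `"high"` if the proximal (myoid/nuclear) side is at
#'   larger indices along the axis, `"low"` otherwise.
#' @return Logical matrix: the myoid-half mask.
#' @export
split_is_mask <- function(is_mask, axis = c("row", "col"),
                          proximal = c("high", "low")) {
  axis <- match.arg(axis); proximal <- match.arg(proximal)
  if (!any(is_mask)) stop("IS mask is empty", call. = FALSE)
  idx <- which(is_mask, arr.ind = TRUE)[, if (axis == "row") 1L else 2L]
  mid <- (min(idx) + max(idx)) / 2
  coord <- if (axis == "row") row(is_mask) else col(is_mask)
  side <- if (proximal == "high") coord > mid else coord < mid
  is_mask & side
}

#' Myoid-to-total-IS integrated density ratio
#'
#' `ID(myoid) / ID(IS)`, in \[0, 1\]: the fraction of the inner segment's
#' signal residing in its proximal (myoid) half, where the Golgi lives.
#'
#' @param image intensity matrix.
#' @param is_mask,myoid_mask logical masks; `myoid_mask` must be a subset
#'   of `is_mask`, and the IS integrated density must be positive.
#' @inheritParams alfa_gfp_ratio
#' @return One-row data.frame with `kind = "myoid_fraction"`.
#' @export
myoid_fraction <- function(image, is_mask, myoid_mask,
                           region_id = "region", group = "unlabeled") {
  if (any(myoid_mask & !is_mask))
    stop("myoid mask must be a subset of the IS mask", call. = FALSE)
  tot <- integrated_density(image, is_mask)
  if (tot <= 0) stop("IS integrated density is zero", call. = FALSE)
  ratio_row(region_id, "myoid_fraction",
            integrated_density(image, myoid_mask) / tot, group)
}

#' IS share of the total photoreceptor integrated density
#'
#' `ID(IS) / (ID(OS) + ID(IS) + ID(ONL))`, in \[0, 1\].
#'
#' @param image intensity matrix.
#' @param masks named list with pairwise-disjoint logical masks `OS`,
#'   `IS`, `ONL`.
#' @inheritParams alfa_gfp_ratio
#' @return One-row data.frame with `kind = "is_fraction"`.
#' @export
is_photoreceptor_fraction <- function(image, masks, region_id = "region",
                                      group = "unlabeled") {
  stopifnot(all(c("OS", "IS", "ONL") %in% names(masks)))
  if (any(masks$OS & masks$IS) || any(masks$OS & masks$ONL) ||
      any(masks$IS & masks$ONL))
    stop("OS/IS/ONL masks must be pairwise disjoint", call. = FALSE)
  ids <- vapply(masks[c("OS", "IS", "ONL")], integrated_density,
                numeric(1L), image = image)
  tot <- sum(ids)
  if (tot <= 0) stop("combined OS+IS+ONL density is zero", call. = FALSE)
  ratio_row(region_id, "is_fraction", ids[["IS"]] / tot, group)
}

#' Integrated density averaged over z-slices
#'
#' Arithmetic mean of the per-slice integrated densities over one mask —
#' the convention of averaging measurements from a few slices of a
#' z-projection stack.
#'
#' @param slices list of intensity matrices (>= 1), all the same shape.
#' @param mask logical matrix.
#' @return Scalar averaged integrated density.
#' @export
zslice_average_density <- function(slices, mask) {
  stopifnot(length(slices) >= 1L)
  mean(vapply(slices, integrated_density, numeric(1L), mask = mask))
}

#' Synthetic layered-retina intensity image
#'
#' Builds a rectified (already-straightened) retinal cross-section as
#' stacked horizontal strata, top to bottom OS / IS / ONL, with the
#' myoid defined as the proximal (ONL-side) half of the IS. Per-layer
#' mean intensities are constant; the myoid half of the IS may be given
#' its own mean to emulate myoid enrichment. Optional i.i.d. Gaussian
#' noise is added per pixel and clipped at zero (negligible bias at the
#' default means and noise scales).
#'
#' @param layer_means named numeric vector `c(OS=, IS=, ONL=)` of mean
#'   intensities (arbitrary units).
#' @param myoid_mean mean intensity of the myoid half of the IS; defaults
#'   to `layer_means["IS"]` (no enrichment). The ellipsoid (distal) half
#'   keeps `layer_means["IS"]`.
#' @param layer_rows named integer vector `c(OS=, IS=, ONL=)` of strata
#'   depths in pixels (IS depth should be even so the halves are exact).
#' @param ncols image width in pixels.
#' @param noise_sd Gaussian pixel noise sd (0 = noise free).
#' @param seed integer seed (noise only).
#' @return List with `image` (a [layer_image()] with masks `OS`, `IS`,
#'   `ONL`, `myoid`) and `truth` — the analytic `myoid_fraction` and
#'   `is_fraction` implied by the configured means and areas.
#' @export
synth_layer_image <- function(layer_means = c(OS = 5, IS = 10, ONL = 5),
                              myoid_mean = NULL,
                              layer_rows = c(OS = 20L, IS = 20L, ONL = 20L),
                              ncols = 40L, noise_sd = 0, seed = 1L) {
  stopifnot(all(c("OS", "IS", "ONL") %in% names(layer_means)),
            all(c("OS", "IS", "ONL") %in% names(layer_rows)),
            all(layer_rows >= 2L), ncols >= 1L, noise_sd >= 0)
  if (is.null(myoid_mean)) myoid_mean <- layer_means[["IS"]]
  nr <- sum(layer_rows[c("OS", "IS", "ONL")])
  rows_os <- seq_len(layer_rows[["OS"]])
  rows_is <- layer_rows[["OS"]] + seq_len(layer_rows[["IS"]])
  rows_onl <- layer_rows[["OS"]] + layer_rows[["IS"]] +
    seq_len(layer_rows[["ONL"]])

  band_mask <- function(rows) {
    m <- matrix(FALSE, nr, ncols); m[rows, ] <- TRUE; m
  }
  masks <- list(OS = band_mask(rows_os), IS = band_mask(rows_is),
                ONL = band_mask(rows_onl))
  masks$myoid <- split_is_mask(masks$IS, axis = "row", proximal = "high")

  img <- matrix(0, nr, ncols)
  img[masks$OS] <- layer_means[["OS"]]
  img[masks$IS] <- layer_means[["IS"]]
  img[masks$myoid] <- myoid_mean
  img[masks$ONL] <- layer_means[["ONL"]]
  if (noise_sd > 0) {
    set.seed(seed)
    img <- pmax(img + matrix(stats::rnorm(nr * ncols, 0, noise_sd),
                             nr, ncols), 0)
  }

  n_my <- sum(masks$myoid)
  n_ell <- sum(masks$IS) - n_my
  id_is <- n_my * myoid_mean + n_ell * layer_means[["IS"]]
  id_os <- sum(masks$OS) * layer_means[["OS"]]
  id_onl <- sum(masks$ONL) * layer_means[["ONL"]]
  list(
    image = layer_image(img, masks),
    truth = list(
      myoid_fraction = n_my * myoid_mean / id_is,
      is_fraction = id_is / (id_os + id_is + id_onl),
      layer_means = layer_means, myoid_mean = myoid_mean,
      noise_sd = noise_sd, seed = seed
    )
  )
}

#' Read a layered image from TIFF files
#'
#' Convenience reader for real data: one intensity TIFF per channel plus
#' single-channel mask TIFFs (non-zero = in mask). Requires the `tiff`
#' package.
#'
#' @param channel_paths named character vector of intensity TIFF paths.
#' @param mask_paths named character vector of mask TIFF paths.
#' @param pixel_size_um pixel size metadata.
#' @return A [layer_image()].
#' @export
read_layer_image <- function(channel_paths, mask_paths = character(),
                             pixel_size_um = NA_real_) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF images requires the 'tiff' package", call. = FALSE)
  # float TIFFs come back in native units; integer TIFFs are scaled to
  # [0, 1] by the reader — all ratios here are invariant to that scale
  as_mat <- function(p) {
    a <- tiff::readTIFF(p)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    a
  }
  layer_image(lapply(channel_paths, as_mat),
              lapply(as.list(mask_paths), function(p) as_mat(p) != 0),
              pixel_size_um)
}
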