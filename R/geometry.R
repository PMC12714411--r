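#' Toy acquisition geometry with box-shaped regions of interest
#'
#' Defines a small 3-D voxel grid and four disjoint box ROIs labelled
#' `amygdala`, `VS`, `lPFC` and `dmPFC`. This is the synthetic stand-in
#' geometry for first-level map analysis; with real data, user-supplied
#' NIfTI masks play the same role.
#'
#' @param dim Integer grid dimensions (default `c(20, 20, 12)`).
#' @param roi_dim Integer box dimensions for each ROI (default `c(4, 4, 4)`).
#' @param roi_origins Optional named list of 1-based corner indices for the
#'   four ROIs; by default the boxes are placed in separate quadrants of
#'   the grid.
#'
#' @return An object of class `pit_geometry`: a list with `dim`, `masks`
#'   (named logical 3-D arrays), and `n_voxels`.
#' @export
toy_geometry <- function(dim = c(20L, 20L, 12L), roi_dim = c(4L, 4L, 4L),
                         roi_origins = NULL) {
  if (length(dim) != 3L || any(dim < 2))
    stop_pitrel("dim must be three integers >= 2", class = "pitrel_geometry_error")
  dim <- as.integer(dim)
  roi_dim <- as.integer(rep(roi_dim, length.out = 3L))
  roi_names <- c("amygdala", "VS", "lPFC", "dmPFC")
  if (is.null(roi_origins)) {
    lo <- pmax(1L, dim %/% 6L)
    hi <- pmax(1L, dim %/% 2L + dim %/% 6L)
    zc <- pmax(1L, dim[3] %/% 4L)
    roi_origins <- list(
      amygdala = c(lo[1], lo[2], zc),
      VS       = c(hi[1], lo[2], zc),
      lPFC     = c(lo[1], hi[2], zc),
      dmPFC    = c(hi[1], hi[2], zc)
    )
  }
  if (!all(roi_names %in% names(roi_origins)))
    stop_pitrel("roi_origins must name all of: ",
                paste(roi_names, collapse = ", "),
                class = "pitrel_geometry_error")
  masks <- list()
  for (nm in roi_names) {
    o <- as.integer(roi_origins[[nm]])
    if (any(o < 1L) || any(o + roi_dim - 1L > dim))
      stop_pitrel("ROI '", nm, "' does not fit inside the grid",
                  class = "pitrel_geometry_error")
    m <- array(FALSE, dim)
    m[o[1]:(o[1] + roi_dim[1] - 1L),
      o[2]:(o[2] + roi_dim[2] - 1L),
      o[3]:(o[3] + roi_dim[3] - 1L)] <- TRUE
    masks[[nm]] <- m
  }
  total <- Reduce(`+`, masks)
  if (any(total > 1L))
    stop_pitrel("ROI boxes overlap", class = "pitrel_geometry_error")
  structure(list(dim = dim, masks = masks, n_voxels = prod(dim)),
            class = "pit_geometry")
}

#' Assemble a geometry from user-supplied ROI masks
#'
#' @param masks Named list of logical (or 0/1) arrays sharing one shape;
#'   masks must be pairwise disjoint and nonempty.
#' @return A `pit_geometry` object.
#' @export
geometry_from_masks <- function(masks) {
  if (!length(masks) || is.null(names(masks)))
    stop_pitrel("masks must be a named list", class = "pitrel_geometry_error")
  dims <- lapply(masks, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop_pitrel("all masks must share one shape", class = "pitrel_geometry_error")
  masks <- lapply(masks, function(m) array(as.logical(round(m)), dim(m)))
  if (any(!vapply(masks, any, TRUE)))
    stop_pitrel("empty ROI mask supplied", class = "pitrel_geometry_error")
  total <- Reduce(`+`, masks)
  if (any(total > 1L))
    stop_pitrel("ROI masks overlap", class = "pitrel_geometry_error")
  structure(list(dim = dim(masks[[1]]), masks = masks,
                 n_voxels = prod(dim(masks[[1]]))),
            class = "pit_geometry")
}

geometry_summary <- function(geometry) {
  list(dim = geometry$dim,
       rois = lapply(geometry$masks, function(m) sum(m)))
}

roi_voxel_index <- function(geometry) {
  # integer ROI label per voxel (0 = outside all ROIs), linear indexing
  lab <- integer(geometry$n_voxels)
  for (i in seq_along(geometry$masks))
    lab[which(geometry$masks[[i]])] <- i
  lab
}
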