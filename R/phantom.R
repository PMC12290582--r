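# Labelled volumetric phantoms: abstract grids carrying region labels,
# generating-model tags and true response scales for ground-truth scoring.

#' Construct a labelled phantom volume
#'
#' Voxels are assigned to the four subcortical auditory regions (left/right
#' inferior colliculus, left/right medial geniculate body) in linear index
#' order; the remainder of the grid is background. MGB voxels additionally
#' carry a ventral/dorsomedial subdivision tag. Each voxel records the model
#' that generates its signal (`h1`, `h2` or `null`) and its true response
#' scale; background voxels are always `null`.
#'
#' @param grid 3D grid dimensions.
#' @param region_sizes Named integer vector of voxels per region; defaults
#'   are the volume-matched ROI sizes (146 per IC, 152 per MGB).
#' @param generating_model Either a single tag (`"h1"`, `"h2"`, `"null"`)
#'   for all auditory voxels or a named character vector per region.
#' @param scale True per-event response amplitude of auditory voxels
#'   (single value or named per region).
#' @param ventral_fraction Fraction of each MGB assigned to the ventral
#'   subdivision.
#' @return A `phantom`: data frame with one row per voxel (`index`, `x`,
#'   `y`, `z`, `region`, `subdivision`, `model`, `scale`) and attributes
#'   `dim` and `region_sizes`.
#' @export
make_phantom <- function(grid = c(12, 12, 6),
                         region_sizes = c("IC-L" = 146, "IC-R" = 146,
                                          "MGB-L" = 152, "MGB-R" = 152),
                         generating_model = "h2", scale = 1,
                         ventral_fraction = 0.5) {
  n <- prod(grid)
  total <- sum(region_sizes)
  if (total > n) {
    stop("grid of ", n, " voxels cannot hold ", total, " region voxels")
  }
  coords <- arrayInd(seq_len(n), .dim = grid)
  region <- rep("background", n)
  pos <- 1L
  for (r in names(region_sizes)) {
    region[seq(pos, pos + region_sizes[[r]] - 1L)] <- r
    pos <- pos + region_sizes[[r]]
  }
  subdivision <- rep(NA_character_, n)
  for (r in grep("^MGB", names(region_sizes), value = TRUE)) {
    idx <- which(region == r)
    nv <- round(length(idx) * ventral_fraction)
    subdivision[idx] <- "dorsomedial"
    subdivision[idx[seq_len(nv)]] <- "ventral"
  }
  pick <- function(x, r, default) {
    if (length(x) == 1L && is.null(names(x))) x else (x[[r]] %||% default)
  }
  model <- rep("null", n)
  scl <- rep(0, n)
  for (r in names(region_sizes)) {
    idx <- region == r
    model[idx] <- pick(generating_model, r, "null")
    scl[idx] <- pick(scale, r, 0)
  }
  if (!all(model %in% c("h1", "h2", "null"))) {
    stop("generating_model tags must be 'h1', 'h2' or 'null'")
  }
  structure(
    data.frame(index = seq_len(n), x = coords[, 1], y = coords[, 2],
               z = coords[, 3], region = region, subdivision = subdivision,
               model = model, scale = scl),
    dim3 = grid, region_sizes = region_sizes,
    class = c("phantom", "data.frame"))
}

#' Region voxel indices of a phantom
#'
#' @param phantom A [make_phantom()] result.
#' @param regions Region names; defaults to all non-background regions.
#' @return Named list of integer voxel indices.
#' @export
phantom_rois <- function(phantom, regions = NULL) {
  regions <- regions %||% setdiff(unique(phantom$region), "background")
  stats::setNames(lapply(regions, function(r) which(phantom$region == r)),
                  regions)
}

#' Write a per-voxel map (or the phantom labels) as NIfTI
#'
#' @param values Numeric vector with one value per phantom voxel, or `NULL`
#'   to write the integer region labels.
#' @param phantom The [make_phantom()] phantom defining the grid.
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_phantom_map <- function(values = NULL, phantom, path) {
  grid <- attr(phantom, "dim3")
  if (is.null(values)) {
    values <- as.integer(factor(phantom$region,
                                levels = c("background",
                                           names(attr(phantom,
                                                      "region_sizes"))))) - 1L
  }
  stopifnot(length(values) == nrow(phantom))
  img <- array(values, dim = grid)
  RNifti::writeNifti(RNifti::asNifti(img), path)
  invisible(path)
}

#' Read a per-voxel map written by [write_phantom_map()]
#'
#' @param path `.nii` path.
#' @return Numeric vector in phantom linear-index order.
#' @export
read_phantom_map <- function(path) {
  as.vector(RNifti::readNifti(path))
}
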