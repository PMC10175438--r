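#' CT volume container
#'
#' A minimal container for a CT volume in Hounsfield units: a 3D voxel array
#' plus the voxel spacing (mm per axis) and the world position of voxel
#' `[1,1,1]`. The third array axis is taken as the proximal-distal (z)
#' direction, with +z proximal.
#'
#' @param voxels 3D numeric array of Hounsfield units.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, world coordinates (mm) of the first voxel
#'   centre.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (any(dim(voxels) < 2L))
    stop("all three axes must have length >= 2")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @exportS3Method base::print
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = "/"),
      " mm\n", sep = "")
  cat("  HU range: ", paste(format(range(x$voxels)), collapse = " .. "), "\n",
      sep = "")
  invisible(x)
}

#' Threshold a CT volume at a bone Hounsfield level
#'
#' Voxels with HU greater than or equal to `threshold` are marked bone. The
#' default of 226 HU is the preset cortical/trabecular bone threshold commonly
#' used for fracture segmentation.
#'
#' @param volume a [ct_volume()].
#' @param threshold HU threshold; voxels `>= threshold` are included.
#' @return A logical 3D array (with `spacing`/`origin` carried as attributes).
#' @export
segment_bone <- function(volume, threshold = 226) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (length(volume$voxels) == 0L) stop("no voxels")
  mask <- volume$voxels >= threshold
  attr(mask, "spacing") <- volume$spacing
  attr(mask, "origin") <- volume$origin
  mask
}

#' Label bone fragments as connected components
#'
#' Separates a bone mask into independent fragments by connected-component
#' labelling (the non-interactive equivalent of seeded region growing for
#' spatially disjoint fragments). Components are labelled `1..K` by decreasing
#' voxel count; components smaller than `min_voxels` are dropped to
#' background.
#'
#' @param mask logical 3D array, e.g. from [segment_bone()].
#' @param connectivity 6, 18 or 26 (default) voxel neighbourhood.
#' @param min_voxels minimum component size kept, in voxels.
#' @param spacing,origin geometry of the grid; taken from `mask` attributes
#'   when present.
#' @return An object of class `fragment_labels` with elements `labels`
#'   (integer 3D array, 0 = background), `n_fragments`, `spacing`, `origin`.
#' @export
label_fragments <- function(mask, connectivity = 26, min_voxels = 50,
                            spacing = attr(mask, "spacing"),
                            origin = attr(mask, "origin")) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  if (is.null(origin)) origin <- c(0, 0, 0)
  lab <- .cc_label_cpp(as.logical(mask), dim(mask), as.integer(connectivity))
  k <- attr(lab, "n_components")
  if (k > 0 && min_voxels > 1) {
    sizes <- tabulate(lab, nbins = k)
    keep <- which(sizes >= min_voxels)
    remap <- integer(k)
    remap[keep] <- seq_along(keep) # sizes already sorted decreasing
    new_lab <- integer(length(lab))
    nz <- lab != 0L
    new_lab[nz] <- remap[lab[nz]]
    lab <- new_lab
    k <- length(keep)
  }
  labels <- array(as.integer(lab), dim = dim(mask))
  structure(list(labels = labels, n_fragments = as.integer(k),
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "fragment_labels")
}

#' @exportS3Method base::print
print.fragment_labels <- function(x, ...) {
  cat("<fragment_labels> ", x$n_fragments, " fragment(s) on a ",
      paste(dim(x$labels), collapse = " x "), " grid\n", sep = "")
  if (x$n_fragments > 0) {
    sizes <- tabulate(x$labels[x$labels > 0], nbins = x$n_fragments)
    cat("  voxels per fragment:", paste(sizes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Split a fragment along a plane or mask
#'
#' Replaces interactive manual separation: the voxels of one labelled
#' fragment are split into two fragments, either on the two sides of an
#' oriented plane (voxels exactly on the plane go to the positive side) or by
#' an explicit logical mask. The negative/`FALSE` part keeps the original
#' label; the positive/`TRUE` part receives label `K + 1`.
#'
#' @param labels a `fragment_labels` object.
#' @param fragment_id label of the fragment to split.
#' @param cut either `list(point = , normal = )` defining an oriented plane
#'   (mm, world coordinates), or a logical array of the same shape as the
#'   label volume.
#' @return A new `fragment_labels` object with `n_fragments` increased by one.
#' @export
split_fragment <- function(labels, fragment_id, cut) {
  stopifnot(inherits(labels, "fragment_labels"))
  sel <- labels$labels == fragment_id
  if (!any(sel)) stop("fragment id ", fragment_id, " does not exist")
  if (is.list(cut)) {
    n <- .normalize(as.numeric(cut$normal))
    p <- as.numeric(cut$point)
    dm <- dim(labels$labels)
    idx <- which(sel, arr.ind = TRUE)
    w <- sweep(idx - 1, 2, labels$spacing, `*`)
    w <- sweep(w, 2, labels$origin, `+`)
    side <- (w %*% n - sum(p * n)) >= 0
    pos <- logical(length(labels$labels))
    dim(pos) <- dm
    pos[idx[side, , drop = FALSE]] <- TRUE
  } else {
    if (!identical(dim(cut), dim(labels$labels)))
      stop("cut mask shape does not match label volume")
    pos <- cut & sel
  }
  a <- sel & pos
  b <- sel & !pos
  if (!any(a) || !any(b)) stop("cut does not split")
  out <- labels
  out$labels[a] <- labels$n_fragments + 1L
  out$n_fragments <- labels$n_fragments + 1L
  out
}
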