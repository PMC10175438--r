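#' Read a CT volume from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` volume and returns a [ct_volume()]. Voxel values
#' are taken as already rescaled to Hounsfield units (NIfTI stores the
#' rescale in scl_slope/scl_inter, applied by the reader). The third axis is
#' assumed to be the proximal-distal direction.
#'
#' @param path path to a NIfTI file.
#' @return A `ct_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  if (length(dim(vox)) != 3L) stop("expected a 3D volume")
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  spacing <- abs(as.numeric(pd[1:3]))
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  ct_volume(vox, spacing = spacing, origin = origin)
}

#' Write a CT volume or label volume to NIfTI
#'
#' @param x a `ct_volume` or `fragment_labels`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "ct_volume")) {
    arr <- x$voxels; spacing <- x$spacing; origin <- x$origin
  } else if (inherits(x, "fragment_labels")) {
    arr <- x$labels; spacing <- x$spacing; origin <- x$origin
  } else stop("x must be a ct_volume or fragment_labels")
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, spacing)
  mat <- diag(4)
  diag(mat)[1:3] <- spacing
  mat[1:3, 4] <- origin
  img <- RNifti::`sform<-`(img, structure(mat, code = 2L))
  img <- RNifti::`qform<-`(img, structure(mat, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Apply the DICOM linear HU rescale
#'
#' Converts stored values to Hounsfield units via
#' `HU = slope * stored + intercept`.
#'
#' @param stored stored pixel values.
#' @param slope,intercept rescale slope and intercept.
#' @return Hounsfield units.
#' @export
hu_rescale <- function(stored, slope = 1, intercept = -1024) {
  if (!is.finite(slope) || !is.finite(intercept))
    stop("rescale slope/intercept must be finite")
  slope * stored + intercept
}

#' Write a mesh as STL
#'
#' Binary little-endian STL by default; `binary = FALSE` writes ASCII.
#'
#' @param mesh a `fragment_mesh` or `gap_surface`.
#' @param path output path.
#' @param binary write binary STL (default).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  V <- mesh$vertices
  Tm <- mesh$triangles
  a <- V[Tm[, 1], , drop = FALSE]
  u <- V[Tm[, 2], , drop = FALSE] - a
  w <- V[Tm[, 3], , drop = FALSE] - a
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(fn^2)); len[len == 0] <- 1
  fn <- fn / len
  nt <- nrow(Tm)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nt), con, size = 4, endian = "little")
    for (i in seq_len(nt)) {
      writeBin(as.numeric(c(fn[i, ], V[Tm[i, 1], ], V[Tm[i, 2], ],
                            V[Tm[i, 3], ])),
               con, size = 4, endian = "little")
      writeBin(as.integer(0L), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nt)) {
      writeLines(sprintf("facet normal %g %g %g", fn[i, 1], fn[i, 2],
                         fn[i, 3]), con)
      writeLines("  outer loop", con)
      for (k in 1:3)
        writeLines(sprintf("    vertex %g %g %g", V[Tm[i, k], 1],
                           V[Tm[i, k], 2], V[Tm[i, k], 3]), con)
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

#' Write a mesh as PLY (binary little-endian)
#'
#' @param mesh a `fragment_mesh` or `gap_surface`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  V <- mesh$vertices
  Tm <- mesh$triangles
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           sprintf("element vertex %d", nrow(V)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(Tm)),
           "property list uchar int vertex_indices", "end_header")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(as.numeric(t(V)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(Tm))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(Tm[i, ] - 1L), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read / write per-vertex articular annotations
#'
#' CSV format: columns `fragment_id`, `vertex_index` (1-based),
#' `is_articular` (0/1). The JSON variant stores, per fragment id, the
#' vector of flags.
#'
#' @param path file path (`.csv` or `.json`).
#' @return A data frame with the three columns.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lst <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- do.call(rbind, lapply(names(lst), function(id) {
      data.frame(fragment_id = as.integer(id),
                 vertex_index = seq_along(lst[[id]]),
                 is_articular = as.integer(lst[[id]]))
    }))
    return(df)
  }
  df <- read.csv(path)
  stopifnot(all(c("fragment_id", "vertex_index", "is_articular") %in%
                names(df)))
  df
}

#' @rdname read_annotations
#' @param annotations either the data frame or a list of per-vertex logical
#'   vectors named/indexed by fragment id.
#' @export
write_annotations <- function(annotations, path) {
  if (is.list(annotations) && !is.data.frame(annotations)) {
    ids <- names(annotations)
    if (is.null(ids)) ids <- as.character(seq_along(annotations))
    annotations <- do.call(rbind, lapply(seq_along(annotations), function(i) {
      data.frame(fragment_id = as.integer(ids[i]),
                 vertex_index = seq_along(annotations[[i]]),
                 is_articular = as.integer(annotations[[i]]))
    }))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    sp <- split(annotations$is_articular, annotations$fragment_id)
    jsonlite::write_json(sp, path)
  } else {
    write.csv(annotations, path, row.names = FALSE)
  }
  invisible(path)
}

# data frame of annotations -> list of logical vectors, one per mesh
.annotation_list <- function(df, meshes) {
  lapply(meshes, function(m) {
    sub <- df[df$fragment_id == m$id, ]
    flags <- logical(nrow(m$vertices))
    flags[sub$vertex_index] <- sub$is_articular > 0
    flags
  })
}

#' Export polylines as JSON
#'
#' Writes fracture lines or loops as JSON arrays of `[x, y, z]` points (mm).
#'
#' @param lines a `fracture_line_set`, a list of `polyline3d`/`gap_loop`
#'   objects, or a single one.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_polylines_json <- function(lines, path) {
  if (inherits(lines, "fracture_line_set")) lines <- lines$lines
  if (inherits(lines, c("polyline3d", "gap_loop"))) lines <- list(lines)
  out <- lapply(lines, function(pl) unname(pl$points))
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}

#' Read / write a cohort table
#'
#' CSV with columns `id`, `gap_area_mm2`, `age`, `sex`, `smoking`, `bmi`,
#' `inadequate_reduction`, `followup_years`, `tka` (plus any extras such as
#' `prognosis`).
#'
#' @param path file path.
#' @return A data frame of class `cohort`.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "gap_area_mm2", "age", "sex", "smoking", "bmi",
            "inadequate_reduction", "followup_years", "tka")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("cohort file lacks columns: ", paste(miss, collapse = ", "))
  if (any(df$followup_years <= 0)) stop("followup_years must be positive")
  if (any(df$gap_area_mm2 < 0)) stop("gap_area_mm2 must be non-negative")
  class(df) <- c("cohort", "data.frame")
  df
}

#' @rdname read_cohort
#' @param cohort a cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, 10))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
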