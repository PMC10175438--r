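#' Close fracture lines into gap loops
#'
#' The free ends of the fracture lines are connected by straight closure
#' segments so that every line becomes part of a closed loop. Ends are paired
#' greedily, closest pair first; the two ends of a single original line are
#' never paired while other lines remain (a chain assembled from two or more
#' lines may close on itself whenever its ends form the closest pair, so
#' independent fracture systems close into independent loops). Ties are
#' broken by lexicographic endpoint order. Already-closed lines pass through
#' unchanged.
#'
#' @param lines a `fracture_line_set` from [trim_to_fracture_lines()], or a
#'   plain list of `polyline3d` objects.
#' @return A list of `gap_loop` objects: `points` (closed polyline, first
#'   point repeated last) and `provenance` (per segment: the source line
#'   index or `"closure"`).
#' @export
close_loops <- function(lines) {
  if (inherits(lines, "fracture_line_set")) lines <- lines$lines
  loops <- list()
  chains <- list()
  for (i in seq_along(lines)) {
    pl <- lines[[i]]
    if (isTRUE(pl$closed)) {
      pts <- pl$points
      loops[[length(loops) + 1L]] <-
        structure(list(points = pts,
                       provenance = rep(paste0("line-", i), nrow(pts) - 1L)),
                  class = "gap_loop")
    } else {
      p <- pl$points
      chains[[length(chains) + 1L]] <-
        list(points = p, prov = rep(paste0("line-", i), nrow(p) - 1L),
             n_lines = 1L)
    }
  }

  close_chain <- function(ch) {
    p <- ch$points
    prov <- ch$prov
    if (any(p[1, ] != p[nrow(p), ])) {
      p <- rbind(p, p[1, ])
      prov <- c(prov, "closure")
    }
    structure(list(points = p, provenance = prov), class = "gap_loop")
  }

  while (length(chains) > 0) {
    if (length(chains) == 1L) {
      loops[[length(loops) + 1L]] <- close_chain(chains[[1]])
      chains <- list()
      break
    }
    # candidate connections: ends of different chains, plus self-closure of
    # chains already containing more than one original line
    ends <- do.call(rbind, lapply(seq_along(chains), function(i) {
      p <- chains[[i]]$points
      rbind(c(i, 1, p[1, ]), c(i, 2, p[nrow(p), ]))
    }))
    best <- NULL
    for (a in seq_len(nrow(ends) - 1)) {
      for (b in (a + 1):nrow(ends)) {
        ca <- ends[a, 1]; cb <- ends[b, 1]
        if (ca == cb && chains[[ca]]$n_lines < 2L) next
        if (ca == cb && !(ends[a, 2] == 1 && ends[b, 2] == 2)) next
        d <- sqrt(sum((ends[a, 3:5] - ends[b, 3:5])^2))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             .lex_less(c(ends[a, 3:5], ends[b, 3:5]),
                       c(ends[best$a, 3:5], ends[best$b, 3:5])))) {
          best <- list(a = a, b = b, d = d)
        }
      }
    }
    ia <- ends[best$a, 1]; ea <- ends[best$a, 2]
    ib <- ends[best$b, 1]; eb <- ends[best$b, 2]
    if (ia == ib) { # self-closure of a composite chain
      loops[[length(loops) + 1L]] <- close_chain(chains[[ia]])
      chains[[ia]] <- NULL
      next
    }
    A <- chains[[ia]]; B <- chains[[ib]]
    # orient so that the connection runs tail(A) -> head(B)
    if (ea == 1) {
      A$points <- A$points[nrow(A$points):1, , drop = FALSE]
      A$prov <- rev(A$prov)
    }
    if (eb == 2) {
      B$points <- B$points[nrow(B$points):1, , drop = FALSE]
      B$prov <- rev(B$prov)
    }
    merged <- list(points = rbind(A$points, B$points),
                   prov = c(A$prov, "closure", B$prov),
                   n_lines = A$n_lines + B$n_lines)
    chains[[max(ia, ib)]] <- NULL
    chains[[min(ia, ib)]] <- merged
  }
  loops
}

#' Construct the spanning surface of a gap loop
#'
#' The loop's best-fit plane (principal components of its points) defines a
#' 2D projection; the projected simple polygon is triangulated by ear
#' clipping and the triangles are lifted back to the original 3D
#' coordinates, so out-of-plane displacement (step-off) inflates the area
#' exactly as a ruled surface would.
#'
#' @param loop a `gap_loop` from [close_loops()].
#' @return An object of class `gap_surface`: `vertices` (the loop points),
#'   `triangles`, and `area` in mm^2. Degenerate (collinear) loops yield area
#'   0 and no triangles.
#' @export
build_surface <- function(loop) {
  stopifnot(inherits(loop, "gap_loop"))
  P <- loop$points
  P <- P[-nrow(P), , drop = FALSE] # drop duplicated closing point
  dup <- c(FALSE, rowSums(abs(diff(P))) < 1e-12)
  if (sqrt(sum((P[1, ] - P[nrow(P), ])^2)) < 1e-12) dup[nrow(P)] <- TRUE
  P <- P[!dup, , drop = FALSE]
  empty <- structure(list(vertices = P, triangles = matrix(integer(0), 0, 3),
                          area = 0), class = "gap_surface")
  if (nrow(unique(P)) < 3) return(empty)

  # canonicalize the cyclic vertex order with frame-invariant keys (distance
  # from the loop centroid) so that the triangulation -- and hence the area of
  # a non-planar loop -- does not depend on the coordinate frame
  ctr <- colMeans(P)
  dc <- rowSums(sweep(P, 2, ctr)^2)
  i0 <- which.max(dc)
  n <- nrow(P)
  ord <- c(i0:n, seq_len(i0 - 1))
  if (dc[ord[2]] < dc[ord[n]]) ord <- c(ord[1], rev(ord[-1]))
  P <- P[ord, , drop = FALSE]

  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-9)) return(empty) # collinear
  xy <- Pc %*% sv$v[, 1:2]

  if (!.polygon_simple_cpp(xy)) stop("non-simple loop")
  Tm <- .earclip_cpp(xy)
  # ear clipping can leave slivers that are degenerate in the projection but
  # lift to spurious 3D area; Lawson-style diagonal flips minimizing the
  # lifted area converge to the natural ruled triangulation
  Tm <- .flip_min_area(P, xy, Tm)
  area <- sum(.tri_areas(P, Tm))
  structure(list(vertices = P, triangles = Tm, area = area),
            class = "gap_surface")
}

# greedy diagonal flips on a polygon triangulation: flip the shared edge of
# a triangle pair whenever the 2D quad is convex and the flip reduces the
# total 3D (lifted) triangle area
.flip_min_area <- function(P, xy, Tm) {
  if (nrow(Tm) < 2) return(Tm)
  tri_area3 <- function(i1, i2, i3) {
    u <- P[i2, ] - P[i1, ]; w <- P[i3, ] - P[i1, ]
    cx <- u[2] * w[3] - u[3] * w[2]
    cy <- u[3] * w[1] - u[1] * w[3]
    cz <- u[1] * w[2] - u[2] * w[1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  cross2 <- function(o, a, b) {
    (xy[a, 1] - xy[o, 1]) * (xy[b, 2] - xy[o, 2]) -
      (xy[a, 2] - xy[o, 2]) * (xy[b, 1] - xy[o, 1])
  }
  for (pass in seq_len(30)) {
    changed <- FALSE
    # interior edges: appear in exactly two triangles
    ed <- rbind(Tm[, 1:2], Tm[, 2:3], Tm[, c(3, 1)])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    tri_of <- rep(seq_len(nrow(Tm)), 3L)
    sp <- split(tri_of, key)
    sp <- sp[lengths(sp) == 2]
    for (pair in sp) {
      t1 <- pair[1]; t2 <- pair[2]
      shared <- intersect(Tm[t1, ], Tm[t2, ])
      if (length(shared) != 2) next
      a <- shared[1]; b <- shared[2]
      c1 <- setdiff(Tm[t1, ], shared)
      c2 <- setdiff(Tm[t2, ], shared)
      if (length(c1) != 1 || length(c2) != 1 || c1 == c2) next
      # flip validity: c1 and c2 strictly on opposite sides of ab, and a, b
      # strictly on opposite sides of c1c2 (convex quad in the projection)
      s1 <- cross2(a, b, c1); s2 <- cross2(a, b, c2)
      s3 <- cross2(c1, c2, a); s4 <- cross2(c1, c2, b)
      if (s1 * s2 >= 0 || s3 * s4 >= 0) next
      cur <- tri_area3(a, b, c1) + tri_area3(a, b, c2)
      alt <- tri_area3(c1, c2, a) + tri_area3(c1, c2, b)
      if (alt < cur - 1e-10) {
        Tm[t1, ] <- c(c1, c2, a)
        Tm[t2, ] <- c(c1, c2, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  Tm
}

#' @exportS3Method base::print
print.gap_surface <- function(x, ...) {
  cat("<gap_surface> ", nrow(x$triangles), " triangles, area ",
      format(x$area, digits = 6), " mm^2\n", sep = "")
  invisible(x)
}

#' Default parameters of the gap-area measurement
#'
#' @param d_max fracture-line proximity threshold, mm (see
#'   [trim_to_fracture_lines()]).
#' @param facing_tol,w_min facing-test parameters of the trim step.
#' @param smooth_iterations contour regularization passes in the trim step.
#' @param axis proximal axis used by the articular heuristic.
#' @param max_angle,band_frac articular heuristic parameters (degrees,
#'   fraction).
#' @return A named list of parameters.
#' @export
gap_params <- function(d_max = 7.5, facing_tol = 0.02, w_min = 1,
                       smooth_iterations = 10, axis = c(0, 0, 1),
                       max_angle = 45, band_frac = 0.15) {
  list(d_max = d_max, facing_tol = facing_tol, w_min = w_min,
       smooth_iterations = smooth_iterations, axis = axis,
       max_angle = max_angle, band_frac = band_frac)
}

#' Measure the 3D gap area of a set of fragment meshes
#'
#' Composes the full measurement: articular delineation on each fragment
#' (annotation if given, heuristic otherwise), contour extraction, trimming
#' to fracture lines, loop closure and spanning-surface construction. The 3D
#' gap area is the total area of all loop surfaces, in mm^2; it captures both
#' in-plane gaps and out-of-plane step-offs between all fragments at the
#' articular level. A single unfractured fragment yields 0.
#'
#' @param meshes list of `fragment_mesh` objects.
#' @param annotations optional articular annotations: a list parallel to
#'   `meshes` (or named by fragment id) of per-vertex logical vectors.
#' @param params parameter list from [gap_params()].
#' @return An object of class `gap_area_result`: `total_area`, `loop_areas`,
#'   `loops`, `surfaces`, `n_fragments`, `n_fracture_lines`, `params`.
#' @export
measure_gap_area <- function(meshes, annotations = NULL,
                             params = gap_params()) {
  if (inherits(meshes, "fragment_mesh")) meshes <- list(meshes)
  stopifnot(length(meshes) >= 1)

  result0 <- function(nlines) {
    structure(list(total_area = 0, loop_areas = numeric(0), loops = list(),
                   surfaces = list(), n_fragments = length(meshes),
                   n_fracture_lines = nlines, params = params),
              class = "gap_area_result")
  }

  ann_for <- function(i, id) {
    if (is.null(annotations)) return(NULL)
    nm <- names(annotations)
    if (!is.null(nm) && as.character(id) %in% nm)
      return(annotations[[as.character(id)]])
    if (i <= length(annotations)) annotations[[i]] else NULL
  }

  contours <- vector("list", length(meshes))
  for (i in seq_along(meshes)) {
    patch <- delineate_articular(meshes[[i]],
                                 annotation = ann_for(i, meshes[[i]]$id),
                                 axis = params$axis,
                                 max_angle = params$max_angle,
                                 band_frac = params$band_frac)
    contours[[i]] <- extract_contours(patch,
                                      smooth_iterations =
                                        params$smooth_iterations %||% 10)
  }

  if (length(meshes) < 2) return(result0(0L))
  lines <- trim_to_fracture_lines(contours, d_max = params$d_max,
                                  facing_tol = params$facing_tol,
                                  w_min = params$w_min)
  if (length(lines$lines) == 0) return(result0(0L))
  loops <- close_loops(lines)
  surfaces <- lapply(loops, build_surface)
  areas <- vapply(surfaces, `[[`, numeric(1), "area")
  structure(list(total_area = sum(areas), loop_areas = areas, loops = loops,
                 surfaces = surfaces, n_fragments = length(meshes),
                 n_fracture_lines = length(lines$lines), params = params),
            class = "gap_area_result")
}

#' @exportS3Method base::print
print.gap_area_result <- function(x, ...) {
  cat("3D gap area: ", format(x$total_area, digits = 6), " mm^2 over ",
      length(x$loop_areas), " loop(s), ", x$n_fragments, " fragment(s)\n",
      sep = "")
  if (length(x$loop_areas) > 0)
    cat("  per-loop areas (mm^2): ",
        paste(format(x$loop_areas, digits = 5), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
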