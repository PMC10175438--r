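#' 3D polyline
#'
#' Ordered 3D point sequence in mm. Closed polylines repeat the first point
#' as the last.
#'
#' @param points numeric matrix (n x 3).
#' @param closed logical flag.
#' @return An object of class `polyline3d`.
#' @export
polyline3d <- function(points, closed = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L)
    stop("a polyline needs >= 2 points with 3 coordinates")
  dup <- c(FALSE, rowSums(abs(diff(points))) == 0)
  points <- points[!dup, , drop = FALSE]
  if (nrow(points) < 2L) stop("consecutive points must be distinct")
  if (closed && any(points[1, ] != points[nrow(points), ]))
    points <- rbind(points, points[1, ])
  structure(list(points = points, closed = closed), class = "polyline3d")
}

# points without the duplicated closing row
.poly_open_points <- function(pl) {
  p <- pl$points
  if (isTRUE(pl$closed)) p[-nrow(p), , drop = FALSE] else p
}

#' Polyline arc length
#' @param pl a `polyline3d`.
#' @return Length in mm.
#' @export
polyline_length <- function(pl) sum(sqrt(rowSums(diff(pl$points)^2)))

#' Delineate the articular surface on a fragment mesh
#'
#' The faithful route is an explicit per-vertex annotation (the in-silico
#' analogue of manually brushing the articular surface): the patch is the set
#' of triangles whose three vertices are all flagged. Without an annotation a
#' geometric heuristic is used, intended for idealized phantoms: triangles
#' whose outward normal lies within `max_angle` of the proximal axis and
#' whose centroid lies in the top `band_frac` of the fragment's proximal
#' extent. In both cases the largest edge-connected component is returned.
#'
#' @param mesh a `fragment_mesh`.
#' @param annotation optional logical vector, one flag per mesh vertex.
#' @param axis proximal direction (unit vector; default +z).
#' @param max_angle maximal angle (degrees) between triangle normal and
#'   `axis`; default 45.
#' @param band_frac fraction of the proximal extent forming the candidate
#'   band; default 0.15.
#' @return An object of class `articular_patch`: `fragment_id`, `mesh`,
#'   `member` (triangle indices), `normal` (area-weighted mean patch normal).
#' @export
delineate_articular <- function(mesh, annotation = NULL, axis = c(0, 0, 1),
                                max_angle = 45, band_frac = 0.15) {
  stopifnot(inherits(mesh, "fragment_mesh"))
  V <- mesh$vertices
  Tm <- mesh$triangles
  axis <- .normalize(as.numeric(axis))

  if (!is.null(annotation)) {
    annotation <- as.logical(annotation)
    if (length(annotation) != nrow(V))
      stop("annotation length must equal the vertex count")
    member <- which(annotation[Tm[, 1]] & annotation[Tm[, 2]] &
                    annotation[Tm[, 3]])
  } else {
    a <- V[Tm[, 1], , drop = FALSE]
    u <- V[Tm[, 2], , drop = FALSE] - a
    w <- V[Tm[, 3], , drop = FALSE] - a
    fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    len <- sqrt(rowSums(fn^2))
    len[len == 0] <- 1
    cosang <- (fn %*% axis) / len
    proj <- V %*% axis
    centroid_proj <- (proj[Tm[, 1]] + proj[Tm[, 2]] + proj[Tm[, 3]]) / 3
    top <- max(proj)
    band <- top - band_frac * (top - min(proj))
    member <- which(cosang >= cos(max_angle * pi / 180) &
                    centroid_proj >= band)
  }
  if (length(member) == 0L) stop("no articular surface found")
  member <- .largest_edge_component(Tm, member)

  # area-weighted mean outward normal over the patch
  sub <- Tm[member, , drop = FALSE]
  a <- V[sub[, 1], , drop = FALSE]
  u <- V[sub[, 2], , drop = FALSE] - a
  w <- V[sub[, 3], , drop = FALSE] - a
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  normal <- .normalize(colSums(fn))

  structure(list(fragment_id = mesh$id, mesh = mesh, member = member,
                 normal = normal),
            class = "articular_patch")
}

#' Surface area of an articular patch
#' @param patch an `articular_patch`.
#' @return Area in mm^2.
#' @export
patch_area <- function(patch) {
  sum(.tri_areas(patch$mesh$vertices,
                 patch$mesh$triangles[patch$member, , drop = FALSE]))
}

# largest edge-connected component of a triangle subset (union-find)
.largest_edge_component <- function(Tm, member) {
  m <- length(member)
  if (m <= 1) return(member)
  sub <- Tm[member, , drop = FALSE]
  nv <- max(Tm)
  ekey <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
  keys <- c(ekey(sub[, 1], sub[, 2]), ekey(sub[, 2], sub[, 3]),
            ekey(sub[, 3], sub[, 1]))
  tri_of <- rep(seq_len(m), 3L)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  sp <- split(tri_of, keys)
  for (grp in sp) {
    if (length(grp) > 1) {
      r <- find(grp[1])
      for (g in grp[-1]) {
        r2 <- find(g)
        if (r2 != r) parent[r2] <- r
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  comp <- split(seq_len(m), roots)
  sizes <- lengths(comp)
  member[comp[[which.max(sizes)]]]
}

#' Extract the boundary contours of an articular patch
#'
#' Boundary edges (edges belonging to exactly one member triangle) are
#' chained into maximal polylines. For patches cut from a closed surface the
#' result is a set of closed loops. Chaining is deterministic: each loop
#' starts at its lexicographically smallest point and proceeds toward the
#' lexicographically smaller neighbour (smaller vertex index on ties).
#'
#' Because a triangle-subset boundary zigzags at the mesh-edge scale, the
#' chained polyline is regularized by `smooth_iterations` Laplacian passes
#' (cyclic for loops, endpoint-preserving otherwise); the result is the
#' geometric contour estimate, as an interactively drawn contour would be
#' smooth. Set `smooth_iterations = 0` for the raw boundary.
#'
#' @param patch an `articular_patch`.
#' @param smooth_iterations Laplacian regularization passes; default 10.
#' @return A list of `polyline3d` objects; each carries the fragment id, the
#'   patch normal and per-edge interior reference points as attributes.
#' @export
extract_contours <- function(patch, smooth_iterations = 10) {
  stopifnot(inherits(patch, "articular_patch"))
  if (length(patch$member) == 0L) stop("empty patch")
  V <- patch$mesh$vertices
  Tm <- patch$mesh$triangles[patch$member, , drop = FALSE]
  nv <- max(patch$mesh$triangles)

  e <- rbind(Tm[, 1:2], Tm[, 2:3], Tm[, c(3, 1)])
  tri_of <- rep(seq_len(nrow(Tm)), 3L)
  key <- pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2])
  cnt <- table(key)
  over <- names(cnt)[cnt > 2]
  if (length(over) > 0) {
    k <- as.numeric(over[1])
    stop(sprintf("non-manifold boundary edge between vertices %d and %d",
                 k %/% (nv + 1), k %% (nv + 1)))
  }
  bidx <- which(key %in% as.numeric(names(cnt)[cnt == 1]))
  if (length(bidx) == 0L) return(list()) # closed surface: no boundary
  be <- e[bidx, , drop = FALSE]
  btri <- tri_of[bidx]

  # incidence: vertex -> rows of be
  inc <- split(rep(seq_len(nrow(be)), 2L), factor(c(be[, 1], be[, 2])))
  inc_v <- as.integer(names(inc))
  used <- logical(nrow(be))
  get_inc <- function(v) {
    p <- match(v, inc_v)
    if (is.na(p)) integer(0) else inc[[p]]
  }

  lex_smallest_vertex <- function(vs) {
    pts <- V[vs, , drop = FALSE]
    o <- .lex_order(cbind(pts, vs))
    vs[o[1]]
  }

  contours <- list()
  repeat {
    rem <- which(!used)
    if (length(rem) == 0) break
    verts_rem <- unique(c(be[rem, 1], be[rem, 2]))
    start <- lex_smallest_vertex(verts_rem)
    # first step: toward lexicographically smaller neighbour
    cand_edges <- get_inc(start)
    cand_edges <- cand_edges[!used[cand_edges]]
    others <- ifelse(be[cand_edges, 1] == start, be[cand_edges, 2],
                     be[cand_edges, 1])
    o <- .lex_order(cbind(V[others, , drop = FALSE], others))
    eidx <- cand_edges[o[1]]
    path <- c(start, others[o[1]])
    edge_seq <- eidx
    used[eidx] <- TRUE
    closed <- FALSE
    repeat {
      v <- path[length(path)]
      nxt <- get_inc(v)
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      others2 <- ifelse(be[nxt, 1] == v, be[nxt, 2], be[nxt, 1])
      o2 <- .lex_order(cbind(V[others2, , drop = FALSE], others2))
      eidx2 <- nxt[o2[1]]
      used[eidx2] <- TRUE
      edge_seq <- c(edge_seq, eidx2)
      nv2 <- others2[o2[1]]
      if (nv2 == start) { closed <- TRUE; break }
      path <- c(path, nv2)
    }
    pl <- polyline3d(V[path, , drop = FALSE], closed = closed)
    attr(pl, "fragment_id") <- patch$fragment_id
    attr(pl, "normal") <- patch$normal
    # centroid of the member triangle adjacent to each traversed edge;
    # used to orient the outward direction of the contour
    tris <- patch$mesh$triangles[patch$member[btri[edge_seq]], ,
                                 drop = FALSE]
    attr(pl, "edge_interior") <-
      (V[tris[, 1], , drop = FALSE] + V[tris[, 2], , drop = FALSE] +
       V[tris[, 3], , drop = FALSE]) / 3
    if (smooth_iterations > 0)
      pl <- .smooth_contour(pl, iterations = smooth_iterations)
    contours[[length(contours) + 1L]] <- pl
  }
  contours
}

#' Trim articular contours down to fracture lines
#'
#' Classifies every contour point as *fracture* (facing another fragment) or
#' *rim* (the free plateau border) and keeps the maximal fracture runs as
#' open polylines. A point is marked fracture when (1) it lies within `d_max`
#' of a contour of a different fragment and (2) that nearest opposing point
#' lies on the outward side of the contour -- assessed on the component of the
#' offset within the articular plane, so that pure step-offs (offset
#' perpendicular to the plane) always qualify. The facing condition prevents
#' peripheral rim arcs near the fracture-line ends from being swept in by
#' proximity alone.
#'
#' @param contours named list: one entry per fragment, each a list of
#'   `polyline3d` contours from [extract_contours()]. A list of
#'   `articular_patch` objects is also accepted.
#' @param d_max proximity threshold in mm; default 7.5.
#' @param facing_tol tolerance on the facing cosine (points are kept while
#'   the outward cosine exceeds `-facing_tol`); default 0.02.
#' @param w_min in-plane offset (mm) below which the opposing contour is
#'   considered directly above/below and facing is not tested; default 1.
#' @param smooth_iterations additional contour regularization passes applied
#'   before classification (default 0: contours from [extract_contours()]
#'   arrive already regularized).
#' @return An object of class `fracture_line_set`: `lines` (open fracture
#'   `polyline3d`s with fragment ids), `rim` (discarded rim runs), and the
#'   parameters used.
#' @export
trim_to_fracture_lines <- function(contours, d_max = 7.5, facing_tol = 0.02,
                                   w_min = 1, smooth_iterations = 0) {
  if (d_max <= 0) stop("d_max must be positive")
  if (length(contours) > 0 && inherits(contours[[1]], "articular_patch"))
    contours <- lapply(contours, extract_contours)
  if (smooth_iterations > 0)
    contours <- lapply(contours, function(pls)
      lapply(pls, .smooth_contour, iterations = smooth_iterations))

  out <- structure(list(lines = list(), rim = list(),
                        params = list(d_max = d_max, facing_tol = facing_tol,
                                      w_min = w_min,
                                      smooth_iterations = smooth_iterations)),
                   class = "fracture_line_set")
  nfrag <- length(contours)
  if (nfrag < 2) return(out)

  seg_of <- function(pls) {
    A <- NULL; B <- NULL
    for (pl in pls) {
      p <- pl$points
      A <- rbind(A, p[-nrow(p), , drop = FALSE])
      B <- rbind(B, p[-1, , drop = FALSE])
    }
    list(A = A, B = B)
  }
  segs <- lapply(contours, seg_of)

  for (f in seq_len(nfrag)) {
    otherA <- do.call(rbind, lapply(segs[-f], `[[`, "A"))
    otherB <- do.call(rbind, lapply(segs[-f], `[[`, "B"))
    if (is.null(otherA) || nrow(otherA) == 0) next
    for (pl in contours[[f]]) {
      P <- .poly_open_points(pl)
      m <- nrow(P)
      if (m < 2) next
      dn <- .point_segments_dist_cpp(P, otherA, otherB)
      nrm <- attr(pl, "normal")

      # outward in-plane direction at each point
      if (isTRUE(pl$closed)) {
        nxt <- c(2:m, 1); prv <- c(m, 1:(m - 1))
      } else {
        nxt <- c(2:m, m); prv <- c(1, 1:(m - 1))
      }
      tg <- P[nxt, , drop = FALSE] - P[prv, , drop = FALSE]
      u <- cbind(tg[, 2] * nrm[3] - tg[, 3] * nrm[2],
                 tg[, 3] * nrm[1] - tg[, 1] * nrm[3],
                 tg[, 1] * nrm[2] - tg[, 2] * nrm[1])
      ul <- sqrt(rowSums(u^2)); ul[ul == 0] <- 1
      u <- u / ul
      # fix the sign once per contour: outward points away from the patch
      # interior, aggregated over all boundary edges (robust against local
      # surface orientation)
      ei <- attr(pl, "edge_interior")
      s_ref <- if (!is.null(ei) && nrow(ei) >= m - 1L) {
        ne <- min(m - !isTRUE(pl$closed), nrow(ei))
        e2 <- c(seq_len(m)[-1], 1)[seq_len(ne)]
        mids <- (P[seq_len(ne), , drop = FALSE] + P[e2, , drop = FALSE]) / 2
        te <- P[e2, , drop = FALSE] - P[seq_len(ne), , drop = FALSE]
        ue <- cbind(te[, 2] * nrm[3] - te[, 3] * nrm[2],
                    te[, 3] * nrm[1] - te[, 1] * nrm[3],
                    te[, 1] * nrm[2] - te[, 2] * nrm[1])
        sum(ue * (mids - ei[seq_len(ne), , drop = FALSE]))
      } else {
        ctr_pt <- colMeans(P)
        sum(u * sweep(P, 2, ctr_pt))
      }
      if (s_ref < 0) u <- -u

      qp <- dn$nearest - P
      w <- qp - outer(as.numeric(qp %*% nrm), nrm)
      wn <- sqrt(rowSums(w^2))
      tl <- sqrt(rowSums(tg^2)); tl[tl == 0] <- 1
      th <- tg / tl
      facing <- wn < w_min
      nz <- !facing & wn > 0
      # the opposing contour must lie on the outward side and across the
      # contour, not along its own continuation (grazing approaches at the
      # rim are not fracture)
      out_cos <- rowSums(u[nz, , drop = FALSE] * w[nz, , drop = FALSE]) /
        wn[nz]
      tan_cos <- abs(rowSums(th[nz, , drop = FALSE] *
                             w[nz, , drop = FALSE])) / wn[nz]
      facing[nz] <- out_cos >= -facing_tol & tan_cos <= 0.9
      frac <- dn$dist <= d_max & facing

      runs <- .circular_runs(frac, circular = isTRUE(pl$closed))
      for (r in runs$true) {
        if (length(r) < 2) next
        line <- polyline3d(P[r, , drop = FALSE],
                           closed = length(r) == m && isTRUE(pl$closed))
        attr(line, "fragment_id") <- attr(pl, "fragment_id")
        out$lines[[length(out$lines) + 1L]] <- line
      }
      for (r in runs$false) {
        if (length(r) < 2) next
        riml <- polyline3d(P[r, , drop = FALSE],
                           closed = length(r) == m && isTRUE(pl$closed))
        attr(riml, "fragment_id") <- attr(pl, "fragment_id")
        out$rim[[length(out$rim) + 1L]] <- riml
      }
    }
  }
  out
}

# cyclic (closed) or endpoint-preserving (open) Laplacian smoothing of a
# contour polyline; removes voxel-lattice zigzag without moving straight
# segments
.smooth_contour <- function(pl, iterations = 10, lambda = 0.5) {
  P <- .poly_open_points(pl)
  m <- nrow(P)
  if (m < 3) return(pl)
  for (i in seq_len(iterations)) {
    if (isTRUE(pl$closed)) {
      nxt <- c(2:m, 1); prv <- c(m, 1:(m - 1))
      P <- P + lambda * ((P[nxt, , drop = FALSE] +
                          P[prv, , drop = FALSE]) / 2 - P)
    } else {
      mid <- 2:(m - 1)
      P[mid, ] <- P[mid, ] + lambda *
        ((P[mid - 1, , drop = FALSE] + P[mid + 1, , drop = FALSE]) / 2 -
         P[mid, , drop = FALSE])
    }
  }
  pts <- if (isTRUE(pl$closed)) rbind(P, P[1, ]) else P
  out <- structure(list(points = pts, closed = isTRUE(pl$closed)),
                   class = "polyline3d")
  for (a in c("fragment_id", "normal", "edge_interior"))
    attr(out, a) <- attr(pl, a)
  out
}

# maximal runs of TRUE (and FALSE) indices, optionally merging across the
# wrap-around of a circular sequence
.circular_runs <- function(flag, circular = TRUE) {
  m <- length(flag)
  if (all(flag)) return(list(true = list(seq_len(m)), false = list()))
  if (!any(flag)) return(list(true = list(), false = list(seq_len(m))))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- lapply(seq_along(r$values), function(i) starts[i]:ends[i])
  vals <- r$values
  if (circular && length(vals) > 1 && vals[1] == vals[length(vals)]) {
    idx[[1]] <- c(idx[[length(idx)]], idx[[1]])
    idx[[length(idx)]] <- NULL
    vals <- vals[-length(vals)]
  }
  list(true = idx[vals], false = idx[!vals])
}

#' @exportS3Method base::print
print.fracture_line_set <- function(x, ...) {
  cat("<fracture_line_set> ", length(x$lines), " fracture line(s), ",
      length(x$rim), " rim run(s) (d_max = ", x$params$d_max, " mm)\n",
      sep = "")
  invisible(x)
}
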