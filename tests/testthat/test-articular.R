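test_that("the articular heuristic finds the top disc of a cylinder", {
  ph <- small_phantom(0, 0) # unfractured cylinder r = 15
  m <- ph$meshes[[1]]
  patch <- delineate_articular(m) # heuristic path
  expect_s3_class(patch, "articular_patch")
  expect_lt(abs(patch_area(patch) - pi * 15^2) / (pi * 15^2), 0.05)
})

test_that("annotations define the patch directly", {
  ph <- small_phantom(0, 0)
  m <- ph$meshes[[1]]
  # whole mesh flagged: patch is the closed surface, no boundary contours
  all_on <- rep(TRUE, nrow(m$vertices))
  patch <- delineate_articular(m, annotation = all_on)
  expect_identical(length(patch$member), nrow(m$triangles))
  expect_length(extract_contours(patch), 0L)

  expect_error(delineate_articular(m, annotation = rep(FALSE, nrow(m$vertices))),
               "no articular surface found")
  expect_error(delineate_articular(m, annotation = TRUE),
               "annotation length")
})

test_that("the top-disc contour is a single loop of length about 2*pi*r", {
  ph <- small_phantom(0, 0)
  patch <- delineate_articular(ph$meshes[[1]],
                               annotation = ph$annotations[[1]])
  ctr <- extract_contours(patch)
  expect_length(ctr, 1L)
  expect_true(ctr[[1]]$closed)
  expect_lt(abs(polyline_length(ctr[[1]]) - 2 * pi * 15) / (2 * pi * 15),
            0.05)
})

test_that("a half-disc patch has boundary length about pi*r + 2r", {
  ph <- small_phantom(0, 0)
  m <- ph$meshes[[1]]
  # flag the annotated top band, restricted to the x <= 0 half
  ann <- ph$annotations[[1]] & m$vertices[, 1] <= 0
  patch <- delineate_articular(m, annotation = ann)
  ctr <- extract_contours(patch)
  expect_length(ctr, 1L)
  len <- polyline_length(ctr[[1]])
  expect_lt(abs(len - (pi * 15 + 2 * 15)) / (pi * 15 + 2 * 15), 0.06)
})

test_that("polyline invariants hold", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  pl <- polyline3d(p, closed = TRUE)
  expect_true(all(pl$points[1, ] == pl$points[nrow(pl$points), ]))
  expect_error(polyline3d(p[1, , drop = FALSE]), ">= 2 points")
  # consecutive duplicates are collapsed
  pl2 <- polyline3d(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_identical(nrow(pl2$points), 2L)
})

test_that("trim classifies fracture versus rim and is symmetric", {
  ph <- small_phantom(3, 0)
  patches <- lapply(seq_along(ph$meshes), function(i)
    delineate_articular(ph$meshes[[i]], annotation = ph$annotations[[i]]))
  contours <- lapply(patches, extract_contours)
  fl <- trim_to_fracture_lines(contours)
  expect_s3_class(fl, "fracture_line_set")
  # one fracture line per fragment, each about the cut chord (2r = 30)
  expect_length(fl$lines, 2L)
  ids <- vapply(fl$lines, attr, numeric(1), "fragment_id")
  expect_setequal(ids, c(1, 2))
  for (l in fl$lines)
    expect_lt(abs(polyline_length(l) - 30) / 30, 0.1)
  # rim runs carry the remaining contour; lengths roughly partition
  total_contour <- sum(vapply(unlist(contours, recursive = FALSE),
                              polyline_length, numeric(1)))
  total_lines <- sum(vapply(fl$lines, polyline_length, numeric(1))) +
    sum(vapply(fl$rim, polyline_length, numeric(1)))
  expect_lt(abs(total_lines - total_contour) / total_contour, 0.05)
})

test_that("a single fragment yields an empty fracture line set", {
  ph <- small_phantom(0, 0)
  patch <- delineate_articular(ph$meshes[[1]],
                               annotation = ph$annotations[[1]])
  fl <- trim_to_fracture_lines(list(extract_contours(patch)))
  expect_length(fl$lines, 0L)
  expect_error(trim_to_fracture_lines(list(), d_max = 0), "d_max")
  expect_error(trim_to_fracture_lines(list(), d_max = -1), "d_max")
})

test_that("trim classification is invariant under rigid motion", {
  ph <- small_phantom(2, 1)
  RM <- random_rotation(11)
  tr <- c(5, -3, 9)
  base <- lapply(seq_along(ph$meshes), function(i)
    extract_contours(delineate_articular(ph$meshes[[i]],
                                         annotation = ph$annotations[[i]])))
  moved <- lapply(seq_along(ph$meshes), function(i) {
    m2 <- transform_mesh(ph$meshes[[i]], rotation = RM, translation = tr)
    extract_contours(delineate_articular(m2,
                                         annotation = ph$annotations[[i]]))
  })
  fl0 <- trim_to_fracture_lines(base)
  fl1 <- trim_to_fracture_lines(moved)
  expect_identical(length(fl0$lines), length(fl1$lines))
  l0 <- sort(vapply(fl0$lines, polyline_length, numeric(1)))
  l1 <- sort(vapply(fl1$lines, polyline_length, numeric(1)))
  expect_equal(l0, l1, tolerance = 1e-8)
})
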