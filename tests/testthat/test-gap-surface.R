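# helper: an open polyline with a fragment id
line3 <- function(pts, id = 1) {
  pl <- polyline3d(pts)
  attr(pl, "fragment_id") <- id
  pl
}

crossprod_area <- function(u, w) {
  sqrt(sum(c(u[2] * w[3] - u[3] * w[2],
             u[3] * w[1] - u[1] * w[3],
             u[1] * w[2] - u[2] * w[1])^2))
}

test_that("two parallel lines close into one quadrilateral loop", {
  l1 <- line3(cbind(0, seq(0, 20, by = 1), 0), id = 1)
  l2 <- line3(cbind(3, seq(20, 0, by = -1), 0), id = 2)
  loops <- close_loops(list(l1, l2))
  expect_length(loops, 1L)
  prov <- loops[[1]]$provenance
  expect_identical(sum(prov == "closure"), 2L)
  # both closure segments have length equal to the offset
  P <- loops[[1]]$points
  seg_len <- sqrt(rowSums((P[-1, ] - P[-nrow(P), ])^2))
  expect_equal(unname(seg_len[prov == "closure"]), c(3, 3), tolerance = 1e-12)
})

test_that("an already-closed loop passes through unchanged", {
  sq <- polyline3d(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0)),
                   closed = TRUE)
  loops <- close_loops(list(sq))
  expect_length(loops, 1L)
  expect_equal(loops[[1]]$points, sq$points)
  expect_false("closure" %in% loops[[1]]$provenance)
})

test_that("a single open line is closed on itself", {
  arc <- line3(cbind(cos(seq(0, pi, length.out = 20)),
                     sin(seq(0, pi, length.out = 20)), 0))
  loops <- close_loops(list(arc))
  expect_length(loops, 1L)
  expect_identical(sum(loops[[1]]$provenance == "closure"), 1L)
})

test_that("independent fracture systems close into independent loops", {
  # two separate cuts, far apart: each pair must close on its own
  a1 <- line3(cbind(0, seq(0, 20, by = 1), 0), id = 1)
  a2 <- line3(cbind(2, seq(0, 20, by = 1), 0), id = 2)
  b1 <- line3(cbind(100, seq(0, 20, by = 1), 0), id = 2)
  b2 <- line3(cbind(102, seq(0, 20, by = 1), 0), id = 3)
  loops <- close_loops(list(a1, a2, b1, b2))
  expect_length(loops, 2L)
  areas <- vapply(loops, function(l) build_surface(l)$area, numeric(1))
  expect_equal(sort(areas), c(40, 40), tolerance = 1e-9)
})

test_that("a planar square loop has its analytic area", {
  sq <- structure(list(points = rbind(c(0, 0, 5), c(10, 0, 5), c(10, 10, 5),
                                      c(0, 10, 5), c(0, 0, 5)),
                       provenance = rep("line-1", 4)),
                  class = "gap_loop")
  s <- build_surface(sq)
  expect_equal(s$area, 100, tolerance = 1e-12)
  expect_gt(nrow(s$triangles), 0)
})

test_that("the ruled quadrilateral area follows L * sqrt(g^2 + s^2)", {
  # combined-displacement oracle over a grid: for two straight parallel
  # lines the spanning surface is planar and the area is exactly the line
  # length times the displacement magnitude
  L <- 30
  for (g in 0:5) for (s in 0:5) {
    if (g == 0 && s == 0) next
    l1 <- line3(cbind(0, seq(0, L, by = 0.5), 0), id = 1)
    l2 <- line3(cbind(g, seq(L, 0, by = -0.5), -s), id = 2)
    loops <- close_loops(list(l1, l2))
    a <- build_surface(loops[[1]])$area
    expect_equal(a, L * sqrt(g^2 + s^2), tolerance = 1e-6)
  }
})

test_that("ruled-surface area matches a brute-force fine triangulation", {
  # independent oracle: Riemann sum over the ruled surface
  # r(t, v) = (1-v) * A(t) + v * B(t) with dense sampling
  set.seed(4)
  tt <- seq(0, 30, by = 0.25)
  A <- cbind(0.3 * sin(tt / 5), tt, 0.2 * cos(tt / 7)) # gently curved rails
  B <- cbind(3 + 0.3 * sin(tt / 5), tt, -4 + 0.2 * cos(tt / 7))
  brute <- 0
  nv <- 200
  for (i in seq_len(length(tt) - 1)) {
    for (j in seq_len(nv)) {
      v0 <- (j - 1) / nv; v1 <- j / nv
      p00 <- (1 - v0) * A[i, ] + v0 * B[i, ]
      p01 <- (1 - v1) * A[i, ] + v1 * B[i, ]
      p10 <- (1 - v0) * A[i + 1, ] + v0 * B[i + 1, ]
      p11 <- (1 - v1) * A[i + 1, ] + v1 * B[i + 1, ]
      c1 <- crossprod_area(p10 - p00, p01 - p00)
      c2 <- crossprod_area(p10 - p11, p01 - p11)
      brute <- brute + c1 / 2 + c2 / 2
    }
  }
  l1 <- line3(A, id = 1)
  l2 <- line3(B[rev(seq_len(nrow(B))), ], id = 2)
  a <- build_surface(close_loops(list(l1, l2))[[1]])$area
  # the rails are parallel curves offset by (3, 0, -4): the ruled surface is
  # planar strip-like; measured and brute-force agree closely
  expect_lt(abs(a - brute) / brute, 0.01)
})

test_that("degenerate loops give zero area and bad loops error", {
  collinear <- structure(list(points = rbind(c(0, 0, 0), c(1, 0, 0),
                                             c(2, 0, 0), c(0, 0, 0)),
                              provenance = rep("line-1", 3)),
                         class = "gap_loop")
  expect_identical(build_surface(collinear)$area, 0)

  bowtie <- structure(list(points = rbind(c(0, 0, 0), c(10, 10, 0),
                                          c(10, 0, 0), c(0, 10, 0),
                                          c(0, 0, 0)),
                           provenance = rep("line-1", 4)),
                      class = "gap_loop")
  expect_error(build_surface(bowtie), "non-simple loop")
})

test_that("measure_gap_area composes the pipeline and handles no fracture", {
  ph1 <- small_phantom(0, 0)
  r0 <- measure_gap_area(ph1$meshes, annotations = ph1$annotations)
  expect_identical(r0$total_area, 0)
  expect_identical(length(r0$loop_areas), 0L)

  ph <- small_phantom(3, 4)
  res <- measure_gap_area(ph$meshes, annotations = ph$annotations)
  expect_lt(abs(res$total_area - ph$truth$total_area) / ph$truth$total_area,
            0.1)
  expect_identical(res$n_fragments, 2L)
  expect_equal(sum(res$loop_areas), res$total_area)
})

test_that("gap area is strictly increasing in the gap at fixed cut", {
  areas <- vapply(1:4, function(g) {
    ph <- small_phantom(g, 0)
    measure_gap_area(ph$meshes, annotations = ph$annotations)$total_area
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
  # analytic slope is the cut chord length (2r = 30 mm per mm of gap)
  expect_lt(max(abs(diff(areas) - 30)) / 30, 0.1)
})
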