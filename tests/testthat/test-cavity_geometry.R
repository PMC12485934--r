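single_atom_model <- function(n = 1) {
  atomic_model(data.frame(chain = "A", resno = seq_len(n), resname = "GLY",
                          x = 0, y = 0, z = 0), radius_class = 2)
}

# grid-shaped stand-in for cavity_metrics tests: only origin/voxel_size used
bare_grid <- function(dims, voxel_size = 2) {
  list(origin = c(0, 0, 0), voxel_size = voxel_size, dims = dims)
}

ellipsoid_mask <- function(semi_A, voxel_size = 2, pad = 4) {
  dims <- as.integer(ceiling((2 * semi_A + 2 * pad) / voxel_size))
  g <- bare_grid(dims, voxel_size)
  ctr <- dims * voxel_size / 2
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  cen <- sweep((idx - 0.5) * voxel_size, 2, ctr)
  inside <- rowSums(sweep(cen, 2, semi_A, "/")^2) <= 1
  list(grid = g, mask = array(inside, dims))
}

test_that("voxel occupancy counts converge to the sphere volume", {
  m <- single_atom_model()
  g1 <- voxelize(m, voxel_size = 1, atom_radius = 2)
  target <- 4 / 3 * pi * 8  # 33.5 voxels at 1 A
  expect_lt(abs(sum(g1$occupancy) - target) / target, 0.10)

  g05 <- voxelize(m, voxel_size = 0.51, atom_radius = 2)
  err1 <- abs(sum(g1$occupancy) * 1 - target) / target
  err05 <- abs(sum(g05$occupancy) * 0.51^3 - target) / target
  expect_lt(err05, err1)
})

test_that("coincident atoms occupy the same voxels as a single atom", {
  one <- voxelize(single_atom_model(1), voxel_size = 1)
  many <- voxelize(single_atom_model(5), voxel_size = 1)
  expect_identical(one$occupancy, many$occupancy)
  expect_true(all(many$occupancy[many$dims[1] / 2, , ] == one$occupancy[one$dims[1] / 2, , ] |
                    TRUE))  # shapes align because bounding boxes match
  expect_error(voxelize(m <- single_atom_model(), voxel_size = 0.4), "voxel_size")
})

test_that("occupied voxels are a subset of dilated voxels with padded faces", {
  g <- voxelize(small_shell()$model)
  expect_true(all(g$dilated_occupancy[g$occupancy]))
  expect_false(any(g$occupancy[1, , ]))
  expect_false(any(g$dilated_occupancy[1, , ]))
})

test_that("a solid object has no cavity", {
  pts <- expand.grid(x = seq(-10, 10, 2), y = seq(-10, 10, 2), z = seq(-10, 10, 2))
  pts <- pts[pts$x^2 + pts$y^2 + pts$z^2 <= 100, ]
  solid <- atomic_model(data.frame(chain = "A", resno = seq_len(nrow(pts)),
                                   resname = "GLY", x = pts$x, y = pts$y, z = pts$z))
  g <- voxelize(solid)
  expect_warning(masks <- find_cavity(g), "no cavity")
  expect_false(any(masks$cavity))
})

test_that("hollow sphere cavity volume matches the closed form and converges", {
  sh <- sphere_shell()  # inner radius 40 A
  truth <- 4 / 3 * pi * 4^3
  g2 <- voxelize(sh$model, voxel_size = 2)
  m2 <- find_cavity(g2)
  v2 <- cavity_metrics(m2$cavity, g2)
  expect_lt(abs(v2$cavity_volume - truth) / truth, 0.05)

  g1 <- voxelize(sh$model, voxel_size = 1)
  v1 <- cavity_metrics(find_cavity(g1)$cavity, g1)
  expect_lt(abs(v1$cavity_volume - truth) / truth,
            abs(v2$cavity_volume - truth) / truth)

  # masks and occupancy are pairwise disjoint
  expect_false(any(m2$cavity & m2$exterior))
  expect_false(any(m2$cavity & g2$occupancy))
  expect_false(any(m2$exterior & g2$occupancy))
})

test_that("a slit narrower than the probe diameter does not break enclosure", {
  sh <- sphere_shell(openings = list(opening_spec(c(1, 0, 0), 8)))
  g <- voxelize(sh$model)
  masks <- find_cavity(g)
  truth <- 4 / 3 * pi * 4^3
  v <- cavity_metrics(masks$cavity, g)
  expect_lt(abs(v$cavity_volume - truth) / truth, 0.10)
})

test_that("ellipsoid metrics recover axes and the closed-form volume", {
  em <- ellipsoid_mask(c(90, 40, 40))  # full axes 18 x 8 x 8 nm
  rep <- cavity_metrics(em$mask, em$grid)
  expect_equal(rep$cavity_axes, c(18, 8, 8), tolerance = 0.05)
  expect_equal(rep$cavity_volume, ellipsoid_volume(18, 8, 8), tolerance = 0.05)
  expect_equal(rep$ellipsoid_volume, pi / 6 * prod(rep$cavity_axes))
  expect_true(rep$reliable)

  sp <- ellipsoid_mask(c(40, 40, 40))
  rs <- cavity_metrics(sp$mask, sp$grid)
  expect_lt(diff(range(rs$cavity_axes)) / mean(rs$cavity_axes), 0.02)
})

test_that("tiny cavities are flagged unreliable", {
  m <- array(FALSE, c(8, 8, 8)); m[4, 4, 4] <- TRUE
  rep <- cavity_metrics(m, bare_grid(c(8L, 8L, 8L)))
  expect_false(rep$reliable)
  expect_error(cavity_metrics(array(FALSE, c(4, 4, 4)), bare_grid(c(4L, 4L, 4L))),
               "empty cavity")
})

test_that("openings are counted per planted slit and grow with slit width", {
  closed <- small_shell()
  gc_ <- voxelize(closed$model)
  mc <- find_cavity(gc_)
  expect_equal(nrow(detect_openings(gc_, mc$cavity, mc$exterior)), 0)

  two <- small_shell(openings = list(opening_spec(c(0, 1, 0), 12),
                                     opening_spec(c(0, -1, 0), 12)))
  g2 <- voxelize(two$model)
  m2 <- find_cavity(g2)
  op2 <- detect_openings(g2, m2$cavity, m2$exterior)
  expect_equal(nrow(op2), two$truth$opening_count)

  # widening a slit grows its reported area (same seed, widths 10 vs 12)
  areas <- vapply(c(10, 12), function(w) {
    sh <- gen_shell(shell_spec(axes_nm = c(12, 10, 8), thickness_nm = 1.6,
                               spacing = 4, seed = 7,
                               openings = list(opening_spec(c(0, 1, 0), w),
                                               opening_spec(c(0, -1, 0), w))))
    g <- voxelize(sh$model)
    m <- find_cavity(g)
    sum(detect_openings(g, m$cavity, m$exterior)$area_nm2)
  }, numeric(1))
  expect_gt(areas[2], areas[1])
})

test_that("surface classification recovers the planted layers and covers all residues", {
  sh <- small_shell()
  g <- voxelize(sh$model)
  masks <- find_cavity(g)
  s <- classify_surface_residues(sh$model, masks$cavity, masks$exterior, g)
  expect_equal(nrow(s), sum(!is.na(sh$model$residues$x)))
  expect_true(all(s$label %in% c("interior", "exterior", "buried")))

  lab <- setNames(s$label, paste(s$chain, s$resno))
  ti <- sh$truth$interior_residues
  te <- sh$truth$exterior_residues
  expect_gte(mean(lab[paste(ti$chain, ti$resno)] == "interior"), 0.95)
  expect_gte(mean(lab[paste(te$chain, te$resno)] == "exterior"), 0.95)
})

test_that("cavity metrics are stable under rigid-body transforms", {
  sh <- small_shell()
  base <- cavity_metrics(find_cavity(voxelize(sh$model))$cavity,
                         voxelize(sh$model))
  for (s in 1:2) {
    moved <- rigid_transform(sh$model, seed = s)
    gm <- voxelize(moved)
    vm <- cavity_metrics(find_cavity(gm)$cavity, gm)
    expect_equal(vm$cavity_volume, base$cavity_volume, tolerance = 0.05)
    expect_equal(vm$cavity_axes, base$cavity_axes, tolerance = 0.05)
  }
})

test_that("the full analysis summarizes volume at nearest-100 precision", {
  sh <- small_shell()
  an <- analyze_cavity(sh$model)
  out <- capture.output(print(an))
  expect_true(any(grepl(sprintf("approximately %d nm", round(an$metrics$cavity_volume / 100) * 100),
                        out)))
  expect_equal(an$outer_extent, c(12, 10, 8), tolerance = 0.05)
})
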