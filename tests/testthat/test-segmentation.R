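test_that("background subtraction clamps at zero and records the scalar", {
  img <- matrix(7, 10, 10)
  out <- subtract_background(img)
  expect_true(all(out == 0))
  expect_equal(attr(out, "background"), 7)

  img2 <- matrix(5, 10, 10)
  img2[4, 6] <- 20
  out2 <- subtract_background(img2, method = "median")
  expect_equal(out2[4, 6], 15)
  expect_equal(sum(out2), 15)

  out3 <- subtract_background(img2,
    method = "mean-of-region",
    empty_region = c(1, 2, 1, 10)
  )
  expect_equal(attr(out3, "background"), 5)
  expect_error(
    subtract_background(img2, "mean-of-region", empty_region = c(1, 20, 1, 5)),
    "outside"
  )
})

test_that("background estimate recovers the generator's level", {
  hits <- vapply(1:20, function(s) {
    cell <- generate_cell(cell_geometry(), seed = s, field_shape = c(128, 128),
      center = c(64, 64))
    out <- render_field(list(cell), fractions = 0.5, seed = s + 100,
      field_shape = c(128, 128))
    b <- attr(subtract_background(out$field$qd), "background")
    abs(b - 100) <= 1.5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("alternating erosion peels solid rectangles one border per pass", {
  sq <- matrix(FALSE, 14, 14)
  sq[3:12, 3:12] <- TRUE # solid 10x10
  e2 <- erode_alternating(sq, 2)
  expect_equal(sum(e2), 36)
  expect_true(all(which(e2, arr.ind = TRUE)[, 1] %in% 5:10))
  # enough iterations empty any mask
  expect_equal(sum(erode_alternating(sq, 10)), 0)
  expect_error(erode_alternating(sq, 0), ">= 1")
})

test_that("erosion matches the brute-force oracle on random masks", {
  withr::with_seed(42, {
    for (rep in 1:30) {
      m <- random_mask(32)
      iters <- sample(1:6, 1)
      conn <- sample(c("alternating", "four", "eight"), 1)
      expect_identical(
        erode_alternating(m, iters, conn),
        brute_force_erode(m, iters, conn)
      )
    }
  })
})

test_that("interior area is monotone non-increasing in erosion iterations", {
  withr::with_seed(11, {
    m <- random_mask(40, n_discs = 4)
  })
  areas <- vapply(1:8, function(k) sum(erode_alternating(m, k)), numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("partition splits the cell exactly and flags degenerate cases", {
  cell <- matrix(FALSE, 30, 30)
  cell[6:25, 6:25] <- TRUE # solid 20x20
  all_qd <- matrix(TRUE, 30, 30)
  p <- partition_cell(cell, 5, all_qd)
  expect_equal(sum(p$pre_interior), 100) # 10x10 core
  expect_equal(sum(p$pre_membrane), 300)
  expect_false(p$degenerate)

  # exact complementary partition on random masks
  withr::with_seed(7, {
    for (rep in 1:20) {
      m <- random_mask(32)
      qd <- random_mask(32, 2)
      pr <- partition_cell(m, sample(1:6, 1), qd)
      expect_true(!any(pr$pre_membrane & pr$pre_interior))
      expect_identical(pr$pre_membrane | pr$pre_interior, m)
      expect_true(!any(pr$membrane & pr$interior))
      expect_identical(pr$membrane | pr$interior, qd & m)
    }
  })

  # erosion exhausting the cell flags, not errors
  small <- matrix(FALSE, 10, 10)
  small[4:6, 4:6] <- TRUE
  expect_true(partition_cell(small, 5, matrix(TRUE, 10, 10))$degenerate)
})

test_that("empty QD mask yields empty compartments and a flagged measurement", {
  cell <- matrix(FALSE, 20, 20)
  cell[4:17, 4:17] <- TRUE
  p <- partition_cell(cell, 3, matrix(FALSE, 20, 20))
  expect_equal(sum(p$membrane) + sum(p$interior), 0)
  m <- measure_cell(p, matrix(1, 20, 20), matrix(2, 20, 20))
  expect_true(m$excluded)
  expect_match(m$exclude_reason, "no QD signal")
})

test_that("QD mask thresholds behave on trivial and sparse images", {
  z <- matrix(0, 20, 20)
  expect_equal(sum(compute_qd_mask(z)), 0)
  one <- z
  one[5, 5] <- 10
  mk <- compute_qd_mask(one, k_sigma = 3)
  expect_equal(which(mk), which(one > 0))
  # noiseless rendered puncta: pixels carrying signal are captured
  cell <- generate_cell(cell_geometry(), seed = 2, field_shape = c(128, 128),
    center = c(64, 64))
  out <- render_field(list(cell), fractions = 0.5, seed = 3,
    field_shape = c(128, 128), noise = noiseless_spec())
  qd <- out$field$qd
  mask <- compute_qd_mask(qd)
  bright <- qd >= 0.1 * max(qd)
  expect_gte(sum(mask & bright) / sum(bright), 0.99)
})

test_that("cell segmentation finds well-separated synthetic cells", {
  cells <- endoquant:::place_cells(cell_geometry(), 3, c(256, 256), seed = 19)
  out <- render_field(cells, fractions = rep(0.5, 3), seed = 20)
  rec <- subtract_background(out$field$receptor)
  seg <- segment_cells(rec)
  expect_equal(sum(seg$cells$retained), 3)
  for (cl in cells) {
    tru <- rasterize_cell(cl, c(256, 256))$cell
    lab <- seg$labels[round(cl$center[1]), round(cl$center[2])]
    expect_gt(lab, 0)
    sm <- seg$labels == lab
    expect_gt(sum(sm & tru) / sum(sm | tru), 0.8)
  }
  # all-background field: zero cells, no error
  empty <- segment_cells(matrix(0, 64, 64))
  expect_equal(nrow(empty$cells), 0)
})

test_that("border-touching cells are flagged and excluded by default", {
  cell <- generate_cell(cell_geometry(radius_range = c(20, 24)),
    seed = 5, field_shape = c(96, 96), center = c(6, 48), allow_border = TRUE
  )
  expect_true(cell$border_touching)
  out <- render_field(list(cell), fractions = 0.5, seed = 6,
    field_shape = c(96, 96))
  rec <- subtract_background(out$field$receptor)
  seg <- segment_cells(rec, exclude_border = TRUE)
  expect_equal(sum(seg$cells$retained), 0)
  expect_true(any(seg$cells$border_touching & !seg$cells$retained))
})

test_that("per-cell sums are plain mask sums and match generator truth", {
  # constant QD image: sums equal compartment sizes
  cell <- matrix(FALSE, 24, 24)
  cell[3:22, 3:22] <- TRUE # 20x20: 5 iterations -> 100 px interior, 300 membrane
  p <- partition_cell(cell, 5, matrix(TRUE, 24, 24))
  m <- measure_cell(p, matrix(1, 24, 24), matrix(3, 24, 24))
  expect_equal(m$qd_interior_sum, 100)
  expect_equal(m$qd_membrane_sum, 300)
  expect_equal(m$syfp_mean, 3)

  # noiseless rendered cell: sums within 5% of true per-compartment flux
  cl <- generate_cell(cell_geometry(), seed = 31, field_shape = c(128, 128),
    center = c(64, 64))
  out <- render_field(list(cl), fractions = 0.5, seed = 32,
    field_shape = c(128, 128), noise = noiseless_spec())
  meas <- internalization_ratio(measure_field(out$field))
  expect_equal(nrow(meas), 1)
  expect_lt(
    abs(meas$qd_interior_sum - out$truth$true_interior_flux) /
      out$truth$true_interior_flux, 0.05
  )
  expect_lt(
    abs(meas$qd_membrane_sum - out$truth$true_membrane_flux) /
      out$truth$true_membrane_flux, 0.05
  )
})
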