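test_that("a static cell is entirely stable with zero dynamic area", {
  m <- disk_mask(20, c(10, 10), 5)
  rm_ <- classify_regions(m, m, m, pixel_size_um = 0.21)
  expect_equal(rm_$pixels[["stable"]], sum(m))
  expect_equal(rm_$dynamic_cell_area, 0)
  expect_equal(rm_$delta_cell_area, 0)
  expect_equal(rm_$cell_area, sum(m) * 0.21^2)
})

test_that("the membership-pair definition labels a hand-built triple", {
  g <- function(px) {
    m <- matrix(FALSE, 4, 6)
    for (p in px) m[p[1], p[2]] <- TRUE
    m
  }
  prev <- g(list(c(1, 1), c(1, 2)))
  curr <- g(list(c(1, 2), c(1, 3), c(1, 4)))
  nxt <- g(list(c(1, 2), c(1, 3)))
  rm_ <- classify_regions(prev, curr, nxt, pixel_size_um = 0.21)
  expect_equal(rm_$labels[1, 2], REGION_CODES[["stable"]])
  expect_equal(rm_$labels[1, 3], REGION_CODES[["protrusion"]])
  expect_equal(rm_$labels[1, 4], REGION_CODES[["short_lived"]])
  expect_equal(rm_$pixels[["retraction"]], 0)
  expect_equal(rm_$dynamic_cell_area, 2 * 0.21^2)
})

test_that("a rigidly translating disk balances protrusion and retraction", {
  masks <- lapply(0:2, function(t) disk_mask(30, c(15, 8 + 3 * t), 6))
  rm_ <- classify_regions(masks[[1]], masks[[2]], masks[[3]], 1)
  expect_lte(abs(rm_$pixels[["protrusion"]] - rm_$pixels[["retraction"]]), 1)
  expect_lt(abs(rm_$delta_cell_area), 1.01)
  expect_gt(rm_$dynamic_cell_area, 0)
  # brute-force set-difference oracle
  oracle <- oracle_classify_pixels(masks[[1]], masks[[2]], masks[[3]])
  expect_identical(unname(rm_$labels), oracle)
})

test_that("region classification validates its inputs", {
  m <- disk_mask(10, c(5, 5), 3)
  expect_error(classify_regions(m, matrix(FALSE, 10, 10), m), "empty")
  expect_error(classify_regions(m[1:5, ], m, m), "dimensions")
})

test_that("speed is the calibrated centroid displacement", {
  m <- disk_mask(30, c(10, 10), 4)
  expect_equal(compute_speed(m, m), 0)
  m2 <- shift_mask(m, 3, 4)
  expect_equal(compute_speed(m, m2, 0.21, 5), 5 * 0.21 / 5)
  # asymmetric growth: centroid shift equals explicit pixel averaging
  m3 <- m; m3[10, 15:17] <- TRUE
  d <- oracle_centroid(m3) - oracle_centroid(m)
  expect_equal(compute_speed(m, m3, 0.21, 5),
               sqrt(sum(d^2)) * 0.21 / 5)
  expect_error(compute_speed(matrix(FALSE, 5, 5), m), "empty")
})

test_that("sequence endpoints and gap-adjacent frames are invalid", {
  mk <- function(n, gaps = integer()) {
    frames <- lapply(seq_len(n), function(t) {
      if (t %in% gaps) matrix(FALSE, 40, 40) else disk_mask(40, c(20, 10 + t), 6)
    })
    mask_sequence(frames, gap_flags = seq_len(n) %in% gaps)
  }
  d5 <- sequence_dynamics(mk(5))
  expect_equal(which(d5$valid), 2:4)
  d7 <- sequence_dynamics(mk(7, gaps = 4))
  expect_equal(which(d7$valid), c(2, 6))
  expect_warning(sequence_dynamics(mk(3, gaps = 2)), "no frame")
})

test_that("rigid translation gives constant dynamic area across valid frames", {
  seq_ <- generate_mask_sequence(
    mask_sim_spec(n_frames = 8, grid_size = 80, speed_px_per_frame = 3, seed = 3))
  d <- sequence_dynamics(seq_)
  dca <- d$dynamic_cell_area[d$valid]
  expect_true(all(dca == dca[1]))
  expect_equal(d$speed[d$valid], rep(3 * 0.21 / 5, sum(d$valid)))
})

test_that("region areas always partition the cell area and reverse in time", {
  set.seed(42)
  for (i in 1:200) {
    prev <- random_mask(); curr <- random_mask(); nxt <- random_mask()
    if (!any(curr)) curr[3, 3] <- TRUE
    f <- classify_regions(prev, curr, nxt, 0.21)
    expect_equal(sum(f$pixels), f$cell_pixels)
    expect_equal(f$dynamic_cell_area,
                 f$cell_area - f$areas[["stable"]])
    # time reversal swaps protrusion and retraction
    b <- classify_regions(nxt, curr, prev, 0.21)
    expect_equal(f$pixels[["protrusion"]], b$pixels[["retraction"]])
    expect_equal(f$pixels[["retraction"]], b$pixels[["protrusion"]])
    expect_equal(f$pixels[["stable"]], b$pixels[["stable"]])
    expect_equal(f$pixels[["short_lived"]], b$pixels[["short_lived"]])
    # oracle equivalence
    expect_identical(unname(f$labels), oracle_classify_pixels(prev, curr, nxt))
  }
})

test_that("mask sequences round-trip through multi-page TIFF", {
  seq_ <- generate_mask_sequence(
    mask_sim_spec(n_frames = 5, grid_size = 64, speed_px_per_frame = 1,
                  shape_noise = 0.5, gap_frames = 3L, seed = 9))
  path <- withr::local_tempfile(fileext = ".tif")
  write_mask_tiff(seq_, path)
  back <- read_mask_tiff(path)
  expect_equal(length(back), length(seq_))
  expect_identical(back$gap_flags, seq_$gap_flags)
  for (i in seq_along(seq_$frames)) {
    expect_identical(back$frames[[i]], seq_$frames[[i]])
  }
})
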