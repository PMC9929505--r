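test_that("rank matching pairs seeds with their apodeme insertion points", {
  # one seed, one surface point: the only pairing
  f1 <- fibre_field(seeds = matrix(c(5, 8, 2), 1),
                    apodeme_surface = matrix(c(1, 2, 2), 1),
                    apodeme_axis = c(1, 0, 0), voxel_size = 0.02)
  p1 <- rank_match(f1)
  expect_equal(p1$insertion, 1L)
  expect_equal(p1$connection_px, sqrt(sum(c(4, 6, 0)^2)))

  # equal counts with strictly monotone anterior-posterior order on both
  # sets: the pairing is the identity permutation of ranks
  n <- 25
  ins <- cbind(seq_len(n) * 2, 5, 5)
  seeds <- cbind(seq_len(n) * 2 + 1, 20, 5)
  f2 <- fibre_field(seeds, ins, c(1, 0, 0), 0.02)
  expect_equal(rank_match(f2)$insertion, seq_len(n))

  # more surface points than seeds: pairing remains a bijection onto its image
  f3 <- fibre_field(seeds, rbind(ins, cbind(seq_len(n) * 2 + 0.5, 5.5, 5)),
                    c(1, 0, 0), 0.02)
  p3 <- rank_match(f3)
  expect_equal(anyDuplicated(p3$insertion), 0L)
})

test_that("a synthetic non-crossing fan is recovered almost perfectly", {
  ff <- make_fibre_field(n = 100, seed = 31)
  pairs <- rank_match(ff$field)
  expect_gte(mean(pairs$insertion == ff$truth$insertion), 0.95)
  rec <- classify_and_measure(ff$field, pairs)
  expect_equal(median(rec$total_length_mm - ff$truth$total_length_mm), 0)
  expect_lt(max(abs(rec$pennation_deg - ff$truth$pennation_deg)), 1)
})

test_that("morphometry output is invariant under rigid translation", {
  ff <- make_fibre_field(n = 40, seed = 8)
  rec1 <- classify_and_measure(ff$field)
  shift <- c(7, 11, 2)
  f2 <- fibre_field(sweep(ff$field$seeds, 2, -shift),
                    sweep(ff$field$apodeme_surface, 2, -shift),
                    ff$field$apodeme_axis, ff$field$voxel_size)
  rec2 <- classify_and_measure(f2)
  expect_equal(rec1$total_length_mm, rec2$total_length_mm, tolerance = 1e-12)
  expect_equal(rec1$pennation_deg, rec2$pennation_deg, tolerance = 1e-12)
})

test_that("filament growth measures the muscle-free corridor", {
  vox <- 0.01
  dims <- c(200, 40, 10)
  # muscle-free corridor of 0.6 mm (60 voxels) along +x, then muscle
  corridor <- array(FALSE, dims)
  corridor[floor(5 + 0.6 / vox):dims[1], , ] <- TRUE
  g <- grow_filament(c(5, 20, 5), c(1, 0, 0), corridor, vox)
  expect_true(g$reliable)
  expect_lte(abs(g$length_mm - 0.6), 1.001 * vox)

  # insertion immediately inside muscle: filament is (near) zero
  all_muscle <- array(TRUE, dims)
  g0 <- grow_filament(c(5, 20, 5), c(1, 0, 0), all_muscle, vox)
  expect_lte(g0$length_mm, 5 * vox)
  expect_lte(g0$length_px, 0.5)

  # ray exits the mask before the threshold: unreliable, fallback length
  empty <- array(FALSE, dims)
  ge <- grow_filament(c(5, 20, 5), c(1, 0, 0), empty, vox, fallback_px = 80)
  expect_false(ge$reliable)
  expect_equal(ge$length_mm, 80 * vox)
})

test_that("attachment classification and exclusions follow the pixel rules", {
  # filament shorter than the fibre diameter (5 px) classifies as direct
  ffd <- make_fibre_field(n = 20, filament_mm = 0.6, voxel_size = 0.02,
                          seed = 5)
  rec <- classify_and_measure(ffd$field)
  expect_true(all(rec$attachment == "filament"))
  expect_lt(max(abs(rec$filament_length_mm - 0.6)), 2 * 0.02)
  expect_equal(rec$fibre_length_mm, rec$total_length_mm - rec$filament_length_mm,
               tolerance = 1e-12)

  ff0 <- make_fibre_field(n = 20, filament_mm = 0, build_mask = TRUE, seed = 6)
  rec0 <- classify_and_measure(ff0$field)
  expect_true(all(rec0$attachment == "direct"))
  expect_equal(rec0$filament_length_mm, rep(0, 20))
  expect_equal(rec0$fibre_length_mm, rec0$total_length_mm)

  # a fibre parallel to the apodeme axis has zero pennation; a fibre shorter
  # than twice the fibre diameter is excluded
  f <- fibre_field(seeds = rbind(c(30, 5, 5), c(48, 5, 5)),
                   apodeme_surface = rbind(c(10, 5, 5), c(47, 5, 5)),
                   apodeme_axis = c(1, 0, 0), voxel_size = 0.02)
  rec2 <- classify_and_measure(f)
  expect_equal(rec2$pennation_deg, c(0, 0))
  expect_false(rec2$excluded[1])   # 20 px = 4 diameters
  expect_true(rec2$excluded[2])    # 1 px < 2 x 5 px
  expect_match(rec2$reason[2], "twice the fibre diameter")
})

test_that("non-binary masks are thresholded with a warning", {
  m <- array(0L, c(4, 4, 2))
  m[3:4, , ] <- 7L
  expect_warning(
    f <- fibre_field(matrix(c(2, 2, 1), 1), matrix(c(1, 1, 1), 1),
                     c(1, 0, 0), 0.02, muscle_mask = m),
    "thresholded")
  expect_true(is.logical(f$muscle_mask))
})
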