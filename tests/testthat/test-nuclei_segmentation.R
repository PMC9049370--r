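# Saliency, corner denoising, gradients, markers and the
# marker-controlled watershed.

test_that("ft_saliency vanishes on uniform images and highlights objects", {
  uni <- array(120L, c(24, 24, 3))
  expect_true(all(ft_saliency(uni) == 0))

  # bright square on dark field: mean saliency inside > outside
  img <- array(30L, c(48, 48, 3))
  img[17:32, 17:32, ] <- 220L
  s <- ft_saliency(img)
  inside <- matrix(FALSE, 48, 48); inside[17:32, 17:32] <- TRUE
  expect_gt(mean(s[inside]), mean(s[!inside]))
  expect_true(all(s >= 0 & s <= 1))

  # scaling contrast up does not decrease the (normalized) max saliency
  img2 <- array(30L, c(48, 48, 3)); img2[17:32, 17:32, ] <- 120L
  expect_gte(max(ft_saliency(img)), max(ft_saliency(img2)) - 1e-9)
})

test_that("gray-only images reduce saliency to the luminance difference", {
  g <- stainseg:::with_seed(2, matrix(sample(0:255, 32 * 32, TRUE), 32, 32))
  img <- array(0L, c(32, 32, 3))
  for (ch in 1:3) img[, , ch] <- g
  s <- ft_saliency(img)
  # a* = b* = 0 everywhere, so the map is driven by L alone: recompute
  lab_of <- function(v) grDevices::convertColor(cbind(v, v, v) / 255,
                                                from = "sRGB", to = "Lab")
  expect_true(max(abs(lab_of(c(g))[, 2:3])) < 1e-6)
})

test_that("remove_corner_noise deletes only small corner blobs", {
  m <- matrix(0L, 100, 100)
  m[2:3, 2:3] <- 1L                 # 4-px blob in the top-left corner
  m[40:70, 40:70] <- 1L             # large central blob
  out <- remove_corner_noise(m, corner_window = 32, max_blob = 200)
  expect_equal(sum(out[1:10, 1:10]), 0)
  expect_equal(sum(out), 31 * 31)

  # large component touching a corner is retained
  m2 <- matrix(0L, 100, 100)
  m2[1:30, 1:30] <- 1L              # area 900 > max_blob
  expect_equal(remove_corner_noise(m2), m2)

  # empty mask unchanged
  expect_equal(remove_corner_noise(matrix(0L, 10, 10)), matrix(0L, 10, 10))

  # central small blob untouched
  m3 <- matrix(0L, 100, 100); m3[50:51, 50:51] <- 1L
  expect_equal(remove_corner_noise(m3), m3)
})

test_that("gradient_magnitude is a Sobel magnitude with symmetry", {
  expect_true(all(gradient_magnitude(matrix(7, 16, 16)) == 0))

  # vertical step edge 0 -> 255: response 4*255 on the two edge columns
  step <- matrix(0, 16, 16); step[, 9:16] <- 255
  g <- gradient_magnitude(step)
  expect_equal(max(g), 4 * 255)
  expect_equal(g[8, 8], 4 * 255)
  expect_true(all(g[, c(1:4, 13:16)] == 0))

  # rotating the input rotates the magnitude field
  m <- stainseg:::with_seed(4, matrix(runif(100, 0, 255), 10, 10))
  rot <- function(x) t(apply(x, 2, rev))
  expect_equal(gradient_magnitude(rot(m)), rot(gradient_magnitude(m)),
               tolerance = 1e-9)
})

test_that("compute_markers finds one component per well-separated nucleus", {
  gt <- make_scene(scene_spec(image_size = c(160, 160), n_nuclei = 2,
                              radius_range = c(14, 18), noise_sd = 0,
                              seed = 21))
  img <- render_rgb(gt)
  sep <- separate_image(img, seed = 1)
  sal <- ft_saliency(sep$foreground)
  mk <- compute_markers(sep$foreground, sal)
  expect_s3_class(mk, "marker_set")
  expect_equal(max(EBImage::bwlabel(mk$foreground_markers)), 2)
  # disjoint marker sets
  expect_true(all(mk$foreground_markers * mk$background_markers == 0))

  # blank image: no markers, degenerate error
  blank <- array(255L, c(64, 64, 3))
  expect_error(compute_markers(blank, matrix(0, 64, 64)), "no foreground")
})

test_that("overlapping nuclei with distinct cores still give two markers", {
  gt <- make_scene(scene_spec(image_size = c(160, 160), n_nuclei = 2,
                              radius_range = c(14, 16), noise_sd = 0,
                              overlap_fraction = 0.3, seed = 33))
  img <- render_rgb(gt)
  sep <- separate_image(img, seed = 1)
  mk <- compute_markers(sep$foreground, ft_saliency(sep$foreground))
  expect_equal(max(EBImage::bwlabel(mk$foreground_markers)), 2)
})

test_that("watershed label count always equals the marker component count", {
  # constructed two-disk fixture
  grad <- matrix(0, 60, 60)
  fg <- matrix(0L, 60, 60); fg[15, 15] <- 1L; fg[45, 45] <- 1L
  bg <- matrix(0L, 60, 60); bg[, 30] <- 1L
  mk <- structure(list(foreground_markers = fg, background_markers = bg),
                  class = "marker_set")
  lab <- watershed_segment(grad, mk)
  expect_equal(max(lab), 2)
  expect_equal(sort(unique(as.integer(lab))), 0:2)

  # single marker, no background: everything is one label
  fg1 <- matrix(0L, 20, 20); fg1[10, 10] <- 1L
  mk1 <- structure(list(foreground_markers = fg1,
                        background_markers = matrix(0L, 20, 20)),
                   class = "marker_set")
  lab1 <- watershed_segment(matrix(0, 20, 20), mk1)
  expect_equal(max(lab1), 1)
  expect_true(all(lab1 == 1))

  # property: K equals component count on random marker fields
  for (s in 1:20) {
    n <- 1 + (s %% 5)
    fgk <- matrix(0L, 40, 40)
    pts <- stainseg:::with_seed(s, cbind(sample(5:35, n), sample(5:35, n)))
    pts <- unique(pts)
    fgk[pts] <- 1L
    k_true <- max(EBImage::bwlabel(fgk))
    mkk <- structure(list(foreground_markers = fgk,
                          background_markers = matrix(0L, 40, 40)),
                     class = "marker_set")
    gradk <- stainseg:::with_seed(s + 500, matrix(runif(1600), 40, 40))
    expect_equal(max(watershed_segment(gradk, mkk)), k_true)
  }
})

test_that("watershed regions partition the image", {
  gt <- tiny_scene(3, size = 128, n = 6, noise = 0)
  seg <- segment_nuclei(render_rgb(gt), stain_cfg = list(seed = 1))
  lab <- seg$labels
  expect_true(all(lab >= 0))
  expect_equal(sort(unique(as.integer(lab[lab > 0]))), seq_len(max(lab)))
  expect_equal(length(lab), prod(dim(lab)))  # labels cover every pixel
})

test_that("segment_nuclei achieves high Dice on non-overlapping scenes", {
  gt <- tiny_scene(9, size = 256, n = 12, noise = 0.01)
  img <- render_rgb(gt)
  seg <- segment_nuclei(img, stain_cfg = list(seed = 1))
  expect_gte(dice((seg$labels > 0) * 1L, gt$mask), 0.80)
  # nuclei image is white outside the segmented nuclei
  expect_true(all(seg$nuclei[, , 1][seg$labels == 0] == 255L))
  # deterministic
  seg2 <- segment_nuclei(img, stain_cfg = list(seed = 1))
  expect_identical(seg$labels, seg2$labels)
})

test_that("an all-eosin image (no nuclei) raises a staged degenerate error", {
  spec <- scene_spec(image_size = c(96, 96), n_nuclei = 1,
                     radius_range = c(5, 6), hematoxylin_density = 0,
                     baseline_h = 0, noise_sd = 0, seed = 2)
  gt <- make_scene(spec)
  gt$H_true[1, ] <- 0
  img <- render_rgb(gt)
  expect_error(segment_nuclei(img, stain_cfg = list(seed = 1)),
               "\\[(markers|stain_separation)\\]")
})

test_that("dice degrades monotonically with nucleus overlap", {
  overlaps <- c(0, 0.2, 0.4)
  dices <- vapply(overlaps, function(ov) {
    gt <- make_scene(scene_spec(image_size = c(192, 192), n_nuclei = 10,
                                radius_range = c(10, 14), noise_sd = 0.01,
                                overlap_fraction = ov, seed = 77))
    seg <- segment_nuclei(render_rgb(gt), stain_cfg = list(seed = 1))
    dice((seg$labels > 0) * 1L, gt$mask)
  }, 0)
  expect_true(all(diff(dices) <= 0.02))  # small tolerance for raster noise
})
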