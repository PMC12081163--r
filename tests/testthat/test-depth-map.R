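# Shared fixtures: a small training sweep, an MD-preset model and a small
# rendered two-depth scene.
sweep_small <- generate_depth_sweep(phantom_params(),
                                    depths = seq(2, 20, 2), grid = c(4, 4),
                                    repeats = 2, seed = 31, n_states = 300)
model_small <- depth_model_preset(sweep_small$records, "MD",
                                  algorithm = "svr", seed = 32)
scene_small <- scene_dip(depths = c(4, 12), size = c(40, 40))
rendered <- render_scene(scene_small, seed = 33)

test_that("scene layouts carry consistent depth, zone and angle fields", {
  for (sc in list(scene_dsp1(size = c(40, 40)), scene_dsp2(size = c(40, 40)),
                  scene_small)) {
    expect_s3_class(sc, "scene_spec")
    expect_equal(dim(sc$depth), c(40L, 40L))
    expect_equal(dim(sc$zones), c(40L, 40L))
    # depth is defined exactly where a zone is defined
    expect_identical(is.na(sc$depth), is.na(sc$zones))
  }
  expect_gt(length(unique(stats::na.omit(as.vector(scene_dsp1(
    size = c(40, 40))$zones)))), 2)
})

test_that("rendering a scene yields a physical-image phantom with truth", {
  expect_s3_class(rendered, "phantom_scene")
  expect_s3_class(rendered$image, "mueller_image")
  expect_equal(dim(rendered$image), c(40L, 40L))
  expect_identical(rendered$truth, scene_small$depth)
  set.seed(34)
  for (i in 1:5) {
    r <- sample(40, 1); c <- sample(40, 1)
    M <- pixel_mueller(rendered$image, r, c)
    expect_true(all(is.finite(M)))
    expect_equal(M[1, 1], 1, tolerance = 1e-6)
  }
})

test_that("rendering is reproducible by seed", {
  r2 <- render_scene(scene_small, seed = 33)
  expect_identical(r2$image$planes, rendered$image$planes)
})

test_that("the depth map recovers the two-layer ordering of the scene", {
  dm <- predict_depth_map(model_small, rendered, grid = c(8, 8),
                          n_states = 300)
  expect_s3_class(dm, "depth_map")
  expect_equal(dim(dm$depth), c(8L, 8L))
  zs <- dm$zone_stats
  expect_equal(zs$zone, sort(unique(as.vector(stats::na.omit(
    as.vector(rendered$zones))))))
  expect_equal(nrow(zs), 2L)
  # retrieved mean depth must separate the shallow and deep zones in order
  zs <- zs[order(zs$true_depth), ]
  expect_lt(zs$mean_depth[1], zs$mean_depth[2])
  expect_lt(abs(zs$mean_depth[1] - zs$true_depth[1]), 2)
  expect_lt(abs(zs$mean_depth[2] - zs$true_depth[2]), 3)
  expect_true(all(is.finite(zs$mae)))
})

test_that("depth maps survive a disk round trip with zone summary", {
  dm <- predict_depth_map(model_small, rendered, grid = c(8, 8),
                          n_states = 300)
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(c(path, paste0(path, ".json"), paste0(path, ".zones.csv"))),
          add = TRUE)
  write_depth_map(dm, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  expect_true(file.exists(paste0(path, ".zones.csv")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  raw <- tiff::readTIFF(path)
  back <- raw * (meta$scale_max - meta$scale_min) + meta$scale_min
  back[abs(back - meta$na_value) < 1e-4] <- NA
  expect_equal(back, dm$depth, tolerance = 1e-4)
  zs <- utils::read.csv(paste0(path, ".zones.csv"))
  expect_equal(zs$mean_depth, dm$zone_stats$mean_depth, tolerance = 1e-10)
})

test_that("printing and plotting a depth map work", {
  dm <- predict_depth_map(model_small, rendered, grid = c(8, 8),
                          n_states = 200)
  expect_output(print(dm), "depth_map")
  pdf(NULL); on.exit(dev.off(), add = TRUE)
  expect_invisible(plot(dm))
})
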