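test_that("a noiseless phantom reproduces the forward model exactly", {
  pre <- get_preset("kidney")
  ph <- generate_phantom(pre, geometry = list(dim = c(1, 1, 1)),
                         noise = noise_spec("gaussian", Inf), seed = 3)
  tr <- ph$truth
  p <- ivim_params(tr$f[1], tr$D[1], tr$Dstar[1], tr$S0[1])
  expect_equal(ph$series$data[1, 1, 1, ],
               ivim_signal(p, pre$minimal_b), tolerance = 1e-12)
})

test_that("phantom generation is bit-identical under a fixed seed", {
  pre <- get_preset("liver")
  a <- generate_phantom(pre, geometry = list(dim = c(3, 3, 1)),
                        noise = noise_spec("rician", 30), seed = 12)
  b <- generate_phantom(pre, geometry = list(dim = c(3, 3, 1)),
                        noise = noise_spec("rician", 30), seed = 12)
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$truth$f, b$truth$f)
  c2 <- generate_phantom(pre, geometry = list(dim = c(3, 3, 1)),
                         noise = noise_spec("rician", 30), seed = 13)
  expect_false(identical(a$series$data, c2$series$data))
})

test_that("segmented fitting of an SNR-50 phantom recovers the truth medians", {
  pre <- get_preset("kidney")
  ph <- generate_phantom(pre, geometry = list(dim = c(10, 10, 1)),
                         noise = noise_spec("rician", 50), seed = 19)
  maps <- fit_volume(ph$series, fit_options(b_threshold = pre$b_threshold))
  ok <- maps$flag == 0
  expect_gt(sum(ok), 80)
  expect_lt(abs(median(maps$D[ok]) - median(ph$truth$D[ok])) /
              median(ph$truth$D[ok]), 0.05)
})

test_that("directional phantoms collapse back to the trace signal", {
  pre <- get_preset("muscle")
  ph <- generate_phantom(pre, geometry = list(dim = c(2, 2, 1)),
                         noise = noise_spec("gaussian", Inf),
                         n_directions = 3, seed = 5)
  expect_equal(dim(ph$series$data)[4], 18L)  # 6 b x 3 directions
  tr <- collapse_trace(ph$series)
  expect_equal(dim(tr$data)[4], 6L)
  p <- ivim_params(ph$truth$f[1], ph$truth$D[1], ph$truth$Dstar[1],
                   ph$truth$S0[1])
  expect_equal(tr$data[1, 1, 1, ], ivim_signal(p, pre$minimal_b),
               tolerance = 1e-10)
})

test_that("DWI series round-trip through NIfTI + FSL tables", {
  pre <- get_preset("kidney")
  ph <- generate_phantom(pre, geometry = list(dim = c(4, 3, 2)),
                         noise = noise_spec("rician", 40),
                         n_directions = 3, seed = 8)
  prefix <- file.path(tempdir(), "phantom_rt")
  paths <- write_dwi(ph$series, prefix)
  expect_true(all(file.exists(paths)))
  back <- read_dwi(paths[["nii"]], bval = paths[["bval"]],
                   bvec = paths[["bvec"]], json = paths[["json"]])
  expect_equal(back$bvalues, ph$series$bvalues)
  expect_equal(back$frames, ph$series$frames)
  expect_equal(as.numeric(back$data), as.numeric(ph$series$data),
               tolerance = 1e-6)  # float32 storage
  expect_equal(dim(back$directions), c(3L, 18L))
})

test_that("the .bval line prints the kidney minimal tier verbatim", {
  pre <- get_preset("kidney")
  ph <- generate_phantom(pre, geometry = list(dim = c(1, 1, 1)),
                         noise = noise_spec("gaussian", Inf), seed = 1)
  prefix <- file.path(tempdir(), "phantom_bval")
  paths <- write_dwi(ph$series, prefix)
  expect_identical(readLines(paths[["bval"]]), "0 30 70 100 200 800")
})

test_that("mismatched b-table lengths are rejected on read", {
  pre <- get_preset("kidney")
  ph <- generate_phantom(pre, geometry = list(dim = c(1, 1, 1)),
                         noise = noise_spec("gaussian", Inf), seed = 1)
  prefix <- file.path(tempdir(), "phantom_bad")
  paths <- write_dwi(ph$series, prefix)
  writeLines("0 30 70 100 200", paths[["bval"]])  # one entry short
  expect_error(read_dwi(paths[["nii"]], bval = paths[["bval"]]),
               "b-table length")
})

test_that("ROI statistics use the declared quantile rule", {
  m <- array(0, c(2, 2, 1))
  m[] <- c(1, 2, 3, 4)
  labels <- array(1L, c(2, 2, 1))
  st <- roi_stats(list(D = m), labels)
  expect_equal(st$median, 2.5)
  expect_equal(st$iqr, unname(diff(quantile(1:4, c(.25, .75), type = 7))))
  expect_equal(st$n, 4L)
  # constant map: mean = median = v, SD = IQR = 0
  m2 <- array(7, c(2, 2, 1))
  st2 <- roi_stats(list(f = m2), labels)
  expect_equal(st2$mean, 7); expect_equal(st2$median, 7)
  expect_equal(st2$sd, 0); expect_equal(st2$iqr, 0)
  # voxel-order invariance
  perm <- array(c(4, 1, 3, 2), c(2, 2, 1))
  stp <- roi_stats(list(D = perm), labels)
  expect_equal(stp$median, st$median)
  expect_equal(stp$iqr, st$iqr)
})

test_that("labels without usable voxels are omitted with a warning", {
  m <- array(1.0, c(2, 1, 1))
  labels <- array(c(1L, 2L), c(2, 1, 1))
  flag <- array(c(0L, 2L), c(2, 1, 1))
  expect_warning(st <- roi_stats(list(D = m), labels, flag = flag),
                 "omitted")
  expect_equal(st$roi, 1)
})

test_that("phantom ROI mean lies within sampling error of the truth mean", {
  pre <- get_preset("pancreas")
  ph <- generate_phantom(pre, geometry = list(dim = c(8, 8, 1)),
                         noise = noise_spec("gaussian", 60), seed = 23)
  maps <- fit_volume(ph$series, fit_options(b_threshold = pre$b_threshold))
  labels <- ph$truth$labels
  st <- roi_stats(maps, labels, flag = maps$flag)
  d_row <- st[st$parameter == "D", ]
  truth_mean <- mean(ph$truth$D[maps$flag == 0])
  se <- d_row$sd / sqrt(d_row$n)
  expect_lt(abs(d_row$mean - truth_mean), 3 * se + 0.05 * truth_mean)
})
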