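test_that("organ presets carry the consensus b-value tiers", {
  k <- get_preset("kidney")
  expect_equal(k$minimal_b, c(0, 30, 70, 100, 200, 800))
  expect_equal(k$b_threshold, 200)
  br <- get_preset("brain")
  expect_equal(br$abbreviated_b, c(0, 300, 1000))
  expect_equal(br$b_threshold, 300)
  pa <- get_preset("pancreas")
  expect_equal(pa$minimal_b, c(0, 0, 50, 200, 290, 600))  # repeated b=0 kept
  expect_error(get_preset("prostate"), "supported organs")
})

test_that("every preset satisfies the tier structure invariants", {
  for (org in ivim_organs()) {
    pre <- get_preset(org)
    expect_length(pre$minimal_b, 6L)
    expect_length(pre$abbreviated_b, 3L)
    expect_true(0 %in% pre$abbreviated_b)
    # abbreviated is a sub-multiset of minimal
    ta <- table(pre$abbreviated_b); tm <- table(pre$minimal_b)
    expect_true(all(names(ta) %in% names(tm)))
    expect_true(all(tm[names(ta)] >= ta))
    expect_true(pre$b_threshold %in% pre$minimal_b)
    expect_true(all(pre$minimal_b %% 10 == 0))
    # at least as many low-b as high-b values
    expect_gte(sum(pre$minimal_b < 200), sum(pre$minimal_b >= 200))
    # priors are valid parameter settings
    expect_true(ivim_identifiable(preset_params(pre)))
  }
})

test_that("a custom priors file overrides the packaged constants", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(kidney = list(
    f = list(mean = 0.3, sd = 0.05), D = list(mean = 1e-3, sd = 1e-4),
    Dstar = list(mean = 0.05, sd = 0.01))), f, auto_unbox = TRUE)
  pre <- get_preset("kidney", priors_file = f)
  expect_equal(pre$prior$f[["mean"]], 0.3)
  expect_error(get_preset("brain", priors_file = f), "no entry")
})

test_that("compliant protocols pass and violations produce fail findings", {
  pre <- get_preset("kidney")
  good <- acquisition_protocol("kidney", pre$minimal_b, n_directions = 3,
                               n_averages = 1, tr = 4, voxel_size = 2.5,
                               slice_thickness = 3, fat_suppression = "SPAIR")
  fd <- check_protocol(good, pre, "minimal")
  expect_false(any(fd$severity == "fail"))
  # muscle requires at least 2 averages
  mus <- get_preset("muscle")
  p1 <- acquisition_protocol("muscle", mus$minimal_b, n_directions = 3,
                             n_averages = 1, tr = 5)
  fd1 <- check_protocol(p1, mus, "minimal")
  expect_equal(fd1$severity[fd1$field == "n_averages"], "fail")
  # advanced tier must still contain the minimal set
  br <- get_preset("brain")
  missing400 <- c(0, 0, 70, 300, 1000, 500, 700)
  p2 <- acquisition_protocol("brain", missing400, n_directions = 3,
                             n_averages = 1, tr = 4)
  fd2 <- check_protocol(p2, br, "advanced")
  expect_equal(fd2$severity[fd2$field == "bvalues"], "fail")
  # organ mismatch is an error, not a finding
  expect_error(check_protocol(p2, mus, "minimal"), "does not match")
})

test_that("each preset's own minimal protocol is self-consistent", {
  for (org in ivim_organs()) {
    pre <- get_preset(org)
    proto <- acquisition_protocol(
      org, pre$minimal_b, n_directions = 3,
      n_averages = pre$averages_min, tr = pre$tr_min,
      voxel_size = mean(pre$resolution_range),
      slice_thickness = mean(pre$slice_range),
      fat_suppression = pre$fat_suppression)
    fd <- check_protocol(proto, pre, "minimal")
    expect_false(any(fd$severity == "fail"), info = org)
  }
})

test_that("protocols round-trip through YAML and JSON", {
  p <- acquisition_protocol("liver", c(0, 10, 20, 100, 200, 500),
                            n_directions = 3, tr = 3.5, te = 55,
                            delta_small = 12, fat_suppression = "SPAIR")
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_protocol(p, f)
    q <- read_protocol(f)
    expect_equal(q$bvalues, p$bvalues)
    expect_equal(q$tr, p$tr)
    expect_equal(q$delta_small, p$delta_small)
  }
})

test_that("reporting checklist has a fixed item count and tracks provision", {
  empty <- reporting_checklist()
  expect_false(any(empty$provided))
  n_items <- nrow(empty)
  full_proto <- acquisition_protocol(
    "liver", c(0, 200, 500), n_directions = 3, n_averages = 2, tr = 3,
    te = 50, delta_big = 25, delta_small = 12, max_gradient = 45,
    slew = 200, field_strength = 3, fat_suppression = "SPAIR",
    voxel_size = 3, slice_thickness = 5, echo_train_length = 60,
    echo_spacing = 0.6, bandwidth = 2200, acceleration_factor = 2,
    oversampling = 1, slice_gap = 0, slice_order = "interleaved",
    reconstruction = "zero-filled to 256")
  meta <- list(preprocessing = "registration",
               fit_algorithm = "segmented_fix_df",
               fit_initial_guess = "D* = 10 D",
               fit_constraints = "f in [0,1]")
  full <- reporting_checklist(full_proto, meta)
  expect_equal(nrow(full), n_items)
  expect_true(all(full$provided))
  # exactly one missing entry when only delta_small is absent
  proto2 <- full_proto
  proto2$delta_small <- NA
  chk2 <- reporting_checklist(proto2, meta)
  expect_equal(sum(!chk2$provided), 1L)
  expect_equal(chk2$item[!chk2$provided], "delta_small")
  expect_match(format(full), "reporting checklist")
})
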