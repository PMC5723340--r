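test_that("synthetic experts are reproducible and recover the generating shape", {
  true <- skewnorm(10, 1, 2)
  lo <- qskewnorm(0.001, 10, 1, 2); hi <- qskewnorm(0.999, 10, 1, 2)
  g1 <- simulate_expert(true, n_chips = 60, lower = lo, upper = hi, seed = 8)
  g2 <- simulate_expert(true, n_chips = 60, lower = lo, upper = hi, seed = 8)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$chips), 60)
  expect_true(all(g1$chips$column >= 0 & g1$chips$column <= 599))
  expect_true(all(chips_to_values(g1) >= lo & chips_to_values(g1) <= hi))
  # range chips occupy the end columns
  expect_true(0 %in% g1$chips$column && 599 %in% g1$chips$column)

  g200 <- simulate_expert(true, n_chips = 200, lower = lo, upper = hi,
                          seed = 15)
  shape_hat <- coef(snorm_fit(chips_to_values(g200)))[["shape"]]
  expect_true(shape_hat >= 1.6 && shape_hat <= 2.4)

  # a range covering too little mass is refused
  expect_error(simulate_expert(true, 50, lower = 9, upper = 11, seed = 1),
               "99")
  expect_error(simulate_expert(true, 5, lower = lo, upper = hi, seed = 1),
               ">= 7")
})

test_that("the batch pipeline runs both entry paths deterministically", {
  own <- scale_spec(9, label = "per type")
  target <- scale_spec(1, label = "total")

  # direct-location path equals a bounds fit after the scale transform
  rec <- run_five_steps(mu0 = 23, bounds = c(180, 240), scale = own,
                        target_scale = target, expert_id = "e3")
  expect_null(rec$step2_fit)
  expect_equal(rec$step3_bounds$mu0, 207)
  ref <- fit_bounds(207, 180, 240)
  expect_equal(rec$step4_prior, ref$dist)

  # chip path: symmetric chips and symmetric bounds give shape ~ 1
  cols <- c(0, 599, 150, 450, 299, 299, 300, 300, 100, 500)
  rows <- ave(cols, cols, FUN = seq_along) - 1
  grid <- roulette_grid(data.frame(column = cols, row = rows),
                        lower = 8, upper = 12)
  rec2 <- run_five_steps(grid = grid, bounds = c(8, 12),
                         scale = scale_spec(1), target_scale = scale_spec(1),
                         expert_id = "sym")
  expect_lt(abs(rec2$step4_prior$shape - 1), 1e-2)
  expect_equal(rec2$step4_prior$mean, coef(rec2$step2_fit)[["mean"]])
  # rerunning with identical inputs reproduces the record
  rec3 <- run_five_steps(grid = grid, bounds = c(8, 12),
                         scale = scale_spec(1), target_scale = scale_spec(1),
                         expert_id = "sym")
  expect_equal(rec2, rec3)

  expect_error(run_five_steps(grid = grid, mu0 = 1, bounds = c(0, 1),
                              scale = own, target_scale = target),
               "exactly one")
  expect_error(run_five_steps(mu0 = 5, bounds = c(2, 1), scale = own,
                              target_scale = target), "lower < upper")
  # stage-labeled error propagation
  bad <- roulette_grid(data.frame(column = c(0, 599, 1), row = c(0, 0, 0)),
                       0, 1)
  expect_error(run_five_steps(grid = bad, bounds = c(0, 1),
                              scale = own, target_scale = target),
               "step 1")
})

test_that("seeded pipelines recover the generating mean across a panel", {
  withr::with_seed(61, {
    mus <- rnorm(10, 20, 5)
    sds <- rexp(10) + 1
    shapes <- exp(runif(10, log(0.5), log(2)))
  })
  errs <- vapply(1:10, function(i) {
    true <- skewnorm(mus[i], sds[i], shapes[i])
    # grid range: the reasonable min/max, wide enough to cover the beliefs;
    # step-3 bounds: the true 5th/95th percentiles
    glo <- qskewnorm(0.001, mus[i], sds[i], shapes[i])
    ghi <- qskewnorm(0.999, mus[i], sds[i], shapes[i])
    lo <- qskewnorm(0.05, mus[i], sds[i], shapes[i])
    hi <- qskewnorm(0.95, mus[i], sds[i], shapes[i])
    grid <- simulate_expert(true, n_chips = 100, lower = glo, upper = ghi,
                            seed = 700 + i)
    rec <- run_five_steps(grid = grid, bounds = c(lo, hi),
                          scale = scale_spec(1), target_scale = scale_spec(1),
                          expert_id = paste0("synthetic-", i))
    abs(rec$step4_prior$mean - mus[i]) / sds[i]
  }, numeric(1))
  expect_lte(mean(errs), 0.1)
})

test_that("sessions round-trip through versioned JSON bit-exactly", {
  pp <- scale_spec(104, label = "per product")
  total <- scale_spec(1, label = "total")
  recs <- c(
    lapply(1:2, function(i) {
      g <- simulate_expert(skewnorm(2, 0.3, 1.3), 30, lower = 1, upper = 3.2,
                           seed = i)
      run_five_steps(grid = g, bounds = c(150, 260), scale = pp,
                     target_scale = total, expert_id = paste0("chip-", i))
    }),
    lapply(3:4, function(i)
      run_five_steps(mu0 = 2 + 0.1 * i, bounds = c(150, 280), scale = pp,
                     target_scale = total, expert_id = paste0("direct-", i)))
  )
  panel <- expert_panel(recs, common_scale = total,
                        posterior = skewnorm(2.29, 0.10, 0.99))
  path <- withr::local_tempfile(fileext = ".json")
  save_session(panel, path)
  panel2 <- load_session(path)
  for (i in seq_along(recs)) {
    expect_identical(panel2$records[[i]]$step4_prior,
                     panel$records[[i]]$step4_prior)
    expect_identical(panel2$records[[i]]$step3_bounds$mu0,
                     panel$records[[i]]$step3_bounds$mu0)
    expect_equal(panel2$records[[i]]$step1_grid, panel$records[[i]]$step1_grid)
  }
  expect_identical(panel2$posterior, panel$posterior)
  expect_identical(panel2$common_scale$label, "total")

  # identical inputs produce byte-identical session files
  path_b <- withr::local_tempfile(fileext = ".json")
  save_session(panel, path_b)
  expect_identical(readLines(path), readLines(path_b))

  # corrupt files are refused with field-level messages
  bad <- jsonlite::read_json(path)
  bad$version <- "99.0"
  path_bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, path_bad, auto_unbox = TRUE, null = "null")
  expect_error(load_session(path_bad), "unsupported session version")

  bad2 <- jsonlite::read_json(path)
  bad2$version <- NULL
  jsonlite::write_json(bad2, path_bad, auto_unbox = TRUE, null = "null")
  expect_error(load_session(path_bad), "version")

  bad3 <- jsonlite::read_json(path)
  bad3$records[[1]]$step1_grid$upper <- bad3$records[[1]]$step1_grid$lower - 1
  jsonlite::write_json(bad3, path_bad, auto_unbox = TRUE, null = "null")
  expect_error(load_session(path_bad), "exceed")

  expect_error(expert_panel(list(recs[[1]], recs[[1]]), total), "unique")
})
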