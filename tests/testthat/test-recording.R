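sorting_toy <- function(seed = 17) {
  make_cell_sorting_model(grid = c(20, 20), n_per_type = 3, target_volume = 9,
                          seed = seed)
}

test_that("reconstruction replays the live trajectory bit-exactly", {
  m <- sorting_toy()
  h <- cpm_run(m, 120, checkpoint_every = 50)
  expect_identical(reconstruct(h, 0)$cell_id, h$initial$cell_id)
  expect_identical(reconstruct(h, 120)$cell_id, h$final_state$cell_id)
  expect_identical(reconstruct(h, 120)$table, h$final_state$table)
  # interior states equal truncated reruns from the same seed
  for (mcs in c(7L, 49L, 50L, 51L, 113L)) {
    rerun <- cpm_run(m, mcs)
    expect_identical(reconstruct(h, mcs)$cell_id, rerun$final_state$cell_id,
                     label = paste("reconstruct at", mcs))
  }
  expect_error(reconstruct(h, 121), class = "cpm_range_error")
  expect_error(reconstruct(h, -1), class = "cpm_range_error")
})

test_that("reconstruction replays division events including the table", {
  m <- make_growing_population_model(grid = c(18, 18), founders = 1, alpha = 0.4,
                                     target_volume = 9, seed = 23)
  h <- cpm_run(m, 20, checkpoint_every = 7)
  expect_gt(glance(h)$n_divisions, 0)
  for (mcs in c(5L, 13L, 20L)) {
    rerun <- cpm_run(m, mcs)
    rec <- reconstruct(h, mcs)
    expect_identical(rec$cell_id, rerun$final_state$cell_id)
    expect_equal(rec$table$id, rerun$final_state$table$id)
  }
})

test_that("histories round-trip through the JSON container", {
  m <- sorting_toy()
  h <- cpm_run(m, 60, checkpoint_every = 25)
  path <- tempfile(fileext = ".history.json")
  save_history(h, path)
  h2 <- load_history(path)
  expect_identical(reconstruct(h2, 60)$cell_id, h$final_state$cell_id)
  expect_identical(reconstruct(h2, 31)$cell_id, reconstruct(h, 31)$cell_id)
  expect_equal(tidy(h2)$boundary_hetero_type, tidy(h)$boundary_hetero_type)

  expect_error(load_history(tempfile(fileext = ".json")), class = "cpm_load_error")
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something-else"), bad, auto_unbox = TRUE)
  expect_error(load_history(bad), class = "cpm_load_error")
})

test_that("delta storage stays far below per-MCS snapshots", {
  # recording cost tracks accepted flips, so a near-equilibrium simulation
  # (low temperature, relaxed cells) stores a small fraction of what
  # one-grid-copy-per-MCS would: the regime delta recording is built for
  sp <- cpm_space(c(30, 30), periodic = TRUE)
  st <- initialize_cells(sp, cell_table("A", 2, 25), seed = 1)
  J <- matrix(c(0, 8, 8, 4), 2, 2)
  m <- cpm_model(sp, st, list(adhesion_penalty(J), volume_penalty(5)),
                 cpm_params(temperature = 2, seed = 1))
  h <- cpm_run(m, 200, checkpoint_every = 0) # no checkpoints: pure deltas
  f <- tempfile(fileext = ".json")
  save_history(h, f)
  snap <- tempfile(fileext = ".json") # per-MCS full grids in the same format
  jsonlite::write_json(lapply(seq_len(200), function(i) h$initial$cell_id), snap)
  expect_lt(file.size(f), file.size(snap) / 3)
  # and the delta stream itself is linear in accepted flips (3 ints per flip)
  n_flips <- sum(vapply(h$deltas, nrow, integer(1)))
  expect_equal(sum(vapply(h$deltas, length, integer(1))), 3L * n_flips)
})

test_that("saved models reproduce their trajectory and survive edits", {
  m <- sorting_toy()
  path <- tempfile(fileext = ".model.json")
  save_model(m, path)
  m2 <- load_model(path)
  h1 <- cpm_run(m, 80)
  h2 <- cpm_run(m2, 80)
  expect_identical(h1$final_state$cell_id, h2$final_state$cell_id)
  expect_identical(h1$deltas, h2$deltas)

  # editing the temperature in the file changes the trajectory
  txt <- readLines(path, warn = FALSE)
  txt <- sub("\"temperature\":20", "\"temperature\":200", txt, fixed = TRUE)
  path3 <- tempfile(fileext = ".model.json")
  writeLines(txt, path3)
  m3 <- load_model(path3)
  expect_equal(m3$params$temperature, 200)
  h3 <- cpm_run(m3, 80)
  expect_false(identical(h1$final_state$cell_id, h3$final_state$cell_id))

  # an unknown penalty name is refused with a configuration error
  txt4 <- sub("\"kind\":\"adhesion\"", "\"kind\":\"antigravity\"", txt, fixed = TRUE)
  path4 <- tempfile(fileext = ".model.json")
  writeLines(txt4, path4)
  expect_error(load_model(path4), class = "cpm_config_error")
})

test_that("models with an ODE layer serialize by builtin name", {
  m <- make_growing_population_model(grid = c(16, 16), seed = 31,
                                     target_volume = 9, alpha = 0.5)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  h1 <- cpm_run(m, 15)
  h2 <- cpm_run(m2, 15)
  expect_identical(h1$final_state$cell_id, h2$final_state$cell_id)
  expect_equal(glance(h1)$n_divisions, glance(h2)$n_divisions)
})

test_that("summaries carry counts, volumes, and recountable boundaries", {
  sp <- cpm_space(c(12, 12), periodic = FALSE)
  st <- initialize_cells(sp, cell_table("A", 3, 9), seed = 2)
  m <- cpm_model(sp, st, list(volume_penalty(5)), cpm_params(seed = 2))
  h0 <- cpm_run(m, 0)
  s0 <- export_summary(h0)
  expect_equal(nrow(s0), 1L)
  expect_equal(s0$n_cells, 3L)

  h <- cpm_run(m, 50, checkpoint_every = 10)
  s <- export_summary(h)
  expect_equal(nrow(s), 51L)
  for (mcs in c(0L, 10L, 23L, 41L, 50L)) {
    st_m <- reconstruct(h, mcs)
    brute <- graphcpm:::boundary_lengths(sp, st_m)
    expect_equal(s$boundary_total[s$mcs == mcs], brute[["total"]],
                 label = paste("boundary at", mcs))
  }
  csv <- tempfile(fileext = ".csv")
  export_summary(h, csv)
  expect_true(file.exists(csv))
  expect_equal(nrow(utils::read.csv(csv)), 51L)
})

test_that("growing populations never lose cells in the count series", {
  m <- make_growing_population_model(grid = c(16, 16), target_volume = 9,
                                     alpha = 0.4, seed = 3)
  h <- cpm_run(m, 20)
  expect_true(all(diff(tidy(h)$n_cells) >= 0))
})

test_that("frames export as CSV and PNG", {
  m <- sorting_toy()
  h <- cpm_run(m, 5)
  csv <- tempfile(fileext = ".csv")
  export_frame(h, 5, csv)
  grid <- as.matrix(utils::read.csv(csv, header = FALSE))
  expect_equal(dim(grid), c(20L, 20L))
  expect_setequal(unique(sort(grid[grid > 0])), sort(h$final_state$table$id))
  pngf <- tempfile(fileext = ".png")
  export_frame(h, 0, pngf)
  img <- png::readPNG(pngf)
  expect_equal(dim(img)[1:2], c(20L, 20L))
})
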