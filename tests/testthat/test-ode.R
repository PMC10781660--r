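# a minimal one-cell world for driving the ODE layer directly
one_cell_world <- function(volume = 9, grid = c(8, 8)) {
  sp <- cpm_space(grid, periodic = FALSE)
  st <- initialize_cells(sp, cell_table("Cell", 1, volume, x = 2, y = 2))
  list(space = sp, state = st)
}

test_that("threshold events are located at the analytic crossing times", {
  w <- one_cell_world()
  intra <- intracellular_model(rhs_constant(0.1), init = 0,
                               events = list(ode_event(1, 1, "up", "divide")))
  xs <- graphcpm:::intracellular_init(intra, w$state)
  set.seed(1)
  out <- advance_with_events(w$space, w$state, intra, xs, 0, 20)
  expect_gte(length(out$events), 1L) # daughters may reach 1 again later
  expect_lt(abs(out$events[[1]]$time - 10), 1e-6)

  intra2 <- intracellular_model(rhs_exponential(1), init = 0.1,
                                events = list(ode_event(1, 1, "up", "divide")))
  xs2 <- graphcpm:::intracellular_init(intra2, w$state)
  set.seed(1)
  out2 <- advance_with_events(w$space, w$state, intra2, xs2, 0, 5)
  expect_lt(abs(out2$events[[1]]$time - log(10)), 1e-6)
})

test_that("a flat right-hand side never fires and states are exact", {
  w <- one_cell_world()
  intra <- intracellular_model(rhs_constant(0), init = 0.5,
                               events = list(ode_event(1, 1, "up", "divide")))
  xs <- graphcpm:::intracellular_init(intra, w$state)
  out <- advance_with_events(w$space, w$state, intra, xs, 0, 50)
  expect_length(out$events, 0L)
  expect_equal(out$intra_state[["1"]], 0.5, tolerance = 1e-9)
})

test_that("division events split the protein exactly and add a daughter", {
  # with dX/dt = alpha*X the population total obeys d(total)/dt = alpha*total
  # regardless of how many divisions occur: conservation at each division plus
  # linear dynamics make the total invariant to the event history
  w <- one_cell_world(volume = 12)
  intra <- intracellular_model(rhs_exponential(0.5), init = 0.5,
                               events = list(ode_event(1, 1, "up", "divide")))
  xs <- graphcpm:::intracellular_init(intra, w$state)
  set.seed(2)
  out <- advance_with_events(w$space, w$state, intra, xs, 0, 3)
  expect_gte(length(out$events), 1L)
  expect_lt(abs(out$events[[1]]$time - log(2) / 0.5), 1e-6)
  expect_equal(nrow(out$state$table), length(out$intra_state))
  expect_equal(sum(unlist(out$intra_state)), 0.5 * exp(0.5 * 3),
               tolerance = 1e-6)
})

test_that("on_division_event conserves flagged components and copies others", {
  intra <- intracellular_model(rhs_constant(0), n_components = 2,
                               init = c(1, 3), conserved = c(TRUE, FALSE))
  xs <- list("5" = c(1, 3))
  set.seed(3)
  xs2 <- on_division_event(intra, xs, 5L, c(5L, 9L))
  expect_setequal(names(xs2), c("5", "9"))
  expect_identical(xs2[["5"]][1] + xs2[["9"]][1], 1)
  expect_identical(xs2[["5"]][2], 3)
  expect_identical(xs2[["9"]][2], 3)
})

test_that("simultaneous-interval events fire in time order", {
  sp <- cpm_space(c(10, 10), periodic = FALSE)
  st <- initialize_cells(sp, cell_table(c("A", "A"), 1, 9,
                                        x = c(0, 6), y = c(0, 6)))
  intra <- intracellular_model(rhs_constant(0.1),
                               events = list(ode_event(1, 1, "up", "divide")))
  xs <- list("1" = 0.8, "2" = 0.5) # crossings at t = 2 and t = 5
  set.seed(4)
  out <- advance_with_events(sp, st, intra, xs, 0, 10)
  expect_gte(length(out$events), 2L)
  times <- vapply(out$events, function(e) unname(e$time), numeric(1))
  parents <- vapply(out$events, function(e) e$parent, integer(1))
  expect_equal(times, sort(times)) # fired in time order
  expect_equal(times[1], 2, tolerance = 1e-5)
  expect_equal(parents[1], 1L)
  hit2 <- which(parents == 2L)[1] # cell 2 fires at its own crossing time
  expect_equal(times[hit2], 5, tolerance = 1e-5)
})

test_that("divisions defer when the cell is one site and re-arm later", {
  sp <- cpm_space(c(6, 6), periodic = FALSE)
  st <- initialize_cells(sp, cell_table("A", 1, 1, x = 2, y = 2))
  intra <- intracellular_model(rhs_constant(0.5), init = 0.9,
                               events = list(ode_event(1, 1, "up", "divide")))
  xs <- graphcpm:::intracellular_init(intra, st)
  set.seed(5)
  out <- advance_with_events(sp, st, intra, xs, 0, 2)
  expect_length(out$events, 0L)           # too small: deferred
  expect_gt(out$intra_state[["1"]], 1)    # protein retained past threshold
  # the cell grows; the deferred event fires immediately on the next advance
  node2 <- space_neighbors(sp, which(out$state$cell_id == 1L))[1]
  st2 <- out$state
  st2$cell_id[node2] <- 1L
  st2 <- recompute_statistics(sp, st2)
  out2 <- advance_with_events(sp, st2, intra, out$intra_state, 2, 2.01)
  expect_length(out2$events, 1L)
  expect_equal(nrow(out2$state$table), 2L)
})

test_that("tightening the tolerance moves event times by less than the coarse one", {
  w <- one_cell_world()
  t_true <- log(5) / 0.7
  t_at <- function(rtol) {
    intra <- intracellular_model(rhs_exponential(0.7), init = 0.2, rtol = rtol,
                                 atol = rtol * 1e-3,
                                 events = list(ode_event(1, 1, "up", "divide")))
    xs <- graphcpm:::intracellular_init(intra, w$state)
    set.seed(6)
    unname(advance_with_events(w$space, w$state, intra, xs, 0, 10)$events[[1]]$time)
  }
  # error controlled relative to the solution scale: rtol * t is the budget
  expect_lt(abs(t_at(1e-5) - t_true), 1e-5 * t_true * 2)
  expect_lt(abs(t_at(1e-8) - t_true), 1e-6)
  expect_lt(abs(t_at(1e-5) - t_at(1e-8)), 1e-5 * t_true * 2)
})

test_that("non-finite derivatives fail loudly naming the cell", {
  w <- one_cell_world()
  intra <- intracellular_model(function(t, x, cell) NaN, init = 1)
  xs <- graphcpm:::intracellular_init(intra, w$state)
  expect_error(advance_with_events(w$space, w$state, intra, xs, 0, 1),
               class = "cpm_integration_failure")
})

test_that("growing-population runs couple grid, table, and protein layers", {
  m <- make_growing_population_model(grid = c(20, 20), founders = 1, alpha = 0.3,
                                     target_volume = 16, seed = 7)
  h <- cpm_run(m, 25)
  s <- tidy(h)
  expect_true(all(diff(s$n_cells) >= 0)) # no death in this fixture
  expect_gt(utils::tail(s$n_cells, 1), 1)
  # protein is conserved across each division instant
  g <- glance(h)
  expect_gt(g$n_divisions, 0)
  expect_false(is.null(h$ode_trace))
})
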