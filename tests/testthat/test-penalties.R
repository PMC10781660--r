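test_that("zero-weight penalties contribute nothing", {
  sp <- grid8()
  set.seed(1)
  st <- random_two_type_state(sp)
  prop <- random_proposal(sp, st)
  expect_equal(penalty_delta(adhesion_penalty(matrix(0, 3, 3)), sp, st, prop), 0)
  expect_equal(penalty_delta(volume_penalty(0), sp, st, prop), 0)
  expect_equal(penalty_delta(perimeter_penalty(0), sp, st, prop), 0)
  expect_equal(penalty_delta(migration_penalty(0), sp, st, prop), 0)
  expect_equal(penalty_delta(chemotaxis_penalty(0, rep(1, sp$n_nodes)), sp, st, prop), 0)
})

test_that("removing an isolated one-node cell releases all its contacts", {
  # von Neumann interaction so the cell has exactly 4 heterotypic contacts
  sp <- cpm_space(c(5, 5), periodic = FALSE, interaction_order = "von_neumann")
  tab <- cell_table("A", 1, 1)
  cell_id <- integer(25)
  center <- graphcpm:::coord_to_node(sp, matrix(c(2L, 2L), 1))
  cell_id[center] <- 1L
  st <- recompute_statistics(sp, graphcpm:::new_cpm_state(cell_id, tab))
  J <- matrix(c(0, 2, 2, 0), 2, 2)
  prop <- cpm_proposal(center, space_neighbors(sp, center)[1], 1L, 0L)
  expect_equal(penalty_delta(adhesion_penalty(J), sp, st, prop), -8)
})

test_that("volume delta matches the quadratic form at the boundary cases", {
  sp <- cpm_space(c(6, 6), periodic = FALSE)
  tab <- cell_table("A", 1, 5)
  cell_id <- integer(36)
  cell_id[c(8, 9, 10, 14, 15)] <- 1L
  st <- recompute_statistics(sp, graphcpm:::new_cpm_state(cell_id, tab))
  expect_equal(st$volume[1], 5L)
  shrink <- cpm_proposal(8L, 7L, 1L, 0L)
  grow <- cpm_proposal(16L, 15L, 0L, 1L)
  pen <- volume_penalty(1)
  expect_equal(penalty_delta(pen, sp, st, shrink), 1) # (4-5)^2 - 0
  expect_equal(penalty_delta(pen, sp, st, grow), 1)   # symmetric
})

test_that("local deltas equal full-Hamiltonian differences on random states", {
  sp <- grid8()
  J <- matrix(c(0, 3, 5,
                3, 1, 7,
                5, 7, 2), 3, 3, byrow = TRUE)
  set.seed(42)
  for (rep in 1:60) {
    st <- random_two_type_state(sp)
    prop <- random_proposal(sp, st)
    if (is.null(prop)) next
    after <- flip_and_recompute(sp, st, prop)
    expect_equal(penalty_delta(adhesion_penalty(J), sp, st, prop),
                 full_H_adhesion(sp, after, J) - full_H_adhesion(sp, st, J),
                 tolerance = 1e-12)
    expect_equal(penalty_delta(volume_penalty(c(2, 3)), sp, st, prop),
                 full_H_volume(after, c(2, 3)) - full_H_volume(st, c(2, 3)),
                 tolerance = 1e-12)
    expect_equal(penalty_delta(perimeter_penalty(0.5), sp, st, prop),
                 full_H_perimeter(sp, after, 0.5) - full_H_perimeter(sp, st, 0.5),
                 tolerance = 1e-12)
  }
})

test_that("adhesion delta is zero for a same-id flip and errors outside J", {
  sp <- grid8()
  set.seed(7)
  st <- random_two_type_state(sp)
  u <- which(st$cell_id == 1L)[1]
  prop_same <- cpm_proposal(u, u, 1L, 1L)
  J <- matrix(1, 3, 3)
  expect_equal(penalty_delta(adhesion_penalty(J), sp, st, prop_same), 0)
  prop <- random_proposal(sp, st)
  expect_error(penalty_delta(adhesion_penalty(matrix(0, 1, 1)), sp, st, prop),
               class = "cpm_config_error")
})

test_that("perimeter penalty demands a target for weighted cells", {
  sp <- cpm_space(c(6, 6), periodic = FALSE)
  tab <- cell_table("A", 1, 4) # no target_perimeter
  st <- initialize_cells(sp, tab, seed = 3)
  prop <- random_proposal(sp, st)
  expect_error(penalty_delta(perimeter_penalty(1), sp, st, prop),
               class = "cpm_config_error")
})

test_that("migration delta vanishes for flat activity landscapes", {
  sp <- cpm_space(c(6, 6), periodic = TRUE)
  st <- initialize_cells(sp, cell_table("A", 2, 4), seed = 2)
  pen <- migration_penalty(10, max_act = 5)
  prop <- random_proposal(sp, st)
  expect_equal(penalty_delta(pen, sp, st, prop), 0) # all activities zero
  # uniform positive activity: geometric means cancel for cell-cell flips
  st$activity <- rep(3, sp$n_nodes)
  cells <- which(st$cell_id > 0)
  pair <- NULL
  for (u in cells) {
    nb <- space_neighbors(sp, u)
    v <- nb[st$cell_id[nb] > 0 & st$cell_id[nb] != st$cell_id[u]]
    if (length(v)) { pair <- c(u, v[1]); break }
  }
  if (!is.null(pair)) {
    prop2 <- cpm_proposal(pair[1], pair[2], st$cell_id[pair[1]], st$cell_id[pair[2]])
    expect_equal(penalty_delta(pen, sp, st, prop2), 0)
  }
})

test_that("migration activity marks gained sites and decays per MCS", {
  sp <- cpm_space(c(6, 6), periodic = TRUE)
  st <- initialize_cells(sp, cell_table("A", 1, 4), seed = 4)
  pen <- migration_penalty(1, max_act = 7)
  prop <- random_proposal(sp, st)
  gained <- graphcpm:::penalty_after_accept(pen, sp, st, prop)
  expect_equal(gained$activity[prop$target], if (prop$new_id > 0) 7 else 0)
  decayed <- graphcpm:::penalties_end_mcs(list(pen), gained)
  expect_equal(decayed$activity[prop$target], max(gained$activity[prop$target] - 1, 0))
})

test_that("chemotaxis favors up-gradient extensions under positive weight", {
  sp <- cpm_space(c(6, 6), periodic = FALSE)
  st <- initialize_cells(sp, cell_table("A", 1, 4, x = 2, y = 2), seed = 1)
  field <- sp$coords[, 2] # increases along the second axis
  pen <- chemotaxis_penalty(2, field)
  cells <- which(st$cell_id == 1L)
  # extension proposal moving right (up-gradient)
  for (u in cells) {
    nb <- space_neighbors(sp, u)
    tgt <- nb[st$cell_id[nb] == 0L & sp$coords[nb, 2] > sp$coords[u, 2]]
    if (length(tgt)) {
      prop <- cpm_proposal(tgt[1], u, 0L, 1L)
      expect_lt(penalty_delta(pen, sp, st, prop), 0)
      break
    }
  }
  # uniform field: no drive
  expect_equal(penalty_delta(chemotaxis_penalty(2, rep(5, sp$n_nodes)), sp, st,
                             cpm_proposal(1L, 2L, 0L, 1L)), 0)
  expect_error(chemotaxis_penalty(1, c(Inf, rep(0, 35))), class = "cpm_config_error")
})

test_that("total_delta is additive and order-independent", {
  sp <- grid8()
  set.seed(9)
  st <- random_two_type_state(sp)
  prop <- random_proposal(sp, st)
  J <- matrix(c(0, 2, 4, 2, 1, 6, 4, 6, 1), 3, 3)
  pens <- list(adhesion_penalty(J), volume_penalty(2),
               perimeter_penalty(0.3))
  expect_equal(total_delta(list(), sp, st, prop), 0)
  expect_identical(total_delta(pens, sp, st, prop),
                   penalty_delta(pens[[1]], sp, st, prop) +
                     penalty_delta(pens[[2]], sp, st, prop) +
                     penalty_delta(pens[[3]], sp, st, prop))
  expect_identical(total_delta(pens, sp, st, prop),
                   total_delta(rev(pens), sp, st, prop))
})

test_that("custom penalties plug into stepping with their after_accept hook", {
  sp <- cpm_space(c(6, 6), periodic = TRUE)
  st <- initialize_cells(sp, cell_table("A", 2, 4), seed = 6)
  hits <- new.env()
  hits$n <- 0L
  pen <- custom_penalty(
    delta = function(space, state, proposal) -100, # always favorable
    after_accept = function(space, state, proposal) {
      hits$n <- hits$n + 1L
      state
    })
  set.seed(1)
  out <- cpm_step(sp, st, list(pen), temperature = 1)
  expect_true(out$accepted || out$vetoed)
  expect_equal(hits$n, as.integer(out$accepted))
})
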