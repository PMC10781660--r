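test_that("acceptance probability follows the Boltzmann rule", {
  expect_equal(accept_probability(-3, 0.5), 1)
  expect_equal(accept_probability(0, 10), 1)
  expect_equal(accept_probability(7 * log(2), 7), 0.5)
  expect_error(accept_probability(1, 0), class = "cpm_parameter_error")
  expect_error(cpm_params(temperature = -1), class = "cpm_parameter_error")
})

test_that("proposals come from heterotypic boundary edges only", {
  sp <- cpm_space(c(4, 4), periodic = FALSE)
  tab <- cell_table("A", 1, 1)
  # uniform grid: nothing to propose
  st0 <- recompute_statistics(sp, graphcpm:::new_cpm_state(integer(16), tab))
  expect_null(propose(sp, st0))

  # exactly one heterotypic edge: an isolated corner pair
  mask <- matrix(FALSE, 4, 4); mask[1, 1:2] <- TRUE
  spm <- cpm_space_from_mask(mask)
  stm <- recompute_statistics(spm, graphcpm:::new_cpm_state(c(1L, 0L), tab))
  set.seed(1)
  for (k in 1:20) {
    prop <- propose(spm, stm)
    expect_setequal(c(prop$target, prop$source), c(1L, 2L))
    expect_true(prop$old_id != prop$new_id)
  }
})

test_that("proposal sampling is uniform over heterotypic edges", {
  sp <- cpm_space(c(6, 6), periodic = TRUE)
  st <- initialize_cells(sp, cell_table(c("A", "B"), 1, 4,
                                        x = c(0, 3), y = c(0, 3)), seed = 1)
  conn_from <- rep.int(seq_len(sp$n_nodes), diff(sp$conn_ptr))
  het <- which(st$cell_id[conn_from] != st$cell_id[sp$conn_idx])
  n_slots <- length(het)
  set.seed(99)
  n_draw <- 10000L
  counts <- integer(n_slots)
  key <- paste(conn_from[het], sp$conn_idx[het])
  for (k in seq_len(n_draw)) {
    p <- propose(sp, st)
    counts[match(paste(p$target, p$source), key)] <-
      counts[match(paste(p$target, p$source), key)] + 1L
  }
  p0 <- 1 / n_slots
  se <- sqrt(p0 * (1 - p0) / n_draw)
  expect_true(all(abs(counts / n_draw - p0) < 4 * se))
})

test_that("the guard classifies simple shapes correctly", {
  sp <- cpm_space(c(5, 5), periodic = FALSE)
  tab <- cell_table("A", 1, 3)
  # path cell a-b-c along a row
  cell_id <- integer(25)
  nodes <- graphcpm:::coord_to_node(sp, cbind(2L, 0:2))
  cell_id[nodes] <- 1L
  st <- recompute_statistics(sp, graphcpm:::new_cpm_state(cell_id, tab))
  expect_false(is_safe_removal(sp, st, nodes[2])) # middle disconnects
  expect_true(is_safe_removal(sp, st, nodes[1]))  # end is a leaf
  expect_true(is_safe_removal(sp, st, nodes[3]))
  expect_error(is_safe_removal(sp, st, which(cell_id == 0L)[1]),
               class = "cpm_contract_violation")

  # 2x2 block: everything removable; a 1-node cell is not
  st2 <- initialize_cells(sp, cell_table("A", 1, 4, x = 1, y = 1))
  for (u in which(st2$cell_id == 1L)) expect_true(is_safe_removal(sp, st2, u))
  st3 <- initialize_cells(sp, cell_table("A", 1, 1, x = 2, y = 2))
  expect_false(is_safe_removal(sp, st3, which(st3$cell_id == 1L)))
  expect_equal(local_topology_check(sp, st3, which(st3$cell_id == 1L)), "unsafe")
})

test_that("the local fast path never contradicts the exact oracle (ring patterns)", {
  sp <- cpm_space(c(5, 5), periodic = FALSE)
  center <- graphcpm:::coord_to_node(sp, matrix(c(2L, 2L), 1))
  ring <- space_neighbors(sp, center, "interaction")
  tab <- cell_table("A", 1, 1)
  n_checked <- 0L
  for (pattern in 0:(2^8 - 1)) {
    members <- ring[bitwAnd(pattern, 2^(0:7)) > 0]
    # the guard's contract presumes a connected cell (the only states the
    # dynamics can reach), so only connected embeddings are in scope
    if (oracle_components(sp, c(center, members)) != 1L) next
    n_checked <- n_checked + 1L
    cell_id <- integer(25)
    cell_id[c(center, members)] <- 1L
    st <- recompute_statistics(sp, graphcpm:::new_cpm_state(cell_id, tab))
    verdict <- local_topology_check(sp, st, center)
    rest <- members
    if (verdict == "safe") {
      expect_true(length(rest) > 0 && oracle_components(sp, rest) == 1L,
                  label = paste("pattern", pattern, "safe but disconnects"))
    } else if (verdict == "unsafe") {
      expect_true(length(rest) == 0 || oracle_components(sp, rest) != 1L,
                  label = paste("pattern", pattern, "unsafe but stays connected"))
    }
    # and the combined decision always matches the oracle
    expect_equal(is_safe_removal(sp, st, center),
                 length(rest) > 0 && oracle_components(sp, rest) == 1L,
                 label = paste("pattern", pattern))
  }
  expect_gt(n_checked, 100L) # the enumeration really covers many patterns
})

test_that("guard decisions agree with the igraph articulation oracle on blobs", {
  for (seed in 1:120) {
    blob <- make_random_blob(sample(8:25, 1), seed = seed)
    sp <- blob$space
    tab <- cell_table("A", 1, length(blob$nodes))
    cell_id <- integer(sp$n_nodes)
    cell_id[blob$nodes] <- 1L
    st <- recompute_statistics(sp, graphcpm:::new_cpm_state(cell_id, tab))
    for (u in blob$nodes) {
      rest <- setdiff(blob$nodes, u)
      truth <- length(rest) > 0 && oracle_components(sp, rest) == 1L
      expect_equal(is_safe_removal(sp, st, u), truth,
                   label = paste("blob", seed, "node", u))
    }
  }
})

test_that("vetoed steps leave the state untouched", {
  sp <- cpm_space(c(5, 5), periodic = FALSE)
  tab <- cell_table("A", 1, 3)
  cell_id <- integer(25)
  nodes <- graphcpm:::coord_to_node(sp, cbind(2L, 0:2))
  cell_id[nodes] <- 1L
  st <- recompute_statistics(sp, graphcpm:::new_cpm_state(cell_id, tab))
  set.seed(2)
  for (k in 1:50) {
    out <- cpm_step(sp, st, list(), temperature = 5)
    if (out$vetoed) {
      expect_identical(out$state$cell_id, st$cell_id)
      expect_false(out$accepted)
    }
  }
})

test_that("strongly favorable guard-safe flips are always accepted", {
  sp <- cpm_space(c(6, 6), periodic = TRUE)
  st <- initialize_cells(sp, cell_table("A", 1, 4), seed = 8)
  pen <- custom_penalty(function(space, state, proposal) -1000)
  set.seed(3)
  acc <- 0L
  tries <- 0L
  for (k in 1:50) {
    out <- cpm_step(sp, st, list(pen), temperature = 10)
    if (!out$vetoed) {
      tries <- tries + 1L
      acc <- acc + as.integer(out$accepted)
    }
  }
  expect_equal(acc, tries)
})

test_that("runs are reproducible and n_mcs = 0 records only the start", {
  m <- make_cell_sorting_model(grid = c(16, 16), n_per_type = 2,
                               target_volume = 9, seed = 21)
  h0 <- cpm_run(m, 0)
  expect_equal(h0$n_mcs, 0L)
  expect_equal(nrow(tidy(h0)), 1L)
  expect_identical(h0$final_state$cell_id, h0$initial$cell_id)

  h1 <- cpm_run(m, 40)
  h2 <- cpm_run(m, 40)
  expect_identical(h1$deltas, h2$deltas)
  expect_identical(h1$final_state$cell_id, h2$final_state$cell_id)
  expect_identical(tidy(h1), tidy(h2))
})

test_that("interpreted and compiled paths both keep cells whole", {
  # custom no-op penalty forces the interpreted path
  m <- make_cell_sorting_model(grid = c(14, 14), n_per_type = 2,
                               target_volume = 9, seed = 13)
  m_custom <- cpm_model(m$space, m$state,
                        c(m$penalties, list(custom_penalty(function(...) 0))),
                        m$params)
  h <- cpm_run(m_custom, 5)
  expect_no_fragmentation(m$space, h, every = 1L)
  h2 <- cpm_run(m, 30)
  expect_no_fragmentation(m$space, h2, every = 10L)
})
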