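hex_state <- function(...) {
  simulation_state(hexagon_fixture(), behavior_config(...))
}

agent_xy <- function(state, id) {
  i <- match(id, state$agents$id)
  c(state$agents$x[i], state$agents$y[i], if (state$dim == 3L) state$agents$z[i])
}

test_that("act_move: bounds, zero step, deterministic bias limit, inert media", {
  st <- hex_state(types = list(lec = list(step_length = 0.1)))
  for (rep in 1:20) {
    before <- agent_xy(st, 1L)
    st <- act_move(st, 1L)
    after <- agent_xy(st, 1L)
    expect_lte(sqrt(sum((after - before)^2)), 0.1 + 1e-12)
  }

  st0 <- hex_state(types = list(lec = list(step_length = 0)))
  st1 <- act_move(st0, 1L)
  expect_identical(st1$agents[, c("x", "y")], st0$agents[, c("x", "y")])
  expect_identical(utils::tail(st1$events$event, 1L), "move")

  stb <- hex_state(types = list(lec = list(step_length = 0.25, noise_weight = 0,
                                           bias = c(1, 0))))
  p0 <- agent_xy(stb, 1L)
  stb <- act_move(stb, 1L)
  expect_equal(agent_xy(stb, 1L), p0 + c(0.25, 0), tolerance = 1e-12)

  media_id <- st$agents$id[st$agents$type == "media"][1L]
  expect_error(act_move(st, media_id), class = "vcellsim_inert_agent")
  expect_error(act_move(st, 9999L), class = "vcellsim_unknown_agent")
})

test_that("act_move rejects a displacement landing on another center", {
  # deterministic biased step of exactly the gap lands on neighbor 2
  hx <- hexagon_fixture()
  gap <- sqrt(sum((hx[2, c("x", "y")] - hx[1, c("x", "y")])^2))
  st <- simulation_state(hx, behavior_config(
    types = list(lec = list(step_length = gap, noise_weight = 0, bias = c(1, 0)))))
  before <- st$agents[, c("x", "y")]
  st <- act_move(st, 1L)
  expect_identical(st$agents[, c("x", "y")], before)
  expect_identical(utils::tail(st$events$event, 1L), "move_rejected")
})

test_that("act_grow: no-op at target, pushes neighbors out, hexagon regression", {
  st <- hex_state()
  m0 <- vcell_measure(st$mesh, 1L)
  st1 <- act_grow(st, 1L, target = m0)
  expect_identical(st1$agents[, c("x", "y")], st$agents[, c("x", "y")])

  target <- 1.5 * m0
  d_before <- vapply(2:7, function(id) sqrt(sum(agent_xy(st, id)^2)), 1.0)
  stg <- act_grow(st, 1L, target = target)
  d_after <- vapply(2:7, function(id) sqrt(sum(agent_xy(stg, id)^2)), 1.0)
  expect_true(all(d_after > d_before))
  expect_equal(agent_xy(stg, 1L), c(0, 0), tolerance = 0)  # grower fixed
  m1 <- vcell_measure(stg$mesh, 1L)
  expect_gte(m1, target)
  expect_lt(m1 / target - 1, 0.05)
  # regression: convergence in 11 push iterations with the default increments
  expect_match(utils::tail(stg$events$detail, 1L), "iters=11")
})

test_that("act_grow decisions are local (independent of far environment)", {
  hx_a <- hexagon_fixture()
  extra <- vcellsim:::.ring_points(12L, 16)
  hx_b <- rbind(hx_a, data.frame(id = 100 + seq_len(12L), type = "media",
                                 x = extra[, 1], y = extra[, 2], z = NA_real_,
                                 info = NA_character_))
  sa <- act_grow(simulation_state(hx_a, behavior_config()), 1L,
                 target = 1.5 * 2 * sqrt(3))
  sb <- act_grow(simulation_state(hx_b, behavior_config()), 1L,
                 target = 1.5 * 2 * sqrt(3))
  ra <- sa$agents[sa$agents$id %in% 1:7, c("x", "y")]
  rb <- sb$agents[sb$agents$id %in% 1:7, c("x", "y")]
  expect_identical(ra, rb)
})

test_that("act_divide: bookkeeping, inheritance, placement distance", {
  st <- hex_state(types = list(lec = list(step_length = 0.1)))
  n0 <- sum(st$agents$alive)
  t0 <- st$agents$target_size[1L]
  st <- act_divide(st, 1L)
  expect_identical(sum(st$agents$alive), n0 + 1L)
  d_row <- which(st$agents$lineage == 1L)
  expect_length(d_row, 1L)
  expect_identical(st$agents$type[d_row], "lec")
  expect_equal(st$agents$target_size[d_row], t0 / 2)
  expect_equal(st$agents$target_size[1L], t0 / 2)
  expect_identical(st$agents$step_length[d_row], 0.1)
  eps_div <- 0.1 * 0.1  # eps_div_frac * step_length
  gap <- sqrt(sum((agent_xy(st, st$agents$id[d_row]) - agent_xy(st, 1L))^2))
  expect_equal(gap, eps_div, tolerance = 1e-12)
  expect_error(act_divide(st, st$agents$id[st$agents$type == "media"][1L]),
               class = "vcellsim_inert_agent")
})

test_that("act_remove: passive conservation and lambda_fill drift", {
  st <- hex_state()
  areas0 <- vapply(1:7, function(id) vcell_measure(st$mesh, id), 1.0)
  st1 <- act_remove(st, 1L, lambda_fill = 0)
  expect_false(1L %in% st1$mesh$ids)
  for (id in 2:7) expect_false(1L %in% neighbors(st1$mesh, id))
  areas1 <- vapply(2:7, function(id) vcell_measure(st1$mesh, id), 1.0)
  expect_equal(sum(areas1), sum(areas0), tolerance = 1e-6)

  st2 <- act_remove(st, 1L, lambda_fill = 0.5)
  d <- vapply(2:7, function(id) sqrt(sum(agent_xy(st2, id)^2)), 1.0)
  expect_equal(d, rep(1, 6L), tolerance = 1e-12)  # ring at 2 halves to 1
  expect_error(act_remove(st1, 1L), class = "vcellsim_unknown_agent")
})

test_that("act_absorb: immediate completion, cyst capture terminates", {
  # the hexagon center is already enclosed by its ring
  st <- hex_state(types = list(lec = list(step_length = 0.1)))
  p0 <- agent_xy(st, 1L)
  st1 <- act_absorb(st, absorber_ids = 2:7, target_id = 1L)
  expect_identical(agent_xy(st1, 1L), p0)
  expect_match(st1$agents$group[1L], "absorbed:2")
  expect_error(act_absorb(st, integer(), 1L), class = "vcellsim_invalid_input")

  # outlying mec drawn into a 2D cyst
  scen <- generate_cyst(2L)
  out_id <- max(scen$id) + 1L
  scen <- rbind(scen, data.frame(id = out_id, type = "mec", x = 4.4, y = 0.4,
                                 z = NA_real_, info = NA_character_))
  st2 <- simulation_state(scen, behavior_config(
    types = list(mec = list(step_length = 0.15))))
  absorbers <- st2$agents$id[st2$agents$type %in% c("lmn", "lec")]
  st2 <- act_absorb(st2, absorbers, out_id)
  iters <- as.integer(sub("iters=", "", utils::tail(st2$events$detail, 1L)))
  expect_lt(iters, 500L)
  nb <- neighbors(st2$mesh, out_id)
  nb_type <- st2$agents$type[match(nb, st2$agents$id)]
  expect_true(all(nb[nb_type != "media"] %in% absorbers))
})

test_that("act_rotate: exact quarter turn, rigidity, full revolution, 3D refusal", {
  st <- hex_state()
  p2 <- agent_xy(st, 2L)   # ring agent at (2, 0)
  st1 <- act_rotate(st, group_ids = 2:7, pivot_id = 1L, theta = pi / 2)
  expect_equal(agent_xy(st1, 2L), c(-p2[2L], p2[1L]), tolerance = 1e-12)

  dist0 <- dist(st$agents[1:7, c("x", "y")])
  expect_equal(as.numeric(dist(st1$agents[1:7, c("x", "y")])),
               as.numeric(dist0), tolerance = 1e-9)

  stk <- st
  for (k in 1:12) stk <- act_rotate(stk, 2:7, 1L, theta = 2 * pi / 12)
  expect_equal(as.matrix(stk$agents[2:7, c("x", "y")]),
               as.matrix(st$agents[2:7, c("x", "y")]), tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(act_rotate(st, c(1L, 2L), 1L, pi), class = "vcellsim_invalid_input")
  scen3 <- generate_cyst(3L, n_lec = 8L, n_mec = 12L, n_media = 48L)
  st3 <- simulation_state(scen3, behavior_config())
  lec3 <- st3$agents$id[st3$agents$type == "lec"]
  expect_error(act_rotate(st3, lec3, 1L, pi / 6),
               class = "vcellsim_unsupported_dimension")
})

test_that("media centers are immutable across behavior sequences", {
  st <- hex_state(types = list(lec = list(step_length = 0.05)))
  med0 <- st$agents[st$agents$type == "media", c("x", "y")]
  st <- act_move(st, 1L)
  st <- act_grow(st, 1L, target = 1.2 * vcell_measure(st$mesh, 1L))
  st <- act_divide(st, 2L)
  st <- act_remove(st, 3L, lambda_fill = 0.3)
  st <- act_rotate(st, c(4L, 5L), 1L, pi / 7)
  expect_identical(st$agents[st$agents$type == "media", c("x", "y")], med0)
})
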