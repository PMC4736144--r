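test_that("simulation_state merges config into agents and validates enclosure", {
  scen <- generate_cyst(2L)
  cfg <- behavior_config(types = list(lec = list(step_length = 0.07,
                                                 target_factor = 1.2)))
  st <- simulation_state(scen, cfg)
  lec <- st$agents[st$agents$type == "lec", ]
  expect_true(all(lec$step_length == 0.07))
  m0 <- vapply(lec$id, function(id) vcell_measure(st$mesh, id), 1.0)
  expect_equal(lec$target_size, 1.2 * m0, tolerance = 1e-12)
  expect_true(all(st$agents$step_length[st$agents$type == "media"] == 0))

  # a biological agent outside the media enclosure is refused loudly
  bad <- rbind(scen, data.frame(id = 99L, type = "lec", x = 30, y = 0,
                                z = NA_real_, info = NA_character_))
  expect_error(simulation_state(bad, cfg),
               class = "vcellsim_enclosure_violation")
})

test_that("config validation and YAML round trip", {
  expect_error(behavior_config(types = list(lec = list(program = "fly"))),
               class = "vcellsim_invalid_input")
  expect_error(behavior_config(types = list(media = list(program = "move"))),
               class = "vcellsim_invalid_input")
  cfg <- behavior_config(steps = 7L, seed = 3L,
                         types = list(lec = list(program = c("move", "divide"),
                                                 step_length = 0.03,
                                                 division_factor = 1.4),
                                      mec = list(program = "move",
                                                 bias = c(0, 1))),
                         theta = pi / 5, lambda_fill = 0.25)
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2, cfg)
  expect_error(read_config(tempfile()), class = "vcellsim_parse_error")
})

test_that("empty programs leave the state unchanged apart from the step index", {
  st <- simulation_state(generate_cyst(2L), behavior_config())
  st1 <- sim_step(st)
  expect_identical(st1$agents, st$agents)
  expect_identical(st1$step_index, st$step_index + 1L)
})

test_that("identical seeds give identical trajectories; different seeds diverge", {
  cfg <- behavior_config(steps = 5L, seed = 11L,
                         types = list(lec = list(program = "move", step_length = 0.04),
                                      mec = list(program = "move", step_length = 0.04)))
  scen <- generate_cyst(2L)
  t1 <- sim_run(cfg, scen)
  t2 <- sim_run(cfg, scen)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$final_state$agents, t2$final_state$agents)

  diverged <- 0L
  for (s in c(1L, 2L, 3L)) {
    cfg_a <- behavior_config(steps = 5L, seed = s,
                             types = list(lec = list(program = "move", step_length = 0.04)))
    cfg_b <- behavior_config(steps = 5L, seed = s + 100L,
                             types = list(lec = list(program = "move", step_length = 0.04)))
    ta <- sim_run(cfg_a, scen); tb <- sim_run(cfg_b, scen)
    if (!isTRUE(all.equal(ta$final_state$agents$x, tb$final_state$agents$x)))
      diverged <- diverged + 1L
  }
  expect_identical(diverged, 3L)
})

test_that("steps = 0 records only the initial state", {
  tr <- sim_run(behavior_config(steps = 0L), generate_cyst(2L))
  expect_identical(nrow(tr$summaries), 1L)
  expect_identical(tr$summaries$step, 0L)
})

test_that("checkpoint round trip is field-identical and resume-equivalent", {
  cfg <- behavior_config(steps = 20L, seed = 5L,
                         types = list(lec = list(program = c("move", "divide"),
                                                 step_length = 0.03,
                                                 division_factor = 1.25),
                                      mec = list(program = "move", step_length = 0.03)))
  scen <- generate_cyst(2L)
  st <- simulation_state(scen, cfg)
  for (k in 1:10) st <- sim_step(st)
  path <- tempfile(fileext = ".json")
  checkpoint_save(st, path)
  st2 <- checkpoint_load(path)
  expect_identical(st2$agents, st$agents)
  expect_identical(st2$step_index, st$step_index)
  expect_identical(st2$rng_state, st$rng_state)
  expect_equal(st2$config, st$config)
  expect_identical(st2$events, st$events)

  # resume 10 more steps vs 20 uninterrupted
  full <- sim_run(cfg, scen)
  resumed <- sim_run(cfg, st2)
  expect_identical(resumed$final_state$agents, full$final_state$agents)
  expect_identical(resumed$final_state$events, full$final_state$events)

  # corruption is a classed error, not a crash
  writeLines(substr(paste(readLines(path), collapse = ""), 1, 50),
             path2 <- tempfile())
  expect_error(checkpoint_load(path2), class = "vcellsim_checkpoint_format")
  writeLines('{"format": "something-else", "version": 1}', path3 <- tempfile())
  expect_error(checkpoint_load(path3), class = "vcellsim_checkpoint_format")
})

test_that("agent counts change only through division and removal", {
  tr <- run_demo("cyst2d", steps = 25L, seed = 3L)
  ev <- tr$events
  n0 <- tr$summaries$n_total[1L]
  n1 <- utils::tail(tr$summaries$n_total, 1L)
  expect_identical(n1, n0 + sum(ev$event == "divide") - sum(ev$event == "remove"))
  # media count constant
  expect_true(all(tr$summaries$n_media == tr$summaries$n_media[1L]))
})
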