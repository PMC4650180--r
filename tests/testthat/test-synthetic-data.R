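# Synthetic-data generator: determinism, degenerate channels, group
# structure and distributional fidelity.

test_that("identical config and seed reproduce identical outputs", {
  cfg <- tiny_sim_config(seed = 11)
  a <- simulate_encounter_histories(cfg)
  b <- simulate_encounter_histories(cfg)
  expect_identical(a$histories$events, b$histories$events)
  pa <- simulate_phenology(cfg)
  pb <- simulate_phenology(cfg)
  expect_identical(pa, pb)
  ia <- simulate_immersion(cfg, pa)
  ib <- simulate_immersion(cfg, pb)
  expect_identical(ia, ib)
})

test_that("noise-free channels give deterministic histories", {
  cfg <- sim_config(rp_category_counts = c(SUCCESS = 20, FAIL = 0, SKIP = 0),
                    n_birds_history_only = 0, n_occasions = 5,
                    phi = 1, p_detect = 1, psi = diag(3), seed = 3)
  eh <- simulate_encounter_histories(cfg)
  expect_true(all(eh$histories$events == "SEEN_SUCCESS"))
})

test_that("default configuration reproduces the study group structure", {
  cfg <- sim_config(seed = 5)
  ph <- simulate_phenology(cfg)
  expect_equal(nrow(ph), 111)
  expect_equal(as.integer(table(ph$label)[rp_states()]), c(64, 29, 18))
  eh <- simulate_encounter_histories(cfg)
  expect_equal(nrow(eh$histories$events), 111 + 88)
})

test_that("zero-SD phenology collapses each group to one date vector", {
  phen <- default_phenology()
  for (g in names(phen)) phen[[g]]$sd[] <- 0
  cfg <- tiny_sim_config(seed = 2, phenology = phen)
  ph <- simulate_phenology(cfg)
  for (g in rp_states()) {
    sub <- ph[ph$label == g, phenology_features()]
    expect_true(all(vapply(sub, function(v) length(unique(v)) == 1,
                           logical(1))))
  }
})

test_that("infeasible event ordering errors and names the group", {
  phen <- default_phenology()
  phen$FAIL$mean["prior_hatch_date"] <- 10  # before laying, SD 0
  phen$FAIL$sd[] <- 0
  cfg <- tiny_sim_config(seed = 2, phenology = phen)
  expect_error(simulate_phenology(cfg), "FAIL")
})

test_that("configuration validation rejects broken probability inputs", {
  bad_psi <- matrix(c(0.5, 0.5, 0.5, 0.3, 0.3, 0.3, 0.2, 0.2, 0.1), 3)
  expect_error(sim_config(psi = bad_psi), "sum to 1")
  expect_error(sim_config(n_occasions = 1), "at least 2")
  expect_error(sim_config(p_detect = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(mixture_weights = c(0.5, 0.4)), "sum to 1")
})

test_that("observed adjacent transitions match psi within 3 binomial SEs", {
  psi <- rbind(c(0.6, 0.3, 0.1), c(0.5, 0.3, 0.2), c(0.79, 0.11, 0.10))
  cfg <- sim_config(rp_category_counts = c(SUCCESS = 200, FAIL = 200,
                                           SKIP = 100),
                    n_birds_history_only = 0, n_occasions = 6,
                    phi = 0.9, p_detect = 0.85, psi = psi, seed = 8)
  eh <- simulate_encounter_histories(cfg)
  emp <- empirical_transition_matrix(eh$histories)
  for (i in 1:3) {
    n_row <- sum(emp$counts[i, ])
    for (j in 1:3) {
      se <- sqrt(psi[i, j] * (1 - psi[i, j]) / n_row)
      expect_lt(abs(emp$matrix[i, j] - psi[i, j]), 3 * se + 1e-12)
    }
  }
})

test_that("one explicit mixture class equals the plain generator", {
  cfg1 <- tiny_sim_config(seed = 21)
  cfg2 <- tiny_sim_config(seed = 21, mixture_weights = 1,
                          psi_classes = list(default_psi()))
  a <- simulate_encounter_histories(cfg1)
  b <- simulate_encounter_histories(cfg2)
  expect_identical(a$histories$events, b$histories$events)
})

test_that("pure-flight budget yields all-dry daytime blocks", {
  act <- default_activity()
  for (g in names(act)) {
    act[[g]]$fly[] <- 1; act[[g]]$rest[] <- 0; act[[g]]$forage[] <- 0
    act[[g]]$noise_sd <- 0
  }
  cfg <- tiny_sim_config(seed = 4, activity = act)
  ph <- simulate_phenology(cfg)
  imm <- simulate_immersion(cfg, ph)
  expect_true(all(imm$wet_fraction[imm$is_daytime] == 0))
  expect_true(all(imm$wet_fraction[!imm$is_daytime] == 1))
})

test_that("block arithmetic: 10-minute blocks give 144 per day, 72 daytime", {
  cfg <- tiny_sim_config(seed = 4)
  ph <- simulate_phenology(cfg)
  imm <- simulate_immersion(cfg, ph)
  b1 <- imm[imm$bird_id == ph$bird_id[1], ]
  days <- as.Date(b1$timestamp, tz = "UTC")
  expect_true(all(table(days) == 144))
  expect_equal(unname(table(b1$is_daytime)["TRUE"]) / length(unique(days)),
               72)
})

test_that("empirical activity frequencies converge to the configuration", {
  act <- default_activity()
  for (g in names(act)) act[[g]]$noise_sd <- 0
  cfg <- sim_config(rp_category_counts = c(SUCCESS = 10, FAIL = 0, SKIP = 0),
                    n_birds_history_only = 0, activity = act, seed = 9)
  ph <- simulate_phenology(cfg)
  imm <- simulate_immersion(cfg, ph)
  day <- imm[imm$is_daytime, ]
  # winter days measured from each bird's own departure; before the
  # day-60 breakpoint the budget is (nearly) constant
  date <- as.Date(day$timestamp, tz = "UTC")
  winter_day <- as.numeric(date) -
    ave(as.numeric(date), day$bird_id, FUN = min)
  early <- day[winter_day < 55, ]
  cls <- classify_block(early$wet_fraction)
  n <- nrow(early)
  expect_gt(n, 1e4)
  for (a in c("FLY", "REST", "FORAGE")) {
    p_cfg <- switch(a,
                    FLY = mean(approx(c(0, 60), c(0.12, 0.12), 0:54)$y),
                    REST = mean(approx(c(0, 60), c(0.68, 0.66), 0:54)$y),
                    FORAGE = mean(approx(c(0, 60), c(0.20, 0.22), 0:54)$y))
    se <- sqrt(p_cfg * (1 - p_cfg) / n)
    expect_lt(abs(mean(cls == a) - p_cfg), 3 * se + 1e-9)
  }
})
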