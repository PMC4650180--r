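# Multi-event CMR: forward likelihood against closed forms and path
# enumeration, ML fitting, model comparison and derived quantities.

test_that("two-occasion closed forms are reproduced", {
  par <- list(phi = 0.9, p = 0.8, psi = diag(3))
  # seen then missed: died (0.1) or survived and missed (0.9 * 0.2)
  ll <- history_loglik(c("SEEN_SUCCESS", "NOT_SEEN"), par)
  expect_equal(exp(ll), 0.28, tolerance = 1e-12)
  # perfect detection and survival: certain history
  ll2 <- history_loglik(c("SEEN_SUCCESS", "SEEN_SUCCESS"),
                        list(phi = 1, p = 1, psi = diag(3)))
  expect_equal(ll2, 0, tolerance = 1e-12)
  # impossible history under identity transitions
  ll3 <- history_loglik(c("SEEN_SUCCESS", "SEEN_FAIL"),
                        list(phi = 1, p = 1, psi = diag(3)))
  expect_identical(ll3, -Inf)
})

test_that("forward recursion equals latent-path enumeration", {
  set.seed(55)
  for (r in 1:12) {
    T <- sample(3:5, 1)
    phi <- runif(1, 0.6, 0.95)
    p <- runif(1, 0.5, 0.95)
    u <- sample(c(0, 0.2), 1)
    psi <- random_psi()
    ev <- c(sample(event_codes()[2:5], 1),
            sample(event_codes(), T - 1, replace = TRUE,
                   prob = c(0.4, 0.15, 0.15, 0.15, 0.15)))
    par <- list(phi = phi, p = p, psi = psi, p_state_unknown = u)
    got <- exp(history_loglik(ev, par))
    want <- enumerate_history_lik(ev, phi, p, psi, u = u)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("mixture likelihood is the pi-weighted sum over classes", {
  set.seed(66)
  psi1 <- random_psi(); psi2 <- random_psi()
  ev <- c("SEEN_FAIL", "NOT_SEEN", "SEEN_SKIP", "SEEN_SKIP")
  par <- list(phi = 0.85, p = 0.7, psi = psi1,
              mixture_weights = c(0.3, 0.7),
              psi_classes = list(psi1, psi2))
  got <- exp(history_loglik(ev, par))
  want <- enumerate_history_lik(ev, 0.85, 0.7, psi1,
                                mixture_weights = c(0.3, 0.7),
                                psi_classes = list(psi1, psi2))
  expect_equal(got, want, tolerance = 1e-12)
  # one explicit class equals the plain likelihood
  one <- history_loglik(ev, list(phi = 0.85, p = 0.7, psi = psi1,
                                 mixture_weights = 1,
                                 psi_classes = list(psi1)))
  plain <- history_loglik(ev, list(phi = 0.85, p = 0.7, psi = psi1))
  expect_equal(one, plain, tolerance = 1e-12)
})

test_that("invalid histories and parameters are rejected", {
  expect_error(history_loglik(c("NOT_SEEN", "SEEN_FAIL"),
                              list(phi = 0.9, p = 0.9, psi = diag(3))),
               "first")
  bad_psi <- matrix(1, 3, 3)
  expect_error(history_loglik(c("SEEN_FAIL", "NOT_SEEN"),
                              list(phi = 0.9, p = 0.9, psi = bad_psi)),
               "sum to 1")
})

test_that("total log-likelihood is additive and order-invariant", {
  cfg <- sim_config(rp_category_counts = c(SUCCESS = 15, FAIL = 10,
                                           SKIP = 5),
                    n_birds_history_only = 0, n_occasions = 5, seed = 77)
  eh <- simulate_encounter_histories(cfg)$histories
  par <- list(phi = 0.9, p = 0.85, psi = default_psi())
  singles <- vapply(seq_len(nrow(eh$events)), function(i) {
    history_loglik(eh$events[i, ], par, sex = eh$sex[i])
  }, numeric(1))
  spec <- mecmr_spec()
  link <- c(stats::qlogis(0.9), stats::qlogis(0.85),
            as.vector(apply(default_psi(), 1,
                            function(r) log(r[2:3] / r[1]))))
  nat <- shearwaterCOE:::mecmr_natural(spec, link, 5)
  ev <- shearwaterCOE:::events_to_int(eh$events)
  tot <- sum(shearwaterCOE:::mecmr_loglik_engine(
    ev, match(eh$sex, c("F", "M")), eh$first_occasion, nat))
  expect_equal(tot, sum(singles), tolerance = 1e-8)
  perm <- sample.int(nrow(ev))
  tot_perm <- sum(shearwaterCOE:::mecmr_loglik_engine(
    ev[perm, ], match(eh$sex, c("F", "M"))[perm],
    eh$first_occasion[perm], nat))
  expect_equal(tot_perm, tot, tolerance = 1e-10)
})

test_that("perfect-observation data drives the MLE to the boundary", {
  cfg <- sim_config(rp_category_counts = c(SUCCESS = 30, FAIL = 20,
                                           SKIP = 10),
                    n_birds_history_only = 0, n_occasions = 5,
                    phi = 1, p_detect = 1, seed = 13)
  eh <- simulate_encounter_histories(cfg)$histories
  fit <- fit_mecmr(eh, mecmr_spec(), n_starts = 2, seed = 1)
  expect_gt(fit$natural$phi[1, 1, 1], 0.999)
  expect_gt(fit$natural$p[1], 0.999)
  expect_true(any(fit$boundary))
})

test_that("MLEs recover the generating parameters", {
  psi <- rbind(c(0.6, 0.3, 0.1), c(0.5, 0.3, 0.2), c(0.79, 0.11, 0.10))
  cfg <- sim_config(rp_category_counts = c(SUCCESS = 150, FAIL = 100,
                                           SKIP = 50),
                    n_birds_history_only = 0, n_occasions = 8,
                    phi = 0.9, p_detect = 0.85, psi = psi, seed = 42)
  eh <- simulate_encounter_histories(cfg)$histories
  fit <- fit_mecmr(eh, mecmr_spec(), n_starts = 2, seed = 2)
  expect_true(fit$converged)
  truth_link <- c(stats::qlogis(0.9), stats::qlogis(0.85),
                  as.vector(apply(psi, 1,
                                  function(r) log(r[2:3] / r[1]))))
  z <- abs(fit$par - truth_link) / fit$se
  expect_true(all(z < 4))
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
})

test_that("model table ranks by AIC and prefers the generating model", {
  cfg <- sim_config(rp_category_counts = c(SUCCESS = 120, FAIL = 80,
                                           SKIP = 40),
                    n_birds_history_only = 0, n_occasions = 7, seed = 19)
  eh <- simulate_encounter_histories(cfg)$histories
  fits <- list(
    psi_state = fit_mecmr(eh, mecmr_spec(), n_starts = 2, seed = 3),
    psi_mixture = fit_mecmr(eh, mecmr_spec(n_mixture_classes = 2),
                            n_starts = 2, seed = 3))
  tab <- model_table(fits)
  expect_equal(tab$delta_aic[1], 0)
  expect_true(all(diff(tab$aic) >= 0))
  # homogeneous truth: the extra mixture parameters are pure penalty
  expect_equal(tab$model[1], "psi_state")
  expect_error(model_table(list(a = fits$psi_state,
                                b = local({
                                  f <- fits$psi_state
                                  f$data_info$n <- 1
                                  f
                                }))), "identical data")
  single <- model_table(fits["psi_state"])
  expect_equal(single$delta_aic, 0)
})

test_that("long-run success: identity, uniform and random psi", {
  # identity transitions: next-year success only from SUCCESS
  cfg <- sim_config(rp_category_counts = c(SUCCESS = 20, FAIL = 15,
                                           SKIP = 10),
                    n_birds_history_only = 0, n_occasions = 5,
                    phi = 1, p_detect = 1, psi = diag(3), seed = 23)
  eh <- simulate_encounter_histories(cfg)$histories
  fit <- fit_mecmr(eh, mecmr_spec(), n_starts = 2, seed = 4)
  nxt <- longrun_success(fit, "next_year", n_boot = 0)
  expect_equal(nxt$estimate, c(1, 0, 0), tolerance = 0.01)
  expect_error(longrun_success(fit, "stationary", n_boot = 0),
               "reducible|periodic")

  expect_equal(unname(stationary_distribution(matrix(1 / 3, 3, 3))),
               rep(1 / 3, 3), tolerance = 1e-12)

  # random psi: left eigenvector equals the power-iteration limit
  set.seed(91)
  for (r in 1:5) {
    psi <- random_psi()
    v <- c(1, 0, 0)
    for (i in 1:2000) v <- as.vector(v %*% psi)
    v <- v / sum(v)
    s <- stationary_distribution(psi)
    expect_equal(unname(s), v, tolerance = 1e-10)
    expect_equal(as.vector(s %*% psi), unname(s), tolerance = 1e-12)
  }
})

test_that("bootstrap intervals cover the point estimate", {
  cfg <- sim_config(rp_category_counts = c(SUCCESS = 80, FAIL = 60,
                                           SKIP = 40),
                    n_birds_history_only = 0, n_occasions = 6, seed = 29)
  eh <- simulate_encounter_histories(cfg)$histories
  fit <- fit_mecmr(eh, mecmr_spec(), n_starts = 2, seed = 5)
  lr <- longrun_success(fit, "next_year", n_boot = 300, seed = 6)
  expect_true(all(lr$lower <= lr$estimate & lr$estimate <= lr$upper))
  st <- longrun_success(fit, "stationary", n_boot = 100, seed = 7)
  expect_equal(length(unique(st$estimate)), 1L)
})

test_that("empirical transition matrix counts adjacent pairs only", {
  ev <- rbind(c("SEEN_SUCCESS", "SEEN_FAIL", "NOT_SEEN"),
              c("SEEN_SUCCESS", "NOT_SEEN", "SEEN_SKIP"))
  h <- shearwaterCOE:::new_encounter_histories(
    ev, sex = c("F", "M"), bird_id = c("x", "y"),
    first_occasion = c(1L, 1L))
  emp <- empirical_transition_matrix(h)
  expect_equal(unname(emp$matrix["SUCCESS", ]), c(0, 1, 0))
  expect_equal(sum(emp$counts), 1L)
  expect_equal(emp$n_gap_pairs, 1L)
  rs <- rowSums(emp$matrix)[rowSums(emp$counts) > 0]
  expect_equal(unname(rs), rep(1, length(rs)))

  none <- shearwaterCOE:::new_encounter_histories(
    matrix(c("SEEN_FAIL", "NOT_SEEN"), 1), "F", "z", 1L)
  expect_error(empirical_transition_matrix(none), "no usable")
})
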