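test_that("trajectory log-likelihood replays moves under the noise-mixed policy", {
  # an arena whose right (HQ) arm is fully rewarding: noise-free chemotaxis
  # always moves right with probability 1, so its own trajectory has log-lik 0
  tr <- treatment("31_vs_1", make_even_layout(31, 31), make_even_layout(31, 1),
                  hq_side = "right")
  chem <- policy_spec("chemotaxis", 0)
  traj <- simulate_trajectory(chem, tr, seed = 5)
  expect_equal(traj$moves$arm, rep("right", 30))
  expect_equal(trajectory_loglik(chem, traj), 0)

  # a contradicting move has zero probability under the deterministic policy
  contra <- manual_trajectory(tr, c("right", "left", "right"))
  expect_identical(trajectory_loglik(chem, contra), -Inf)

  # single move from the symmetric post-initialization state: log 0.5
  one <- manual_trajectory(make_treatment("8e_vs_8e"), "right")
  expect_equal(trajectory_loglik(policy_spec("relative_successes", 0), one),
               log(0.5))

  # arena/trajectory consistency is checked when a treatment is supplied
  expect_error(
    trajectory_loglik(chem, contra, make_treatment("4e_vs_8e")),
    "rewards do not match")
})

test_that("evidence integrates the noise parameter and converges with the grid", {
  # a move at probability 0.5 under every theta integrates to exactly log 0.5
  one <- manual_trajectory(make_treatment("8e_vs_8e"), "left")
  for (gs in c(11, 101)) {
    ev <- marginal_loglik("relative_successes", list(one), theta_grid_size = gs)
    expect_equal(ev$log_marginal_likelihood, log(0.5), tolerance = 1e-12)
    expect_lte(ev$log_marginal_likelihood,
               max(ev$per_theta_loglik) + 1e-12)
  }

  # trapezoid evidence converges at second order in the grid spacing
  tr <- make_treatment("4e_vs_8e")
  trajs <- simulate_replicates(policy_spec("relative_successes", 0.1), tr,
                               50, seed = 11)
  e1 <- marginal_loglik("relative_successes", trajs, 101)$log_marginal_likelihood
  e2 <- marginal_loglik("relative_successes", trajs, 201)$log_marginal_likelihood
  e3 <- marginal_loglik("relative_successes", trajs, 401)$log_marginal_likelihood
  expect_lt(abs(e1 - e2), 1e-3)
  expect_lt(abs(e2 - e3), abs(e1 - e2) / 2)  # error shrinks with the grid

  # a deterministic-policy mismatch at theta = 0 only censors that grid point
  expect_true(is.finite(
    marginal_loglik("autocorrelation", trajs)$log_marginal_likelihood))

  expect_error(marginal_loglik("relative_successes", trajs, 2), ">= 3")
})

test_that("the generating model dominates a mismatched one in evidence", {
  tr <- make_treatment("4e_vs_8e")
  trajs <- simulate_replicates(policy_spec("relative_successes", 0.1), tr,
                               100, seed = 21)
  e_gen <- marginal_loglik("relative_successes", trajs)$log_marginal_likelihood
  e_alt <- marginal_loglik("anti_autocorrelation", trajs)$log_marginal_likelihood
  expect_gt(e_gen, e_alt)
})

test_that("evidence is invariant to trajectory order and uninformative padding", {
  tr <- make_treatment("4e_vs_8e")
  trajs <- simulate_replicates(policy_spec("most_successes", 0.15), tr,
                               30, seed = 31)
  models <- c("most_successes", "relative_successes", "chemotaxis")
  ev_fwd <- vapply(models, function(m)
    marginal_loglik(m, trajs)$log_marginal_likelihood, numeric(1))
  ev_rev <- vapply(models, function(m)
    marginal_loglik(m, rev(trajs))$log_marginal_likelihood, numeric(1))
  expect_equal(ev_fwd, ev_rev)

  # a single symmetric move costs log 0.5 under every model: posteriors fixed
  pad <- manual_trajectory(make_treatment("8e_vs_8e"), "right")
  sel0 <- select_model(trajs, models = models)
  sel1 <- select_model(c(trajs, list(pad)), models = models)
  expect_equal(vapply(sel1, `[[`, numeric(1), "posterior_probability"),
               vapply(sel0, `[[`, numeric(1), "posterior_probability"),
               tolerance = 1e-9)
  expect_equal(
    sel1[[1]]$log_marginal_likelihood - sel0[[1]]$log_marginal_likelihood,
    log(0.5), tolerance = 1e-9)
})

test_that("model ranking normalises posteriors and breaks ties lexicographically", {
  # every model predicts a lone symmetric move at 0.5: exact evidence tie
  one <- manual_trajectory(make_treatment("8e_vs_8e"), "right")
  sel <- select_model(list(one),
                      models = c("relative_successes", "most_successes"))
  post <- vapply(sel, `[[`, numeric(1), "posterior_probability")
  expect_equal(post, c(0.5, 0.5))
  expect_equal(sum(post), 1)
  expect_equal(sel[[1]]$model_id, "most_successes")  # lexicographic tie-break

  df <- as.data.frame(sel)
  expect_named(df, c("model", "log_evidence", "posterior", "theta_hat"))
  path <- withr::local_tempfile(fileext = ".json")
  write_evidence(sel, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$posterior, df$posterior)
})

test_that("model selection recovers the generating rule on a small dataset", {
  trajs <- simulate_replicates(policy_spec("autocorrelation", 0.05),
                               make_treatment("4e_vs_8e"), 40, seed = 51)
  sel <- select_model(trajs, models = c("autocorrelation",
                                        "anti_autocorrelation",
                                        "relative_successes", "chemotaxis"))
  expect_equal(sel[[1]]$model_id, "autocorrelation")
  expect_gt(sel[[1]]$posterior_probability, 0.9)
})
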