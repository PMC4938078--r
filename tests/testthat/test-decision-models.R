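test_that("a fresh belief state encodes the uniform prior, and arena init consumes site 1", {
  s <- init_state()
  expect_equal(c(s$A_R, s$A_L, s$B_R, s$B_L), c(1, 1, 1, 1))
  expect_true(is.na(s$last_move))
  expect_equal(c(s$pos_R, s$pos_L), c(0L, 0L))
  expect_equal(s$A_R / (s$A_R + s$B_R), 0.5)

  tr <- make_treatment("4e_vs_8e")
  s1 <- initialize_on_arena(s, tr)
  expect_equal(c(s1$A_R, s1$A_L, s1$B_R, s1$B_L), c(2, 2, 1, 1))
  expect_equal(c(s1$pos_R, s1$pos_L), c(1L, 1L))
  expect_equal(base_prob(policy_spec("relative_successes"), s1), 0.5)
  expect_error(initialize_on_arena(s1, tr), "already initialized")
})

test_that("state updates move one leading edge and conserve total observations", {
  tr <- make_treatment("4e_vs_8e")
  s <- initialize_on_arena(init_state(), tr)
  s <- update_state(s, "right", rewarded = TRUE)
  expect_equal(s$A_R, 3)
  expect_equal(s$pos_R, 2L)
  s <- update_state(s, "left", rewarded = FALSE)
  expect_equal(s$B_L, 2)
  expect_equal(s$last_move, "left")
  expect_false(s$last_rewarded)

  # conservation: after k updates the four counts sum to 4 + 2 (init) + k
  k <- 2
  expect_equal(s$A_R + s$B_R + s$A_L + s$B_L, 6 + k)
  # discovered sites per arm = A + B - 2
  expect_equal(s$pos_R, as.integer(s$A_R + s$B_R - 2))
  expect_equal(s$pos_L, as.integer(s$A_L + s$B_L - 2))

  s$pos_R <- 31L
  expect_error(update_state(s, "right", rewarded = FALSE), "past the end")
})

test_that("each model's printed formula gives the expected move probabilities", {
  st <- function(A_R, B_R, A_L, B_L, last = NA_character_) {
    s <- init_state(31L)
    s$A_R <- A_R; s$B_R <- B_R; s$A_L <- A_L; s$B_L <- B_L
    s$last_move <- last
    s
  }
  p <- function(model, s, fR = FALSE, fL = FALSE) {
    base_prob(policy_spec(model), s, fR, fL)
  }

  # relative successes: A_R / (A_R + A_L)
  expect_equal(p("relative_successes", st(3, 1, 1, 1)), 0.75)
  # most successes: tie -> 0.5
  expect_equal(p("most_successes", st(2, 1, 2, 3)), 0.5)
  expect_equal(p("most_successes", st(3, 1, 2, 1)), 1)
  # highest mean: 2/3 > 1/3
  expect_equal(p("highest_mean", st(2, 1, 1, 2)), 1)
  expect_equal(p("highest_mean", st(2, 4, 1, 2)), 0.5)  # 1/3 = 1/3 tie
  # relative means at a symmetric state
  expect_equal(p("relative_means", st(2, 1, 2, 1)), 0.5)
  expect_equal(p("relative_means", st(2, 1, 1, 2)), (2 / 3) / (2 / 3 + 1 / 3))
  # probability matching equals the posterior superiority probability
  expect_equal(p("probability_matching", st(2, 1, 1, 2)), 5 / 6,
               tolerance = 1e-12)
  # most likely thresholds it
  expect_equal(p("most_likely", st(2, 1, 1, 2)), 1)
  expect_equal(p("most_likely", st(1, 2, 2, 1)), 0)
  # persistence rules fall back to 0.5 before any move
  expect_equal(p("autocorrelation", st(1, 1, 1, 1)), 0.5)
  expect_equal(p("anti_autocorrelation", st(1, 1, 1, 1)), 0.5)
  expect_equal(p("autocorrelation", st(1, 1, 1, 1, last = "right")), 1)
  expect_equal(p("anti_autocorrelation", st(1, 1, 1, 1, last = "right")), 0)
  # chemotaxis follows the food indicator of the next site
  expect_equal(p("chemotaxis", st(1, 1, 1, 1), fR = TRUE, fL = FALSE), 1)
  expect_equal(p("chemotaxis", st(1, 1, 1, 1), fR = FALSE, fL = TRUE), 0)
  expect_equal(p("chemotaxis", st(1, 1, 1, 1), fR = TRUE, fL = TRUE), 0.5)

  expect_error(policy_spec("minimise_regret"), "arg")
})

test_that("posterior superiority is exact, symmetric, and monotone", {
  expect_equal(beta_superiority(1, 1, 1, 1), 0.5)
  # closed form by direct integration: X_R ~ Beta(2,1), X_L ~ Beta(1,2)
  expect_equal(beta_superiority(2, 1, 1, 2), 5 / 6, tolerance = 1e-12)
  # swapping the arms complements the probability
  set.seed(41)
  for (i in 1:20) {
    cnt <- sample.int(8, 4, replace = TRUE)
    pr <- beta_superiority(cnt[1], cnt[2], cnt[3], cnt[4])
    ps <- beta_superiority(cnt[3], cnt[4], cnt[1], cnt[2])
    expect_equal(pr + ps, 1, tolerance = 1e-12)
    expect_true(pr >= 0 && pr <= 1)
  }
  # strictly increasing in the right arm's successes
  vals <- vapply(1:8, function(k) beta_superiority(k, 1, 1, 1), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(beta_superiority(0, 1, 1, 1), "counts")
  # non-integer counts fall back to quadrature and agree with the sum
  expect_equal(beta_superiority(2 + 1e-12, 1, 1, 2), 5 / 6, tolerance = 1e-6)
})

test_that("noise mixes the policy with a fair coin", {
  expect_equal(apply_noise(1, 0), 1)
  expect_equal(apply_noise(1, 1), 0.5)
  expect_equal(apply_noise(0.75, 0.2), 0.7)
  expect_error(apply_noise(1.2, 0.1), "0, 1")
  expect_error(apply_noise(0.5, -0.1), "theta")
})

test_that("all models give complementary mirror-symmetric probabilities on random states", {
  set.seed(7)
  dets <- c("autocorrelation", "anti_autocorrelation", "most_successes",
            "highest_mean", "most_likely", "chemotaxis", "gittins")
  for (i in 1:150) {
    s <- random_belief_state()
    m <- mirror_state(s)
    fR <- sample(c(TRUE, FALSE), 1)
    fL <- sample(c(TRUE, FALSE), 1)
    for (model in model_ids()) {
      spec <- policy_spec(model, theta = 0)
      pr <- base_prob(spec, s, fR, fL)
      expect_true(pr >= 0 && pr <= 1)
      expect_equal(base_prob(spec, m, fL, fR), 1 - pr, tolerance = 1e-9)
      if (model %in% dets) expect_true(pr %in% c(0, 0.5, 1))
    }
  }
})

test_that("vectorised replay probabilities match the scalar policy", {
  tr <- make_treatment("4r_vs_8r", seed = 31)
  traj <- simulate_trajectory(policy_spec("relative_successes", 0.3), tr,
                              seed = 8)
  st <- physbandit:::replay_states(traj)
  for (model in model_ids()) {
    pv <- physbandit:::policy_prob_vec(model, st, discount = 0.9)
    s <- initialize_on_arena(init_state(), tr)
    for (k in seq_len(nrow(traj$moves))) {
      fR <- s$pos_R < 31 && traj$right[s$pos_R + 1] > 0
      fL <- s$pos_L < 31 && traj$left[s$pos_L + 1] > 0
      ps <- base_prob(policy_spec(model), s, fR, fL)
      expect_equal(pv[k], ps, tolerance = 1e-12)
      s <- update_state(s, traj$moves$arm[k],
                        rewarded = traj$moves$reward[k] > 0)
    }
  }
})
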