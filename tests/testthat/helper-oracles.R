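# Independent oracles used to freeze expected values.

# Finite-horizon dynamic-programming oracle for the Gittins index of a
# Beta(A, B) Bernoulli arm: memoised top-down recursion over
# (successes, failures, steps-remaining), horizon chosen so the discarded
# tail is < 1e-8 of a unit perpetuity; the index is the retirement rate at
# which playing and retiring tie at the root, found by uniroot.
oracle_gittins <- function(A, B, gamma, tol = 1e-6) {
  if (gamma == 0) return(A / (A + B))
  H <- as.integer(ceiling(log(1e-8) / log(gamma)))
  value_gap <- function(lambda) {
    memo <- new.env(parent = emptyenv())
    rec <- function(a, b, t) {
      if (t == 0L) return(0)
      key <- sprintf("%d_%d_%d", a, b, t)
      v <- memo[[key]]
      if (!is.null(v)) return(v)
      mu <- a / (a + b)
      retire <- lambda * (1 - gamma^t) / (1 - gamma)
      play <- mu * (1 + gamma * rec(a + 1L, b, t - 1L)) +
        (1 - mu) * gamma * rec(a, b + 1L, t - 1L)
      v <- max(retire, play)
      memo[[key]] <- v
      v
    }
    mu <- A / (A + B)
    play <- mu * (1 + gamma * rec(A + 1L, B, H - 1L)) +
      (1 - mu) * gamma * rec(A, B + 1L, H - 1L)
    play - lambda * (1 - gamma^H) / (1 - gamma)
  }
  stats::uniroot(value_gap, c(A / (A + B), 1 - 1e-9), tol = tol)$root
}

# Monte-Carlo oracle for P(X_R > X_L) under independent Beta posteriors.
oracle_beta_superiority_mc <- function(A_R, B_R, A_L, B_L, n = 1e6) {
  mean(stats::rbeta(n, A_R, B_R) > stats::rbeta(n, A_L, B_L))
}

# A random belief state on a 31-site arena, counts consistent with the
# positions (pos = A + B - 2 per arm).
random_belief_state <- function(max_sites = 6L) {
  s <- init_state(arm_length = 31L)
  s$A_R <- sample.int(max_sites, 1L)
  s$B_R <- sample.int(max_sites, 1L)
  s$A_L <- sample.int(max_sites, 1L)
  s$B_L <- sample.int(max_sites, 1L)
  s$pos_R <- as.integer(s$A_R + s$B_R - 2)
  s$pos_L <- as.integer(s$A_L + s$B_L - 2)
  s$last_move <- sample(c("left", "right", NA_character_), 1L)
  s
}

# Swap the two arms of a belief state.
mirror_state <- function(s) {
  m <- s
  m$A_R <- s$A_L; m$A_L <- s$A_R
  m$B_R <- s$B_L; m$B_L <- s$B_R
  m$pos_R <- s$pos_L; m$pos_L <- s$pos_R
  m$last_move <- if (is.na(s$last_move)) NA_character_ else {
    if (s$last_move == "left") "right" else "left"
  }
  m
}

# Minimal hand-built trajectory (bypasses the simulator) on a treatment.
manual_trajectory <- function(treatment, arms, hq_side = treatment$hq_side) {
  sides <- physbandit:::treatment_sides(treatment)
  pos <- c(left = 1L, right = 1L)
  rows <- lapply(seq_along(arms), function(k) {
    a <- arms[k]
    pos[a] <<- pos[a] + 1L
    data.frame(step = k, arm = a, site = pos[[a]],
               reward = as.numeric(sides[[a]])[pos[[a]]],
               stringsAsFactors = FALSE)
  })
  L <- length(sides$left)
  last_arm <- arms[length(arms)]
  physbandit:::new_trajectory(
    treatment_name = treatment$name, hq_side = hq_side,
    moves = do.call(rbind, rows),
    end_cause = if (last_arm == hq_side) "hq_end_first" else "lq_end_first",
    left = as.numeric(sides$left), right = as.numeric(sides$right),
    arm_length = if (pos[[last_arm]] == L) L else NA_integer_)
}
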