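#' Forward simulation of arm exploration
#'
#' `simulate_trajectory()` grows one replicate on a two-armed arena: starting
#' from the forced first site on each arm, the cell repeatedly draws a
#' direction from the noise-mixed policy, advances that arm's leading edge by
#' one site and registers the reward, until either arm's last site is reached
#' — the arm "chosen" by the replicate, which ends the trajectory.
#'
#' @param spec A [policy_spec()].
#' @param treatment A [treatment()].
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param graded Use graded success increments for non-binary rewards
#'   (default `FALSE`: any positive magnitude counts as one success).
#' @return A `pb_trajectory`: list with `treatment_name`, `hq_side`, `moves`
#'   (data frame `step`, `arm`, `site`, `reward`), `end_cause`
#'   (`"hq_end_first"` or `"lq_end_first"`), `seed`, `excluded`, the per-side
#'   layouts `left`/`right` and `arm_length`.
#' @examples
#' tr <- make_treatment("4e_vs_8e")
#' simulate_trajectory(policy_spec("relative_successes", 0.1), tr, seed = 1)
#' @export
simulate_trajectory <- function(spec, treatment, seed = NULL, graded = FALSE) {
  stopifnot(inherits(spec, "policy_spec"), inherits(treatment, "treatment"))
  sides <- treatment_sides(treatment)
  left <- as.numeric(sides$left)
  right <- as.numeric(sides$right)
  L <- length(left)
  theta <- spec$theta
  model <- spec$model
  disc <- spec$gittins_discount

  with_seed(seed, {
    A_R <- 2; A_L <- 2; B_R <- 1; B_L <- 1
    pos_R <- 1L; pos_L <- 1L
    last_move <- NA_character_
    cap <- 2L * (L - 1L)
    arm <- character(cap); site <- integer(cap); rew <- numeric(cap)
    t <- 0L
    repeat {
      food_R <- pos_R < L && right[pos_R + 1L] > 0
      food_L <- pos_L < L && left[pos_L + 1L] > 0
      p <- apply_noise(
        policy_prob(model, A_R, B_R, A_L, B_L, last_move, food_R, food_L, disc),
        theta)
      mv <- if (stats::runif(1) < p) "right" else "left"
      t <- t + 1L
      if (mv == "right") {
        pos_R <- pos_R + 1L
        r <- right[pos_R]
        s <- pos_R
        if (r > 0) A_R <- A_R + (if (graded) r / 0.05 else 1) else B_R <- B_R + 1
      } else {
        pos_L <- pos_L + 1L
        r <- left[pos_L]
        s <- pos_L
        if (r > 0) A_L <- A_L + (if (graded) r / 0.05 else 1) else B_L <- B_L + 1
      }
      arm[t] <- mv; site[t] <- s; rew[t] <- r
      last_move <- mv
      if (s == L) break
    }
    end_arm <- arm[t]
    new_trajectory(
      treatment_name = treatment$name, hq_side = treatment$hq_side,
      moves = data.frame(step = seq_len(t), arm = arm[seq_len(t)],
                         site = site[seq_len(t)], reward = rew[seq_len(t)],
                         stringsAsFactors = FALSE),
      end_cause = if (end_arm == treatment$hq_side) "hq_end_first" else "lq_end_first",
      seed = seed, left = left, right = right, arm_length = L)
  })
}

# Low-level trajectory constructor shared by the simulator and the CSV reader.
new_trajectory <- function(treatment_name, hq_side, moves, end_cause,
                           seed = NULL, left = NULL, right = NULL,
                           arm_length = NA_integer_, excluded = FALSE) {
  structure(
    list(treatment_name = treatment_name, hq_side = hq_side, moves = moves,
         end_cause = end_cause, seed = seed, excluded = excluded,
         left = left, right = right, arm_length = arm_length),
    class = "pb_trajectory")
}

#' @export
print.pb_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s (HQ %s): %d moves, %s%s\n",
              x$treatment_name, x$hq_side, nrow(x$moves), x$end_cause,
              if (isTRUE(x$excluded)) " [excluded]" else ""))
  invisible(x)
}

# Check trajectory invariants: per-arm sites consecutive from 2, trajectory
# ends exactly when one arm's last site is first reached. Returns TRUE or
# stops with the offending move index.
validate_trajectory <- function(traj) {
  mv <- traj$moves
  if (!all(mv$arm %in% c("left", "right"))) {
    bad <- which(!mv$arm %in% c("left", "right"))[1L]
    stop("move ", bad, ": unknown arm label '", mv$arm[bad], "'", call. = FALSE)
  }
  for (a in c("left", "right")) {
    s <- mv$site[mv$arm == a]
    if (length(s) && !identical(as.integer(s), seq.int(2L, 1L + length(s)))) {
      bad <- which(mv$arm == a)[which(as.integer(s) != seq.int(2L, 1L + length(s)))[1L]]
      stop("move ", bad, ": ", a, " arm sites not consecutive from 2",
           call. = FALSE)
    }
  }
  L <- traj$arm_length
  if (is.finite(L)) {
    hit <- which(mv$site == L)
    if (length(hit) != 1L || hit != nrow(mv)) {
      stop("trajectory must end exactly when an arm's last site is reached",
           call. = FALSE)
    }
  }
  TRUE
}

#' Simulate a batch of replicates on one treatment
#'
#' Convenience wrapper: draws `n` independent trajectories with per-replicate
#' seeds derived from `seed`. For random or non-binary treatments a fresh
#' arena can be instantiated per replicate via `fresh_arenas`.
#'
#' @inheritParams simulate_trajectory
#' @param n Number of replicates.
#' @param fresh_arenas Re-instantiate the treatment's random layouts for
#'   every replicate (needs `treatment` to be a registry name).
#' @param treatment A [treatment()] or, when `fresh_arenas = TRUE`, a
#'   registry name.
#' @return List of `pb_trajectory` objects.
#' @export
simulate_replicates <- function(spec, treatment, n, seed = NULL,
                                fresh_arenas = FALSE, graded = FALSE) {
  seeds <- derive_seeds(seed, 2L * n)
  lapply(seq_len(n), function(i) {
    tr <- if (fresh_arenas) {
      make_treatment(treatment, seed = seeds[n + i])
    } else treatment
    simulate_trajectory(spec, tr, seed = seeds[i], graded = graded)
  })
}

#' Site-discovery difference curve
#'
#' The exploration statistic of the study: whenever the i-th site is first
#' reached on either arm (i.e. the larger of the two leading edges first
#' equals i), the number of sites discovered on the LQ arm is subtracted
#' from the number discovered on the HQ arm. Positive values mean the HQ arm
#' leads. The curve averages this difference over replicates at each rank
#' and reports a 1.96 standard-error band.
#'
#' @param trajectories List of `pb_trajectory` from a single treatment.
#' @param carry_forward If a replicate's trajectory stops before rank i
#'   (possible only for externally truncated data), carry its final
#'   difference forward (default) instead of dropping it.
#' @param include_excluded Include replicates flagged as excluded.
#' @return A `discovery_curve` data frame: `rank`, `mean_diff`,
#'   `half_width` (1.96 s.e.; 0 when fewer than 2 replicates contribute),
#'   `n`.
#' @export
first_discovery_difference <- function(trajectories, carry_forward = TRUE,
                                       include_excluded = FALSE) {
  trajectories <- drop_excluded(trajectories, include_excluded)
  if (length(trajectories) == 0L) stop("no trajectories supplied", call. = FALSE)
  nm <- unique(vapply(trajectories, `[[`, "", "treatment_name"))
  if (length(nm) > 1L) {
    stop("all trajectories must come from the same treatment", call. = FALSE)
  }
  L <- max(vapply(trajectories, function(x) {
    l <- x$arm_length
    if (is.finite(l)) as.integer(l) else max(x$moves$site)
  }, integer(1)))
  diffs <- vapply(trajectories, function(traj) {
    hq_is_right <- traj$hq_side == "right"
    pos_hq <- 1L; pos_lq <- 1L
    out <- rep(NA_real_, L)
    out[1L] <- 0
    for (k in seq_len(nrow(traj$moves))) {
      on_hq <- (traj$moves$arm[k] == "right") == hq_is_right
      if (on_hq) pos_hq <- pos_hq + 1L else pos_lq <- pos_lq + 1L
      m <- max(pos_hq, pos_lq)
      if (is.na(out[m])) out[m] <- pos_hq - pos_lq
    }
    if (carry_forward) {
      last <- max(which(!is.na(out)))
      if (last < L) out[(last + 1L):L] <- out[last]
    }
    out
  }, numeric(L))
  diffs <- matrix(diffs, nrow = L)
  mean_diff <- apply(diffs, 1L, mean, na.rm = TRUE)
  n_at <- apply(diffs, 1L, function(x) sum(!is.na(x)))
  se <- apply(diffs, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) 0 else stats::sd(x) / sqrt(length(x))
  })
  structure(
    data.frame(rank = seq_len(L), mean_diff = mean_diff,
               half_width = 1.96 * se, n = n_at),
    class = c("discovery_curve", "data.frame"), treatment = nm)
}

#' Write a discovery curve as TSV
#' @param curve A [first_discovery_difference()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_discovery_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

drop_excluded <- function(trajectories, include_excluded) {
  if (include_excluded) return(trajectories)
  Filter(function(x) !isTRUE(x$excluded), trajectories)
}

#' Proportion of replicates choosing the HQ arm
#'
#' The fraction of replicates that reached the end of the HQ arm before the
#' LQ arm, with a two-sided exact binomial test against the chance level 0.5.
#' Undefined for equal-quality treatments (both arms carry the same total
#' reward), which have no HQ arm.
#'
#' @param trajectories List of `pb_trajectory` from unequal-arm treatments.
#' @param include_excluded Include replicates flagged as excluded.
#' @return List with `proportion`, `p_value`, `n_hq_first`, `n`.
#' @export
proportion_hq_first <- function(trajectories, include_excluded = FALSE) {
  trajectories <- drop_excluded(trajectories, include_excluded)
  if (length(trajectories) == 0L) stop("no trajectories supplied", call. = FALSE)
  eq <- vapply(trajectories, function(x) {
    if (is.null(x$left) || is.null(x$right)) return(FALSE)
    isTRUE(all.equal(sum(x$left), sum(x$right)))
  }, logical(1))
  if (any(eq)) {
    stop("HQ arm undefined: equal-quality treatment", call. = FALSE)
  }
  k <- sum(vapply(trajectories, `[[`, "", "end_cause") == "hq_end_first")
  n <- length(trajectories)
  bt <- stats::binom.test(k, n, p = 0.5, alternative = "two.sided")
  list(proportion = k / n, p_value = bt$p.value, n_hq_first = k, n = n)
}

#' Benchmark policies on a stationary two-armed Bernoulli bandit
#'
#' Simulates each policy for `n_steps` pulls on a bandit with fixed success
#' probabilities and no arm exhaustion, and reports the mean cumulative
#' reward with its Monte-Carlo standard error. The Gittins policy provides
#' the best-achievable benchmark to which heuristics are compared.
#'
#' @param specs List of [policy_spec()]s.
#' @param bandit Length-2 vector of success probabilities, `(left, right)`.
#' @param n_steps Pulls per simulation.
#' @param n_sims Simulations per policy.
#' @param seed Integer seed.
#' @return Data frame: `model`, `theta`, `mean_reward`, `se`.
#' @export
compare_performance <- function(specs, bandit = c(0.3, 0.6), n_steps = 100L,
                                n_sims = 200L, seed = NULL) {
  if (inherits(specs, "policy_spec")) specs <- list(specs)
  if (any(bandit < 0 | bandit > 1) || length(bandit) != 2L) {
    stop("`bandit` must be two probabilities in [0, 1]", call. = FALSE)
  }
  p_left <- bandit[1L]; p_right <- bandit[2L]
  rows <- lapply(specs, function(spec) {
    if (spec$model == "gittins") {
      ensure_gittins_lattice(spec$gittins_discount, n_steps + 2L)
    }
    totals <- with_seed(seed, {
      vapply(seq_len(n_sims), function(i) {
        A_R <- 1; A_L <- 1; B_R <- 1; B_L <- 1
        last_move <- NA_character_
        total <- 0
        for (t in seq_len(n_steps)) {
          p <- apply_noise(
            policy_prob(spec$model, A_R, B_R, A_L, B_L, last_move,
                        FALSE, FALSE, spec$gittins_discount),
            spec$theta)
          mv <- if (stats::runif(1) < p) "right" else "left"
          rew <- stats::runif(1) < (if (mv == "right") p_right else p_left)
          if (mv == "right") {
            if (rew) A_R <- A_R + 1 else B_R <- B_R + 1
          } else {
            if (rew) A_L <- A_L + 1 else B_L <- B_L + 1
          }
          total <- total + rew
          last_move <- mv
        }
        total
      }, numeric(1))
    })
    data.frame(model = spec$model, theta = spec$theta,
               mean_reward = mean(totals),
               se = stats::sd(totals) / sqrt(n_sims))
  })
  do.call(rbind, rows)
}
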