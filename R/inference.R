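#' @title Bayesian model selection for exploration trajectories
#' @description Internal replay machinery plus the exported evidence
#'   functions. A trajectory fixes the state sequence regardless of the
#'   model under evaluation, so the per-move conditioning variables are
#'   reconstructed once and every model's move probabilities are evaluated
#'   vectorised over them.
#' @name inference
NULL

# Reconstruct the pre-move belief-state table of a trajectory: one row per
# move with columns A_R, B_R, A_L, B_L, pos_R, pos_L, last_move, food_R,
# food_L and the realised move. Layouts come from the trajectory itself or
# from `treatment`.
replay_states <- function(traj, treatment = NULL) {
  left <- traj$left
  right <- traj$right
  if ((is.null(left) || is.null(right)) && !is.null(treatment)) {
    sides <- treatment_sides(treatment)
    left <- as.numeric(sides$left)
    right <- as.numeric(sides$right)
  }
  mv <- traj$moves
  n <- nrow(mv)
  is_r <- mv$arm == "right"
  succ <- mv$reward > 0
  prev <- function(x) if (n > 1L) c(0, x[-n]) else 0
  cum_r_succ <- prev(cumsum(is_r & succ))
  cum_r_fail <- prev(cumsum(is_r & !succ))
  cum_l_succ <- prev(cumsum(!is_r & succ))
  cum_l_fail <- prev(cumsum(!is_r & !succ))
  pos_R <- 1L + prev(cumsum(is_r))
  pos_L <- 1L + prev(cumsum(!is_r))
  L <- traj$arm_length
  if (!is.finite(L) && !is.null(left)) L <- length(left)
  food_at <- function(layout, pos) {
    if (is.null(layout)) return(rep(FALSE, n))
    nxt <- pos + 1L
    ok <- nxt <= length(layout)
    out <- rep(FALSE, n)
    out[ok] <- layout[nxt[ok]] > 0
    out
  }
  data.frame(
    A_R = 2 + cum_r_succ, B_R = 1 + cum_r_fail,
    A_L = 2 + cum_l_succ, B_L = 1 + cum_l_fail,
    pos_R = pos_R, pos_L = pos_L,
    last_move = c(NA_character_, mv$arm[-n])[seq_len(n)],
    food_R = food_at(right, pos_R), food_L = food_at(left, pos_L),
    move = mv$arm, arm_length = if (is.finite(L)) L else NA_integer_,
    stringsAsFactors = FALSE)
}

# Realised noise-free probabilities of a model along a trajectory, with
# forced moves (other arm exhausted) flagged.
realized_probs <- function(model, traj, treatment = NULL, discount = 0.9) {
  st <- replay_states(traj, treatment)
  p0 <- policy_prob_vec(model, st, discount)
  r <- ifelse(st$move == "right", p0, 1 - p0)
  L <- st$arm_length[1L]
  forced <- if (is.na(L)) rep(FALSE, nrow(st)) else {
    (st$move == "right" & st$pos_L >= L) | (st$move == "left" & st$pos_R >= L)
  }
  list(p = r, forced = forced)
}

#' Log-likelihood of a trajectory under a policy
#'
#' Replays the trajectory and accumulates the log probability of each
#' realised move under the noise-mixed policy. Moves forced by an exhausted
#' opposite arm contribute log 1. A deterministic policy (`theta = 0`) that
#' contradicts a move yields `-Inf`.
#'
#' @param spec A [policy_spec()].
#' @param trajectory A `pb_trajectory`.
#' @param treatment Optional [treatment()] supplying the arena when the
#'   trajectory does not carry its layouts (e.g. after CSV import). Checked
#'   for consistency with the recorded rewards when both are available.
#' @return The log-likelihood (may be `-Inf`).
#' @export
trajectory_loglik <- function(spec, trajectory, treatment = NULL) {
  stopifnot(inherits(spec, "policy_spec"), inherits(trajectory, "pb_trajectory"))
  if (!is.null(treatment)) check_consistency(trajectory, treatment)
  rp <- realized_probs(spec$model, trajectory, treatment, spec$gittins_discount)
  pr <- apply_noise(rp$p, spec$theta)
  sum(log(pr[!rp$forced]))
}

check_consistency <- function(traj, treatment) {
  sides <- treatment_sides(treatment)
  L <- length(sides$left)
  if (is.finite(traj$arm_length) && traj$arm_length != L) {
    stop("trajectory arm length (", traj$arm_length,
         ") does not match treatment (", L, ")", call. = FALSE)
  }
  mv <- traj$moves
  for (a in c("left", "right")) {
    lay <- as.numeric(sides[[a]])
    rows <- mv$arm == a
    if (any(abs(mv$reward[rows] - lay[mv$site[rows]]) > 1e-12)) {
      stop("trajectory rewards do not match the ", a, " arm layout",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Marginal likelihood of a model with the noise parameter integrated out
#'
#' Sums the trajectory log-likelihoods on an evenly spaced grid of the noise
#' fraction theta, then integrates over a uniform prior on \[0, 1\] by the
#' trapezoid rule, stabilised with log-sum-exp. Also reports the grid
#' argmax `theta_hat`. Theta is shared across all trajectories (one noise
#' parameter per model).
#'
#' @param model_id One of [model_ids()].
#' @param trajectories List of `pb_trajectory`.
#' @param theta_grid_size Grid points on \[0, 1\] (>= 3, default 101).
#' @param gittins_discount Fixed discount for the `gittins` model (not
#'   integrated over; the benchmark enters with its discount pinned).
#' @param include_excluded Include replicates flagged as excluded.
#' @return A `model_evidence`: list with `model_id`,
#'   `log_marginal_likelihood`, `posterior_probability` (filled by
#'   [select_model()]), `theta_grid`, `per_theta_loglik`, `theta_hat`.
#' @export
marginal_loglik <- function(model_id, trajectories, theta_grid_size = 101L,
                            gittins_discount = 0.9, include_excluded = FALSE) {
  model_id <- match.arg(model_id, model_ids())
  if (theta_grid_size < 3L) stop("`theta_grid_size` must be >= 3", call. = FALSE)
  trajectories <- drop_excluded(trajectories, include_excluded)
  if (length(trajectories) == 0L) stop("no trajectories supplied", call. = FALSE)
  if (model_id == "gittins") {
    lens <- vapply(trajectories, function(x) {
      if (is.finite(x$arm_length)) x$arm_length else max(x$moves$site)
    }, numeric(1))
    ensure_gittins_lattice(gittins_discount, max(lens) + 1L)
  }
  q <- unlist(lapply(trajectories, function(traj) {
    rp <- realized_probs(model_id, traj, NULL, gittins_discount)
    rp$p[!rp$forced]
  }))
  grid <- seq(0, 1, length.out = theta_grid_size)
  ll <- vapply(grid, function(th) sum(log((1 - th) * q + th / 2)), numeric(1))
  h <- 1 / (theta_grid_size - 1)
  logw <- log(c(h / 2, rep(h, theta_grid_size - 2L), h / 2))
  log_ev <- logsumexp(logw + ll)
  if (!is.finite(log_ev)) {
    warning("evidence for '", model_id, "' is -Inf on the whole theta grid")
  }
  structure(
    list(model_id = model_id, log_marginal_likelihood = log_ev,
         posterior_probability = NA_real_, theta_grid = grid,
         per_theta_loglik = ll, theta_hat = grid[which.max(ll)]),
    class = "model_evidence")
}

#' @export
print.model_evidence <- function(x, ...) {
  cat(sprintf("<model_evidence> %s: log evidence %.3f, theta_hat %.3f%s\n",
              x$model_id, x$log_marginal_likelihood, x$theta_hat,
              if (is.na(x$posterior_probability)) "" else
                sprintf(", posterior %.3f", x$posterior_probability)))
  invisible(x)
}

#' Rank decision models by marginal likelihood
#'
#' Computes each candidate model's evidence on the pooled trajectories
#' (treatments share one noise parameter per model), converts evidences to
#' posterior model probabilities under a uniform model prior, and returns
#' the models ranked by evidence (ties broken lexicographically).
#'
#' @param trajectories List of `pb_trajectory` (may pool several treatments).
#' @param models Character vector of model ids (default: all ten).
#' @inheritParams marginal_loglik
#' @return A `model_selection`: list of `model_evidence`, best first.
#' @examples
#' \donttest{
#' tr <- make_treatment("4e_vs_8e")
#' trajs <- simulate_replicates(policy_spec("relative_successes", 0.1), tr,
#'                              n = 20, seed = 1)
#' sel <- select_model(trajs, models = c("relative_successes", "chemotaxis"))
#' sel[[1]]$model_id
#' }
#' @export
select_model <- function(trajectories, models = model_ids(),
                         theta_grid_size = 101L, gittins_discount = 0.9,
                         include_excluded = FALSE) {
  models <- match.arg(models, model_ids(), several.ok = TRUE)
  ev <- lapply(models, marginal_loglik, trajectories = trajectories,
               theta_grid_size = theta_grid_size,
               gittins_discount = gittins_discount,
               include_excluded = include_excluded)
  logz <- vapply(ev, `[[`, numeric(1), "log_marginal_likelihood")
  post <- exp(logz - logsumexp(logz))
  post <- post / sum(post)
  ord <- order(-logz, models)
  ev <- lapply(seq_along(ev), function(i) {
    e <- ev[[i]]
    e$posterior_probability <- post[i]
    e
  })[ord]
  structure(ev, class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection> models ranked by log marginal likelihood:\n")
  for (e in x) {
    cat(sprintf("  %-22s log evidence %10.3f  posterior %.4f  theta_hat %.3f\n",
                e$model_id, e$log_marginal_likelihood,
                e$posterior_probability, e$theta_hat))
  }
  invisible(x)
}

#' @export
as.data.frame.model_selection <- function(x, ...) {
  data.frame(
    model = vapply(x, `[[`, "", "model_id"),
    log_evidence = vapply(x, `[[`, numeric(1), "log_marginal_likelihood"),
    posterior = vapply(x, `[[`, numeric(1), "posterior_probability"),
    theta_hat = vapply(x, `[[`, numeric(1), "theta_hat"))
}

#' Write model-selection results as JSON
#'
#' Serialises a [select_model()] result as a list of
#' `{model, log_evidence, posterior, theta_hat}` records.
#'
#' @param selection A `model_selection`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(selection, path) {
  jsonlite::write_json(as.data.frame(selection), path, auto_unbox = TRUE,
                       digits = I(17), dataframe = "rows")
  invisible(path)
}
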