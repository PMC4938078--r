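#' The ten candidate decision models
#'
#' Model identifiers accepted throughout the package, in increasing order of
#' computational sophistication: movement persistence and alternation
#' (`autocorrelation`, `anti_autocorrelation`), count comparisons
#' (`most_successes`, `highest_mean`), proportional sampling rules
#' (`relative_successes`, `relative_means`), posterior-comparison rules
#' (`most_likely`, `probability_matching`), gradient following
#' (`chemotaxis`), and the optimal discounted-bandit benchmark (`gittins`).
#'
#' @return Character vector of the ten model ids.
#' @export
model_ids <- function() {
  c("autocorrelation", "anti_autocorrelation", "most_successes",
    "highest_mean", "relative_successes", "relative_means",
    "most_likely", "probability_matching", "chemotaxis", "gittins")
}

#' Specify a decision policy
#'
#' A policy is a decision model plus the behavioural noise level `theta`:
#' the fraction of moves on which the cell ignores the model and moves at
#' random. The Gittins benchmark additionally carries the discount applied
#' to future rewards.
#'
#' @param model One of [model_ids()].
#' @param theta Noise fraction in \[0, 1\].
#' @param gittins_discount Discount factor in \[0, 1) (gittins model only).
#' @return A `policy_spec` object.
#' @examples
#' policy_spec("relative_successes", theta = 0.1)
#' @export
policy_spec <- function(model, theta = 0.1, gittins_discount = 0.9) {
  model <- match.arg(model, model_ids())
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1) {
    stop("`theta` must be a single value in [0, 1]", call. = FALSE)
  }
  if (gittins_discount < 0 || gittins_discount >= 1) {
    stop("`gittins_discount` must be in [0, 1)", call. = FALSE)
  }
  structure(list(model = model, theta = theta,
                 gittins_discount = gittins_discount),
            class = "policy_spec")
}

#' @export
print.policy_spec <- function(x, ...) {
  extra <- if (x$model == "gittins") sprintf(", discount = %g", x$gittins_discount) else ""
  cat(sprintf("<policy_spec> %s (theta = %g%s)\n", x$model, x$theta, extra))
  invisible(x)
}

#' Read a policy specification from JSON or YAML
#'
#' Accepts `{"model": "relative_successes", "theta": 0.1}` (optionally with
#' `"gittins_discount"`), in either format, chosen by file extension.
#'
#' @param path File path (`.json`, `.yml` or `.yaml`).
#' @return A [policy_spec()].
#' @export
read_policy_spec <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  policy_spec(obj$model, obj$theta %||% 0.1, obj$gittins_discount %||% 0.9)
}

#' Probability that the right arm's food density exceeds the left's
#'
#' With independent uniform priors, the food density on each arm has a
#' Beta(A, B) posterior after A - 1 observed rewards and B - 1 blanks (the
#' extra 1 in each count is the prior pseudo-observation). This returns
#' `P(X_R > X_L)` for `X_R ~ Beta(A_R, B_R)` and `X_L ~ Beta(A_L, B_L)`,
#' by the exact finite-sum identity when `A_R` is a positive integer
#'
#' \deqn{P(X_R > X_L) = \sum_{i=0}^{A_R - 1}
#'   \frac{B(A_L + i,\, B_L + B_R)}{(B_R + i)\, B(1 + i,\, B_R)\, B(A_L, B_L)}}
#'
#' and by adaptive quadrature (absolute tolerance 1e-8) otherwise.
#'
#' @param A_R,B_R,A_L,B_L Success/failure counts (pseudo-observations
#'   included), all >= 1.
#' @return `P(X_R > X_L)` in \[0, 1\].
#' @examples
#' beta_superiority(2, 1, 1, 2)  # 5/6
#' @export
beta_superiority <- function(A_R, B_R, A_L, B_L) {
  counts <- c(A_R, B_R, A_L, B_L)
  if (any(!is.finite(counts)) || any(counts < 1)) {
    stop("all counts must be finite and >= 1", call. = FALSE)
  }
  if (A_R == round(A_R)) {
    i <- 0:(A_R - 1)
    sum(exp(lbeta(A_L + i, B_L + B_R) - log(B_R + i) -
              lbeta(1 + i, B_R) - lbeta(A_L, B_L)))
  } else {
    stats::integrate(function(x) stats::pbeta(x, A_L, B_L) * stats::dbeta(x, A_R, B_R),
                     0, 1, abs.tol = 1e-8, rel.tol = 1e-10)$value
  }
}

# Vectorised, memoised beta_superiority over count columns.
beta_superiority_vec <- local({
  memo <- new.env(parent = emptyenv())
  function(A_R, B_R, A_L, B_L) {
    key <- paste(A_R, B_R, A_L, B_L, sep = ",")
    out <- numeric(length(key))
    for (k in unique(key)) {
      v <- memo[[k]]
      if (is.null(v)) {
        idx1 <- match(k, key)
        v <- beta_superiority(A_R[idx1], B_R[idx1], A_L[idx1], B_L[idx1])
        memo[[k]] <- v
      }
      out[key == k] <- v
    }
    out
  }
})

#' Mix behavioural noise into a move probability
#'
#' With probability `theta` the cell ignores the model and moves left or
#' right by a fair coin, giving the mixture `(1 - theta) * p + theta / 2`.
#' For `theta > 0` every move has positive probability, which keeps
#' trajectory likelihoods finite.
#'
#' @param p Noise-free probability of moving right, in \[0, 1\].
#' @param theta Noise fraction in \[0, 1\].
#' @return Probability in `[theta/2, 1 - theta/2]`.
#' @examples
#' apply_noise(0.75, 0.2)  # 0.7
#' @export
apply_noise <- function(p, theta) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    stop("`p` must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1) {
    stop("`theta` must be a single value in [0, 1]", call. = FALSE)
  }
  (1 - theta) * p + theta / 2
}

# Scalar noise-free right-move probability. `last_move` is "left"/"right"/NA;
# food_R/food_L flag food at the next available site on each arm.
# Deterministic comparisons use exact integer arithmetic (cross products for
# the means) and a small tolerance where the compared quantities are
# themselves computed numerically (posterior comparison, Gittins indices).
policy_prob <- function(model, A_R, B_R, A_L, B_L, last_move, food_R, food_L,
                        discount = 0.9) {
  switch(model,
    autocorrelation = if (is.na(last_move)) 0.5 else as.numeric(last_move == "right"),
    anti_autocorrelation = if (is.na(last_move)) 0.5 else as.numeric(last_move == "left"),
    most_successes = (A_R > A_L) + 0.5 * (A_R == A_L),
    highest_mean = {
      cr <- A_R * (A_L + B_L); cl <- A_L * (A_R + B_R)
      (cr > cl) + 0.5 * (cr == cl)
    },
    relative_successes = A_R / (A_R + A_L),
    relative_means = {
      mr <- A_R / (A_R + B_R); ml <- A_L / (A_L + B_L)
      mr / (mr + ml)
    },
    most_likely = {
      if (A_R == A_L && B_R == B_L) 0.5 else {
        q <- beta_superiority_vec(A_R, B_R, A_L, B_L)
        (q > 0.5 + 1e-9) + 0.5 * (abs(q - 0.5) <= 1e-9)
      }
    },
    probability_matching = beta_superiority_vec(A_R, B_R, A_L, B_L),
    chemotaxis = {
      if (food_R && !food_L) 1 else if (food_L && !food_R) 0 else 0.5
    },
    gittins = {
      if (A_R == A_L && B_R == B_L) 0.5 else {
        iR <- gittins_index_cached(A_R, B_R, discount)
        iL <- gittins_index_cached(A_L, B_L, discount)
        (iR > iL + 1e-9) + 0.5 * (abs(iR - iL) <= 1e-9)
      }
    },
    stop("unknown model '", model, "'", call. = FALSE))
}

#' Noise-free move probability of a decision model
#'
#' Evaluates the model's probability of moving right given the belief state
#' and the food indicators for the next available site on each arm
#' (`FALSE` past the end of an arm). The probability of moving left is the
#' complement; tied deterministic comparisons return 0.5.
#'
#' @param spec A [policy_spec()].
#' @param state A `belief_state` (see [init_state()]).
#' @param food_next_R,food_next_L Is there food at site `pos + 1` on the
#'   right / left arm?
#' @return Probability of moving right, before noise mixing.
#' @examples
#' s <- init_state()
#' s$A_R <- 3; s$A_L <- 1
#' base_prob(policy_spec("relative_successes"), s, FALSE, FALSE)  # 0.75
#' @export
base_prob <- function(spec, state, food_next_R = FALSE, food_next_L = FALSE) {
  stopifnot(inherits(spec, "policy_spec"), inherits(state, "belief_state"))
  policy_prob(spec$model, state$A_R, state$B_R, state$A_L, state$B_L,
              state$last_move, food_next_R, food_next_L,
              discount = spec$gittins_discount)
}

# Vectorised policy probabilities over a replayed state table (one row per
# move; columns A_R, B_R, A_L, B_L, last_move, food_R, food_L). Must agree
# with policy_prob() row by row.
policy_prob_vec <- function(model, st, discount = 0.9) {
  with(st, switch(model,
    autocorrelation = ifelse(is.na(last_move), 0.5, as.numeric(last_move == "right")),
    anti_autocorrelation = ifelse(is.na(last_move), 0.5, as.numeric(last_move == "left")),
    most_successes = (A_R > A_L) + 0.5 * (A_R == A_L),
    highest_mean = {
      cr <- A_R * (A_L + B_L); cl <- A_L * (A_R + B_R)
      (cr > cl) + 0.5 * (cr == cl)
    },
    relative_successes = A_R / (A_R + A_L),
    relative_means = {
      mr <- A_R / (A_R + B_R); ml <- A_L / (A_L + B_L)
      mr / (mr + ml)
    },
    most_likely = {
      sym <- A_R == A_L & B_R == B_L
      q <- beta_superiority_vec(A_R, B_R, A_L, B_L)
      ifelse(sym, 0.5, (q > 0.5 + 1e-9) + 0.5 * (abs(q - 0.5) <= 1e-9))
    },
    probability_matching = beta_superiority_vec(A_R, B_R, A_L, B_L),
    chemotaxis = ifelse(food_R & !food_L, 1, ifelse(food_L & !food_R, 0, 0.5)),
    gittins = {
      sym <- A_R == A_L & B_R == B_L
      iR <- vapply(seq_along(A_R), function(i)
        gittins_index_cached(A_R[i], B_R[i], discount), numeric(1))
      iL <- vapply(seq_along(A_L), function(i)
        gittins_index_cached(A_L[i], B_L[i], discount), numeric(1))
      ifelse(sym, 0.5, (iR > iL + 1e-9) + 0.5 * (abs(iR - iL) <= 1e-9))
    },
    stop("unknown model '", model, "'", call. = FALSE)))
}
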