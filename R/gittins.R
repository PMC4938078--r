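#' Gittins index of a Beta-Bernoulli arm by the calibration method
#'
#' The Gittins index of an arm with Beta(A, B) belief over its Bernoulli
#' reward probability is the constant per-step payoff `lambda*` that makes a
#' discounted decision-maker indifferent between retiring on `lambda*`
#' forever and playing the arm (with the option to retire later). It is
#' found by bisection on `lambda`: for each candidate the optimal-stopping
#' value of the arm is computed by backward induction over the posterior
#' lattice `(A + i, B + j)`, truncated at the first horizon `T` with
#' `discount^T < 1e-8` (hard cap 2000 steps), so the truncation error is
#' negligible relative to `tol`.
#'
#' @param A,B Posterior counts (successes/failures incl. pseudo-observations),
#'   both >= 1.
#' @param discount Discount factor in \[0, 1). At 0 the index is the myopic
#'   posterior mean `A / (A + B)`, returned exactly.
#' @param tol Bisection tolerance on the index (default 1e-4).
#' @return The index, a value in \[`A/(A+B)`, 1\].
#' @examples
#' gittins_index(1, 1, discount = 0)    # 0.5 exactly
#' gittins_index(1, 1, discount = 0.9)  # about 0.70: exploration bonus
#' @export
gittins_index <- function(A, B, discount, tol = 1e-4, bracket = NULL) {
  if (A < 1 || B < 1) stop("A and B must be >= 1", call. = FALSE)
  if (discount < 0 || discount >= 1) {
    stop("`discount` must be in [0, 1)", call. = FALSE)
  }
  mu0 <- A / (A + B)
  if (discount == 0) return(mu0)
  H <- min(2000L, as.integer(ceiling(log(1e-8) / log(discount))))
  gpow <- discount^(0:H)
  annuity <- cumsum(gpow)            # annuity[t] = (1 - discount^t)/(1 - discount)
  # Optimal-stopping value of the play option at the root, given retirement
  # rate lambda; vectorised backward induction over lattice depths.
  root_play_minus_retire <- function(lambda) {
    V <- numeric(H + 1L)             # depth H: no steps remain, value 0
    for (s in (H - 1L):0L) {
      i <- 0:s
      mu <- (A + i) / (A + B + s)
      play <- mu * (1 + discount * V[i + 2L]) + (1 - mu) * discount * V[i + 1L]
      retire <- lambda * annuity[H - s]
      V <- pmax(play, retire)
      if (s == 0L) return(play[1L] - retire)
    }
  }
  lo <- mu0
  hi <- 1
  if (!is.null(bracket)) {
    # a valid pre-bracket (e.g. from monotone neighbours) shortens bisection
    if (bracket[1L] >= mu0 && bracket[2L] <= 1 && bracket[1L] < bracket[2L]) {
      lo <- bracket[1L]
      hi <- bracket[2L]
    }
  }
  if (hi >= 1 && root_play_minus_retire(1) >= 0) return(1)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (root_play_minus_retire(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Per-discount memo of computed indices, shared across the package.
.gittins_memo <- new.env(parent = emptyenv())

gittins_index_cached <- function(A, B, discount, tol = 1e-4) {
  if (A != round(A) || B != round(B)) {
    return(gittins_index(A, B, discount, tol))
  }
  dkey <- sprintf("d%.10g", discount)
  tab <- .gittins_memo[[dkey]]
  if (is.null(tab)) {
    tab <- new.env(parent = emptyenv())
    .gittins_memo[[dkey]] <- tab
  }
  key <- paste(A, B, sep = ",")
  v <- tab[[key]]
  if (is.null(v)) {
    v <- gittins_index(A, B, discount, tol)
    tab[[key]] <- v
  }
  v
}

# Fill the memo for every integer state with A + B <= max_total, walking the
# lattice by depth so each bisection is bracketed by the already-computed
# neighbours: index(A-1, B) <= index(A, B) <= index(A, B-1). Cuts the
# per-state bisection from ~13 iterations to a handful; called before
# simulating the Gittins policy over long horizons.
ensure_gittins_lattice <- function(discount, max_total, tol = 1e-4) {
  if (discount == 0) return(invisible())
  dkey <- sprintf("d%.10g", discount)
  tab <- .gittins_memo[[dkey]]
  if (is.null(tab)) {
    tab <- new.env(parent = emptyenv())
    .gittins_memo[[dkey]] <- tab
  }
  for (d in 2:max_total) {
    for (a in seq_len(d - 1L)) {
      b <- d - a
      key <- paste(a, b, sep = ",")
      if (!is.null(tab[[key]])) next
      lo <- if (a > 1L) tab[[paste(a - 1L, b, sep = ",")]] else NULL
      hi <- if (b > 1L) tab[[paste(a, b - 1L, sep = ",")]] else NULL
      bracket <- c(max(a / (a + b), (lo %||% 0) - tol), min(1, (hi %||% 1) + tol))
      tab[[key]] <- gittins_index(a, b, discount, tol, bracket = bracket)
    }
  }
  invisible()
}

#' Tabulate Gittins indices on a posterior lattice
#'
#' Computes (and memoises) the index for every integer pair with
#' `A + B <= max_total`, returning a `gittins_table` that [gittins_policy()]
#' can consult; missing entries are computed on demand.
#'
#' @param discount Discount factor in \[0, 1).
#' @param max_total Largest `A + B` to pre-compute (default 12).
#' @param tol Bisection tolerance.
#' @return A `gittins_table`: list with `discount`, `tol` and a data frame
#'   `values` with columns `A`, `B`, `index`.
#' @export
gittins_table <- function(discount = 0.9, max_total = 12L, tol = 1e-4) {
  grid <- expand.grid(A = 1:(max_total - 1L), B = 1:(max_total - 1L))
  grid <- grid[grid$A + grid$B <= max_total, ]
  grid <- grid[order(grid$A, grid$B), ]
  grid$index <- mapply(function(a, b) gittins_index_cached(a, b, discount, tol),
                       grid$A, grid$B)
  rownames(grid) <- NULL
  structure(list(discount = discount, tol = tol, values = grid),
            class = "gittins_table")
}

#' @export
print.gittins_table <- function(x, ...) {
  cat(sprintf("<gittins_table> discount %g, %d entries (A+B <= %d)\n",
              x$discount, nrow(x$values), max(x$values$A + x$values$B)))
  invisible(x)
}

#' Write / read a Gittins table as JSON
#' @param table A [gittins_table()].
#' @param path File path.
#' @return `write_gittins_table()`: `path` invisibly; `read_gittins_table()`:
#'   a `gittins_table`.
#' @export
write_gittins_table <- function(table, path) {
  jsonlite::write_json(
    list(discount = table$discount, tol = table$tol, values = table$values),
    path, auto_unbox = TRUE, digits = I(17), dataframe = "columns")
  invisible(path)
}

#' @rdname write_gittins_table
#' @export
read_gittins_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(discount = obj$discount, tol = obj$tol,
                 values = as.data.frame(obj$values)),
            class = "gittins_table")
}

#' Gittins-index policy over a belief state
#'
#' Moves towards the arm with the higher index: probability 1 of moving
#' right if the right arm's index is higher, 0 if lower, 0.5 at a tie.
#' Index values come from `table` when supplied (extended on demand via the
#' package memo) or are computed directly.
#'
#' @param state A `belief_state`.
#' @param discount Discount factor; ignored when `table` is given.
#' @param table Optional [gittins_table()].
#' @return Probability of moving right (0, 0.5 or 1), before noise mixing.
#' @export
gittins_policy <- function(state, discount = 0.9, table = NULL) {
  stopifnot(inherits(state, "belief_state"))
  if (!is.null(table)) discount <- table$discount
  policy_prob("gittins", state$A_R, state$B_R, state$A_L, state$B_L,
              state$last_move, FALSE, FALSE, discount = discount)
}
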