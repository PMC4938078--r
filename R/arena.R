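#' Arm layouts and two-armed arena treatments
#'
#' An arm is a line of `arm_length` 1 mm agar sites; site 1 (adjacent to the
#' start block) always carries food so that the cell samples both arms at
#' least once. Each site either holds blank agar (magnitude 0) or oat-agar at
#' a given w/v oat concentration (0.05 = 5% in the binary treatments).
#' `arm_layout()` validates a magnitude vector and stamps it with the
#' `arm_layout` class.
#'
#' @param sites Numeric vector of per-site reward magnitudes (fraction w/v
#'   oat concentration; 0 for blank agar).
#' @return An `arm_layout` object (numeric vector with class attribute).
#' @examples
#' arm_layout(c(0.05, 0, 0.05))
#' @export
arm_layout <- function(sites) {
  sites <- as.numeric(sites)
  if (length(sites) < 2L) stop("an arm needs at least 2 sites", call. = FALSE)
  if (anyNA(sites) || any(sites < 0)) {
    stop("site magnitudes must be non-negative and non-missing", call. = FALSE)
  }
  if (sites[1L] <= 0) stop("site 1 must be rewarding", call. = FALSE)
  structure(sites, class = "arm_layout")
}

#' @export
print.arm_layout <- function(x, ...) {
  cat(sprintf("<arm_layout> %d sites, %d rewarding, total %.4g\n",
              length(x), sum(x > 0), sum(x)))
  invisible(x)
}

#' Evenly distributed reward layout
#'
#' Places `n_rewards` food sites of equal `magnitude` on an arm, spread as
#' evenly as the 1 mm site grid allows. Reward k of n (k = 0..n-1) occupies
#' site `1 + round(k * (L - 1) / (n - 1))`; with `n_rewards = 1` only site 1
#' is rewarding. Deterministic.
#'
#' @param arm_length Number of sites on the arm (default 31).
#' @param n_rewards Number of rewarding sites, between 1 and `arm_length`.
#' @param magnitude Oat concentration at each reward site (default 0.05).
#' @return An [arm_layout()].
#' @examples
#' which(make_even_layout(31, 8) > 0)
#' @export
make_even_layout <- function(arm_length = 31L, n_rewards, magnitude = 0.05) {
  arm_length <- as.integer(arm_length)
  n_rewards <- as.integer(n_rewards)
  if (n_rewards < 1L || n_rewards > arm_length) {
    stop("`n_rewards` must be between 1 and `arm_length`", call. = FALSE)
  }
  pos <- if (n_rewards == 1L) 1L else {
    1L + as.integer(round((0:(n_rewards - 1L)) * (arm_length - 1) / (n_rewards - 1)))
  }
  sites <- numeric(arm_length)
  sites[pos] <- magnitude
  arm_layout(sites)
}

#' Randomly distributed reward layout
#'
#' Site 1 is always rewarding; the remaining `n_rewards - 1` reward positions
#' are drawn uniformly without replacement from sites `2..arm_length`.
#' Bit-for-bit reproducible from `seed`.
#'
#' @inheritParams make_even_layout
#' @param seed Integer seed for the position draw.
#' @return An [arm_layout()].
#' @export
make_random_layout <- function(arm_length = 31L, n_rewards, magnitude = 0.05,
                               seed = NULL) {
  arm_length <- as.integer(arm_length)
  n_rewards <- as.integer(n_rewards)
  if (n_rewards < 1L || n_rewards > arm_length) {
    stop("`n_rewards` must be between 1 and `arm_length`", call. = FALSE)
  }
  pos <- with_seed(seed, {
    if (n_rewards > 1L) c(1L, sample(2:arm_length, n_rewards - 1L)) else 1L
  })
  sites <- numeric(arm_length)
  sites[pos] <- magnitude
  arm_layout(sites)
}

#' Non-binary (graded reward) arm pair
#'
#' Builds the HQ/LQ pair of the non-binary bandit: both arms carry
#' `n_rewards` rewarding sites at random positions (site 1 included), with
#' magnitudes drawn uniformly on [1%, 8%] oat-agar and then rescaled so the
#' HQ arm's magnitudes sum to `hq_total` and the LQ arm's to `hq_total / 2` —
#' the HQ arm carries exactly twice the total oat content of the LQ arm.
#' After rescaling, magnitudes are clipped back into [0.01, 0.08] and
#' renormalised iteratively (at most 100 rounds, tolerance 1e-9); the 2:1
#' total constraint always wins over the per-site range.
#'
#' The default `hq_total` of `n_rewards * 0.05` gives a mean site
#' concentration of 5% on the HQ arm and 2.5% on the LQ arm, mirroring the
#' 5% reward concentration of the binary treatments.
#'
#' @inheritParams make_random_layout
#' @param hq_total Target sum of site concentrations on the HQ arm.
#' @return A list with elements `hq` and `lq`, both [arm_layout()]s.
#' @export
make_nonbinary_pair <- function(arm_length = 31L, n_rewards = 8L,
                                hq_total = n_rewards * 0.05, seed = NULL) {
  if (n_rewards < 1L) stop("`n_rewards` must be >= 1", call. = FALSE)
  if (hq_total <= 0) stop("`hq_total` must be positive", call. = FALSE)
  with_seed(seed, {
    build <- function(total) {
      pos <- if (n_rewards > 1L) c(1L, sample(2:arm_length, n_rewards - 1L)) else 1L
      mag <- stats::runif(n_rewards, 0.01, 0.08)
      mag <- mag * (total / sum(mag))
      for (i in seq_len(100L)) {
        clipped <- pmin(pmax(mag, 0.01), 0.08)
        clipped <- clipped * (total / sum(clipped))
        if (max(abs(clipped - mag)) < 1e-9) {
          mag <- clipped
          break
        }
        mag <- clipped
      }
      mag <- mag * (total / sum(mag))  # totals exact even if range unsatisfiable
      sites <- numeric(arm_length)
      sites[pos] <- mag
      arm_layout(sites)
    }
    list(hq = build(hq_total), lq = build(hq_total / 2))
  })
}

#' Treatment: a named pair of arm layouts
#'
#' Bundles the HQ and LQ arm layouts with the side assignment. The arm with
#' the greater total reward is the high-quality (HQ) arm; which physical side
#' (left/right) carries it is randomised between replicates in the
#' experiments, so `hq_side` is assignable per replicate.
#'
#' @param name Treatment label, e.g. `"4e_vs_8e"`.
#' @param hq_arm,lq_arm [arm_layout()]s; `sum(hq_arm)` must be >= `sum(lq_arm)`.
#' @param hq_side `"left"` or `"right"`.
#' @param layout_kind `"even"`, `"random"` or `"nonbinary"`.
#' @param seed Seed used to instantiate random layouts (recorded, may be NULL).
#' @return A `treatment` object (list).
#' @export
treatment <- function(name, hq_arm, lq_arm, hq_side = "right",
                      layout_kind = c("even", "random", "nonbinary"),
                      seed = NULL) {
  layout_kind <- match.arg(layout_kind)
  stopifnot(inherits(hq_arm, "arm_layout"), inherits(lq_arm, "arm_layout"))
  if (length(hq_arm) != length(lq_arm)) {
    stop("both arms must have the same length", call. = FALSE)
  }
  if (sum(hq_arm) < sum(lq_arm)) {
    stop("HQ arm must carry at least as much total reward as LQ arm",
         call. = FALSE)
  }
  hq_side <- match.arg(hq_side, c("left", "right"))
  structure(
    list(name = name, hq_arm = hq_arm, lq_arm = lq_arm, hq_side = hq_side,
         layout_kind = layout_kind, seed = seed,
         equal_arms = isTRUE(all.equal(as.numeric(hq_arm), as.numeric(lq_arm)))),
    class = "treatment")
}

#' @export
print.treatment <- function(x, ...) {
  cat(sprintf("<treatment> %s: HQ %d sites (total %.4g) on %s, LQ %d sites (total %.4g)\n",
              x$name, sum(x$hq_arm > 0), sum(x$hq_arm), x$hq_side,
              sum(x$lq_arm > 0), sum(x$lq_arm)))
  invisible(x)
}

# Layouts keyed by physical side.
treatment_sides <- function(tr) {
  if (tr$hq_side == "right") {
    list(left = tr$lq_arm, right = tr$hq_arm)
  } else {
    list(left = tr$hq_arm, right = tr$lq_arm)
  }
}

#' Registry of the study's twelve treatments
#'
#' Returns constructors for the named treatments: the four equal-arm
#' baselines (31_vs_31, 1_vs_1, 8e_vs_8e, 8r_vs_8r), the strongly unequal
#' baseline 1_vs_8e, the 1:2 treatments 4e_vs_8e / 4r_vs_8r and their doubled
#' counterparts 8e_vs_16e / 8r_vs_16r, the harder 11:16 discriminations
#' 11e_vs_16e / 11r_vs_16r, and the graded-reward `nonbinary` bandit.
#' Suffix `e` marks evenly spaced reward sites, `r` random placement.
#'
#' @return Named list of functions `function(hq_side, seed)` returning a
#'   [treatment()]. Random and non-binary entries require a `seed`.
#' @examples
#' names(treatment_registry())
#' @export
treatment_registry <- function() {
  L <- 31L
  even_tr <- function(name, n_lq, n_hq) {
    function(hq_side = "right", seed = NULL) {
      treatment(name, make_even_layout(L, n_hq), make_even_layout(L, n_lq),
                hq_side, "even", seed)
    }
  }
  random_tr <- function(name, n_lq, n_hq) {
    function(hq_side = "right", seed = NULL) {
      if (is.null(seed)) stop("treatment '", name, "' needs a seed", call. = FALSE)
      seeds <- derive_seeds(seed, 2L)
      treatment(name, make_random_layout(L, n_hq, seed = seeds[1L]),
                make_random_layout(L, n_lq, seed = seeds[2L]),
                hq_side, "random", seed)
    }
  }
  list(
    "31_vs_31" = even_tr("31_vs_31", 31L, 31L),
    "1_vs_1" = even_tr("1_vs_1", 1L, 1L),
    "8e_vs_8e" = even_tr("8e_vs_8e", 8L, 8L),
    "8r_vs_8r" = random_tr("8r_vs_8r", 8L, 8L),
    "1_vs_8e" = even_tr("1_vs_8e", 1L, 8L),
    "4e_vs_8e" = even_tr("4e_vs_8e", 4L, 8L),
    "4r_vs_8r" = random_tr("4r_vs_8r", 4L, 8L),
    "8e_vs_16e" = even_tr("8e_vs_16e", 8L, 16L),
    "8r_vs_16r" = random_tr("8r_vs_16r", 8L, 16L),
    "11e_vs_16e" = even_tr("11e_vs_16e", 11L, 16L),
    "11r_vs_16r" = random_tr("11r_vs_16r", 11L, 16L),
    "nonbinary" = function(hq_side = "right", seed = NULL) {
      if (is.null(seed)) stop("treatment 'nonbinary' needs a seed", call. = FALSE)
      pair <- make_nonbinary_pair(L, 8L, seed = seed)
      treatment("nonbinary", pair$hq, pair$lq, hq_side, "nonbinary", seed)
    })
}

#' Instantiate a treatment by name
#'
#' @param name One of the names in [treatment_registry()].
#' @param hq_side `"left"` or `"right"`.
#' @param seed Integer seed; required for random/non-binary treatments.
#' @return A [treatment()].
#' @export
make_treatment <- function(name, hq_side = "right", seed = NULL) {
  reg <- treatment_registry()
  if (!name %in% names(reg)) {
    stop("unknown treatment '", name, "'; see treatment_registry()", call. = FALSE)
  }
  reg[[name]](hq_side = hq_side, seed = seed)
}

#' Write / read an arena as JSON
#'
#' Serialises a [treatment()] as
#' `{"name", "arm_length", "left", "right", "hq_side", "seed"}` with full
#' numeric precision; `read_arena()` inverts it exactly.
#'
#' @param tr A [treatment()].
#' @param path File path.
#' @return `write_arena()`: `path`, invisibly. `read_arena()`: a [treatment()].
#' @export
write_arena <- function(tr, path) {
  sides <- treatment_sides(tr)
  obj <- list(name = tr$name, arm_length = length(tr$hq_arm),
              left = as.numeric(sides$left), right = as.numeric(sides$right),
              hq_side = tr$hq_side, layout_kind = tr$layout_kind,
              seed = tr$seed)
  # digits = I(17): decimal significand long enough for exact double round-trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_arena
#' @export
read_arena <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  left <- arm_layout(obj$left)
  right <- arm_layout(obj$right)
  if (obj$hq_side == "right") {
    hq <- right; lq <- left
  } else {
    hq <- left; lq <- right
  }
  treatment(obj$name, hq, lq, obj$hq_side, obj$layout_kind %||% "even",
            obj$seed)
}
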