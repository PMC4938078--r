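#' Specify a synthetic dataset
#'
#' Describes a simulated experiment: which treatments to run, how many
#' replicates of each, the generating decision policy, and the fraction of
#' replicates flagged as excluded (emulating replicates discarded when the
#' cell left the arm). The defaults mirror the study's scale of tens of
#' replicates per treatment; real exclusion frequency is unreported, so it
#' defaults to 0.
#'
#' @param treatments Character vector of [treatment_registry()] names.
#' @param n_replicates Replicates per treatment (default 30).
#' @param model Generating [policy_spec()].
#' @param seed Master integer seed; everything downstream derives from it.
#' @param exclusion_rate Fraction in \[0, 1) of replicates flagged excluded.
#' @return A `dataset_spec` object.
#' @export
dataset_spec <- function(treatments, n_replicates = 30L,
                         model = policy_spec("relative_successes", 0.1),
                         seed = 1L, exclusion_rate = 0) {
  reg <- names(treatment_registry())
  unknown <- setdiff(treatments, reg)
  if (length(unknown)) {
    stop("unknown treatment(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (exclusion_rate < 0 || exclusion_rate >= 1) {
    stop("`exclusion_rate` must be in [0, 1)", call. = FALSE)
  }
  stopifnot(inherits(model, "policy_spec"))
  structure(list(treatments = treatments, n_replicates = as.integer(n_replicates),
                 model = model, seed = as.integer(seed),
                 exclusion_rate = exclusion_rate),
            class = "dataset_spec")
}

#' Generate a synthetic trajectory dataset
#'
#' For each treatment and replicate: instantiates the arena (fresh random
#' layouts per replicate for random/non-binary treatments), randomises which
#' side carries the HQ arm by a fair coin, simulates a trajectory with the
#' generating policy, and flags `exclusion_rate` of replicates as excluded
#' (they stay in the files; analysis functions skip them by default). The
#' manifest records every derived seed, so the dataset is bit-for-bit
#' reproducible from the spec alone.
#'
#' @param spec A [dataset_spec()].
#' @return A `pb_dataset`: list with `trajectories` (named list of
#'   `pb_trajectory`), `manifest` (data frame: `replicate_id`, `treatment`,
#'   `arena_seed`, `traj_seed`, `hq_side`, `excluded`) and `spec`.
#' @examples
#' ds <- generate_dataset(dataset_spec("4e_vs_8e", n_replicates = 5, seed = 7))
#' length(ds$trajectories)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  rows <- list()
  trajs <- list()
  with_seed(spec$seed, {
    for (tn in spec$treatments) {
      for (i in seq_len(spec$n_replicates)) {
        arena_seed <- sample.int(.Machine$integer.max, 1L)
        traj_seed <- sample.int(.Machine$integer.max, 1L)
        hq_side <- sample(c("left", "right"), 1L)
        excluded <- stats::runif(1) < spec$exclusion_rate
        tr <- make_treatment(tn, hq_side = hq_side, seed = arena_seed)
        traj <- simulate_trajectory(spec$model, tr, seed = traj_seed)
        traj$excluded <- excluded
        id <- sprintf("%s_%03d", tn, i)
        trajs[[id]] <- traj
        rows[[id]] <- data.frame(
          replicate_id = id, treatment = tn, arena_seed = arena_seed,
          traj_seed = traj_seed, hq_side = hq_side, excluded = excluded,
          stringsAsFactors = FALSE)
      }
    }
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(trajectories = trajs, manifest = manifest, spec = spec),
            class = "pb_dataset")
}

#' @export
print.pb_dataset <- function(x, ...) {
  cat(sprintf("<pb_dataset> %d trajectories over %d treatment(s), model %s (theta %g), seed %d\n",
              length(x$trajectories), length(x$spec$treatments),
              x$spec$model$model, x$spec$model$theta, x$spec$seed))
  invisible(x)
}

#' Write a dataset manifest as YAML
#'
#' Records the generating spec and every per-replicate seed and side
#' assignment, sufficient to regenerate the dataset exactly.
#'
#' @param dataset A [generate_dataset()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(dataset, path) {
  spec <- dataset$spec
  obj <- list(
    treatments = as.list(spec$treatments),
    n_replicates = spec$n_replicates,
    model = list(model = spec$model$model, theta = spec$model$theta,
                 gittins_discount = spec$model$gittins_discount),
    seed = spec$seed,
    exclusion_rate = spec$exclusion_rate,
    replicates = lapply(seq_len(nrow(dataset$manifest)), function(i) {
      as.list(dataset$manifest[i, ])
    }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Write / read trajectories as CSV
#'
#' One move per row with mandatory header columns `replicate_id`,
#' `treatment`, `hq_side`, `step`, `arm`, `site`, `reward`, plus an
#' `excluded` flag column (absent columns are treated as all-`FALSE` on
#' read). `read_trajectories()` validates each replicate — known arm labels,
#' per-arm site sequences consecutive from 2 — and reports malformed input
#' with the offending data row number. Arm length (and hence the end cause)
#' is taken from the terminal site, where a trajectory ends by construction.
#'
#' @param trajectories List of `pb_trajectory` or a `pb_dataset`.
#' @param path File path (UTF-8 CSV).
#' @return `write_trajectories()`: `path` invisibly; `read_trajectories()`:
#'   named list of `pb_trajectory`.
#' @export
write_trajectories <- function(trajectories, path) {
  if (inherits(trajectories, "pb_dataset")) trajectories <- trajectories$trajectories
  ids <- names(trajectories) %||% sprintf("rep_%03d", seq_along(trajectories))
  if (is.null(names(trajectories))) names(trajectories) <- ids
  rows <- lapply(ids, function(id) {
    traj <- trajectories[[id]]
    cbind(data.frame(replicate_id = id, treatment = traj$treatment_name,
                     hq_side = traj$hq_side, stringsAsFactors = FALSE),
          traj$moves,
          data.frame(excluded = isTRUE(traj$excluded)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trajectories
#' @param arenas Optional named list of [treatment()]s keyed by treatment
#'   name, re-attaching full arm layouts (needed by models that look ahead
#'   to undiscovered sites, e.g. chemotaxis).
#' @export
read_trajectories <- function(path, arenas = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  needed <- c("replicate_id", "treatment", "hq_side", "step", "arm", "site",
              "reward")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  if (!"excluded" %in% names(df)) df$excluded <- FALSE
  bad_arm <- which(!df$arm %in% c("left", "right"))
  if (length(bad_arm)) {
    stop("row ", bad_arm[1L], ": unknown arm label '", df$arm[bad_arm[1L]],
         "'", call. = FALSE)
  }
  out <- list()
  for (id in unique(df$replicate_id)) {
    rows <- which(df$replicate_id == id)
    sub <- df[rows, ]
    sub <- sub[order(sub$step), ]
    for (a in c("left", "right")) {
      s <- sub$site[sub$arm == a]
      expect <- seq.int(2L, 1L + length(s))
      if (length(s) && !identical(as.integer(s), expect)) {
        bad <- rows[which(sub$arm == a)[which(as.integer(s) != expect)[1L]]]
        stop("row ", bad, ": ", a,
             " arm sites of replicate '", id, "' not consecutive from 2",
             call. = FALSE)
      }
    }
    tn <- sub$treatment[1L]
    hq_side <- sub$hq_side[1L]
    L <- sub$site[nrow(sub)]
    tr <- if (!is.null(arenas) && tn %in% names(arenas)) arenas[[tn]] else NULL
    sides <- if (!is.null(tr)) treatment_sides(tr) else NULL
    end_arm <- sub$arm[nrow(sub)]
    out[[id]] <- new_trajectory(
      treatment_name = tn, hq_side = hq_side,
      moves = data.frame(step = sub$step, arm = sub$arm,
                         site = as.integer(sub$site), reward = sub$reward,
                         stringsAsFactors = FALSE),
      end_cause = if (end_arm == hq_side) "hq_end_first" else "lq_end_first",
      seed = NULL,
      left = if (!is.null(sides)) as.numeric(sides$left) else NULL,
      right = if (!is.null(sides)) as.numeric(sides$right) else NULL,
      arm_length = as.integer(L), excluded = isTRUE(sub$excluded[1L]))
  }
  out
}
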