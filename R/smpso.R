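#' Integer hyperparameter search space
#'
#' The box of integer-valued hyperparameters searched by [smpso_optimize()].
#' The default is the forecaster's space: blocks per stack, MLP width, pool
#' kernel, downsample factor, and lookback.
#'
#' @param names Dimension names.
#' @param lower,upper Integer bounds per dimension.
#' @return An object of class `search_space`.
#' @export
search_space <- function(names = c("n_blocks", "mlp_units", "n_pool_kernel_size",
                                   "n_freq_downsample", "lookback"),
                         lower = c(1, 100, 2, 1, 5),
                         upper = c(5, 500, 5, 5, 24)) {
  stopifnot(length(names) == length(lower), length(lower) == length(upper),
            all(lower <= upper))
  structure(list(names = names, lower = as.numeric(lower),
                 upper = as.numeric(upper)),
            class = "search_space")
}

#' Pareto dominance of objective vectors (both minimized)
#'
#' @param a,b Finite numeric objective vectors of equal length.
#' @return `TRUE` iff `a` is no worse than `b` in every objective and
#'   strictly better in at least one.
#' @export
dominates <- function(a, b) {
  stopifnot(length(a) == length(b), all(is.finite(a)), all(is.finite(b)))
  all(a <= b) && any(a < b)
}

#' Crowding distance of archive entries
#'
#' NSGA-II crowding distance over the objective space; boundary entries (the
#' extremes of each objective) get infinite distance.
#'
#' @param objectives Matrix (entries x objectives).
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(objectives) {
  n <- nrow(objectives)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (j in seq_len(ncol(objectives))) {
    o <- objectives[, j]
    ord <- order(o)
    rng <- o[ord[n]] - o[ord[1L]]
    d[ord[c(1L, n)]] <- Inf
    if (rng > 0) {
      for (i in 2:(n - 1L)) {
        d[ord[i]] <- d[ord[i]] + (o[ord[i + 1L]] - o[ord[i - 1L]]) / rng
      }
    }
  }
  d
}

new_archive <- function(capacity = 50L) {
  structure(list(positions = NULL, objectives = NULL,
                 capacity = as.integer(capacity)),
            class = "pareto_archive")
}

archive_size <- function(archive) {
  if (is.null(archive$objectives)) 0L else nrow(archive$objectives)
}

#' Insert a candidate into a bounded Pareto archive
#'
#' The candidate enters iff no current entry dominates it; entries it
#' dominates are removed. When the archive exceeds capacity, the entry with
#' the smallest crowding distance is pruned (boundary entries are never
#' pruned).
#'
#' @param archive A `pareto_archive`.
#' @param position Numeric decision vector.
#' @param objectives Finite numeric objective vector.
#' @return The updated archive.
#' @export
update_archive <- function(archive, position, objectives) {
  if (archive_size(archive) == 0L) {
    archive$positions <- matrix(position, nrow = 1L)
    archive$objectives <- matrix(objectives, nrow = 1L)
    return(archive)
  }
  n <- archive_size(archive)
  dominated_by_entry <- vapply(seq_len(n), function(i)
    dominates(archive$objectives[i, ], objectives) ||
      all(archive$objectives[i, ] == objectives), TRUE)
  if (any(dominated_by_entry)) return(archive)
  beats <- vapply(seq_len(n), function(i)
    dominates(objectives, archive$objectives[i, ]), TRUE)
  keep <- !beats
  archive$positions <- rbind(archive$positions[keep, , drop = FALSE], position)
  archive$objectives <- rbind(archive$objectives[keep, , drop = FALSE], objectives)
  if (archive_size(archive) > archive$capacity) {
    d <- crowding_distance(archive$objectives)
    drop_i <- which.min(d)
    archive$positions <- archive$positions[-drop_i, , drop = FALSE]
    archive$objectives <- archive$objectives[-drop_i, , drop = FALSE]
  }
  archive
}

#' Constriction factor for the velocity update
#'
#' `chi = 2 / |2 - phi - sqrt(phi^2 - 4*phi)|` with `phi = c1 + c2` when
#' `c1 + c2 > 4`, and `chi = 1` otherwise.
#'
#' @param c1,c2 Acceleration coefficients.
#' @return Scalar constriction factor.
#' @export
constriction <- function(c1, c2) {
  phi <- c1 + c2
  if (phi <= 4) return(1)
  2 / abs(2 - phi - sqrt(phi^2 - 4 * phi))
}

# One speed-constrained velocity/position update. Velocities are clamped to
# +/- delta_j = (upper_j - lower_j) / 2; positions are clamped into the box
# with velocity sign reversal at a bound.
velocity_position_update <- function(position, velocity, pbest, leader, space,
                                     inertia = 0.1) {
  d <- length(position)
  c1 <- runif(1, 1.5, 2.5); c2 <- runif(1, 1.5, 2.5)
  r1 <- runif(d); r2 <- runif(d)
  chi <- constriction(c1, c2)
  v <- chi * (inertia * velocity + c1 * r1 * (pbest - position) +
                c2 * r2 * (leader - position))
  delta <- (space$upper - space$lower) / 2
  v <- pmin(pmax(v, -delta), delta)
  x <- position + v
  low_hit <- x < space$lower; up_hit <- x > space$upper
  x[low_hit] <- space$lower[low_hit]
  x[up_hit] <- space$upper[up_hit]
  v[low_hit | up_hit] <- -v[low_hit | up_hit]
  list(position = x, velocity = v)
}

# Polynomial mutation (distribution index eta_m) of one position vector;
# each coordinate mutates with probability 1/d.
polynomial_mutation <- function(position, space, eta_m = 20) {
  d <- length(position)
  for (j in seq_len(d)) {
    if (runif(1) >= 1 / d) next
    x <- position[j]; lo <- space$lower[j]; up <- space$upper[j]
    if (up <= lo) next
    u <- runif(1)
    delta1 <- (x - lo) / (up - lo); delta2 <- (up - x) / (up - lo)
    pw <- 1 / (eta_m + 1)
    if (u < 0.5) {
      val <- 2 * u + (1 - 2 * u) * (1 - delta1)^(eta_m + 1)
      deltaq <- val^pw - 1
    } else {
      val <- 2 * (1 - u) + 2 * (u - 0.5) * (1 - delta2)^(eta_m + 1)
      deltaq <- 1 - val^pw
    }
    position[j] <- min(max(x + deltaq * (up - lo), lo), up)
  }
  position
}

#' Decode a continuous position into integer hyperparameters
#'
#' Each coordinate is rounded half-up to the nearest integer and clamped
#' into its bounds.
#'
#' @param position Numeric position vector.
#' @param space A [search_space()].
#' @return Named integer vector.
#' @export
decode_position <- function(position, space) {
  v <- floor(position + 0.5)
  v <- pmin(pmax(v, space$lower), space$upper)
  stats::setNames(as.integer(v), space$names)
}

# Binary tournament on crowding distance (larger wins) for leader selection.
select_leader <- function(archive) {
  n <- archive_size(archive)
  if (n == 1L) return(archive$positions[1L, ])
  d <- crowding_distance(archive$objectives)
  i <- sample.int(n, 1L); j <- sample.int(n, 1L)
  pick <- if (d[i] > d[j]) i else if (d[j] > d[i]) j else sample(c(i, j), 1L)
  archive$positions[pick, ]
}

#' Speed-constrained multi-objective particle swarm optimization
#'
#' Minimizes a vector-valued objective over an integer box: particles move
#' under the constriction-factor velocity rule with speed clamping, 15% of
#' particles undergo polynomial mutation each iteration, and an external
#' bounded archive keeps the mutually nondominated evaluations (crowding
#' distance pruning). Candidate evaluations are cached by decoded integer
#' key; evaluation failures yield a logged sentinel that never enters the
#' archive.
#'
#' @param evaluate_fn Function taking a named integer vector (a decoded
#'   candidate) and returning a finite numeric objective vector (minimized).
#' @param space A [search_space()].
#' @param swarm_size Number of particles (default 20).
#' @param iterations Number of update iterations (default 25).
#' @param capacity Archive capacity (default 50).
#' @param seed Master seed; the run is bit-reproducible from it.
#' @return A list of class `smpso_result`: the final `archive`, the
#'   `evaluations` tibble (decoded candidates and objectives), and counts.
#' @export
smpso_optimize <- function(evaluate_fn, space, swarm_size = 20L,
                           iterations = 25L, capacity = 50L, seed = 1L) {
  stopifnot(inherits(space, "search_space"), swarm_size >= 1, iterations >= 0)
  d <- length(space$lower)
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L; n_failures <- 0L
  eval_decoded <- function(position) {
    hp <- decode_position(position, space)
    key <- paste(hp, collapse = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    obj <- tryCatch(evaluate_fn(hp), error = function(e) {
      warning("candidate evaluation failed (", conditionMessage(e),
              "); skipping", call. = FALSE)
      NULL
    })
    n_evals <<- n_evals + 1L
    if (is.null(obj) || !all(is.finite(obj))) {
      n_failures <<- n_failures + 1L
      obj <- list(sentinel = TRUE)
    } else {
      obj <- list(sentinel = FALSE, objectives = as.numeric(obj), hp = hp)
    }
    cache[[key]] <- obj
    obj
  }
  local_seed(seed, {
    pos <- sapply(seq_len(d), function(j) runif(swarm_size, space$lower[j], space$upper[j]))
    pos <- matrix(pos, nrow = swarm_size)
    vel <- matrix(0, swarm_size, d)
    archive <- new_archive(capacity)
    pbest_pos <- pos
    pbest_obj <- vector("list", swarm_size)
    for (i in seq_len(swarm_size)) {
      r <- eval_decoded(pos[i, ])
      if (!r$sentinel) {
        pbest_obj[[i]] <- r$objectives
        archive <- update_archive(archive, pos[i, ], r$objectives)
      }
    }
    for (iter in seq_len(iterations)) {
      if (archive_size(archive) == 0L) break
      mutate_n <- max(0L, round(0.15 * swarm_size))
      mutate_idx <- if (mutate_n > 0) sample.int(swarm_size, mutate_n) else integer(0)
      for (i in seq_len(swarm_size)) {
        leader <- select_leader(archive)
        pb <- if (is.null(pbest_obj[[i]])) pos[i, ] else pbest_pos[i, ]
        upd <- velocity_position_update(pos[i, ], vel[i, ], pb, leader, space)
        x <- upd$position
        if (i %in% mutate_idx) x <- polynomial_mutation(x, space)
        pos[i, ] <- x; vel[i, ] <- upd$velocity
        r <- eval_decoded(x)
        if (r$sentinel) next
        archive <- update_archive(archive, x, r$objectives)
        if (is.null(pbest_obj[[i]]) || dominates(r$objectives, pbest_obj[[i]])) {
          pbest_pos[i, ] <- x; pbest_obj[[i]] <- r$objectives
        } else if (!dominates(pbest_obj[[i]], r$objectives)) {
          if (runif(1) < 0.5) { pbest_pos[i, ] <- x; pbest_obj[[i]] <- r$objectives }
        }
      }
    }
    evals <- eapply(cache, identity)
    ok <- Filter(function(e) !e$sentinel, evals)
    ev_tbl <- if (length(ok)) {
      dplyr::bind_rows(lapply(ok, function(e) {
        tibble::as_tibble_row(c(as.list(e$hp),
                                list(mae = e$objectives[1L],
                                     cwc = e$objectives[2L])))
      }))
    } else tibble::tibble()
    structure(list(archive = archive, space = space, evaluations = ev_tbl,
                   n_evaluations = n_evals, n_failures = n_failures,
                   seed = seed),
              class = "smpso_result")
  })
}

#' @export
print.smpso_result <- function(x, ...) {
  cat(sprintf("SMPSO result: %d unique evaluations (%d failed), archive of %d\n",
              x$n_evaluations, x$n_failures, archive_size(x$archive)))
  invisible(x)
}

#' Pick one configuration from a Pareto archive
#'
#' Objectives are min-max normalized over the archive; the entry closest
#' (Euclidean) to the ideal point (0, 0) wins; ties go to the entry with
#' the lower second objective (CWC).
#'
#' @param result An `smpso_result` (or a bare `pareto_archive`).
#' @param space The [search_space()] (taken from the result when omitted).
#' @return Named integer vector of decoded hyperparameters, with the chosen
#'   objective vector in attribute `"objectives"`.
#' @export
select_final <- function(result, space = NULL) {
  archive <- if (inherits(result, "smpso_result")) result$archive else result
  if (is.null(space) && inherits(result, "smpso_result")) space <- result$space
  n <- archive_size(archive)
  if (n == 0L) stop("empty archive", call. = FALSE)
  obj <- archive$objectives
  rng <- apply(obj, 2L, function(o) {
    r <- max(o) - min(o); if (r == 0) 1 else r
  })
  norm <- sweep(sweep(obj, 2L, apply(obj, 2L, min), `-`), 2L, rng, `/`)
  dist <- sqrt(rowSums(norm^2))
  best <- which(dist <= min(dist) + 1e-12)
  if (length(best) > 1L) best <- best[which.min(obj[best, 2L])]
  hp <- decode_position(archive$positions[best, ], space)
  attr(hp, "objectives") <- obj[best, ]
  hp
}

#' Objective evaluation for one hyperparameter candidate
#'
#' Trains the Gaussian-likelihood forecaster with the candidate's
#' architecture under a shared (reduced) training budget and scores it on
#' the validation partition: MAE of the interval median, and CWC of the
#' 90% Monte-Carlo interval.
#'
#' @param hp Named integer vector with entries `n_blocks`, `mlp_units`,
#'   `n_pool_kernel_size`, `n_freq_downsample`, `lookback`.
#' @param train_series,val_series Scaled, gap-free series tibbles (the
#'   chronological partitions).
#' @param target,covariates Channel names.
#' @param horizon Forecast horizon.
#' @param range_a Normalization range of the target in the scaled units
#'   (1 when metrics are computed on the scaled scale).
#' @param level Confidence level (default 0.90).
#' @param max_epochs,patience Shared training budget (defaults 150 / 50).
#' @param n_samples Monte-Carlo draws for the interval (default 200).
#' @param seed Seed shared across candidates for comparability.
#' @param ... Further [nhits_config()] overrides.
#' @return Numeric vector `c(mae, cwc)`.
#' @export
evaluate_candidate <- function(hp, train_series, val_series, target,
                               covariates, horizon, range_a = 1, level = 0.90,
                               max_epochs = 150L, patience = 50L,
                               n_samples = 200L, seed = 1L, ...) {
  lookback <- as.integer(hp[["lookback"]])
  cfg <- nhits_config(lookback = lookback, horizon = horizon,
                      n_blocks = hp[["n_blocks"]],
                      mlp_units = hp[["mlp_units"]],
                      n_pool_kernel_size = hp[["n_pool_kernel_size"]],
                      n_freq_downsample = hp[["n_freq_downsample"]],
                      loss = "gaussian", level = level,
                      max_epochs = max_epochs, patience = patience,
                      seed = seed, ...)
  tr_w <- make_windows(train_series, target, covariates, lookback, horizon)
  va_w <- make_windows(val_series, target, covariates, lookback, horizon)
  fit <- fit_nhits(tr_w, va_w, cfg)
  pred <- stats::predict(fit, va_w)
  iv <- mc_intervals(pred$mu, pred$sigma, n_samples = n_samples,
                     level = level, seed = seed)
  mae <- mean(abs(iv$median - va_w$C))
  im <- interval_metrics(va_w$C, iv$lower, iv$upper, range_a = range_a)
  c(mae = mae, cwc = im$cwc)
}
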