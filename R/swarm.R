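#' Swarm optimizer settings
#'
#' Configuration shared by the quantum-behaved ([run_qpso()]) and standard
#' ([run_pso()]) binary particle swarm optimizers.
#'
#' @param S Swarm size (default 20).
#' @param T Number of iterations (default 200).
#' @param alpha Contraction-expansion coefficient of the QPSO: either a
#'   single constant or `c(high, low)` for a linear decay across iterations
#'   (default `c(1, 0.5)`).
#' @param w PSO inertia weight, `c(high, low)` linear schedule (default
#'   `c(0.9, 0.4)`).
#' @param c1,c2 PSO cognitive and social acceleration constants (default 2).
#' @param vmax PSO velocity clamp (default 4).
#' @param seed Integer seed; every random draw of a run derives from it.
#' @return List of class `swarm_control`.
#' @export
swarm_control <- function(S = 20L, T = 200L, alpha = c(1, 0.5),
                          w = c(0.9, 0.4), c1 = 2, c2 = 2, vmax = 4,
                          seed = NULL) {
  if (S < 2L) stopf("swarm size S must be >= 2")
  if (T < 1L) stopf("iteration count T must be >= 1")
  if (any(alpha <= 0)) stopf("alpha must be positive")
  if (length(alpha) == 1L) alpha <- c(alpha, alpha)
  if (length(w) == 1L) w <- c(w, w)
  structure(list(S = as.integer(S), T = as.integer(T), alpha = alpha,
                 w = w, c1 = c1, c2 = c2, vmax = vmax, seed = seed),
            class = "swarm_control")
}

#' Mean best position of a swarm
#'
#' Component-wise mean of all particles' personal-best positions; the
#' attractor spread of the quantum update scales with each particle's
#' distance to it.
#'
#' @param pbest S x d matrix of personal-best positions.
#' @return Numeric d-vector.
#' @export
compute_mbest <- function(pbest) {
  stopifnot(is.matrix(pbest), nrow(pbest) >= 1L)
  colMeans(pbest)
}

#' Per-particle attractor point
#'
#' Dimension-wise convex combination of the personal and global best,
#' `p = phi * pbest + (1 - phi) * gbest` with `phi ~ U(0, 1)` drawn per
#' dimension (or supplied for testing).
#'
#' @param pbest,gbest Numeric d-vectors.
#' @param phi Optional d-vector of mixing weights; drawn uniformly if
#'   missing.
#' @return Numeric d-vector.
#' @export
attractor <- function(pbest, gbest, phi = stats::runif(length(pbest))) {
  phi * pbest + (1 - phi) * gbest
}

#' Quantum position update
#'
#' Samples the next position around the attractor:
#' `X' = p +/- alpha * |mbest - X| * ln(1/u)` with `u ~ U(0, 1)` per
#' dimension and the sign negative when `s >= 0.5`, positive otherwise
#' (`s ~ U(0, 1)`). When a particle sits on the mean best position the
#' spread term vanishes and the particle lands exactly on its attractor.
#'
#' @param X Current position (d-vector).
#' @param mbest Swarm mean-best position (d-vector).
#' @param p Attractor point (d-vector).
#' @param alpha Contraction-expansion coefficient (scalar).
#' @param u,s Optional d-vectors of uniform draws (drawn if missing).
#' @return New position (d-vector).
#' @export
qpso_position_update <- function(X, mbest, p, alpha,
                                 u = stats::runif(length(X)),
                                 s = stats::runif(length(X))) {
  sign <- ifelse(s >= 0.5, -1, 1)
  p + sign * alpha * abs(mbest - X) * log(1 / u)
}

#' Stochastic binarization of a real position
#'
#' Each dimension becomes 1 with probability `sigmoid(x) = 1/(1 + exp(-x))`:
#' bit_j = 1 iff `sigmoid(x_j) > u_j` with `u_j ~ U(0, 1)`. A 1 marks the
#' corresponding feature-vector entry as selected.
#'
#' @param x Real position vector.
#' @param u Optional uniform draws (drawn if missing).
#' @return Integer 0/1 vector of the same length.
#' @export
binarize <- function(x, u = stats::runif(length(x))) {
  as.integer(sigmoid(x) > u)
}

#' Personal-best update rule
#'
#' Strict improvement replaces the personal best; an equal or worse fitness
#' keeps the old one.
#'
#' @param pbest_position,pbest_fitness Current personal best and its
#'   fitness.
#' @param position,fitness Candidate position and its fitness.
#' @return List with `position` and `fitness` after the update.
#' @export
update_pbest <- function(pbest_position, pbest_fitness, position, fitness) {
  if (fitness > pbest_fitness)
    list(position = position, fitness = fitness)
  else
    list(position = pbest_position, fitness = pbest_fitness)
}

#' Run the binary quantum-behaved particle swarm optimizer
#'
#' Maximizes `fitness(mask)` over d-bit masks. Particles carry real-valued
#' positions; each iteration recomputes the swarm mean-best position,
#' samples a new position around each particle's attractor with spread
#' proportional to its distance from the mean best, binarizes it through
#' the sigmoid rule and re-evaluates the fitness. The global-best fitness
#' trace is monotone non-decreasing by construction and the whole run is
#' reproducible from `control$seed`.
#'
#' @param fitness Function taking an integer 0/1 vector of length `d` and
#'   returning a scalar in \[0, 1\]. Must be deterministic per mask.
#' @param d Number of bits (feature-vector entries).
#' @param control A [swarm_control()] configuration.
#' @return List of class `swarm_result`: `mask` (best 0/1 vector),
#'   `fitness`, `trace` (gbest fitness, initial state plus one entry per
#'   iteration), `position` (real gbest position), `evaluations`,
#'   `Q` (final per-particle mean search scope, `2 alpha |mbest - X|`,
#'   a diagnostic), and `optimizer`.
#' @examples
#' target <- c(1, 0, 1, 1, 0, 0)
#' res <- run_qpso(function(m) mean(m == target), d = 6,
#'                 control = swarm_control(T = 50, seed = 1))
#' res$mask
#' @export
run_qpso <- function(fitness, d, control = swarm_control()) {
  run_swarm(fitness, d, control, method = "qpso")
}

#' Run the standard binary particle swarm optimizer
#'
#' Velocity-based baseline sharing [run_qpso()]'s interface and sigmoid
#' binarization: `v' = w v + c1 r1 (pbest - X) + c2 r2 (gbest - X)` with
#' velocities clamped to `[-vmax, vmax]`, then `X' = X + v'`.
#'
#' @inheritParams run_qpso
#' @return As [run_qpso()].
#' @export
run_pso <- function(fitness, d, control = swarm_control()) {
  run_swarm(fitness, d, control, method = "pso")
}

run_swarm <- function(fitness, d, control, method = c("qpso", "pso")) {
  method <- match.arg(method)
  stopifnot(inherits(control, "swarm_control"), d >= 1L)
  S <- control$S; T <- control$T
  eval_mask <- function(mask) {
    f <- fitness(mask)
    if (!is.finite(f)) stopf("fitness returned a non-finite value (%s)", f)
    f
  }
  with_seed(control$seed, {
    X <- matrix(stats::runif(S * d, -1, 1), S, d)
    V <- matrix(0, S, d)
    masks <- matrix(0L, S, d)
    fit <- numeric(S)
    for (i in seq_len(S)) {
      masks[i, ] <- binarize(X[i, ])
      fit[i] <- eval_mask(masks[i, ])
    }
    pbest <- X
    pbest_fit <- fit
    pbest_mask <- masks
    gi <- which.max(pbest_fit)
    gbest <- pbest[gi, ]
    gbest_fit <- pbest_fit[gi]
    gbest_mask <- pbest_mask[gi, ]
    trace <- numeric(T + 1L)
    trace[1L] <- gbest_fit
    evals <- S
    Q <- numeric(S)
    for (t in seq_len(T)) {
      frac <- if (T > 1L) (t - 1) / (T - 1) else 0
      if (method == "qpso") {
        mbest <- compute_mbest(pbest)
        alpha <- control$alpha[1] - (control$alpha[1] - control$alpha[2]) * frac
      } else {
        w <- control$w[1] - (control$w[1] - control$w[2]) * frac
      }
      for (i in seq_len(S)) {
        if (method == "qpso") {
          p <- attractor(pbest[i, ], gbest)
          Q[i] <- mean(2 * alpha * abs(mbest - X[i, ]))
          X[i, ] <- qpso_position_update(X[i, ], mbest, p, alpha)
        } else {
          r1 <- stats::runif(d); r2 <- stats::runif(d)
          V[i, ] <- w * V[i, ] + control$c1 * r1 * (pbest[i, ] - X[i, ]) +
            control$c2 * r2 * (gbest - X[i, ])
          V[i, ] <- pmin(pmax(V[i, ], -control$vmax), control$vmax)
          X[i, ] <- X[i, ] + V[i, ]
        }
        mask <- binarize(X[i, ])
        f <- eval_mask(mask)
        evals <- evals + 1L
        if (f > pbest_fit[i]) {
          pbest[i, ] <- X[i, ]
          pbest_fit[i] <- f
          pbest_mask[i, ] <- mask
          if (f > gbest_fit) {
            gbest <- X[i, ]
            gbest_fit <- f
            gbest_mask <- mask
          }
        }
      }
      trace[t + 1L] <- gbest_fit
    }
    structure(
      list(mask = gbest_mask, fitness = gbest_fit, position = gbest,
           trace = trace, evaluations = evals, Q = Q,
           optimizer = method, control = control),
      class = "swarm_result"
    )
  })
}

#' @export
print.swarm_result <- function(x, ...) {
  cat(sprintf("%s run: d = %d, best fitness = %.4f, %d bits selected, %d evaluations\n",
              toupper(x$optimizer), length(x$mask), x$fitness,
              sum(x$mask), x$evaluations))
  invisible(x)
}

#' Serialize a swarm result to JSON
#'
#' @param result A `swarm_result` from [run_qpso()] or [run_pso()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
swarm_result_to_json <- function(result, path) {
  stopifnot(inherits(result, "swarm_result"))
  payload <- list(
    optimizer = result$optimizer,
    mask = result$mask,
    fitness = result$fitness,
    trace = result$trace,
    evaluations = result$evaluations,
    control = result$control[c("S", "T", "alpha", "w", "c1", "c2", "vmax",
                               "seed")]
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
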