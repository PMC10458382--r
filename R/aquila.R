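# Aquila Optimization: a population metaheuristic with four eagle-hunting
# search steps (vertical dive, glide attack, search-around-prey,
# walk-and-grab). The modified variant (MAO) replaces the Levy-flight factor
# of the glide step, and the constant exploitation factor of the
# search-around step, with an epoch-decaying, sign-flipping search control
# factor (M-SCF).

#' Bounded search space
#'
#' @param lb,ub numeric vectors of lower/upper bounds (\code{lb < ub}
#'   elementwise).
#' @param integer_mask logical vector: dimensions decoded by rounding
#'   (search itself stays continuous).
#' @param log_mask logical vector: dimensions sampled and stepped in log10
#'   space (bounds are transformed internally; emitted positions stay on the
#'   search scale and are back-transformed by
#'   \code{\link{decode_position}}).
#' @param names optional dimension names.
#' @return A \code{search_space} object.
#' @export
search_space <- function(lb, ub, integer_mask = NULL, log_mask = NULL,
                         names = NULL) {
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  d <- length(lb)
  if (length(ub) != d) stopf("`lb` and `ub` must have equal length")
  if (any(lb >= ub)) stopf("`lb` must be strictly below `ub` in every dimension")
  integer_mask <- integer_mask %||% rep(FALSE, d)
  log_mask <- log_mask %||% rep(FALSE, d)
  if (length(integer_mask) != d || length(log_mask) != d)
    stopf("masks must match the number of dimensions")
  if (any(log_mask & lb <= 0))
    stopf("log-scaled dimensions require strictly positive bounds")
  structure(list(lb = lb, ub = ub, integer_mask = as.logical(integer_mask),
                 log_mask = as.logical(log_mask), names = names),
            class = "search_space")
}

#' Aquila Optimizer configuration
#'
#' Defaults reproduce the study-scale configuration (population 250,
#' 250 epochs); hyperparameter tuning uses a smaller budget by passing its
#' own values.
#'
#' @param pop_size population size (>= 2).
#' @param max_iter number of epochs T (>= 2).
#' @param variant \code{"MAO"} (modified, default) or \code{"AO"}
#'   (original Levy-flight glide and constant exploitation factor).
#' @param seed RNG seed; runs are bit-reproducible per seed.
#' @param phase_switch fraction of epochs spent in the exploration phase
#'   (steps 1-2) before switching to exploitation (steps 3-4); default 2/3.
#' @param spiral_U,spiral_omega,spiral_r1 spiral-shape constants of the glide
#'   step (defaults 0.00565, 0.005, 10).
#' @param levy_beta Levy-stable index for the Mantegna step generator
#'   (default 1.5).
#' @param mscf_alt use the alternative algebraic reading of the search
#'   control factor, \code{2 exp(1 - t) (0.1 t / T) dir}, instead of the
#'   default \code{2 exp(1 - 0.1 t^2 / T) dir}.
#' @return An \code{ao_config} object.
#' @export
ao_config <- function(pop_size = 250, max_iter = 250,
                      variant = c("MAO", "AO"), seed = 1, phase_switch = 2 / 3,
                      spiral_U = 0.00565, spiral_omega = 0.005,
                      spiral_r1 = 10, levy_beta = 1.5, mscf_alt = FALSE) {
  variant <- match.arg(variant)
  if (pop_size < 2) stopf("`pop_size` must be >= 2")
  if (max_iter < 2) stopf("`max_iter` must be >= 2 (the quality function is undefined at T = 1)")
  if (phase_switch <= 0 || phase_switch >= 1) stopf("`phase_switch` must lie in (0, 1)")
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter), variant = variant,
                 seed = as.integer(seed), phase_switch = phase_switch,
                 spiral_U = spiral_U, spiral_omega = spiral_omega,
                 spiral_r1 = spiral_r1, levy_beta = levy_beta,
                 mscf_alt = mscf_alt),
            class = "ao_config")
}

#' Direction control factor
#'
#' @param r uniform draw in [0, 1].
#' @return +1 if \code{r < 0.5}, else -1.
#' @export
direction_factor <- function(r) {
  if (r < 0 || r > 1) stopf("`r` must lie in [0, 1]")
  if (r < 0.5) 1 else -1
}

#' Modified search control factor (M-SCF)
#'
#' \code{2 exp(1 - 0.1 t^2 / T) * dir(r)}: magnitude at most \code{2e},
#' non-increasing in the epoch, with a random sign flip. The alternative
#' reading \code{2 exp(1 - t) (0.1 t / T) dir(r)} is available via
#' \code{alt = TRUE}.
#'
#' @param t current epoch (0 <= t <= T).
#' @param T maximum epoch (>= 1).
#' @param r uniform draw in [0, 1] controlling the sign.
#' @param alt use the alternative algebraic reading.
#' @return Signed scalar factor.
#' @export
m_scf <- function(t, T, r, alt = FALSE) {
  if (T < 1) stopf("`T` must be >= 1")
  d <- direction_factor(r)
  if (alt) 2 * exp(1 - t) * (0.1 * t / T) * d
  else 2 * exp(1 - 0.1 * t * t / T) * d
}

#' Levy-stable step vector (Mantegna's algorithm)
#'
#' @param dim number of dimensions (>= 1).
#' @param beta stability index (default 1.5).
#' @param scale overall step scale (default 0.01, as in the original
#'   optimizer).
#' @return Numeric vector of heavy-tailed steps.
#' @export
levy_flight <- function(dim, beta = 1.5, scale = 0.01) {
  if (dim < 1) stopf("`dim` must be >= 1")
  sigma <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- rnorm(dim) * sigma
  v <- rnorm(dim)
  scale * u / abs(v)^(1 / beta)
}

clamp_position <- function(pos, lb, ub) pmin(pmax(pos, lb), ub)

# Map bounds onto the optimizer's internal scale (log10 where masked).
to_search_scale <- function(v, log_mask) {
  v[log_mask] <- log10(v[log_mask])
  v
}

# Per-dimension spiral coordinates of the glide step.
spiral_xy <- function(dim, r1, U, omega) {
  D1 <- seq_len(dim)
  rs <- r1 + U * D1
  theta <- -omega * D1 + 3 * pi / 2
  list(x = rs * sin(theta), y = rs * cos(theta))
}

#' Expanded exploration: vertical dive attack
#'
#' \code{best (1 - t/T) + (mean - best r)} with a fresh uniform \code{r},
#' clamped to the box.
#'
#' @param best best position so far.
#' @param mean_pos population mean position.
#' @param t,T epoch and maximum epoch.
#' @param lb,ub bounds.
#' @param r uniform draw in [0, 1] (fresh by default).
#' @return New position vector.
#' @export
step1_vertical_dive <- function(best, mean_pos, t, T, lb, ub, r = runif(1)) {
  clamp_position(best * (1 - t / T) + (mean_pos - best * r), lb, ub)
}

#' Narrowed exploration: full search with a short glide attack
#'
#' \code{S_R + F (best - current) r (y - x)} with per-dimension spiral
#' coordinates \code{(x, y)}; the factor \code{F} is the M-SCF under the
#' modified variant and a Levy-flight vector under the original.
#'
#' @param random_sol a randomly selected population member's position.
#' @param best best position so far.
#' @param current the candidate's current position.
#' @param t,T epoch and maximum epoch.
#' @param lb,ub bounds.
#' @param config an \code{\link{ao_config}}.
#' @param factor optional explicit search factor (scalar or per-dimension
#'   vector) overriding the variant's own draw.
#' @param r uniform draw in [0, 1] (fresh by default).
#' @return New position vector.
#' @export
step2_glide <- function(random_sol, best, current, t, T, lb, ub, config,
                        factor = NULL, r = runif(1)) {
  dim <- length(current)
  sp <- spiral_xy(dim, config$spiral_r1, config$spiral_U, config$spiral_omega)
  fac <- factor %||%
    (if (config$variant == "MAO") m_scf(t, T, runif(1), config$mscf_alt)
     else levy_flight(dim, config$levy_beta))
  clamp_position(random_sol + fac * (best - current) * r * (sp$y - sp$x),
                 lb, ub)
}

#' Expanded exploitation: search around prey and attack
#'
#' Per dimension j: \code{lb_j + r1 (ub_j - lb_j) + r2 (S_R_j - best_j) F
#' (1 - t/T)}; \code{F} is the M-SCF under the modified variant and the
#' original optimizer's constant exploitation factor 0.1 otherwise.
#'
#' @inheritParams step2_glide
#' @param r1,r2 uniform draws in [0, 1] (fresh by default).
#' @return New position vector.
#' @export
step3_search_around <- function(random_sol, best, t, T, lb, ub, config,
                                r1 = runif(1), r2 = runif(1)) {
  fac <- if (config$variant == "MAO") m_scf(t, T, runif(1), config$mscf_alt)
         else 0.1
  clamp_position(lb + r1 * (ub - lb) +
                   r2 * (random_sol - best) * fac * (1 - t / T), lb, ub)
}

#' Narrowed exploitation: walk and grab prey
#'
#' \code{QF best - G1 current r - G2 lev(D)} with quality function
#' \code{QF = t^((2r - 1)/(1 - T)^2)}, movement factor \code{G1 = 2 r - 1}
#' and flight slope \code{G2 = 2 (1 - t/T)}.
#'
#' @param best,current positions.
#' @param t,T epoch and maximum epoch (T >= 2).
#' @param lb,ub bounds.
#' @param config an \code{\link{ao_config}}.
#' @param qf_r,g1_r,r uniform draws in [0, 1] (fresh by default).
#' @return New position vector.
#' @export
step4_walk_grab <- function(best, current, t, T, lb, ub, config,
                            qf_r = runif(1), g1_r = runif(1), r = runif(1)) {
  qf <- quality_function(t, T, qf_r)
  g1 <- 2 * g1_r - 1
  g2 <- 2 * (1 - t / T)
  lev <- levy_flight(length(current), config$levy_beta)
  clamp_position(qf * best - (g1 * current * r) - g2 * lev, lb, ub)
}

#' Quality function of the walk-and-grab step
#' @param t,T epoch and maximum epoch (T >= 2).
#' @param r uniform draw in [0, 1].
#' @return \code{t^((2r - 1)/(1 - T)^2)}.
#' @export
quality_function <- function(t, T, r) {
  if (T < 2) stopf("quality function requires T >= 2")
  t^((2 * r - 1) / (1 - T)^2)
}

#' Minimize a bounded black-box objective with the Aquila Optimizer
#'
#' The population is initialized uniformly in the box. During the first
#' \code{phase_switch} fraction of epochs each candidate moves by the
#' vertical-dive or glide step (fair coin); afterwards by the
#' search-around-prey or walk-and-grab step. Replacement is greedy (a move is
#' kept only if it improves the candidate's fitness), so the best-so-far
#' trace is non-increasing. Dimensions flagged \code{log_mask} are searched
#' in log10 coordinates; the objective receives positions on the search
#' scale (use \code{\link{decode_position}} to map back).
#'
#' @param objective function mapping a position vector to a finite scalar
#'   (lower is better).
#' @param space a \code{\link{search_space}}.
#' @param config an \code{\link{ao_config}}.
#' @return An \code{ao_result}: list with \code{best_position},
#'   \code{best_fitness}, \code{history} (per-epoch best fitness, length
#'   \code{max_iter}), \code{evaluations}, \code{variant}.
#' @examples
#' sp <- search_space(rep(-100, 5), rep(100, 5))
#' res <- ao_optimize(function(x) sum(x^2), sp,
#'                    ao_config(pop_size = 20, max_iter = 50, seed = 7))
#' res$best_fitness
#' @export
ao_optimize <- function(objective, space, config = ao_config()) {
  if (!inherits(space, "search_space")) stopf("`space` must be a search_space")
  if (!inherits(config, "ao_config")) stopf("`config` must be an ao_config")
  lb <- to_search_scale(space$lb, space$log_mask)
  ub <- to_search_scale(space$ub, space$log_mask)
  d <- length(lb)
  evals <- 0L
  eval_fit <- function(pos) {
    evals <<- evals + 1L
    f <- objective(pos)
    if (!is.finite(f))
      stopf("objective returned a non-finite value at position (%s)",
            paste(signif(pos, 6), collapse = ", "))
    f
  }
  local_seed(config$seed, {
    T_max <- config$max_iter
    np <- config$pop_size
    pop <- matrix(runif(np * d), nrow = np) * rep(ub - lb, each = np) +
      rep(lb, each = np)
    fit <- apply(pop, 1, eval_fit)
    best_i <- which.min(fit)
    best <- pop[best_i, ]
    best_fit <- fit[best_i]
    history <- numeric(T_max)
    switch_epoch <- config$phase_switch * T_max
    for (t in seq_len(T_max)) {
      mean_pos <- colMeans(pop)
      for (i in seq_len(np)) {
        rnd <- pop[sample.int(np, 1), ]
        new_pos <- if (t <= switch_epoch) {
          if (runif(1) < 0.5)
            step1_vertical_dive(best, mean_pos, t, T_max, lb, ub)
          else
            step2_glide(rnd, best, pop[i, ], t, T_max, lb, ub, config)
        } else {
          if (runif(1) < 0.5)
            step3_search_around(rnd, best, t, T_max, lb, ub, config)
          else
            step4_walk_grab(best, pop[i, ], t, T_max, lb, ub, config)
        }
        new_fit <- eval_fit(new_pos)
        if (new_fit < fit[i]) {          # greedy replacement
          pop[i, ] <- new_pos
          fit[i] <- new_fit
          if (new_fit < best_fit) {
            best <- new_pos
            best_fit <- new_fit
          }
        }
      }
      history[t] <- best_fit
    }
    structure(list(best_position = best, best_fitness = best_fit,
                   history = history, evaluations = evals,
                   variant = config$variant),
              class = "ao_result")
  })
}

#' @export
print.ao_result <- function(x, ...) {
  cat(sprintf("<ao_result> %s: best fitness %.6g after %d evaluations (%d epochs)\n",
              x$variant, x$best_fitness, x$evaluations, length(x$history)))
  invisible(x)
}

#' Standard benchmark objectives
#'
#' Sphere, Rastrigin and Ackley functions, each with global minimum 0 at the
#' origin.
#'
#' @return Named list of objective functions.
#' @examples
#' benchmarks()$sphere(rep(0, 10))
#' @export
benchmarks <- function() {
  list(
    sphere = function(x) sum(x^2),
    rastrigin = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
    ackley = function(x) {
      n <- length(x)
      -20 * exp(-0.2 * sqrt(sum(x^2) / n)) - exp(sum(cos(2 * pi * x)) / n) +
        20 + exp(1)
    }
  )
}
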