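#' Sampler configuration
#'
#' Settings for the Hit-and-Run chain. The Boltzmann bias strength `beta`
#' interpolates between uniform sampling of the flux polytope (`beta = 0`)
#' and maximization of the linear objective `L(f)` (`beta -> Inf`): sampled
#' states appear with probability proportional to `exp(beta * L(f))`.
#'
#' Burn-in defaults to `10 D^2` steps and thinning to `D` (set when the
#' chain is run, once `D` is known): conservative choices given that a
#' rounded chain decorrelates in O(D^2) steps.
#'
#' @param n_samples Number of retained samples.
#' @param burn_in Discarded initial steps (`NULL` = `10 D^2`).
#' @param thinning Keep every `thinning`-th step (`NULL` = `D`).
#' @param beta Bias strength, `>= 0`.
#' @param objective Linear functional over full fluxes: either a named
#'   numeric vector of coefficients by reaction id, or a single reaction id
#'   (its flux), or `NULL` (required iff `beta > 0`).
#' @param seed RNG seed (mandatory; all runs are reproducible).
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_samples, burn_in = NULL, thinning = NULL,
                           beta = 0, objective = NULL, seed = 1234L) {
  stopifnot(n_samples >= 1, beta >= 0)
  if (beta > 0 && is.null(objective))
    stop("a linear objective is required when beta > 0")
  structure(list(n_samples = as.integer(n_samples), burn_in = burn_in,
                 thinning = thinning, beta = beta, objective = objective,
                 seed = as.integer(seed)),
            class = "sampler_config")
}

# Resolve an objective spec into a coefficient vector over reactions.
objective_vector <- function(objective, poly) {
  n <- length(poly$reaction_ids)
  w <- numeric(n)
  if (is.null(objective)) return(w)
  if (is.character(objective)) {
    j <- match(objective, poly$reaction_ids)
    if (anyNA(j)) stop("objective names unknown reactions: ",
                       paste(objective[is.na(j)], collapse = ", "))
    w[j] <- 1
  } else if (is.numeric(objective)) {
    if (is.null(names(objective)))
      stop("numeric objectives must be named by reaction id")
    j <- match(names(objective), poly$reaction_ids)
    if (anyNA(j)) stop("objective names unknown reactions: ",
                       paste(names(objective)[is.na(j)], collapse = ", "))
    w[j] <- objective
  } else stop("unsupported objective specification")
  w
}

#' Sample one point of a chord under a Boltzmann bias
#'
#' Exact inverse-CDF draw from the density proportional to
#' `exp(beta * slope * t)` on `[t_min, t_max]` — the projection of the
#' Boltzmann flux distribution onto the current Hit-and-Run direction. The
#' log-domain formulation stays stable for `|beta * slope * (t_max - t_min)|`
#' up to around 1e3 (and degrades gracefully beyond: draws concentrate at
#' the favored endpoint).
#'
#' @param t_min,t_max Chord interval, `t_min < t_max`.
#' @param beta Bias strength.
#' @param slope Directional derivative of the objective along the chord.
#' @param u Uniform random number in (0, 1); defaults to `runif(1)`.
#' @return A draw `t` in `[t_min, t_max]`.
#' @export
chord_sample <- function(t_min, t_max, beta = 0, slope = 0,
                         u = stats::runif(1)) {
  stopifnot(t_min < t_max)
  w <- beta * slope * (t_max - t_min)
  if (!is.finite(w)) stop("non-finite Boltzmann exponent")
  if (abs(w) < 1e-12) return(t_min + u * (t_max - t_min))
  if (w < 0) return(t_max - (chord_sample(0, 1, 1, -w, u)) * (t_max - t_min))
  # F^-1(u) on [0,1] for density ~ exp(w x): log1p(u (e^w - 1)) / w
  x <- if (w > 30) {
    # log-domain: log(u e^w + (1-u)) = w + log(u + (1-u) e^-w)
    (w + log(u + (1 - u) * exp(-w))) / w
  } else {
    log1p(u * expm1(w)) / w
  }
  t_min + x * (t_max - t_min)
}

#' Hit-and-Run sampling of a flux polytope
#'
#' Markov chain over the reduced polytope: from the current interior point,
#' draw an isotropic random direction under the rounding metric (a
#' standard-normal vector, normalized — the Marsaglia method — then mapped
#' through the Cholesky factor of the ellipsoid shape), compute the chord
#' through the polytope, and draw the next point on the chord uniformly
#' (`beta = 0`) or from the exponential chord density (`beta > 0`,
#' [chord_sample()]). Identical configuration and seed give a bit-identical
#' result.
#'
#' @param poly A [flux_polytope()].
#' @param config A [sampler_config()].
#' @param start Strictly interior starting point (`NULL`: rounding center
#'   or Chebyshev point).
#' @param rounding A `rounding_ellipsoid` (`NULL`: identity metric).
#' @param retry_cap Direction retries on numerically empty chords.
#' @return An object of class `sample_set`: `samples` (n x reactions),
#'   `independent_samples` (n x D), `meta`.
#' @export
hit_and_run <- function(poly, config, start = NULL, rounding = NULL,
                        retry_cap = 100L) {
  stopifnot(inherits(poly, "flux_polytope"),
            inherits(config, "sampler_config"))
  D <- poly$D
  burn_in <- if (is.null(config$burn_in)) 10L * D^2 else config$burn_in
  thinning <- max(1L, if (is.null(config$thinning)) D else config$thinning)
  set.seed(config$seed)
  Lmat <- if (is.null(rounding)) diag(D) else {
    ev <- eigen(rounding$shape, symmetric = TRUE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), D)
  }
  x <- if (!is.null(start)) as.numeric(start)
    else if (!is.null(rounding)) rounding$center
    else find_interior_point(poly)
  if (any(poly$h - poly$G %*% x <= 0))
    stop("hit_and_run: starting point is not strictly interior")
  w <- objective_vector(config$objective, poly)
  g_red <- as.vector(crossprod(poly$B, w))  # objective gradient, reduced
  n_steps <- burn_in + config$n_samples * thinning
  keep <- matrix(NA_real_, config$n_samples, D)
  GT <- poly$G
  kept <- 0L; step <- 0L
  while (kept < config$n_samples) {
    step <- step + 1L
    if (step > n_steps + retry_cap * config$n_samples)
      stop("hit_and_run: chain failed to advance (degenerate polytope?)")
    ok <- FALSE
    for (try in seq_len(retry_cap)) {
      z <- stats::rnorm(D)
      d <- as.vector(Lmat %*% z)
      nd <- sqrt(sum(d^2))
      if (nd < 1e-300) next
      d <- d / nd
      a <- as.vector(GT %*% d)
      s <- poly$h - as.vector(GT %*% x)
      pos <- a > 1e-14; neg <- a < -1e-14
      if (!any(pos) || !any(neg))
        stop("hit_and_run: unbounded chord; polytope must be bounded")
      t_max <- min(s[pos] / a[pos]); t_min <- max(-s[neg] / -a[neg])
      if (t_max - t_min > 1e-13 && t_min < 1e-9 && t_max > -1e-9) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("hit_and_run: no usable chord after ", retry_cap,
                  " retries; interior point too close to the boundary")
    slope <- sum(g_red * d)
    tt <- chord_sample(t_min, t_max, config$beta, slope)
    x <- x + tt * d
    if (step > burn_in && (step - burn_in) %% thinning == 0L) {
      kept <- kept + 1L
      keep[kept, ] <- x
    }
  }
  colnames(keep) <- poly$independent_ids
  samples <- keep %*% t(poly$B)
  colnames(samples) <- poly$reaction_ids
  structure(list(
    samples = samples, independent_samples = keep,
    meta = list(config = config, burn_in = burn_in, thinning = thinning,
                D = D, seed = config$seed,
                objective_mean = if (any(w != 0)) mean(samples %*% w) else NA)
  ), class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("Flux sample set: %d samples x %d reactions (D = %d, beta = %g, seed = %d)\n",
              nrow(x$samples), ncol(x$samples), x$meta$D,
              x$meta$config$beta, x$meta$seed))
  invisible(x)
}

#' Integrated autocorrelation time of a chain projection
#'
#' Windowed-sum estimate `tau = 1 + 2 sum_k rho_k`, with the window chosen
#' self-consistently (smallest `W >= 5 tau(W)`). For the slowest mode of a
#' sampled polytope, project the chain on the rounding ellipsoid's longest
#' axis.
#'
#' @param series Numeric vector, a scalar projection of the chain
#'   (length >= 100).
#' @return Estimated integrated autocorrelation time (>= 0.5).
#' @export
autocorrelation_time <- function(series) {
  n <- length(series)
  if (n < 100) {
    warning("chain too short for a reliable autocorrelation time")
    return(NA_real_)
  }
  if (stats::sd(series) == 0) return(1)
  lag_max <- min(n - 1L, 2000L)
  rho <- stats::acf(series, lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[-1]
  tau <- 1
  for (W in seq_len(lag_max)) {
    tau <- 1 + 2 * sum(rho[seq_len(W)])
    if (W >= 5 * tau) break
  }
  max(tau, 0.5)
}

#' Write / read a sample set (CSV + JSON sidecar)
#'
#' The CSV holds one full flux vector per row with reaction identifiers as
#' header; the JSON sidecar stores the configuration, seed and diagnostics
#' so a scan can be resumed or audited.
#'
#' @param ss A `sample_set`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `read_sample_set()` returns the restored `sample_set` (without
#'   the reduced coordinates).
#' @export
write_sample_set <- function(ss, path) {
  utils::write.csv(as.data.frame(ss$samples), path, row.names = FALSE)
  meta <- ss$meta
  meta$config <- unclass(meta$config)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_sample_set
#' @export
read_sample_set <- function(path) {
  samples <- as.matrix(utils::read.csv(path, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- meta$config
  meta$config <- sampler_config(
    n_samples = cfg$n_samples,
    burn_in = cfg$burn_in, thinning = cfg$thinning, beta = cfg$beta,
    objective = if (is.null(cfg$objective)) NULL else unlist(cfg$objective),
    seed = cfg$seed)
  structure(list(samples = samples, independent_samples = NULL, meta = meta),
            class = "sample_set")
}
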