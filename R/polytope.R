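# Reduced row echelon form by Gauss-Jordan elimination with partial
# pivoting inside the fixed column order, so the pivot/free column split is
# deterministic and unique for a given reaction ordering.
rref <- function(M, tol = 1e-9) {
  M <- as.matrix(M)
  m <- nrow(M); n <- ncol(M)
  pivots <- integer()
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    i <- which.max(abs(M[row:m, col])) + row - 1L
    if (abs(M[i, col]) <= tol) next
    if (i != row) M[c(i, row), ] <- M[c(row, i), ]
    M[row, ] <- M[row, ] / M[row, col]
    others <- setdiff(seq_len(m), row)
    M[others, ] <- M[others, ] - outer(M[others, col], M[row, ])
    M[others, col] <- 0  # exact zeros in the pivot column
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(R = M, pivots = pivots, rank = length(pivots))
}

#' Reduce a network's steady-state space to an independent-flux polytope
#'
#' Transforms the stoichiometric matrix to reduced row echelon form
#' (Gauss-Jordan elimination), which uniquely splits the fluxes into pivot
#' (dependent) and free (independent) variables and expresses every flux as
#' a linear function of the `D = N - rank(S)` independent ones. All flux
#' bounds, crowding rows and (for coupled networks) shared-coupling rows are
#' then mapped into inequality rows `G t <= h` over the independent
#' coordinates.
#'
#' Sampling requires a bounded body, so every flux must have finite bounds;
#' infinite bounds are replaced by `+/- fmax` (with a message), mirroring
#' the treatment of effectively unbounded nutrients such as oxygen.
#'
#' @param net A [metabolic_network()] or coupled network.
#' @param crowding Optional [crowding_spec()]; its rows are appended.
#' @param fmax Finite cap replacing infinite bounds.
#' @param tol Pivot tolerance of the elimination.
#' @return An object of class `flux_polytope`: `independent_ids`, `B` (N x D
#'   affine map), `offset`, `G`, `h`, `D`, `reaction_ids`.
#' @examples
#' poly <- flux_polytope(minimal_as_network(minimal_params(), 0.5))
#' poly$D # 2
#' @export
flux_polytope <- function(net, crowding = NULL, fmax = 1e4, tol = 1e-9) {
  S <- net$stoich
  n <- ncol(S)
  rr <- rref(S, tol = tol)
  pivots <- rr$pivots
  free <- setdiff(seq_len(n), pivots)
  D <- length(free)
  # dependent fluxes: R[, pivots] = I => f_piv = -R[, free] f_free
  B <- matrix(0, n, D, dimnames = list(colnames(S), colnames(S)[free]))
  B[free, ] <- diag(D)
  if (length(pivots))
    B[pivots, ] <- -rr$R[seq_along(pivots), free, drop = FALSE]
  lb <- net$lb; ub <- net$ub
  inf_b <- !is.finite(lb) | !is.finite(ub)
  if (any(inf_b)) {
    message("capping infinite bounds at +/-", fmax, " for: ",
            paste(net$reactions[inf_b], collapse = ", "))
    lb[!is.finite(lb)] <- -fmax
    ub[!is.finite(ub)] <- fmax
  }
  G <- rbind(B, -B)
  h <- c(ub, -lb)
  labels <- c(paste0("ub:", net$reactions), paste0("lb:", net$reactions))
  if (!is.null(net$shared_constraints)) {
    sc <- net$shared_constraints
    G <- rbind(G, sc$A %*% B)
    h <- c(h, sc$b)
    labels <- c(labels, paste0("shared:", seq_len(nrow(sc$A))))
  }
  if (!is.null(crowding)) {
    cr <- crowding_rows(net, crowding)
    G <- rbind(G, cr$A %*% B)
    h <- c(h, cr$b)
    labels <- c(labels, paste0("crowding:", seq_len(nrow(cr$A))))
  }
  # drop numerically-zero rows (fluxes fully determined to constants are
  # impossible here since the system is homogeneous, but dependent rows of
  # B can vanish)
  keep <- rowSums(abs(G)) > tol | h < 0
  rownames(G) <- labels
  structure(list(
    independent_ids = colnames(S)[free],
    reaction_ids = colnames(S),
    B = B, offset = numeric(n),
    G = G[keep, , drop = FALSE], h = h[keep],
    D = D, rank = rr$rank
  ), class = "flux_polytope")
}

#' @export
print.flux_polytope <- function(x, ...) {
  cat(sprintf("Flux polytope: D = %d independent fluxes (%s%s), %d inequality rows\n",
              x$D, paste(utils::head(x$independent_ids, 5), collapse = ", "),
              if (x$D > 5) ", ..." else "", nrow(x$G)))
  invisible(x)
}

#' Reconstruct full flux vectors from independent coordinates
#'
#' @param poly A [flux_polytope()].
#' @param t Vector of length `D` or matrix with `D` columns.
#' @return Full flux vector/matrix over all reactions.
#' @export
full_fluxes <- function(poly, t) {
  if (is.matrix(t)) {
    out <- t %*% t(poly$B)
    colnames(out) <- poly$reaction_ids
    out
  } else {
    stats::setNames(as.vector(poly$B %*% t) + poly$offset, poly$reaction_ids)
  }
}

# Per-coordinate LP bounds of the polytope; also detects unboundedness.
polytope_box <- function(poly) {
  D <- poly$D
  lo <- hi <- numeric(D)
  bg <- box_guess(poly)  # coarse a-priori box from single-coordinate rows
  for (j in seq_len(D)) {
    ej <- numeric(D); ej[j] <- 1
    lpmin <- solve_lp(ej, A = poly$G, b = poly$h, lb = bg$lo, ub = bg$hi)
    lpmax <- solve_lp(ej, A = poly$G, b = poly$h, lb = bg$lo, ub = bg$hi,
                      maximize = TRUE)
    if (lpmin$status != "optimal" || lpmax$status != "optimal")
      stop("polytope is empty or unbounded along ", poly$independent_ids[j])
    lo[j] <- lpmin$value; hi[j] <- lpmax$value
  }
  list(lo = lo, hi = hi)
}

# Crude finite box: single-coordinate rows first, LP fallback for the rest.
box_guess <- function(poly) {
  D <- poly$D
  lo <- rep(-Inf, D); hi <- rep(Inf, D)
  single <- which(rowSums(poly$G != 0) == 1)
  for (r in single) {
    j <- which(poly$G[r, ] != 0)
    a <- poly$G[r, j]; bd <- poly$h[r] / a
    if (a > 0) hi[j] <- min(hi[j], bd) else lo[j] <- max(lo[j], bd)
  }
  if (any(hi < lo))
    stop("infeasible polytope: contradictory bound rows for ",
         paste(poly$independent_ids[hi < lo], collapse = ", "))
  for (j in which(!is.finite(lo) | !is.finite(hi))) {
    ej <- numeric(D); ej[j] <- 1
    for (s in c(FALSE, TRUE)) {
      if (s && is.finite(hi[j])) next
      if (!s && is.finite(lo[j])) next
      lp <- solve_lp(ej, A = poly$G, b = poly$h, lb = -Inf, ub = Inf,
                     maximize = s)
      if (lp$status == "infeasible")
        stop("infeasible polytope: no point satisfies the constraints")
      if (lp$status != "optimal")
        stop("polytope unbounded along ", poly$independent_ids[j],
             "; add finite flux bounds (or a crowding constraint)")
      if (s) hi[j] <- lp$value else lo[j] <- lp$value
    }
  }
  list(lo = lo, hi = hi)
}

#' Find a strictly interior point of a flux polytope
#'
#' Chebyshev-center linear program: maximize the minimum slack radius `r`
#' over `G t + ||g_i|| r <= h`. Falls back to a Motzkin-style iterative
#' relaxation (repeatedly stepping past the most violated half-space) if the
#' LP route fails. Errors distinguish an infeasible polytope from one with
#' an empty interior (degenerate, at most a point/facet).
#'
#' @param poly A [flux_polytope()].
#' @param eps Required minimum slack.
#' @return Numeric vector of length `D`, strictly interior.
#' @export
find_interior_point <- function(poly, eps = 1e-9) {
  D <- poly$D
  bg <- box_guess(poly)
  norms <- sqrt(rowSums(poly$G^2))
  span <- max(bg$hi - bg$lo, 1)
  obj <- c(numeric(D), -1)  # minimize -r
  Ax <- cbind(poly$G, norms)
  lp <- solve_lp(obj, A = Ax, b = poly$h,
                 lb = c(bg$lo, 0), ub = c(bg$hi, span))
  if (lp$status == "optimal") {
    r <- lp$x[D + 1]
    if (r <= eps) {
      # feasible but no interior
      feas <- solve_lp(numeric(D), A = poly$G, b = poly$h,
                       lb = bg$lo, ub = bg$hi)
      if (feas$status == "optimal")
        stop("degenerate polytope: nonempty but with empty interior ",
             "(Chebyshev radius ", signif(max(r, 0), 3), ")")
      stop("infeasible polytope: no point satisfies the constraints")
    }
    return(lp$x[seq_len(D)])
  }
  if (lp$status == "infeasible")
    stop("infeasible polytope: no point satisfies the constraints")
  motzkin_point(poly, eps = eps)
}

# Motzkin-style relaxation: project beyond the most violated constraint
# until all slacks clear eps; diverges only for (near-)empty interiors.
motzkin_point <- function(poly, eps = 1e-9, max_iter = 5000L, lambda = 1.8) {
  bg <- box_guess(poly)
  x <- (bg$lo + bg$hi) / 2
  norms2 <- rowSums(poly$G^2)
  target <- pmax(eps, 1e-6 * abs(poly$h))
  for (it in seq_len(max_iter)) {
    slack <- poly$h - as.vector(poly$G %*% x)
    viol <- slack - target
    i <- which.min(viol)
    if (viol[i] >= 0) return(x)
    x <- x + lambda * (-viol[i] / norms2[i]) * poly$G[i, ]
  }
  stop("infeasible or empty-interior polytope: Motzkin relaxation did not ",
       "converge")
}

#' Chord of a line through a flux polytope
#'
#' For a strictly interior `point` and a `direction`, returns the exact
#' parameter interval `(t_min, t_max)` for which `point + t * direction`
#' satisfies every inequality, with `t_min < 0 < t_max`.
#'
#' @param poly A [flux_polytope()].
#' @param point Interior point (length `D`).
#' @param direction Direction vector (length `D`).
#' @return Numeric `c(t_min, t_max)`.
#' @export
chord <- function(poly, point, direction) {
  a <- as.vector(poly$G %*% direction)
  s <- poly$h - as.vector(poly$G %*% point)
  if (any(s < -1e-9))
    stop("chord: point is not inside the polytope")
  pos <- a > 1e-14; neg <- a < -1e-14
  if (!any(pos) || !any(neg)) {
    bad <- if (!any(pos)) "+" else "-"
    stop("unbounded chord in direction ", bad,
         paste(signif(direction, 3), collapse = ","),
         "; the polytope must be bounded for sampling")
  }
  t_max <- min(s[pos] / a[pos])
  t_min <- max(-s[neg] / -a[neg])
  c(t_min = t_min, t_max = t_max)
}

#' Rounding ellipsoid of a flux polytope
#'
#' Computes a metric under which the polytope is approximately round, so
#' Hit-and-Run directions favor the long axes and the chain mixes
#' polynomially despite anisotropy (flux polytopes of realistic networks
#' have axis ratios of order 1e4). The default method iteratively estimates
#' the sample covariance from short uniform chains and re-transforms
#' (covariance rounding); `"box"` uses the analytic axis-aligned box metric
#' from per-coordinate LP bounds (exact for boxes, a cheap first guess
#' otherwise).
#'
#' @param poly A [flux_polytope()].
#' @param method `"covariance"` or `"box"`.
#' @param seed RNG seed for the internal chains.
#' @param rounds Covariance-rounding iterations.
#' @param n_chain Chain length per iteration.
#' @param target_ratio Warn if the transformed body still has an estimated
#'   axis ratio above this.
#' @return An object of class `rounding_ellipsoid`: `center` (interior),
#'   `shape` (SPD matrix), `axis_ratio` (longest/shortest axis of the
#'   original body estimate).
#' @export
round_polytope <- function(poly, method = c("covariance", "box"),
                           seed = 1234L, rounds = 3L, n_chain = 400L * poly$D,
                           target_ratio = 10) {
  method <- match.arg(method)
  x0 <- find_interior_point(poly)
  box <- polytope_box(poly)
  w <- pmax(box$hi - box$lo, 1e-12)
  shape <- diag((w / sqrt(12))^2, poly$D)  # uniform-box covariance
  center <- (box$lo + box$hi) / 2
  # center must be interior; fall back to the Chebyshev point
  if (any(poly$h - poly$G %*% center <= 0)) center <- x0
  if (method == "box") {
    ell <- structure(list(center = center, shape = shape,
                          axis_ratio = max(w) / min(w)),
                     class = "rounding_ellipsoid")
    return(ell)
  }
  ratio0 <- NULL
  for (it in seq_len(rounds)) {
    ell <- structure(list(center = center, shape = shape, axis_ratio = NA),
                     class = "rounding_ellipsoid")
    cfg <- sampler_config(n_samples = n_chain, burn_in = 10L * poly$D,
                          thinning = 1L, beta = 0,
                          seed = seed + it)
    ss <- hit_and_run(poly, cfg, start = center, rounding = ell)
    X <- ss$independent_samples
    shape_new <- stats::cov(X)
    # regularize: keep SPD even for thin directions
    ev <- eigen(shape_new, symmetric = TRUE)
    lam <- pmax(ev$values, max(ev$values) * 1e-10)
    shape <- ev$vectors %*% (lam * t(ev$vectors))
    center_new <- colMeans(X)
    if (all(poly$h - poly$G %*% center_new > 0)) center <- center_new
    if (is.null(ratio0)) ratio0 <- sqrt(max(lam) / min(lam))
  }
  ev <- eigen(shape, symmetric = TRUE)
  center <- unname(center); dimnames(shape) <- NULL
  structure(list(center = center, shape = shape,
                 axis_ratio = sqrt(max(ev$values) / min(ev$values)),
                 initial_axis_ratio = max(w) / min(w),
                 target_ratio = target_ratio),
            class = "rounding_ellipsoid")
}

#' @export
print.rounding_ellipsoid <- function(x, ...) {
  cat(sprintf("Rounding ellipsoid in dimension %d, axis ratio %.3g\n",
              length(x$center), x$axis_ratio))
  invisible(x)
}

#' Serialize / restore polytopes and rounding ellipsoids as JSON
#'
#' Matrices are stored row-major with identifiers preserved so preprocessing
#' can be cached between scans.
#'
#' @param x A [flux_polytope()] or [round_polytope()] result.
#' @param path JSON file path.
#' @return `read_polytope()` returns the restored object.
#' @export
write_polytope <- function(x, path) {
  if (inherits(x, "flux_polytope")) {
    obj <- list(type = "flux_polytope",
                independent_ids = x$independent_ids,
                reaction_ids = x$reaction_ids,
                B = as.vector(t(x$B)), offset = x$offset,
                G = as.vector(t(x$G)), h = x$h,
                G_rows = rownames(x$G),
                D = x$D, rank = x$rank)
  } else if (inherits(x, "rounding_ellipsoid")) {
    obj <- list(type = "rounding_ellipsoid", center = x$center,
                shape = as.vector(t(x$shape)), axis_ratio = x$axis_ratio)
  } else stop("cannot serialize object of class ", class(x)[1])
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_polytope
#' @export
read_polytope <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "flux_polytope")) {
    n <- length(obj$reaction_ids); D <- obj$D
    B <- matrix(obj$B, n, D, byrow = TRUE,
                dimnames = list(obj$reaction_ids, obj$independent_ids))
    G <- matrix(obj$G, ncol = D, byrow = TRUE)
    rownames(G) <- obj$G_rows
    structure(list(independent_ids = obj$independent_ids,
                   reaction_ids = obj$reaction_ids,
                   B = B, offset = obj$offset, G = G, h = obj$h,
                   D = D, rank = obj$rank),
              class = "flux_polytope")
  } else if (identical(obj$type, "rounding_ellipsoid")) {
    D <- length(obj$center)
    structure(list(center = obj$center,
                   shape = matrix(obj$shape, D, D, byrow = TRUE),
                   axis_ratio = obj$axis_ratio),
              class = "rounding_ellipsoid")
  } else stop("unrecognized JSON container: ", path)
}
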