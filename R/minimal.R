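#' Flux state of one coarse-grained cell
#'
#' Assembles a consistent flux vector of the lumped model from the two free
#' fluxes. The pyruvate balance `f_ox + f_ldh = 2 f_glyc` and the ATP
#' accounting `f_atp = 2 f_glyc + 18 f_ox` (default yields) are imposed by
#' construction; glucose intake equals the glycolytic flux.
#'
#' @param f_glyc Glycolytic flux (mM/min, glucose units).
#' @param f_ldh LDH flux (mM/min, pyruvate units); negative means lactate
#'   intake through reverse LDH.
#' @param params A [minimal_params()] object.
#' @return An object of class `cell_fluxes` with fields `f_glyc`, `f_ox`,
#'   `f_ldh`, `U_G_in`, `f_atp`.
#' @export
cell_fluxes <- function(f_glyc, f_ldh, params) {
  stopifnot(inherits(params, "minimal_params"))
  f_ox <- params$pyr_per_glc * f_glyc - f_ldh
  if (f_ox < -1e-12)
    stop("negative OXPHOS flux: f_ldh exceeds available pyruvate")
  f_ox <- max(f_ox, 0)
  structure(list(
    f_glyc = f_glyc, f_ox = f_ox, f_ldh = f_ldh,
    U_G_in = f_glyc,
    f_atp = params$y_glyc * f_glyc + params$y_ox * f_ox
  ), class = "cell_fluxes")
}

#' @export
print.cell_fluxes <- function(x, ...) {
  cat(sprintf(
    "cell fluxes (mM/min): glyc %.5g | ox %.5g | LDH %+.5g | ATP %.5g\n",
    x$f_glyc, x$f_ox, x$f_ldh, x$f_atp))
  invisible(x)
}

# Left-hand side of the crowding constraint for one cell; the LDH term enters
# with |f_ldh| so lactate intake occupies volume too.
crowding_lhs <- function(cf, params) {
  params$a_glyc * cf$f_glyc + params$a_ox * cf$f_ox +
    params$a_ldh * abs(cf$f_ldh)
}

#' Crowding-constraint slack of a cell state
#'
#' Returns `phi_atp - (a_glyc f_glyc + a_ox f_ox + a_ldh |f_ldh|)`;
#' non-negative for every feasible state, zero when the volume budget is
#' saturated.
#'
#' @inheritParams cell_fluxes
#' @param cf A [cell_fluxes()] object.
#' @return Numeric slack.
#' @export
crowding_slack <- function(cf, params) params$phi_atp - crowding_lhs(cf, params)

#' ATP-maximizing state of a single crowding-constrained cell
#'
#' Closed-form optimum of the single-cell model. Below the crowding onset
#' `u_G` all glucose is fully oxidized (`f_atp = 38 U_G` at the default
#' yields, `f_ldh = 0`). Between `u_G` and the full-fermentation threshold
#' `v_G` the volume budget is saturated: the glucose flux that OXPHOS can no
#' longer process is diverted to LDH, with
#' `f_ox = (phi_atp - (a_glyc + 2 a_ldh) U_G) / (a_ox - a_ldh)` and
#' `f_ldh = 2 U_G - f_ox`. Above `v_G` one cell cannot process the supplied
#' glucose at all: the intake is capped at `v_G` and the returned object
#' carries attribute `capped = TRUE`.
#'
#' @param params A [minimal_params()] object.
#' @param U_G Glucose supply flux (mM/min), non-negative.
#' @return A [cell_fluxes()] object; attribute `capped` flags `U_G > v_G`.
#' @examples
#' p <- minimal_params()
#' single_cell_optimum(p, 0.5)$f_atp # 19
#' @export
single_cell_optimum <- function(params, U_G) {
  stopifnot(inherits(params, "minimal_params"),
            is.numeric(U_G), length(U_G) == 1L, is.finite(U_G))
  if (U_G < 0) stop("'U_G' must be non-negative")
  th <- thresholds(params)
  capped <- U_G > th$v_G
  u <- min(U_G, th$v_G)
  if (u <= th$u_G) {
    cf <- cell_fluxes(u, 0, params)
  } else {
    f_ox <- (params$phi_atp - (params$a_glyc + params$pyr_per_glc * params$a_ldh) * u) /
      (params$a_ox - params$a_ldh)
    f_ox <- max(f_ox, 0)
    cf <- cell_fluxes(u, params$pyr_per_glc * u - f_ox, params)
  }
  attr(cf, "capped") <- capped
  cf
}

# Componentwise feasible range of one cell over its (g, lambda) polygon,
# where g is the glucose intake and lambda the LDH flux (negative = lactate
# intake). Constraints (all linear):
#   g >= 0, g <= g_avail
#   lambda >= -l_avail              (lactate available from the partner)
#   f_ox = p g - lambda >= 0
#   y1 g + yo (p g - lambda) >= f_atp_min      (survival)
#   a_glyc g + a_ox (p g - lambda) +/- a_ldh lambda <= phi   (crowding, |.|)
# Extremes of each flux are attained at polygon vertices, enumerated exactly
# by intersecting constraint lines.
acceptor_range <- function(params, g_avail, l_avail) {
  p <- params$pyr_per_glc; y1 <- params$y_glyc; yo <- params$y_ox
  # rows: A %*% (g, lambda) <= b
  A <- rbind(
    c(-1, 0),                                   # g >= 0
    c(1, 0),                                    # g <= g_avail
    c(0, -1),                                   # lambda >= -l_avail
    c(-p, 1),                                   # f_ox >= 0
    c(-(y1 + p * yo), yo),                      # survival
    c(params$a_glyc + p * params$a_ox, -params$a_ox + params$a_ldh),
    c(params$a_glyc + p * params$a_ox, -params$a_ox - params$a_ldh)
  )
  b <- c(0, g_avail, l_avail, 0, -params$f_atp_min,
         params$phi_atp, params$phi_atp)
  n <- nrow(A)
  verts <- list()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    M <- A[c(i, j), , drop = FALSE]
    if (abs(det(M)) < 1e-14) next
    v <- solve(M, b[c(i, j)])
    if (all(A %*% v <= b + 1e-9)) verts[[length(verts) + 1L]] <- v
  }
  if (!length(verts))
    stop("starvation: the acceptor cell has no feasible state")
  V <- do.call(rbind, verts)
  g <- V[, 1]; lam <- V[, 2]
  fx <- cbind(f_glyc = g, f_ox = p * g - lam, f_ldh = lam,
              U_G_in = g, f_atp = y1 * g + yo * (p * g - lam))
  list(lo = apply(fx, 2, min), hi = apply(fx, 2, max), vertices = V)
}

# Build the acceptor_min / acceptor_max cell_fluxes pair from the polygon
# range: the feasible states minimizing / maximizing ATP production, with the
# componentwise per-flux range attached as attribute "range" (componentwise
# bounds need not be jointly attained).
acceptor_bounds <- function(params, g_avail, l_avail) {
  rng <- acceptor_range(params, g_avail, l_avail)
  V <- rng$vertices
  p <- params$pyr_per_glc; y1 <- params$y_glyc; yo <- params$y_ox
  atp <- y1 * V[, 1] + yo * (p * V[, 1] - V[, 2])
  vmin <- V[which.min(atp), ]; vmax <- V[which.max(atp), ]
  lo <- cell_fluxes(vmin[1], vmin[2], params)
  hi <- cell_fluxes(vmax[1], vmax[2], params)
  attr(lo, "range") <- rbind(lo = rng$lo, hi = rng$hi)
  attr(hi, "range") <- rbind(lo = rng$lo, hi = rng$hi)
  list(min = lo, max = hi)
}

#' Closed-form solution of the donor/acceptor lactate-shuttle model
#'
#' Two replicas of the crowding-constrained cell share a glucose supply
#' `U_G`. The donor maximizes its ATP production and can only secrete
#' lactate; the acceptor must produce at least `f_atp_min` of ATP and can
#' also import lactate through reverse LDH. The piecewise solution has four
#' regimes in the total supply:
#' \describe{
#'   \item{starved}{`U_G < 2 u_G0`: both cells cannot survive (error);}
#'   \item{glucose-shared}{`2 u_G0 <= U_G <= u_G1`: the donor takes all
#'     glucose except the `u_G0` the acceptor needs, both fully oxidative;}
#'   \item{lactate-subsidized}{`u_G1 < U_G <= u_G2`: the donor overflows
#'     lactate, the acceptor replaces glucose by donor lactate; the rerouted
#'     glucose is `delta_U_G = c (U_G - u_G1)/(38/18 - c)` with
#'     `c = (2 a_ox + a_glyc)/(a_ox - a_ldh)` (default yields);}
#'   \item{full-sequestration}{`U_G > u_G2`: the donor takes all glucose it
#'     can use (at most `v_G`); the acceptor state is no longer unique and
#'     its feasible range is reported.}
#' }
#'
#' @param params A [minimal_params()] object.
#' @param U_G Total glucose supply to the pair (mM/min).
#' @return An object of class `two_cell_solution` with fields `donor`,
#'   `acceptor_min`, `acceptor_max` ([cell_fluxes()]), `delta_U_G`, `regime`,
#'   `U_G`.
#' @examples
#' p <- minimal_params()
#' two_cell_solution(p, 2)
#' @export
two_cell_solution <- function(params, U_G) {
  stopifnot(inherits(params, "minimal_params"))
  th <- thresholds(params)
  if (U_G < 2 * th$u_G0 - 1e-12)
    stop(sprintf(
      "starvation: total glucose supply %.6g is below 2*u_G0 = %.6g",
      U_G, 2 * th$u_G0))
  p <- params$pyr_per_glc
  y_tot <- params$y_glyc + p * params$y_ox
  cc <- th$overflow_gain
  if (U_G <= th$u_G1) {
    regime <- "glucose-shared"
    delta <- 0
    donor <- single_cell_optimum(params, U_G - th$u_G0)
    acc <- cell_fluxes(th$u_G0, 0, params)
    acc_min <- acc_max <- acc
  } else if (U_G <= th$u_G2) {
    regime <- "lactate-subsidized"
    delta <- cc * (U_G - th$u_G1) / (y_tot / params$y_ox - cc)
    donor <- single_cell_optimum(params, U_G - th$u_G0 + delta)
    g_acc <- th$u_G0 - delta
    acc <- cell_fluxes(g_acc, -donor$f_ldh, params)
    # spec contract: the acceptor's own crowding constraint is assumed
    # non-binding in this regime
    if (crowding_slack(acc, params) < -1e-9)
      stop("model assumption violated: acceptor crowding constraint binds ",
           "in the lactate-subsidized regime")
    acc_min <- acc_max <- acc
  } else {
    regime <- "full-sequestration"
    delta <- th$u_G0
    donor <- single_cell_optimum(params, U_G)   # caps at v_G internally
    g_avail <- max(0, U_G - donor$U_G_in)
    ab <- acceptor_bounds(params, g_avail, donor$f_ldh)
    acc_min <- ab$min; acc_max <- ab$max
  }
  structure(list(
    donor = donor, acceptor_min = acc_min, acceptor_max = acc_max,
    delta_U_G = delta, regime = regime, U_G = U_G,
    thresholds = th
  ), class = "two_cell_solution")
}

#' @export
print.two_cell_solution <- function(x, ...) {
  cat(sprintf("Two-cell lactate-shuttle solution at U_G = %.6g (%s)\n",
              x$U_G, x$regime))
  cat("  donor:    "); print(x$donor)
  if (identical(x$acceptor_min, x$acceptor_max)) {
    cat("  acceptor: "); print(x$acceptor_min)
  } else {
    cat("  acceptor (ATP-min): "); print(x$acceptor_min)
    cat("  acceptor (ATP-max): "); print(x$acceptor_max)
  }
  cat(sprintf("  glucose rerouted delta_U_G = %.6g\n", x$delta_U_G))
  invisible(x)
}
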