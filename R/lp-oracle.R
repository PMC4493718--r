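#' Linear-programming oracle for the donor/acceptor model
#'
#' Independent verification route for [two_cell_solution()]: the six-flux
#' model (glycolysis, OXPHOS and LDH per cell) is written down as a linear
#' program — pyruvate balance per cell, crowding constraint per cell (with
#' the absolute-value LDH term encoded as two rows for the acceptor),
#' survival bound per cell, shared glucose supply and donor-to-acceptor-only
#' lactate shuttle — and solved with a generic simplex routine. The donor's
#' ATP production is maximized first; among ATP-optimal donor states the
#' minimal-glucose one is selected (the autonomous-maximizer solution
#' concept: ATP-equal completions that burn extra glucose through
#' fermentation are discarded), and the acceptor's feasible range is then
#' obtained by minimizing/maximizing each acceptor flux with the donor so
#' pinned.
#'
#' @inheritParams two_cell_solution
#' @return An object of class `two_cell_solution` (same shape as
#'   [two_cell_solution()]); the acceptor bound objects carry the
#'   componentwise flux ranges in attribute `"range"`.
#' @export
lp_oracle <- function(params, U_G) {
  stopifnot(inherits(params, "minimal_params"))
  th <- thresholds(params)
  p <- params$pyr_per_glc; y1 <- params$y_glyc; yo <- params$y_ox
  # variables x = (g_d, ox_d, l_d, g_a, ox_a, l_a)
  n <- 6L
  lmax <- p * th$v_G  # largest lactate flux any cell can carry
  lb <- c(0, 0, 0, 0, 0, -lmax)
  ub <- c(rep(th$v_G, 1), rep(lmax, 2), th$v_G, lmax, lmax)
  Aeq <- rbind(
    c(p, -1, -1, 0, 0, 0),   # donor pyruvate balance
    c(0, 0, 0, p, -1, -1))   # acceptor pyruvate balance
  beq <- c(0, 0)
  a_g <- params$a_glyc; a_o <- params$a_ox; a_l <- params$a_ldh
  A <- rbind(
    c(a_g, a_o, a_l, 0, 0, 0),        # donor crowding (l_d >= 0)
    c(0, 0, 0, a_g, a_o, a_l),        # acceptor crowding, +a_ldh row
    c(0, 0, 0, a_g, a_o, -a_l),       # acceptor crowding, -a_ldh row
    c(-y1, -yo, 0, 0, 0, 0),          # donor survival
    c(0, 0, 0, -y1, -yo, 0),          # acceptor survival
    c(1, 0, 0, 1, 0, 0),              # shared glucose
    c(0, 0, -1, 0, 0, -1))            # joint lactate non-negativity
  b <- c(params$phi_atp, params$phi_atp, params$phi_atp,
         -params$f_atp_min, -params$f_atp_min, U_G, 0)
  obj_don <- c(y1, yo, 0, 0, 0, 0)
  opt <- solve_lp(obj_don, A, b, Aeq, beq, lb, ub, maximize = TRUE)
  if (opt$status != "optimal")
    stop(sprintf(
      "starvation: two-cell LP is %s at U_G = %.6g (survival needs U_G >= %.6g)",
      opt$status, U_G, 2 * th$u_G0))
  don_atp <- opt$value
  # The ATP-optimal donor flux vector is degenerate (oxidation can be traded
  # for fermentation plus extra glucose at equal ATP); the model's solution
  # concept is the autonomous ATP-maximizing donor at its glucose share, i.e.
  # the minimal-glucose optimum. Resolve the tie lexicographically, then pin
  # the donor (objective and glucose intake fix its whole flux vector).
  pin <- 1e-9 * (1 + abs(don_atp))
  A1 <- rbind(A, -obj_don); b1 <- c(b, -(don_atp - pin))
  g_opt <- solve_lp(c(1, 0, 0, 0, 0, 0), A1, b1, Aeq, beq, lb, ub)
  if (g_opt$status != "optimal") stop("lp_oracle: donor tie-break LP failed")
  A2 <- rbind(A1, c(1, 0, 0, 0, 0, 0))
  b2 <- c(b1, g_opt$value + pin)
  span <- function(w) {
    lo <- solve_lp(w, A2, b2, Aeq, beq, lb, ub, maximize = FALSE)
    hi <- solve_lp(w, A2, b2, Aeq, beq, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("lp_oracle: acceptor range subproblem failed")
    list(lo = lo$value, hi = hi$value, xlo = lo$x, xhi = hi$x)
  }
  r_g <- span(c(0, 0, 0, 1, 0, 0))
  r_ox <- span(c(0, 0, 0, 0, 1, 0))
  r_l <- span(c(0, 0, 0, 0, 0, 1))
  r_atp <- span(c(0, 0, 0, y1, yo, 0))
  rng <- rbind(
    lo = c(f_glyc = r_g$lo, f_ox = r_ox$lo, f_ldh = r_l$lo,
           U_G_in = r_g$lo, f_atp = r_atp$lo),
    hi = c(f_glyc = r_g$hi, f_ox = r_ox$hi, f_ldh = r_l$hi,
           U_G_in = r_g$hi, f_atp = r_atp$hi))
  x_atp_lo <- r_atp$xlo; x_atp_hi <- r_atp$xhi
  donor <- cell_fluxes(g_opt$x[1], g_opt$x[3], params)
  acc_min <- cell_fluxes(x_atp_lo[4], x_atp_lo[6], params)
  acc_max <- cell_fluxes(x_atp_hi[4], x_atp_hi[6], params)
  attr(acc_min, "range") <- rng
  attr(acc_max, "range") <- rng
  delta <- max(0, min(th$u_G0, donor$U_G_in - (U_G - th$u_G0)))
  regime <- if (U_G <= th$u_G1 + 1e-12) "glucose-shared"
    else if (U_G <= th$u_G2 + 1e-12) "lactate-subsidized"
    else "full-sequestration"
  structure(list(
    donor = donor, acceptor_min = acc_min, acceptor_max = acc_max,
    delta_U_G = delta, regime = regime, U_G = U_G, thresholds = th
  ), class = "two_cell_solution")
}
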