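#' Parameters of the coarse-grained crowding-constrained cell model
#'
#' Bundles the volume-per-flux coefficients of the three lumped ATP-producing
#' pathways (glycolysis, LDH, OXPHOS), the volume fraction available for ATP
#' production, the integer yields of the lumped stoichiometry, and the minimum
#' ATP flux a cell needs to survive.
#'
#' The defaults are the empirical estimates used throughout the model:
#' `a_glyc = 3e-3`, `a_ldh = 4.6e-4`, `a_ox = 2e-1` (min/mM) and
#' `phi_atp = 0.4`. Glycolysis yields 2 ATP and 2 pyruvate per glucose and
#' oxidation yields 18 ATP per pyruvate, so the maximum yield is 38 ATP per
#' glucose. When `f_atp_min` is `NULL` it defaults to `1 * u_G` (numerically:
#' the survival ATP flux equals one crowding-threshold unit of glucose flux,
#' the "1 u_G" convention of the large-network model), so the starvation
#' supply is `u_G0 = u_G / 38`. Any larger value up to the crowding capacity
#' may be supplied; note that for `f_atp_min >= 38 u_G` the acceptor of the
#' two-cell model has no crowding slack left and the lactate-subsidized
#' regime disappears (lactate ATP is more volume-costly per ATP than glucose
#' ATP whenever `(a_ox + a_ldh)/y_ox > (a_glyc + 2 a_ox)/38`).
#'
#' @param a_glyc Volume occupied per unit glycolytic flux (min/mM).
#' @param a_ldh Volume occupied per unit LDH flux (min/mM).
#' @param a_ox Volume occupied per unit OXPHOS flux, in pyruvate units (min/mM).
#' @param phi_atp Volume fraction available for ATP production, in (0, 1].
#' @param f_atp_min Minimum ATP production flux per cell (mM/min); default
#'   `(y_glyc + pyr_per_glc * y_ox) * u_G`.
#' @param y_glyc ATP per glucose via glycolysis (integer).
#' @param y_ox ATP per pyruvate via oxidation (integer).
#' @param pyr_per_glc Pyruvate molecules per glucose (integer).
#'
#' @return An object of class `minimal_params`.
#' @examples
#' p <- minimal_params()
#' thresholds(p)
#' @export
minimal_params <- function(a_glyc = 3e-3, a_ldh = 4.6e-4, a_ox = 2e-1,
                           phi_atp = 0.4, f_atp_min = NULL,
                           y_glyc = 2L, y_ox = 18L, pyr_per_glc = 2L) {
  for (nm in c("a_glyc", "a_ldh", "a_ox")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm))
  }
  if (!is.numeric(phi_atp) || phi_atp <= 0 || phi_atp > 1)
    stop("'phi_atp' must lie in (0, 1]")
  if (!(a_ldh < a_glyc && a_glyc < a_ox))
    stop("coefficients must be ordered a_ldh < a_glyc < a_ox")
  y_glyc <- as.integer(y_glyc); y_ox <- as.integer(y_ox)
  pyr_per_glc <- as.integer(pyr_per_glc)
  if (any(c(y_glyc, y_ox, pyr_per_glc) < 1L))
    stop("yields must be positive integers")
  y_tot <- y_glyc + pyr_per_glc * y_ox
  u_g <- phi_atp / (pyr_per_glc * a_ox + a_glyc)
  if (is.null(f_atp_min)) f_atp_min <- u_g
  if (!is.numeric(f_atp_min) || f_atp_min < 0)
    stop("'f_atp_min' must be non-negative")
  structure(list(
    a_glyc = a_glyc, a_ldh = a_ldh, a_ox = a_ox, phi_atp = phi_atp,
    f_atp_min = f_atp_min, y_glyc = y_glyc, y_ox = y_ox,
    pyr_per_glc = pyr_per_glc
  ), class = "minimal_params")
}

#' @export
print.minimal_params <- function(x, ...) {
  cat("Coarse-grained crowding model parameters\n")
  cat(sprintf("  a_glyc = %g, a_ldh = %g, a_ox = %g (min/mM)\n",
              x$a_glyc, x$a_ldh, x$a_ox))
  cat(sprintf("  phi_atp = %g, f_atp_min = %g mM/min\n",
              x$phi_atp, x$f_atp_min))
  cat(sprintf("  yields: %d ATP + %d pyruvate per glucose, %d ATP per pyruvate\n",
              x$y_glyc, x$pyr_per_glc, x$y_ox))
  invisible(x)
}

#' Read model parameters from a JSON file
#'
#' Accepts a flat JSON object whose keys match the arguments of
#' [minimal_params()]; missing keys fall back to the defaults.
#'
#' @param path JSON file path.
#' @return A [minimal_params()] object.
#' @export
read_minimal_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(minimal_params))
  bad <- setdiff(names(obj), known)
  if (length(bad))
    stop("unknown parameter fields: ", paste(bad, collapse = ", "))
  do.call(minimal_params, obj)
}

#' Glucose-supply thresholds of the crowding-constrained model
#'
#' Computes the five characteristic glucose fluxes of the model:
#' \describe{
#'   \item{u_G}{crowding onset, `phi_atp / (2 a_ox + a_glyc)`: above it the
#'     fully oxidative strategy no longer fits in the volume budget and
#'     lactate overflow starts;}
#'   \item{v_G}{full fermentation, `phi_atp / (2 a_ldh + a_glyc)`: the largest
#'     glucose flux one cell can process at all;}
#'   \item{u_G0}{minimum per-cell glucose supply that avoids starvation,
#'     `f_atp_min / 38` at the default yields;}
#'   \item{u_G1}{`u_G + u_G0`, onset of the lactate-subsidized regime of the
#'     donor/acceptor pair;}
#'   \item{u_G2}{total supply above which the donor sequesters all glucose and
#'     the acceptor lives on lactate alone.}
#' }
#'
#' `u_G2` solves the shuttle balance at full rerouting: with
#' `c = (2 a_ox + a_glyc)/(a_ox - a_ldh)`,
#' `u_G2 = u_G1 + u_G0 (38/18 - c)/c` (default yields).
#'
#' @param params A [minimal_params()] object.
#' @return An object of class `mm_thresholds` with fields
#'   `u_G`, `v_G`, `u_G0`, `u_G1`, `u_G2` (mM/min).
#' @examples
#' thresholds(minimal_params())
#' @export
thresholds <- function(params) {
  stopifnot(inherits(params, "minimal_params"))
  p <- params$pyr_per_glc
  y_tot <- params$y_glyc + p * params$y_ox
  u_g <- params$phi_atp / (p * params$a_ox + params$a_glyc)
  v_g <- params$phi_atp / (p * params$a_ldh + params$a_glyc)
  u_g0 <- params$f_atp_min / y_tot
  cc <- (p * params$a_ox + params$a_glyc) / (params$a_ox - params$a_ldh)
  ratio <- y_tot / params$y_ox
  if (ratio <= cc)
    stop("degenerate parameters: the lactate-subsidized regime requires ",
         "y_tot/y_ox > (p*a_ox + a_glyc)/(a_ox - a_ldh)")
  u_g1 <- u_g + u_g0
  u_g2 <- u_g1 + u_g0 * (ratio - cc) / cc
  structure(list(u_G = u_g, v_G = v_g, u_G0 = u_g0, u_G1 = u_g1, u_G2 = u_g2,
                 overflow_gain = cc),
            class = "mm_thresholds")
}

#' @export
print.mm_thresholds <- function(x, ...) {
  cat("Glucose thresholds (mM/min):\n")
  cat(sprintf("  u_G  = %.6g  (crowding onset)\n", x$u_G))
  cat(sprintf("  v_G  = %.6g  (full fermentation)\n", x$v_G))
  cat(sprintf("  u_G0 = %.6g  (per-cell survival supply)\n", x$u_G0))
  cat(sprintf("  u_G1 = %.6g  (lactate subsidy onset)\n", x$u_G1))
  cat(sprintf("  u_G2 = %.6g  (full glucose sequestration)\n", x$u_G2))
  invisible(x)
}
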