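#' Crowding-constraint specification
#'
#' The generalized crowding constraint for a large network reads
#' `a_glyc f_HEX + a_PDH f_PDH + a_LDH |f_LDH| + a_GLUN f_GLUN <= phi`,
#' limiting the volume (or proteome) fraction the ATP-producing machinery
#' may occupy. The LDH flux enters through its absolute value because
#' lactate intake (negative LDH flux in an acceptor cell) occupies enzyme
#' volume just as secretion does; [crowding_rows()] encodes it exactly as two
#' linear rows.
#'
#' Coefficients default to the coarse-grained empirical values; glutaminase
#' shares the PDH coefficient by default (both are mitochondrial
#' volume-occupying fluxes) and is only used when the network maps a
#' `glutaminase` role.
#'
#' @param coefficients Named vector of volume-per-flux coefficients; names
#'   are role keys (`hexokinase`, `PDH`, `LDH`, `glutaminase`).
#' @param phi Volume-fraction budget.
#' @param absolute_value_roles Roles whose flux enters as `|f|` when the
#'   mapped reaction can run backwards.
#' @return An object of class `crowding_spec`.
#' @export
crowding_spec <- function(coefficients = c(hexokinase = 3e-3, PDH = 2e-1,
                                           LDH = 4.6e-4, glutaminase = 2e-1),
                          phi = 0.4,
                          absolute_value_roles = "LDH") {
  if (any(coefficients < 0)) stop("crowding coefficients must be >= 0")
  if (phi <= 0) stop("'phi' must be positive")
  structure(list(coefficients = coefficients, phi = phi,
                 absolute_value_roles = absolute_value_roles),
            class = "crowding_spec")
}

#' @rdname crowding_spec
#' @param params A [minimal_params()] object to lift into a spec.
#' @export
crowding_spec_from_params <- function(params) {
  crowding_spec(coefficients = c(hexokinase = params$a_glyc,
                                 PDH = params$a_ox, LDH = params$a_ldh,
                                 glutaminase = params$a_ox),
                phi = params$phi_atp)
}

#' Crowding constraint as linear inequality rows
#'
#' Builds the inequality rows `A f <= b` over the full flux vector. For each
#' cell (one for a plain network, donor and acceptor for a coupled one): if
#' the LDH-role reaction cannot run backwards a single row with `+a_LDH` is
#' emitted; if it can, the absolute value is encoded exactly as two rows, one
#' with `+a_LDH f_LDH` and one with `-a_LDH f_LDH`, whose conjunction equals
#' the `|f_LDH|` constraint.
#'
#' @param net A [metabolic_network()] or coupled network.
#' @param spec A [crowding_spec()].
#' @return A list with matrix `A` and vector `b`.
#' @export
crowding_rows <- function(net, spec) {
  stopifnot(inherits(spec, "crowding_spec"))
  n <- length(net$reactions)
  cells <- if (!is.null(net$cells)) net$cells else list(net$roles)
  A <- NULL
  for (roles in cells) {
    base <- numeric(n)
    ldh_cols <- integer()
    for (role in names(spec$coefficients)) {
      id <- roles[[role]]
      if (is.null(id)) {
        if (role %in% c("hexokinase", "PDH", "LDH"))
          stop(sprintf("configuration error: role '%s' is not mapped", role))
        next  # optional roles (glutaminase) may be absent
      }
      j <- match(id, net$reactions)
      cf <- spec$coefficients[[role]]
      if (role %in% spec$absolute_value_roles && net$lb[j] < 0)
        ldh_cols <- c(ldh_cols, j)
      else base[j] <- base[j] + cf
    }
    if (length(ldh_cols)) {
      for (sgn in c(+1, -1)) {
        row <- base
        for (j in ldh_cols)
          row[j] <- row[j] + sgn * spec$coefficients[["LDH"]]
        A <- rbind(A, row)
      }
    } else A <- rbind(A, base)
  }
  rownames(A) <- NULL
  list(A = A, b = rep(spec$phi, nrow(A)))
}

#' Replicate a network into a lactate-coupled donor/acceptor pair
#'
#' Duplicates the network with `_don` / `_acc` suffixes and adds the two
#' shared constraints of the coupled system: the glucose uptakes share the
#' total supply (`U_G_don + U_G_acc <= U_G_total`) and the joint lactate
#' exchange is non-negative (`U_LAC_don + U_LAC_acc >= 0`; there is no
#' external lactate source). The donor's lactate exchange and LDH are
#' clamped to secretion only (lower bounds at 0) while the acceptor's are
#' opened to run backwards, unless `symmetric = TRUE`, in which case both
#' replicas keep reversible lactate reactions.
#'
#' @param net A [metabolic_network()] with `glucose_uptake` and
#'   `lactate_exchange` roles mapped.
#' @param U_G_total Total glucose supply shared by the pair.
#' @param symmetric Keep both cells lactate-reversible.
#' @param fmax Finite magnitude used when opening the acceptor's lactate
#'   bounds.
#' @return An object of class `c("coupled_network", "metabolic_network")`
#'   with extra fields `cells` (per-cell role maps), `shared_constraints`
#'   (`A f <= b` rows) and `U_G_total`.
#' @export
couple_cells <- function(net, U_G_total, symmetric = FALSE, fmax = 1e4) {
  stopifnot(inherits(net, "metabolic_network"))
  for (role in c("glucose_uptake", "lactate_exchange")) role_reaction(net, role)
  n <- length(net$reactions)
  suff <- function(x, s) paste0(x, s)
  S <- rbind(
    cbind(net$stoich, matrix(0, nrow(net$stoich), n)),
    cbind(matrix(0, nrow(net$stoich), n), net$stoich))
  rownames(S) <- c(suff(net$species, "_don"), suff(net$species, "_acc"))
  colnames(S) <- c(suff(net$reactions, "_don"), suff(net$reactions, "_acc"))
  lb <- c(net$lb, net$lb); ub <- c(net$ub, net$ub)
  rev <- c(net$reversible, net$reversible)
  # only the lactate exchange differs between the cells; internal LDH
  # reversibility is whatever the single-cell network declares
  lac_idx <- match(net$roles[["lactate_exchange"]], net$reactions)
  # donor: secretion only
  if (!symmetric) {
    lb[lac_idx] <- pmax(lb[lac_idx], 0)
    rev[lac_idx] <- FALSE
  }
  # acceptor: reversible lactate
  lb[n + lac_idx] <- pmin(lb[n + lac_idx], -fmax)
  rev[n + lac_idx] <- TRUE
  cells <- list(
    donor = stats::setNames(lapply(net$roles, suff, s = "_don"),
                            names(net$roles)),
    acceptor = stats::setNames(lapply(net$roles, suff, s = "_acc"),
                               names(net$roles)))
  if (symmetric) {
    lb[lac_idx] <- pmin(lb[lac_idx], -fmax)
    rev[lac_idx] <- TRUE
  }
  glc <- c(match(net$roles[["glucose_uptake"]], net$reactions),
           n + match(net$roles[["glucose_uptake"]], net$reactions))
  lac_ex <- c(match(net$roles[["lactate_exchange"]], net$reactions),
              n + match(net$roles[["lactate_exchange"]], net$reactions))
  A <- matrix(0, 2, 2 * n, dimnames = list(NULL, colnames(S)))
  A[1, glc] <- 1                 # shared glucose supply
  A[2, lac_ex] <- -1             # joint lactate >= 0, as -sum <= 0
  b <- c(U_G_total, 0)
  out <- metabolic_network(S, lb, ub, rev, roles = list())
  out$cells <- cells
  out$roles <- cells$donor   # convenience: donor roles as default
  out$shared_constraints <- list(A = A, b = b)
  out$U_G_total <- U_G_total
  out$symmetric <- symmetric
  class(out) <- c("coupled_network", "metabolic_network")
  out
}

#' @export
print.coupled_network <- function(x, ...) {
  cat(sprintf(
    "Coupled donor/acceptor network: %d reactions (%d per cell), U_G_total = %g%s\n",
    length(x$reactions), length(x$reactions) / 2, x$U_G_total,
    if (isTRUE(x$symmetric)) " (symmetric lactate)" else ""))
  invisible(x)
}

#' Set the glucose supply of a network
#'
#' For a plain network, sets the upper bound of the glucose uptake reaction;
#' for a coupled pair, sets each cell's uptake cap and the shared-supply
#' right-hand side to `U_G` (either cell may take up to the whole supply,
#' jointly limited by the shared row).
#'
#' @param net A [metabolic_network()] or coupled network.
#' @param U_G Glucose supply.
#' @return The modified network.
#' @export
set_glucose <- function(net, U_G) {
  if (inherits(net, "coupled_network")) {
    for (cell in net$cells) {
      j <- match(cell[["glucose_uptake"]], net$reactions)
      net$ub[j] <- U_G
    }
    net$shared_constraints$b[1] <- U_G
    net$U_G_total <- U_G
  } else {
    j <- role_reaction(net, "glucose_uptake")
    net$ub[j] <- U_G
  }
  net
}
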