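#' ATP production flux of a flux vector
#'
#' At steady state ATP production equals consumption, so the ATP production
#' of a network state is the flux through the ATP-demand reaction (this
#' avoids double counting over the many ATP-producing reactions of a large
#' network).
#'
#' @param f Flux vector (named or in network order) or sample matrix.
#' @param net A [metabolic_network()] with an `atp_demand` role; for coupled
#'   networks pass `cell` to pick the replica.
#' @param cell For coupled networks: `"donor"` or `"acceptor"`.
#' @return Numeric flux (vector if `f` is a matrix).
#' @export
atp_flux <- function(f, net, cell = "donor") {
  roles <- if (!is.null(net$cells)) net$cells[[cell]] else net$roles
  id <- roles[["atp_demand"]]
  if (is.null(id))
    stop("configuration error: role 'atp_demand' is not mapped")
  j <- match(id, net$reactions)
  if (is.matrix(f)) f[, j] else f[[j]]
}

flux_of <- function(f, net, role, cell = "donor") {
  roles <- if (!is.null(net$cells)) net$cells[[cell]] else net$roles
  id <- roles[[role]]
  if (is.null(id)) stop("configuration error: role '", role,
                        "' is not mapped")
  j <- match(id, net$reactions)
  if (is.matrix(f)) f[, j] else f[[j]]
}

#' Fermentative and oxidative pathway fractions
#'
#' Splits the pyruvate-equivalent carbon flow of one cell between
#' fermentation (pyruvate to lactate via LDH) and oxidation (pyruvate into
#' the TCA cycle via PDH). In `"pyruvate"` mode the fractions are shares of
#' the pyruvate-equivalent throughput (lactate production counts its
#' positive part, so a lactate-importing cell is fully oxidative); in
#' `"atp"` mode the shares are ATP-weighted (glycolytic ATP per glucose vs
#' oxidative ATP per pyruvate, with the yields taken from `yields`).
#'
#' @param f Flux vector or sample matrix.
#' @param net Network with `LDH`, `PDH`, `glucose_uptake` roles mapped.
#' @param mode `"pyruvate"` or `"atp"`.
#' @param yields ATP yields used in `"atp"` mode: per glucose via
#'   glycolysis and per pyruvate via oxidation.
#' @param cell Replica for coupled networks.
#' @return A list (or data.frame for matrices) with `fermentative` and
#'   `oxidative` fractions in `[0, 1]` summing to 1; both `NA` with
#'   attribute `degenerate = TRUE` when the cell carries no pyruvate flux.
#' @export
pathway_fractions <- function(f, net, mode = c("pyruvate", "atp"),
                              yields = c(glyc = 2, ox = 18),
                              cell = "donor") {
  mode <- match.arg(mode)
  ldh <- flux_of(f, net, "LDH", cell)
  pdh <- flux_of(f, net, "PDH", cell)
  if (mode == "pyruvate") {
    ferm <- pmax(ldh, 0)
    oxid <- pmax(pdh, 0)
  } else {
    glc <- flux_of(f, net, "glucose_uptake", cell)
    ferm <- yields[["glyc"]] * pmax(glc, 0) *
      ifelse(pmax(ldh, 0) + pmax(pdh, 0) > 0,
             pmax(ldh, 0) / (pmax(ldh, 0) + pmax(pdh, 0)), 0)
    # glycolytic ATP credited to fermentation in proportion to the pyruvate
    # sent to LDH; oxidative ATP is the PDH throughput times its yield
    oxid <- yields[["ox"]] * pmax(pdh, 0)
  }
  tot <- ferm + oxid
  degen <- tot <= 0
  fr <- ifelse(degen, NA_real_, ferm / tot)
  ox <- ifelse(degen, NA_real_, oxid / tot)
  out <- list(fermentative = fr, oxidative = ox)
  attr(out, "degenerate") <- degen
  out
}

batch_se <- function(x, n_batches = 20L) {
  n <- length(x)
  if (n < 2L * n_batches) return(stats::sd(x) / sqrt(max(n, 1)))
  bsize <- n %/% n_batches
  means <- vapply(seq_len(n_batches), function(i)
    mean(x[((i - 1L) * bsize + 1L):(i * bsize)]), 0)
  stats::sd(means) / sqrt(n_batches)
}

scan_point_stats <- function(ss, net) {
  coupled <- !is.null(net$cells)
  cells <- if (coupled) c("donor", "acceptor") else "donor"
  out <- list()
  for (cl in cells) {
    pre <- if (coupled) paste0(cl, "_") else ""
    for (role in c("atp_demand", "LDH", "PDH", "hexokinase",
                   "glucose_uptake", "lactate_exchange")) {
      roles <- if (coupled) net$cells[[cl]] else net$roles
      if (is.null(roles[[role]])) next
      v <- flux_of(ss$samples, net, role, cl)
      out[[paste0(pre, role, "_mean")]] <- mean(v)
      out[[paste0(pre, role, "_se")]] <- batch_se(v)
    }
    pf <- pathway_fractions(ss$samples, net, cell = cl)
    out[[paste0(pre, "fermentative_fraction")]] <- mean(pf$fermentative,
                                                        na.rm = TRUE)
    out[[paste0(pre, "oxidative_fraction")]] <- mean(pf$oxidative,
                                                     na.rm = TRUE)
  }
  out
}

#' Scan flux statistics over a glucose-supply grid
#'
#' For each glucose supply in `grid`: set the supply ([set_glucose()]),
#' rebuild the polytope (with the crowding rows), find an interior point,
#' round, run the Hit-and-Run chain, and reduce the samples to means and
#' batch-mean standard errors of the key fluxes (ATP demand, LDH, PDH,
#' hexokinase, glucose uptake, lactate exchange — per cell for coupled
#' networks) plus pathway fractions. Grid points whose polytope is
#' infeasible (below the survival bound) are flagged and skipped.
#'
#' @param net A [metabolic_network()] or coupled network.
#' @param grid Numeric vector of glucose supplies.
#' @param config A [sampler_config()]; per-point seeds are derived from
#'   `config$seed` so the scan is reproducible.
#' @param crowding A [crowding_spec()] appended to every polytope.
#' @param rounding_seed Seed offset for the rounding preprocessing.
#' @return A `data.frame` with one row per grid point (`U_G`, `feasible`,
#'   statistics columns).
#' @export
glucose_scan <- function(net, grid, config, crowding = NULL,
                         rounding_seed = 1L) {
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    ug <- grid[i]
    net_i <- set_glucose(net, ug)
    row <- list(U_G = ug, feasible = TRUE)
    res <- tryCatch({
      poly <- flux_polytope(net_i, crowding = crowding)
      ell <- round_polytope(poly, seed = config$seed + rounding_seed)
      cfg <- config
      cfg$seed <- config$seed + i
      ss <- hit_and_run(poly, cfg, rounding = ell)
      c(row, scan_point_stats(ss, net_i))
    }, error = function(e) {
      row$feasible <- FALSE
      c(row, message = conditionMessage(e))
    })
    rows[[i]] <- res
  }
  nm <- unique(unlist(lapply(rows, names)))
  df <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(nm, names(r))
    for (m in miss) r[[m]] <- NA
    as.data.frame(r[nm], stringsAsFactors = FALSE)
  }))
  df
}

#' Scan the Boltzmann bias at fixed glucose supply
#'
#' Samples the polytope at each `beta` in `betas` and reports the mean of
#' the objective together with its ratio to the linear-programming maximum
#' over the same polytope; also reports the smallest grid `beta` whose mean
#' reaches `lp_fraction` of the maximum (attribute `beta_at_fraction`).
#'
#' @param net Network (plain or coupled).
#' @param U_G Glucose supply.
#' @param betas Non-negative bias grid.
#' @param config A [sampler_config()] whose `objective` is scanned.
#' @param crowding A [crowding_spec()].
#' @param lp_fraction Reporting threshold (default 0.98).
#' @return A `data.frame` (`beta`, `objective_mean`, `objective_se`,
#'   `lp_max`, `ratio`), with attribute `beta_at_fraction`.
#' @export
beta_scan <- function(net, U_G, betas, config, crowding = NULL,
                      lp_fraction = 0.98) {
  net <- set_glucose(net, U_G)
  poly <- flux_polytope(net, crowding = crowding)
  ell <- round_polytope(poly, seed = config$seed)
  w <- objective_vector(config$objective, poly)
  g_red <- as.vector(crossprod(poly$B, w))
  bg <- box_guess(poly)
  lp <- solve_lp(g_red, A = poly$G, b = poly$h, lb = bg$lo, ub = bg$hi,
                 maximize = TRUE)
  if (lp$status != "optimal") stop("LP maximization failed: ", lp$status)
  rows <- lapply(seq_along(betas), function(i) {
    cfg <- config
    cfg$beta <- betas[i]
    cfg$seed <- config$seed + i
    ss <- hit_and_run(poly, cfg, rounding = ell)
    v <- as.vector(ss$samples %*% w)
    data.frame(beta = betas[i], objective_mean = mean(v),
               objective_se = batch_se(v), lp_max = lp$value,
               ratio = mean(v) / lp$value)
  })
  df <- do.call(rbind, rows)
  hit <- df$beta[df$ratio >= lp_fraction]
  attr(df, "beta_at_fraction") <- if (length(hit)) min(hit) else NA_real_
  attr(df, "lp_fraction") <- lp_fraction
  df
}

#' Pearson correlation matrix of sampled fluxes
#'
#' Exact sample Pearson matrix `r = cov(X, Y) / (sd(X) sd(Y))` over the
#' selected fluxes. Fluxes with zero sample variance (pinned by the
#' constraints) get `r = 0` in their row and column, flagged in attribute
#' `zero_variance`, with the diagonal kept at 1.
#'
#' @param ss A `sample_set` (or a plain sample matrix with column names).
#' @param flux_ids Reaction identifiers to include (default: all).
#' @return An object of class `correlation_matrix`: the matrix `r` with a
#'   `zero_variance` attribute.
#' @export
pearson_matrix <- function(ss, flux_ids = NULL) {
  X <- if (inherits(ss, "sample_set")) ss$samples else as.matrix(ss)
  if (nrow(X) < 2) stop("need at least 2 samples")
  if (!is.null(flux_ids)) {
    miss <- setdiff(flux_ids, colnames(X))
    if (length(miss)) stop("unknown fluxes: ", paste(miss, collapse = ", "))
    X <- X[, flux_ids, drop = FALSE]
  }
  sds <- apply(X, 2, stats::sd)
  zv <- sds <= max(1e-12, 1e-10 * max(abs(X)))
  r <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  if (any(!zv))
    r[!zv, !zv] <- stats::cor(X[, !zv, drop = FALSE])
  diag(r) <- 1
  structure(r, zero_variance = colnames(X)[zv], class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Pearson correlation matrix over", ncol(x), "fluxes\n")
  print(round(unclass(x), 3))
  zv <- attr(x, "zero_variance")
  if (length(zv)) cat("zero-variance fluxes (r set to 0):",
                      paste(zv, collapse = ", "), "\n")
  invisible(x)
}

#' Mean absolute donor-acceptor cross-correlation
#'
#' Summary of inter-cellular metabolic coupling: the mean `|r|` over the
#' off-diagonal donor x acceptor block of a correlation matrix.
#'
#' @param cm A [pearson_matrix()] result.
#' @param donor_ids,acceptor_ids Flux identifiers of the two blocks.
#' @return Mean absolute off-diagonal-block correlation.
#' @export
offdiag_block_norm <- function(cm, donor_ids, acceptor_ids) {
  mean(abs(unclass(cm)[donor_ids, acceptor_ids]))
}
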