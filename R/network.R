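#' Stoichiometric metabolic network
#'
#' Container for a metabolic network: stoichiometric matrix, flux bounds,
#' reversibility flags and a role map tying biologically meaningful fluxes
#' (glucose uptake, lactate exchange, hexokinase, LDH, PDH, glutaminase, ATP
#' demand, objective components) to reaction identifiers.
#'
#' Sign convention for exchange fluxes: uptake reactions carry positive flux
#' when importing, secretion reactions positive flux when exporting; an
#' exchange with a negative lower bound can run backwards (e.g. a reversible
#' lactate exchange imports lactate at negative flux).
#'
#' @param stoich Numeric matrix, species x reactions, with dimnames.
#' @param lb,ub Flux bounds, one per reaction.
#' @param reversible Logical flags, one per reaction; must agree with
#'   `lb < 0`.
#' @param roles Named list/character mapping role keys to reaction ids.
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(stoich, lb, ub, reversible = lb < 0,
                              roles = list()) {
  stoich <- as.matrix(stoich)
  if (is.null(rownames(stoich)) || is.null(colnames(stoich)))
    stop("'stoich' needs species row names and reaction column names")
  n <- ncol(stoich)
  if (anyDuplicated(colnames(stoich)))
    stop("duplicate reaction identifiers: ",
         paste(unique(colnames(stoich)[duplicated(colnames(stoich))]),
               collapse = ", "))
  if (anyDuplicated(rownames(stoich)))
    stop("duplicate species identifiers")
  if (length(lb) != n || length(ub) != n || length(reversible) != n)
    stop("bounds/reversibility length must match the reaction count")
  if (any(!is.finite(stoich))) stop("non-finite stoichiometric coefficient")
  if (any(lb > ub)) {
    bad <- colnames(stoich)[lb > ub][1]
    stop("lower bound exceeds upper bound for reaction ", bad)
  }
  if (any(!reversible & lb < 0))
    stop("irreversible reaction with negative lower bound: ",
         colnames(stoich)[!reversible & lb < 0][1])
  orphan <- rowSums(stoich != 0) == 0
  if (any(orphan))
    stop("orphan species (appear in no reaction): ",
         paste(rownames(stoich)[orphan], collapse = ", "))
  roles <- lapply(roles, as.character)
  unknown <- setdiff(unlist(roles), colnames(stoich))
  if (length(unknown))
    stop("role map names unknown reactions: ", paste(unknown, collapse = ", "))
  structure(list(
    stoich = stoich,
    species = rownames(stoich),
    reactions = colnames(stoich),
    lb = as.numeric(lb), ub = as.numeric(ub),
    reversible = as.logical(reversible),
    roles = roles
  ), class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("Metabolic network: %d species, %d reactions (%d reversible)\n",
              length(x$species), length(x$reactions), sum(x$reversible)))
  if (length(x$roles))
    cat("  roles:", paste(names(x$roles), unlist(x$roles), sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

role_reaction <- function(net, role) {
  id <- net$roles[[role]]
  if (is.null(id))
    stop(sprintf("configuration error: role '%s' is not mapped to a reaction",
                 role))
  match(id, net$reactions)
}

#' Read a metabolic network from a file
#'
#' Dispatches on the file extension: `.xml`/`.sbml` are parsed as SBML
#' (Level 2 with kinetic-law bound parameters, or Level 3 with fbc-style
#' bound attributes), anything else as the package's tabular reaction
#' dialect (see [write_network_tab()]).
#'
#' @param source Path to an SBML or tabular reaction file.
#' @param roles Optional role map (named list role -> reaction id), e.g. read
#'   from a JSON sidecar.
#' @return A [metabolic_network()].
#' @export
read_network <- function(source, roles = list()) {
  if (!file.exists(source)) stop("file not found: ", source)
  if (grepl("\\.(xml|sbml)$", source, ignore.case = TRUE))
    read_network_sbml(source, roles = roles)
  else read_network_tab(source, roles = roles)
}

#' Tabular reaction dialect
#'
#' One reaction per line:
#' `id <TAB> reversible(0/1) <TAB> lb <TAB> ub <TAB> equation`, where the
#' equation is `coeff*met + ... --> coeff*met + ...` for irreversible and
#' `... <=> ...` for reversible reactions; either side may be empty (exchange
#' reactions). Lines starting with `#` are comments. Round-tripping through
#' [write_network_tab()] and [read_network_tab()] is lossless.
#'
#' @param path File path.
#' @param roles Optional role map.
#' @return A [metabolic_network()].
#' @export
read_network_tab <- function(path, roles = list()) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  ids <- character(); lb <- ub <- numeric(); rev <- logical()
  stoich_list <- list()
  species <- character()
  parse_side <- function(s, sign, id) {
    s <- trimws(s)
    if (s == "") return(numeric())
    terms <- strsplit(s, "\\s*\\+\\s*")[[1]]
    out <- numeric()
    for (tm in terms) {
      m <- regmatches(tm, regexec("^([0-9.eE+-]+)\\*(\\S+)$", tm))[[1]]
      if (length(m) == 3) { cf <- as.numeric(m[2]); met <- m[3] }
      else if (grepl("^\\S+$", tm)) { cf <- 1; met <- tm }
      else stop("parse error in reaction ", id, ": bad term '", tm, "'")
      if (!is.finite(cf) || cf == 0)
        stop("parse error in reaction ", id, ": zero or non-finite coefficient")
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * cf
    }
    out
  }
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 5)
      stop("parse error: expected 5 tab-separated fields in line: ", ln)
    id <- trimws(f[1])
    if (id %in% ids) stop("duplicate reaction identifier: ", id)
    r <- as.integer(f[2]); l <- as.numeric(f[3]); u <- as.numeric(f[4])
    if (is.na(r) || !(r %in% 0:1))
      stop("parse error in reaction ", id, ": reversible flag must be 0 or 1")
    if (is.na(l) || is.na(u) || l > u)
      stop("parse error in reaction ", id, ": bad bounds")
    eq <- f[5]
    arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>" else
      if (grepl("-->", eq, fixed = TRUE)) "-->" else
        stop("parse error in reaction ", id, ": missing arrow")
    if ((arrow == "<=>") != (r == 1L))
      stop("parse error in reaction ", id,
           ": arrow and reversible flag disagree")
    sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
    if (length(sides) == 1) sides <- c(sides, "")
    st <- parse_side(sides[1], -1, id)
    pr <- parse_side(sides[2], +1, id)
    all_c <- st
    for (met in names(pr))
      all_c[met] <- (if (is.na(all_c[met])) 0 else all_c[met]) + pr[met]
    all_c <- all_c[all_c != 0]
    ids <- c(ids, id); lb <- c(lb, l); ub <- c(ub, u); rev <- c(rev, r == 1L)
    stoich_list[[id]] <- all_c
    species <- union(species, names(all_c))
  }
  S <- matrix(0, length(species), length(ids),
              dimnames = list(species, ids))
  for (id in ids) S[names(stoich_list[[id]]), id] <- stoich_list[[id]]
  metabolic_network(S, lb, ub, rev, roles)
}

#' @rdname read_network_tab
#' @param net A [metabolic_network()] to serialize.
#' @export
write_network_tab <- function(net, path) {
  fmt_num <- function(x) formatC(x, format = "g", digits = 17)
  lines <- vapply(seq_along(net$reactions), function(j) {
    col <- net$stoich[, j]
    side <- function(sel, sgn) {
      idx <- which(sel)
      if (!length(idx)) return("")
      paste(vapply(idx, function(i) {
        cf <- abs(col[i])
        if (cf == 1) net$species[i]
        else paste0(fmt_num(cf), "*", net$species[i])
      }, ""), collapse = " + ")
    }
    arrow <- if (net$reversible[j]) "<=>" else "-->"
    eq <- paste(side(col < 0), arrow, side(col > 0))
    paste(net$reactions[j], as.integer(net$reversible[j]),
          fmt_num(net$lb[j]), fmt_num(net$ub[j]), trimws(eq), sep = "\t")
  }, "")
  writeLines(c("# id\treversible\tlb\tub\tequation", lines), path)
  invisible(path)
}

#' @rdname read_network
#' @export
read_network_sbml <- function(source, roles = list()) {
  doc <- xml2::read_xml(source)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  get_attr <- function(nodes, a) xml2::xml_attr(nodes, a)
  sp_id <- get_attr(sp_nodes, "id")
  boundary <- get_attr(sp_nodes, "boundaryCondition") %in% c("true", "1")
  internal <- sp_id[!boundary]
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx_nodes)) stop("parse error: SBML file has no reactions")
  n <- length(rx_nodes)
  ids <- get_attr(rx_nodes, "id")
  if (anyDuplicated(ids))
    stop("duplicate reaction identifiers in SBML: ",
         ids[duplicated(ids)][1])
  rev_attr <- get_attr(rx_nodes, "reversible")
  rev <- is.na(rev_attr) | rev_attr %in% c("true", "1")  # SBML default: true
  # global fbc-style parameters (L3) for bound lookup
  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(get_attr(par_nodes, "value")),
                             get_attr(par_nodes, "id"))
  lb <- rep(-Inf, n); ub <- rep(Inf, n)
  S <- matrix(0, length(internal), n, dimnames = list(internal, ids))
  for (j in seq_len(n)) {
    rx <- rx_nodes[[j]]
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(rx, paste0("./", tag, "/speciesReference"))
      for (ref in refs) {
        met <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        cf <- if (is.na(st)) 1 else as.numeric(st)
        if (!is.finite(cf)) stop("parse error in reaction ", ids[j],
                                 ": bad stoichiometry")
        if (met %in% internal) S[met, j] <- S[met, j] + side * cf
      }
    }
    # bounds: L3 fbc attributes, else kinetic-law local parameters
    lbp <- xml2::xml_attr(rx, "lowerFluxBound")
    ubp <- xml2::xml_attr(rx, "upperFluxBound")
    if (!is.na(lbp) && lbp %in% names(par_val)) lb[j] <- par_val[[lbp]]
    if (!is.na(ubp) && ubp %in% names(par_val)) ub[j] <- par_val[[ubp]]
    kl <- xml2::xml_find_all(
      rx, ".//kineticLaw//parameter | .//kineticLaw//localParameter")
    if (length(kl)) {
      kid <- xml2::xml_attr(kl, "id")
      kval <- as.numeric(xml2::xml_attr(kl, "value"))
      for (k in seq_along(kid)) {
        if (grepl("^(LOWER_BOUND|LB)", kid[k], ignore.case = TRUE))
          lb[j] <- kval[k]
        if (grepl("^(UPPER_BOUND|UB)", kid[k], ignore.case = TRUE))
          ub[j] <- kval[k]
      }
    }
    if (!rev[j] && !is.finite(lb[j])) lb[j] <- 0
  }
  lb[!is.finite(lb) & !rev] <- 0
  # drop species never touched (external/boundary leftovers)
  S <- S[rowSums(S != 0) > 0, , drop = FALSE]
  # harmonize: reversibility flag follows the declared attribute, but a
  # reversible reaction whose lower bound was raised to >= 0 is effectively
  # irreversible in the flux space; keep the declared flag for reporting.
  lb[rev & !is.finite(lb)] <- -Inf
  metabolic_network(S, lb, ub, rev | lb < 0, roles)
}

#' Coarse-grained cell as a stoichiometric network
#'
#' Builds the six-reaction network mirroring the lumped model: glucose
#' uptake, lumped glycolysis (`glc -> 2 pyr + 2 atp` at default yields),
#' lumped oxidation (`pyr -> 18 atp`), LDH (`pyr <=> lac`), lactate exchange
#' (secretion-only, as for a single cell) and ATP demand with lower bound
#' `f_atp_min`. The role map is fully populated, so the network composes with
#' [crowding_rows()], [couple_cells()] and the sampler, and its LP optimum
#' reproduces [single_cell_optimum()].
#'
#' @param params A [minimal_params()] object.
#' @param U_G Glucose supply: upper bound of the uptake reaction.
#' @param atp_lb Lower bound of the ATP demand reaction (default 0; set to
#'   `params$f_atp_min` to impose survival).
#' @param fmax Finite cap used for otherwise unbounded fluxes.
#' @return A [metabolic_network()].
#' @examples
#' net <- minimal_as_network(minimal_params(), U_G = 0.5)
#' @export
minimal_as_network <- function(params, U_G = 1, atp_lb = 0, fmax = 1e4) {
  stopifnot(inherits(params, "minimal_params"))
  p <- params$pyr_per_glc; y1 <- params$y_glyc; yo <- params$y_ox
  sp <- c("glc", "pyr", "lac", "atp")
  rx <- c("GLC_up", "GLYC", "OX", "LDH", "LAC_ex", "ATP_demand")
  S <- matrix(0, 4, 6, dimnames = list(sp, rx))
  S["glc", "GLC_up"] <- 1
  S["glc", "GLYC"] <- -1; S["pyr", "GLYC"] <- p; S["atp", "GLYC"] <- y1
  S["pyr", "OX"] <- -1; S["atp", "OX"] <- yo
  S["pyr", "LDH"] <- -1; S["lac", "LDH"] <- 1
  S["lac", "LAC_ex"] <- -1
  S["atp", "ATP_demand"] <- -1
  lb <- c(0, 0, 0, -fmax, 0, atp_lb)
  ub <- c(U_G, fmax, fmax, fmax, fmax, fmax)
  metabolic_network(S, lb, ub, reversible = lb < 0, roles = list(
    glucose_uptake = "GLC_up", hexokinase = "GLYC", PDH = "OX",
    LDH = "LDH", lactate_exchange = "LAC_ex", atp_demand = "ATP_demand",
    objective = "ATP_demand"))
}

#' Validate a flux vector against a network
#'
#' Diagnostic report: maximum mass-balance residual `max |S f|`, bound
#' violations, shared-coupling violations (for coupled networks) and, when a
#' crowding specification is given, the crowding slack. The report passes
#' when everything is within `tol`.
#'
#' @param net A [metabolic_network()] or [couple_cells()] result.
#' @param f Flux vector (length = reaction count) or matrix (rows = samples).
#' @param tol Tolerance.
#' @param crowding Optional [crowding_spec()].
#' @return A list with fields `ok`, `max_residual`, `bound_violations`
#'   (character), `crowding_slack` (or `NA`), `coupling_ok`.
#' @export
validate_flux <- function(net, f, tol = 1e-8, crowding = NULL) {
  if (is.matrix(f)) {
    reports <- apply(f, 1, validate_flux, net = net, tol = tol,
                     crowding = crowding)
    return(list(ok = all(vapply(reports, `[[`, TRUE, "ok")),
                reports = reports))
  }
  if (length(f) != length(net$reactions))
    stop("flux vector length ", length(f), " does not match reaction count ",
         length(net$reactions))
  resid <- max(abs(net$stoich %*% f))
  low <- f < net$lb - tol; high <- f > net$ub + tol
  bad <- c(
    if (any(low)) paste0(net$reactions[low], " < lb by ",
                         signif(net$lb[low] - f[low], 3)),
    if (any(high)) paste0(net$reactions[high], " > ub by ",
                          signif(f[high] - net$ub[high], 3)))
  coupling_ok <- TRUE
  if (!is.null(net$shared_constraints)) {
    sc <- net$shared_constraints
    coupling_ok <- all(sc$A %*% f <= sc$b + tol)
  }
  cs <- NA_real_
  if (!is.null(crowding)) {
    cr <- crowding_rows(net, crowding)
    cs <- min(cr$b - cr$A %*% f)
  }
  list(ok = resid <= tol && !length(bad) && coupling_ok &&
         (is.na(cs) || cs >= -tol),
       max_residual = resid, bound_violations = bad,
       crowding_slack = cs, coupling_ok = coupling_ok)
}
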