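#' Built-in validation fixtures
#'
#' Deterministic small objects with analytically known properties, used to
#' validate the sampler and the reduction machinery:
#' \describe{
#'   \item{minimal-single}{the six-reaction coarse-grained cell
#'     ([minimal_as_network()]); reduces to a 2-dimensional polytope;}
#'   \item{minimal-two-cell}{the donor/acceptor coupling of the same cell
#'     (donor lactate exchange secretion-only);}
#'   \item{triangle-toy}{the 2-simplex `x, y >= 0, x + y <= 1` as a bare
#'     polytope; uniform marginals are Beta(1, 2);}
#'   \item{anisotropic-box}{the box `[0, 1] x [0, 1e4]` as a bare polytope;
#'     axis ratio 1e4, for rounding tests.}
#' }
#'
#' @param name Fixture name.
#' @param U_G Glucose supply for the network fixtures.
#' @param params Model parameters for the network fixtures.
#' @param atp_lb ATP-demand lower bound (defaults to the survival flux for
#'   the two-cell fixture, 0 for the single cell).
#' @return A list with elements among `net`, `poly` (bare polytopes come
#'   without a network), `crowding`, `params`.
#' @export
fixture <- function(name = c("minimal-single", "minimal-two-cell",
                             "triangle-toy", "anisotropic-box"),
                    U_G = 1, params = minimal_params(), atp_lb = NULL) {
  name <- match.arg(name)
  switch(name,
    "minimal-single" = {
      net <- minimal_as_network(params, U_G = U_G,
                                atp_lb = if (is.null(atp_lb)) 0 else atp_lb)
      list(net = net, crowding = crowding_spec_from_params(params),
           params = params)
    },
    "minimal-two-cell" = {
      net <- minimal_as_network(
        params, U_G = U_G,
        atp_lb = if (is.null(atp_lb)) params$f_atp_min else atp_lb)
      cpl <- couple_cells(net, U_G_total = U_G)
      list(net = cpl, crowding = crowding_spec_from_params(params),
           params = params)
    },
    "triangle-toy" = {
      G <- rbind(c(-1, 0), c(0, -1), c(1, 1))
      poly <- structure(list(
        independent_ids = c("x", "y"), reaction_ids = c("x", "y"),
        B = diag(2), offset = c(0, 0), G = G, h = c(0, 0, 1),
        D = 2L, rank = 0L), class = "flux_polytope")
      dimnames(poly$B) <- list(c("x", "y"), c("x", "y"))
      list(poly = poly)
    },
    "anisotropic-box" = {
      G <- rbind(diag(2), -diag(2))
      poly <- structure(list(
        independent_ids = c("x", "y"), reaction_ids = c("x", "y"),
        B = diag(2), offset = c(0, 0), G = G, h = c(1, 1e4, 0, 0),
        D = 2L, rank = 0L), class = "flux_polytope")
      dimnames(poly$B) <- list(c("x", "y"), c("x", "y"))
      list(poly = poly)
    })
}

#' Write a named fixture to disk
#'
#' Network fixtures are written as a tabular reaction file plus a JSON role
#' map; bare polytope fixtures as a polytope JSON container.
#'
#' @param name Fixture name (see [fixture()]).
#' @param dir Output directory (created if needed).
#' @inheritParams fixture
#' @return Invisibly, the paths written.
#' @export
make_fixture <- function(name, dir = ".", U_G = 1,
                         params = minimal_params()) {
  fx <- fixture(name, U_G = U_G, params = params)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(fx$net)) {
    if (inherits(fx$net, "coupled_network")) {
      # serialize the underlying single cell plus coupling metadata
      tab <- file.path(dir, paste0(name, ".tsv"))
      single <- minimal_as_network(params, U_G = U_G,
                                   atp_lb = params$f_atp_min)
      write_network_tab(single, tab)
      meta <- file.path(dir, paste0(name, ".roles.json"))
      jsonlite::write_json(list(roles = single$roles, coupled = TRUE,
                                U_G_total = U_G),
                           meta, auto_unbox = TRUE, digits = NA)
      paths <- c(tab, meta)
    } else {
      tab <- file.path(dir, paste0(name, ".tsv"))
      write_network_tab(fx$net, tab)
      meta <- file.path(dir, paste0(name, ".roles.json"))
      jsonlite::write_json(list(roles = fx$net$roles, coupled = FALSE),
                           meta, auto_unbox = TRUE, digits = NA)
      paths <- c(tab, meta)
    }
  } else {
    pj <- file.path(dir, paste0(name, ".polytope.json"))
    write_polytope(fx$poly, pj)
    paths <- pj
  }
  invisible(paths)
}

#' Load a fixture written by [make_fixture()]
#'
#' @param tab Path to the `.tsv` network file.
#' @return A network (coupled if the role sidecar says so).
#' @export
load_fixture <- function(tab) {
  meta_path <- sub("\\.tsv$", ".roles.json", tab)
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  roles <- as.list(meta$roles %||% list())
  net <- read_network_tab(tab, roles = roles)
  if (isTRUE(meta$coupled))
    net <- couple_cells(net, U_G_total = meta$U_G_total %||% 1)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a
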