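toy_tab <- function(path) {
  writeLines(c(
    "# id\treversible\tlb\tub\tequation",
    "A_in\t0\t0\t5\t --> A",
    "conv\t1\t-10\t10\tA <=> B",
    "B_out\t0\t0\t5\tB --> "), path)
  path
}

test_that("tabular dialect parses a 3-reaction toy network", {
  f <- withr::local_tempfile(fileext = ".tsv")
  toy_tab(f)
  net <- read_network(f)
  expect_length(net$species, 2)
  expect_length(net$reactions, 3)
  expect_equal(sum(net$reversible), 1)
  expect_equal(net$stoich["A", "conv"], -1)
  expect_equal(net$stoich["B", "conv"], 1)
})

test_that("tabular round trip is lossless", {
  p <- default_params
  net <- minimal_as_network(p, U_G = 0.731, atp_lb = 0.1234)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network_tab(net, f)
  back <- read_network_tab(f, roles = net$roles)
  expect_identical(back$reactions, net$reactions)
  expect_identical(sort(back$species), sort(net$species))
  expect_equal(back$stoich[net$species, ], net$stoich)
  expect_equal(back$lb, net$lb)
  expect_equal(back$ub, net$ub)
  expect_identical(back$reversible, net$reversible)
})

test_that("parse errors name the offending record", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("r1\t0\t0\t1\t --> A", "r1\t0\t0\t1\tA --> "), f)
  expect_error(read_network_tab(f), "duplicate reaction identifier: r1")
  writeLines("r1\t0\t5\t1\t --> A", f)
  expect_error(read_network_tab(f), "r1.*bad bounds")
  writeLines("r1\t0\t0\t1\tA <=> B", f)
  expect_error(read_network_tab(f), "disagree")
  writeLines("r1\t0\t0\t1\t0*A --> B", f)
  expect_error(read_network_tab(f), "zero or non-finite")
})

test_that("network invariants are enforced by the constructor", {
  S <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("a", "b"), c("r1", "r2")))
  expect_error(metabolic_network(S, lb = c(-1, 0), ub = c(1, 1),
                                 reversible = c(FALSE, FALSE)),
               "irreversible reaction with negative lower bound")
  S2 <- rbind(S, c(0, 0))
  rownames(S2) <- c("a", "b", "orphan")
  expect_error(metabolic_network(S2, lb = c(0, 0), ub = c(1, 1)), "orphan")
})

test_that("SBML reader parses species, reactions, bounds, reversibility", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">
 <model id="toy">
  <listOfSpecies>
   <species id="A" boundaryCondition="false"/>
   <species id="B" boundaryCondition="false"/>
   <species id="X" boundaryCondition="true"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="vin" reversible="false">
    <listOfReactants><speciesReference species="X"/></listOfReactants>
    <listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>
    <kineticLaw>
     <listOfParameters>
      <parameter id="LOWER_BOUND" value="0"/>
      <parameter id="UPPER_BOUND" value="5"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
   <reaction id="conv" reversible="true">
    <listOfReactants><speciesReference species="A"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>
    <kineticLaw>
     <listOfParameters>
      <parameter id="LOWER_BOUND" value="-10"/>
      <parameter id="UPPER_BOUND" value="10"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
   <reaction id="vout" reversible="false">
    <listOfReactants><speciesReference species="B"/></listOfReactants>
    <kineticLaw>
     <listOfParameters>
      <parameter id="UPPER_BOUND" value="7"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, f)
  net <- read_network(f)
  expect_length(net$species, 2)   # boundary species dropped
  expect_length(net$reactions, 3)
  expect_equal(sum(net$reversible), 1)
  expect_equal(net$lb, c(0, -10, 0))
  expect_equal(net$ub, c(5, 10, 7))
  expect_equal(net$stoich["B", "conv"], 2)
})

test_that("minimal fixture network reproduces the closed-form optimum", {
  p <- default_params
  net <- minimal_as_network(p, U_G = 0.5)
  expect_length(net$species, 4)
  expect_length(net$reactions, 6)
  # LP maximization of ATP demand with crowding must give f_ATP = 19
  poly <- flux_polytope(net, crowding = crowding_spec_from_params(p))
  w <- as.vector(crossprod(poly$B, as.numeric(poly$reaction_ids == "ATP_demand")))
  bg <- crowdflux:::box_guess(poly)
  lp <- solve_lp(w, A = poly$G, b = poly$h, lb = bg$lo, ub = bg$hi,
                 maximize = TRUE)
  expect_equal(lp$value, 19, tolerance = 1e-8)
  # zero glucose: only the zero flux vector is feasible
  net0 <- minimal_as_network(p, U_G = 0)
  poly0 <- flux_polytope(net0, crowding = crowding_spec_from_params(p))
  bg0 <- crowdflux:::box_guess(poly0)
  lp0 <- solve_lp(w, A = poly0$G, b = poly0$h, lb = bg0$lo, ub = bg0$hi,
                  maximize = TRUE)
  expect_equal(lp0$value, 0, tolerance = 1e-10)
})

test_that("couple_cells builds a block-diagonal joint network", {
  net <- minimal_as_network(default_params, U_G = 1)
  cpl <- couple_cells(net, U_G_total = 1)
  expect_length(cpl$reactions, 12)
  expect_equal(nrow(cpl$shared_constraints$A), 2)
  n <- length(net$reactions)
  # each replica keeps its internal stoichiometry exactly
  expect_equal(unname(cpl$stoich[1:4, 1:n]), unname(net$stoich))
  expect_equal(unname(cpl$stoich[5:8, n + 1:n]), unname(net$stoich))
  # off-diagonal blocks are zero
  expect_true(all(cpl$stoich[1:4, n + 1:n] == 0))
  expect_true(all(cpl$stoich[5:8, 1:n] == 0))
  # donor lactate exchange secretion-only, acceptor reversible
  expect_equal(cpl$lb[match("LAC_ex_don", cpl$reactions)], 0)
  expect_lt(cpl$lb[match("LAC_ex_acc", cpl$reactions)], 0)
  expect_error(couple_cells(metabolic_network(
    matrix(1, 1, 1, dimnames = list("a", "r")), 0, 1), 1),
    "glucose_uptake")
})

test_that("symmetric coupling keeps both lactate exchanges reversible", {
  net <- minimal_as_network(default_params, U_G = 1)
  cpl <- couple_cells(net, U_G_total = 1, symmetric = TRUE)
  expect_lt(cpl$lb[match("LAC_ex_don", cpl$reactions)], 0)
  expect_lt(cpl$lb[match("LAC_ex_acc", cpl$reactions)], 0)
})

test_that("two-row |f_LDH| crowding encoding equals the absolute value", {
  p <- default_params
  net <- minimal_as_network(p, U_G = 1)
  cpl <- couple_cells(net, U_G_total = 1)
  spec <- crowding_spec_from_params(p)
  cr <- crowding_rows(cpl, spec)
  expect_equal(nrow(cr$A), 4)  # two rows per cell (LDH reversible)
  # randomized membership check against direct |f| evaluation
  set.seed(42)
  idx <- function(id) match(id, cpl$reactions)
  for (i in 1:200) {
    f <- numeric(length(cpl$reactions))
    f[idx(c("GLYC_don", "OX_don", "LDH_don", "GLYC_acc", "OX_acc",
            "LDH_acc"))] <- stats::runif(6, -2, 2)
    direct <- function(sfx) {
      p$a_glyc * f[idx(paste0("GLYC", sfx))] +
        p$a_ox * f[idx(paste0("OX", sfx))] +
        p$a_ldh * abs(f[idx(paste0("LDH", sfx))]) <= p$phi_atp
    }
    expect_identical(all(cr$A %*% f <= cr$b),
                     direct("_don") && direct("_acc"))
  }
  # pure lactate intake x is feasible iff a_LDH * x <= phi
  f <- numeric(length(cpl$reactions))
  f[idx("LDH_acc")] <- -p$phi_atp / p$a_ldh * 0.999
  expect_true(all(cr$A %*% f <= cr$b))
  f[idx("LDH_acc")] <- -p$phi_atp / p$a_ldh * 1.001
  expect_false(all(cr$A %*% f <= cr$b))
})

test_that("full fermentation saturates glucose intake at v_G", {
  # crowding row alone: max U_G with f_HEX = U_G, f_LDH = 2 U_G is v_G
  p <- default_params
  net <- minimal_as_network(p, U_G = 1e4)
  poly <- flux_polytope(net, crowding = crowding_spec_from_params(p))
  w <- as.vector(crossprod(poly$B, as.numeric(poly$reaction_ids == "GLC_up")))
  bg <- crowdflux:::box_guess(poly)
  lp <- solve_lp(w, A = poly$G, b = poly$h, lb = bg$lo, ub = bg$hi,
                 maximize = TRUE)
  expect_equal(lp$value, default_th$v_G, tolerance = 1e-8)
})

test_that("validate_flux reports residuals and bound violations", {
  p <- default_params
  net <- minimal_as_network(p, U_G = 0.5)
  expect_true(validate_flux(net, numeric(6))$ok)
  good <- single_cell_optimum(p, 0.5)
  f <- c(0.5, 0.5, 1, 0, 0, 19)  # GLC_up, GLYC, OX, LDH, LAC_ex, ATP
  expect_true(validate_flux(net, f)$ok)
  f_bad <- f; f_bad[1] <- 0.5 + 1e-3  # violates the uptake bound
  rep <- validate_flux(net, f_bad)
  expect_false(rep$ok)
  expect_match(rep$bound_violations, "GLC_up")
  expect_error(validate_flux(net, numeric(3)), "does not match")
})
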