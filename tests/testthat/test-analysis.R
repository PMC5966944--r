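mk_sol <- function(v, ids = names(v)) {
  names(v) <- ids
  structure(list(v = v, status = "optimal"), class = "vf_solution")
}

test_that("percent changes follow the control-denominator convention", {
  a <- mk_sol(c(r1 = 1.0, r2 = 2.0, r3 = 0.0, r4 = 0.5))
  b <- mk_sol(c(r1 = 1.8, r2 = 2.0, r3 = 0.7, r4 = -0.5))
  cmp <- percent_change_map(a, b)
  expect_equal(cmp$percent_change[1], 80)
  expect_equal(cmp$class[1], "increased")
  expect_equal(cmp$percent_change[2], 0)
  expect_equal(cmp$class[2], "unchanged")
  expect_true(is.na(cmp$percent_change[3]))
  expect_equal(cmp$class[3], "undefined")
  expect_true(cmp$sign_flip[4])
  expect_equal(cmp$percent_change[4], -200)

  # self-comparison is identically zero where defined
  self <- percent_change_map(a, a)
  expect_true(all(self$percent_change[!is.na(self$percent_change)] == 0))
  expect_error(percent_change_map(a, mk_sol(c(x = 1))), "mismatched")
})

test_that("cofactor ledgers balance and identify carriers", {
  net <- stoichiometric_network(
    list(metabolite("A"), metabolite("atp", cofactor = TRUE),
         metabolite("adp", cofactor = TRUE),
         metabolite("X", role = "external", compartment = "m")),
    list(reaction("make", c(A = 1, adp = -1, atp = 1)),
         reaction("use", c(A = -1, atp = -1, adp = 1)),
         reaction("exp", c(A = -1, X = 1), kind = "exchange")))
  sol <- mk_sol(c(make = 2, use = 2, exp = 0))
  led <- cofactor_ledger(net, sol, "atp")
  expect_equal(led$production, 2)
  expect_equal(led$consumption, -2)
  expect_equal(led$net, 0)
  expect_error(cofactor_ledger(net, sol, "A"), "not flagged")
  expect_error(cofactor_ledger(net, sol, "zz"), "unknown")
})

test_that("GT3 optimum balances every cofactor and internal metabolite", {
  net <- build_gt3_network()
  sc <- make_scenario(net, seed = 3,
                      params = list(targets = gt3_reference_targets("N")$targets))
  sol <- mk_sol(sc$v_true)
  tol <- 1e-8 * (1 + max(abs(sc$v_true)))
  for (cid in c("atp", "adp", "nadh", "nadph", "fadh2")) {
    led <- cofactor_ledger(net, sol, cid)
    expect_lt(abs(led$net), tol)
    expect_equal(led$production, -led$consumption, tolerance = 1e-6)
  }
  # ... and indeed every internal metabolite nets to zero
  S <- build_matrix(net)
  expect_lt(max(abs(S %*% as.numeric(sc$v_true))), tol)

  # NADPH sources include the oxidative PPP; sinks include flavonoid
  # reductive steps
  led <- cofactor_ledger(net, sol, "nadph")
  producers <- led$contributions$reaction_id[led$contributions$contribution > 0]
  consumers <- led$contributions$reaction_id[led$contributions$contribution < 0]
  expect_true(all(c("Vg6pdh", "Vgnd") %in% producers))
  expect_true(any(c("Vlcc", "Vtannins") %in% consumers))
})

test_that("2-oxoglutarate branch shares are normalised and responsive", {
  net <- stoichiometric_network(
    list(metabolite("akg"), metabolite("X", role = "external", compartment = "m"),
         metabolite("Y", role = "external", compartment = "m"),
         metabolite("Z", role = "external", compartment = "m")),
    list(reaction("feed", c(X = -1, akg = 1), kind = "exchange"),
         reaction("useA", c(akg = -1, Y = 1), kind = "exchange"),
         reaction("useB", c(akg = -1, Z = 1), kind = "exchange")))
  sol <- mk_sol(c(feed = 4, useA = 3, useB = 1))
  tab <- akg_branch_summary(net, sol)
  expect_equal(tab$share[tab$reaction_id == "useA"], 0.75)
  expect_equal(tab$share[tab$reaction_id == "useB"], 0.25)
  expect_equal(sum(tab$share), 1)
  expect_error(akg_branch_summary(toy_chain_network(), sol), "absent")

  # GT3: shares sum to one and the expected consumers appear
  gt3 <- build_gt3_network()
  scN <- make_scenario(gt3, seed = 5,
                       params = list(targets = gt3_reference_targets("N")$targets))
  tabN <- akg_branch_summary(gt3, mk_sol(scN$v_true))
  expect_equal(sum(tabN$share), 1, tolerance = 1e-9)
  expect_true(all(c("Vkgdh", "Vgogat") %in% tabN$reaction_id))
  expect_true(all(c("Vdhq", "Vflav", "Vanthoc") %in% tabN$reaction_id))
  expect_true(all(tabN$share >= 0))

  # capping GOGAT at half its control flux lowers its share of the budget
  ids <- reaction_ids(gt3)
  revs <- vapply(gt3$reactions, `[[`, TRUE, "reversible")
  lb <- ifelse(revs, -Inf, 0); ub <- rep(Inf, length(ids))
  tg <- gt3_reference_targets("N")$targets
  jj <- match(names(tg), ids)
  lb[jj] <- ub[jj] <- tg
  gogat_ctrl <- unname(scN$v_true["Vgogat"])
  expect_gt(gogat_ctrl, 0)
  ub[match("Vgogat", ids)] <- 0.5 * gogat_ctrl
  cpl <- list(A = matrix(as.numeric(ids %in% c("Vnrj1", "Vnrj2")), 1),
              lower = 3.54, upper = 3.54, labels = "respiration_atp")
  prL <- flux_problem(build_matrix(gt3), lb, ub, ids, couplings = cpl)
  solL <- minimize_flux(prL)
  expect_equal(solL$status, "optimal")
  tabL <- akg_branch_summary(gt3, solL)
  shareN <- tabN$share[tabN$reaction_id == "Vgogat"]
  shareL <- tabL$share[tabL$reaction_id == "Vgogat"]
  expect_lt(shareL, shareN)
})

test_that("flux maps export to DOT and GraphML and round-trip topology", {
  td <- withr::local_tempdir()
  net <- toy_chain_network()
  sol <- mk_sol(c(up = 2, conv = 2, out = 2))
  pdot <- file.path(td, "map.dot")
  export_flux_map(net, sol, pdot, format = "dot")
  txt <- readLines(pdot)
  expect_true(any(grepl("conv", txt)))

  # zero-flux reactions stay in the map at minimum width
  sol0 <- mk_sol(c(up = 2, conv = 0, out = 2))
  export_flux_map(net, sol0, pdot, format = "dot")
  expect_true(any(grepl("conv", readLines(pdot))))

  pgml <- file.path(td, "map.graphml")
  export_flux_map(net, list(sol, mk_sol(c(up = 1, conv = 3, out = 2))),
                  pgml, format = "graphml")
  g <- igraph::read_graph(pgml, format = "graphml")
  expect_equal(igraph::vcount(g), length(net$metabolites) + length(net$reactions))
  expect_equal(igraph::ecount(g), sum(lengths(lapply(net$reactions, `[[`, "stoich"))))
  expect_true("red" %in% igraph::E(g)$color)   # conv increased
  expect_error(export_flux_map(net, sol, pdot, format = "svg"))
})
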