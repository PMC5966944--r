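test_that("build_matrix balances internal metabolites only", {
  net1 <- stoichiometric_network(
    list(metabolite("A")),
    list(reaction("r1", c(A = 1)), reaction("r2", c(A = -1))))
  expect_equal(unname(build_matrix(net1)), matrix(c(1, -1), 1, 2))

  # an external species contributes no balance row
  net2 <- stoichiometric_network(
    list(metabolite("A", role = "external", compartment = "medium"),
         metabolite("B")),
    list(reaction("r1", c(A = 1, B = -1), kind = "exchange")))
  expect_equal(nrow(build_matrix(net2)), 1L)
  expect_equal(rownames(build_matrix(net2)), "B")

  fork <- stoichiometric_network(
    list(metabolite("A")),
    list(reaction("r1", c(A = 1)), reaction("r2", c(A = -1)),
         reaction("r3", c(A = -1))))
  expect_equal(unname(build_matrix(fork)), matrix(c(1, -1, -1), 1, 3))
})

test_that("permuting reaction order permutes matrix columns identically", {
  net <- build_gt3_network()
  S <- build_matrix(net)
  set.seed(7)
  for (rep in 1:5) {
    perm <- sample(length(net$reactions))
    net_p <- stoichiometric_network(net$metabolites, net$reactions[perm],
                                    provenance = net$provenance)
    expect_identical(build_matrix(net_p), S[, perm])
  }
})

test_that("network invariants are enforced", {
  expect_error(metabolite("atp", role = "external", cofactor = TRUE), "cofactor")
  expect_error(reaction("r", numeric(0)), "non-empty")
  expect_error(reaction("r", c(A = -1), capacity = -2), "capacity")
  expect_error(stoichiometric_network(
    list(metabolite("A"), metabolite("A")),
    list(reaction("r", c(A = 1)))), "duplicated metabolite")
  expect_error(stoichiometric_network(
    list(metabolite("A")),
    list(reaction("r", c(B = 1)))), "unknown metabolite")
  # exchange must touch an external species
  expect_error(stoichiometric_network(
    list(metabolite("A")),
    list(reaction("r", c(A = 1), kind = "exchange"))), "external")
  # a network of only externals has no balance row
  expect_error(stoichiometric_network(
    list(metabolite("A", role = "external", compartment = "medium")),
    list(reaction("r", c(A = 1), kind = "exchange"))), "internal")
})

test_that("the GT3 reconstruction has the curated structure", {
  net <- build_gt3_network()
  expect_silent(validate_network(net))
  ids <- reaction_ids(net)
  named <- c("Vglc-up", "Vfru-up", "Vno3-up", "Vnr", "Vgs", "Vgogat", "Vpfp",
             "Vpk", "Vmacl", "Vshik", "Vpal", "Vcoum", "Vnar", "Vdhq", "Vlcc",
             "Vanthoc", "Vflav", "Vtannins", "Vstilb", "Vcw", "Vprotein",
             "Vdag", "Vnucleotides", "Vac-mal", "Vac-glc", "Vac-fru",
             "Vac-suc", "Vac-Glu", "Vac-Asp", "Vac-Ala", "Vac-Phe", "Vnrj1",
             "Vnrj2", "Vadk", "Vnga-ATPm", "Vkgdh")
  expect_true(all(named %in% ids))

  rx <- function(id) net$reactions[[match(id, ids)]]
  # dioxygenase steps consume 2-oxoglutarate and release succinate
  for (id in c("Vanthoc", "Vflav", "Vdhq")) {
    st <- rx(id)$stoich
    expect_lt(st[["akg"]], 0)
    expect_gt(st[["succ"]], 0)
  }
  # nitrate assimilation path present and connected
  expect_equal(rx("Vno3-up")$stoich[["no3"]], 1)
  expect_lt(rx("Vnr")$stoich[["no3"]], 0)
  expect_lt(rx("Vgs")$stoich[["nh4"]], 0)
  expect_lt(rx("Vgogat")$stoich[["gln"]], 0)
  # oxidative phosphorylation converts redox carriers to ATP
  expect_lt(rx("Vnrj1")$stoich[["nadh"]], 0)
  expect_gt(rx("Vnrj1")$stoich[["atp"]], 0)
  expect_lt(rx("Vnrj2")$stoich[["fadh2"]], 0)
  # maintenance hydrolyses ATP
  expect_equal(rx("Vnga-ATPm")$stoich[["atp"]], -1)
  expect_equal(rx("Vnga-ATPm")$kind, "maintenance")
  # phenolic branch reaches central metabolism only through phenylalanine:
  # cinnamate is produced solely by Vpal from phe
  producers_cin <- ids[vapply(net$reactions, function(r)
    "cin" %in% names(r$stoich) && r$stoich[["cin"]] > 0, TRUE)]
  expect_equal(producers_cin, "Vpal")
  # the three reversible flavonoid-core steps
  expect_true(all(vapply(c("Vnar", "Vdhq", "Vlcc"),
                         function(id) rx(id)$reversible, TRUE)))
})

test_that("cofactor rows are balanced for any null-space flux vector", {
  net <- build_gt3_network()
  S <- build_matrix(net)
  cof <- vapply(net$metabolites, function(m) m$cofactor, TRUE)
  cof_ids <- metabolite_ids(net)[cof]
  P <- diag(ncol(S)) - pracma_like_pinv(S) %*% S
  set.seed(11)
  for (k in 1:5) {
    v <- as.numeric(P %*% rnorm(ncol(S)))
    prod <- S[cof_ids, , drop = FALSE] %*% v
    expect_lt(max(abs(prod)), 1e-8 * (1 + max(abs(v))))
  }
})
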