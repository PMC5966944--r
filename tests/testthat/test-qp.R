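test_that("the fork problem solves by symmetry and under a binding bound", {
  sol <- minimize_flux(fork_problem())
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$v), c(2, 1, 1), tolerance = 1e-10)
  expect_equal(sol$objective, 6, tolerance = 1e-10)

  sol2 <- minimize_flux(fork_problem(ub2 = 0.5))
  expect_equal(unname(sol2$v), c(2, 0.5, 1.5), tolerance = 1e-10)
  expect_true(sol2$at_bound[2])

  # weighted split: flux prefers the cheap branch in ratio w3:w2
  solw <- minimize_flux(fork_problem(weights = c(1, 1, 3)))
  expect_equal(unname(solw$v[2] / solw$v[3]), 3, tolerance = 1e-8)
})

test_that("a fully fixed problem returns the point or detects contradiction", {
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("r1", "r2")))
  pr <- flux_problem(S, lb = c(2, 2), ub = c(2, 2))
  sol <- minimize_flux(pr)
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$v), c(2, 2))

  pr_bad <- flux_problem(S, lb = c(2, 1), ub = c(2, 1))
  expect_equal(minimize_flux(pr_bad)$status, "infeasible")
})

test_that("infeasible problems are reported, never silently near-solved", {
  # production fixed > 0 with no consumer
  S <- matrix(1, 1, 1, dimnames = list("A", "r1"))
  pr <- flux_problem(S, lb = 2, ub = 2)
  sol <- minimize_flux(pr)
  expect_equal(sol$status, "infeasible")
  expect_false(isTRUE(sol$status == "optimal"))
  expect_true(is.na(sol$kkt_residual))
})

test_that("solver matches the enumeration oracle on random small problems", {
  agree <- 0L
  for (seed in 1:40) {
    pr <- random_small_problem(seed)
    a <- minimize_flux(pr)
    b <- solve_oracle_small(pr)
    expect_identical(a$status == "optimal", b$status == "optimal",
                     info = sprintf("seed %d status mismatch", seed))
    if (a$status == "optimal") {
      expect_lt(max(abs(a$v - b$v)) / (1 + max(abs(b$v))), 1e-6)
      agree <- agree + 1L
    }
  }
  expect_gt(agree, 10L)  # the generator must produce mostly solvable cases
})

test_that("optimal solutions satisfy tight feasibility tolerances", {
  for (seed in c(3, 17, 29)) {
    pr <- random_small_problem(seed)
    sol <- minimize_flux(pr)
    if (sol$status != "optimal") next
    v <- as.numeric(sol$v)
    expect_lt(max(abs(pr$S %*% v)), 1e-8 * (1 + max(abs(v))))
    expect_lt(max(pr$lb - v, v - pr$ub, 0), 1e-9 * (1 + max(abs(v))))
  }
})

test_that("solution is invariant to reaction permutation (uniqueness)", {
  net <- build_gt3_network()
  tg <- gt3_reference_targets("N")
  sc <- make_scenario(net, seed = 8, params = list(targets = tg$targets))
  ids <- reaction_ids(net)
  revs <- vapply(net$reactions, `[[`, TRUE, "reversible")
  lb <- ifelse(revs, -Inf, 0); ub <- rep(Inf, length(ids))
  jj <- match(names(tg$targets), ids)
  lb[jj] <- ub[jj] <- tg$targets
  pr <- flux_problem(build_matrix(net), lb, ub, ids)
  v0 <- minimize_flux(pr)$v
  set.seed(21)
  for (k in 1:3) {
    perm <- sample(length(ids))
    prp <- flux_problem(pr$S[, perm], lb[perm], ub[perm], ids[perm])
    vp <- minimize_flux(prp)$v
    expect_lt(max(abs(vp[ids] - v0[ids])), 1e-6 * (1 + max(abs(v0))))
  }
})

test_that("scaling all constraint data scales the optimum exactly", {
  pr <- fork_problem(ub2 = 0.8)
  v0 <- as.numeric(minimize_flux(pr)$v)
  for (lam in c(0.5, 2, 10)) {
    vs <- as.numeric(minimize_flux(scale_problem(pr, lam))$v)
    expect_lt(max(abs(vs - lam * v0)) / (1 + max(abs(lam * v0))), 1e-8)
  }
})

test_that("relaxing a bound never increases the optimal objective", {
  tight <- minimize_flux(fork_problem(ub2 = 0.5))$objective
  loose <- minimize_flux(fork_problem(ub2 = 0.9))$objective
  free <- minimize_flux(fork_problem())$objective
  expect_true(tight >= loose && loose >= free)
})

test_that("KKT audit passes at optima and catches perturbed solutions", {
  pr <- fork_problem()
  sol <- minimize_flux(pr)
  rep <- check_kkt(pr, sol)
  expect_true(rep$ok)
  expect_lt(rep$stationarity, 1e-8)
  expect_lt(rep$primal_balance, 1e-8)

  # perturb a free flux: stationarity must break
  bad <- sol
  bad$v["r2"] <- bad$v["r2"] + 0.1
  bad$v["r3"] <- bad$v["r3"] - 0.1   # keep the balance, break optimality
  repb <- check_kkt(pr, bad)
  expect_gt(repb$stationarity, 1e-6)

  # capacity-limited fork: multiplier on the active bound is non-negative
  solc <- minimize_flux(fork_problem(ub2 = 0.5))
  repc <- check_kkt(fork_problem(ub2 = 0.5), solc)
  expect_true(repc$ok)
  expect_lte(repc$multiplier_sign_violation, 1e-8)
  expect_error(check_kkt(pr, minimize_flux(
    flux_problem(matrix(1, 1, 1, dimnames = list("A", "r")), 2, 2))),
    "optimal")
})

test_that("infeasibility diagnosis names the offending constraint", {
  # dead-end production fixed at 2: slack must be ~ -2 on that constraint
  S <- matrix(1, 1, 1, dimnames = list("A", "r1"))
  pr <- flux_problem(S, lb = 2, ub = 2)
  rep <- diagnose_infeasibility(pr)
  expect_equal(rep$constraint, "r1")
  expect_equal(rep$slack, -2, tolerance = 1e-4)

  # feasible problem: empty report
  expect_equal(nrow(diagnose_infeasibility(fork_problem())), 0L)

  # respiration demanded above what the network can sustain
  net <- toy_chain_network()
  S2 <- build_matrix(net)
  ids <- reaction_ids(net)
  lb <- c(1, 0, 0); ub <- c(1, 2, Inf)   # uptake fixed 1, conv capped at 2
  cpl <- list(A = matrix(c(0, 1, 0), 1), lower = 5, upper = 5, labels = "resp")
  prc <- flux_problem(S2, lb, ub, ids, couplings = cpl)
  expect_equal(minimize_flux(prc)$status, "infeasible")
  repc <- diagnose_infeasibility(prc)
  expect_true("resp" %in% repc$constraint)
})

test_that("a solution at the unbounded-marker cap raises a warning", {
  # internal loop: r1 forward, r2 backward, both unbounded; fixing their
  # difference leaves the loop free, but fixing the sum via coupling at a
  # huge value pushes both to the cap
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("f", "b")))
  cpl <- list(A = matrix(c(1, 1), 1), lower = 1.99e6, upper = 1.99e6, labels = "push")
  pr <- flux_problem(S, lb = c(-Inf, -Inf), ub = c(Inf, Inf),
                     reaction_ids = c("f", "b"), couplings = cpl)
  expect_warning(minimize_flux(pr), "cap")
})
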