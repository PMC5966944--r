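# shared in-code fixtures: tiny networks and a random small-problem generator

# A -> split into two branches; uptake fixed at `fix`
fork_problem <- function(fix = 2, ub2 = Inf, weights = NULL) {
  S <- matrix(c(1, -1, -1), 1, 3, dimnames = list("A", c("r1", "r2", "r3")))
  flux_problem(S, lb = c(fix, 0, 0), ub = c(fix, ub2, Inf),
               reaction_ids = c("r1", "r2", "r3"), weights = weights)
}

toy_chain_network <- function() {
  stoichiometric_network(
    list(metabolite("X", role = "external", compartment = "medium"),
         metabolite("A"), metabolite("B"),
         metabolite("P", role = "external", compartment = "sink")),
    list(reaction("up", c(X = -1, A = 1), kind = "exchange"),
         reaction("conv", c(A = -1, B = 1)),
         reaction("out", c(B = -1, P = 1), kind = "exchange")))
}

autocatalytic_network <- function() {
  stoichiometric_network(
    list(metabolite("A"), metabolite("X", role = "external", compartment = "medium")),
    list(reaction("dup", c(A = 1), name = "mass from nothing"),
         reaction("drain", c(A = -1, X = 1), kind = "exchange")))
}

# random bound-structured QP over a sparse random stoichiometry; built so the
# active-set enumeration stays small (n <= 12)
random_small_problem <- function(seed) {
  set.seed(seed)
  n <- sample(6:9, 1)
  m <- sample(2:4, 1)
  repeat {
    S <- matrix(0, m, n)
    for (j in seq_len(n)) {
      idx <- sample(m, min(m, sample(1:2, 1)))
      S[idx, j] <- sample(c(-2, -1, 1, 2), length(idx), replace = TRUE)
    }
    if (all(rowSums(S != 0) > 0)) break
  }
  lb <- rep(-Inf, n); ub <- rep(Inf, n)
  kind <- sample(c("irr", "rev", "cap"), n, replace = TRUE, prob = c(0.55, 0.25, 0.2))
  lb[kind == "irr"] <- 0
  cap <- kind == "cap"
  ub[cap] <- runif(sum(cap), 0.5, 3)
  lb[cap] <- ifelse(runif(sum(cap)) < 0.5, 0, -ub[cap])
  # drive the system: one fixed exchange
  jf <- sample(n, 1)
  val <- runif(1, 0.3, 1.5)
  lb[jf] <- ub[jf] <- val
  weights <- if (runif(1) < 0.4) runif(n, 0.5, 2) else NULL
  couplings <- NULL
  if (runif(1) < 0.3) {
    a <- numeric(n); a[sample(n, 2)] <- 1
    couplings <- list(A = matrix(a, 1), lower = runif(1, 0.2, 1),
                      upper = NA, labels = "cpl")
    couplings$upper <- couplings$lower
  }
  flux_problem(S, lb, ub, paste0("r", seq_len(n)),
               couplings = couplings, weights = weights)
}

# plain SVD pseudo-inverse, independent of package internals
pracma_like_pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# measurement set whose component masses sum to a chosen fraction of 1 g DW
coverage_components <- function(total_g, day = 4, n_parts = 4) {
  parts <- rep(total_g / n_parts, n_parts)
  data.frame(component_id = paste0("comp", seq_len(n_parts)), day = day,
             value = parts * 1000, unit = "mg_per_gDW", molar_mass = 150,
             stringsAsFactors = FALSE)
}

exp_biomass_measurements <- function(mu = 0.288, X0 = 1.6,
                                     days = c(0, 2, 4, 6), components = NULL,
                                     ...) {
  measurement_set(days, X0 * exp(mu * days), components = components, ...)
}
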