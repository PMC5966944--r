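#' Built-in reference exchange targets for the GT3 demonstration
#'
#' Synthetic but physiologically plausible accumulation/biomass fluxes
#' (mmol gDW^-1 day^-1) for a control ("N") and a nitrogen-limited ("N-")
#' culture at day 4, together with the condition's specific growth rate and
#' respiration-derived ATP synthesis rate. The nitrogen-limited set encodes
#' the qualitative response of this cell line: polyphenol and sugar
#' accumulation up, protein synthesis, amino-acid pools and malate storage
#' down, respiration reduced. These are synthetic demonstration values
#' (the study's own constraint tables are not redistributed with the
#' package), so comparisons against them test the pipeline, not the
#' original culture.
#'
#' @param condition `"N"` (control) or `"N-"` (low nitrogen).
#' @return list with `targets` (named numeric, 16 fluxes), `mu` (day^-1),
#'   `respiration_atp` (mmol gDW^-1 day^-1), `condition`.
#' @export
gt3_reference_targets <- function(condition = c("N", "N-")) {
  condition <- match.arg(condition)
  if (condition == "N") {
    targets <- c(
      "Vac-mal" = 0.15, "Vac-glc" = 0.15, "Vac-fru" = 0.12, "Vac-suc" = 0.05,
      "Vac-Glu" = 0.040, "Vac-Asp" = 0.020, "Vac-Ala" = 0.015, "Vac-Phe" = 0.005,
      "Vanthoc" = 0.0015, "Vflav" = 0.0004, "Vtannins" = 0.004, "Vstilb" = 0.0002,
      "Vcw" = 0.45, "Vprotein" = 1.10, "Vdag" = 0.00005, "Vnucleotides" = 0.040)
    list(targets = targets, mu = 0.288, respiration_atp = 3.54, condition = "N")
  } else {
    targets <- c(
      "Vac-mal" = 0.10, "Vac-glc" = 0.25, "Vac-fru" = 0.20, "Vac-suc" = 0.08,
      "Vac-Glu" = 0.015, "Vac-Asp" = 0.008, "Vac-Ala" = 0.006, "Vac-Phe" = 0.004,
      "Vanthoc" = 0.004, "Vflav" = 0.0009, "Vtannins" = 0.007, "Vstilb" = 0.0005,
      "Vcw" = 0.40, "Vprotein" = 0.65, "Vdag" = 0.00005, "Vnucleotides" = 0.030)
    list(targets = targets, mu = 0.288, respiration_atp = 2.86, condition = "N-")
  }
}

# molar masses (g/mol) used when fabricating mass-based concentrations
gt3_molar_masses <- function() c(
  "Vac-mal" = 134.09, "Vac-glc" = 180.16, "Vac-fru" = 180.16, "Vac-suc" = 342.30,
  "Vac-Glu" = 147.13, "Vac-Asp" = 133.10, "Vac-Ala" = 89.09, "Vac-Phe" = 165.19,
  "Vanthoc" = 449.4, "Vflav" = 302.2, "Vtannins" = 290.3, "Vstilb" = 228.2,
  "Vcw" = 162.14, "Vprotein" = 110.0, "Vdag" = 600.0, "Vnucleotides" = 330.0)

#' Build a synthetic scenario with a known ground-truth flux vector
#'
#' Fixes (or draws) targets for the measured exchange fluxes, solves the
#' flux-minimization problem once, and stores the optimum as the
#' ground-truth vector `v_true`. Because `v_true` is itself the minimum-norm
#' point of its own constraint set, the estimation pipeline applied to
#' noise-free measurements fabricated from it must return it exactly — the
#' property the recovery harness tests.
#'
#' @param network a `vf_network`; default [build_gt3_network()].
#' @param seed integer seed; all scenario randomness flows through it.
#' @param params optional list:
#'   * `targets`: named numeric of fixed exchange targets (skips drawing);
#'   * `target_center`: named numeric around which targets are drawn
#'     uniformly in `center * range_rel` (default the control reference
#'     set);
#'   * `range_rel`: length-2 relative draw range (default `c(0.7, 1.3)`);
#'   * `mu`: specific growth rate, day^-1 (default 0.288, the day-4
#'     exponential-phase value);
#'   * `X0`: initial biomass, g DW L^-1 (default 1.6);
#'   * `noise_cv`: multiplicative lognormal coefficient of variation for
#'     fabricated measurements (default 0.05);
#'   * `days`: sampling days (default `c(0, 4, 6, 8, 11)`);
#'   * `eval_day`: the steady-state day the flux problem refers to
#'     (default 4);
#'   * `capacity_reactions`: reactions receiving a fabricated measured
#'     capacity (default a panel of central/flavonoid enzymes);
#'   * `capacity_alpha`: range of the capacity/|flux| headroom factor,
#'     `>= 1` so capacities never cut the truth (default `c(1.5, 3)`);
#'   * `respiration_atp`: ATP synthesis rate imposed as a coupling when
#'     solving for `v_true` (default 3.54, the day-4 control respiration).
#'     A rate above the stoichiometric minimum leaves the maintenance
#'     reaction positive, as in a real culture; `NA` drops the coupling,
#'     which parks the truth at minimal respiration (zero maintenance).
#' @param max_retries re-draw attempts if a drawn target set is infeasible.
#' @return a `vf_scenario`.
#' @export
make_scenario <- function(network = build_gt3_network(), seed = 1L,
                          params = list(), max_retries = 10L) {
  set.seed(seed)
  p <- params
  mu <- p$mu %||% 0.288
  X0 <- p$X0 %||% 1.6
  noise_cv <- p$noise_cv %||% 0.05
  days <- p$days %||% c(0, 4, 6, 8, 11)
  eval_day <- p$eval_day %||% 4
  range_rel <- p$range_rel %||% c(0.7, 1.3)
  center <- p$target_center %||% gt3_reference_targets("N")$targets
  capacity_reactions <- p$capacity_reactions %||%
    intersect(c("Vhk", "Vfk", "Vpfk", "Vpfp", "Vpk", "Vpepc", "Vcs", "Vidh",
                "Vkgdh", "Vg6pdh", "Vme", "Vpal", "Vchs"),
              reaction_ids(network))
  capacity_alpha <- p$capacity_alpha %||% c(1.5, 3)
  respiration_atp <- p$respiration_atp %||% 3.54
  if (any(capacity_alpha < 1))
    vf_stop("capacity_alpha must be >= 1 (capacities must not cut the truth)")
  if (mu <= 0 && is.null(p$targets)) vf_stop("mu must be positive")

  ids <- reaction_ids(network)
  unknown <- setdiff(names(p$targets %||% center), ids)
  if (length(unknown))
    vf_stop("target(s) reference unknown reaction(s): %s", paste(unknown, collapse = ", "))

  revs <- vapply(network$reactions, `[[`, TRUE, "reversible")
  base_lb <- ifelse(revs, -Inf, 0)
  base_ub <- rep(Inf, length(ids))

  solve_targets <- function(tg) {
    lb <- base_lb; ub <- base_ub
    j <- match(names(tg), ids)
    lb[j] <- ub[j] <- tg
    cpl <- NULL
    if (!is.na(respiration_atp)) {
      cpl <- list(A = matrix(as.numeric(ids %in% c("Vnrj1", "Vnrj2")), 1),
                  lower = respiration_atp, upper = respiration_atp,
                  labels = "respiration_atp")
    }
    pr <- flux_problem(build_matrix(network), lb, ub, ids, couplings = cpl)
    minimize_flux(pr)
  }

  if (!is.null(p$targets)) {
    targets <- p$targets
    sol <- solve_targets(targets)
    if (sol$status != "optimal")
      vf_stop("scenario targets give an infeasible flux problem (status %s)", sol$status)
  } else {
    sol <- NULL
    for (k in seq_len(max_retries)) {
      targets <- center * stats::runif(length(center), range_rel[1], range_rel[2])
      s <- solve_targets(targets)
      if (s$status == "optimal") { sol <- s; break }
    }
    if (is.null(sol))
      vf_stop("no feasible target draw in %d attempts", max_retries)
  }

  alpha <- stats::runif(length(capacity_reactions), capacity_alpha[1], capacity_alpha[2])
  names(alpha) <- capacity_reactions

  v_true <- sol$v
  structure(list(network = network, v_true = v_true, mu_true = mu, X0 = X0,
                 noise_cv = noise_cv, seed = seed, days = days,
                 eval_day = eval_day, targets = targets,
                 measured = names(targets), capacity_alpha = alpha,
                 atp_synthesis_rate = unname(v_true["Vnrj1"] + v_true["Vnrj2"]),
                 balance_residual = sol$balance_residual),
            class = "vf_scenario")
}

#' @export
print.vf_scenario <- function(x, ...) {
  cat(sprintf("Synthetic scenario (seed %d): mu=%.3f/day, X0=%.2f gDW/L, noise CV=%.0f%%\n",
              x$seed, x$mu_true, x$X0, 100 * x$noise_cv))
  cat(sprintf("  %d fixed exchange targets, %d fabricated capacities, ATP rate %.3f\n",
              length(x$targets), length(x$capacity_alpha), x$atp_synthesis_rate))
  invisible(x)
}

# unbiased multiplicative lognormal noise: E[factor] = 1, CV = cv
lnorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Fabricate a measurement set from a scenario
#'
#' Inverts the measurement-to-constraint conversion: biomass follows
#' `X0 * exp(mu * t)`, each measured component's concentration is
#' `v_true / mu` (the steady-state accumulation corresponding to its
#' ground-truth flux; amino-acid components are written mass-based to
#' exercise the unit conversion), capacities are `alpha * |v_true|` with
#' `alpha >= 1`, and the ATP synthesis rate is the ground-truth
#' `Vnrj1 + Vnrj2`. All quantities carry multiplicative lognormal noise of
#' the scenario's CV (exact at `noise_cv = 0`).
#'
#' @param scenario a `vf_scenario`.
#' @param days sampling days (default the scenario's).
#' @return a `vf_measurements`.
#' @export
simulate_measurements <- function(scenario, days = scenario$days) {
  stopifnot(inherits(scenario, "vf_scenario"))
  if (!length(days)) vf_stop("days must be non-empty")
  if (scenario$mu_true <= 0) vf_stop("mu_true must be positive")
  set.seed(scenario$seed + 1L)
  cv <- scenario$noise_cv
  mm <- gt3_molar_masses()
  mass_based <- c("Vac-Glu", "Vac-Asp", "Vac-Ala", "Vac-Phe")

  biomass <- scenario$X0 * exp(scenario$mu_true * days) * lnorm_factor(length(days), cv)

  comp <- do.call(rbind, lapply(days, function(d) {
    conc <- as.numeric(scenario$v_true[scenario$measured]) / scenario$mu_true *
      lnorm_factor(length(scenario$measured), cv)
    unit <- rep("mmol_per_gDW", length(conc))
    mmass <- unname(mm[scenario$measured])
    sel <- scenario$measured %in% mass_based & !is.na(mmass)
    conc[sel] <- conc[sel] * mmass[sel]
    unit[sel] <- "mg_per_gDW"
    data.frame(component_id = scenario$measured, day = d, value = conc,
               unit = unit, molar_mass = mmass, stringsAsFactors = FALSE)
  }))

  caps <- scenario$capacity_alpha *
    abs(as.numeric(scenario$v_true[names(scenario$capacity_alpha)])) *
    lnorm_factor(length(scenario$capacity_alpha), cv)

  atp <- scenario$atp_synthesis_rate * lnorm_factor(1, cv)

  measurement_set(timepoints = days, biomass = biomass, components = comp,
                  capacities = caps, atp_synthesis_rate = atp,
                  condition = sprintf("synthetic_seed%d", scenario$seed))
}

#' Run the full estimation pipeline against the ground truth
#'
#' simulate -> estimate growth -> assemble constraints -> solve -> compare
#' to `v_true`. Because the scenario's truth is the minimum-norm point of
#' its own constraint set, noise-free recovery must be exact; with noise
#' the report quantifies estimator error.
#'
#' @param scenario a `vf_scenario`.
#' @param days sampling days passed to [simulate_measurements()].
#' @return list of class `vf_recovery`: `max_rel_flux_error` (max over
#'   reactions of `|v - v_true| / (1 + |v_true|)`), `balance_residual`,
#'   `sign_coverage` (fraction of fluxes with `|v_true| > 1e-6` whose
#'   direction is recovered), `solution`, `v_true`, `mu_hat`.
#' @export
recovery_harness <- function(scenario, days = scenario$days) {
  stopifnot(inherits(scenario, "vf_scenario"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      vf_stop("recovery pipeline failed at stage '%s': %s", what, conditionMessage(e)))
  }
  ms <- stage("simulate", simulate_measurements(scenario, days))
  gr <- stage("growth", estimate_growth_rate(ms, scenario$eval_day))
  pr <- stage("assemble",
              assemble_problem(scenario$network, ms, scenario$eval_day, growth = gr))
  sol <- stage("solve", minimize_flux(pr))
  if (sol$status != "optimal")
    vf_stop("recovery pipeline failed at stage 'solve': status %s", sol$status)

  v <- as.numeric(sol$v); vt <- as.numeric(scenario$v_true)
  rel <- abs(v - vt) / (1 + abs(vt))
  sig <- abs(vt) > 1e-6
  structure(list(
    max_rel_flux_error = max(rel),
    balance_residual = sol$balance_residual,
    sign_coverage = if (any(sig)) mean(sign(v[sig]) == sign(vt[sig])) else NA_real_,
    mu_hat = gr$mu, solution = sol, v_true = scenario$v_true),
    class = "vf_recovery")
}

#' @export
print.vf_recovery <- function(x, ...) {
  cat(sprintf("Recovery report: max relative flux error %.3g, sign coverage %.1f%%, balance residual %.3g\n",
              x$max_rel_flux_error, 100 * x$sign_coverage, x$balance_residual))
  cat(sprintf("  estimated mu: %.4f day^-1\n", x$mu_hat))
  invisible(x)
}
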