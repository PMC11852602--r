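von_mises_voigt <- function(S) {
  sqrt(0.5 * ((S[, 1] - S[, 2])^2 + (S[, 2] - S[, 3])^2 +
                (S[, 3] - S[, 1])^2) + 3 * (S[, 4]^2 + S[, 5]^2 + S[, 6]^2))
}

#' Solve all load cases on one mesh
#'
#' Assembles and factorizes the stiffness once and back-solves every load
#' case, returning the per-element von Mises stress of each.
#'
#' @param mesh a [mesh_model()].
#' @param E per-element moduli (MPa).
#' @param nu Poisson's ratio.
#' @param load_cases list of [load_case()] objects.
#' @param fixed_set fully fixed facet set.
#' @return Matrix (elements x cases) of von Mises stresses (MPa).
#' @export
solve_load_cases <- function(mesh, E, nu, load_cases, fixed_set = "base") {
  K <- assemble_elastic(mesh, E, nu)
  fixed_nodes <- facet_nodes(mesh, mesh$facet_sets[[fixed_set]])
  fixed_dofs <- as.vector(outer(3L * (fixed_nodes - 1L), 1:3, `+`))
  ndof <- nrow(K)
  free <- setdiff(seq_len(ndof), fixed_dofs)
  Kff <- methods::as(methods::as(K[free, free, drop = FALSE],
                                 "symmetricMatrix"), "CsparseMatrix")
  ch <- tryCatch(Cholesky(Kff, LDL = FALSE), error = function(e) {
    abort(paste0("singular system: ", conditionMessage(e)),
          class = "osteosim_singular_system")
  })
  vm <- matrix(0, n_elements(mesh), length(load_cases))
  for (j in seq_along(load_cases)) {
    cs <- load_cases[[j]]
    f <- traction_forces(mesh, mesh$facet_sets[[cs$joint_set]],
                         force_vector(cs$joint_force_N, cs$joint_angle_deg)) +
      traction_forces(mesh, mesh$facet_sets[[cs$muscle_set]],
                      force_vector(cs$muscle_force_N, cs$muscle_angle_deg))
    u <- numeric(ndof)
    u[free] <- as.vector(solve(ch, f[free], system = "A"))
    S <- fem_element_stress(mesh$nodes, mesh$tets, E, nu, u)
    vm[, j] <- von_mises_voigt(S)
  }
  colnames(vm) <- vapply(load_cases, function(x) x$name, "")
  vm
}

#' Initialize the remodeling state
#'
#' Builds the day-stepping state: per-element porosity/density/modulus,
#' the equilibrium stimulus, and per-class BMU history buffers pre-filled
#' with the equilibrium activation density `fa0 * Sr(P0)` (the skeleton is
#' assumed at remodeling equilibrium before surgery). The
#' cortical/cancellous classification is fixed at initialization.
#'
#' @param mesh the (implanted) [mesh_model()] the simulation runs on.
#' @param material material-field tibble from [build_material_field()].
#' @param phi0 per-element equilibrium stimulus (MPa; `NA` allowed on
#'   implant elements).
#' @param load_cases list of [load_case()] objects.
#' @param params a [remodeling_params()].
#' @param mapping the [material_mapping()] (for `rho_0` and clamps).
#' @param protocol optional [stimulation_protocol()].
#' @param phi_hat optional per-element normalized potential (required when
#'   the protocol has a positive amplitude).
#' @param nu Poisson's ratio for the daily solves.
#' @param phi_frozen optional per-element stimulus held fixed for the whole
#'   run (no finite-element updates); used for controlled kinetics
#'   experiments such as total disuse (`phi_frozen = 0`).
#' @return A list of class `remodel_state` (day counter at 0).
#' @export
init_disuse_state <- function(mesh, material, phi0, load_cases,
                              params = remodeling_params(),
                              mapping = material_mapping(),
                              protocol = NULL, phi_hat = NULL, nu = 0.3,
                              phi_frozen = NULL) {
  bone <- which(!material$is_implant)
  if (!length(bone)) abort("mesh has no bone elements")
  if (!is.null(protocol) && protocol$amplitude > 0 && is.null(phi_hat)) {
    abort("phi_hat is required for a protocol with positive amplitude")
  }
  cls <- material$bone_class[bone]
  idx_cor <- bone[cls == "cortical"]
  idx_can <- bone[cls == "cancellous"]
  fa0 <- disuse_activation_frequency(1, 1, params$kappa_d1, params$kappa_d2,
                                     params$fa_max)
  p0 <- material$porosity
  hist_cor <- if (length(idx_cor)) {
    bmu_history(fa0 * specific_surface(p0[idx_cor]),
                params$cortical["T_R"], params$cortical["T_I"],
                params$cortical["T_F"])
  }
  hist_can <- if (length(idx_can)) {
    bmu_history(fa0 * specific_surface(p0[idx_can]),
                params$cancellous["T_R"], params$cancellous["T_I"],
                params$cancellous["T_F"])
  }
  if (any(!is.finite(phi0[bone])) || any(phi0[bone] <= 0)) {
    abort("phi0 must be finite and positive on all bone elements")
  }
  structure(list(
    mesh = mesh, nu = nu, load_cases = load_cases, params = params,
    mapping = mapping, protocol = protocol,
    phi_hat = phi_hat %||% rep(0, n_elements(mesh)),
    phi0 = phi0,
    phi = if (!is.null(phi_frozen)) rep_len(phi_frozen, n_elements(mesh)),
    phi_static = !is.null(phi_frozen), day = 0L,
    porosity = material$porosity, rho = material$rho, E = material$E,
    bone_class = material$bone_class, is_implant = material$is_implant,
    idx_bone = bone, idx_cor = idx_cor, idx_can = idx_can,
    hist_cor = hist_cor, hist_can = hist_can,
    q_r_cor = resorption_rate("cortical", params),
    q_r_can = resorption_rate("cancellous", params),
    q_f_cor = filling_rate(resorption_rate("cortical", params),
                           params$cortical["T_R"], params$cortical["T_F"]),
    q_f_can = filling_rate(resorption_rate("cancellous", params),
                           params$cancellous["T_R"], params$cancellous["T_F"])
  ), class = "remodel_state")
}

#' Advance the remodeling state by one day
#'
#' The daily loop: (1) on FE-update days, re-solve the load cases on the
#' current stiffness field and recompute the daily stimulus; (2) evaluate
#' the disuse sigmoid; (3) apply electrical modulation; (4) append
#' `fa_eff * Sr(P)` to the class history buffers; (5) evaluate the delayed
#' window integrals; (6) advance porosity by forward Euler with clamping;
#' (7) propagate density and modulus through the coupled material laws.
#'
#' @param state a `remodel_state` from [init_disuse_state()].
#' @return The advanced state (day counter incremented).
#' @export
step_day <- function(state) {
  p <- state$params
  day <- state$day + 1L
  if (!isTRUE(state$phi_static) &&
      (is.null(state$phi) || (day - 1L) %% p$fe_update_interval == 0)) {
    vm <- solve_load_cases(state$mesh, state$E, state$nu, state$load_cases)
    cycles <- vapply(state$load_cases, function(x) x$cycles, 0)
    state$phi <- daily_stimulus(vm, cycles, p$m)
  }
  b <- state$idx_bone
  fa <- disuse_activation_frequency(state$phi[b], state$phi0[b],
                                    p$kappa_d1, p$kappa_d2, p$fa_max)
  fa_eff <- es_modulated_activation(fa, state$phi_hat[b], day,
                                    state$protocol)
  act <- numeric(n_elements(state$mesh))
  act[b] <- fa_eff * specific_surface(state$porosity[b])

  clamp <- state$mapping$porosity_clamp
  if (length(state$idx_cor)) {
    state$hist_cor <- bmu_push(state$hist_cor, act[state$idx_cor])
    ct <- bmu_counts(state$hist_cor, p$dt_days)
    dp <- porosity_rate(ct$n_r, ct$n_f, state$q_r_cor, state$q_f_cor)
    state$porosity[state$idx_cor] <-
      pmin(pmax(state$porosity[state$idx_cor] + p$dt_days * dp,
                clamp[1]), clamp[2])
  }
  if (length(state$idx_can)) {
    state$hist_can <- bmu_push(state$hist_can, act[state$idx_can])
    ct <- bmu_counts(state$hist_can, p$dt_days)
    dp <- porosity_rate(ct$n_r, ct$n_f, state$q_r_can, state$q_f_can)
    state$porosity[state$idx_can] <-
      pmin(pmax(state$porosity[state$idx_can] + p$dt_days * dp,
                clamp[1]), clamp[2])
  }
  state$rho[b] <- porosity_to_density(state$porosity[b], state$mapping$rho_0)
  state$E[b] <- density_to_modulus(state$rho[b])
  if (any(!is.finite(state$E[b])) || any(state$E[b] <= 0)) {
    abort(sprintf("non-positive stiffness at day %d", day))
  }
  state$day <- day
  state
}

#' Run the day-stepping loop
#'
#' Steps the state forward `days` days, recording the daily mean density
#' per bone class (and per femoral zone when the mesh provides zones) and
#' per-element density snapshots at requested days.
#'
#' @param state a `remodel_state` (fresh or previously advanced; the run
#'   continues from `state$day`).
#' @param days number of days to simulate.
#' @param snapshot_days days (absolute) at which to store the full density
#'   field.
#' @return A list of class `remodel_sim`: `timeseries` (tibble: `day`,
#'   `mean_rho_cortical`, `mean_rho_cancellous`, `mean_rho_neck`, rates in
#'   g/(cm^3 day)), `snapshots` (named list of density vectors) and
#'   `state` (the final state).
#' @export
run_simulation <- function(state, days = state$params$total_days,
                           snapshot_days = integer()) {
  if (days < 0) abort("days must be >= 0")
  zone <- state$mesh$meta$zone
  neck <- if (!is.null(zone)) {
    intersect(which(zone == "neck"), state$idx_bone)
  } else integer()
  n <- days
  day_v <- integer(n); cor_v <- can_v <- neck_v <- numeric(n)
  snaps <- list()
  if (state$day %in% snapshot_days) {
    snaps[[as.character(state$day)]] <- state$rho
  }
  for (i in seq_len(n)) {
    state <- step_day(state)
    day_v[i] <- state$day
    cor_v[i] <- if (length(state$idx_cor)) mean(state$rho[state$idx_cor]) else NA_real_
    can_v[i] <- if (length(state$idx_can)) mean(state$rho[state$idx_can]) else NA_real_
    neck_v[i] <- if (length(neck)) mean(state$rho[neck]) else NA_real_
    if (state$day %in% snapshot_days) {
      snaps[[as.character(state$day)]] <- state$rho
    }
  }
  ts <- tibble(day = day_v, mean_rho_cortical = cor_v,
               mean_rho_cancellous = can_v, mean_rho_neck = neck_v)
  dt <- state$params$dt_days
  ts$rate_cortical <- c(NA_real_, diff(ts$mean_rho_cortical)) / dt
  ts$rate_cancellous <- c(NA_real_, diff(ts$mean_rho_cancellous)) / dt
  ts$rate_neck <- c(NA_real_, diff(ts$mean_rho_neck)) / dt
  structure(list(timeseries = ts, snapshots = snaps, state = state),
            class = "remodel_sim")
}

#' @export
print.remodel_sim <- function(x, ...) {
  cat(sprintf("<remodel_sim> %d day(s) recorded, final day %d\n",
              nrow(x$timeseries), x$state$day))
  invisible(x)
}

#' Prepare the inputs of a disuse-remodeling run
#'
#' Solves the intact model for all load cases, matches implanted bone
#' elements to intact elements by nearest centroid, evaluates the
#' element-wise equilibrium stimulus, builds the implanted material field
#' and (when a protocol is given) solves the electrostatic problem.
#'
#' @param implanted,intact [mesh_model()] fixtures. `intact = NULL` uses
#'   the implanted mesh as its own reference (then `Phi = Phi0` at day 1, a
#'   homeostatic run).
#' @param hu_implanted,hu_intact per-element HU fields (defaults:
#'   [synthetic_hu_field()] on each mesh).
#' @param mapping a [material_mapping()].
#' @param load_cases list of [load_case()] objects.
#' @param params a [remodeling_params()].
#' @param protocol optional [stimulation_protocol()].
#' @param dielectric a [dielectric_params()].
#' @param nu Poisson's ratio.
#' @return A list with `material`, `material_intact`, `phi0`,
#'   `sigma_intact` (intact von Mises per case, mapped to implanted
#'   elements), `matching` (tibble), `potential` (or `NULL`) and the
#'   echoed inputs.
#' @export
prepare_disuse_inputs <- function(implanted, intact = NULL,
                                  hu_implanted = NULL, hu_intact = NULL,
                                  mapping = material_mapping(),
                                  load_cases = default_load_cases(),
                                  params = remodeling_params(),
                                  protocol = NULL,
                                  dielectric = dielectric_params(),
                                  nu = 0.3) {
  self_ref <- is.null(intact)
  if (self_ref) {
    intact <- implanted
    hu_intact <- hu_implanted
  }
  hu_implanted <- hu_implanted %||% synthetic_hu_field(implanted)
  hu_intact <- hu_intact %||% synthetic_hu_field(intact)
  material <- build_material_field(implanted, hu_implanted, mapping)
  material_intact <- build_material_field(intact, hu_intact, mapping)

  vm_intact <- solve_load_cases(intact, material_intact$E, nu, load_cases)
  matching <- if (self_ref) {
    tibble(element_id = seq_len(n_elements(implanted)),
           ref_id = seq_len(n_elements(implanted)), distance = 0)
  } else {
    match_elements(implanted, intact)
  }
  bone <- which(!material$is_implant)
  ref <- matching$ref_id[match(bone, matching$element_id)]
  if (any(is.na(ref))) {
    abort(sprintf("%d bone element(s) have no intact counterpart",
                  sum(is.na(ref))))
  }
  cycles <- vapply(load_cases, function(x) x$cycles, 0)
  phi0 <- rep(NA_real_, n_elements(implanted))
  phi0[bone] <- equilibrium_stimulus(vm_intact[ref, , drop = FALSE],
                                     cycles, params$m, params$phi0_floor)
  potential <- NULL
  if (!is.null(protocol)) {
    potential <- solve_electrostatics(implanted, dielectric, protocol)
  }
  list(material = material, material_intact = material_intact,
       phi0 = phi0, sigma_intact = vm_intact[ref, , drop = FALSE],
       matching = matching, potential = potential,
       implanted = implanted, intact = intact, mapping = mapping,
       load_cases = load_cases, params = params, protocol = protocol,
       nu = nu)
}

#' Simulate disuse remodeling end to end
#'
#' Convenience wrapper: [prepare_disuse_inputs()], [init_disuse_state()]
#' and [run_simulation()] in one call.
#'
#' @inheritParams prepare_disuse_inputs
#' @param days run length in days (default `params$total_days`).
#' @param snapshot_days days at which to store density snapshots.
#' @return A `remodel_sim` (see [run_simulation()]); the prepared inputs
#'   are attached as `sim$inputs`.
#' @export
simulate_remodeling <- function(implanted, intact = NULL,
                                hu_implanted = NULL, hu_intact = NULL,
                                mapping = material_mapping(),
                                load_cases = default_load_cases(),
                                params = remodeling_params(),
                                protocol = NULL,
                                dielectric = dielectric_params(),
                                nu = 0.3, days = params$total_days,
                                snapshot_days = integer()) {
  inp <- prepare_disuse_inputs(implanted, intact, hu_implanted, hu_intact,
                               mapping, load_cases, params, protocol,
                               dielectric, nu)
  state <- init_disuse_state(inp$implanted, inp$material, inp$phi0,
                             inp$load_cases, inp$params, inp$mapping,
                             inp$protocol,
                             phi_hat = if (!is.null(inp$potential))
                               inp$potential$phi_hat,
                             nu = inp$nu)
  sim <- run_simulation(state, days, snapshot_days)
  sim$inputs <- inp
  sim
}

#' Run a grid of stimulation scenarios
#'
#' Executes several stimulation protocols (amplitudes and window
#' durations) on the same geometry and loads. The pre-stimulation prefix
#' (days before the earliest `start_day`) is simulated once and shared, so
#' all scenarios branch from an identical state.
#'
#' @inheritParams prepare_disuse_inputs
#' @param scenarios a data frame with columns `amplitude` and
#'   `duration_days` (and optionally `start_day`, `voltage_V`); one run per
#'   row.
#' @param days total run length in days.
#' @param snapshot_days days at which to store density snapshots.
#' @return A list of class `scenario_grid`: `sims` (one `remodel_sim` per
#'   row, named `A<amplitude>_d<duration>`), `scenarios` (the input tibble
#'   with final mean densities appended) and `inputs`.
#' @export
run_scenario_grid <- function(implanted, intact = NULL,
                              hu_implanted = NULL, hu_intact = NULL,
                              mapping = material_mapping(),
                              load_cases = default_load_cases(),
                              params = remodeling_params(),
                              scenarios = tibble(amplitude = c(0, 0.3, 0.5, 0.7),
                                                 duration_days = 100),
                              dielectric = dielectric_params(),
                              nu = 0.3, days = params$total_days,
                              snapshot_days = integer()) {
  scenarios <- as_tibble(scenarios)
  if (!all(c("amplitude", "duration_days") %in% names(scenarios))) {
    abort("scenarios needs columns amplitude and duration_days")
  }
  if (!"start_day" %in% names(scenarios)) scenarios$start_day <- 101
  if (!"voltage_V" %in% names(scenarios)) scenarios$voltage_V <- 32
  inp <- prepare_disuse_inputs(implanted, intact, hu_implanted, hu_intact,
                               mapping, load_cases, params,
                               protocol = stimulation_protocol(
                                 voltage_V = scenarios$voltage_V[1]),
                               dielectric = dielectric, nu = nu)
  state0 <- init_disuse_state(inp$implanted, inp$material, inp$phi0,
                              inp$load_cases, inp$params, inp$mapping,
                              protocol = NULL,
                              phi_hat = inp$potential$phi_hat, nu = inp$nu)
  prefix_days <- min(scenarios$start_day) - 1L
  prefix_days <- max(min(prefix_days, days), 0L)
  pre <- run_simulation(state0, prefix_days, snapshot_days)
  sims <- vector("list", nrow(scenarios))
  names(sims) <- sprintf("A%g_d%g", scenarios$amplitude,
                         scenarios$duration_days)
  for (i in seq_len(nrow(scenarios))) {
    st <- pre$state
    st$protocol <- stimulation_protocol(
      voltage_V = scenarios$voltage_V[i],
      amplitude = scenarios$amplitude[i],
      start_day = scenarios$start_day[i],
      duration_days = scenarios$duration_days[i])
    tail_sim <- run_simulation(st, days - prefix_days, snapshot_days)
    ts <- dplyr::bind_rows(pre$timeseries, tail_sim$timeseries)
    dt <- params$dt_days
    ts$rate_cortical <- c(NA_real_, diff(ts$mean_rho_cortical)) / dt
    ts$rate_cancellous <- c(NA_real_, diff(ts$mean_rho_cancellous)) / dt
    ts$rate_neck <- c(NA_real_, diff(ts$mean_rho_neck)) / dt
    sims[[i]] <- structure(list(
      timeseries = ts,
      snapshots = c(pre$snapshots, tail_sim$snapshots),
      state = tail_sim$state), class = "remodel_sim")
  }
  scenarios$final_rho_neck <- vapply(sims, function(s) {
    tail(s$timeseries$mean_rho_neck, 1)
  }, 0)
  scenarios$final_rho_cortical <- vapply(sims, function(s) {
    tail(s$timeseries$mean_rho_cortical, 1)
  }, 0)
  scenarios$final_rho_cancellous <- vapply(sims, function(s) {
    tail(s$timeseries$mean_rho_cancellous, 1)
  }, 0)
  structure(list(sims = sims, scenarios = scenarios, inputs = inp),
            class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat(sprintf("<scenario_grid> %d scenario(s)\n", nrow(x$scenarios)))
  print(x$scenarios)
  invisible(x)
}
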