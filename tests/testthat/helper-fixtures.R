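# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_femur_pair <- function(target = 4000) {
  cached(paste0("femur_pair_", target), {
    fx <- femur_fixture_params(target_element_count = target)
    intact <- generate_proximal_femur(fx)
    fx$implanted <- TRUE
    implanted <- generate_proximal_femur(do.call(femur_fixture_params, fx))
    list(intact = intact, implanted = implanted)
  })
}

small_pair_solves <- function(target = 4000) {
  cached(paste0("pair_solves_", target), {
    pair <- small_femur_pair(target)
    mat_i <- build_material_field(pair$intact,
                                  synthetic_hu_field(pair$intact))
    mat_p <- build_material_field(pair$implanted,
                                  synthetic_hu_field(pair$implanted))
    vm_i <- solve_load_cases(pair$intact, mat_i$E, 0.3, default_load_cases())
    vm_p <- solve_load_cases(pair$implanted, mat_p$E, 0.3,
                             default_load_cases())
    list(pair = pair, mat_i = mat_i, mat_p = mat_p, vm_i = vm_i, vm_p = vm_p,
         matching = match_elements(pair$implanted, pair$intact))
  })
}

# Brute-force oracle for the delayed BMU window integrals: the full daily
# history (oldest first) is summed over explicit index windows.
brute_force_counts <- function(full_history, t_r, t_i, t_f, dt = 1) {
  n <- length(full_history)
  n_r <- sum(full_history[(n - t_r + 1):n]) * dt
  lo <- n - (t_r + t_i + t_f) + 1
  hi <- n - (t_r + t_i)
  n_f <- sum(full_history[lo:hi]) * dt
  list(n_r = n_r, n_f = n_f)
}

# Minimal single-element "mesh + state" harness for kinetics tests: a tiny
# block whose elements are all one bone class, driven by a frozen stimulus.
frozen_state <- function(phi_ratio, class = "cortical", params = NULL,
                         porosity = 0.05, amplitude = 0, phi_hat = 1,
                         start_day = 101, duration_days = Inf) {
  mesh <- cached("unit_block", generate_block_fixture(1, 1, 1, c(2, 2, 2)))
  n <- n_elements(mesh)
  params <- params %||% remodeling_params(fe_update_interval = 1e6)
  mapping <- material_mapping()
  rho <- porosity_to_density(porosity, mapping$rho_0)
  material <- tibble::tibble(
    element_id = seq_len(n), hu = NA_real_, rho = rho, porosity = porosity,
    E = density_to_modulus(rho), bone_class = class,
    is_implant = FALSE)
  protocol <- if (amplitude > 0) {
    stimulation_protocol(amplitude = amplitude, start_day = start_day,
                         duration_days = duration_days)
  }
  init_disuse_state(mesh, material, phi0 = rep(1, n),
                    load_cases = default_load_cases(), params = params,
                    mapping = mapping, protocol = protocol,
                    phi_hat = rep(phi_hat, n), phi_frozen = phi_ratio)
}
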