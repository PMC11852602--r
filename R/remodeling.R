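#' Disuse-remodeling parameters
#'
#' All rate constants of the BMU population-kinetics model. Stage durations
#' differ between cortical bone (resorption/reversal/filling 24/8/64 days)
#' and cancellous bone (60/57/197 days). The BMU advances `v` mm/day;
#' `d_bmu`, `d_e` and `d_o` are its geometric parameters (cancellous groove
#' width/depth and cortical osteon diameter). The disuse sigmoid is
#' `fa = fa_max / (1 + exp((Phi/Phi0 - kappa_d1)/kappa_d2))`.
#'
#' @param m stimulus exponent of the daily power-mean (default 4).
#' @param kappa_d1,kappa_d2 sigmoid shape factors (0.5, 0.1).
#' @param fa_max maximum disuse activation frequency, BMUs/(mm^3 day).
#' @param cortical,cancellous named numeric vectors `c(T_R=, T_I=, T_F=)`
#'   of BMU stage durations in days.
#' @param v BMU advance rate, mm/day.
#' @param d_bmu,d_e,d_o BMU geometry, mm.
#' @param dt_days time step (days).
#' @param total_days default run length.
#' @param fe_update_interval days between finite-element stress updates.
#' @param phi0_floor lower bound applied to the equilibrium stimulus (MPa).
#' @return A list of class `remodeling_params`.
#' @export
remodeling_params <- function(m = 4, kappa_d1 = 0.5, kappa_d2 = 0.1,
                              fa_max = 0.1,
                              cortical = c(T_R = 24, T_I = 8, T_F = 64),
                              cancellous = c(T_R = 60, T_I = 57, T_F = 197),
                              v = 0.01, d_bmu = 0.65, d_e = 0.05, d_o = 0.2,
                              dt_days = 1, total_days = 300,
                              fe_update_interval = 1,
                              phi0_floor = 1e-6) {
  vals <- c(m, kappa_d1, kappa_d2, fa_max, cortical, cancellous, v,
            d_bmu, d_e, d_o, dt_days, fe_update_interval)
  if (any(vals <= 0)) abort("all remodeling parameters must be positive")
  for (cl in list(cortical, cancellous)) {
    if (!all(c("T_R", "T_I", "T_F") %in% names(cl))) {
      abort("stage durations need names T_R, T_I, T_F")
    }
  }
  structure(list(m = m, kappa_d1 = kappa_d1, kappa_d2 = kappa_d2,
                 fa_max = fa_max, cortical = cortical,
                 cancellous = cancellous, v = v, d_bmu = d_bmu,
                 d_e = d_e, d_o = d_o, dt_days = dt_days,
                 total_days = total_days,
                 fe_update_interval = fe_update_interval,
                 phi0_floor = phi0_floor),
            class = "remodeling_params")
}

#' Daily mechanical stimulus
#'
#' Cycle-weighted power mean of the equivalent stresses over the day's load
#' cases: `Phi = (sum_j n_j * sigma_j^m)^(1/m)` (MPa).
#'
#' @param sigma_bar numeric matrix (elements x cases) or vector (one
#'   element) of von Mises stresses, MPa.
#' @param cycles per-case daily cycle counts `n_j`.
#' @param m stimulus exponent.
#' @return per-element stimulus Phi (MPa).
#' @export
daily_stimulus <- function(sigma_bar, cycles, m = 4) {
  if (is.vector(sigma_bar)) sigma_bar <- matrix(sigma_bar, nrow = 1L)
  if (ncol(sigma_bar) != length(cycles)) {
    abort("one cycle count per load case required")
  }
  if (any(sigma_bar < 0)) abort("equivalent stresses must be non-negative")
  if (m <= 0) abort("m must be positive")
  drop((sigma_bar^m %*% cycles)^(1 / m))
}

#' Equilibrium (pre-operative) stimulus
#'
#' The daily stimulus of the intact femur with the printed cycle counts
#' 6000/2000/2000, evaluated element-wise and floored away from zero so
#' the stimulus ratio stays defined in unloaded regions.
#'
#' @param sigma_bar_intact matrix (elements x 3) of intact-model von Mises
#'   stresses per load case.
#' @param cycles cycle counts (default `c(6000, 2000, 2000)`).
#' @param m stimulus exponent.
#' @param floor lower bound (MPa).
#' @return per-element equilibrium stimulus Phi0 (MPa).
#' @export
equilibrium_stimulus <- function(sigma_bar_intact,
                                 cycles = c(6000, 2000, 2000), m = 4,
                                 floor = 1e-6) {
  pmax(daily_stimulus(sigma_bar_intact, cycles, m), floor)
}

#' Disuse activation frequency
#'
#' Sigmoid in the stimulus ratio: full activation (`fa -> fa_max`) under
#' total disuse, vanishing activation under habitual loading. Strictly
#' decreasing in `Phi`; exponent overflow saturates to the limits.
#'
#' @param phi daily stimulus (MPa).
#' @param phi0 equilibrium stimulus (MPa, > 0).
#' @param kappa_d1,kappa_d2 sigmoid shape factors.
#' @param fa_max maximum activation frequency.
#' @return activation frequency in `(0, fa_max)`.
#' @export
disuse_activation_frequency <- function(phi, phi0, kappa_d1 = 0.5,
                                        kappa_d2 = 0.1, fa_max = 0.1) {
  if (any(phi0 <= 0)) abort("phi0 must be positive")
  x <- (phi / phi0 - kappa_d1) / kappa_d2
  fa_max / (1 + exp(pmin(x, 700)))
}

#' Specific surface of bone
#'
#' Internal surface area per unit volume (mm^2/mm^3) as a quintic in
#' porosity: `32.1 p - 93.9 p^2 + 134 p^3 - 101 p^4 + 28.8 p^5`; zero at
#' both a solid (`p = 0`) and a fully porous (`p = 1`) element.
#'
#' @param p_t porosity in `[0, 1]`.
#' @return specific surface (mm^2/mm^3).
#' @export
specific_surface <- function(p_t) {
  if (any(p_t < 0 | p_t > 1, na.rm = TRUE)) {
    abort("porosity must lie in [0, 1]")
  }
  pmax(p_t * (32.1 + p_t * (-93.9 + p_t * (134 + p_t * (-101 + p_t * 28.8)))), 0)
}

#' BMU resorption and filling rates
#'
#' Cortical BMUs resorb a cylindrical tunnel
#' (`Q_R = pi * d_o^2 * v / 4`); cancellous BMUs resorb a semi-elliptic
#' surface groove (`Q_R = pi * d_e * d_bmu * v / 4`), both in mm^3/day.
#' The filling rate is closed by the equilibrium balance
#' `Q_F = Q_R * T_R / T_F`, so a constant history yields exactly zero net
#' porosity change.
#'
#' @param bone_class `"cortical"` or `"cancellous"` (vectorized).
#' @param params a [remodeling_params()].
#' @return `resorption_rate()`: Q_R per element (mm^3/day);
#'   `filling_rate()`: Q_F (mm^3/day).
#' @export
resorption_rate <- function(bone_class, params = remodeling_params()) {
  q_can <- pi * params$d_e * params$d_bmu * params$v / 4
  q_cor <- pi * params$d_o^2 * params$v / 4
  ifelse(bone_class == "cortical", q_cor, q_can)
}

#' @rdname resorption_rate
#' @param q_r resorption rate (mm^3/day).
#' @param t_r,t_f resorption / filling stage durations (days).
#' @export
filling_rate <- function(q_r, t_r, t_f) {
  if (any(t_f <= 0)) abort("T_F must be positive")
  q_r * t_r / t_f
}

#' Net porosity rate from BMU populations
#'
#' `dP/dt = Q_R * N_R - Q_F * N_F` (1/day); positive means net resorption
#' (bone loss).
#'
#' @param n_r,n_f BMU densities in resorption / filling (BMUs/mm^3).
#' @param q_r,q_f per-BMU resorption / filling rates (mm^3/day).
#' @return porosity rate (1/day).
#' @export
porosity_rate <- function(n_r, n_f, q_r, q_f) {
  q_r * n_r - q_f * n_f
}

#' Electrically modulated activation frequency
#'
#' Inside the stimulation window the disuse activation frequency is
#' suppressed in proportion to the local normalized potential:
#' `fa_eff = fa * (1 - A * phi_hat)`; outside the window `fa_eff = fa`.
#'
#' @param fa disuse activation frequency.
#' @param phi_hat normalized potential in `[0, 1]`.
#' @param day current simulation day.
#' @param protocol a [stimulation_protocol()] (or `NULL` for no
#'   stimulation).
#' @return effective activation frequency in `[0, fa]`.
#' @export
es_modulated_activation <- function(fa, phi_hat, day, protocol = NULL) {
  if (!in_stimulation_window(day, protocol)) return(fa)
  fa * (1 - protocol$amplitude * phi_hat)
}

# ---- delayed-integral ring buffer ------------------------------------------

#' BMU history ring buffer
#'
#' Holds, per element, the last `T_R + T_I + T_F` daily values of
#' `fa * Sr` (BMU activation density per day). `bmu_counts()` evaluates
#' the two delayed window integrals: `N_R` sums the newest `T_R` entries
#' (BMUs currently resorbing) and `N_F` the oldest `T_F` entries (BMUs
#' that reached the filling stage), each times the daily step. Entries
#' before day 1 hold the equilibrium pre-fill value.
#'
#' @param prefill per-element pre-fill value (equilibrium `fa0 * Sr`).
#' @param t_r,t_i,t_f stage durations (days).
#' @return A list of class `bmu_history` (`mat`, `cursor`, stage lengths).
#' @export
bmu_history <- function(prefill, t_r, t_i, t_f) {
  len <- as.integer(t_r + t_i + t_f)
  structure(list(mat = matrix(prefill, nrow = length(prefill), ncol = len),
                 cursor = len, t_r = as.integer(t_r), t_i = as.integer(t_i),
                 t_f = as.integer(t_f)),
            class = "bmu_history")
}

#' @rdname bmu_history
#' @param history a `bmu_history`.
#' @param values per-element daily values of `fa_eff * Sr` to append.
#' @export
bmu_push <- function(history, values) {
  len <- ncol(history$mat)
  history$cursor <- history$cursor %% len + 1L
  history$mat[, history$cursor] <- values
  history
}

ring_columns <- function(cursor, len, ages) {
  ((cursor - ages - 1L) %% len) + 1L
}

#' @rdname bmu_history
#' @param dt daily step (days).
#' @return `bmu_counts()` returns a list with per-element `n_r` and `n_f`
#'   (BMUs/mm^3).
#' @export
bmu_counts <- function(history, dt = 1) {
  len <- ncol(history$mat)
  # columns ordered oldest-to-newest so the summation order matches a
  # chronological windowed sum bit for bit
  cols_r <- ring_columns(history$cursor, len, (history$t_r - 1L):0)
  ages_f <- (len - 1L):(history$t_r + history$t_i)
  cols_f <- ring_columns(history$cursor, len, ages_f)
  list(n_r = rowSums(history$mat[, cols_r, drop = FALSE]) * dt,
       n_f = rowSums(history$mat[, cols_f, drop = FALSE]) * dt)
}
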