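# Deterministic MD-system bookkeeping: KCl ion counts at a target
# molarity with neutralization, leaflet lipid composition at a stated
# ratio, and snapshot scheduling.

# Round half away from zero (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

#' Ion counts for a salted, neutralized water box
#'
#' Base ion pairs are `n = round(molarity * n_water / water_molarity)`
#' (round half up; `water_molarity` defaults to 55.5 mol/L). A solute net
#' charge of `+z` is neutralized by removing `z` cations (adding `z`
#' anions-worth of imbalance for negative charges, symmetrically), so the
#' final counts always satisfy
#' `n_cation - n_anion + solute_net_charge = 0`.
#'
#' @param n_water Number of water molecules (>= 0).
#' @param molarity Target salt concentration (mol/L, >= 0).
#' @param solute_net_charge Signed integer net charge of the solute (e).
#' @param water_molarity Molar concentration of pure water (mol/L).
#' @return Named integer vector `c(n_cation, n_anion)`.
#' @export
#' @examples
#' ion_counts(16000, 0.15, solute_net_charge = 4) # 39 cations, 43 anions
ion_counts <- function(n_water, molarity, solute_net_charge = 0,
                       water_molarity = 55.5) {
  if (n_water < 0 || molarity < 0) {
    stop("`n_water` and `molarity` must be >= 0", call. = FALSE)
  }
  n <- round_half_up(molarity * n_water / water_molarity)
  z <- as.integer(solute_net_charge)
  n_cation <- n - max(z, 0L)
  n_anion <- n + min(z, 0L)
  if (n_cation < 0 || n_anion < 0) {
    stop("neutralization demand (", z, ") exceeds base ion pairs (", n,
         "); use a larger water box", call. = FALSE)
  }
  c(n_cation = as.integer(n_cation), n_anion = as.integer(n_anion))
}

#' Leaflet lipid composition at a stated primary:sterol ratio
#'
#' @param n_primary Number of primary (phospholipid) molecules per
#'   leaflet (>= 0).
#' @param ratio Positive integer pair `(primary, sterol)`; sterol count is
#'   `round(n_primary * ratio[2] / ratio[1])` (round half up).
#' @return Named integer vector `c(n_primary, n_sterol)`.
#' @export
#' @examples
#' leaflet_composition(110, c(10, 1)) # 11 sterols
leaflet_composition <- function(n_primary, ratio = c(10, 1)) {
  if (n_primary < 0) stop("`n_primary` must be >= 0", call. = FALSE)
  if (length(ratio) != 2 || ratio[1] <= 0 || ratio[2] < 0) {
    stop("`ratio` must be (primary, sterol) with primary > 0", call. = FALSE)
  }
  n_sterol <- round_half_up(n_primary * ratio[2] / ratio[1])
  c(n_primary = as.integer(n_primary), n_sterol = as.integer(n_sterol))
}

#' Snapshot schedule over a trajectory window
#'
#' Times are taken on the half-open window `(start, end]` at the given
#' spacing, so a 10 ns window sampled every 50 ps yields exactly 200
#' snapshots. A window length that is not an integer multiple of the
#' interval triggers a warning and the count is floored.
#'
#' @param window_start,window_end Window bounds (ns), `end > start`.
#' @param interval_ps Snapshot spacing (ps), > 0.
#' @return List with `n_snapshots` and `times_ns` (snapshot times, ns).
#' @export
#' @examples
#' snapshot_schedule(140, 150, 50)$n_snapshots # 200
snapshot_schedule <- function(window_start, window_end, interval_ps) {
  if (window_end <= window_start) {
    stop("`window_end` must exceed `window_start`", call. = FALSE)
  }
  if (interval_ps <= 0) stop("`interval_ps` must be positive", call. = FALSE)
  window_ps <- (window_end - window_start) * 1000
  n_exact <- window_ps / interval_ps
  n <- floor(n_exact + 1e-9)
  if (abs(n_exact - round(n_exact)) > 1e-9) {
    warning("window length (", window_ps, " ps) is not a multiple of the ",
            "interval (", interval_ps, " ps); flooring to ", n, " snapshots")
  } else {
    n <- round(n_exact)
  }
  times <- window_start + seq_len(n) * interval_ps / 1000
  list(n_snapshots = as.integer(n), times_ns = times)
}
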