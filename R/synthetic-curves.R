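# Synthetic dose-response and binding-trace series.

#' Simulate a DARTS dose-response (stabilization) series
#'
#' Protection signal follows a 4PL curve in dose with additive Gaussian
#' noise; emulates a densitometric/coverage readout of drug-dependent
#' protease resistance.
#'
#' @param target A [target_spec()] supplying `ec50` and `hill`.
#' @param doses Sorted positive dose vector (uM).
#' @param noise_sd Gaussian noise SD on the signal scale (fraction of the
#'   top-bottom span when `bottom = 0`, `top = 1`).
#' @param seed Integer seed.
#' @param bottom,top Signal asymptotes.
#' @return Data frame with columns `dose` and `signal`.
#' @export
#' @examples
#' tgt <- target_spec("P0001", c(1, 10), ec50 = 280, hill = 1)
#' simulate_dose_series(tgt, doses = 10 * sqrt(10)^(0:6), noise_sd = 0)
simulate_dose_series <- function(target, doses, noise_sd = 0.03, seed = 1L,
                                 bottom = 0, top = 1) {
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  if (is.unsorted(doses)) stop("doses must be sorted increasing",
                               call. = FALSE)
  mu <- fourpl(doses, bottom, top, target$ec50, target$hill)
  eps <- if (noise_sd > 0) {
    with_substream(substream_seed(seed, "dose_series"),
                   stats::rnorm(length(doses), sd = noise_sd))
  } else rep(0, length(doses))
  data.frame(dose = doses, signal = mu + eps)
}

#' Simulate a binding (saturation) trace
#'
#' Fraction bound from the exact 1:1 quadratic isotherm plus Gaussian
#' noise; emulates a normalized microscale-thermophoresis saturation
#' readout.
#'
#' @param kd Dissociation constant (uM), > 0.
#' @param protein_conc Total protein concentration (uM), > 0.
#' @param ligand_series Total ligand concentrations (uM, >= 0).
#' @param noise_sd Gaussian noise SD on the fraction-bound scale.
#' @param seed Integer seed.
#' @return Data frame with columns `ligand` and `fraction_bound`.
#' @export
#' @examples
#' simulate_binding_trace(204, 0.05, c(0, 50, 204, 1000), noise_sd = 0)
simulate_binding_trace <- function(kd, protein_conc, ligand_series,
                                   noise_sd = 0.02, seed = 1L) {
  if (kd <= 0) stop("`kd` must be positive", call. = FALSE)
  if (protein_conc <= 0) stop("`protein_conc` must be positive",
                              call. = FALSE)
  if (any(ligand_series < 0)) stop("ligand concentrations must be >= 0",
                                   call. = FALSE)
  mu <- isotherm_fraction_bound(ligand_series, protein_conc, kd)
  eps <- if (noise_sd > 0) {
    with_substream(substream_seed(seed, "binding_trace"),
                   stats::rnorm(length(ligand_series), sd = noise_sd))
  } else rep(0, length(ligand_series))
  data.frame(ligand = ligand_series, fraction_bound = mu + eps)
}

#' Packaged demo configurations for the binding experiments
#'
#' `mst_demo_config()` is the packaged synthetic MST scenario: generator
#' truth Kd 204 uM, protein 0.05 uM, a 12-point half-log ligand series
#' centred near Kd, noise SD 0.02. `darts_dose_demo_config()` is the
#' packaged DARTS dose-series scenario: EC50 truth 280 uM, Hill 1, seven
#' half-log doses spanning 10-10000 uM, noise SD 0.03.
#'
#' @return A named list of generator arguments.
#' @export
mst_demo_config <- function() {
  list(kd = 204, protein_conc = 0.05,
       ligand_series = 2 * sqrt(10)^(0:11), noise_sd = 0.02)
}

#' @rdname mst_demo_config
#' @export
darts_dose_demo_config <- function() {
  list(ec50 = 280, hill = 1, doses = 10 * sqrt(10)^(0:6),
       noise_sd = 0.03, bottom = 0, top = 1)
}
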