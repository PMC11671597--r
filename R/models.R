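# Shared model functions: the four-parameter logistic and the exact 1:1
# binding isotherm. Both the synthetic generators and the fitters evaluate
# these, so a noiseless generated series is reproduced exactly by the model.

#' Four-parameter logistic (4PL) dose-response curve
#'
#' `y = bottom + (top - bottom) / (1 + (ec50/x)^hill)`; increasing in `x`
#' for `hill > 0`, with `y(ec50) = (top + bottom)/2`.
#'
#' @param dose Dose vector (> 0; `Inf` allowed and returns `top`).
#' @param bottom,top Lower/upper asymptotes (signal units).
#' @param ec50 Half-maximal dose (same units as `dose`), > 0.
#' @param hill Hill slope, > 0.
#' @return Signal vector.
#' @export
fourpl <- function(dose, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / dose)^hill)
}

#' Exact 1:1 binding isotherm (quadratic mass-balance solution)
#'
#' Fraction of protein bound at total protein `P`, total ligand `L` and
#' dissociation constant `Kd`:
#' `f = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / (2 P)`.
#' In the dilute limit `P -> 0` this reduces to `L / (L + Kd)`.
#'
#' @param ligand Total ligand concentration vector (uM, >= 0).
#' @param protein_conc Total protein concentration (uM, > 0).
#' @param kd Dissociation constant (uM, > 0).
#' @return Fraction bound in `[0, 1]`.
#' @export
isotherm_fraction_bound <- function(ligand, protein_conc, kd) {
  if (kd <= 0) stop("`kd` must be positive", call. = FALSE)
  if (protein_conc <= 0) stop("`protein_conc` must be positive",
                              call. = FALSE)
  s <- protein_conc + ligand + kd
  disc <- pmax(s^2 - 4 * protein_conc * ligand, 0)
  (s - sqrt(disc)) / (2 * protein_conc)
}
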