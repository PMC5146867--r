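#' Contrast agent specification
#'
#' Describes a SPION-based contrast agent by its relaxivities and its
#' oligonucleotide conjugation chemistry. The default values describe a
#' dextran-coated iron oxide (Molday-Ion-like) particle carrying
#' NeutrAvidin-linked biotinylated sODN probes: longitudinal relaxivity
#' r1 = 15.4 and transverse relaxivity r2 = 33.9 s^-1 mM^-1, with
#' 3 nmol sODN conjugated per mg Fe.
#'
#' @param name Agent label.
#' @param r1 Longitudinal relaxivity, s^-1 mM^-1.
#' @param r2 Transverse relaxivity, s^-1 mM^-1. Bound iron at concentration
#'   `c` mM elevates R2* by `r2 * c` s^-1.
#' @param fe_mass_per_np Grams of iron per nanoparticle.
#' @param sodn_per_mg_fe Conjugation ratio, nmol sODN per mg Fe.
#' @return An object of class `contrast_agent`.
#' @examples
#' ag <- contrast_agent()
#' ag$r2   # 33.9
#' @export
contrast_agent <- function(name = "SPION-sODN",
                           r1 = 15.4,
                           r2 = 33.9,
                           fe_mass_per_np = 5.6e-19,
                           sodn_per_mg_fe = 3) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(is.numeric(r2) && r2 > 0)) stop("r2 must be positive")
  if (!(is.numeric(r1) && r1 >= 0)) stop("r1 must be non-negative")
  if (r2 < r1) stop("transverse relaxivity r2 must be >= r1")
  if (!(fe_mass_per_np > 0)) stop("fe_mass_per_np must be positive")
  if (!(sodn_per_mg_fe > 0)) stop("sodn_per_mg_fe must be positive")
  structure(
    list(name = name, r1 = r1, r2 = r2,
         fe_mass_per_np = fe_mass_per_np,
         sodn_per_mg_fe = sodn_per_mg_fe),
    class = "contrast_agent"
  )
}

#' sODN dose implied by an iron dose
#'
#' The probe is conjugated at a fixed ratio of sODN to iron, so an iron
#' dose fixes the oligonucleotide dose: 4 mg Fe/kg at 3 nmol/mg gives
#' 12 nmol sODN per kg.
#'
#' @param fe_dose_mg_per_kg Iron dose, mg Fe per kg body weight.
#' @param agent A [contrast_agent()].
#' @return Dose in nmol sODN per kg.
#' @export
sodn_dose <- function(fe_dose_mg_per_kg, agent = contrast_agent()) {
  stopifnot(is.numeric(fe_dose_mg_per_kg), fe_dose_mg_per_kg >= 0)
  fe_dose_mg_per_kg * agent$sodn_per_mg_fe
}

#' Iron atoms per nanoparticle
#'
#' Converts the per-particle iron mass to a number of Fe atoms
#' (5.6e-19 g per particle is about 6000 atoms).
#'
#' @param agent A [contrast_agent()].
#' @param fe_atomic_mass Atomic mass of iron, g/mol.
#' @return Number of iron atoms (not rounded).
#' @export
fe_atoms_per_np <- function(agent = contrast_agent(),
                            fe_atomic_mass = 55.845) {
  avogadro <- 6.02214076e23
  agent$fe_mass_per_np / (fe_atomic_mass / avogadro)
}
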