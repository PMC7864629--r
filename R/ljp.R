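#' Relative ionic mobility table
#'
#' Limiting ionic mobilities relative to K+ used by [compute_ljp()]. Values
#' are diffusion-coefficient-like relative mobilities u_i =
#' lambda_i / (z_i^2 * lambda_K) with lambda the limiting molar conductivity
#' and lambda_K = 73.5 S cm^2/mol, the normalisation conventional in
#' patch-clamp junction-potential calculators. Sources: standard limiting
#' conductivities for the inorganic ions (e.g. Na+ 50.1, Cl- 76.35, HCO3-
#' 44.5, Ca2+ 119, Mg2+ 106, SO4(2-) 160, H2PO4- 33 S cm^2/mol);
#' methylsulfate 48.8 S cm^2/mol; HEPES anion ~22 S cm^2/mol. The mobilities
#' of the large organic phosphates (phosphocreatine, ATP, GTP) are not well
#' tabulated; the shipped values (0.25) are estimates for slow polyvalent
#' organic anions and are documented as such.
#'
#' @return A data.frame with columns `species`, `charge`, `mobility`.
#' @export
mobility_table <- function() {
  data.frame(
    species = c("K", "Na", "Li", "Cs", "Ca", "Mg", "Cl", "Br", "F",
                "HCO3", "H2PO4", "HPO4", "SO4", "MeSO4", "gluconate",
                "acetate", "HEPES", "glutamate", "PCr", "ATP", "GTP"),
    charge = c(1, 1, 1, 1, 2, 2, -1, -1, -1,
               -1, -1, -2, -2, -1, -1,
               -1, -1, -1, -2, -2, -3),
    mobility = c(1.000, 0.682, 0.525, 1.050, 0.4048, 0.361, 1.0388, 1.0651,
                 0.7533, 0.605, 0.449, 0.388, 0.544, 0.663, 0.330,
                 0.556, 0.300, 0.380, 0.250, 0.250, 0.250),
    stringsAsFactors = FALSE)
}

#' Construct a solution composition for junction-potential calculation
#'
#' Describes the free-ion composition of one solution. Mobilities are looked
#' up in [mobility_table()] unless supplied; a charged species without a
#' known mobility is an error naming the species.
#'
#' @param species Character vector of species names.
#' @param conc_mm Numeric vector of free-ion concentrations (mM).
#' @param charge Integer vector of signed valences. Looked up from the
#'   mobility table when `NULL`.
#' @param mobility Numeric vector of relative mobilities (K+ = 1). Looked up
#'   when `NULL`.
#' @param temperature_k Temperature in kelvin (default 306.65 K = 33.5 C,
#'   the midpoint of a 32-35 C recording bath).
#' @param charge_tol Electroneutrality tolerance in mM of charge; the summed
#'   charge concentration must not exceed it.
#' @return An object of class `solution_composition`.
#' @export
solution_composition <- function(species, conc_mm, charge = NULL,
                                 mobility = NULL, temperature_k = 306.65,
                                 charge_tol = 1) {
  tab <- mobility_table()
  species <- as.character(species)
  if (any(conc_mm < 0)) stop("concentrations must be >= 0")
  idx <- match(species, tab$species)
  if (is.null(charge)) {
    if (anyNA(idx)) {
      stop("no tabulated valence/mobility for species: ",
           paste(species[is.na(idx)], collapse = ", "))
    }
    charge <- tab$charge[idx]
  }
  if (is.null(mobility)) {
    if (anyNA(idx)) {
      stop("no tabulated mobility for species: ",
           paste(species[is.na(idx)], collapse = ", "))
    }
    mobility <- tab$mobility[idx]
  }
  stopifnot(length(charge) == length(species),
            length(mobility) == length(species),
            length(conc_mm) == length(species))
  net <- sum(conc_mm * charge)
  if (abs(net) > charge_tol) {
    stop(sprintf("composition is not electroneutral (net %+.2f mM charge)",
                 net))
  }
  structure(
    data.frame(species = species, conc_mm = as.numeric(conc_mm),
               charge = as.integer(charge), mobility = as.numeric(mobility),
               stringsAsFactors = FALSE),
    temperature_k = temperature_k,
    class = c("solution_composition", "data.frame"))
}

#' K-methylsulfate internal (pipette) solution
#'
#' Free-ion decomposition of a standard K-methylsulfate whole-cell internal
#' (in mM: 120 K-MeSO4, 10 KCl, 10 HEPES, 10 Na2-phosphocreatine, 4 Mg-ATP,
#' 0.4 Na3-GTP, pH 7.35 with KOH). HEPES (pKa ~7.5) is taken as 43% anionic
#' at pH 7.35 with the matching K+ contributed by the KOH titration; the
#' nucleotide salts are taken as fully dissociated (ATP as its Mg-buffered
#' divalent form).
#'
#' @param temperature_k Temperature in kelvin.
#' @return A [solution_composition()].
#' @export
kmeso4_internal <- function(temperature_k = 306.65) {
  hepes_anion <- 10 * 0.43
  solution_composition(
    species = c("K", "Na", "Mg", "Cl", "MeSO4", "HEPES", "PCr", "ATP", "GTP"),
    conc_mm = c(130 + hepes_anion,      # 120 KMeSO4 + 10 KCl + KOH titrant
                20 + 1.2,               # 10 Na2-PCr + 0.4 Na3-GTP
                4, 10, 120, hepes_anion, 10, 4, 0.4),
    temperature_k = temperature_k)
}

#' Bicarbonate-buffered aCSF (bath) solution
#'
#' Free-ion decomposition of a standard recording aCSF (in mM: 125 NaCl,
#' 26 NaHCO3, 2.5 KCl, 1.25 NaH2PO4, 1 MgSO4, 22 glucose, 2 CaCl2). Glucose
#' is neutral and omitted; phosphate is entered as H2PO4-.
#'
#' @param temperature_k Temperature in kelvin.
#' @return A [solution_composition()].
#' @export
acsf_bath <- function(temperature_k = 306.65) {
  solution_composition(
    species = c("Na", "K", "Mg", "Ca", "Cl", "HCO3", "H2PO4", "SO4"),
    conc_mm = c(125 + 26 + 1.25, 2.5, 1, 2, 125 + 2.5 + 4, 26, 1.25, 1),
    temperature_k = temperature_k)
}

#' Liquid junction potential by the stationary Henderson equation
#'
#' Computes the junction potential between a pipette and a bath solution with
#' the stationary Henderson equation using relative ionic mobilities
#' (diffusion-coefficient weighting; see [mobility_table()]).
#'
#' The returned value follows the sign convention used to correct
#' pipette-referenced recordings: it is the potential of the pipette interior
#' relative to the bath (phi_pipette - phi_bath), and is *added* to recorded
#' potentials (see [ljp_correct()]). For a K+-rich pipette facing a Na+-rich
#' bath the value is negative. The function is antisymmetric: swapping the
#' two solutions negates the result.
#'
#' @param pipette,bath [solution_composition()] objects.
#' @param temperature_k Temperature in kelvin; defaults to the pipette
#'   solution's temperature attribute.
#' @return Junction potential in mV (pipette minus bath).
#' @examples
#' compute_ljp(kmeso4_internal(), acsf_bath())
#' @export
compute_ljp <- function(pipette, bath,
                        temperature_k = attr(pipette, "temperature_k")) {
  stopifnot(inherits(pipette, "solution_composition"),
            inherits(bath, "solution_composition"))
  merged <- merge(
    as.data.frame(pipette), as.data.frame(bath),
    by = c("species", "charge", "mobility"), all = TRUE,
    suffixes = c("_pip", "_bath"))
  merged$conc_mm_pip[is.na(merged$conc_mm_pip)] <- 0
  merged$conc_mm_bath[is.na(merged$conc_mm_bath)] <- 0
  z <- merged$charge
  u <- merged$mobility
  cp <- merged$conc_mm_pip
  cb <- merged$conc_mm_bath
  rt_f <- 8.314462618 * temperature_k / 96485.33212 * 1000  # mV
  s_pip <- sum(z^2 * u * cp)
  s_bath <- sum(z^2 * u * cb)
  if (s_pip <= 0 || s_bath <= 0) stop("a solution has no mobile charge")
  num <- sum(z * u * (cb - cp))
  den <- sum(z^2 * u * (cb - cp))
  if (den == 0) {
    # degenerate Henderson prefactor; limit num/den * log(s_pip/s_bath) with
    # s_pip == s_bath is 0 only when num == 0 too (identical solutions)
    if (num == 0) return(0)
    stop("zero Henderson denominator with non-zero numerator; ",
         "compositions too symmetric for the stationary approximation")
  }
  # phi_bath - phi_pip, then negated to the pipette-referenced convention
  v_bath_minus_pip <- rt_f * (num / den) * log(s_pip / s_bath)
  -v_bath_minus_pip
}

#' Apply a liquid-junction-potential correction exactly once
#'
#' Shifts reported potentials by the junction potential. For a
#' [voltage_trace()] the voltage samples and the holding potential are
#' shifted and the `ljp_corrected` flag is set; correcting an
#' already-corrected trace is an error. Plain numeric values are shifted
#' arithmetically.
#'
#' @param x A [voltage_trace()] or numeric vector of potentials (mV).
#' @param ljp Junction potential in mV as returned by [compute_ljp()]
#'   (pipette minus bath; added to recorded values).
#' @return The corrected object.
#' @examples
#' ljp_correct(-45, -8.2)  # -53.2
#' @export
ljp_correct <- function(x, ljp) {
  stopifnot(is.numeric(ljp), length(ljp) == 1, is.finite(ljp))
  if (inherits(x, "voltage_trace")) {
    if (x$ljp_corrected) {
      stop("trace is already LJP-corrected (", x$ljp_mv,
           " mV); refusing to correct twice")
    }
    x$voltage <- x$voltage + ljp
    x$holding_potential <- x$holding_potential + ljp
    x$ljp_corrected <- TRUE
    x$ljp_mv <- ljp
    return(x)
  }
  if (!is.numeric(x)) stop("`x` must be a voltage_trace or numeric")
  x + ljp
}
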