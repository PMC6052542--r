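#' @importFrom utils read.csv write.csv
#' @importFrom stats sd setNames uniroot rlnorm
#' @importFrom tools md5sum
NULL

# Atomic masses used throughout COD stoichiometry (g/mol).
.ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)
.O2_MASS <- 2 * 15.999

#' Construct an elemental formula for COD stoichiometry
#'
#' Represents a compound as C/H/O/N atom counts, the basis for theoretical
#' oxygen demand. Organic nitrogen is assumed to leave as ammonia on full
#' oxidation (standard COD convention).
#'
#' @param carbon,hydrogen,oxygen,nitrogen Non-negative integer atom counts.
#' @return An object of class `chemical_formula`.
#' @examples
#' chemical_formula(6, 12, 6)  # glucose
#' @export
chemical_formula <- function(carbon, hydrogen, oxygen = 0, nitrogen = 0) {
  counts <- c(C = carbon, H = hydrogen, O = oxygen, N = nitrogen)
  if (any(counts < 0)) stop("atom counts must be non-negative")
  if (carbon < 1) stop("organic compounds require at least one carbon")
  structure(as.list(counts), class = "chemical_formula")
}

#' Molecular weight of a formula
#'
#' @param formula A `chemical_formula`.
#' @return Molecular weight in g/mol.
#' @export
molecular_weight <- function(formula) {
  stopifnot(inherits(formula, "chemical_formula"))
  sum(.ATOMIC_MASS * unlist(formula[c("C", "H", "O", "N")]))
}

#' Theoretical oxygen demand of a compound
#'
#' The mass of O2 required to fully oxidize one gram of compound to CO2 and
#' H2O, with organic nitrogen released as NH3:
#' ThOD = MW(O2) * (C + H/4 - O/2 - 3N/4) / MW(compound).
#'
#' @param formula A `chemical_formula`.
#' @return Theoretical oxygen demand in g COD per g compound.
#' @examples
#' theoretical_oxygen_demand(chemical_formula(6, 12, 6))   # glucose, ~1.066
#' theoretical_oxygen_demand(chemical_formula(6, 12, 2))   # hexanoic, ~2.204
#' @export
theoretical_oxygen_demand <- function(formula) {
  stopifnot(inherits(formula, "chemical_formula"))
  mw <- molecular_weight(formula)
  if (mw <= 0) stop("molecular weight must be positive")
  o2_mol <- formula$C + formula$H / 4 - formula$O / 2 - 3 * formula$N / 4
  if (o2_mol <= 0) {
    stop("non-oxidizable formula: oxygen demand expression is <= 0")
  }
  .O2_MASS * o2_mol / mw
}

.registry_env <- new.env(parent = emptyenv())

#' The packaged compound registry
#'
#' Loads the per-compound constants shipped with the package: elemental
#' formula, theoretical COD factor (computed from the formula, or a fixed
#' literature factor for lumped pools such as protein, carbohydrate and
#' unknown COD), carbon count, monocarboxylic-acid flag and, where relevant
#' for titer reporting, aqueous solubility at ambient temperature.
#'
#' @param path Optional path to an alternative registry CSV with the same
#'   columns as `inst/extdata/compounds.csv`.
#' @return A data.frame with one row per compound, including a `thod` column
#'   in g COD per g compound.
#' @export
compound_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.registry_env$registry)) return(.registry_env$registry)
    path <- system.file("extdata", "compounds.csv", package = "mcfatea")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  needs <- is.na(reg$thod) | reg$source == "formula"
  reg$thod[needs] <- vapply(which(needs), function(i) {
    theoretical_oxygen_demand(
      chemical_formula(reg$C[i], reg$H[i], reg$O[i], reg$N[i])
    )
  }, numeric(1))
  if (cache) .registry_env$registry <- reg
  reg
}

#' Look up one compound in the registry
#'
#' @param name Compound name as registered (e.g. `"hexanoic"`).
#' @param registry A registry data.frame; defaults to the packaged one.
#' @return A one-row data.frame (the compound spec).
#' @export
get_compound <- function(name, registry = compound_registry()) {
  i <- match(name, registry$name)
  if (is.na(i)) {
    stop(sprintf(
      "unknown compound '%s'; registered compounds: %s",
      name, paste(registry$name, collapse = ", ")
    ))
  }
  registry[i, , drop = FALSE]
}

#' COD factor for a compound name
#'
#' @inheritParams get_compound
#' @return g COD per g compound.
#' @export
cod_factor <- function(name, registry = compound_registry()) {
  get_compound(name, registry)$thod
}

#' Convert between mass and COD concentration units
#'
#' Multiplies (or, for `cod_to_mass`, divides) a mass concentration by the
#' compound's theoretical COD factor. The two functions are exact inverses.
#'
#' @param concentration Concentration in mg compound per L (`mass_to_cod`)
#'   or mg COD per L (`cod_to_mass`); must be non-negative.
#' @param compound Compound name or a one-row spec from the registry.
#' @param registry Registry data.frame.
#' @return Converted concentration (mg COD/L, respectively mg/L).
#' @export
mass_to_cod <- function(concentration, compound, registry = compound_registry()) {
  if (any(concentration < 0)) stop("concentration must be non-negative")
  if (is.character(compound)) compound <- get_compound(compound, registry)
  concentration * compound$thod
}

#' @rdname mass_to_cod
#' @export
cod_to_mass <- function(concentration, compound, registry = compound_registry()) {
  if (any(concentration < 0)) stop("concentration must be non-negative")
  if (is.character(compound)) compound <- get_compound(compound, registry)
  concentration / compound$thod
}

#' Classify a compound by carboxylic-acid chain length
#'
#' Linear monocarboxylic acids with 2-5 carbons are short-chain fatty acids
#' (SCFA), those with 6-8 carbons medium-chain fatty acids (MCFA); everything
#' else is "other". Chain parity (odd/even carbon number) is reported for
#' monocarboxylic acids only.
#'
#' @param compound Compound name or registry row.
#' @param registry Registry data.frame.
#' @return A list with elements `class` (one of `"SCFA"`, `"MCFA"`,
#'   `"other"`) and `parity` (`"odd_chain"`, `"even_chain"` or `"n/a"`).
#' @export
classify_compound <- function(compound, registry = compound_registry()) {
  if (is.character(compound)) compound <- get_compound(compound, registry)
  n <- compound$carbon_count
  if (isTRUE(compound$acid_flag)) {
    cls <- if (n >= 2 && n <= 5) "SCFA" else if (n >= 6 && n <= 8) "MCFA" else "other"
    parity <- if (n %% 2 == 1) "odd_chain" else "even_chain"
  } else {
    cls <- "other"
    parity <- "n/a"
  }
  list(class = cls, parity = parity)
}

# Vectorized class lookup used by the metrics layer.
.compound_classes <- function(names, registry = compound_registry()) {
  vapply(names, function(nm) {
    i <- match(nm, registry$name)
    if (is.na(i)) return("other")
    classify_compound(registry[i, , drop = FALSE], registry)$class
  }, character(1))
}

.compound_parity <- function(names, registry = compound_registry()) {
  vapply(names, function(nm) {
    i <- match(nm, registry$name)
    if (is.na(i)) return("n/a")
    classify_compound(registry[i, , drop = FALSE], registry)$parity
  }, character(1))
}
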