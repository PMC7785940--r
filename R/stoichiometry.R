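#' Canonical ion names
#'
#' The fixed 18-ion decomposition used throughout the package. Media are
#' modeled on ions rather than salts to avoid the "ion confounding" effect:
#' several salts contribute the same ion, so salt-level factors cannot
#' identify per-ion causes. `MoO2` labels the molybdate anion released by
#' sodium molybdate (one Mo anion and two Na+ per formula unit); `EDTA`
#' counts the free chelator anion. No speciation or chelation equilibrium is
#' modeled: Fe2+ and EDTA- are counted independently.
#'
#' @return Character vector of the 18 ion names, in canonical column order.
#' @export
ion_names <- function() {
  c("NH4", "NO3", "K", "Ca", "Mg", "PO4", "SO4", "Cl", "Fe",
    "BO3", "Mn", "Zn", "Cu", "MoO2", "Na", "Co", "I", "EDTA")
}

pm_extdata <- function(file) {
  path <- system.file("extdata", file, package = "phytomedia")
  if (!nzchar(path)) stop("fixture not found: ", file)
  path
}

#' Salt registry
#'
#' Versioned table of salts with hydrate formula, molar mass (g/mol) and
#' integer stoichiometric ion yields. Covers the 14 MS salts plus the extra
#' salts appearing in the B5 and St media.
#'
#' @return Data frame with columns `salt`, `formula`, `molar_mass` and one
#'   integer column per ion in [ion_names()].
#' @export
salt_registry <- function() {
  reg <- utils::read.csv(pm_extdata("salt_registry.csv"), check.names = FALSE)
  stopifnot(all(reg$molar_mass > 0), all(ion_names() %in% names(reg)))
  reg
}

lookup_salt <- function(salt, registry = salt_registry()) {
  i <- match(salt, registry$salt)
  if (anyNA(i)) {
    stop("unknown salt(s): ", paste(salt[is.na(i)], collapse = ", "))
  }
  registry[i, , drop = FALSE]
}

#' Convert a salt concentration to millimolar
#'
#' @param salt Salt name present in the registry.
#' @param conc Concentration in mg/L (scalar, >= 0).
#' @param registry Salt registry data frame.
#' @return The salt's molar concentration in mM (`conc / molar_mass`).
#' @export
salt_to_millimolar <- function(salt, conc, registry = salt_registry()) {
  stopifnot(length(conc) == 1, is.finite(conc))
  if (conc < 0) stop("negative concentration for ", salt)
  conc / lookup_salt(salt, registry)$molar_mass
}

#' Ion contributions of a single salt
#'
#' @inheritParams salt_to_millimolar
#' @return Named numeric vector over the 18 canonical ions (mM): the salt's
#'   millimolar concentration times each stoichiometric yield.
#' @export
salt_ions <- function(salt, conc, registry = salt_registry()) {
  mM <- salt_to_millimolar(salt, conc, registry)
  yields <- as.numeric(lookup_salt(salt, registry)[, ion_names()])
  stats::setNames(mM * yields, ion_names())
}

#' Construct a medium recipe
#'
#' @param concentrations Named numeric vector, salt name -> mg/L.
#' @param label Text label for the medium.
#' @param passthrough Named character vector of non-mineral components
#'   (vitamins, PGRs); carried along, never computed on.
#' @param registry Salt registry used to validate salt names.
#' @return Object of class `medium_recipe`.
#' @export
medium_recipe <- function(concentrations, label = "",
                          passthrough = character(),
                          registry = salt_registry()) {
  stopifnot(is.numeric(concentrations), !is.null(names(concentrations)))
  if (any(concentrations < 0)) stop("salt concentrations must be >= 0")
  lookup_salt(names(concentrations), registry)
  structure(list(concentrations = concentrations, label = label,
                 passthrough = passthrough),
            class = "medium_recipe")
}

#' @export
print.medium_recipe <- function(x, ...) {
  cat("<medium_recipe>", if (nzchar(x$label)) x$label else "(unlabeled)", "\n")
  print(round(x$concentrations, 4))
  invisible(x)
}

#' Convert a recipe to an ion profile
#'
#' Sums per-salt ion contributions; the result is the model-input
#' representation of the medium.
#'
#' @param recipe A [medium_recipe()] or a named numeric vector of mg/L.
#' @param registry Salt registry.
#' @return Named numeric vector over all 18 ions (mM), zeros included.
#' @export
recipe_to_ions <- function(recipe, registry = salt_registry()) {
  conc <- if (inherits(recipe, "medium_recipe")) recipe$concentrations else recipe
  prof <- stats::setNames(numeric(18), ion_names())
  if (length(conc) == 0) return(prof)
  if (any(conc < 0)) stop("salt concentrations must be >= 0")
  reg <- lookup_salt(names(conc), registry)
  mM <- conc / reg$molar_mass
  yields <- as.matrix(reg[, ion_names()])
  prof + drop(mM %*% yields)
}

#' Factor-to-salt groupings of the design space
#'
#' The five-factor grouping of the 14 MS salts: NH4NO3 and KNO3 alone, the
#' three "mesos" salts, the seven trace-element ("micros") salts, and the
#' two iron-chelate salts.
#'
#' @return Named list: factor name -> character vector of salt names.
#' @export
factor_groups <- function() {
  fs <- utils::read.csv(pm_extdata("factor_space.csv"))
  stats::setNames(strsplit(fs$salts, ";", fixed = TRUE), fs$factor)
}

#' Factor bounds of the design space
#'
#' @return Data frame with columns `factor`, `low`, `high` (dimensionless
#'   multiplier units, 1 = the base medium concentration).
#' @export
factor_space <- function() {
  utils::read.csv(pm_extdata("factor_space.csv"))[, c("factor", "low", "high")]
}

#' Scale a base recipe by factor levels
#'
#' Each salt's concentration is multiplied by the level of the factor whose
#' group contains it; salts outside every group are left unchanged. Levels
#' outside the declared factor ranges are allowed (with a warning) for
#' exploratory use.
#'
#' @param levels Named numeric vector of multipliers, one per factor.
#' @param base Base [medium_recipe()] (default MS).
#' @param groups Factor -> salt list mapping, as [factor_groups()].
#' @param warn_range Warn when a level falls outside the design bounds.
#' @return A [medium_recipe()].
#' @export
factors_to_recipe <- function(levels, base = ms_recipe(),
                              groups = factor_groups(), warn_range = TRUE) {
  stopifnot(all(names(groups) %in% names(levels)))
  if (warn_range) {
    fs <- factor_space()
    lv <- levels[fs$factor]
    out <- lv < fs$low - 1e-9 | lv > fs$high + 1e-9
    if (any(out)) {
      warning("factor level(s) outside design range: ",
              paste(fs$factor[out], collapse = ", "))
    }
  }
  conc <- base$concentrations
  for (f in names(groups)) {
    hit <- intersect(groups[[f]], names(conc))
    conc[hit] <- conc[hit] * levels[[f]]
  }
  medium_recipe(conc, label = sprintf("%s scaled", base$label),
                passthrough = base$passthrough)
}

#' Ion table for a whole design
#'
#' Row-wise composition of [factors_to_recipe()] and [recipe_to_ions()]:
#' the run x ion matrix used as model input.
#'
#' @param design Data frame or matrix with one column per factor
#'   (multiplier units).
#' @param base Base recipe scaled by the factor levels.
#' @param groups Factor -> salt grouping.
#' @return Numeric matrix, runs x 18 ions.
#' @export
design_to_ion_table <- function(design, base = ms_recipe(),
                                groups = factor_groups()) {
  design <- as.data.frame(design)
  stopifnot(all(names(groups) %in% names(design)))
  out <- t(vapply(seq_len(nrow(design)), function(i) {
    lv <- unlist(design[i, names(groups), drop = TRUE])
    recipe_to_ions(factors_to_recipe(lv, base, groups, warn_range = FALSE))
  }, numeric(18)))
  rownames(out) <- rownames(design)
  out
}

#' Salt table for a whole design
#'
#' @inheritParams design_to_ion_table
#' @return Numeric matrix, runs x salts (mg/L), columns the base recipe's
#'   salts. This is the input representation used for the neural-network
#'   models.
#' @export
design_to_salt_table <- function(design, base = ms_recipe(),
                                 groups = factor_groups()) {
  design <- as.data.frame(design)
  out <- t(vapply(seq_len(nrow(design)), function(i) {
    lv <- unlist(design[i, names(groups), drop = TRUE])
    factors_to_recipe(lv, base, groups, warn_range = FALSE)$concentrations
  }, numeric(length(base$concentrations))))
  rownames(out) <- rownames(design)
  out
}

#' Round half away from zero
#'
#' Printed tables in media formulation work round 5 upward in magnitude
#' (2.845 -> 2.85), unlike R's bankers rounding; comparisons against printed
#' values use this convention.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
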