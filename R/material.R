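#' Parse a molecular formula into element counts
#'
#' @param formula Character scalar such as `"C4H10O2"` or `"H2O"`.
#' @return Named integer vector of atom counts per element.
#' @examples
#' parse_formula("C4H10O2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (length(toks) == 0L || sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse formula: '", formula, "'", call. = FALSE)
  counts <- integer(0)
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    .element(sym)  # validates symbol
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts
}

#' Construct a material from elemental mass fractions
#'
#' @param mass_fractions Named numeric vector (element symbol -> mass fraction);
#'   must sum to 1.
#' @param density Bulk density in g/cm^3.
#' @param name Label for the material.
#' @return An object of class `material` with fields `name`, `density` and an
#'   `elements` data frame (`symbol`, `Z`, `A`, `I_elem`, `w`).
#' @export
material <- function(mass_fractions, density, name = "material") {
  stopifnot(is.numeric(mass_fractions), !is.null(names(mass_fractions)))
  if (any(mass_fractions < 0) || any(mass_fractions > 1))
    stop("mass fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(mass_fractions) - 1) > 1e-9)
    stop("mass fractions must sum to 1 (got ", sum(mass_fractions), ")", call. = FALSE)
  if (!is.numeric(density) || density <= 0)
    stop("density must be positive", call. = FALSE)
  syms <- names(mass_fractions)
  els <- lapply(syms, .element)
  out <- list(
    name = name,
    density = density,
    elements = data.frame(
      symbol = syms,
      Z = vapply(els, `[[`, numeric(1), "Z"),
      A = vapply(els, `[[`, numeric(1), "A"),
      I_elem = vapply(els, `[[`, numeric(1), "I"),
      w = as.numeric(mass_fractions),
      stringsAsFactors = FALSE
    )
  )
  class(out) <- "material"
  out
}

#' @export
print.material <- function(x, ...) {
  cat("<material>", x$name, " density", x$density, "g/cm3\n")
  print(x$elements, row.names = FALSE)
  invisible(x)
}

#' Compose a mixture of molecular components into a material
#'
#' Elemental mass fractions are obtained from the molecular formulas and the
#' component proportions. With `basis = "volume"` the proportions are volume
#' parts and each component's mass is proportion x density; with
#' `basis = "mass"` they are mass parts directly. The bulk density of the
#' mixture is set to `final_density` when given (a measured value overrides the
#' ideal-mixing estimate), otherwise to the ideal-mixing estimate.
#'
#' @param components Named numeric vector: molecular formula -> proportion,
#'   e.g. `c(C4H10O2 = 7, H2O = 3)`.
#' @param basis `"mass"` or `"volume"`.
#' @param component_densities Densities (g/cm^3) per component, required for
#'   the volume basis.
#' @param final_density Measured bulk density (g/cm^3) overriding ideal mixing.
#' @param name Material label.
#' @return A [material] object.
#' @examples
#' compose_mixture(c(H2O = 1), basis = "mass", final_density = 1.0)
#' @export
compose_mixture <- function(components, basis = c("mass", "volume"),
                            component_densities = NULL, final_density = NULL,
                            name = "mixture") {
  basis <- match.arg(basis)
  stopifnot(is.numeric(components), !is.null(names(components)))
  if (any(components <= 0)) stop("proportions must be > 0", call. = FALSE)
  n <- length(components)
  if (basis == "volume") {
    if (is.null(component_densities) || length(component_densities) != n)
      stop("volume basis requires one density per component", call. = FALSE)
    masses <- components * component_densities
  } else {
    masses <- components
  }
  masses <- masses / sum(masses)

  w <- numeric(0)
  for (k in seq_len(n)) {
    counts <- parse_formula(names(components)[k])
    A <- vapply(names(counts), function(s) .element(s)$A, numeric(1))
    elw <- counts * A / sum(counts * A)     # mass fraction within component
    for (s in names(elw))
      w[s] <- (if (s %in% names(w)) w[[s]] else 0) + masses[k] * elw[[s]]
  }
  w <- w / sum(w)

  if (is.null(final_density)) {
    final_density <- if (basis == "volume") {
      sum(components * component_densities) / sum(components)
    } else {
      stop("mass basis requires final_density (no ideal-mixing estimate possible)",
           call. = FALSE)
    }
  }
  material(w, density = final_density, name = name)
}

#' The alcohol-based liquid scintillator (AbLS) composition
#'
#' 2-ethoxyethanol (C4H10O2) and water mixed 7:3 by volume (component
#' densities 0.930 and 0.998 g/cm^3), with the bulk density pinned to the
#' measured 0.945 g/cm^3. The trace fluors (PPO, bis-MSB) are neglected.
#'
#' @param basis Mixing convention for the 7:3 ratio; the packaged default is
#'   volume (the common lab convention for solvent mixing).
#' @return A [material] object.
#' @export
abls_material <- function(basis = c("volume", "mass")) {
  basis <- match.arg(basis)
  compose_mixture(
    c(C4H10O2 = 7, H2O = 3), basis = basis,
    component_densities = if (basis == "volume") c(0.930, 0.998) else NULL,
    final_density = 0.945, name = paste0("AbLS (7:3 ", basis, ")")
  )
}

#' Liquid water reference material
#' @return A [material] object (density 1.0 g/cm^3).
#' @export
water_material <- function() {
  compose_mixture(c(H2O = 1), basis = "mass", final_density = 1.0, name = "water")
}

#' Effective atomic number of a material
#'
#' Mayneord power law with electron-number-fraction weights:
#' `Zeff = (sum_i alpha_i Z_i^m)^(1/m)` with `alpha_i` proportional to
#' `w_i Z_i / A_i`. The conventional medical-physics exponent is m = 2.94.
#'
#' @param comp A [material] object.
#' @param exponent Power-law exponent m (> 0).
#' @return Dimensionless effective atomic number.
#' @export
effective_atomic_number <- function(comp, exponent = 2.94) {
  stopifnot(inherits(comp, "material"))
  if (!is.numeric(exponent) || exponent <= 0) stop("exponent must be > 0", call. = FALSE)
  e <- comp$elements
  if (nrow(e) == 0L) stop("empty composition", call. = FALSE)
  alpha <- e$w * e$Z / e$A
  alpha <- alpha / sum(alpha)
  sum(alpha * e$Z^exponent)^(1 / exponent)
}

#' Mean excitation energy of a material (Bragg additivity)
#'
#' `ln I = sum_i (w_i Z_i / A_i) ln I_i / sum_i (w_i Z_i / A_i)` with the
#' ICRU-37 condensed-phase elemental I-values.
#'
#' @param comp A [material] object.
#' @return Mean excitation energy in eV.
#' @export
mean_excitation_energy <- function(comp) {
  stopifnot(inherits(comp, "material"))
  e <- comp$elements
  if (any(!is.finite(e$I_elem)) || any(e$I_elem <= 0))
    stop("missing elemental mean excitation energy", call. = FALSE)
  u <- e$w * e$Z / e$A
  exp(sum(u * log(e$I_elem)) / sum(u))
}

#' Electron density of a material
#'
#' @param comp A [material] object.
#' @return Electrons per gram, `N_A * sum_i w_i Z_i / A_i`.
#' @export
electron_density <- function(comp) {
  stopifnot(inherits(comp, "material"))
  e <- comp$elements
  .NAVO * sum(e$w * e$Z / e$A)
}

# mean Z/A (mol electrons per gram) -- used by the stopping-power module
.z_over_a <- function(comp) sum(comp$elements$w * comp$elements$Z / comp$elements$A)

#' Write / read a material definition as JSON
#'
#' @param comp A [material] object.
#' @param path File path.
#' @return `write_material` returns `path` invisibly; `read_material` returns
#'   a [material] object.
#' @export
write_material <- function(comp, path) {
  stopifnot(inherits(comp, "material"))
  obj <- list(name = comp$name, density = comp$density,
              mass_fractions = as.list(stats::setNames(comp$elements$w, comp$elements$symbol)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_material
#' @export
read_material <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  material(unlist(obj$mass_fractions), density = obj$density, name = obj$name)
}
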