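#' Optical properties of a homogeneous medium
#'
#' Bundle of the four quantities governing light transport in a turbid
#' medium: absorption coefficient `mu_a` (mm^-1), scattering coefficient
#' `mu_s` (mm^-1), scattering anisotropy `g` (the mean cosine of the
#' deflection angle, dimensionless) and refractive index `n`.
#'
#' @param mu_a Absorption coefficient, per mm (>= 0).
#' @param mu_s Scattering coefficient, per mm (>= 0).
#' @param g Anisotropy factor, in (-1, 1).
#' @param n Refractive index (>= 1).
#' @return An object of class `optical_properties`.
#' @examples
#' optical_properties(mu_a = 0.015, mu_s = 8, g = 0.9, n = 1.37)
#' @export
optical_properties <- function(mu_a, mu_s, g, n) {
  stopifnot(is.numeric(mu_a), is.numeric(mu_s), is.numeric(g), is.numeric(n))
  if (mu_a < 0 || mu_s < 0)
    stop("mu_a and mu_s must be nonnegative")
  if (g <= -1 || g >= 1)
    stop("anisotropy g must lie strictly between -1 and 1")
  if (n < 1)
    stop("refractive index n must be >= 1")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("optical properties: mu_a=%.4g /mm  mu_s=%.4g /mm  g=%.3g  n=%.3g\n",
              x$mu_a, x$mu_s, x$g, x$n))
  invisible(x)
}

#' Tissue layer with per-wavelength optical properties
#'
#' @param name Layer label (e.g. `"dermis"`).
#' @param thickness Layer thickness in mm (finite, > 0).
#' @param props A data frame with columns `wavelength_nm`, `mu_a`, `mu_s`,
#'   `g`, `n`; one row per wavelength, coefficients in per-mm units.
#' @return An object of class `tissue_layer`.
#' @export
tissue_layer <- function(name, thickness, props) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(thickness) || length(thickness) != 1 ||
      !is.finite(thickness) || thickness <= 0)
    stop("layer thickness must be a finite positive number (mm)")
  req <- c("wavelength_nm", "mu_a", "mu_s", "g", "n")
  if (!is.data.frame(props) || !all(req %in% names(props)))
    stop("props must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (anyNA(props[req]))
    stop("layer '", name, "': incomplete property record (NA values)")
  for (i in seq_len(nrow(props)))
    optical_properties(props$mu_a[i], props$mu_s[i], props$g[i], props$n[i])
  structure(list(name = name, thickness = thickness,
                 props = props[order(props$wavelength_nm), req]),
            class = "tissue_layer")
}

#' Look up a layer's optical properties at a wavelength
#'
#' Exact match only: the transport model treats each simulation wavelength
#' as its own property record.
#'
#' @param layer A [tissue_layer()].
#' @param wavelength Wavelength in nm.
#' @return An [optical_properties()] object.
#' @export
layer_props <- function(layer, wavelength) {
  stopifnot(inherits(layer, "tissue_layer"))
  i <- match(wavelength, layer$props$wavelength_nm)
  if (is.na(i))
    stop("layer '", layer$name, "' has no properties at ", wavelength, " nm")
  p <- layer$props[i, ]
  optical_properties(p$mu_a, p$mu_s, p$g, p$n)
}

#' Ordered stack of tissue layers
#'
#' Layers are ordered from the illuminated surface downward; the depth
#' coordinate is 0 at the surface and increases into the tissue. Layer
#' boundaries are contiguous by construction (each layer starts where the
#' previous one ends).
#'
#' @param layers A list of [tissue_layer()] objects, surface first.
#' @param n_above Refractive index of the ambient medium above the stack
#'   (default 1.0, air).
#' @param n_below Refractive index of the medium backing the stack
#'   (default 1.37: an index-matched tissue backing, so light leaving the
#'   bottom is not artificially reflected at a tissue/air interface).
#' @param fat_thickness_x Optional record of the variable fat depth (mm)
#'   when built by [build_tumor_stack()].
#' @return An object of class `tissue_stack`.
#' @export
tissue_stack <- function(layers, n_above = 1.0, n_below = 1.37,
                         fat_thickness_x = NA_real_) {
  if (!is.list(layers) || length(layers) < 1 ||
      !all(vapply(layers, inherits, logical(1), "tissue_layer")))
    stop("layers must be a non-empty list of tissue_layer objects")
  if (n_above < 1 || n_below < 1) stop("ambient refractive indices must be >= 1")
  structure(list(layers = layers, n_above = n_above, n_below = n_below,
                 fat_thickness_x = fat_thickness_x),
            class = "tissue_stack")
}

#' @export
print.tissue_stack <- function(x, ...) {
  b <- stack_boundaries(x)
  cat(sprintf("tissue stack: %d layer(s), total depth %.3g mm (n_above=%.3g, n_below=%.3g)\n",
              length(x$layers), max(b), x$n_above, x$n_below))
  for (i in seq_along(x$layers))
    cat(sprintf("  [%d] %-10s %6.2f mm  (z = %.2f..%.2f mm)\n", i,
                x$layers[[i]]$name, x$layers[[i]]$thickness, b[i], b[i + 1]))
  invisible(x)
}

#' Depth positions of the layer boundaries
#'
#' @param stack A [tissue_stack()].
#' @return Numeric vector of length `n_layers + 1`: 0, then the cumulative
#'   sum of layer thicknesses (mm).
#' @export
stack_boundaries <- function(stack) {
  stopifnot(inherits(stack, "tissue_stack"))
  c(0, cumsum(vapply(stack$layers, function(l) l$thickness, numeric(1))))
}

#' Resolve a stack to a per-layer property matrix at one wavelength
#'
#' @param stack A [tissue_stack()].
#' @param wavelength Wavelength in nm; every layer must carry a record at it.
#' @return A data frame with one row per layer: `name`, `thickness`,
#'   `mu_a`, `mu_s`, `g`, `n`.
#' @export
resolve_stack <- function(stack, wavelength) {
  rows <- lapply(stack$layers, function(l) {
    p <- layer_props(l, wavelength)
    data.frame(name = l$name, thickness = l$thickness,
               mu_a = p$mu_a, mu_s = p$mu_s, g = p$g, n = p$n)
  })
  do.call(rbind, rows)
}

#' Absorber extinction spectrum
#'
#' @param name Label, e.g. `"icg_monomer"` or `"lja"`.
#' @param wavelengths Strictly increasing nm grid.
#' @param epsilon Decadic molar extinction coefficients (per M per cm),
#'   nonnegative, one per wavelength.
#' @return An object of class `absorber_spectrum`.
#' @export
absorber_spectrum <- function(name, wavelengths, epsilon) {
  stopifnot(length(wavelengths) == length(epsilon), length(wavelengths) >= 2)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(epsilon < 0)) stop("epsilon must be nonnegative")
  structure(list(name = name, wavelengths = as.numeric(wavelengths),
                 epsilon = as.numeric(epsilon)),
            class = "absorber_spectrum")
}

#' Interpolate a spectrum's extinction at a wavelength
#'
#' Linear interpolation between grid points; requesting a wavelength
#' outside the tabulated range is an error.
#'
#' @param spectrum An [absorber_spectrum()].
#' @param wavelength Wavelength in nm (may be a vector).
#' @return Extinction coefficient(s), per M per cm.
#' @export
epsilon_at <- function(spectrum, wavelength) {
  stopifnot(inherits(spectrum, "absorber_spectrum"))
  rng <- range(spectrum$wavelengths)
  if (any(wavelength < rng[1] | wavelength > rng[2]))
    stop("wavelength outside the spectrum range [", rng[1], ", ", rng[2], "] nm")
  approx(spectrum$wavelengths, spectrum$epsilon, xout = wavelength)$y
}

#' Convert molar concentration to an absorption coefficient
#'
#' Beer-Lambert bridge: a decadic extinction `epsilon` (per M per cm) at
#' concentration `c` gives the natural-log absorption coefficient
#' `mu_a = ln(10) * epsilon * c / 10` in per-mm units.
#'
#' @param spectrum An [absorber_spectrum()].
#' @param concentration Molar concentration (M, >= 0).
#' @param wavelength Wavelength in nm, within the spectrum range.
#' @return Absorption coefficient, per mm.
#' @examples
#' sp <- absorber_spectrum("flat", c(700, 900), c(1e5, 1e5))
#' molar_to_mua(sp, 1e-5, 800)  # ln(10) * 1 cm^-1 = 0.2303 mm^-1
#' @export
molar_to_mua <- function(spectrum, concentration, wavelength) {
  if (concentration < 0) stop("concentration must be nonnegative")
  eps <- epsilon_at(spectrum, wavelength)
  log(10) * eps * concentration / 10
}

#' Mix contrast-agent absorption into tissue optical properties
#'
#' The agent-loaded properties are the linear combination of the tissue
#' values and the agent contribution: `mu_a` and `mu_s` add, while `g` and
#' `n` are inherited from the tissue. The agent is treated as
#' non-scattering by default (`agent_mus = 0`).
#'
#' @param tissue An [optical_properties()] object.
#' @param agent_mua Agent absorption contribution, per mm (>= 0).
#' @param agent_mus Agent scattering contribution, per mm (>= 0, default 0).
#' @return An [optical_properties()] object.
#' @export
mix_properties <- function(tissue, agent_mua, agent_mus = 0) {
  stopifnot(inherits(tissue, "optical_properties"))
  if (agent_mua < 0 || agent_mus < 0)
    stop("agent contributions must be nonnegative")
  optical_properties(tissue$mu_a + agent_mua, tissue$mu_s + agent_mus,
                     tissue$g, tissue$n)
}

#' Contrast-agent loading of a tumor
#'
#' Describes the dose assumption under which agent optical properties are
#' mixed into the tumor layer: a fraction of a weight-based intravenous
#' dose distributes uniformly through the tumor volume.
#'
#' @param dose_mg_per_kg Injected dose (mg of agent per kg body mass).
#' @param body_mass_kg Body mass in kg (default 0.020, a 20 g mouse).
#' @param uptake_fraction Fraction of the injected dose reaching the tumor,
#'   in (0, 1] (default 0.01).
#' @param tumor_volume_mm3 Tumor volume in mm^3 (default 50).
#' @param molar_mass_g_mol Molar mass of the absorbing species (g/mol).
#' @return An object of class `agent_loading`.
#' @export
agent_loading <- function(dose_mg_per_kg = 5, body_mass_kg = 0.020,
                          uptake_fraction = 0.01, tumor_volume_mm3 = 50,
                          molar_mass_g_mol = 775) {
  vals <- c(dose_mg_per_kg, body_mass_kg, uptake_fraction,
            tumor_volume_mm3, molar_mass_g_mol)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all agent_loading fields must be positive")
  if (uptake_fraction > 1) stop("uptake_fraction must lie in (0, 1]")
  structure(list(dose_mg_per_kg = dose_mg_per_kg, body_mass_kg = body_mass_kg,
                 uptake_fraction = uptake_fraction,
                 tumor_volume_mm3 = tumor_volume_mm3,
                 molar_mass_g_mol = molar_mass_g_mol),
            class = "agent_loading")
}

#' Tumor agent concentration implied by a dose assumption
#'
#' `concentration [M] = dose * body_mass * uptake_fraction * 1000 /
#' (molar_mass * tumor_volume)` with dose in mg/kg, mass in kg, molar mass
#' in g/mol and volume in mm^3 (1 L = 1e6 mm^3).
#'
#' @param loading An [agent_loading()].
#' @return Molar concentration (M).
#' @examples
#' dose_to_concentration(agent_loading())  # ~2.58e-5 M
#' @export
dose_to_concentration <- function(loading) {
  stopifnot(inherits(loading, "agent_loading"))
  with(loading,
       dose_mg_per_kg * body_mass_kg * uptake_fraction * 1000 /
         (molar_mass_g_mol * tumor_volume_mm3))
}

#' Build the four-layer tumor-under-fat stack
#'
#' Constructs the epidermis (0.1 mm) / dermis (2.0 mm) / fat (variable
#' `x` mm) / tumor (2.0 mm) stack used throughout the depth-scan
#' experiments, optionally mixing a contrast agent into the tumor layer at
#' the concentration implied by a dose assumption. With `fat_thickness_mm
#' = 0` the fat layer is omitted.
#'
#' @param fat_thickness_mm Fat layer thickness `x`, in 0..6 mm.
#' @param wavelengths Wavelengths (nm) that must have property records;
#'   agent absorption is mixed in at each of them.
#' @param agent Optional list with elements `spectrum`
#'   (an [absorber_spectrum()]) and `loading` (an [agent_loading()]).
#' @param table Optical-property table (data frame as returned by
#'   [default_tissue_table()]); defaults to the packaged table.
#' @param n_above,n_below Ambient refractive indices (see [tissue_stack()]).
#' @return A [tissue_stack()].
#' @examples
#' st <- build_tumor_stack(2)
#' stack_boundaries(st)  # 0, 0.1, 2.1, 4.1, 6.1
#' @export
build_tumor_stack <- function(fat_thickness_mm, wavelengths = c(808, 852, 890),
                              agent = NULL, table = default_tissue_table(),
                              n_above = 1.0, n_below = 1.37) {
  if (!is.numeric(fat_thickness_mm) || fat_thickness_mm < 0 ||
      fat_thickness_mm > 6)
    stop("fat_thickness_mm must lie in [0, 6]")
  mk <- function(lname, thick) {
    sub <- table[table$layer == lname & table$wavelength_nm %in% wavelengths, ]
    if (nrow(sub) < length(wavelengths))
      stop("property table lacks layer '", lname, "' at some of wavelengths ",
           paste(wavelengths, collapse = ", "), " nm")
    tissue_layer(lname, thick,
                 data.frame(wavelength_nm = sub$wavelength_nm,
                            mu_a = sub$mu_a, mu_s = sub$mu_s,
                            g = sub$g, n = sub$n))
  }
  thicknesses <- list(epidermis = 0.1, dermis = 2.0, fat = fat_thickness_mm,
                      tumor = 2.0)
  layers <- list()
  for (lname in names(thicknesses)) {
    if (thicknesses[[lname]] <= 0) next
    lyr <- mk(lname, thicknesses[[lname]])
    if (lname == "tumor" && !is.null(agent)) {
      conc <- dose_to_concentration(agent$loading)
      for (i in seq_len(nrow(lyr$props))) {
        amua <- molar_to_mua(agent$spectrum, conc, lyr$props$wavelength_nm[i])
        mixed <- mix_properties(
          optical_properties(lyr$props$mu_a[i], lyr$props$mu_s[i],
                             lyr$props$g[i], lyr$props$n[i]), amua)
        lyr$props$mu_a[i] <- mixed$mu_a
        lyr$props$mu_s[i] <- mixed$mu_s
      }
    }
    layers[[length(layers) + 1]] <- lyr
  }
  tissue_stack(layers, n_above = n_above, n_below = n_below,
               fat_thickness_x = fat_thickness_mm)
}

#' Depth span of a named layer within a stack
#'
#' @param stack A [tissue_stack()].
#' @param name Layer name to locate.
#' @return Numeric `c(top, bottom)` depth in mm.
#' @export
layer_span <- function(stack, name) {
  idx <- which(vapply(stack$layers, function(l) l$name, character(1)) == name)
  if (length(idx) == 0) stop("stack has no layer named '", name, "'")
  b <- stack_boundaries(stack)
  c(b[idx[1]], b[idx[1] + 1])
}
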