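#' Physical constants and unit conversions
#'
#' The package works in a consistent pN / nm / ns unit system. The derived
#' mass unit is 1 pN ns^2 / nm = 1e-21 kg; energies are in pN nm
#' (1 pN nm = 1e-21 J); temperatures in K.
#'
#' @return A named list with `kB` (Boltzmann constant, pN nm / K), `dalton`
#'   (one unified atomic mass unit in internal mass units), `avogadro`, and
#'   `joule_per_kcal`.
#' @export
dna_constants <- function() {
  list(
    kB = 0.0138064852,          # pN nm / K
    dalton = 1.66053906660e-6,  # 1 Da in units of 1e-21 kg
    avogadro = 6.02214076e23,
    joule_per_kcal = 4184
  )
}

#' Thermal energy kBT
#'
#' @param temperature Temperature in K.
#' @return Thermal energy in pN nm (4.1419 at 300 K).
#' @export
kBT <- function(temperature = 300) dna_constants()$kB * temperature

#' Convert a per-bond energy in pN nm to kcal/mol
#'
#' Multiplies by Avogadro's number and converts J to thermochemical kcal
#' (4184 J). A base-stacking free energy of 42.2 pN nm per bond corresponds
#' to about 6.07 kcal/mol.
#'
#' @param e_pnnm Energy per bond, pN nm.
#' @return Energy in kcal/mol.
#' @export
pnnm_to_kcal_per_mol <- function(e_pnnm) {
  k <- dna_constants()
  e_pnnm * 1e-21 * k$avogadro / k$joule_per_kcal
}

# Average nucleotide-monophosphate masses, Da. A base-pair node carries the
# sum over both strands of the pair.
.nt_mass_da <- c(A = 313.2, C = 289.2, G = 329.2, T = 304.2)
.nt_complement <- c(A = "T", C = "G", G = "C", T = "A")

base_pair_mass <- function(base) {
  # base: one of A/C/G/T, "avg" (sequence-averaged pair) or "-" (single
  # strand marker: one averaged nucleotide). Internal mass units.
  da <- vapply(base, function(b) {
    if (b == "avg") {
      mean(.nt_mass_da) * 2
    } else if (b == "-") {
      mean(.nt_mass_da)
    } else {
      if (!b %in% names(.nt_mass_da)) stop("invalid base character: ", b)
      .nt_mass_da[[b]] + .nt_mass_da[[.nt_complement[[b]]]]
    }
  }, numeric(1))
  unname(da) * dna_constants()$dalton
}

# Principal moments of inertia for a node treated as a rigid cylinder of
# radius 1 nm and height 0.34 nm about its base-pair frame axes (x, y, z with
# z along the helix axis); mass in internal units, result mass nm^2.
node_inertia <- function(mass, radius = 1, height = 0.34) {
  ixy <- mass * (3 * radius^2 + height^2) / 12
  iz <- mass * radius^2 / 2
  cbind(ixy, ixy, iz, deparse.level = 0)
}

#' Default mechanical and interaction parameter table
#'
#' Sequence-averaged B-DNA defaults used by all parametric builders. The
#' per-step elastic constants follow from a stretch modulus of 1100 pN, a
#' bending persistence length of 50 nm and a torsional persistence length of
#' 100 nm at the 0.34 nm rise (shear stiffness is set equal to the stretch
#' stiffness as an isotropic simplification). Crossover steps keep the
#' translational stiffness but are 10x softer in all rotations. All values can
#' be overridden so that refined, sequence-dependent tables can be dropped in.
#'
#' @param temperature Temperature in K used for the thermal-energy-derived
#'   entries.
#' @return A named list of parameters (units in the element descriptions).
#' @export
default_parameter_table <- function(temperature = 300) {
  kt <- kBT(temperature)
  rise <- 0.34
  list(
    name = "bdna_average_v1",
    rise = rise,                      # nm
    twist = 34.3,                     # degrees
    stretch_modulus = 1100,           # pN
    persistence_length_bend = 50,     # nm
    persistence_length_twist = 100,   # nm
    k_stretch = 1100 / rise,          # pN/nm
    k_shear = 1100 / rise,            # pN/nm
    k_bend = kt * 50 / rise,          # pN nm / rad^2 (tilt, roll)
    k_twist = kt * 100 / rise,        # pN nm / rad^2
    crossover_rot_soften = 10,        # rotational softening factor
    ss_persistence_length = 1,        # nm, single-stranded DNA
    ss_contour_per_nt = 0.63,         # nm per nucleotide
    helix_pitch = 2.5,                # nm, inter-helix distance in lattices
    hydro_radius = 1.1,               # nm
    q_eff = 0.48,                     # effective charge per bp, units of e
    bjerrum_length = 0.714,           # nm (water, 300 K)
    elec_cutoff_debye = 3,            # cutoff as multiple of the Debye length
    morse = list(epsilon = 42.79, a = 2.668, r0 = 0.3742),
    temperature = temperature
  )
}

# Per-step 6x6 stiffness matrices, diagonal by default.
step_stiffness_matrix <- function(params = default_parameter_table()) {
  diag(c(params$k_shear, params$k_shear, params$k_stretch,
         params$k_bend, params$k_bend, params$k_twist))
}

# Crossover junctions are the flexible spots of an origami lattice: the
# whole 6x6 table is softened relative to an intrahelical step. Softening the
# translations matters mechanically and numerically alike, because the
# 2.5 nm inter-helix lever arm converts translational stiffness into a large
# effective rotational stiffness on the two joined nodes.
crossover_stiffness_matrix <- function(params = default_parameter_table()) {
  s <- params$crossover_rot_soften
  diag(c(params$k_shear / s, params$k_shear / s, params$k_stretch / s,
         params$k_bend / s, params$k_bend / s, params$k_twist / s))
}

# Entropic-spring constant for an ssDNA connection of n_nt nucleotides:
# k = 3 kBT / (2 Lp Lc).
ssdna_spring_constant <- function(n_nt, params = default_parameter_table()) {
  lc <- n_nt * params$ss_contour_per_nt
  3 * kBT(params$temperature) / (2 * params$ss_persistence_length * lc)
}
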