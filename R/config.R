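#' Coarse-grained geometry and energy configuration
#'
#' Geometry constants of the two-bead-per-nucleotide RNA model and the force
#' constants of its energy terms.  Duplex regions are ideal A-form helices:
#' 11 base pairs per turn with a 2.73 Angstrom rise, giving a pitch of
#' ~30 Angstrom, and backbone beads at 12.5 Angstrom from the helix axis,
#' giving a duplex width (twice the maximal radial backbone distance) of
#' ~25 Angstrom.  All distances are in Angstrom, energies in units of kBT.
#'
#' @param bp_per_turn Base pairs per helical turn of the ideal A-form duplex.
#' @param rise Axial rise per base pair (Angstrom).
#' @param backbone_radius Radial distance of backbone beads from the helix
#'   axis (Angstrom); the duplex width is twice this value.
#' @param base_radius Radial distance of base beads from the helix axis.
#' @param bead_radius_backbone,bead_radius_base Hard-sphere radii used when
#'   rendering AFM surfaces (Angstrom).
#' @param strand_phase Azimuthal offset (degrees) of the second strand's
#'   backbone relative to its pairing partner; controls the groove asymmetry
#'   that the AFM tip senses as corrugation.
#' @param link_len Maximal comfortable span of one single-stranded link
#'   (Angstrom).
#' @param clash_dist Minimal allowed distance between non-bonded beads.
#' @param junction_gap Distance from a junction centre to the start of each
#'   emanating helix axis (Angstrom).
#' @param loop_gap Distance from a helix inner end to the hairpin-loop centre.
#' @param k_length,k_angle,k_dihedral Harmonic force constants for covalent
#'   bond-length (kBT/A^2), angle and dihedral (kBT/rad^2) terms.
#' @param k_angle_linker Weak angle constant applied to single-stranded
#'   linker triples.
#' @param k_pair,k_stack Force constants of the flat-bottom distance wells
#'   restraining base pairing and intra-helix stacking.
#' @param pair_halfwidth,stack_halfwidth Half-widths of those flat bottoms
#'   (Angstrom).
#' @param softcore_k Height of the soft-core repulsion at zero separation
#'   (kBT); clashes are expensive but always finite.
#' @param dh_amp,dh_lambda,dh_cut Amplitude (kBT), screening length and
#'   cutoff (Angstrom) of the screened-charge backbone repulsion.
#'
#' @return A list of class `cg_config`.
#' @export
cg_config <- function(bp_per_turn = 11, rise = 2.73,
                      backbone_radius = 12.5, base_radius = 4.0,
                      bead_radius_backbone = 4.0, bead_radius_base = 3.5,
                      strand_phase = -140, link_len = 6.5, clash_dist = 6.0,
                      junction_gap = 14.0, loop_gap = 6.0,
                      k_length = 10, k_angle = 5, k_dihedral = 2,
                      k_angle_linker = 0.3, k_pair = 5, k_stack = 5,
                      pair_halfwidth = 1.0, stack_halfwidth = 0.75,
                      softcore_k = 2000, dh_amp = 0.5, dh_lambda = 10,
                      dh_cut = 30) {
  cfg <- list(bp_per_turn = bp_per_turn, rise = rise,
              backbone_radius = backbone_radius, base_radius = base_radius,
              bead_radius_backbone = bead_radius_backbone,
              bead_radius_base = bead_radius_base,
              strand_phase = strand_phase, link_len = link_len,
              clash_dist = clash_dist, junction_gap = junction_gap,
              loop_gap = loop_gap, k_length = k_length, k_angle = k_angle,
              k_dihedral = k_dihedral, k_angle_linker = k_angle_linker,
              k_pair = k_pair, k_stack = k_stack,
              pair_halfwidth = pair_halfwidth,
              stack_halfwidth = stack_halfwidth,
              softcore_k = softcore_k, dh_amp = dh_amp,
              dh_lambda = dh_lambda, dh_cut = dh_cut)
  class(cfg) <- "cg_config"
  cfg
}

#' Scaling factors of the dynamic-fitting objective
#'
#' Weights of the total energy
#' `E_total = V_AFM + theta_c * (E_angle + E_length + E_dih) +
#'  theta_stacking * E_stacking + theta_pairing * E_pairing +
#'  theta_contact * E_contact`,
#' where `V_AFM = theta_afm * N * kBT * (1 - C_AFM)` couples the image
#' cross-correlation `C_AFM` into the energy and `N` is the total bead count.
#' The weights are empirical; the defaults are chosen so that a noiseless
#' phantom image is recovered by the default annealing schedule.
#'
#' @param theta_afm Scaling of the AFM pseudopotential (dimensionless).
#' @param theta_c Scaling of the covalent terms.
#' @param theta_stacking,theta_pairing,theta_contact Scalings of the
#'   noncovalent terms.
#' @param kBT Energy unit; all force constants are expressed in kBT, so the
#'   default is 1.
#'
#' @return A list of class `fit_weights`.
#' @export
fit_weights <- function(theta_afm = 3, theta_c = 1, theta_stacking = 1,
                        theta_pairing = 1, theta_contact = 0.5, kBT = 1) {
  stopifnot(theta_afm >= 0, theta_c >= 0, theta_stacking >= 0,
            theta_pairing >= 0, theta_contact >= 0, kBT > 0)
  w <- list(theta_afm = theta_afm, theta_c = theta_c,
            theta_stacking = theta_stacking, theta_pairing = theta_pairing,
            theta_contact = theta_contact, kBT = kBT)
  class(w) <- "fit_weights"
  w
}
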