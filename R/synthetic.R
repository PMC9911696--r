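#' Phantom specifications
#'
#' Ground-truth test molecules: an 80-nt three-helix-junction RNA whose
#' junction geometry presets produce visually distinct topologies on the
#' mica plane, plus a small hairpin.  Presets:
#' \describe{
#'   \item{Y}{arms fanned at +/- 75 degrees: a Y-shaped particle}
#'   \item{candy}{one arm coaxially stacked on the closing helix, the other
#'     perpendicular: an elongated particle with a side lobe}
#'   \item{compact}{one arm swept back against the closing helix, the other coaxial:
#'     a folded, compact footprint}
#'   \item{hairpin}{a 14-nt stem-loop used for cheap unit tests}
#' }
#'
#' @param preset Preset name.
#' @return List with `name`, `db` (dot-bracket), `seq`,
#'   `junction_geometry`.
#' @export
phantom_spec <- function(preset = c("Y", "candy", "compact", "hairpin")) {
  preset <- match.arg(preset)
  if (preset == "hairpin") {
    db <- "(((((....)))))"
    return(list(name = preset, db = db, seq = complementary_seq(db),
                junction_geometry = NULL))
  }
  db <- paste0("...",                     # 5' tail (3 nt)
               strrep("(", 10),           # closing helix P1 (10 bp)
               ".....",                   # junction linker (5 nt)
               strrep("(", 9), "....", strrep(")", 9),  # arm helix + loop
               ".....",                   # junction linker
               strrep("(", 9), "....", strrep(")", 9),  # arm helix + loop
               ".....",                   # junction linker
               strrep(")", 10),           # P1 3' strand
               "..")                      # 3' tail (2 nt)
  jg <- switch(preset,
               Y = list("1" = c(75, -75)),
               candy = list("1" = c(0, -90)),
               compact = list("1" = c(100, 0)))
  list(name = preset, db = db, seq = complementary_seq(db),
       junction_geometry = jg)
}

# Watson-Crick-consistent sequence for a dot-bracket string: paired
# positions alternate G-C / C-G, unpaired positions are A.
complementary_seq <- function(db) {
  ss_ch <- strsplit(db, "")[[1]]
  n <- length(ss_ch)
  seqv <- rep("A", n)
  stack <- integer(0)
  toggle <- TRUE
  for (i in seq_len(n)) {
    if (ss_ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ss_ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      seqv[j] <- if (toggle) "G" else "C"
      seqv[i] <- if (toggle) "C" else "G"
      toggle <- !toggle
    }
  }
  paste(seqv, collapse = "")
}

#' Build a ground-truth phantom structure
#'
#' Deterministic per (preset, seed): the same spec rebuilds bit-identically.
#' With `chains = 2` a second copy is placed facing the first (rotated 180
#' degrees, offset along x) and the declared kissing-loop partner
#' nucleotides are recorded in attribute `"kl_pairs"` for use as inter-chain
#' pairing restraints.
#'
#' @param spec A [phantom_spec()] (or preset name).
#' @param seed Optional jitter seed forwarded to [assemble_topology()].
#' @param chains 1 (monomer) or 2 (dimer).
#' @param kl_loops For dimers: which loop (1 or 2, in sequence order) of
#'   each monomer forms the kissing-loop contact.
#' @param config A [cg_config()].
#' @return A `cg_structure` (with `ss`); dimers carry `"kl_pairs"`.
#' @export
make_phantom <- function(spec = phantom_spec("Y"), seed = NULL, chains = 1,
                         kl_loops = c(1, 1), config = cg_config()) {
  if (is.character(spec)) spec <- phantom_spec(spec)
  ss <- parse_dotbracket(spec$db, spec$seq)
  cg <- assemble_topology(ss, junction_geometry = spec$junction_geometry,
                          seed = seed, config = config)
  attr(cg, "preset") <- spec$name
  if (chains == 1) return(cg)
  if (chains != 2) stop("chains must be 1 or 2")
  n <- ss$n
  span <- diff(range(cg$xyz[, 1]))
  other <- transform_cg(cg, rotz(pi),
                        pivot = colMeans(cg$xyz),
                        translation = c(span + 35, 0, 0))
  xyz <- rbind(cg$xyz, other$xyz)
  nt <- c(cg$nt, other$nt + n)
  chain <- c(rep(1L, n_beads(cg)), rep(2L, n_beads(other)))
  helix <- c(cg$helix, other$helix)
  bonds <- rbind(cg$bonds, other$bonds + n_beads(cg))
  dimer <- new_cg_structure(xyz, nt, chain, rep(cg$role, 2), helix, bonds,
                            ss = NULL, config = config)
  attr(dimer, "monomer_ss") <- ss
  loops <- split(which(is.na(ss$paired) & seq_len(n) > 3 &
                         seq_len(n) < n - 2),
                 cumsum(c(1, diff(which(is.na(ss$paired) & seq_len(n) > 3 &
                                          seq_len(n) < n - 2)) != 1)))
  hp <- Filter(function(v) length(v) == 4, loops)  # hairpin loops
  if (length(hp) >= max(kl_loops)) {
    la <- hp[[kl_loops[1]]]
    lb <- hp[[kl_loops[2]]] + n
    attr(dimer, "kl_pairs") <- cbind(la, rev(lb))
  }
  attr(dimer, "preset") <- paste0(spec$name, "-dimer")
  dimer
}

#' Render a noisy AFM image ladder for a structure
#'
#' Renders once, then adds each noise level with its own deterministic
#' sub-seed.  Level 0 may be included to carry the clean image.
#'
#' @param cg Ground-truth `cg_structure`.
#' @param tip A [tip_model()].
#' @param levels Percent noise levels (default: the twelve-level ladder).
#' @param seed Base seed; level k uses `seed + k`.
#' @param pixel_size Angstrom per pixel.
#' @return Named list of `afm_image`s (`level_5`, ...), with the clean
#'   render as attribute `"clean"` and the generation parameters as
#'   attribute `"manifest"`.
#' @export
make_afm_ladder <- function(cg, tip = tip_model(),
                            levels = noise_ladder_levels(), seed = 1,
                            pixel_size = 5) {
  clean <- render_surface(cg, tip = tip, pixel_size = pixel_size)
  out <- lapply(seq_along(levels), function(k) {
    if (levels[k] == 0) clean else add_noise(clean, levels[k],
                                             seed = seed + k)
  })
  names(out) <- paste0("level_", levels)
  attr(out, "clean") <- clean
  attr(out, "manifest") <- list(levels = levels, seed = seed,
                                tip_radius_nm = tip$radius,
                                pixel_size = pixel_size)
  out
}

#' Synthesize a SAXS mixture of known volume fractions
#'
#' Computes per-structure Debye curves on a common grid, mixes them with
#' the stated fractions, attaches a Poisson-like error model
#' `sigma = noise_frac * (sqrt(I * I(0)) + floor_frac * I(0))` and, unless
#' `noiseless`, adds Gaussian noise of exactly that sigma -- so the truth
#' scores chi-square ~ 1 against the mixture.
#'
#' @param structures List of `cg_structure`s (the conformers).
#' @param fractions Volume fractions (simplex).
#' @param q_grid Scattering grid.
#' @param noise_frac Relative error scale.
#' @param floor_frac Error floor as a fraction of I(0).
#' @param seed RNG seed for the noise draw.
#' @param noiseless Skip the noise draw (sigma still attached).
#' @return List with `curves` (per-conformer `saxs_profile`s), `mixture`
#'   (noisy experimental-like profile with sigma), `true_mixture`
#'   (noise-free), `fractions`, `manifest`.
#' @export
make_saxs_mixture <- function(structures, fractions,
                              q_grid = default_q_grid(),
                              noise_frac = 0.001, floor_frac = 0.001,
                              seed = 1, noiseless = FALSE) {
  stopifnot(length(structures) == length(fractions))
  curves <- lapply(structures, debye_profile, q_grid = q_grid)
  truth <- synthesize_ensemble(curves, fractions)
  i0 <- truth$I[1]
  sigma <- noise_frac * (sqrt(pmax(truth$I, 0) * i0) + floor_frac * i0)
  I_obs <- if (noiseless) truth$I else
    truth$I + with_seed(seed, rnorm(length(sigma), 0, sigma))
  list(curves = curves,
       mixture = saxs_profile(q_grid, I_obs, sigma),
       true_mixture = truth,
       fractions = fractions,
       manifest = list(fractions = fractions, noise_frac = noise_frac,
                       floor_frac = floor_frac, seed = seed,
                       noiseless = noiseless, n_q = length(q_grid)))
}

#' Generate a two-component synthetic ITC thermogram
#'
#' Component 1 is a one-site exothermic binder (typical sigmoidal
#' isotherm); component 2 is a two-site endothermic-then-exothermic binder
#' (induced-fit-like signature).  Each injection's heat is rendered as a
#' Gaussian power pulse -- component 1 fast (narrow, early), component 2
#' slow (broad, late), so the two mix as two well-separated rank-1 terms --
#' and white noise is added at the stated signal-to-noise ratio.
#'
#' @param p1 List `N`, `kd`, `dh` of the exothermic component.
#' @param p2 List of two site lists (`N`, `kd`, `dh` each), endo + exo.
#' @param weights Mixing weights (molar fractions of the two populations).
#' @param snr Peak signal-to-noise ratio; `Inf` disables noise.
#' @param n_inj Number of injections.
#' @param m Time samples per injection trace.
#' @param dt Sampling interval (s).
#' @param seed RNG seed.
#' @param cell_conc,syringe_conc,inj_vol,cell_vol Titration schedule.
#' @return A `thermogram` with attributes `"truth"` (list with the
#'   ground-truth per-component isotherms and parameters) and
#'   `"manifest"`.
#' @export
make_itc_two_component <- function(
    p1 = list(N = 1, kd = 1e-6, dh = -10),
    p2 = list(list(N = 0.5, kd = 5e-7, dh = 15),
              list(N = 0.5, kd = 5e-6, dh = -25)),
    weights = c(0.7, 0.2), snr = 20, n_inj = 25, m = 120, dt = 1,
    seed = 1, cell_conc = 70e-6, syringe_conc = 700e-6, inj_vol = 2,
    cell_vol = 200) {
  ndh1 <- model_isotherm(list(p1), n_inj, inj_vol, cell_vol, cell_conc,
                         syringe_conc)$ndh
  ndh2 <- model_isotherm(p2, n_inj, inj_vol, cell_vol, cell_conc,
                         syringe_conc)$ndh
  moles <- syringe_conc * rep_len(inj_vol, n_inj) * 1e-6
  heat1 <- weights[1] * ndh1 * moles * 1e9  # kcal -> microcal
  heat2 <- weights[2] * ndh2 * moles * 1e9
  tt <- (seq_len(m) - 1) * dt
  shape <- function(center, width) {
    s <- exp(-(tt - center)^2 / (2 * width^2))
    s / (sum(s) * dt)  # unit area under trapezoid-free Riemann sum
  }
  s1 <- shape(0.25 * m * dt, 0.04 * m * dt)
  s2 <- shape(0.50 * m * dt, 0.06 * m * dt)
  M <- outer(s1, heat1) + outer(s2, heat2)
  if (is.finite(snr) && max(abs(M)) > 0) {
    M <- M + with_seed(seed, matrix(rnorm(length(M), 0,
                                          max(abs(M)) / snr), nrow(M)))
  }
  th <- thermogram(M, dt = dt, inj_vol = inj_vol, cell_conc = cell_conc,
                   syringe_conc = syringe_conc, cell_vol = cell_vol)
  attr(th, "truth") <- list(ndh1 = weights[1] * ndh1,
                            ndh2 = weights[2] * ndh2,
                            ndh_total = weights[1] * ndh1 + weights[2] * ndh2,
                            p1 = p1, p2 = p2, weights = weights)
  attr(th, "manifest") <- list(p1 = p1, p2 = p2, weights = weights,
                               snr = snr, n_inj = n_inj, m = m, dt = dt,
                               seed = seed, cell_conc = cell_conc,
                               syringe_conc = syringe_conc,
                               inj_vol = inj_vol, cell_vol = cell_vol)
  th
}

#' Generate a complete synthetic scenario bundle
#'
#' Everything the pipeline consumes, generated from one seed with the full
#' parameter manifest attached: ground-truth phantoms of the three junction
#' presets, a twelve-level noisy AFM ladder of the first, a three-component
#' SAXS mixture, and a two-component ITC thermogram.  Regenerating from the
#' manifest reproduces the bundle bit-identically.
#'
#' @param seed Master seed.
#' @param presets Phantom presets entering the bundle.
#' @param fractions SAXS mixture volume fractions (one per preset).
#' @param noise_levels AFM ladder levels.
#' @return A list of class `scenario_bundle` with `phantoms`, `afm_ladder`,
#'   `saxs`, `itc` and `manifest`.
#' @export
make_scenario_bundle <- function(seed = 1,
                                 presets = c("Y", "candy", "compact"),
                                 fractions = c(0.2, 0.3, 0.5),
                                 noise_levels = noise_ladder_levels()) {
  manifest <- list(seed = seed, presets = presets, fractions = fractions,
                   noise_levels = noise_levels)
  phantoms <- lapply(presets, function(p) make_phantom(p, seed = seed))
  names(phantoms) <- presets
  bundle <- list(
    phantoms = phantoms,
    afm_ladder = make_afm_ladder(phantoms[[1]], levels = noise_levels,
                                 seed = seed * 101L),
    saxs = make_saxs_mixture(phantoms, fractions, seed = seed * 211L),
    itc = make_itc_two_component(seed = seed * 307L),
    manifest = manifest)
  class(bundle) <- "scenario_bundle"
  bundle
}

#' Regenerate a bundle from its manifest
#'
#' @param manifest The `manifest` element of a [make_scenario_bundle()].
#' @return A `scenario_bundle` identical to the original.
#' @export
regenerate_bundle <- function(manifest) {
  make_scenario_bundle(seed = manifest$seed, presets = manifest$presets,
                       fractions = manifest$fractions,
                       noise_levels = manifest$noise_levels)
}
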