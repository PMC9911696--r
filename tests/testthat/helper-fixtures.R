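# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, fixture_env)) assign(name, build(), fixture_env)
  get(name, fixture_env)
}

phantom_Y <- function() fixture("phantom_Y", function() make_phantom("Y"))
phantom_candy <- function() fixture("phantom_candy",
                                    function() make_phantom("candy"))
phantom_compact <- function() fixture("phantom_compact",
                                      function() make_phantom("compact"))
phantom_hairpin <- function() fixture("phantom_hairpin",
                                      function() make_phantom("hairpin"))

phantom_set <- function() list(phantom_Y(), phantom_candy(),
                               phantom_compact())

# deterministic lattice fill of a sphere, used as a scattering phantom
sphere_beads <- function(radius = 50, spacing = 8) {
  g <- seq(-radius, radius, by = spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
}

# single free-standing bead as a minimal renderable "molecule"
single_bead_cg <- function(role = "BB") {
  rnatopo:::new_cg_structure(matrix(0, 1, 3), 1L, 1L, role, NA_integer_,
                             matrix(integer(0), ncol = 2),
                             config = cg_config())
}

complementary_seq_test <- function(db) rnatopo:::complementary_seq(db)

make_isotherm <- function(ndh, ratio) {
  structure(data.frame(injection = seq_along(ndh), ratio = ratio,
                       ndh = ndh),
            class = c("isotherm", "data.frame"))
}

itc_default_schedule <- list(cell = 70e-6, syringe = 700e-6, inj_vol = 2,
                             cell_vol = 200)
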