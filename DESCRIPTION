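Package: bonefiber
Title: Building and Mechanically Testing Mineralized Collagen Fiber Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing all-atom models of bone at the nanoscale:
    a collagen fibril in a triclinic unit cell is unwrapped into a nanofiber
    that is periodic only along its axis, replicated laterally into a fiber
    bundle, and mineralized by packing hydroxyapatite, water and ions into
    the intra- and extra-fibrillar volumes according to target mass
    fractions. Includes triclinic-cell algebra (fractional transforms,
    periodic wrapping, minimum-image distances, replication), distance-based
    bond perception and periodic-bond classification, a seeded
    rejection-sampling molecular packer, a composition solver that converts
    mass fractions into molecule budgets, and the mechanics of simulated
    uniaxial tensile tests: strain schedules, the virial stress tensor, and
    Young's-modulus estimation by linear regression over the elastic strain
    window. A minimal molecular-dynamics engine (velocity Verlet, Langevin
    thermostat, harmonic bonds plus Lennard-Jones interactions) makes the
    whole protocol executable at desk scale on synthetic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
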