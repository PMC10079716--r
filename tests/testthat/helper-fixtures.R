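# Shared fixtures and independent oracles.

g1150 <- beam_geometry(1150)

# Independent closed-form inversion of the sphere-shadow measurements: the two
# shadow edges sit at radial positions rho_c -/+ M/2, whose ray angles are
# theta -/+ alpha; atan of the edge tangents gives theta and alpha directly.
# Kept separate from the package's fixed-point solver on purpose.
closed_form_single_marker <- function(major, radial, diameter, sdd) {
  t_out <- (radial + major / 2) / sdd
  t_in <- (radial - major / 2) / sdd
  theta <- (atan(t_out) + atan(t_in)) / 2
  alpha <- (atan(t_out) - atan(t_in)) / 2
  dist <- (diameter / 2) / sin(alpha)
  list(cf = 100 * sdd / (dist * cos(theta)),
       depth = dist * cos(theta),
       theta_deg = theta * 180 / pi)
}

# random valid sphere for property tests (assumes RNG seeded by caller)
random_sphere <- function(sdd = 1150) {
  repeat {
    r <- runif(1, 5, 20)
    z <- runif(1, 400, sdd - 100)
    x <- runif(1, -250, 250)
    y <- runif(1, -250, 250)
    d <- sqrt(x^2 + y^2 + z^2)
    if (z - r <= 0 || z + r >= sdd || d <= r) next
    theta <- acos(z / d)
    alpha <- asin(r / d)
    if (theta + alpha < pi / 2 - 0.05) {
      return(sphere3d(c(x, y, z), 2 * r))
    }
  }
}

# noiseless default study, built once per test run
.fixtures <- new.env(parent = emptyenv())

default_records <- function() {
  if (is.null(.fixtures$records)) .fixtures$records <- generate_study()
  .fixtures$records
}

default_table <- function() {
  if (is.null(.fixtures$table)) {
    .fixtures$table <- compute_study_table(default_records())
  }
  .fixtures$table
}
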