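# single neutral free bead: minimal hand-built system for integrator checks
one_bead_system <- function() {
  structure(list(
    beads = tibble::tibble(id = 1L, molecule_id = 1L, dendrimer_id = NA_integer_,
                           species = "surfactant-counterion", type = 7L, charge = 0),
    bonds = tibble::tibble(i = integer(), j = integer(), type = integer()),
    n_beads = 1L, n_d = 0L, n_s = 0L, N_t = 0L, N_d = 0L
  ), class = "md_system")
}

# 52-bead WCA gas: surfactant chains with the bonds stripped, charges unused
wca_gas <- function(L = 8, seed = 5) {
  asm <- assemble_system(n_d = 0, n_s = 13, L = L, seed = seed)
  asm$system$bonds <- asm$system$bonds[0, ]
  asm
}

test_that("forces are exact negative gradients of the potential", {
  asm <- assemble_system(n_d = 1, n_s = 6, G = 1, S = 2, L = 12, seed = 3)
  ff <- force_field(eps_tt = 1.5)
  set.seed(2)
  for (meth in c("none", "cutoff", "ewald")) {
    f0 <- compute_forces(asm$system, asm$frame, ff, coulomb = meth)
    for (k in 1:8) {
      i <- sample(asm$system$n_beads, 1)
      dim <- sample(3, 1)
      h <- 1e-5
      pp <- asm$frame$positions; pp[i, dim] <- pp[i, dim] + h
      pm <- asm$frame$positions; pm[i, dim] <- pm[i, dim] - h
      ep <- compute_forces(asm$system, md_frame(pp, 12), ff, meth)$epot
      em <- compute_forces(asm$system, md_frame(pm, 12), ff, meth)$epot
      fnum <- -(ep - em) / (2 * h)
      expect_lt(abs(fnum - f0$forces[i, dim]) / max(1, abs(f0$forces[i, dim])),
                1e-6)
    }
    # Newton's third law: pair forces sum to zero
    expect_lt(max(abs(colSums(f0$forces))), 1e-10)
  }
})

test_that("a free bead with no friction moves ballistically", {
  sys <- one_bead_system()
  fr <- md_frame(matrix(c(1, 1, 1), 1), 20)
  v <- matrix(c(0.3, -0.2, 0.1), 1)
  tr <- run_langevin(sys, fr, force_field(gamma_star = 0), n_steps = 100,
                     stride = 0, velocities = v, coulomb = "none")
  expect_equal(tr$final$positions[1, ], c(1, 1, 1) + 100 * 0.005 * v[1, ],
               tolerance = 1e-12)
})

test_that("a FENE dimer oscillates at the small-amplitude analytic period", {
  # pure FENE (LJ off): linearizing U = -k R0^2/2 ln(1 - r^2/R0^2) at r -> 0
  # gives U ~ k r^2 / 2, so the separation obeys mu r'' = -k r with
  # mu = m/2: omega = sqrt(2 k / m), period 2 pi / sqrt(60)
  sys <- build_system(0, 1)
  sys$beads <- sys$beads[1:2, ]
  sys$beads$charge <- c(0, 0)
  sys$bonds <- sys$bonds[1, ]
  sys$n_beads <- 2L
  pos <- rbind(c(10, 10, 10), c(10.05, 10, 10))
  ff <- force_field(eps_tt = 0, eps_other = 0, gamma_star = 0, dt_star = 0.001)
  tr <- run_langevin(sys, md_frame(pos, 20), ff, n_steps = 2000, stride = 1,
                     velocities = matrix(0, 2, 3), coulomb = "none")
  sep <- vapply(tr$frames, function(f) f$positions[2, 1] - f$positions[1, 1],
                numeric(1))
  # period from the first two sign changes of the separation velocity
  crossings <- which(diff(sign(sep)) != 0)
  period <- 2 * diff(crossings[1:2]) * 0.001
  expect_equal(period, 2 * pi / sqrt(60), tolerance = 0.01)
})

test_that("without a thermostat the integrator conserves energy", {
  asm <- wca_gas()
  set.seed(6)
  eq <- run_langevin(asm$system, asm$frame, force_field(eps_tt = 1),
                     n_steps = 5e3, stride = 0, coulomb = "none")
  fr <- md_frame(eq$final$positions, 8)
  tr <- run_langevin(asm$system, fr, force_field(eps_tt = 1, gamma_star = 0),
                     n_steps = 1e4, stride = 200,
                     velocities = eq$final$velocities, coulomb = "none")
  E <- tr$log$pe + tr$log$ke
  expect_lt((max(E) - min(E)) / asm$system$n_beads, 1e-3)
})

test_that("the Langevin thermostat holds the kinetic temperature at T*", {
  asm <- wca_gas()
  tr <- run_langevin(asm$system, asm$frame, force_field(eps_tt = 1),
                     n_steps = 5e4, stride = 100, seed = 7, coulomb = "none")
  Tbar <- mean(tr$log$temperature[tr$log$step > 5e3])
  expect_gt(Tbar, 0.95)
  expect_lt(Tbar, 1.05)
})

test_that("runs are reproducible and restartable bitwise under one seed discipline", {
  asm <- wca_gas()
  ff <- force_field(eps_tt = 1)
  set.seed(9)
  whole <- run_langevin(asm$system, asm$frame, ff, n_steps = 200, stride = 100,
                        coulomb = "none")
  set.seed(9)
  part1 <- run_langevin(asm$system, asm$frame, ff, n_steps = 100, stride = 100,
                        coulomb = "none")
  part2 <- continue_langevin(part1, 100, stride = 100)
  expect_identical(part2$final$positions, whole$final$positions)
  expect_identical(part2$final$velocities, whole$final$velocities)
  # zero steps returns only the initial frame
  z <- run_langevin(asm$system, asm$frame, ff, n_steps = 0, stride = 100,
                    seed = 1, coulomb = "none")
  expect_length(z$frames, 1)
  expect_identical(z$frames[[1]]$positions, asm$frame$positions)
})

test_that("bond overstretch aborts with a diagnostic", {
  sys <- build_system(0, 1)
  sys$beads <- sys$beads[1:2, ]
  sys$beads$charge <- c(0, 0)
  sys$bonds <- sys$bonds[1, ]
  sys$n_beads <- 2L
  pos <- rbind(c(5, 5, 5), c(6.4, 5, 5)) # bond at 1.4, close to R0 = 1.5
  v <- rbind(c(-50, 0, 0), c(50, 0, 0))
  expect_error(
    run_langevin(sys, md_frame(pos, 20), force_field(eps_tt = 0, eps_other = 0,
                                                     gamma_star = 0),
                 n_steps = 100, stride = 0, velocities = v, coulomb = "none"),
    "overstretched"
  )
})

test_that("Ewald solver matches an independent direct Ewald sum and the bare Coulomb limit", {
  # random neutral charge set vs plain-R Ewald at different splitting params
  set.seed(31)
  n <- 40
  pos <- matrix(runif(3 * n, 0, 8), n, 3)
  q <- rep(c(1, -1), n / 2)
  got <- ewald_coulomb(pos, q, box_L = 8, rc = 4, tol = 1e-6)
  ref <- oracle_ewald_energy(pos, q, L = 8, alpha = 1.1, kmax = 11, rc = 3.99)
  expect_equal(got$energy, ref, tolerance = 1e-5)
  # forces are gradients of the Ewald energy
  for (k in 1:5) {
    i <- sample(n, 1); dim <- sample(3, 1); h <- 1e-5
    pp <- pos; pp[i, dim] <- pp[i, dim] + h
    pm <- pos; pm[i, dim] <- pm[i, dim] - h
    fnum <- -(ewald_coulomb(pp, q, 8, 4, 1e-6)$energy -
                ewald_coulomb(pm, q, 8, 4, 1e-6)$energy) / (2 * h)
    expect_equal(fnum, got$forces[i, dim], tolerance = 1e-4)
  }
  # two opposite unit charges in a large box: force ~ bare Coulomb derivative
  p2 <- rbind(c(30, 30, 30), c(31, 30, 30))
  f2 <- ewald_coulomb(p2, c(1, -1), box_L = 60, rc = 20, tol = 1e-6)
  expect_equal(abs(f2$forces[1, 1]), 1, tolerance = 1e-4) # |F| = lambda_B*/r^2
  # all charges zero: zero forces
  f0 <- ewald_coulomb(pos, rep(0, n), 8, 4, 1e-4)
  expect_equal(max(abs(f0$forces)), 0)
  expect_error(ewald_coulomb(pos, rep(1, n), 8, 4, 1e-4), "electroneutral")
})

test_that("Ewald energy of a rock-salt lattice reproduces the Madelung constant", {
  nside <- 4
  g <- as.matrix(expand.grid(x = 0:(nside - 1), y = 0:(nside - 1),
                             z = 0:(nside - 1)))
  q <- (-1)^rowSums(g)
  ew <- ewald_coulomb(g, q, box_L = nside, rc = 2, tol = 1e-7)
  # lattice energy per ion is -M/2 in units of q^2/a
  expect_equal(-2 * ew$energy / nrow(g), 1.747565, tolerance = 1e-5)
})

test_that("neighbor search equals the brute-force distance matrix", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(40:200, 1)
    L <- runif(1, 6, 15)
    rc <- runif(1, 1, 2.5)
    A <- matrix(runif(3 * n, -L, 2 * L), n, 3) # deliberately unwrapped
    pr <- neighbor_pairs(A, NULL, L, rc)
    D <- oracle_dist(A, A, L)
    want <- which(D < rc & upper.tri(D), arr.ind = TRUE)
    expect_identical(nrow(pr), nrow(want))
    got_keys <- paste(pmin(pr$i, pr$j), pmax(pr$i, pr$j))
    want_keys <- paste(want[, 1], want[, 2])
    expect_setequal(got_keys, want_keys)
  }
})
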