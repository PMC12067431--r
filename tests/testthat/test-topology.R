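# independent count oracles from the tree growth rules: spacers double each
# generation starting from 4 (two per core bead), each spacer holds S beads
oracle_N_t <- function(G) 2^(G + 1)
oracle_N_d <- function(G, S) 2 + S * (2^(G + 2) - 4)

test_that("dendrimer terminal and monomer counts match the enumeration oracle", {
  for (G in c(1, 2, 3, 5, 7)) {
    d <- dendrimer_topology(G, 4)
    expect_identical(attr(d, "N_t"), as.integer(oracle_N_t(G)))
    expect_identical(attr(d, "N_d"), as.integer(oracle_N_d(G, 4)))
  }
  expect_identical(attr(dendrimer_topology(3, 4), "N_t"), 16L)
  expect_identical(attr(dendrimer_topology(7, 4), "N_t"), 256L)
})

test_that("the dendrimer bond graph is a trifunctional tree with +1 terminals", {
  d <- dendrimer_topology(2, 3)
  n <- nrow(d$beads)
  expect_identical(nrow(d$bonds), n - 1L) # tree edge count
  # acyclic and connected: n-1 edges + single component
  comp <- oracle_components(d$bonds, n)
  expect_true(all(comp == 1L))
  deg <- tabulate(c(d$bonds[, 1], d$bonds[, 2]), nbins = n)
  expect_true(all(deg[d$beads$species == "dendrimer-core"] == 3))
  expect_true(all(deg[d$beads$species == "dendrimer-terminal"] == 1))
  branch <- deg == 3 & d$beads$species == "dendrimer-interior"
  spacer <- deg == 2
  expect_identical(sum(branch) + sum(spacer) + 2L +
                     sum(d$beads$species == "dendrimer-terminal"), n)
  expect_true(all(d$beads$charge[d$beads$species == "dendrimer-terminal"] == 1))
  expect_true(all(d$beads$charge[d$beads$species != "dendrimer-terminal"] == 0))
  expect_error(dendrimer_topology(0, 4), "integers >= 1")
  expect_error(dendrimer_topology(3, -1), "integers >= 1")
})

test_that("terminal count is independent of the spacer length", {
  for (S in 1:6) {
    expect_identical(attr(dendrimer_topology(3, S), "N_t"), 16L)
  }
  # G1 S1 degenerates to the bare branch skeleton, still a tree
  d <- dendrimer_topology(1, 1)
  expect_identical(nrow(d$bonds), nrow(d$beads) - 1L)
})

test_that("a surfactant is a 4-bead path with a single -1 head", {
  s <- surfactant_topology()
  expect_identical(nrow(s$beads), 4L)
  expect_identical(nrow(s$bonds), 3L)
  expect_equal(sum(s$beads$charge), -1)
  deg <- tabulate(c(s$bonds[, 1], s$bonds[, 2]), nbins = 4)
  expect_identical(sort(deg), c(1L, 1L, 2L, 2L)) # path graph
  expect_identical(s$beads$species[1], "surfactant-head")
})

test_that("assembled systems are electroneutral with the right bookkeeping", {
  sys <- build_system(2, 600, G = 3, S = 4)
  expect_identical(sys$n_beads, 2L * 114L + 4L * 600L + 2L * 16L + 600L)
  expect_equal(sum(sys$beads$charge), 0)
  expect_identical(sum(sys$beads$species == "dendrimer-counterion"), 2L * 16L)
  expect_identical(sum(sys$beads$species == "surfactant-counterion"), 600L)
  # dendrimer-free system
  sys0 <- build_system(0, 1)
  expect_identical(sys0$n_beads, 5L) # 4 chain beads + 1 cation
  expect_equal(sum(sys0$beads$charge), 0)
  # electroneutrality across architectures
  for (G in 1:4) {
    expect_equal(sum(build_system(1, 17, G = G, S = 2)$beads$charge), 0)
  }
})

test_that("assembly placement is deterministic under a fixed seed and respects separations", {
  a1 <- assemble_system(n_d = 1, n_s = 8, G = 1, S = 2, L = 14, seed = 42)
  a2 <- assemble_system(n_d = 1, n_s = 8, G = 1, S = 2, L = 14, seed = 42)
  expect_identical(a1$frame$positions, a2$frame$positions)
  # non-bonded separations at or above the placement threshold
  P <- a1$frame$positions
  D <- oracle_dist(P, P, 14)
  bonded <- matrix(FALSE, nrow(P), nrow(P))
  bonded[as.matrix(a1$system$bonds[, c("i", "j")])] <- TRUE
  bonded <- bonded | t(bonded)
  diag(D) <- Inf
  expect_gt(min(D[!bonded]), 0.8)
  expect_error(assemble_system(n_d = 0, n_s = 500, L = 5, seed = 1),
               "infeasible packing")
})
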