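# two surfactant chains with the closest tail-tail pair at distance `gap`
two_chain_frame <- function(gap, L = 20) {
  sys <- build_system(0, 2)
  pos <- matrix(0, sys$n_beads, 3)
  pos[1, ] <- c(1, 0, 0) # head 1
  pos[2:4, ] <- cbind(2:4, 0, 0) # tails 1
  pos[5, ] <- c(1, gap, 0) # head 2
  pos[6:8, ] <- cbind(2:4, gap, 0) # tails 2
  pos[9:10, ] <- cbind(15, c(1, 3), 0) # the two cations, far away
  list(system = sys, frame = md_frame(pos, L))
}

test_that("the tail-tail contact criterion splits chains into micelles", {
  near <- two_chain_frame(1.4)
  m <- find_micelles(near$frame, near$system)
  expect_identical(nrow(m), 1L)
  expect_identical(m$mass, 2L)
  far <- two_chain_frame(1.6)
  m2 <- find_micelles(far$frame, far$system)
  expect_identical(nrow(m2), 2L)
  expect_identical(m2$mass, c(1L, 1L)) # two unimers
  # strictness: exactly at r* is not bound
  at <- two_chain_frame(1.5)
  expect_identical(nrow(find_micelles(at$frame, at$system)), 2L)
})

test_that("planted micelle masses are recovered exactly", {
  sp <- plant_spec(masses = c(1, 1, 5, 20), seed = 4)
  pf <- plant_frame(sp)
  m <- find_micelles(pf$frame, pf$system)
  expect_identical(sort(m$mass), c(1L, 1L, 5L, 20L))
  # partition: chains are covered exactly once
  expect_identical(sort(unlist(m$chains)), 1:27)
})

test_that("head-terminal contacts classify micelles as free, corona or bridge", {
  sp <- plant_spec(masses = c(3, 4, 2), n_d = 2,
                   attach = list(1, c(1, 2), integer(0)), G = 1, S = 1,
                   seed = 8)
  pf <- plant_frame(sp)
  m <- bind_micelles_to_dendrimers(find_micelles(pf$frame, pf$system),
                                   pf$frame, pf$system)
  expect_identical(m$kind[match(1:3, m$micelle)], c("corona", "bridge", "free"))
  expect_identical(m$bound_dendrimers[[match(2, m$micelle)]], c(1L, 2L))
  # mass-1 chain bound to both dendrimers is a bridge micelle of mass 1
  sp1 <- plant_spec(masses = 1, n_d = 2, attach = list(c(1, 2)), G = 1, S = 1,
                    seed = 9)
  pf1 <- plant_frame(sp1)
  m1 <- bind_micelles_to_dendrimers(find_micelles(pf1$frame, pf1$system),
                                    pf1$frame, pf1$system)
  expect_identical(m1$kind, "bridge")
  expect_identical(m1$mass, 1L)
})

test_that("mixed clusters are components of the bipartite binding graph", {
  # bridge(10) joining both dendrimers plus corona(5) on dendrimer 1
  sp <- plant_spec(masses = c(10, 5), n_d = 2, attach = list(c(1, 2), 1),
                   G = 1, S = 1, seed = 10)
  pf <- plant_frame(sp)
  ag <- analyze_frame(pf$frame, pf$system)
  expect_identical(nrow(ag), 1L)
  expect_identical(ag$s, 15L)
  expect_identical(ag$d, 2L)
  expect_identical(ag$n_br, 1L)
  expect_identical(ag$n_cor, 1L)
  # two dendrimers with one corona each -> two (s, 1) aggregates
  sp2 <- plant_spec(masses = c(6, 7), n_d = 2, attach = list(1, 2),
                    G = 1, S = 1, seed = 11)
  ag2 <- with(plant_frame(sp2), analyze_frame(frame, system))
  expect_identical(sort(ag2$s), c(6L, 7L))
  expect_identical(ag2$d, c(1L, 1L))
  # in d = 1 clusters every micelle is corona
  expect_identical(ag2$n_br, c(0L, 0L))
})

test_that("free dendrimers appear as (0,1) aggregates with charge +N_t", {
  sp <- plant_spec(masses = 2, n_d = 2, attach = list(1), G = 1, S = 1,
                   seed = 12)
  pf <- plant_frame(sp)
  ag <- analyze_frame(pf$frame, pf$system)
  free_d <- ag[ag$s == 0, ]
  expect_identical(nrow(free_d), 1L)
  expect_identical(free_d$d, 1L)
  expect_identical(free_d$index, 0L)
  expect_identical(free_d$ch, pf$system$N_t)
})

test_that("counterion condensation counts and exclusive nearest assignment", {
  # ion between two unimers: 1.3 sigma from a bead of chain 1 and 1.4 from
  # chain 2 -> condensed on aggregate 1 only under exclusive assignment,
  # on both when exclusive = FALSE
  sys <- build_system(0, 2)
  pos <- matrix(0, sys$n_beads, 3)
  pos[1:4, ] <- cbind(c(0, 1, 2, 3), 0, 0) # chain 1
  pos[5:8, ] <- cbind(c(0, 1, 2, 3) + 5.7, 0, 0) # chain 2 (gap 2.7 > r*)
  pos[9, ] <- c(4.3, 0, 0) # cation: 1.3 from tail at 3, 1.4 from head at 5.7
  pos[10, ] <- c(15, 15, 15) # second cation far away
  fr <- md_frame(pos, 30)
  ag <- analyze_frame(fr, sys)
  expect_identical(ag$n_sc[order(ag$aggregate)], c(1L, 0L))
  ag2 <- analyze_frame(fr, sys, exclusive = FALSE)
  expect_identical(sort(ag2$n_sc), c(1L, 1L))
  # an ion farther than r* from every bead stays free
  expect_identical(sum(ag$n_sc), 1L)
  expect_identical(sum(ag$n_dc), 0L)
})

test_that("analysis is invariant under global translation and rewrapping", {
  sp <- random_plant_spec(77)
  pf <- plant_frame(sp)
  base <- analyze_frame(pf$frame, pf$system)
  L <- pf$frame$box_L
  for (shift in list(c(3.1, -7.7, 12.9), c(L / 2, L / 2, L / 2))) {
    moved <- md_frame(sweep(pf$frame$positions, 2, shift, `+`), L)
    got <- analyze_frame(moved, pf$system)
    expect_identical(agg_key(got), agg_key(base))
  }
  # unwrapped copies of the same coordinates analyse identically
  unwrapped <- pf$frame$positions + L * matrix(
    sample(-2:2, 3 * nrow(pf$frame$positions), replace = TRUE),
    ncol = 3)
  got <- analyze_frame(md_frame(unwrapped, L), pf$system)
  expect_identical(agg_key(got), agg_key(base))
})

test_that("every frame partitions chains: aggregate s-sums equal n_s", {
  for (seed in 101:110) {
    pf <- plant_frame(random_plant_spec(seed))
    ag <- analyze_frame(pf$frame, pf$system)
    expect_identical(sum(ag$s), sum(pf$system$n_s))
    # absorbed + free chains account for every chain
    expect_identical(absorbed_surfactants(ag) + sum(ag$s[ag$d == 0]),
                     pf$system$n_s)
  }
})

test_that("cluster pipeline agrees with the O(N^2) brute-force oracle", {
  for (seed in 201:215) {
    pf <- plant_frame(random_plant_spec(seed))
    got <- analyze_frame(pf$frame, pf$system)
    want <- oracle_analyze(pf$frame, pf$system)
    expect_identical(agg_key(got), agg_key(want))
    # non-exclusive condensation route agrees too
    got2 <- analyze_frame(pf$frame, pf$system, exclusive = FALSE)
    want2 <- oracle_analyze(pf$frame, pf$system, exclusive = FALSE)
    expect_identical(agg_key(got2), agg_key(want2))
  }
})
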