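#' @importFrom rlang .data
NULL

# species labels and their numeric LAMMPS types
.species_levels <- c(
  "dendrimer-core" = 1L,
  "dendrimer-interior" = 2L,
  "dendrimer-terminal" = 3L,
  "surfactant-head" = 4L,
  "surfactant-tail" = 5L,
  "dendrimer-counterion" = 6L,
  "surfactant-counterion" = 7L
)

.species_charge <- c(
  "dendrimer-core" = 0, "dendrimer-interior" = 0, "dendrimer-terminal" = 1,
  "surfactant-head" = -1, "surfactant-tail" = 0,
  "dendrimer-counterion" = -1, "surfactant-counterion" = 1
)

#' Dendrimer topology
#'
#' Builds the bead-spring tree of a generation-`G`, spacer-`S` dendrimer:
#' a core of two bonded monomers, each a trifunctional branch point spawning
#' two spacers; every spacer consists of `S` bonds (`S - 1` intermediate
#' beads plus its end bead), and branch points double the number of spacers
#' each generation.  The beads ending the generation-`G` spacers are the
#' terminal groups and carry charge +1; all other dendrimer beads are
#' neutral.
#'
#' @param G dendrimer generation, integer >= 1
#' @param S spacer length in bonds, integer >= 1
#' @return a list of class `md_fragment` with elements `beads` (tibble:
#'   `species`, `charge`) and `bonds` (two-column integer matrix of local
#'   bead indices), plus attributes `N_d` (total bead count) and `N_t`
#'   (terminal count), both computed from the explicitly built tree.
#' @examples
#' d <- dendrimer_topology(3, 4)
#' attr(d, "N_t") # 16
#' @export
dendrimer_topology <- function(G, S) {
  if (length(G) != 1 || length(S) != 1 || is.na(G) || is.na(S) ||
      G < 1 || S < 1 || G != round(G) || S != round(S)) {
    stop("`G` and `S` must be integers >= 1", call. = FALSE)
  }
  G <- as.integer(G); S <- as.integer(S)
  species <- c("dendrimer-core", "dendrimer-core")
  bonds_i <- 1L; bonds_j <- 2L
  # grow two spacers per branch point, generation by generation
  frontier <- c(1L, 2L) # beads that spawn spacers at the next generation
  nb <- 2L
  for (gen in seq_len(G)) {
    terminal_gen <- gen == G
    new_frontier <- integer(2L * length(frontier))
    k <- 0L
    for (bp in frontier) {
      for (arm in 1:2) {
        prev <- bp
        for (b in seq_len(S)) {
          nb <- nb + 1L
          sp <- if (b == S) {
            if (terminal_gen) "dendrimer-terminal" else "dendrimer-interior"
          } else "dendrimer-interior"
          species <- c(species, sp)
          bonds_i <- c(bonds_i, prev); bonds_j <- c(bonds_j, nb)
          prev <- nb
        }
        k <- k + 1L
        new_frontier[k] <- prev
      }
    }
    frontier <- new_frontier
  }
  beads <- tibble::tibble(
    species = species,
    charge = unname(.species_charge[species])
  )
  out <- list(beads = beads, bonds = cbind(i = bonds_i, j = bonds_j))
  attr(out, "N_d") <- nrow(beads)
  attr(out, "N_t") <- sum(species == "dendrimer-terminal")
  class(out) <- "md_fragment"
  out
}

#' Surfactant topology
#'
#' One anionic surfactant chain: a monovalent negatively charged head bead
#' followed by three neutral hydrophobic tail beads, joined linearly by
#' three bonds.
#'
#' @return an `md_fragment` (see [dendrimer_topology()]).
#' @export
surfactant_topology <- function() {
  beads <- tibble::tibble(
    species = c("surfactant-head", rep("surfactant-tail", 3)),
    charge = c(-1, 0, 0, 0)
  )
  out <- list(beads = beads, bonds = cbind(i = 1:3, j = 2:4))
  attr(out, "N_d") <- 4L
  attr(out, "N_t") <- 0L
  class(out) <- "md_fragment"
  out
}

#' Molecular system of dendrimers, surfactants and counterions
#'
#' Assembles the full topological description of `n_d` dendrimers and `n_s`
#' surfactant chains plus the counterions required for exact
#' electroneutrality: one monovalent anion per dendrimer terminal group
#' (`n_d * N_t` dendrimer counterions) and one monovalent cation per
#' surfactant chain (`n_s` surfactant counterions).
#'
#' @param n_d number of dendrimers (>= 0)
#' @param n_s number of surfactant chains (>= 0)
#' @param G,S dendrimer generation and spacer length (see
#'   [dendrimer_topology()]); ignored when `n_d = 0`
#' @return an object of class `md_system`: list with `beads` (tibble: `id`,
#'   `molecule_id`, `dendrimer_id`, `species`, `type`, `charge`), `bonds`
#'   (tibble: `i`, `j`, `type`), and scalars `n_beads`, `n_d`, `n_s`, `N_t`,
#'   `N_d`.
#' @examples
#' sys <- build_system(n_d = 2, n_s = 10, G = 3, S = 4)
#' sum(sys$beads$charge) # 0
#' @export
build_system <- function(n_d, n_s, G = 3, S = 4) {
  if (n_d < 0 || n_s < 0) stop("`n_d` and `n_s` must be >= 0", call. = FALSE)
  frag_d <- if (n_d > 0) dendrimer_topology(G, S) else NULL
  frag_s <- surfactant_topology()
  N_d <- if (n_d > 0) attr(frag_d, "N_d") else 0L
  N_t <- if (n_d > 0) attr(frag_d, "N_t") else 0L

  species <- character(0); charge <- numeric(0)
  mol <- integer(0); dend <- integer(0)
  bi <- integer(0); bj <- integer(0); btype <- integer(0)
  offset <- 0L; mol_id <- 0L
  for (k in seq_len(n_d)) {
    mol_id <- mol_id + 1L
    species <- c(species, frag_d$beads$species)
    charge <- c(charge, frag_d$beads$charge)
    mol <- c(mol, rep(mol_id, N_d))
    dend <- c(dend, rep(k, N_d))
    bi <- c(bi, frag_d$bonds[, 1] + offset)
    bj <- c(bj, frag_d$bonds[, 2] + offset)
    btype <- c(btype, rep(1L, nrow(frag_d$bonds)))
    offset <- offset + N_d
  }
  for (k in seq_len(n_s)) {
    mol_id <- mol_id + 1L
    species <- c(species, frag_s$beads$species)
    charge <- c(charge, frag_s$beads$charge)
    mol <- c(mol, rep(mol_id, 4L))
    dend <- c(dend, rep(NA_integer_, 4L))
    bi <- c(bi, frag_s$bonds[, 1] + offset)
    bj <- c(bj, frag_s$bonds[, 2] + offset)
    btype <- c(btype, rep(2L, 3L))
    offset <- offset + 4L
  }
  n_anion <- n_d * N_t
  n_cation <- n_s
  for (sp in c(rep("dendrimer-counterion", n_anion),
               rep("surfactant-counterion", n_cation))) {
    mol_id <- mol_id + 1L
    species <- c(species, sp)
    charge <- c(charge, .species_charge[[sp]])
    mol <- c(mol, mol_id)
    dend <- c(dend, NA_integer_)
  }

  beads <- tibble::tibble(
    id = seq_along(species),
    molecule_id = mol,
    dendrimer_id = dend,
    species = species,
    type = unname(.species_levels[species]),
    charge = charge
  )
  bonds <- tibble::tibble(i = bi, j = bj, type = btype)
  stopifnot(sum(beads$charge) == 0)
  structure(
    list(beads = beads, bonds = bonds,
         n_beads = nrow(beads), n_d = as.integer(n_d), n_s = as.integer(n_s),
         N_t = as.integer(N_t), N_d = as.integer(N_d), G = G, S = S),
    class = "md_system"
  )
}

#' @export
print.md_system <- function(x, ...) {
  cat(sprintf(
    "<md_system> %d beads | %d dendrimer(s) G%dS%d (N_d=%d, N_t=%d) | %d surfactant chain(s) | %d bonds | net charge %g\n",
    x$n_beads, x$n_d, x$G %||% NA, x$S %||% NA, x$N_d, x$N_t, x$n_s,
    nrow(x$bonds), sum(x$beads$charge)
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single-frame coordinate set
#'
#' @param positions numeric `n x 3` matrix of bead coordinates in sigma
#' @param box_L cubic box edge length in sigma
#' @param step integration step the frame was recorded at
#' @return an object of class `md_frame`.
#' @export
md_frame <- function(positions, box_L, step = 0L) {
  positions <- as.matrix(positions)
  dimnames(positions) <- NULL
  stopifnot(ncol(positions) == 3, box_L > 0)
  structure(list(positions = wrap_positions(positions, box_L),
                 box_L = box_L, step = as.integer(step)),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("<md_frame> %d beads, box L = %g, step %d\n",
              nrow(x$positions), x$box_L, x$step))
  invisible(x)
}

#' Wrap coordinates into the primary periodic cell [0, L)
#'
#' @param positions `n x 3` coordinate matrix
#' @param box_L cubic box edge
#' @return wrapped coordinate matrix.
#' @export
wrap_positions <- function(positions, box_L) {
  positions - box_L * floor(positions / box_L)
}
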