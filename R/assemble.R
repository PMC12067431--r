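# minimum-image distances from one point to a set of points (rows)
.mi_dist <- function(p, pts, L) {
  d <- abs(sweep(pts, 2, p))
  d <- pmin(d, L - d)
  sqrt(rowSums(d^2))
}

.rand_dir <- function() {
  repeat {
    v <- stats::rnorm(3)
    s <- sqrt(sum(v^2))
    if (s > 1e-8) return(v / s)
  }
}

#' Assemble an electroneutral periodic system with initial coordinates
#'
#' Builds the topology with [build_system()] and places it in a cubic
#' periodic box: dendrimers by self-avoiding breadth-first growth along
#' their bond trees, surfactants as straight chains with random position and
#' orientation, counterions uniformly at random.  Placement enforces a
#' minimum-image separation of at least `min_sep` between non-bonded beads,
#' so the configuration can be integrated directly.  Deterministic under a
#' fixed `seed`.
#'
#' @inheritParams build_system
#' @param L cubic box edge in sigma
#' @param seed integer seed; `NULL` leaves the RNG state alone
#' @param min_sep minimum allowed non-bonded bead separation (default 0.85)
#' @param bond_length initial bond length in sigma (default 0.97)
#' @param max_tries placement retries per bead before the molecule is
#'   regrown; packing that still fails is reported as infeasible
#' @return list with elements `system` (an `md_system`) and `frame`
#'   (an `md_frame`).
#' @examples
#' as0 <- assemble_system(n_d = 0, n_s = 5, L = 20, seed = 1)
#' as0$system
#' @export
assemble_system <- function(n_d, n_s, G = 3, S = 4, L, seed = NULL,
                            min_sep = 0.85, bond_length = 0.97,
                            max_tries = 200) {
  if (!is.null(seed)) set.seed(seed)
  sys <- build_system(n_d, n_s, G = G, S = S)
  n <- sys$n_beads
  if (n * pi / 6 / L^3 > 0.35) {
    stop("infeasible packing: bead volume fraction ", round(n * pi / 6 / L^3, 2),
         " exceeds 0.35 for L = ", L, call. = FALSE)
  }
  pos <- matrix(NA_real_, n, 3)
  placed <- 0L

  place_bead <- function(anchor, pos, placed, parent = NA_integer_) {
    for (try in seq_len(max_tries)) {
      p <- if (is.null(anchor)) stats::runif(3, 0, L) else anchor + bond_length * .rand_dir()
      if (placed > 0L) {
        d <- .mi_dist(p %% L, pos[seq_len(placed), , drop = FALSE], L)
        if (!is.na(parent)) d <- d[-parent]
        if (length(d) && min(d) < min_sep) next
      }
      return(p %% L)
    }
    NULL
  }

  # dendrimers: beads appear in construction order; each bead's parent is the
  # lower-index end of its bond
  if (n_d > 0) {
    frag <- dendrimer_topology(G, S)
    parent_of <- integer(sys$N_d)
    parent_of[frag$bonds[, 2]] <- frag$bonds[, 1]
    for (k in seq_len(n_d)) {
      off <- (k - 1L) * sys$N_d
      ok <- FALSE
      for (regrow in 1:20) {
        fail <- FALSE
        for (b in seq_len(sys$N_d)) {
          anchor <- if (b == 1L) NULL else pos[off + parent_of[b], ]
          par_idx <- if (b == 1L) NA_integer_ else off + parent_of[b]
          p <- place_bead(anchor, pos, placed, parent = par_idx)
          if (is.null(p)) { fail <- TRUE; break }
          placed <- placed + 1L
          pos[off + b, ] <- p
        }
        if (!fail) { ok <- TRUE; break }
        placed <- off # discard partial molecule and regrow
      }
      if (!ok) stop("infeasible packing: dendrimer ", k,
                    " could not be grown at L = ", L, call. = FALSE)
    }
  }

  # surfactants: straight chains
  off <- n_d * sys$N_d
  for (k in seq_len(n_s)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      origin <- stats::runif(3, 0, L)
      dir <- .rand_dir()
      chain <- sweep(outer(0:3, dir) * bond_length, 2, origin, `+`) %% L
      if (placed > 0L) {
        dmin <- min(apply(chain, 1, function(p)
          min(.mi_dist(p, pos[seq_len(placed), , drop = FALSE], L))))
        if (dmin < min_sep) next
      }
      pos[off + (k - 1L) * 4L + 1:4, ] <- chain
      placed <- placed + 4L
      ok <- TRUE
      break
    }
    if (!ok) stop("infeasible packing: surfactant ", k,
                  " could not be placed at L = ", L, call. = FALSE)
  }

  # counterions
  off <- n_d * sys$N_d + 4L * n_s
  n_ion <- n - off
  for (k in seq_len(n_ion)) {
    p <- place_bead(NULL, pos, placed)
    if (is.null(p)) stop("infeasible packing: counterion ", k,
                         " could not be placed at L = ", L, call. = FALSE)
    placed <- placed + 1L
    pos[off + k, ] <- p
  }

  list(system = sys, frame = md_frame(pos, L, step = 0L))
}
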