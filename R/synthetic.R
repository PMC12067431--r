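#' Specification of a planted configuration
#'
#' Describes a frame with known ground-truth aggregate structure:
#' surfactant micelles of given masses, each free or attached to one or
#' more dendrimers (corona/bridge), plus counterions with planted
#' condensed/free status.  Geometric construction keeps every intended
#' contact at `r_star - margin` or closer and every unintended pair at
#' `r_star + margin` or farther, so the distance criteria of the analysis
#' are unambiguous.
#'
#' @param masses integer vector of micelle masses (chains per micelle)
#' @param attach list parallel to `masses`: integer vector of dendrimer
#'   ids each micelle is bound to (`integer(0)` = free micelle)
#' @param n_d number of dendrimers in the system (default: highest id in
#'   `attach`, or 0)
#' @param G,S dendrimer architecture (defaults G = 1, S = 1 keep planted
#'   systems small; any architecture works)
#' @param condensed_dc,condensed_sc integer vectors: number of condensed
#'   dendrimer / surfactant counterions to plant on each aggregate, in
#'   aggregate order (see Details); recycled scalars allowed
#' @param margin safety distance in sigma separating planted distances
#'   from the r* threshold (default 0.2)
#' @param r_star analysis contact distance the margins refer to
#' @param box_L cubic box edge; `NULL` chooses the smallest box that fits
#'   the planted layout
#' @param seed integer seed for the (small) geometric randomness
#'
#' @details Aggregates are the connected components of the planted
#' micelle-dendrimer attachment graph, numbered with micelle-containing
#' components first (in order of their lowest micelle id), then free
#' dendrimers in id order; that is also the order `condensed_dc` /
#' `condensed_sc` refer to.
#'
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(masses, attach = NULL, n_d = NULL, G = 1, S = 1,
                       condensed_dc = 0, condensed_sc = 0,
                       margin = 0.2, r_star = 1.5, box_L = NULL,
                       seed = NULL) {
  masses <- as.integer(masses)
  stopifnot(all(masses >= 1), margin > 0, margin < r_star)
  if (is.null(attach)) attach <- rep(list(integer(0)), length(masses))
  stopifnot(length(attach) == length(masses))
  attach <- lapply(attach, function(a) sort(unique(as.integer(a))))
  max_ref <- if (length(unlist(attach))) max(unlist(attach)) else 0L
  n_d <- as.integer(n_d %||% max_ref)
  if (max_ref > n_d) stop("`attach` references dendrimer ", max_ref,
                          " but n_d = ", n_d, call. = FALSE)
  spec <- structure(list(
    masses = masses, attach = attach, n_d = n_d, G = G, S = S,
    condensed_dc = condensed_dc, condensed_sc = condensed_sc,
    margin = margin, r_star = r_star, box_L = box_L, seed = seed
  ), class = "plant_spec")
  spec$aggregates <- .plant_aggregates(spec)
  na <- nrow(spec$aggregates)
  spec$condensed_dc <- as.integer(rep_len(condensed_dc, na))
  spec$condensed_sc <- as.integer(rep_len(condensed_sc, na))
  spec
}

# derive ground-truth aggregates from the attachment graph
.plant_aggregates <- function(spec) {
  n_mic <- length(spec$masses)
  n_d <- spec$n_d
  g <- igraph::make_empty_graph(n_mic + n_d, directed = FALSE)
  for (m in seq_len(n_mic)) {
    for (dd in spec$attach[[m]]) g <- igraph::add_edges(g, c(m, n_mic + dd))
  }
  comp <- igraph::components(g)$membership
  mic_comp <- comp[seq_len(n_mic)]
  den_comp <- if (n_d > 0) comp[n_mic + seq_len(n_d)] else integer(0)
  # order: micelle-containing components by lowest micelle id, then free dendrimers
  comp_order <- unique(c(mic_comp, den_comp))
  rows <- lapply(comp_order, function(a) {
    mics <- which(mic_comp == a)
    dens <- which(den_comp == a)
    kinds <- if (length(mics)) {
      vapply(spec$attach[mics], function(at) {
        if (length(at) == 0) "free" else if (length(at) == 1) "corona" else "bridge"
      }, character(1))
    } else character(0)
    tibble::tibble(
      s = sum(spec$masses[mics]), d = length(dens),
      n_br = sum(kinds == "bridge"), n_cor = sum(kinds == "corona"),
      micelle_ids = list(mics), dendrimers = list(dens),
      micelles = list(tibble::tibble(micelle = mics,
                                     mass = spec$masses[mics], kind = kinds))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$aggregate <- seq_len(nrow(out))
  out
}

# points uniformly in a ball of radius r around center
.ball <- function(n, center, r) {
  out <- matrix(NA_real_, n, 3)
  k <- 0L
  while (k < n) {
    p <- stats::runif(3, -r, r)
    if (sum(p^2) <= r^2) { k <- k + 1L; out[k, ] <- center + p }
  }
  out
}

#' Build a planted frame with ground-truth labels
#'
#' Realises a [plant_spec()] geometrically: each aggregate occupies its own
#' well-separated region of the box; within a region, micelle tails form a
#' tight cluster (mimicking the dense hydrophobic core), heads sit on a
#' shell around it, and each intended micelle-dendrimer bond is realised by
#' moving one dedicated terminal bead of the dendrimer to `r_star - margin`
#' of a head of the micelle.  Condensed counterions are placed at
#' `r_star - margin` of a bead of their target aggregate; free counterions
#' in a reserved empty region.  A verification pass asserts that every
#' planted margin holds.
#'
#' @param spec a [plant_spec()]
#' @param verify check all planted distance margins (default TRUE)
#' @return list with `frame` (an `md_frame`), `system` (the matching
#'   `md_system`), and `labels` — the ground-truth aggregate table in the
#'   schema of [analyze_frame()] (columns `s`, `d`, `index`, `n_br`,
#'   `n_cor`, `n_dc`, `n_sc`, `ch`, `micelles`).
#' @export
plant_frame <- function(spec, verify = TRUE) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n_s <- sum(spec$masses)
  sys <- build_system(spec$n_d, n_s, G = spec$G, S = spec$S)
  agg <- spec$aggregates
  na <- nrow(agg)
  near <- spec$r_star - spec$margin - 0.05 # intended-contact distance
  far_gap <- 10 # sub-center spacing within a region

  # capacity: one terminal per intended bond
  if (spec$n_d > 0) {
    need <- table(factor(unlist(spec$attach), levels = seq_len(spec$n_d)))
    if (any(need > sys$N_t)) {
      stop("dendrimer architecture G", spec$G, "S", spec$S, " has N_t = ",
           sys$N_t, " terminals; a dendrimer cannot bind ", max(need),
           " micelles", call. = FALSE)
    }
  }

  # region layout: one region per aggregate plus one for free ions
  n_regions <- na + 1L
  items_per_agg <- vapply(seq_len(na), function(a) {
    length(agg$micelle_ids[[a]]) + length(agg$dendrimers[[a]])
  }, numeric(1))
  sub_grid <- ceiling(max(c(1, items_per_agg))^(1 / 3))
  region_extent <- far_gap * sub_grid
  pitch <- region_extent + far_gap
  gdim <- ceiling(n_regions^(1 / 3))
  need_L <- gdim * pitch
  L <- spec$box_L %||% need_L
  if (L < need_L) {
    stop("unrealizable packing: planted layout needs box_L >= ", need_L,
         " but box_L = ", L, call. = FALSE)
  }
  region_center <- function(k) { # k in 1..n_regions, 0-based grid coords
    k0 <- k - 1L
    (c(k0 %% gdim, (k0 %/% gdim) %% gdim, k0 %/% (gdim * gdim)) + 0.5) * pitch
  }
  sub_center <- function(rc, j) { # j-th sub-site in region centered rc
    j0 <- j - 1L
    rc - region_extent / 2 +
      (c(j0 %% sub_grid, (j0 %/% sub_grid) %% sub_grid,
         j0 %/% (sub_grid^2)) + 0.5) * far_gap
  }

  pos <- matrix(NA_real_, sys$n_beads, 3)
  b <- sys$beads
  head_idx <- which(b$species == "surfactant-head")
  term_by_dend <- split(which(b$species == "dendrimer-terminal"),
                        b$dendrimer_id[which(b$species == "dendrimer-terminal")])
  used_terminals <- lapply(seq_len(max(1, spec$n_d)), function(i) integer(0))
  head_pos_of_mic <- vector("list", length(spec$masses))

  # chain bead indices per global chain id (chains numbered in bead order)
  chain_beads <- lapply(seq_len(n_s), function(ch) {
    h <- head_idx[ch]
    h:(h + 3L)
  })
  # assign chains to micelles in id order
  chain_of_mic <- split(seq_len(n_s),
                        rep(seq_along(spec$masses), spec$masses))

  for (a in seq_len(na)) {
    rc <- region_center(a)
    j <- 0L
    # dendrimers: blob at a sub-site; terminals kept for later relocation
    for (dd in agg$dendrimers[[a]]) {
      j <- j + 1L
      ctr <- sub_center(rc, j)
      beads_d <- which(b$dendrimer_id == dd & !is.na(b$dendrimer_id))
      pos[beads_d, ] <- .ball(length(beads_d), ctr, 0.5)
    }
    # micelles: tail cluster + head shell
    for (m in agg$micelle_ids[[a]]) {
      j <- j + 1L
      ctr <- sub_center(rc, j)
      chains <- chain_of_mic[[m]]
      mass <- length(chains)
      hp <- matrix(NA_real_, mass, 3)
      for (q in seq_along(chains)) {
        cb <- chain_beads[[chains[q]]]
        tails <- .ball(3, ctr, 0.45)
        # head on a shell of radius 2 around the tail core
        u <- .rand_dir()
        hp[q, ] <- ctr + 2.0 * u
        pos[cb[1], ] <- hp[q, ]
        pos[cb[2:4], ] <- tails
      }
      head_pos_of_mic[[m]] <- hp
      # realise each intended bond: move a dedicated terminal next to a head
      at <- spec$attach[[m]]
      for (q in seq_along(at)) {
        dd <- at[q]
        terms <- term_by_dend[[as.character(dd)]]
        free_t <- setdiff(terms, used_terminals[[dd]])
        tsel <- free_t[1]
        used_terminals[[dd]] <- c(used_terminals[[dd]], tsel)
        hsel <- hp[1 + (q - 1) %% mass, ] # distinct heads when available
        if (mass >= length(at)) hsel <- hp[q, ]
        dir_out <- .rand_dir()
        pos[tsel, ] <- hsel + near * dir_out
      }
    }
  }

  # counterions: planted condensed on target aggregates, remainder free
  anion_idx <- which(b$species == "dendrimer-counterion")
  cation_idx <- which(b$species == "surfactant-counterion")
  place_condensed <- function(ion_rows, counts) {
    taken <- 0L
    for (a in seq_len(na)) {
      k <- counts[a]
      if (k == 0) next
      # anchor beads: any structural bead of the aggregate
      anchor_beads <- c(
        unlist(lapply(agg$dendrimers[[a]], function(dd) which(b$dendrimer_id == dd))),
        unlist(chain_beads[unlist(chain_of_mic[agg$micelle_ids[[a]]])])
      )
      if (!length(anchor_beads)) stop("aggregate ", a, " has no beads to condense on")
      for (q in seq_len(k)) {
        taken <- taken + 1L
        if (taken > length(ion_rows)) {
          stop("not enough counterions to satisfy planted condensation",
               call. = FALSE)
        }
        anc <- anchor_beads[1 + (q - 1) %% length(anchor_beads)]
        pos[ion_rows[taken], ] <<- pos[anc, ] + near * .rand_dir()
      }
    }
    taken
  }
  used_an <- place_condensed(anion_idx, spec$condensed_dc)
  used_cat <- place_condensed(cation_idx, spec$condensed_sc)
  free_ions <- c(anion_idx[seq_len(length(anion_idx) - used_an) + used_an],
                 cation_idx[seq_len(length(cation_idx) - used_cat) + used_cat])
  if (length(free_ions)) {
    rc <- region_center(n_regions)
    pos[free_ions, ] <- .ball(length(free_ions), rc, region_extent / 2 + 1)
  }

  frame <- md_frame(pos, L, step = 0L)

  labels <- agg
  labels$n_dc <- spec$condensed_dc
  labels$n_sc <- spec$condensed_sc
  labels$index <- aggregate_index(labels$s, labels$d, n_s)
  labels$ch <- effective_charge(labels$s, labels$d, sys$N_t,
                                labels$n_sc, labels$n_dc)
  labels$chains <- lapply(labels$micelle_ids, function(ms)
    sort(unlist(chain_of_mic[ms])))

  if (verify) .verify_plant(frame, sys, spec, labels, chain_of_mic)

  list(frame = frame, system = sys,
       labels = labels[, c("aggregate", "s", "d", "index", "n_br", "n_cor",
                           "n_dc", "n_sc", "ch", "micelles", "dendrimers",
                           "chains")])
}

# assert that planted margins hold: intended contacts < r* - margin (with
# slack), unintended pairs > r* + margin
.verify_plant <- function(frame, sys, spec, labels, chain_of_mic) {
  r_lo <- spec$r_star - spec$margin
  r_hi <- spec$r_star + spec$margin
  L <- frame$box_L
  b <- sys$beads
  # chains of the same micelle are mutually linked through the tail cluster;
  # chains of different micelles must be distant
  tails <- which(b$species == "surfactant-tail")
  mic_of_chain <- integer(sys$n_s)
  for (m in seq_along(chain_of_mic)) mic_of_chain[chain_of_mic[[m]]] <- m
  pr <- neighbor_pairs(frame$positions[tails, , drop = FALSE], NULL, L, r_hi)
  ch_i <- (pr$i - 1L) %/% 3L + 1L
  ch_j <- (pr$j - 1L) %/% 3L + 1L
  cross <- mic_of_chain[ch_i] != mic_of_chain[ch_j]
  if (any(cross)) stop("planted margin violated: tail contact across micelles")
  # every planted bond realised, no spurious head-terminal contact
  heads <- which(b$species == "surfactant-head")
  terms <- which(b$species == "dendrimer-terminal")
  if (length(terms)) {
    pr <- neighbor_pairs(frame$positions[heads, , drop = FALSE],
                         frame$positions[terms, , drop = FALSE], L, r_hi)
    got <- dplyr::distinct(tibble::tibble(
      mic = mic_of_chain[pr$i], den = b$dendrimer_id[terms][pr$j]))
    want <- dplyr::bind_rows(lapply(seq_along(spec$attach), function(m) {
      if (length(spec$attach[[m]])) tibble::tibble(mic = m, den = spec$attach[[m]])
    }))
    if (is.null(want) || !all(c("mic", "den") %in% names(want))) {
      want <- tibble::tibble(mic = integer(), den = integer())
    }
    if (nrow(got) != nrow(want) ||
        !setequal(paste(got$mic, got$den), paste(want$mic, want$den))) {
      stop("planted margin violated: head-terminal contacts do not match spec")
    }
    # realised contacts must clear the lower margin too
    if (nrow(pr) && any(pr$dist >= r_lo)) {
      ok <- pr$dist < r_lo
      # at least one sub-margin contact per intended pair
      chk <- tibble::tibble(mic = mic_of_chain[pr$i],
                            den = b$dendrimer_id[terms][pr$j], ok = ok) |>
        dplyr::group_by(.data$mic, .data$den) |>
        dplyr::summarise(any_ok = any(.data$ok), .groups = "drop")
      if (!all(chk$any_ok)) stop("planted bond weaker than r* - margin")
    }
  }
  invisible(TRUE)
}

#' Planted multi-frame trajectory
#'
#' Realises a list of [plant_spec()]s as consecutive frames over one shared
#' topology (all specs must imply the same `n_d`, `n_s`, dendrimer
#' architecture and counterion counts).
#'
#' @param specs list of `plant_spec` objects
#' @return list with `frames` (list of `md_frame`), `system`, and `labels`
#'   (row-bound ground-truth tables with a `frame` column).
#' @export
plant_trajectory <- function(specs) {
  stopifnot(length(specs) >= 1)
  key <- function(sp) c(sp$n_d, sum(sp$masses), sp$G, sp$S)
  k0 <- key(specs[[1]])
  for (sp in specs) {
    if (!identical(key(sp), k0)) {
      stop("all plant specs in a trajectory must share n_d, n_s, G, S",
           call. = FALSE)
    }
  }
  built <- lapply(specs, plant_frame)
  frames <- lapply(seq_along(built), function(k) {
    fr <- built[[k]]$frame
    fr$step <- k
    fr
  })
  labels <- purrr::imap_dfr(built, function(bb, k) {
    tibble::tibble(frame = k, bb$labels)
  })
  list(frames = frames, system = built[[1]]$system, labels = labels)
}
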