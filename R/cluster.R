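#' Contact-distance parameters for the aggregate taxonomy
#'
#' A single contact distance \eqn{r^* = 1.5\sigma} governs all three
#' criteria: chain-chain binding (tail-tail), micelle-dendrimer binding
#' (head-terminal), and counterion condensation (ion to any aggregate
#' bead).  All comparisons are strict (`< r_star`) on minimum-image
#' center-to-center distances.
#'
#' @param r_star contact distance in sigma (default 1.5)
#' @return a named list of class `cutoff_params`.
#' @export
cutoff_params <- function(r_star = 1.5) {
  stopifnot(r_star > 0)
  structure(list(r_star = r_star), class = "cutoff_params")
}

# surfactant chain table: one row per chain with bead index ranges
.chain_table <- function(system) {
  b <- system$beads
  heads <- which(b$species == "surfactant-head")
  tibble::tibble(
    chain = seq_along(heads),
    molecule_id = b$molecule_id[heads],
    head = heads
  )
}

#' Detect surfactant micelles in one frame
#'
#' A micelle is a maximal set of surfactant chains in which each chain is
#' bound to at least one other chain of the set; two chains are bound when
#' any pair of tail beads from the two distinct chains is separated by less
#' than `r_star` (minimum image).  Single unbound chains are micelles of
#' mass 1 (unimers).
#'
#' @param frame an `md_frame`
#' @param system an `md_system`
#' @param cutoffs a [cutoff_params()] list
#' @return tibble with one row per micelle: `micelle` (id within frame),
#'   `mass`, and list-column `chains` (surfactant chain indices 1..n_s).
#' @export
find_micelles <- function(frame, system, cutoffs = cutoff_params()) {
  b <- system$beads
  n_s <- system$n_s
  if (n_s == 0) {
    return(tibble::tibble(micelle = integer(), mass = integer(),
                          chains = list()))
  }
  tails <- which(b$species == "surfactant-tail")
  chain_of_tail <- match(b$molecule_id[tails], unique(b$molecule_id[tails]))
  pr <- neighbor_pairs(frame$positions[tails, , drop = FALSE], NULL,
                       frame$box_L, cutoffs$r_star)
  ci <- chain_of_tail[pr$i]
  cj <- chain_of_tail[pr$j]
  keep <- ci != cj
  g <- igraph::make_empty_graph(n_s, directed = FALSE)
  if (any(keep)) g <- igraph::add_edges(g, rbind(ci[keep], cj[keep]))
  comp <- igraph::components(g)$membership[seq_len(n_s)]
  comp <- match(comp, unique(comp)) # stable ids in chain order
  tibble::tibble(chain = seq_len(n_s), micelle = comp) |>
    dplyr::group_by(.data$micelle) |>
    dplyr::summarise(mass = dplyr::n(), chains = list(.data$chain),
                     .groups = "drop") |>
    dplyr::arrange(.data$micelle)
}

#' Bind micelles to dendrimers and classify them
#'
#' A micelle and a dendrimer are bound when the head bead of at least one
#' of the micelle's chains is within `r_star` of at least one terminal
#' group of the dendrimer.  Micelles bound to no dendrimer are `free`, to
#' exactly one `corona`, to two or more `bridge`.
#'
#' @param micelles output of [find_micelles()]
#' @inheritParams find_micelles
#' @return `micelles` with added columns `bound_dendrimers` (list of
#'   dendrimer ids) and `kind` (factor free/corona/bridge).
#' @export
bind_micelles_to_dendrimers <- function(micelles, frame, system,
                                        cutoffs = cutoff_params()) {
  b <- system$beads
  heads <- which(b$species == "surfactant-head")
  terms <- which(b$species == "dendrimer-terminal")
  chain_of_head <- seq_along(heads)
  micelle_of_chain <- integer(length(heads))
  for (r in seq_len(nrow(micelles))) {
    micelle_of_chain[micelles$chains[[r]]] <- micelles$micelle[r]
  }
  bound <- rep(list(integer(0)), nrow(micelles))
  if (length(heads) && length(terms) && system$n_d > 0) {
    pr <- neighbor_pairs(frame$positions[heads, , drop = FALSE],
                         frame$positions[terms, , drop = FALSE],
                         frame$box_L, cutoffs$r_star)
    if (nrow(pr)) {
      mic <- micelle_of_chain[chain_of_head[pr$i]]
      den <- b$dendrimer_id[terms][pr$j]
      links <- dplyr::distinct(tibble::tibble(mic = mic, den = den))
      for (r in seq_len(nrow(micelles))) {
        bound[[r]] <- sort(links$den[links$mic == micelles$micelle[r]])
      }
    }
  }
  nb <- lengths(bound)
  micelles$bound_dendrimers <- bound
  micelles$kind <- dplyr::case_when(
    nb == 0 ~ "free", nb == 1 ~ "corona", TRUE ~ "bridge"
  )
  micelles
}

#' Group classified micelles and dendrimers into aggregates
#'
#' Mixed clusters are connected components of the bipartite
#' micelle-dendrimer binding graph.  Free micelles become (s, 0)
#' aggregates; dendrimers bound to no micelle become (0, 1) aggregates.
#'
#' @param micelles classified micelles from [bind_micelles_to_dendrimers()]
#' @param system an `md_system`
#' @return tibble with one row per aggregate: `aggregate`, `s`, `d`,
#'   `n_br`, `n_cor`, list-columns `micelle_ids`, `dendrimers`, `chains`,
#'   and nested `micelles` (mass, kind per member micelle).
#' @export
find_mixed_clusters <- function(micelles, system) {
  n_mic <- nrow(micelles)
  n_d <- system$n_d
  # vertices: 1..n_mic micelles, n_mic+1..n_mic+n_d dendrimers
  edges <- NULL
  for (r in seq_len(n_mic)) {
    bd <- micelles$bound_dendrimers[[r]]
    if (length(bd)) edges <- rbind(edges, cbind(r, n_mic + bd))
  }
  g <- igraph::make_empty_graph(n = n_mic + n_d, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  comp <- match(comp, unique(comp))
  agg_of_mic <- comp[seq_len(n_mic)]
  agg_of_den <- if (n_d > 0) comp[n_mic + seq_len(n_d)] else integer(0)

  rows <- lapply(sort(unique(comp)), function(a) {
    mics <- which(agg_of_mic == a)
    dens <- which(agg_of_den == a)
    mt <- micelles[mics, , drop = FALSE]
    tibble::tibble(
      aggregate = a,
      s = sum(mt$mass),
      d = length(dens),
      n_br = sum(mt$kind == "bridge"),
      n_cor = sum(mt$kind == "corona"),
      micelle_ids = list(mt$micelle),
      dendrimers = list(dens),
      chains = list(sort(unlist(mt$chains))),
      micelles = list(mt[, c("micelle", "mass", "kind")])
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(aggregate = integer(), s = integer(), d = integer(),
                          n_br = integer(), n_cor = integer(),
                          micelle_ids = list(), dendrimers = list(),
                          chains = list(), micelles = list())
  } else {
    out$aggregate <- seq_len(nrow(out))
  }
  out
}

#' Count condensed counterions per aggregate
#'
#' A counterion is condensed when its minimum-image distance to at least
#' one bead of an aggregate (dendrimer beads or member-chain beads) is
#' below `r_star`.  When a counterion lies within `r_star` of beads of
#' several aggregates it is assigned exclusively to the aggregate owning
#' the nearest bead (`exclusive = TRUE`, default), which keeps the global
#' charge ledger exact; `exclusive = FALSE` counts it on every such
#' aggregate.
#'
#' @param aggregates output of [find_mixed_clusters()]
#' @inheritParams find_micelles
#' @param exclusive assign a multiply-proximal counterion to the
#'   nearest-bead aggregate only
#' @return `aggregates` with integer columns `n_dc` (condensed dendrimer
#'   counterions, anions) and `n_sc` (condensed surfactant counterions,
#'   cations).
#' @export
count_condensed_counterions <- function(aggregates, frame, system,
                                        cutoffs = cutoff_params(),
                                        exclusive = TRUE) {
  b <- system$beads
  na <- nrow(aggregates)
  aggregates$n_dc <- integer(na)
  aggregates$n_sc <- integer(na)
  ions <- which(b$species %in% c("dendrimer-counterion", "surfactant-counterion"))
  if (!length(ions) || na == 0) return(aggregates)
  ion_kind <- b$species[ions]

  # aggregate membership per structural bead
  agg_of_bead <- rep(NA_integer_, system$n_beads)
  chain_tab <- .chain_table(system)
  for (r in seq_len(na)) {
    dens <- aggregates$dendrimers[[r]]
    if (length(dens)) {
      agg_of_bead[which(b$dendrimer_id %in% dens)] <- aggregates$aggregate[r]
    }
    ch <- aggregates$chains[[r]]
    if (length(ch)) {
      mols <- chain_tab$molecule_id[ch]
      agg_of_bead[which(b$molecule_id %in% mols)] <- aggregates$aggregate[r]
    }
  }
  struct <- which(!is.na(agg_of_bead))
  pr <- neighbor_pairs(frame$positions[ions, , drop = FALSE],
                       frame$positions[struct, , drop = FALSE],
                       frame$box_L, cutoffs$r_star)
  if (!nrow(pr)) return(aggregates)
  pr$agg <- agg_of_bead[struct[pr$j]]
  if (exclusive) {
    hits <- pr |>
      dplyr::group_by(ion = .data$i) |>
      dplyr::slice_min(.data$dist, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  } else {
    hits <- dplyr::distinct(tibble::tibble(ion = pr$i, agg = pr$agg))
  }
  tal <- hits |>
    dplyr::mutate(kind = ion_kind[.data$ion]) |>
    dplyr::count(.data$agg, .data$kind)
  for (r in seq_len(nrow(tal))) {
    a <- match(tal$agg[r], aggregates$aggregate)
    if (tal$kind[r] == "dendrimer-counterion") {
      aggregates$n_dc[a] <- aggregates$n_dc[a] + tal$n[r]
    } else {
      aggregates$n_sc[a] <- aggregates$n_sc[a] + tal$n[r]
    }
  }
  aggregates
}

#' Total absorbed surfactants in a set of aggregates
#'
#' A surfactant chain is absorbed when it belongs to a mixed cluster
#' (an aggregate with `d > 0`); the complement are chains in free
#' micelles.
#'
#' @param aggregates an aggregate table with columns `s` and `d`
#' @return integer count of absorbed chains.
#' @export
absorbed_surfactants <- function(aggregates) {
  sum(aggregates$s[aggregates$d > 0])
}

#' Full aggregate analysis of one frame
#'
#' Runs the whole taxonomy pipeline on a frame: micelle detection,
#' dendrimer binding and bridge/corona classification, mixed-cluster
#' labelling, counterion condensation and effective charge
#' \eqn{ch = d N_t - s + n_{sc} - n_{dc}}.
#'
#' @inheritParams find_micelles
#' @inheritParams count_condensed_counterions
#' @param frame_id integer label stored in the `frame` column
#' @return tibble with one row per aggregate: `frame`, `aggregate`, `s`,
#'   `d`, `index` (the aggregate index \eqn{n_{s,d}}), `n_br`, `n_cor`,
#'   `n_dc`, `n_sc`, `ch`, plus list-columns `micelles`, `dendrimers`,
#'   `chains`.
#' @export
analyze_frame <- function(frame, system, cutoffs = cutoff_params(),
                          exclusive = TRUE, frame_id = frame$step) {
  mic <- find_micelles(frame, system, cutoffs)
  mic <- bind_micelles_to_dendrimers(mic, frame, system, cutoffs)
  agg <- find_mixed_clusters(mic, system)
  agg <- count_condensed_counterions(agg, frame, system, cutoffs, exclusive)
  agg$index <- aggregate_index(agg$s, agg$d, system$n_s)
  agg$ch <- effective_charge(agg$s, agg$d, system$N_t, agg$n_sc, agg$n_dc)
  tibble::tibble(
    frame = frame_id,
    agg[, c("aggregate", "s", "d", "index", "n_br", "n_cor",
            "n_dc", "n_sc", "ch", "micelles", "dendrimers", "chains")]
  )
}

#' Aggregate analysis of a trajectory
#'
#' Maps [analyze_frame()] over a list of frames (or an `md_trajectory`)
#' and row-binds the per-frame aggregate tables.
#'
#' @param frames list of `md_frame` objects, or an `md_trajectory`
#' @inheritParams analyze_frame
#' @return tibble of aggregates across frames (see [analyze_frame()]).
#' @export
analyze_trajectory <- function(frames, system = NULL,
                               cutoffs = cutoff_params(), exclusive = TRUE) {
  if (inherits(frames, "md_trajectory")) {
    system <- system %||% frames$system
    frames <- frames$frames
  }
  stopifnot(!is.null(system))
  purrr::imap_dfr(frames, function(fr, k) {
    analyze_frame(fr, system, cutoffs, exclusive,
                  frame_id = if (!is.null(fr$step)) fr$step else k)
  })
}
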