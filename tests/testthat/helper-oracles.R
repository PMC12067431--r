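# Independent brute-force oracles, written in plain base R on purpose:
# they share no code path with the package implementation (no compiled
# neighbour search, no igraph).

# full minimum-image distance matrix between rows of A and B
oracle_dist <- function(A, B, L) {
  out <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    d <- abs(outer(A[, k], B[, k], "-")) %% L
    d <- pmin(d, L - d)
    out <- out + d^2
  }
  sqrt(out)
}

# connected components by BFS flood fill over an n-vertex undirected graph
# given as a 2-column edge matrix; returns membership 1..n_comp in
# first-seen vertex order
oracle_components <- function(edges, n) {
  adj <- vector("list", n)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in adj[[u]]) {
        if (is.na(comp[w])) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

# complete O(N^2) aggregate analysis of one frame
oracle_analyze <- function(frame, system, r_star = 1.5, exclusive = TRUE) {
  b <- system$beads
  L <- frame$box_L
  P <- frame$positions
  n_s <- system$n_s
  n_d <- system$n_d

  heads <- which(b$species == "surfactant-head")
  tails <- which(b$species == "surfactant-tail")
  chain_of_tail <- rep(seq_len(n_s), each = 3)
  chain_of_head <- seq_len(n_s)

  # chain-binding graph: any tail-tail pair below r* across distinct chains
  edges <- matrix(integer(0), 0, 2)
  if (n_s > 1) {
    D <- oracle_dist(P[tails, , drop = FALSE], P[tails, , drop = FALSE], L)
    hit <- which(D < r_star & upper.tri(D), arr.ind = TRUE)
    ci <- chain_of_tail[hit[, 1]]; cj <- chain_of_tail[hit[, 2]]
    keep <- ci != cj
    edges <- unique(cbind(pmin(ci[keep], cj[keep]), pmax(ci[keep], cj[keep])))
  }
  mic_of_chain <- if (n_s > 0) oracle_components(edges, n_s) else integer(0)
  n_mic <- if (n_s > 0) max(mic_of_chain) else 0L

  # micelle-dendrimer binding via head-terminal contacts
  terms <- which(b$species == "dendrimer-terminal")
  bind <- matrix(FALSE, max(1, n_mic), max(1, n_d))
  if (n_mic > 0 && n_d > 0 && length(terms)) {
    D <- oracle_dist(P[heads, , drop = FALSE], P[terms, , drop = FALSE], L)
    hit <- which(D < r_star, arr.ind = TRUE)
    if (nrow(hit)) {
      for (r in seq_len(nrow(hit))) {
        m <- mic_of_chain[chain_of_head[hit[r, 1]]]
        dd <- b$dendrimer_id[terms[hit[r, 2]]]
        bind[m, dd] <- TRUE
      }
    }
  }
  kind <- if (n_mic > 0) {
    nb <- rowSums(bind[seq_len(n_mic), , drop = FALSE])
    ifelse(nb == 0, "free", ifelse(nb == 1, "corona", "bridge"))
  } else character(0)

  # bipartite components -> aggregates
  bedges <- which(bind, arr.ind = TRUE)
  bedges <- cbind(bedges[, 1], n_mic + bedges[, 2])
  comp <- oracle_components(bedges, n_mic + n_d)
  agg_of_mic <- comp[seq_len(n_mic)]
  agg_of_den <- if (n_d > 0) comp[n_mic + seq_len(n_d)] else integer(0)
  agg_ids <- unique(c(agg_of_mic, agg_of_den))

  mass_of_mic <- tabulate(mic_of_chain, nbins = max(1, n_mic))

  rows <- lapply(seq_along(agg_ids), function(k) {
    a <- agg_ids[k]
    mics <- which(agg_of_mic == a)
    dens <- which(agg_of_den == a)
    data.frame(aggregate = k,
               s = sum(mass_of_mic[mics]), d = length(dens),
               n_br = sum(kind[mics] == "bridge"),
               n_cor = sum(kind[mics] == "corona"))
  })
  agg <- do.call(rbind, rows)

  # condensation: nearest structural bead decides the aggregate
  agg_of_bead <- rep(NA_integer_, system$n_beads)
  for (k in seq_along(agg_ids)) {
    a <- agg_ids[k]
    dens <- which(agg_of_den == a)
    if (length(dens)) agg_of_bead[b$dendrimer_id %in% dens] <- k
    mics <- which(agg_of_mic == a)
    for (m in mics) {
      for (ch in which(mic_of_chain == m)) {
        h <- heads[ch]
        agg_of_bead[h:(h + 3)] <- k
      }
    }
  }
  struct <- which(!is.na(agg_of_bead))
  ions <- which(b$species %in% c("dendrimer-counterion", "surfactant-counterion"))
  agg$n_dc <- 0L; agg$n_sc <- 0L
  if (length(ions) && length(struct)) {
    D <- oracle_dist(P[ions, , drop = FALSE], P[struct, , drop = FALSE], L)
    for (r in seq_along(ions)) {
      within <- which(D[r, ] < r_star)
      if (!length(within)) next
      if (exclusive) {
        tgt <- agg_of_bead[struct[within[which.min(D[r, within])]]]
        tgts <- tgt
      } else {
        tgts <- unique(agg_of_bead[struct[within]])
      }
      for (tgt in tgts) {
        if (b$species[ions[r]] == "dendrimer-counterion") {
          agg$n_dc[tgt] <- agg$n_dc[tgt] + 1L
        } else {
          agg$n_sc[tgt] <- agg$n_sc[tgt] + 1L
        }
      }
    }
  }
  agg$ch <- agg$d * system$N_t - agg$s + agg$n_sc - agg$n_dc
  agg
}

# canonical sortable key for comparing aggregate tables regardless of id order
agg_key <- function(df) {
  k <- df[order(df$s, df$d, df$n_br, df$n_cor, df$n_dc, df$n_sc), ]
  paste(k$s, k$d, k$n_br, k$n_cor, k$n_dc, k$n_sc, k$ch, collapse = ";")
}

# direct Ewald summation in plain R (independent of the compiled solver);
# alpha/kmax chosen by the caller
oracle_ewald_energy <- function(pos, q, L, alpha, kmax, rc) {
  n <- nrow(pos)
  e_real <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      d <- abs(pos[a, ] - pos[b, ])
      d <- pmin(d, L - d)
      r <- sqrt(sum(d^2))
      if (r < rc) e_real <- e_real + q[a] * q[b] * erfc_r(alpha * r) / r
    }
  }
  e_recip <- 0
  V <- L^3
  for (nx in -kmax:kmax) for (ny in -kmax:kmax) for (nz in -kmax:kmax) {
    if (nx == 0 && ny == 0 && nz == 0) next
    if (nx^2 + ny^2 + nz^2 > kmax^2) next
    k <- 2 * pi * c(nx, ny, nz) / L
    k2 <- sum(k^2)
    ph <- pos %*% k
    S <- sum(q * exp(1i * ph))
    e_recip <- e_recip + exp(-k2 / (4 * alpha^2)) / k2 * Mod(S)^2
  }
  e_recip <- e_recip * 2 * pi / V
  e_self <- -alpha / sqrt(pi) * sum(q^2)
  e_real + e_recip + e_self
}

erfc_r <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# random planted spec for fuzzing, sized to stay under ~500 beads
random_plant_spec <- function(seed) {
  set.seed(seed)
  n_d <- sample(0:2, 1)
  n_mic <- sample(1:6, 1)
  masses <- sample(1:12, n_mic, replace = TRUE)
  attach <- lapply(seq_len(n_mic), function(m) {
    if (n_d == 0) return(integer(0))
    k <- sample(0:n_d, 1, prob = c(0.4, rep(0.6 / n_d, n_d)))
    if (k == 0) integer(0) else sort(sample(seq_len(n_d), k))
  })
  # respect terminal capacity of the G1S1 architecture (N_t = 4)
  if (n_d > 0) {
    per_d <- tabulate(unlist(attach), nbins = n_d)
    while (any(per_d > 4)) {
      dd <- which.max(per_d)
      m <- which(vapply(attach, function(a) dd %in% a, logical(1)))[1]
      attach[[m]] <- setdiff(attach[[m]], dd)
      per_d <- tabulate(unlist(attach), nbins = n_d)
    }
  }
  spec <- plant_spec(masses = masses, attach = attach, n_d = n_d,
                     G = 1, S = 1, seed = seed + 1000)
  na <- nrow(spec$aggregates)
  # plant some condensation without exceeding ion budgets
  n_an <- n_d * 4; n_cat <- sum(masses)
  cdc <- if (n_an > 0) stats::rmultinom(1, sample(0:min(3, n_an), 1), rep(1, na))[, 1] else rep(0L, na)
  csc <- stats::rmultinom(1, sample(0:min(4, n_cat), 1), rep(1, na))[, 1]
  plant_spec(masses = masses, attach = attach, n_d = n_d, G = 1, S = 1,
             condensed_dc = cdc, condensed_sc = csc, seed = seed + 1000)
}
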