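#' Aggregate index
#'
#' Uniquely encodes an aggregate of `s` surfactant chains and `d`
#' dendrimers as a single integer: \eqn{n_{s,d} = d\,n_s + s} for
#' \eqn{s > 0}, and \eqn{n_{0,1} = 0} for a free dendrimer.  The pair
#' (0, d) with \eqn{d \ne 1} is not an admissible aggregate.
#'
#' @param s surfactant chains in the aggregate (vectorised)
#' @param d dendrimers in the aggregate (vectorised)
#' @param n_s total surfactant chains in the system
#' @return integer index vector.
#' @seealso [index_to_sd()] for the inverse mapping.
#' @examples
#' aggregate_index(0, 1, 600) # 0
#' aggregate_index(66, 1, 600) # 666
#' @export
aggregate_index <- function(s, d, n_s) {
  if (any(s < 0) || any(d < 0)) stop("`s` and `d` must be >= 0", call. = FALSE)
  if (any(s == 0 & d != 1)) {
    stop("inadmissible aggregate: s = 0 requires d = 1", call. = FALSE)
  }
  if (any(s > n_s)) stop("`s` cannot exceed n_s", call. = FALSE)
  as.integer(ifelse(s == 0, 0L, d * n_s + s))
}

#' Inverse of the aggregate index
#'
#' Recovers (s, d) from \eqn{n_{s,d}}: for \eqn{n > 0},
#' \eqn{d = (n - 1)\ \mathrm{div}\ n_s} and \eqn{s = n - d\,n_s};
#' \eqn{n = 0} maps to the free dendrimer (0, 1).
#'
#' @param n aggregate index (vectorised)
#' @param n_s total surfactant chains in the system
#' @return tibble with columns `n`, `s`, `d`.
#' @export
index_to_sd <- function(n, n_s) {
  if (any(n < 0)) stop("aggregate index must be >= 0", call. = FALSE)
  d <- ifelse(n == 0, 1L, (n - 1L) %/% n_s)
  s <- ifelse(n == 0, 0L, n - d * n_s)
  tibble::tibble(n = as.integer(n), s = as.integer(s), d = as.integer(d))
}

#' Effective charge of an aggregate
#'
#' \deqn{ch = d N_t - s + n_{sc} - n_{dc}}
#' in units of e: the intrinsic dendrimer charge \eqn{d N_t} plus the
#' surfactant head charge \eqn{-s}, corrected by condensed surfactant
#' counterions (cations, \eqn{+n_{sc}}) and dendrimer counterions (anions,
#' \eqn{-n_{dc}}).  A free dendrimer has charge \eqn{+N_t}; a free micelle
#' \eqn{-s}.
#'
#' @param s,d aggregate composition
#' @param N_t terminal groups per dendrimer
#' @param n_sc,n_dc condensed surfactant / dendrimer counterion counts
#' @return effective charge in units of e.
#' @export
effective_charge <- function(s, d, N_t, n_sc = 0, n_dc = 0) {
  d * N_t - s + n_sc - n_dc
}

.count_hist <- function(x) {
  if (!length(x)) return(tibble::tibble(value = integer(), count = integer()))
  tb <- table(x)
  tibble::tibble(value = as.integer(names(tb)), count = as.integer(tb))
}

#' Accumulate ensemble statistics over analyzed frames
#'
#' Builds every histogram and index-conditioned mean of the aggregate
#' analysis from a per-frame aggregate table (see [analyze_trajectory()]):
#' per-frame histograms of the absorbed-surfactant count \eqn{H(s)}, free
#' micelle / free dendrimer / mixed cluster counts; mass histograms of
#' free, bridge and corona micelles; the aggregate-index histogram
#' \eqn{H(n_{s,d})} with per-index occurrence counts; index-conditioned
#' means of micelle number/mass, condensed counterions and effective
#' charge; and the mean fractions \eqn{f_s}, \eqn{f_{dc}}, \eqn{f_{sc}}.
#'
#' @param aggregates tibble from [analyze_trajectory()] / [analyze_frame()]
#' @param system the `md_system` the frames belong to (supplies `n_s`,
#'   `n_d`, `N_t`); alternatively pass them via `...` as named scalars
#' @param min_occurrence reliability threshold: index-conditioned means are
#'   flagged reliable only for indices observed strictly more than this
#'   many times (default 10)
#' @param n_s,n_d,N_t system constants, used when `system` is NULL
#' @return an object of class `ensemble_stats`.
#' @export
aggregate_stats <- function(aggregates, system = NULL, min_occurrence = 10,
                            n_s = system$n_s, n_d = system$n_d,
                            N_t = system$N_t) {
  stopifnot(!is.null(n_s), !is.null(n_d), !is.null(N_t))
  frames <- unique(aggregates$frame)
  n_frames <- length(frames)

  per_frame <- aggregates |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(
      s_abs = sum(.data$s[.data$d > 0]),
      n_fmic = sum(.data$d == 0),
      n_funi = sum(.data$d == 0 & .data$s == 1),
      n_fdend = sum(.data$d == 1 & .data$s == 0),
      n_mixc = sum(.data$d > 0 & .data$s > 0),
      n_dc_tot = sum(.data$n_dc),
      n_sc_tot = sum(.data$n_sc),
      .groups = "drop"
    )

  mic_long <- aggregates |>
    dplyr::select("frame", "index", "micelles") |>
    tidyr::unnest("micelles")

  index_means <- aggregates |>
    dplyr::group_by(index = .data$index) |>
    dplyr::summarise(
      occurrence = dplyr::n(),
      s = .data$s[1], d = .data$d[1],
      n_br = mean(.data$n_br), n_cor = mean(.data$n_cor),
      n_dc = mean(.data$n_dc), n_sc = mean(.data$n_sc),
      ch = mean(.data$ch),
      .groups = "drop"
    )
  mass_means <- mic_long |>
    dplyr::filter(.data$kind != "free") |>
    dplyr::group_by(index = .data$index, kind = .data$kind) |>
    dplyr::summarise(m = mean(.data$mass), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "m")
  if (!"bridge" %in% names(mass_means)) mass_means$bridge <- NA_real_
  if (!"corona" %in% names(mass_means)) mass_means$corona <- NA_real_
  mass_means <- dplyr::rename(mass_means, m_br = "bridge", m_cor = "corona")
  index_means <- dplyr::left_join(index_means, mass_means, by = "index") |>
    dplyr::mutate(reliable = .data$occurrence > min_occurrence) |>
    dplyr::arrange(.data$index)

  structure(list(
    H_s = .count_hist(per_frame$s_abs),
    H_nfmic = .count_hist(per_frame$n_fmic),
    H_nfuni = .count_hist(per_frame$n_funi),
    H_nfdend = .count_hist(per_frame$n_fdend),
    H_nmixc = .count_hist(per_frame$n_mixc),
    H_mfmic = .count_hist(mic_long$mass[mic_long$kind == "free"]),
    H_mbr = .count_hist(mic_long$mass[mic_long$kind == "bridge"]),
    H_mcor = .count_hist(mic_long$mass[mic_long$kind == "corona"]),
    H_index = .count_hist(aggregates$index),
    index_means = index_means,
    fractions = tibble::tibble(
      f_s = mean(per_frame$s_abs) / n_s,
      f_dc = if (n_d > 0) mean(per_frame$n_dc_tot) / (n_d * N_t) else NA_real_,
      f_sc = if (n_s > 0) mean(per_frame$n_sc_tot) / n_s else NA_real_
    ),
    per_frame = per_frame,
    n_frames = n_frames, n_s = n_s, n_d = n_d, N_t = N_t,
    min_occurrence = min_occurrence
  ), class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("<ensemble_stats> %d frames | n_s=%d n_d=%d N_t=%d\n",
              x$n_frames, x$n_s, x$n_d, x$N_t))
  fr <- x$fractions
  cat(sprintf("  f_s = %.3f | f_dc = %.3f | f_sc = %.3f\n",
              fr$f_s, fr$f_dc, fr$f_sc))
  cat(sprintf("  %d distinct aggregate indices (%d reliable at occurrence > %d)\n",
              nrow(x$index_means), sum(x$index_means$reliable),
              x$min_occurrence))
  invisible(x)
}

#' Index-conditioned means with reliability filtering
#'
#' Per-index means of micelle number and mass, condensed counterions and
#' effective charge, reported only for aggregate indices observed strictly
#' more than `min_occurrence` times; rarer indices are excluded (set
#' `keep_unreliable = TRUE` to keep them flagged).
#'
#' @param stats an `ensemble_stats` object
#' @param min_occurrence occurrence threshold (default taken from `stats`)
#' @param keep_unreliable keep excluded rows with `reliable = FALSE`
#' @return tibble of per-index means.
#' @export
index_conditioned_means <- function(stats, min_occurrence = stats$min_occurrence,
                                    keep_unreliable = FALSE) {
  im <- stats$index_means |>
    dplyr::mutate(reliable = .data$occurrence > min_occurrence)
  if (keep_unreliable) im else dplyr::filter(im, .data$reliable)
}

#' Statistically favored mixed clusters
#'
#' Locates the highest local maximum of the aggregate-index histogram
#' \eqn{H(n_{s,d})} within the range of `d`-dendrimer mixed clusters
#' (\eqn{d\,n_s < n \le (d+1)\,n_s}).  Zero-count gaps are merged before
#' neighbour comparison; a bin is a local maximum when strictly greater
#' than both retained neighbours (one neighbour at the range ends).  Ties
#' between equal maxima resolve to the lower index with a warning.
#'
#' @param stats an `ensemble_stats` object
#' @param d number of dendrimers in the favored cluster (1 or 2 in the
#'   two-dendrimer systems studied)
#' @param smooth apply a window-3 moving-average smoothing before peak
#'   finding (off by default)
#' @return one-row tibble `d`, `index`, `s_f`, `s_f_per_d`, `count`; a
#'   zero-row tibble when the d-range holds no observations (favored
#'   cluster absent).
#' @export
favored_clusters <- function(stats, d, smooth = FALSE) {
  h <- stats$H_index
  n_s <- stats$n_s
  h <- h[h$value > d * n_s & h$value <= (d + 1) * n_s & h$count > 0, ]
  if (!nrow(h)) {
    return(tibble::tibble(d = integer(), index = integer(), s_f = integer(),
                          s_f_per_d = numeric(), count = numeric()))
  }
  h <- h[order(h$value), ]
  y <- as.numeric(h$count)
  if (smooth && length(y) >= 3) {
    y <- stats::filter(y, rep(1 / 3, 3), sides = 2)
    y[1] <- h$count[1]; y[length(y)] <- h$count[nrow(h)]
    y <- as.numeric(y)
  }
  k <- length(y)
  # endpoints compare against their single existing neighbour
  is_max <- if (k == 1) TRUE else y > c(-Inf, y[-k]) & y > c(y[-1], -Inf)
  cand <- which(is_max)
  if (!length(cand)) cand <- which.max(y) # plateau-only histogram
  best <- cand[y[cand] == max(y[cand])]
  if (length(best) > 1) {
    warning("tie between favored-cluster peaks at indices ",
            paste(h$value[best], collapse = ", "),
            "; choosing the lower index", call. = FALSE)
    best <- best[1]
  }
  idx <- as.integer(h$value[best])
  tibble::tibble(d = as.integer(d), index = idx, s_f = as.integer(idx - d * n_s),
                 s_f_per_d = (idx - d * n_s) / d, count = h$count[best])
}

#' Global charge ledger check
#'
#' Per frame, the sum of aggregate effective charges plus the charges of
#' free (uncondensed) counterions must vanish exactly; this is an identity
#' of the taxonomy when counterion assignment is exclusive.
#'
#' @param aggregates per-frame aggregate table
#' @param system the `md_system`
#' @return tibble with columns `frame` and `total_charge`.
#' @export
charge_ledger <- function(aggregates, system) {
  n_anion <- system$n_d * system$N_t
  n_cation <- system$n_s
  aggregates |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(
      total_charge = sum(.data$ch) -
        (n_anion - sum(.data$n_dc)) + (n_cation - sum(.data$n_sc)),
      .groups = "drop"
    )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ensemble_stats object
#'
#' Returns the index-conditioned means table (one row per aggregate index)
#' with occurrence counts and reliability flags.
#'
#' @param x an `ensemble_stats` object
#' @param ... unused
#' @return a tibble.
#' @export
tidy.ensemble_stats <- function(x, ...) {
  index_conditioned_means(x, keep_unreliable = TRUE)
}

#' One-row summary of an ensemble_stats object
#'
#' @param x an `ensemble_stats` object
#' @param ... unused
#' @return a tibble with frame count, mean fractions and mean micelle
#'   numbers.
#' @export
glance.ensemble_stats <- function(x, ...) {
  tibble::tibble(
    n_frames = x$n_frames,
    f_s = x$fractions$f_s,
    f_dc = x$fractions$f_dc,
    f_sc = x$fractions$f_sc,
    mean_n_fmic = mean(x$per_frame$n_fmic),
    mean_n_funi = mean(x$per_frame$n_funi),
    mean_n_mixc = mean(x$per_frame$n_mixc),
    n_indices = nrow(x$index_means),
    n_reliable = sum(x$index_means$reliable)
  )
}

#' Plot ensemble histograms
#'
#' `autoplot()` draws the aggregate-index histogram on a log-linear scale
#' with vertical separators between the d = 0, 1, 2 index ranges (the
#' layout used throughout the aggregate analysis), or any of the other
#' accumulated histograms.
#'
#' @param object an `ensemble_stats` object
#' @param which histogram to draw: `"index"`, `"s"`, `"n_fmic"`,
#'   `"m_fmic"`, `"m_br"`, `"m_cor"`, `"n_fdend"`, `"n_mixc"`
#' @param probability normalise counts to probabilities by total
#'   observations
#' @param ... unused
#' @return a ggplot object.
#' @export
autoplot.ensemble_stats <- function(object, which = "index",
                                    probability = TRUE, ...) {
  which <- match.arg(which, c("index", "s", "n_fmic", "m_fmic", "m_br",
                              "m_cor", "n_fdend", "n_mixc"))
  h <- switch(which,
    index = object$H_index, s = object$H_s, n_fmic = object$H_nfmic,
    m_fmic = object$H_mfmic, m_br = object$H_mbr, m_cor = object$H_mcor,
    n_fdend = object$H_nfdend, n_mixc = object$H_nmixc
  )
  ylab <- if (probability) "probability" else "count"
  if (probability && nrow(h)) h$count <- h$count / sum(h$count)
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$value, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = switch(which, index = expression(n[s * "," * d]), which),
      y = ylab
    ) +
    ggplot2::theme_bw()
  if (which == "index") {
    seps <- (1:2) * object$n_s + 0.5
    p <- p + ggplot2::geom_vline(xintercept = seps, linetype = 1) +
      ggplot2::scale_y_log10()
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Summary table of the aggregate analysis
#'
#' Writes (or returns) the headline quantities: mean fractions, favored
#' clusters per d with their mean effective charge.
#'
#' @param stats an `ensemble_stats` object
#' @param d_values d ranges to scan for favored clusters
#' @return list with `fractions` (one-row tibble) and `favored` (one row
#'   per d with the favored index, s_f, s_f/d and its mean effective
#'   charge `ch_f`).
#' @export
stats_summary <- function(stats, d_values = 1:2) {
  fav <- purrr::map_dfr(d_values, function(d) favored_clusters(stats, d))
  if (nrow(fav)) {
    im <- stats$index_means[, c("index", "ch")]
    fav <- dplyr::left_join(fav, im, by = "index") |>
      dplyr::rename(ch_f = "ch")
  }
  list(fractions = stats$fractions, favored = fav)
}
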