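#' Write a LAMMPS data file (atom_style full)
#'
#' Emits header, `Masses`, `Atoms` (id molecule type charge x y z) and
#' `Bonds` sections.  The species-to-numeric-type mapping is recorded in
#' the header comment.
#'
#' @param system an `md_system`
#' @param frame an `md_frame` with coordinates for every bead
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(system, frame, path) {
  b <- system$beads
  stopifnot(nrow(frame$positions) == system$n_beads)
  map <- paste(sprintf("%d=%s", .species_levels, names(.species_levels)),
               collapse = " ")
  lines <- c(
    paste("# dendrisurf data file | species:", map),
    "",
    sprintf("%d atoms", system$n_beads),
    sprintf("%d bonds", nrow(system$bonds)),
    sprintf("%d atom types", length(.species_levels)),
    "1 bond types",
    "",
    sprintf("0.0 %.10g xlo xhi", frame$box_L),
    sprintf("0.0 %.10g ylo yhi", frame$box_L),
    sprintf("0.0 %.10g zlo zhi", frame$box_L),
    "",
    "Masses",
    "",
    sprintf("%d 1.0", seq_along(.species_levels)),
    "",
    "Atoms # full",
    "",
    sprintf("%d %d %d %.17g %.17g %.17g %.17g",
            b$id, b$molecule_id, b$type, b$charge,
            frame$positions[, 1], frame$positions[, 2], frame$positions[, 3])
  )
  if (nrow(system$bonds)) {
    lines <- c(lines, "", "Bonds", "",
               sprintf("%d %d %d %d", seq_len(nrow(system$bonds)),
                       system$bonds$type, system$bonds$i, system$bonds$j))
  }
  writeLines(lines, path)
  invisible(path)
}

.parse_section <- function(lines, name, n, ncol_min, path) {
  hdr <- grep(paste0("^", name, "\\b"), lines)
  if (!length(hdr)) {
    if (n == 0) return(NULL)
    stop("malformed data file ", path, ": missing '", name, "' section",
         call. = FALSE)
  }
  start <- hdr[1] + 1
  while (start <= length(lines) && !nzchar(trimws(lines[start]))) start <- start + 1
  rows <- lines[seq(start, length.out = n)]
  bad <- which(!nzchar(trimws(rows)))
  if (length(bad)) {
    stop("malformed data file ", path, ": '", name, "' section ends early at line ",
         start + bad[1] - 1, call. = FALSE)
  }
  con <- textConnection(rows)
  on.exit(close(con))
  out <- utils::read.table(con)
  if (ncol(out) < ncol_min) {
    stop("malformed data file ", path, ": '", name, "' section at line ", start,
         " has ", ncol(out), " columns, expected >= ", ncol_min, call. = FALSE)
  }
  out
}

#' Read a LAMMPS data file (atom_style full)
#'
#' Losslessly recovers ids, molecule ids, species (from the numeric type),
#' charges, bonds and coordinates written by [write_lammps_data()].
#'
#' @param path data file
#' @return list with `system` (an `md_system`) and `frame` (an `md_frame`).
#' @export
read_lammps_data <- function(path) {
  lines <- readLines(path)
  grab <- function(pat) {
    ln <- grep(pat, lines, value = TRUE)
    if (!length(ln)) stop("malformed data file ", path, ": missing '",
                          pat, "' header", call. = FALSE)
    as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][1])
  }
  n_atoms <- grab("atoms$")
  n_bonds <- grab("bonds$")
  xhi <- {
    ln <- grep("xlo xhi", lines, value = TRUE)
    if (!length(ln)) stop("malformed data file ", path, ": missing box bounds",
                          call. = FALSE)
    v <- as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][1:2])
    v[2] - v[1]
  }
  at <- .parse_section(lines, "Atoms", n_atoms, 7, path)
  at <- at[order(at[[1]]), ]
  type <- as.integer(at[[3]])
  if (any(!type %in% .species_levels)) {
    stop("malformed data file ", path, ": unknown atom type ",
         paste(setdiff(type, .species_levels), collapse = ","), call. = FALSE)
  }
  species <- names(.species_levels)[match(type, .species_levels)]
  bonds <- if (n_bonds > 0) {
    bo <- .parse_section(lines, "Bonds", n_bonds, 4, path)
    tibble::tibble(i = as.integer(bo[[3]]), j = as.integer(bo[[4]]),
                   type = as.integer(bo[[2]]))
  } else tibble::tibble(i = integer(), j = integer(), type = integer())

  mol <- as.integer(at[[2]])
  # dendrimer ids: consecutive numbering of molecules containing dendrimer beads
  is_dend <- species %in% c("dendrimer-core", "dendrimer-interior",
                            "dendrimer-terminal")
  dend_mols <- unique(mol[is_dend])
  dendrimer_id <- ifelse(is_dend, match(mol, dend_mols), NA_integer_)
  n_d <- length(dend_mols)
  n_s <- length(unique(mol[species == "surfactant-head"]))
  N_t <- if (n_d > 0) sum(species == "dendrimer-terminal") %/% n_d else 0L
  N_d <- if (n_d > 0) sum(is_dend) %/% n_d else 0L

  beads <- tibble::tibble(
    id = as.integer(at[[1]]), molecule_id = mol,
    dendrimer_id = as.integer(dendrimer_id),
    species = species, type = type, charge = as.numeric(at[[4]])
  )
  sys <- structure(
    list(beads = beads,
         bonds = bonds[, c("i", "j", "type")],
         n_beads = as.integer(n_atoms), n_d = n_d, n_s = n_s,
         N_t = as.integer(N_t), N_d = as.integer(N_d), G = NA, S = NA),
    class = "md_system"
  )
  frame <- md_frame(as.matrix(at[, 5:7]), xhi, step = 0L)
  list(system = sys, frame = frame)
}

#' Write frames as a LAMMPS dump trajectory
#'
#' Text dump with `ITEM: ATOMS id type x y z` records, one block per frame.
#'
#' @param frames list of `md_frame` objects (or a single one)
#' @param system the matching `md_system` (supplies the type column)
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_lammps_dump <- function(frames, system, path) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(c(
      "ITEM: TIMESTEP", as.character(fr$step),
      "ITEM: NUMBER OF ATOMS", as.character(nrow(fr$positions)),
      "ITEM: BOX BOUNDS pp pp pp",
      sprintf("0.0 %.10g", fr$box_L), sprintf("0.0 %.10g", fr$box_L),
      sprintf("0.0 %.10g", fr$box_L),
      "ITEM: ATOMS id type x y z",
      sprintf("%d %d %.10g %.10g %.10g", system$beads$id, system$beads$type,
              fr$positions[, 1], fr$positions[, 2], fr$positions[, 3])
    ), con)
  }
  invisible(path)
}

#' Read a LAMMPS dump trajectory
#'
#' Parses text dump frames (`id type x y z`, or unwrapped `xu yu zu`;
#' coordinates are wrapped into the primary cell on read so wrapped and
#' unwrapped dumps analyse identically).  Atoms are re-ordered by id and,
#' when a `system` is given, checked against its bead count.
#'
#' @param path dump file
#' @param stride keep every `stride`-th frame (default 1 = all)
#' @param system optional `md_system` for id reconciliation
#' @return list of `md_frame` objects.
#' @export
read_lammps_dump <- function(path, stride = 1L, system = NULL) {
  lines <- readLines(path)
  starts <- grep("^ITEM: TIMESTEP", lines)
  if (!length(starts)) stop("not a LAMMPS dump file: ", path, call. = FALSE)
  starts <- starts[seq(1, length(starts), by = stride)]
  frames <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    i <- starts[k]
    step <- as.integer(lines[i + 1])
    n <- as.integer(lines[i + 3])
    bl <- as.numeric(strsplit(trimws(lines[i + 5]), "\\s+")[[1]])
    box_L <- bl[2] - bl[1]
    cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", lines[i + 8]), "\\s+")[[1]]
    xcols <- match(c("x", "y", "z"), cols)
    if (anyNA(xcols)) xcols <- match(c("xu", "yu", "zu"), cols)
    idcol <- match("id", cols)
    if (anyNA(xcols) || is.na(idcol)) {
      stop("dump frame at line ", i, " lacks id and x y z (or xu yu zu) columns",
           call. = FALSE)
    }
    body <- lines[i + 8 + seq_len(n)]
    if (anyNA(body)) {
      stop("dump frame ", k, " (step ", step, ") is truncated", call. = FALSE)
    }
    con <- textConnection(body)
    tab <- tryCatch(utils::read.table(con), error = function(e) {
      stop("dump frame ", k, " (step ", step, ") is malformed: ",
           conditionMessage(e), call. = FALSE)
    })
    close(con)
    if (!is.null(system) && n != system$n_beads) {
      stop("dump frame ", k, " (step ", step, ") has ", n,
           " atoms but the topology has ", system$n_beads, call. = FALSE)
    }
    ids <- as.integer(tab[[idcol]])
    if (!is.null(system) && !setequal(ids, system$beads$id)) {
      stop("dump frame ", k, " (step ", step,
           ") atom ids do not match the topology", call. = FALSE)
    }
    ord <- order(ids)
    frames[[k]] <- md_frame(as.matrix(tab[ord, xcols]), box_L, step = step)
  }
  frames
}

#' Write an aggregate table as TSV
#'
#' Flat per-frame aggregate records (list columns dropped):
#' frame, index, s, d, n_br, n_cor, n_dc, n_sc, ch.
#'
#' @param aggregates tibble from [analyze_trajectory()]
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_aggregate_table <- function(aggregates, path) {
  flat <- aggregates[, c("frame", "index", "s", "d", "n_br", "n_cor",
                         "n_dc", "n_sc", "ch")]
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' All model, integrator and analysis parameters of one run.  The
#' `"paper"` preset reproduces the published parameterisation exactly:
#' two dendrimers, 600 surfactant chains, box L* = 70, eps* in
#' {1.25, 1.5, 1.6}, k* = 30, R0* = 1.5, LJ tail cutoff 2.5, Coulomb
#' cutoff 10 with force tolerance 1e-4, gamma* = 1, dt* = 0.005, T* = 1,
#' e* = 9; the `"desk"` preset is the reduced single-dendrimer system
#' used for qualitative checks (1 G3S4 dendrimer, 60 chains, L* = 30).
#'
#' @param preset `"paper"`, `"desk"`, or `"none"`
#' @param ... overrides for individual fields
#' @return a named list of class `run_config`.
#' @export
run_config <- function(preset = c("paper", "desk", "none"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    G = 3L, S = 4L, n_d = 2L, n_s = 600L, L_star = 70,
    eps_tt = 1.5, eps_other = 1, rc_lj_tt = 2.5, rc_lj_other = 2^(1 / 6),
    k_fene = 30, R0 = 1.5, e_star = 9, T_star = 1, sigma = 1, mass = 1,
    rc_coul = 10, coul_tolerance = 1e-4, gamma_star = 1, dt_star = 0.005,
    L_box = NULL,
    equil_steps = 1e6, n_steps = 1e7, relax_steps = 2000L,
    dump_stride = 1000L, r_star = 1.5, min_occurrence = 10L,
    seed = 1L, coulomb = "ewald"
  )
  if (preset == "desk") {
    cfg$n_d <- 1L; cfg$n_s <- 60L; cfg$L_star <- 30
    cfg$equil_steps <- 1e5; cfg$n_steps <- 2e5
    cfg$coulomb <- "cutoff"
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read / write a flat key-value run configuration file
#'
#' One `key = value` pair per line; `#` starts a comment.
#'
#' @param path config file
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- strsplit(lines, "=")
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  cfg <- run_config("none")
  for (k in seq_along(keys)) {
    key <- keys[k]
    if (!key %in% names(cfg)) stop("unknown config key '", key, "' in ", path,
                                   call. = FALSE)
    old <- cfg[[key]]
    cfg[[key]] <- if (is.character(old) || is.null(old)) vals[k] else
      if (is.integer(old)) as.integer(vals[k]) else as.numeric(vals[k])
  }
  cfg
}

#' @rdname read_run_config
#' @param config a `run_config`
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  keep <- !vapply(config, is.null, logical(1))
  writeLines(sprintf("%s = %s", names(config)[keep],
                     vapply(config[keep], format, "")), path)
  invisible(path)
}
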