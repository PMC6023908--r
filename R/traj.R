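# element masses (amu) keyed by the first letter of the atom name; used for
# centre-of-mass weights unless the selection config overrides them
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06)

.mass_from_name <- function(name, overrides = NULL) {
  m <- rep(NA_real_, length(name))
  if (!is.null(overrides) && length(overrides))
    m <- unname(unlist(overrides)[name])
  miss <- is.na(m)
  if (any(miss)) {
    el <- toupper(substr(gsub("^[0-9]+", "", name[miss]), 1L, 1L))
    m[miss] <- .element_masses[el]
  }
  if (anyNA(m))
    stop("cannot assign a mass to atom name(s): ",
         paste(unique(name[is.na(m)]), collapse = ", "))
  m
}

# minimal-image displacement along one axis
.wrap <- function(dx, L) dx - L * round(dx / L)

#' Assemble a trajectory system from coordinates and a selection config
#'
#' Binds frames, the atom table and resolved role selections (solute
#' molecules, lipid atoms, phosphate/ester/glycerol oxygens, hydrogen-bond
#' donors with their attached hydrogens, acceptors by chemical class,
#' orientation vector pairs and ring triplets) into one object consumed by
#' the analysis functions.
#'
#' @param gro list with \code{atoms} and \code{frames}, as returned by
#'   \code{\link{read_gro}} (or built in code).
#' @param config selection configuration: an R list or a YAML file path (see
#'   \code{\link{read_selection_config}}). Expected fields:
#'   \code{lipid_resnames}, \code{solute_resnames}, \code{roles} (named list
#'   \code{phosphate}/\code{ester}/\code{glycerol} of resname -> atom-name
#'   vectors), \code{donors} (list of \code{resname}/\code{atom}/
#'   \code{hydrogen}), \code{acceptors} (list of \code{resname}/\code{atom}/
#'   \code{class}), \code{orient_vector} (\code{resname}/\code{from}/
#'   \code{to}), \code{ring_triplet} (\code{resname}/\code{atoms}), optional
#'   \code{masses} (atom name -> amu).
#' @return object of class \code{trajectory_system}.
#' @export
trajectory_system <- function(gro, config) {
  if (is.character(config)) config <- read_selection_config(config)
  atoms <- gro$atoms
  frames <- gro$frames
  n <- nrow(atoms)
  if (!length(frames)) stop("no frames")
  for (fr in frames) {
    if (nrow(fr$coords) != n) stop("frame atom count differs from atom table")
    if (any(fr$box <= 0)) stop("box components must be positive")
  }
  atoms$mass <- .mass_from_name(atoms$name, config$masses)

  find_role <- function(role) {
    spec <- config$roles[[role]]
    if (is.null(spec)) return(integer(0))
    idx <- integer(0)
    for (rn in names(spec))
      idx <- c(idx, which(atoms$resname == rn & atoms$name %in% spec[[rn]]))
    sort(idx)
  }

  lipid_idx <- which(atoms$resname %in% config$lipid_resnames)
  solute_idx <- which(atoms$resname %in% config$solute_resnames)
  if (!length(solute_idx)) stop("selection for role 'solute' is empty")
  solute_mols <- split(solute_idx, atoms$resid[solute_idx])

  donors <- do.call(rbind, lapply(config$donors, function(d) {
    di <- which(atoms$resname == d$resname & atoms$name == d$atom)
    if (!length(di)) return(NULL)
    hi <- vapply(di, function(i) {
      cand <- which(atoms$resid == atoms$resid[i] &
                    atoms$resname == d$resname & atoms$name == d$hydrogen)
      if (length(cand) != 1L)
        stop(sprintf("donor %s/%s: expected exactly one attached hydrogen %s",
                     d$resname, d$atom, d$hydrogen))
      cand
    }, integer(1))
    side <- if (d$resname %in% config$solute_resnames) "solute" else "lipid"
    data.frame(donor = di, hydrogen = hi, side = side,
               stringsAsFactors = FALSE)
  }))
  acceptors <- do.call(rbind, lapply(config$acceptors, function(a) {
    ai <- which(atoms$resname == a$resname & atoms$name == a$atom)
    if (!length(ai)) return(NULL)
    side <- if (a$resname %in% config$solute_resnames) "solute" else "lipid"
    data.frame(index = ai, class = a$class, side = side,
               stringsAsFactors = FALSE)
  }))

  orient_pairs <- NULL
  if (!is.null(config$orient_vector)) {
    ov <- config$orient_vector
    orient_pairs <- t(vapply(solute_mols, function(ix) {
      fr <- ix[atoms$name[ix] == ov$from]
      to <- ix[atoms$name[ix] == ov$to]
      if (length(fr) != 1L || length(to) != 1L)
        stop("orientation vector atoms not found in every solute")
      c(fr, to)
    }, integer(2)))
  }
  ring_triplets <- NULL
  if (!is.null(config$ring_triplet)) {
    rt <- config$ring_triplet
    ring_triplets <- t(vapply(solute_mols, function(ix) {
      pts <- vapply(rt$atoms, function(nm) {
        p <- ix[atoms$name[ix] == nm]
        if (length(p) != 1L) stop("ring atom ", nm, " missing in a solute")
        p
      }, integer(1))
      pts
    }, integer(3)))
  }

  structure(list(atoms = atoms, frames = frames,
                 selections = list(lipid = lipid_idx,
                                   solute_mols = solute_mols,
                                   phosphate = find_role("phosphate"),
                                   ester = find_role("ester"),
                                   glycerol = find_role("glycerol"),
                                   donors = donors, acceptors = acceptors,
                                   orient_pairs = orient_pairs,
                                   ring_triplets = ring_triplets)),
            class = "trajectory_system")
}

#' Read a YAML selection configuration
#' @param path YAML file mapping roles to residue/atom names; see
#'   \code{\link{trajectory_system}} for the expected fields.
#' @return the configuration as a list.
#' @export
read_selection_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  yaml::read_yaml(path)
}

#' @export
print.trajectory_system <- function(x, ...) {
  cat("trajectory system:", nrow(x$atoms), "atoms,",
      length(x$frames), "frames\n")
  cat(sprintf("  %d lipid atoms, %d solute molecules\n",
              length(x$selections$lipid), length(x$selections$solute_mols)))
  cat(sprintf("  time span %.3f - %.3f ns\n",
              x$frames[[1L]]$time_ns,
              x$frames[[length(x$frames)]]$time_ns))
  invisible(x)
}

# mass-weighted COM z of a whole molecule: atoms are first made whole across
# the periodic boundary relative to the first atom
.molecule_com <- function(coords, box, idx, mass) {
  ref <- coords[idx[1L], ]
  d <- sweep(coords[idx, , drop = FALSE], 2L, ref)
  for (ax in 1:3) d[, ax] <- .wrap(d[, ax], box[ax])
  w <- mass[idx] / sum(mass[idx])
  ref + colSums(d * w)
}

.bilayer_com_z <- function(coords, box, lipid_idx, mass) {
  # lipids assumed whole and centred within the box; plain weighted mean
  sum(coords[lipid_idx, 3L] * mass[lipid_idx]) / sum(mass[lipid_idx])
}

#' Assign lipids to bilayer leaflets
#'
#' Labels each lipid as belonging to the upper or lower leaflet by the sign
#' of its phosphate z coordinate relative to the bilayer centre of mass,
#' using the minimal image along z.
#'
#' @param traj a \code{\link{trajectory_system}}.
#' @param frame frame index (default 1).
#' @return named character vector ("upper"/"lower"), one entry per lipid
#'   bearing a phosphate atom, named by residue index.
#' @export
assign_leaflets <- function(traj, frame = 1L) {
  stopifnot(inherits(traj, "trajectory_system"))
  sel <- traj$selections
  if (!length(sel$lipid)) stop("selection for role 'lipid' is empty")
  if (!length(sel$phosphate)) stop("selection for role 'phosphate' is empty")
  fr <- traj$frames[[frame]]
  zc <- .bilayer_com_z(fr$coords, fr$box, sel$lipid, traj$atoms$mass)
  dz <- .wrap(fr$coords[sel$phosphate, 3L] - zc, fr$box[3L])
  lab <- ifelse(dz > 0, "upper", "lower")
  names(lab) <- traj$atoms$resid[sel$phosphate]
  if (length(unique(lab)) == 1L)
    warning("all phosphate atoms lie on one side of the bilayer centre")
  lab
}

#' Insertion-depth profile along the bilayer normal
#'
#' For every frame, computes the mass-weighted bilayer centre of mass and
#' reports the mean absolute z offset (minimal image) of solute molecule
#' centres of mass, of phosphate atoms, and of per-lipid glycerol-group
#' centres of mass.
#'
#' @param traj a \code{\link{trajectory_system}}.
#' @return data frame of class \code{depth_profile} with columns
#'   \code{time_ns}, \code{solute_z}, \code{phosphate_z}, \code{glycerol_z}
#'   (nm).
#' @export
depth_profile <- function(traj) {
  stopifnot(inherits(traj, "trajectory_system"))
  sel <- traj$selections
  for (role in c("lipid", "phosphate", "glycerol"))
    if (!length(sel[[role]]))
      stop("selection for role '", role, "' is empty")
  mass <- traj$atoms$mass
  gly_mols <- split(sel$glycerol, traj$atoms$resid[sel$glycerol])
  rows <- lapply(traj$frames, function(fr) {
    zc <- .bilayer_com_z(fr$coords, fr$box, sel$lipid, mass)
    Lz <- fr$box[3L]
    sol_z <- vapply(sel$solute_mols, function(ix)
      abs(.wrap(.molecule_com(fr$coords, fr$box, ix, mass)[3L] - zc, Lz)),
      numeric(1))
    p_z <- abs(.wrap(fr$coords[sel$phosphate, 3L] - zc, Lz))
    g_z <- vapply(gly_mols, function(ix)
      abs(.wrap(.molecule_com(fr$coords, fr$box, ix, mass)[3L] - zc, Lz)),
      numeric(1))
    c(time_ns = fr$time_ns, solute_z = mean(sol_z),
      phosphate_z = mean(p_z), glycerol_z = mean(g_z))
  })
  out <- as.data.frame(do.call(rbind, rows))
  structure(out, class = c("depth_profile", "data.frame"))
}

#' Count hydrogen bonds in a single frame
#'
#' Applies the geometric criterion: a donor-acceptor pair is hydrogen bonded
#' when the donor-acceptor distance is at most \code{d_max} and the
#' hydrogen-donor-acceptor angle is at most \code{angle_max}, under the
#' minimal-image convention. Only pairs across the solute/lipid divide are
#' counted (solute donors to lipid acceptors and vice versa), classified by
#' the acceptor chemical class.
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param box length-3 box vector (nm).
#' @param donors data frame with columns \code{donor}, \code{hydrogen},
#'   \code{side}.
#' @param acceptors data frame with columns \code{index}, \code{class},
#'   \code{side}.
#' @param criteria list with \code{d_max} (nm) and \code{angle_max}
#'   (degrees); defaults 0.35 nm and 30 degrees.
#' @return named numeric vector of bond counts per acceptor class, with a
#'   \code{"total"} element.
#' @export
count_hbonds <- function(coords, box, donors, acceptors,
                         criteria = list(d_max = 0.35, angle_max = 30)) {
  if (is.null(donors) || !nrow(donors)) stop("donor selection is empty")
  if (is.null(acceptors) || !nrow(acceptors))
    stop("acceptor selection is empty")
  if (criteria$d_max <= 0 || criteria$angle_max <= 0)
    stop("criteria must be positive")
  classes <- sort(unique(acceptors$class))
  counts <- stats::setNames(numeric(length(classes)), classes)
  cosmax <- cos(criteria$angle_max * pi / 180)
  for (k in seq_len(nrow(donors))) {
    d <- donors$donor[k]; h <- donors$hydrogen[k]
    acc <- acceptors[acceptors$side != donors$side[k], , drop = FALSE]
    if (!nrow(acc)) next
    da <- sweep(coords[acc$index, , drop = FALSE], 2L, coords[d, ])
    for (ax in 1:3) da[, ax] <- .wrap(da[, ax], box[ax])
    dist <- sqrt(rowSums(da^2))
    near <- which(dist <= criteria$d_max)
    if (!length(near)) next
    dh <- .wrap(coords[h, ] - coords[d, ], box)
    ndh <- sqrt(sum(dh^2))
    for (j in near) {
      ca <- sum(da[j, ] * dh) / (dist[j] * ndh)
      if (ca >= cosmax)
        counts[acc$class[j]] <- counts[acc$class[j]] + 1
    }
  }
  c(counts, total = sum(counts))
}

#' Hydrogen-bond time series and trailing-window means
#'
#' Per-frame hydrogen-bond counts by acceptor class, normalised per solute
#' molecule, plus the mean over a trailing time window (e.g. the last 100 ns
#' of a production run).
#'
#' @param traj a \code{\link{trajectory_system}}.
#' @param criteria geometric criteria, see \code{\link{count_hbonds}}.
#' @param window_ns trailing-window length for the summary means.
#' @return data frame of class \code{hbond_series} (\code{time_ns} plus one
#'   column per acceptor class and \code{total}), with attribute
#'   \code{window_means}.
#' @export
hbond_timeseries <- function(traj,
                             criteria = list(d_max = 0.35, angle_max = 30),
                             window_ns = NULL) {
  stopifnot(inherits(traj, "trajectory_system"))
  sel <- traj$selections
  n_sol <- length(sel$solute_mols)
  rows <- lapply(traj$frames, function(fr) {
    ct <- count_hbonds(fr$coords, fr$box, sel$donors, sel$acceptors,
                       criteria) / n_sol
    c(time_ns = fr$time_ns, ct)
  })
  out <- as.data.frame(do.call(rbind, rows))
  t_end <- max(out$time_ns)
  span <- t_end - min(out$time_ns)
  if (is.null(window_ns)) window_ns <- span
  if (window_ns <= 0) stop("window must be positive")
  if (window_ns > span + 1e-9)
    stop("window exceeds the trajectory time span")
  tail_rows <- out$time_ns >= t_end - window_ns
  wm <- colMeans(out[tail_rows, -1L, drop = FALSE])
  structure(out, class = c("hbond_series", "data.frame"),
            window_means = wm, window_ns = window_ns)
}

# ---- orientation angles ----

.angle_from_z <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(NA_real_)
  acos(max(-1, min(1, v[3L] / nv))) * 180 / pi
}

#' Build an angle distribution histogram
#'
#' @param theta_deg angles in degrees on [0, 180]; NAs are dropped and
#'   counted as skipped samples.
#' @param bin_deg uniform bin width in degrees (default 2).
#' @param fold if \code{TRUE}, map theta to min(theta, 180 - theta), merging
#'   the two supplementary-angle populations arising from the two leaflets.
#' @return object of class \code{angle_distribution}: \code{bin_edges},
#'   \code{density} (probability per degree), \code{n_samples},
#'   \code{n_skipped}, \code{fold}.
#' @export
angle_distribution <- function(theta_deg, bin_deg = 2, fold = FALSE) {
  skipped <- sum(is.na(theta_deg))
  th <- theta_deg[!is.na(theta_deg)]
  if (!length(th)) stop("no angle samples")
  if (any(th < -1e-9 | th > 180 + 1e-9)) stop("angles must lie in [0, 180]")
  if (fold) th <- pmin(th, 180 - th)
  edges <- seq(0, 180, by = bin_deg)
  if (abs(edges[length(edges)] - 180) > 1e-9)
    stop("bin width must divide 180")
  counts <- graphics::hist(th, breaks = edges, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  # hist() with right=FALSE still closes the last bin; exact 180 lands there
  structure(list(bin_edges = edges,
                 density = counts / (length(th) * bin_deg),
                 n_samples = length(th), n_skipped = skipped, fold = fold),
            class = "angle_distribution")
}

#' @export
print.angle_distribution <- function(x, ...) {
  cat(sprintf("angle distribution: %d samples, %g-degree bins%s\n",
              x$n_samples, diff(x$bin_edges[1:2]),
              if (x$fold) " (folded to [0, 90])" else ""))
  md <- angle_modes(x, n = 2)
  cat("  principal mode(s) near:", paste(round(md, 1), collapse = ", "),
      "degrees\n")
  if (x$n_skipped) cat("  skipped samples:", x$n_skipped, "\n")
  invisible(x)
}

#' @export
plot.angle_distribution <- function(x, ...) {
  mids <- x$bin_edges[-length(x$bin_edges)] + diff(x$bin_edges) / 2
  graphics::plot(mids, x$density, type = "h",
                 xlab = "angle from bilayer normal (degrees)",
                 ylab = "probability density (per degree)", ...)
  invisible(x)
}

#' Locate the modes of an angle distribution
#'
#' @param x an \code{\link{angle_distribution}}.
#' @param n maximum number of modes to return.
#' @param min_frac local maxima below this fraction of the global maximum are
#'   ignored.
#' @return bin midpoints (degrees) of the principal local maxima, ordered by
#'   density.
#' @export
angle_modes <- function(x, n = 2, min_frac = 0.5) {
  d <- x$density
  mids <- x$bin_edges[-length(x$bin_edges)] + diff(x$bin_edges) / 2
  pad <- c(-Inf, d, -Inf)
  is_max <- d >= pad[seq_along(d)] & d > pad[seq_along(d) + 2L]
  keep <- which(is_max & d >= min_frac * max(d))
  keep <- keep[order(d[keep], decreasing = TRUE)]
  mids[utils::head(keep, n)]
}

#' Solute bond-vector tilt angles relative to the bilayer normal
#'
#' For every solute in every frame, takes the vector between the configured
#' orientation atom pair and measures its angle to the +z axis (the bilayer
#' normal). Unfolded distributions on [0, 180] retain the two supplementary-
#' angle populations produced by solutes in opposite leaflets; folding maps
#' them onto a single mode.
#'
#' @param traj a \code{\link{trajectory_system}} with an
#'   \code{orient_vector} configured.
#' @param fold fold the distribution onto [0, 90].
#' @param bin_deg histogram bin width (degrees).
#' @param skip_ns discard frames earlier than this time.
#' @return an \code{\link{angle_distribution}}.
#' @export
bond_vector_angles <- function(traj, fold = FALSE, bin_deg = 2,
                               skip_ns = 0) {
  stopifnot(inherits(traj, "trajectory_system"))
  pairs <- traj$selections$orient_pairs
  if (is.null(pairs)) stop("no orientation vector pair configured")
  th <- unlist(lapply(traj$frames, function(fr) {
    if (fr$time_ns < skip_ns) return(NULL)
    apply(pairs, 1L, function(p) {
      v <- .wrap(fr$coords[p[2L], ] - fr$coords[p[1L], ], fr$box)
      .angle_from_z(v)
    })
  }))
  angle_distribution(th, bin_deg = bin_deg, fold = fold)
}

#' Ring-plane normal angles relative to the bilayer normal
#'
#' The plane of the solute's aromatic ring is defined by three configured
#' ring atoms; its normal (cross product of the two in-plane edge vectors)
#' is measured against the +z axis. Collinear triplets are skipped and
#' counted.
#'
#' @inheritParams bond_vector_angles
#' @return an \code{\link{angle_distribution}}.
#' @export
ring_normal_angles <- function(traj, fold = FALSE, bin_deg = 2,
                               skip_ns = 0) {
  stopifnot(inherits(traj, "trajectory_system"))
  trips <- traj$selections$ring_triplets
  if (is.null(trips)) stop("no ring triplet configured")
  th <- unlist(lapply(traj$frames, function(fr) {
    if (fr$time_ns < skip_ns) return(NULL)
    apply(trips, 1L, function(p) {
      e1 <- .wrap(fr$coords[p[2L], ] - fr$coords[p[1L], ], fr$box)
      e2 <- .wrap(fr$coords[p[3L], ] - fr$coords[p[1L], ], fr$box)
      nrm <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
               e1[3L] * e2[1L] - e1[1L] * e2[3L],
               e1[1L] * e2[2L] - e1[2L] * e2[1L])
      .angle_from_z(nrm)
    })
  }))
  angle_distribution(th, bin_deg = bin_deg, fold = fold)
}
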