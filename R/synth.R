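# run expr under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic ITC thermogram with known partition parameters
#'
#' Produces the heat-flow record of a lipid-into-solute titration whose
#' per-injection heats are successive differences of the partition isotherm
#' (see \code{\link{eval_partition_model}}) under the overflow dilution
#' model, rendered as exponential-decay pulses (time constant \code{tau_s})
#' whose areas equal the per-injection heats. Noise can be added to the
#' per-injection heats (as a fraction of the final cumulative heat) and/or
#' to the heat-flow trace.
#'
#' @param K true partition constant, L/mol.
#' @param dH true transfer enthalpy, cal/mol.
#' @param schedule an \code{\link{injection_schedule}}.
#' @param tau_s pulse decay time constant, seconds (must be well below the
#'   injection spacing so pulses do not overlap).
#' @param dt_s sampling interval of the heat-flow trace, seconds.
#' @param heat_noise_frac standard deviation of Gaussian noise added to each
#'   per-injection heat, expressed as a fraction of the final cumulative
#'   heat.
#' @param flow_noise_ucal_s standard deviation of Gaussian noise added to
#'   every heat-flow sample, ucal/s.
#' @param flow_noise_frac alternative relative form: heat-flow noise SD as a
#'   fraction of the peak absolute heat flow of the noiseless trace.
#' @param dilute_solute use the overflow dilution of the solute
#'   concentration (default) or hold it constant.
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @return list with \code{thermogram} (data frame \code{time_s},
#'   \code{heat_flow_ucal_per_s}), \code{schedule}, and \code{truth}
#'   (K, dH, per-injection heats in ucal).
#' @export
gen_itc <- function(K = 800, dH = -4000, schedule = injection_schedule(),
                    tau_s = 30, dt_s = 1, heat_noise_frac = 0,
                    flow_noise_ucal_s = 0, flow_noise_frac = 0,
                    dilute_solute = TRUE, seed = NULL) {
  stopifnot(inherits(schedule, "injection_schedule"))
  if (K < 0) stop("K must be non-negative")
  if (tau_s >= schedule$spacing_s / 5)
    stop("pulse decay constant too large: pulses would overlap")
  conc <- concentrations_after_injections(schedule, dilute_solute)
  V <- schedule$cell_ul * 1e-6
  H <- eval_partition_model(K, dH, V, conc$solute_M, conc$lipid_M)  # cal
  dh_ucal <- diff(c(0, H)) * 1e6
  .with_seed(seed, {
    if (heat_noise_frac > 0)
      dh_ucal <- dh_ucal + stats::rnorm(length(dh_ucal),
                                        sd = heat_noise_frac *
                                          abs(H[length(H)]) * 1e6)
    n <- length(dh_ucal)
    s <- schedule$spacing_s
    t <- seq(0, (n + 1) * s, by = dt_s)
    hf <- numeric(length(t))
    for (i in seq_len(n)) {
      t0 <- i * s
      on_t <- t >= t0
      hf[on_t] <- hf[on_t] + dh_ucal[i] / tau_s * exp(-(t[on_t] - t0) / tau_s)
    }
    flow_sd <- flow_noise_ucal_s + flow_noise_frac * max(abs(hf))
    if (flow_sd > 0)
      hf <- hf + stats::rnorm(length(hf), sd = flow_sd)
    list(thermogram = data.frame(time_s = t, heat_flow_ucal_per_s = hf),
         schedule = schedule,
         truth = list(K = K, dH = dH, heat_ucal = dh_ucal,
                      tau_s = tau_s, dilute_solute = dilute_solute))
  })
}

#' Generate a synthetic lipid melting curve (and optional spectra)
#'
#' Samples the Boltzmann sigmoid used by \code{\link{fit_boltzmann}} on a
#' temperature grid (by default stepped 3/2/1 degrees C as the grid
#' approaches the transition), replicated and with Gaussian noise on the
#' band position. Default parameters emulate a phosphatidylcholine
#' multilamellar-vesicle chain-melting transition near 24 degrees C read
#' from the CH2 symmetric-stretch band near 2850 cm^-1.
#'
#' @param Tm true transition temperature, degrees C.
#' @param width transition width, degrees C.
#' @param nu_gel,nu_fluid low- and high-temperature band-position
#'   asymptotes, cm^-1.
#' @param temps temperature grid; default steps of 3, 2 and 1 degrees C with
#'   the finest sampling around \code{Tm}.
#' @param replicates number of replicate curves.
#' @param noise_sd Gaussian noise SD on the band position, cm^-1.
#' @param spectra also emit a full Gaussian-band spectrum per temperature
#'   and replicate (2 cm^-1 grid) with the band centred at the sigmoid
#'   value, plus an out-of-window band near 2920 cm^-1.
#' @param seed RNG seed.
#' @return list with \code{curve} (data frame \code{temperature_C},
#'   \code{wavenumber_cm1}, \code{replicate}), optional \code{spectra} (list
#'   of data frames) with a \code{manifest}, and \code{truth}.
#' @export
gen_melting_curve <- function(Tm = 23.69, width = 0.8, nu_gel = 2850.4,
                              nu_fluid = 2852.9, temps = NULL,
                              replicates = 3, noise_sd = 0,
                              spectra = FALSE, seed = NULL) {
  if (width <= 0) stop("width must be positive")
  if (nu_fluid <= nu_gel) stop("nu_fluid must exceed nu_gel")
  if (is.null(temps))
    temps <- Tm + c(-9, -6, -4, -2, -1, 0, 1, 2, 4, 6, 9)
  if (min(temps) > Tm - 3 * width || max(temps) < Tm + 3 * width)
    warning("temperature grid does not span Tm +/- 3 widths")
  sigmoid <- function(Tt) nu_fluid + (nu_gel - nu_fluid) /
    (1 + exp((Tt - Tm) / width))
  .with_seed(seed, {
    curve <- do.call(rbind, lapply(seq_len(replicates), function(r) {
      nu <- sigmoid(temps)
      if (noise_sd > 0) nu <- nu + stats::rnorm(length(nu), sd = noise_sd)
      data.frame(temperature_C = temps, wavenumber_cm1 = nu, replicate = r)
    }))
    out <- list(curve = curve,
                truth = list(Tm = Tm, width = width, nu_gel = nu_gel,
                             nu_fluid = nu_fluid))
    if (spectra) {
      grid <- seq(2800, 2950, by = 2)
      out$spectra <- lapply(seq_len(nrow(curve)), function(i) {
        centre <- curve$wavenumber_cm1[i]
        data.frame(wavenumber_cm1 = grid,
                   absorbance = exp(-(grid - centre)^2 / (2 * 5^2)) +
                     0.8 * exp(-(grid - 2920)^2 / (2 * 5^2)))
      })
      out$manifest <- data.frame(spectrum = seq_len(nrow(curve)),
                                 temperature_C = curve$temperature_C,
                                 replicate = curve$replicate)
    }
    out
  })
}

# internal: template of per-atom offsets (relative to the molecule COM) for
# one pseudo-solute; z offsets are negated for the lower leaflet
.solute_template <- function(tilt_deg, ring_tilt_deg) {
  th <- tilt_deg * pi / 180
  ph <- ring_tilt_deg * pi / 180
  # ring normal at ph from +z, in the xz-plane; e1/e2 orthonormal in-plane
  e1 <- c(cos(ph), 0, -sin(ph))
  e2 <- c(0, 1, 0)
  off <- rbind(CV = c(0, 0, 0),
               NV = 0.5 * c(sin(th), 0, cos(th)),
               CR1 = c(0.25, 0.10, 0),
               CR2 = c(0.25, 0.10, 0) + 0.14 * e1,
               CR3 = c(0.25, 0.10, 0) + 0.14 * e2,
               ND = c(-0.20, -0.15, 0),
               HD = c(-0.20, -0.15, 0) + c(0.10, 0, 0))
  m <- .mass_from_name(rownames(off))
  sweep(off, 2L, colSums(off * m / sum(m)))  # recentre COM at the origin
}

#' Generate a schematic bilayer-plus-solute trajectory with known geometry
#'
#' Builds a two-leaflet slab of pseudo-lipids (phosphate, ester-oxygen,
#' glycerol and chain beads on a lateral grid) and rigid pseudo-solutes
#' placed at prescribed centre-of-mass depths, bond-vector tilts and
#' ring-plane tilts, mirrored between the leaflets. A per-frame hydrogen-
#' bond schedule is realised by moving dedicated lipid phosphate-oxygen
#' partner atoms into or out of the geometric hydrogen-bond criterion
#' (collinear placements at 0.30 nm when bonded, 0.80 nm otherwise). The
#' geometry is schematic, not physical: only the observables the analysis
#' functions measure are controlled.
#'
#' @param n_lipids number of structural lipids (split evenly between
#'   leaflets).
#' @param n_solutes number of solutes (even; half per leaflet).
#' @param depth_nm prescribed |z| offset of each solute COM from the bilayer
#'   COM; a scalar or one value per frame (e.g. a decreasing ramp to emulate
#'   adsorption from water to the interface).
#' @param tilt_deg bond-vector tilt from the bilayer normal in the upper
#'   leaflet (mirrored to 180 - tilt in the lower leaflet).
#' @param ring_tilt_deg ring-plane-normal tilt from the bilayer normal.
#' @param hbond_schedule integer vector, hydrogen bonds per solute for each
#'   frame (0 to 4); default none.
#' @param n_frames number of frames (defaults to the schedule/depth length).
#' @param times_ns frame times; default 0, 1, 2, ... ns.
#' @param box box vector, nm.
#' @param leaflet_z phosphate |z| offset from the bilayer centre, nm.
#' @param seed unused RNG hook kept for interface symmetry (the construction
#'   is deterministic).
#' @return list with \code{gro} (atoms + frames, consumable by
#'   \code{\link{trajectory_system}}), \code{config} (selection
#'   configuration), and \code{truth}.
#' @export
gen_membrane_traj <- function(n_lipids = 128, n_solutes = 32,
                              depth_nm = 1.2, tilt_deg = 35,
                              ring_tilt_deg = 30, hbond_schedule = NULL,
                              n_frames = NULL, times_ns = NULL,
                              box = c(6.4, 6.4, 7.0), leaflet_z = 2.0,
                              seed = NULL) {
  if (n_lipids < 2 || n_lipids %% 2 != 0)
    stop("n_lipids must be even and >= 2")
  if (n_solutes < 2 || n_solutes %% 2 != 0)
    stop("n_solutes must be even and >= 2")
  if (is.null(n_frames))
    n_frames <- max(length(hbond_schedule), length(depth_nm), 1L)
  if (is.null(hbond_schedule)) hbond_schedule <- rep(0L, n_frames)
  if (length(hbond_schedule) != n_frames)
    stop("hbond_schedule length must equal n_frames")
  if (any(hbond_schedule < 0 | hbond_schedule > 4))
    stop("hbond_schedule entries must be between 0 and 4")
  depth_nm <- rep_len(depth_nm, n_frames)
  if (any(depth_nm < 0) || any(depth_nm + 0.5 > box[3L] / 2))
    stop("requested solute depth lies outside the box")
  if (leaflet_z + 0.5 > box[3L] / 2) stop("leaflet_z too large for the box")
  if (is.null(times_ns)) times_ns <- seq_len(n_frames) - 1
  zc <- box[3L] / 2

  # structural lipids: P / two ester O / glycerol bead / two chain beads
  n_leaf <- n_lipids / 2L
  nx <- ceiling(sqrt(n_leaf))
  sx <- box[1L] / nx; sy <- box[2L] / nx
  lipid_names <- c("P", "OE1", "OE2", "CG", "C1", "C2")
  lipid_zoff <- c(P = leaflet_z, OE1 = 1.6, OE2 = 1.6, CG = 1.5,
                  C1 = 1.0, C2 = 0.5)
  template <- .solute_template(tilt_deg, ring_tilt_deg)

  atoms <- list(); row0 <- 0L; resid <- 0L
  lipid_base <- list(); lipid_rows <- list()
  add_block <- function(resname, names) {
    resid <<- resid + 1L
    atoms[[length(atoms) + 1L]] <<-
      data.frame(resid = resid, resname = resname, name = names)
    rows <- row0 + seq_along(names)
    row0 <<- row0 + length(names)
    rows
  }
  for (leaf in c(1, -1)) {
    for (k in seq_len(n_leaf)) {
      ix <- (k - 1L) %% nx; iy <- (k - 1L) %/% nx
      x <- (ix + 0.5) * sx; y <- (iy + 0.5) * sy
      lipid_rows[[length(lipid_rows) + 1L]] <- add_block("LIP", lipid_names)
      lipid_base[[length(lipid_base) + 1L]] <-
        cbind(x + c(0, 0.1, -0.1, 0, 0, 0), y + c(0, 0, 0, 0.1, 0, 0),
              zc + leaf * unname(lipid_zoff))
    }
  }

  # solutes on a coarser offset grid, half per leaflet, mirrored
  n_sleaf <- n_solutes / 2L
  nsx <- ceiling(sqrt(n_sleaf))
  ssx <- box[1L] / nsx; ssy <- box[2L] / nsx
  solute_xy <- list(); solute_leaf <- integer(0); solute_rows <- list()
  for (leaf in c(1, -1)) {
    for (k in seq_len(n_sleaf)) {
      ix <- (k - 1L) %% nsx; iy <- (k - 1L) %/% nsx
      solute_rows[[length(solute_rows) + 1L]] <-
        add_block("ALK", rownames(template))
      solute_xy[[length(solute_xy) + 1L]] <-
        c((ix + 0.5) * ssx + sx / 2, (iy + 0.5) * ssy + sy / 2)
      solute_leaf <- c(solute_leaf, leaf)
    }
  }

  # four hydrogen-bond partner oxygens per solute, single-atom lipid residues
  n_part <- 4L
  partner_rows <- matrix(0L, n_solutes, n_part)
  for (s in seq_len(n_solutes)) for (j in seq_len(n_part))
    partner_rows[s, j] <- add_block("LIP", "OP")

  atoms <- do.call(rbind, atoms)
  base <- matrix(NA_real_, nrow(atoms), 3L,
                 dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_along(lipid_rows)) base[lipid_rows[[i]], ] <- lipid_base[[i]]

  beta <- c(0, 15, -15, 28) * pi / 180  # H-D-A angles of the four partners
  nd_row <- which(atoms$name == "ND")
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    co <- base
    for (s in seq_len(n_solutes)) {
      leaf <- solute_leaf[s]
      tpl <- template
      if (leaf < 0) tpl[, 3L] <- -tpl[, 3L]
      centre <- c(solute_xy[[s]], zc + leaf * depth_nm[f])
      co[solute_rows[[s]], ] <- sweep(tpl, 2L, centre, "+")
    }
    for (s in seq_len(n_solutes)) {
      d <- co[nd_row[s], ]
      for (j in seq_len(n_part)) {
        r <- if (j <= hbond_schedule[f]) 0.30 else 0.80
        co[partner_rows[s, j], ] <-
          d + r * c(cos(beta[j]), sin(beta[j]), 0)
      }
    }
    frames[[f]] <- list(coords = co, box = box, time_ns = times_ns[f])
  }

  config <- list(
    lipid_resnames = "LIP", solute_resnames = "ALK",
    roles = list(phosphate = list(LIP = "P"),
                 ester = list(LIP = c("OE1", "OE2")),
                 glycerol = list(LIP = "CG")),
    donors = list(list(resname = "ALK", atom = "ND", hydrogen = "HD")),
    acceptors = list(list(resname = "LIP", atom = "OP", class = "phosphate"),
                     list(resname = "LIP", atom = "OE1", class = "ester"),
                     list(resname = "LIP", atom = "OE2", class = "ester")),
    orient_vector = list(resname = "ALK", from = "CV", to = "NV"),
    ring_triplet = list(resname = "ALK", atoms = c("CR1", "CR2", "CR3")))

  list(gro = list(atoms = atoms, frames = frames),
       config = config,
       truth = list(depth_nm = depth_nm, tilt_deg = tilt_deg,
                    ring_tilt_deg = ring_tilt_deg,
                    hbond_schedule = hbond_schedule,
                    leaflet = ifelse(solute_leaf > 0, "upper", "lower"),
                    phosphate_z = leaflet_z, glycerol_z = 1.5,
                    times_ns = times_ns))
}

#' Generate a synthetic root-length bioassay table
#'
#' Emulates a randomized-block phytotoxicity assay: per-dish mean root
#' lengths equal the control mean scaled by a per-treatment growth-
#' inhibition effect, plus an additive block effect and Gaussian noise,
#' truncated at zero. The default effects reproduce the inhibition
#' magnitudes of a gramine/hordenine seedling assay (roughly 21-73 percent
#' inhibition), with seven blocks and the control plated twice per block.
#'
#' @param effects named numeric vector of fractional growth inhibition per
#'   treatment (0 = no effect, 1 = complete inhibition).
#' @param control_mean control mean root length, mm.
#' @param control_label treatment label used for the control.
#' @param n_blocks number of blocks.
#' @param control_reps_per_block control dishes per block.
#' @param block_sd SD of the additive block effects, mm.
#' @param noise_sd SD of the per-dish noise, mm.
#' @param seed RNG seed.
#' @return list with \code{table} (data frame \code{treatment}, \code{block},
#'   \code{dish}, \code{root_length_mm}) and \code{truth}.
#' @export
gen_bioassay <- function(effects = c("Hordenine 0.5 mM" = 0.212,
                                     "Hordenine 1 mM" = 0.275,
                                     "Gramine 0.5 mM" = 0.629,
                                     "Gramine 1 mM" = 0.726,
                                     "Gramine 0.5 mM + Hordenine 0.5 mM" =
                                       0.645),
                         control_mean = 22.6, control_label = "Control",
                         n_blocks = 7, control_reps_per_block = 2,
                         block_sd = 1.0, noise_sd = 1.5, seed = NULL) {
  if (control_mean <= 0) stop("control mean must be positive")
  if (is.null(names(effects)) || any(!nzchar(names(effects))))
    stop("effects must be a named vector")
  .with_seed(seed, {
    block_eff <- stats::rnorm(n_blocks, sd = block_sd)
    all_treat <- c(rep(control_label, control_reps_per_block),
                   names(effects))
    all_eff <- c(rep(0, control_reps_per_block), unname(effects))
    rows <- list(); dish <- 0L
    for (b in seq_len(n_blocks)) {
      for (k in seq_along(all_treat)) {
        dish <- dish + 1L
        val <- control_mean * (1 - all_eff[k]) + block_eff[b] +
          stats::rnorm(1, sd = noise_sd)
        rows[[dish]] <- data.frame(treatment = all_treat[k], block = b,
                                   dish = dish,
                                   root_length_mm = max(0, val))
      }
    }
    list(table = do.call(rbind, rows),
         truth = list(effects = effects, control_mean = control_mean,
                      block_effects = block_eff, noise_sd = noise_sd))
  })
}
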