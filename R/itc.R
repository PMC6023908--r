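#' Injection schedule for an ITC titration
#'
#' Describes the sequence of syringe injections of a titration experiment in
#' which a concentrated lipid vesicle suspension is injected into a sample
#' cell containing a dilute solute (e.g. an alkaloid) solution. The defaults
#' reproduce a typical VP-ITC protocol: a small first injection followed by
#' 28 injections of 10 uL, 600 s apart, 10 mM lipid titrated into a
#' 1.4565 mL cell holding 10 uM solute.
#'
#' @param injection_ul numeric vector of injection volumes in microlitres.
#' @param spacing_s seconds between consecutive injections.
#' @param cell_ul active cell volume in microlitres.
#' @param syringe_lipid_M lipid concentration in the syringe, mol/L.
#' @param cell_solute_M initial solute concentration in the cell, mol/L.
#' @param exclude_first drop the first injection from fitted heats (its
#'   volume still counts toward the dilution bookkeeping).
#' @return An object of class \code{injection_schedule}.
#' @examples
#' sched <- injection_schedule()
#' length(sched$injection_ul)  # 29
#' @export
injection_schedule <- function(injection_ul = c(2, rep(10, 28)),
                               spacing_s = 600,
                               cell_ul = 1456.5,
                               syringe_lipid_M = 0.01,
                               cell_solute_M = 1e-5,
                               exclude_first = TRUE) {
  if (length(injection_ul) < 1L || any(!is.finite(injection_ul)) ||
      any(injection_ul <= 0))
    stop("injection volumes must be a non-empty vector of positive numbers")
  if (!is.finite(cell_ul) || cell_ul <= max(injection_ul))
    stop("cell volume must exceed the largest injection volume")
  if (!is.finite(spacing_s) || spacing_s <= 0)
    stop("spacing must be positive")
  if (syringe_lipid_M < 0 || cell_solute_M < 0)
    stop("concentrations must be non-negative")
  structure(list(injection_ul = as.numeric(injection_ul),
                 spacing_s = spacing_s,
                 cell_ul = cell_ul,
                 syringe_lipid_M = syringe_lipid_M,
                 cell_solute_M = cell_solute_M,
                 exclude_first = isTRUE(exclude_first)),
            class = "injection_schedule")
}

#' @export
print.injection_schedule <- function(x, ...) {
  cat("ITC injection schedule\n")
  cat(sprintf("  %d injections (%s uL), %g s apart\n",
              length(x$injection_ul),
              paste(unique(x$injection_ul), collapse = "/"), x$spacing_s))
  cat(sprintf("  cell %g uL; syringe lipid %g M; cell solute %g M\n",
              x$cell_ul, x$syringe_lipid_M, x$cell_solute_M))
  cat(sprintf("  first injection %s\n",
              if (x$exclude_first) "excluded from fitting" else "included"))
  invisible(x)
}

#' Cell concentrations after each injection
#'
#' Tracks lipid and solute concentrations in a constant-volume (overflow)
#' cell. Each injection of volume v into a cell of volume V displaces a
#' fraction v/V of the current contents, so after injection i the fraction
#' of original cell content retained is f_i = prod_j (1 - v_j / V). The
#' solute is diluted to its initial concentration times f_i while the lipid
#' accumulates to the syringe concentration times (1 - f_i).
#'
#' @param schedule an \code{\link{injection_schedule}}.
#' @param dilute_solute if \code{FALSE}, the solute concentration is held at
#'   its initial value (no-dilution variant).
#' @return data frame with one row per injection: \code{injection},
#'   \code{volume_ul}, \code{retained_fraction}, \code{lipid_M},
#'   \code{solute_M}.
#' @export
concentrations_after_injections <- function(schedule, dilute_solute = TRUE) {
  stopifnot(inherits(schedule, "injection_schedule"))
  v <- schedule$injection_ul
  V <- schedule$cell_ul
  if (any(v >= V)) stop("injection volume >= cell volume")
  f <- cumprod(1 - v / V)
  data.frame(injection = seq_along(v),
             volume_ul = v,
             retained_fraction = f,
             lipid_M = schedule$syringe_lipid_M * (1 - f),
             solute_M = if (dilute_solute) schedule$cell_solute_M * f
                        else rep(schedule$cell_solute_M, length(v)))
}

#' Integrate an ITC thermogram into per-injection heats
#'
#' Splits the heat-flow record into one window per injection (injection i
#' starts at t = i * spacing and ends at the next injection start), removes a
#' baseline interpolated linearly between the medians of the last fraction of
#' each inter-injection interval, and integrates the corrected heat flow by
#' the trapezoidal rule. Heats are signed: exothermic peaks give negative
#' values.
#'
#' @param thermogram data frame with columns \code{time_s} (strictly
#'   increasing) and \code{heat_flow_ucal_per_s}.
#' @param schedule an \code{\link{injection_schedule}}.
#' @param dilute_solute passed to
#'   \code{\link{concentrations_after_injections}}.
#' @param plateau_frac fraction of each inter-injection interval, taken from
#'   its end, whose median anchors the baseline (default 0.1).
#' @return An object of class \code{injection_heats}: a data frame with
#'   columns \code{injection}, \code{heat_ucal}, \code{cumulative_ucal},
#'   \code{lipid_M}, \code{solute_M}, plus the schedule as an attribute.
#' @export
integrate_thermogram <- function(thermogram, schedule, dilute_solute = TRUE,
                                 plateau_frac = 0.1) {
  stopifnot(inherits(schedule, "injection_schedule"))
  if (!all(c("time_s", "heat_flow_ucal_per_s") %in% names(thermogram)))
    stop("thermogram needs columns time_s and heat_flow_ucal_per_s")
  t <- thermogram$time_s
  hf <- thermogram$heat_flow_ucal_per_s
  if (length(t) < 2L) stop("thermogram series is too short")
  if (any(!is.finite(t)) || any(!is.finite(hf)))
    stop("thermogram contains non-finite values")
  if (any(diff(t) <= 0)) stop("thermogram time must be strictly increasing")

  n <- length(schedule$injection_ul)
  s <- schedule$spacing_s
  starts <- s * seq_len(n)
  ends <- c(starts[-1L], starts[n] + s)
  tol <- 1e-9 * max(abs(t))
  late <- which(ends > max(t) + tol)
  if (length(late))
    stop(sprintf("thermogram ends before the window of injection %d",
                 late[1L]))

  # baseline anchors: median heat flow over the trailing plateau of each
  # inter-injection interval (the pre-first-injection interval included)
  anchor_t <- c(starts, ends[n])
  iv_start <- c(0, starts)
  anchor_v <- vapply(seq_along(anchor_t), function(k) {
    lo <- anchor_t[k] - plateau_frac * (anchor_t[k] - iv_start[k])
    sel <- t >= lo & t <= anchor_t[k] + tol
    if (!any(sel)) sel <- which.min(abs(t - anchor_t[k]))
    stats::median(hf[sel])
  }, numeric(1))
  baseline <- stats::approx(anchor_t, anchor_v, xout = t, rule = 2)$y
  corr <- hf - baseline

  # windows are half-open: the sample at the next injection start carries
  # that injection's rising edge and belongs to the next window
  trapz <- function(lo, hi) {
    sel <- t >= lo - tol & t < hi - tol
    tt <- t[sel]; yy <- corr[sel]
    if (length(tt) < 2L)
      stop(sprintf("no samples inside window [%g, %g]", lo, hi))
    sum(diff(tt) * (yy[-1L] + yy[-length(yy)])) / 2
  }
  dh <- vapply(seq_len(n), function(i) trapz(starts[i], ends[i]), numeric(1))

  conc <- concentrations_after_injections(schedule, dilute_solute)
  out <- data.frame(injection = seq_len(n),
                    heat_ucal = dh,
                    cumulative_ucal = cumsum(dh),
                    lipid_M = conc$lipid_M,
                    solute_M = conc$solute_M)
  structure(out, class = c("injection_heats", "data.frame"),
            schedule = schedule, dilute_solute = dilute_solute)
}

#' Build an injection-heats table from known per-injection heats
#'
#' Convenience constructor used when per-injection heats are available
#' directly (e.g. exported from instrument software) rather than as a raw
#' thermogram.
#'
#' @param heat_ucal per-injection heats in microcalories, one per scheduled
#'   injection.
#' @inheritParams integrate_thermogram
#' @return An \code{injection_heats} object.
#' @export
injection_heats <- function(heat_ucal, schedule, dilute_solute = TRUE) {
  stopifnot(inherits(schedule, "injection_schedule"))
  if (length(heat_ucal) != length(schedule$injection_ul))
    stop("one heat per scheduled injection is required")
  conc <- concentrations_after_injections(schedule, dilute_solute)
  out <- data.frame(injection = seq_along(heat_ucal),
                    heat_ucal = as.numeric(heat_ucal),
                    cumulative_ucal = cumsum(as.numeric(heat_ucal)),
                    lipid_M = conc$lipid_M,
                    solute_M = conc$solute_M)
  structure(out, class = c("injection_heats", "data.frame"),
            schedule = schedule, dilute_solute = dilute_solute)
}

#' Cumulative heat predicted by the lipid partition model
#'
#' Evaluates the one-site partition equilibrium for solute transfer from
#' water to a lipid bilayer: the cumulative heat after reaching lipid
#' concentration C_L and solute concentration C_A in the cell is
#' \deqn{\Sigma \delta h = \Delta H \, V_{cell} \, C_A \frac{K C_L}{1 + K C_L}}
#' where K (L/mol) is the partition constant and \eqn{\Delta H} (cal/mol) the
#' molar enthalpy of transfer.
#'
#' @param K partition constant, L/mol (must be non-negative).
#' @param dH transfer enthalpy, cal/mol.
#' @param cell_volume_L cell volume in litres.
#' @param C_A,C_L solute and lipid concentrations in the cell, mol/L
#'   (vectorised).
#' @return predicted cumulative heat in calories.
#' @examples
#' eval_partition_model(1000, -5000, 1.4565e-3, 1e-5, 1e-3)  # -3.641e-5 cal
#' @export
eval_partition_model <- function(K, dH, cell_volume_L, C_A, C_L) {
  if (!is.finite(K) || K < 0) stop("K must be non-negative")
  if (any(C_A < 0) || any(C_L < 0)) stop("concentrations must be non-negative")
  dH * cell_volume_L * C_A * (K * C_L) / (1 + K * C_L)
}

#' Fit the lipid partition model to cumulative injection heats
#'
#' Nonlinear least-squares fit of the partition model (see
#' \code{\link{eval_partition_model}}) to the cumulative heats of a lipid-
#' into-solute titration, with the partition constant K and transfer enthalpy
#' dH free. When the schedule excludes the first injection, the fitted series
#' is the cumulative heat of the remaining injections and the model is
#' referenced to the state after the excluded injection, i.e. the predicted
#' value at injection i is H(i) - H(i0) with i0 the last excluded injection;
#' this keeps the model consistent with per-injection heats defined as
#' successive differences of the partition isotherm.
#'
#' @param heats an \code{injection_heats} object (from
#'   \code{\link{integrate_thermogram}} or \code{\link{injection_heats}}).
#' @param schedule optional; defaults to the schedule attached to
#'   \code{heats}.
#' @param accessible_lipid_fraction fraction of the injected lipid treated as
#'   accessible to the solute (1 = all lipid; 0.5 restricts to the outer
#'   leaflet of intact vesicles).
#' @return An object of class \code{partition_fit} with components \code{K}
#'   (L/mol), \code{dH} (cal/mol), \code{K_se}, \code{dH_se}, \code{rss}
#'   (ucal^2), \code{converged}, \code{fitted_ucal}, \code{data}.
#' @seealso \code{\link{eval_partition_model}},
#'   \code{\link{integrate_thermogram}}
#' @export
fit_partition <- function(heats, schedule = attr(heats, "schedule"),
                          accessible_lipid_fraction = 1) {
  stopifnot(inherits(heats, "injection_heats"),
            inherits(schedule, "injection_schedule"))
  fl <- accessible_lipid_fraction
  if (!is.finite(fl) || fl <= 0 || fl > 1)
    stop("accessible_lipid_fraction must be in (0, 1]")
  n_excl <- if (schedule$exclude_first) 1L else 0L
  use <- heats$injection > n_excl
  if (sum(use) < 5L) stop("at least 5 usable injections are required")

  V <- schedule$cell_ul * 1e-6                     # litres
  y <- cumsum(heats$heat_ucal[use])                # ucal (fit scale)
  CA <- heats$solute_M[use]
  CL <- heats$lipid_M[use] * fl
  if (n_excl > 0L) {
    CA0 <- heats$solute_M[n_excl]
    CL0 <- heats$lipid_M[n_excl] * fl
  } else {
    CA0 <- schedule$cell_solute_M
    CL0 <- 0
  }

  out <- list(K = NA_real_, dH = NA_real_, K_se = NA_real_, dH_se = NA_real_,
              rss = NA_real_, converged = FALSE, message = NULL,
              data = data.frame(injection = heats$injection[use],
                                cumulative_ucal = y, solute_M = CA,
                                lipid_M = CL),
              fitted_ucal = rep(NA_real_, sum(use)),
              cell_volume_L = V, accessible_lipid_fraction = fl,
              reference = list(C_A = CA0, C_L = CL0),
              call = match.call())
  class(out) <- "partition_fit"

  scale <- max(abs(y))
  if (!is.finite(scale) || scale == 0) {
    out$message <- "all cumulative heats are zero: K is not identifiable"
    return(out)
  }

  # initial values: dH from the apparent plateau, K from the lipid
  # concentration at half the final cumulative heat
  dH0 <- y[length(y)] * 1e-6 / (V * CA[length(CA)])
  half <- which(abs(y) >= abs(y[length(y)]) / 2)[1L]
  K0 <- 1 / CL[half]
  # model evaluated in ucal so the optimizer works at O(1)-O(10) residuals;
  # tight ftol/ptol: near-linear low-K isotherms stall early otherwise
  model <- function(K, dH) {
    (eval_partition_model(K, dH, V, CA, CL) -
       eval_partition_model(K, dH, V, CA0, CL0)) * 1e6
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ model(K, dH),
                      start = list(K = K0, dH = dH0),
                      lower = c(K = 0, dH = -Inf),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 1000, maxfev = 10000,
                        ftol = 1e-15, ptol = 1e-13)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out$message <- conditionMessage(fit)
    return(out)
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(K = NA_real_, dH = NA_real_))
  out$K <- unname(cf["K"]); out$dH <- unname(cf["dH"])
  out$K_se <- unname(se["K"]); out$dH_se <- unname(se["dH"])
  out$fitted_ucal <- as.numeric(stats::fitted(fit))
  out$rss <- sum((y - out$fitted_ucal)^2)
  out$converged <- isTRUE(fit$convInfo$isConv) && all(is.finite(cf))
  out
}

#' @export
print.partition_fit <- function(x, digits = 4, ...) {
  cat("Lipid partition model fit\n")
  if (!x$converged && is.null(x$message))
    cat("  (fit did not converge)\n")
  if (!is.null(x$message)) cat("  ", x$message, "\n", sep = "")
  cat(sprintf("  K  = %s L/mol (SE %s)\n",
              format(x$K, digits = digits), format(x$K_se, digits = 3)))
  cat(sprintf("  dH = %s cal/mol (SE %s)\n",
              format(x$dH, digits = digits), format(x$dH_se, digits = 3)))
  cat(sprintf("  RSS = %s ucal^2 over %d injections\n",
              format(x$rss, digits = 3), nrow(x$data)))
  invisible(x)
}

#' @export
coef.partition_fit <- function(object, ...) {
  c(K = object$K, dH = object$dH)
}

#' @export
summary.partition_fit <- function(object, ...) {
  tab <- data.frame(estimate = c(object$K, object$dH),
                    std_error = c(object$K_se, object$dH_se),
                    row.names = c("K (L/mol)", "dH (cal/mol)"))
  structure(list(coefficients = tab, rss = object$rss,
                 converged = object$converged, n = nrow(object$data),
                 message = object$message),
            class = "summary.partition_fit")
}

#' @export
print.summary.partition_fit <- function(x, ...) {
  cat("Lipid partition model fit\n")
  print(x$coefficients)
  cat(sprintf("RSS %s ucal^2, n = %d, converged: %s\n",
              format(x$rss, digits = 3), x$n, x$converged))
  if (!is.null(x$message)) cat(x$message, "\n")
  invisible(x)
}

#' @export
predict.partition_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_ucal)
  raw <- eval_partition_model(object$K, object$dH, object$cell_volume_L,
                              newdata$solute_M, newdata$lipid_M)
  ref <- eval_partition_model(object$K, object$dH, object$cell_volume_L,
                              object$reference$C_A, object$reference$C_L)
  (raw - ref) * 1e6
}

#' @export
residuals.partition_fit <- function(object, ...) {
  object$data$cumulative_ucal - object$fitted_ucal
}

#' @export
plot.partition_fit <- function(x, ...) {
  graphics::plot(x$data$lipid_M * 1e3, x$data$cumulative_ucal,
                 xlab = "lipid concentration in cell (mM)",
                 ylab = "cumulative heat (ucal)", ...)
  ord <- order(x$data$lipid_M)
  graphics::lines(x$data$lipid_M[ord] * 1e3, x$fitted_ucal[ord], col = 2)
  invisible(x)
}
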