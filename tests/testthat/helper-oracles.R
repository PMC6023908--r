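# Independent oracles used by the unit and acceptance tests. These
# deliberately re-derive each quantity by the most direct route available
# (explicit loops, mass balances, exhaustive scans) so they share no code
# path with the package implementation.

# iterative overflow-cell mass balance: track moles in the cell step by step
oracle_concentrations <- function(injection_ul, cell_ul, syringe_lipid_M,
                                  cell_solute_M) {
  V <- cell_ul * 1e-6               # L
  n_sol <- cell_solute_M * V        # mol in cell
  n_lip <- 0
  out <- matrix(NA_real_, length(injection_ul), 2,
                dimnames = list(NULL, c("lipid_M", "solute_M")))
  for (i in seq_along(injection_ul)) {
    v <- injection_ul[i] * 1e-6
    # the injected volume displaces an equal volume of the pre-existing
    # cell contents; the injected aliquot itself is retained
    keep <- 1 - v / V
    n_lip <- n_lip * keep + syringe_lipid_M * v
    n_sol <- n_sol * keep
    out[i, ] <- c(n_lip / V, n_sol / V)
  }
  out
}

# brute-force all-pairs hydrogen-bond scan with explicit per-axis minimal
# image and acos-based angle test
oracle_hbonds <- function(coords, box, donors, acceptors,
                          d_max = 0.35, angle_max = 30) {
  classes <- sort(unique(acceptors$class))
  counts <- stats::setNames(numeric(length(classes)), classes)
  mi <- function(a, b) {
    d <- a - b
    for (ax in 1:3) d[ax] <- d[ax] - box[ax] * round(d[ax] / box[ax])
    d
  }
  for (k in seq_len(nrow(donors))) {
    for (m in seq_len(nrow(acceptors))) {
      if (donors$side[k] == acceptors$side[m]) next
      d <- coords[donors$donor[k], ]
      h <- coords[donors$hydrogen[k], ]
      a <- coords[acceptors$index[m], ]
      da <- mi(a, d)
      if (sqrt(sum(da^2)) > d_max) next
      dh <- mi(h, d)
      ang <- acos(max(-1, min(1, sum(da * dh) /
                                (sqrt(sum(da^2)) * sqrt(sum(dh^2))))))
      if (ang * 180 / pi <= angle_max)
        counts[acceptors$class[m]] <- counts[acceptors$class[m]] + 1
    }
  }
  c(counts, total = sum(counts))
}

# a random small donor/acceptor system for the hydrogen-bond oracle tests
random_hbond_frame <- function(n_donors = 20, n_acceptors = 40,
                               box = c(3, 3, 3)) {
  n <- 2 * n_donors + n_acceptors
  coords <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                  stats::runif(n, 0, box[3]))
  donors <- data.frame(donor = seq_len(n_donors),
                       hydrogen = n_donors + seq_len(n_donors),
                       side = "solute")
  # hydrogens near their donors
  coords[donors$hydrogen, ] <- coords[donors$donor, ] +
    matrix(stats::rnorm(3 * n_donors, sd = 0.04), ncol = 3)
  acceptors <- data.frame(index = 2 * n_donors + seq_len(n_acceptors),
                          class = sample(c("phosphate", "ester", "glycerol"),
                                         n_acceptors, replace = TRUE),
                          side = "lipid")
  list(coords = coords, box = box, donors = donors, acceptors = acceptors)
}

# exhaustive pairwise Tukey-Kramer comparison built from first principles:
# sums of squares assembled by hand, one explicit test per pair
oracle_tukey_matrix <- function(values, groups, blocks = NULL,
                                alpha = 0.05) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  fit <- if (is.null(blocks)) stats::lm(values ~ groups)
         else stats::lm(values ~ groups + as.factor(blocks))
  df_res <- fit$df.residual
  mse <- sum(stats::residuals(fit)^2) / df_res
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  sig <- matrix(FALSE, k, k, dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[i] - means[j]) / se
    p <- stats::ptukey(q, nmeans = k, df = df_res, lower.tail = FALSE)
    sig[i, j] <- sig[j, i] <- p < alpha
  }
  sig
}

# check a compact letter display against a significance matrix: two
# treatments must share at least one letter iff they are NOT significantly
# different
cld_consistent <- function(letters_named, sig) {
  labs <- names(letters_named)
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (i >= j) next
    share <- length(intersect(strsplit(letters_named[i], "")[[1]],
                              strsplit(letters_named[j], "")[[1]])) > 0
    if (share == sig[labs[i], labs[j]]) return(FALSE)
  }
  TRUE
}

# minimal in-memory bilayer for hand-constructed trajectory tests
make_tiny_traj <- function(frames, atoms, config) {
  trajectory_system(list(atoms = atoms, frames = frames), config)
}
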