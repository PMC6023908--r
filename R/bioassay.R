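#' Per-treatment summary of a root-length bioassay
#'
#' Computes the mean, sample standard deviation (n - 1 denominator) and
#' replicate count per treatment over replicate-level values (per-dish
#' means), plus the growth-inhibition percentage of each treatment relative
#' to the control.
#'
#' @param table data frame with columns \code{treatment} and
#'   \code{root_length_mm} (one row per replicate/dish).
#' @param control label of the control treatment; set to \code{NULL} to skip
#'   inhibition percentages.
#' @return data frame of class \code{bioassay_summary} with columns
#'   \code{treatment}, \code{mean_mm}, \code{sd_mm}, \code{n},
#'   \code{inhibition_pct}.
#' @export
summarize_bioassay <- function(table, control = "Control") {
  stopifnot(all(c("treatment", "root_length_mm") %in% names(table)))
  if (nrow(table) == 0L) stop("empty bioassay table")
  if (any(table$root_length_mm < 0)) stop("root lengths must be >= 0")
  sp <- split(table$root_length_mm, table$treatment)
  out <- data.frame(
    treatment = names(sp),
    mean_mm = vapply(sp, mean, numeric(1)),
    sd_mm = vapply(sp, function(x)
      if (length(x) > 1L) stats::sd(x) else NA_real_, numeric(1)),
    n = vapply(sp, length, integer(1)),
    row.names = NULL)
  if (!is.null(control)) {
    if (!control %in% out$treatment)
      stop("control treatment '", control, "' not found")
    cm <- out$mean_mm[out$treatment == control]
    out$inhibition_pct <- inhibition_percentage(out$mean_mm, cm)
  }
  # control first, then by decreasing mean
  ord <- order(out$treatment != control, -out$mean_mm)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("bioassay_summary", "data.frame"),
            control = control)
}

#' Growth-inhibition percentage relative to the control
#'
#' @param mean_treatment treatment mean root length(s), mm (vectorised).
#' @param mean_control control mean root length, mm (must be positive).
#' @return percentage inhibition, \code{100 * (control - treatment) /
#'   control}.
#' @examples
#' inhibition_percentage(17.8, 22.6)  # 21.2
#' @export
inhibition_percentage <- function(mean_treatment, mean_control) {
  if (!is.finite(mean_control) || mean_control <= 0)
    stop("control mean must be positive")
  100 * (mean_control - mean_treatment) / mean_control
}

# Tukey(-Kramer) pairwise comparisons from group means, sizes and the ANOVA
# residual mean square
.tukey_pairs <- function(means, ns, mse, df_res, alpha) {
  k <- length(means)
  labs <- names(means)
  pairs <- utils::combn(k, 2)
  out <- data.frame(a = labs[pairs[1L, ]], b = labs[pairs[2L, ]])
  out$diff <- means[pairs[1L, ]] - means[pairs[2L, ]]
  out$se <- sqrt(mse / 2 * (1 / ns[pairs[1L, ]] + 1 / ns[pairs[2L, ]]))
  out$q <- abs(out$diff) / out$se
  # a perfect fit (zero residual MS) leaves q as 0/0; equal means are then
  # trivially non-significant, unequal ones trivially significant
  zero_se <- out$se == 0
  scale <- max(abs(means), 1)
  out$q[zero_se] <- ifelse(abs(out$diff[zero_se]) < 1e-10 * scale, 0, Inf)
  out$p_adj <- stats::ptukey(out$q, nmeans = k, df = df_res,
                             lower.tail = FALSE)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

# compact letter display by insert-and-absorb: start from one group holding
# every treatment; every significant pair splits each group containing both;
# groups that become subsets of another are absorbed
.cld_insert_absorb <- function(labs, sig_pairs) {
  groups <- list(labs)
  if (nrow(sig_pairs)) {
    for (r in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs$a[r]; b <- sig_pairs$b[r]
      new_groups <- list()
      for (g in groups) {
        if (a %in% g && b %in% g) {
          new_groups <- c(new_groups, list(setdiff(g, a)),
                          list(setdiff(g, b)))
        } else new_groups <- c(new_groups, list(g))
      }
      # absorb: drop any group that is a subset (or later duplicate) of
      # another surviving group
      keep <- rep(TRUE, length(new_groups))
      for (i in seq_along(new_groups)) for (j in seq_along(new_groups)) {
        if (i == j || !keep[i] || !keep[j]) next
        gi <- new_groups[[i]]; gj <- new_groups[[j]]
        if (all(gi %in% gj) && (length(gi) < length(gj) || j < i))
          keep[i] <- FALSE
      }
      groups <- new_groups[keep]
    }
  }
  # order groups by the rank of their best-placed member for stable letters
  first_rank <- vapply(groups, function(g) min(match(g, labs)), numeric(1))
  groups <- groups[order(first_rank)]
  letters_out <- vapply(labs, function(l) {
    paste0(letters[which(vapply(groups, function(g) l %in% g, logical(1)))],
           collapse = "")
  }, character(1))
  letters_out
}

#' Randomized-block ANOVA with Tukey HSD and compact letter display
#'
#' Fits a two-way fixed-effects ANOVA (treatment + block) to replicate-level
#' root lengths, performs all pairwise treatment comparisons with the
#' studentized-range (Tukey HSD) test using the ANOVA residual mean square
#' (Tukey-Kramer standard errors under unequal replication), and summarises
#' the result as a compact letter display in which treatments share a letter
#' if and only if they are not significantly different.
#'
#' @param table data frame with columns \code{treatment},
#'   \code{root_length_mm} and (when \code{block = TRUE}) \code{block}.
#' @param control control label, passed to \code{\link{summarize_bioassay}}.
#' @param alpha family-wise significance level (default 0.05).
#' @param block include the block factor; when blocks are incomplete an
#'   error lists the missing treatment x block cells unless
#'   \code{fall_back_one_way = TRUE}.
#' @param fall_back_one_way drop the block factor instead of erroring when
#'   the design is unbalanced.
#' @return object of class \code{bioassay_test}: \code{summary} (the
#'   \code{\link{summarize_bioassay}} table with a \code{letters} column),
#'   \code{anova} (data frame), \code{pairs} (pairwise table with
#'   Tukey-adjusted p values), \code{alpha}, \code{blocked}.
#' @export
anova_tukey_cld <- function(table, control = "Control", alpha = 0.05,
                            block = TRUE, fall_back_one_way = FALSE) {
  stopifnot(all(c("treatment", "root_length_mm") %in% names(table)))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  table$treatment <- factor(table$treatment)
  k <- nlevels(table$treatment)
  if (k < 2L) stop("at least two treatments are required")
  if (any(tapply(table$root_length_mm, table$treatment, length) < 2L))
    stop("every treatment needs at least two replicates")

  blocked <- isTRUE(block) && "block" %in% names(table)
  if (blocked) {
    table$block <- factor(table$block)
    cells <- table(table$treatment, table$block)
    if (any(cells == 0L)) {
      missing_cells <- which(cells == 0L, arr.ind = TRUE)
      msg <- paste(sprintf("%s x block %s",
                           rownames(cells)[missing_cells[, 1L]],
                           colnames(cells)[missing_cells[, 2L]]),
                   collapse = ", ")
      if (!fall_back_one_way)
        stop("unbalanced design; empty cells: ", msg)
      blocked <- FALSE
    }
  }
  fml <- if (blocked) root_length_mm ~ treatment + block
         else root_length_mm ~ treatment
  fit <- stats::aov(fml, data = table)
  an <- as.data.frame(stats::anova(fit))
  df_res <- stats::df.residual(fit)
  mse <- an["Residuals", "Mean Sq"]

  means <- tapply(table$root_length_mm, table$treatment, mean)
  ns <- tapply(table$root_length_mm, table$treatment, length)
  pairs <- .tukey_pairs(means, ns, mse, df_res, alpha)
  ord_labs <- names(sort(means, decreasing = TRUE))
  letters_out <- .cld_insert_absorb(ord_labs,
                                    pairs[pairs$significant, , drop = FALSE])

  smry <- summarize_bioassay(table, control = control)
  smry$letters <- unname(letters_out[match(smry$treatment,
                                           names(letters_out))])
  structure(list(summary = smry, anova = an, pairs = pairs,
                 alpha = alpha, blocked = blocked,
                 mse = mse, df_residual = df_res),
            class = "bioassay_test")
}

#' @export
print.bioassay_test <- function(x, digits = 3, ...) {
  cat(sprintf("Bioassay ANOVA (%s) with Tukey HSD, alpha = %g\n",
              if (x$blocked) "treatment + block" else "treatment only",
              x$alpha))
  s <- x$summary
  s$mean_mm <- round(s$mean_mm, 1)
  s$sd_mm <- round(s$sd_mm, 1)
  if (!is.null(s$inhibition_pct))
    s$inhibition_pct <- round(s$inhibition_pct, 1)
  print(as.data.frame(s))
  Ftr <- x$anova["treatment", ]
  cat(sprintf("treatment F(%d, %d) = %.3g, p = %.3g\n",
              Ftr$Df, x$df_residual, Ftr$`F value`, Ftr$`Pr(>F)`))
  invisible(x)
}

#' @export
print.bioassay_summary <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}
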