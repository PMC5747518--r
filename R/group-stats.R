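#' Mann-Whitney U test (unpaired, two-tailed)
#'
#' The U statistic counts, over all pairs, how often a value of `a`
#' exceeds one of `b` (ties count one half). For small samples
#' (`min(n_a, n_b) <= 8`) without ties the two-tailed p value comes from
#' the exact null distribution of U; otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param a,b Numeric samples (non-empty).
#' @return List with `U` (for sample `a`), `U_b`, `p_value`, `method`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  Ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  Ub <- na * nb - Ua
  ties <- any(duplicated(c(a, b)))
  if (min(na, nb) <= 8L && !ties) {
    # exact two-tailed p from the null distribution of U
    p <- min(1, 2 * stats::pwilcox(min(Ua, Ub), na, nb))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tie_tab <- table(c(a, b))
    n <- na + nb
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (abs(Ua - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal_approx"
  }
  list(U = Ua, U_b = Ub, p_value = p, method = method)
}

#' Hodges-Lehmann shift estimate with confidence interval
#'
#' The estimate is the median of all pairwise differences `a_i - b_j`; the
#' confidence interval inverts the Mann-Whitney test via order statistics
#' of the sorted pairwise-difference list (assuming similarly shaped
#' distributions).
#'
#' @param a,b Numeric samples (non-empty).
#' @param confidence Nominal coverage (default 0.95).
#' @return List with `estimate`, `ci_lower`, `ci_upper`, `confidence`.
#' @export
hodges_lehmann <- function(a, b, confidence = 0.95) {
  if (!length(a) || !length(b)) stop("empty sample")
  diffs <- sort(as.vector(outer(a, b, `-`)))
  est <- stats::median(diffs)
  m <- length(a) * length(b)
  alpha <- 1 - confidence
  # largest k with P(U <= k - 1) <= alpha/2 under the null
  k <- stats::qwilcox(alpha / 2, length(a), length(b))
  if (stats::pwilcox(k - 1, length(a), length(b)) > alpha / 2) k <- k - 1L
  if (k < 1L || m - k > length(diffs)) {
    lo <- diffs[1L]; hi <- diffs[m]
  } else {
    lo <- diffs[k]; hi <- diffs[m - k + 1L]
  }
  list(estimate = est, ci_lower = lo, ci_upper = hi, confidence = confidence)
}

#' Compare a per-cell metric across groups
#'
#' Per-group mean and SEM plus pairwise Mann-Whitney tests and
#' Hodges-Lehmann shift estimates. P values are reported unadjusted by
#' default (matching pairwise reporting conventions for this kind of
#' data); Holm adjustment is available behind a flag.
#'
#' @param metric Numeric vector, one value per cell.
#' @param labels Group labels, same length (at least 2 groups).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return List of class `"group_comparison"` with `groups` (data frame:
#'   group, n, mean, sem) and `pairs` (data frame: group_a, group_b, n_a,
#'   n_b, U, p_value, hl_estimate, ci_lower, ci_upper).
#' @export
summarize_groups <- function(metric, labels, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (length(metric) != length(labels)) stop("metric and labels lengths differ")
  sp <- split(metric, labels)
  if (length(sp) < 2L) stop("need at least 2 groups")
  groups <- do.call(rbind, lapply(names(sp), function(g) {
    x <- sp[[g]]
    data.frame(group = g, n = length(x), mean = mean(x),
               sem = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (any(groups$n < 2L)) {
    warning("group(s) with n < 2: SEM undefined")
  }
  cmb <- utils::combn(names(sp), 2L)
  pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
    ga <- cmb[1L, j]; gb <- cmb[2L, j]
    mw <- mann_whitney(sp[[ga]], sp[[gb]])
    hl <- hodges_lehmann(sp[[ga]], sp[[gb]])
    data.frame(group_a = ga, group_b = gb, n_a = length(sp[[ga]]),
               n_b = length(sp[[gb]]), U = mw$U, p_value = mw$p_value,
               hl_estimate = hl$estimate, ci_lower = hl$ci_lower,
               ci_upper = hl$ci_upper, stringsAsFactors = FALSE)
  }))
  if (adjust == "holm") pairs$p_adjusted <- stats::p.adjust(pairs$p_value, "holm")
  structure(list(groups = groups, pairs = pairs, adjust = adjust),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group summaries (mean +- SEM):\n")
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    cat(sprintf("  %-12s n = %3d  %.3g +- %.3g\n", g$group, g$n, g$mean, g$sem))
  }
  cat("Pairwise Mann-Whitney / Hodges-Lehmann:\n")
  for (i in seq_len(nrow(x$pairs))) {
    p <- x$pairs[i, ]
    cat(sprintf("  %s vs %s: U = %g, p = %.3g, HL = %.3g [%.3g, %.3g]\n",
                p$group_a, p$group_b, p$U, p$p_value, p$hl_estimate,
                p$ci_lower, p$ci_upper))
  }
  invisible(x)
}
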