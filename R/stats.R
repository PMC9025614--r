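# Nonparametric statistical layer: Kruskal-Wallis on midranks with tie
# correction, exact two-group permutation p-values, and pairwise
# significance matrices.
#
# The pairwise test is the two-sample special case of Kruskal-Wallis
# (equivalent to a tie-corrected two-sided rank-sum test); for the default
# animal-level unit (n = 6 per group) the permutation null is enumerated
# in full (C(12,6) = 924 splits).

# H statistic on midranks with the standard tie correction.
# Returns NA when every value is identical (degenerate: no ranking).
kw_statistic <- function(values, g) {
  N <- length(values)
  r <- rank(values)           # midranks
  Rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  H0 <- 12 / (N * (N + 1)) * sum(n * (Rbar - (N + 1) / 2)^2)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) return(NA_real_)   # all values identical
  H0 / C
}

#' Kruskal-Wallis test for two or more groups
#'
#' Computes the Kruskal-Wallis H statistic on midranks with the standard
#' tie correction. The p-value comes from the chi-square approximation
#' with k - 1 degrees of freedom (default), from full enumeration of the
#' two-group permutation null (`p_method = "exact"`, recommended for small
#' samples), or from Monte-Carlo permutation (`"montecarlo"`, any k).
#' Degenerate all-equal input returns H = 0, p = 1 with a warning.
#'
#' @param samples list of two or more numeric vectors, one per group.
#' @param p_method `"asymptotic"`, `"exact"` (two groups only) or
#'   `"montecarlo"`.
#' @param n_perm Monte-Carlo resamples (default 10000).
#' @param seed seed for the Monte-Carlo substream (ignored otherwise).
#' @param max_enum largest number of splits enumerated exactly before
#'   `"exact"` refuses (guards memory; C(12,6) = 924 is far below it).
#' @return List with `statistic` (H), `p.value`, `df`, `method`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)), p_method = "exact")
kruskal_wallis <- function(samples,
                           p_method = c("asymptotic", "exact", "montecarlo"),
                           n_perm = 10000L, seed = 1L, max_enum = 2e5) {
  p_method <- match.arg(p_method)
  if (!is.list(samples) || length(samples) < 2L)
    stop("samples must be a list of >= 2 groups")
  n <- lengths(samples)
  if (any(n < 1L)) stop("every group must have >= 1 observation")
  values <- unlist(samples, use.names = FALSE)
  if (anyNA(values)) stop("samples must not contain NA")
  g <- rep(seq_along(samples), n)
  k <- length(samples)

  H <- kw_statistic(values, g)
  if (is.na(H)) {
    warning("all values identical; degenerate Kruskal-Wallis (H = 0, p = 1)")
    return(list(statistic = 0, p.value = 1, df = k - 1L,
                method = "degenerate"))
  }

  p <- switch(p_method,
    asymptotic = pchisq(H, df = k - 1L, lower.tail = FALSE),
    exact = {
      if (k != 2L)
        stop("exact enumeration is implemented for two groups only")
      if (choose(sum(n), n[1]) > max_enum)
        stop("too many splits to enumerate exactly (", choose(sum(n), n[1]),
             " > max_enum); use p_method = 'montecarlo'")
      perm_p_two_group(values, n[1], H)
    },
    montecarlo = {
      old <- set_local_seed(substream_seed(seed, "kw-mc"))
      Hp <- replicate(n_perm, kw_statistic(values, sample(g)))
      restore_seed(old)
      (1 + sum(Hp >= H - 1e-9, na.rm = TRUE)) / (n_perm + 1)
    })
  list(statistic = H, p.value = p, df = k - 1L, method = p_method)
}

# Exact permutation p for the two-group H statistic: enumerate every
# assignment of n1 of the N pooled observations to group 1. For fixed
# pooled ranks, H is a function of the group-1 rank sum alone, so each
# split costs one column sum.
perm_p_two_group <- function(values, n1, H_obs) {
  N <- length(values)
  n2 <- N - n1
  r <- rank(values)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  cmb <- combn(N, n1)
  R1 <- colSums(matrix(r[cmb], nrow = n1))
  cc <- (N + 1) / 2
  Tsum <- sum(r)
  H_all <- (12 / (N * (N + 1)) *
              (n1 * (R1 / n1 - cc)^2 + n2 * ((Tsum - R1) / n2 - cc)^2)) / C
  mean(H_all >= H_obs - 1e-9)
}

# Aggregate a measurement table to per-group value vectors for one
# endpoint at one unit of analysis.
endpoint_values <- function(measurements, endpoint = c("orthokeratosis", "thickness"),
                            unit = c("animal", "scale", "reading")) {
  endpoint <- match.arg(endpoint)
  unit <- match.arg(unit)
  validate_measurements(measurements)
  groups <- unique(measurements$group)
  tc <- thickness_cols(measurements)
  vals <- lapply(groups, function(g) {
    sub <- measurements[measurements$group == g, , drop = FALSE]
    if (endpoint == "orthokeratosis") {
      x <- orthokeratosis_degree(sub$A_um, sub$B_um)
      switch(unit,
             animal = as.numeric(tapply(x, sub$animal, mean)),
             scale = x,
             reading = x)   # degree has no sub-scale level
    } else {
      th <- as.matrix(sub[tc])
      switch(unit,
             animal = as.numeric(tapply(as.vector(th),
                                        rep(sub$animal, times = ncol(th)),
                                        mean)),
             scale = rowMeans(th),
             reading = as.vector(th))
    }
  })
  names(vals) <- groups
  vals
}

#' Pairwise Kruskal-Wallis comparison matrix
#'
#' For every unordered pair of groups, runs the two-sample Kruskal-Wallis
#' test on the chosen endpoint aggregated to the chosen unit of analysis
#' (default: per-animal means, the exchangeable unit of the study design)
#' and assembles the symmetric p-value matrix with S/N significance flags
#' at level `alpha`. No multiple-testing correction is applied by default;
#' Holm or Benjamini-Hochberg adjustment is opt-in.
#'
#' With `exact = TRUE` (default) the permutation null is enumerated in
#' full whenever the pair's split count is at most `max_enum`, falling
#' back to seeded Monte-Carlo permutation otherwise.
#'
#' @param measurements a measurement data frame.
#' @param endpoint `"orthokeratosis"` (per-scale degree) or `"thickness"`.
#' @param unit `"animal"` (per-animal means, default), `"scale"` or
#'   `"reading"`.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default), `"holm"` or `"BH"`.
#' @param exact use permutation p-values (TRUE, default) or the chi-square
#'   approximation.
#' @param n_perm,seed Monte-Carlo fallback parameters.
#' @param max_enum enumeration ceiling, see [kruskal_wallis()].
#' @return An object of class `pairwise_matrix`: `labels`, symmetric `p`
#'   matrix (diagonal `NA`), `flags` ("S"/"N"), `long` data frame
#'   (`group_a, group_b, p, flag`), plus `endpoint`, `unit`, `alpha`,
#'   `adjust`.
#' @export
pairwise_comparisons <- function(measurements,
                                 endpoint = c("orthokeratosis", "thickness"),
                                 unit = c("animal", "scale", "reading"),
                                 alpha = 0.05,
                                 adjust = c("none", "holm", "BH"),
                                 exact = TRUE, n_perm = 10000L, seed = 1L,
                                 max_enum = 2e5) {
  endpoint <- match.arg(endpoint)
  unit <- match.arg(unit)
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  vals <- endpoint_values(measurements, endpoint, unit)
  labels <- names(vals)
  if (length(labels) < 2L) stop("need >= 2 groups for pairwise comparisons")
  short <- lengths(vals) < 2L
  if (any(short))
    stop("unit '", unit, "' yields < 2 observations in group(s): ",
         paste(labels[short], collapse = ", "))

  k <- length(labels)
  p <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  pairs <- which(upper.tri(p), arr.ind = TRUE)
  pv <- apply(pairs, 1, function(ij) {
    pair <- vals[c(ij[1], ij[2])]
    method <- if (!exact) "asymptotic"
      else if (choose(sum(lengths(pair)), lengths(pair)[1]) <= max_enum)
        "exact" else "montecarlo"
    res <- withCallingHandlers(
      kruskal_wallis(pair, p_method = method, n_perm = n_perm, seed = seed,
                     max_enum = max_enum),
      warning = function(w) {
        if (grepl("degenerate", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    res$p.value
  })
  if (adjust != "none") pv <- p.adjust(pv, method = adjust)
  p[pairs] <- pv
  p[pairs[, c(2, 1), drop = FALSE]] <- pv

  flags <- ifelse(p <= alpha, "S", "N")
  long <- data.frame(group_a = labels[pairs[, 1]],
                     group_b = labels[pairs[, 2]],
                     p = pv, flag = ifelse(pv <= alpha, "S", "N"),
                     stringsAsFactors = FALSE)
  structure(list(labels = labels, p = p, flags = flags, long = long,
                 endpoint = endpoint, unit = unit, alpha = alpha,
                 adjust = adjust),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Pairwise Kruskal-Wallis comparisons: %s (unit: %s%s)\n\n",
              x$endpoint, x$unit,
              if (x$adjust != "none") paste0(", ", x$adjust, "-adjusted")
              else ""))
  cells <- matrix("", nrow(x$p), ncol(x$p), dimnames = dimnames(x$p))
  off <- !is.na(x$p)
  cells[off] <- sprintf("%s (%s)", x$flags[off],
                        formatC(x$p[off], digits = digits, format = "g"))
  print(cells, quote = FALSE)
  cat(sprintf("\nS = statistically significant; N = non-significant; p <= %g\n",
              x$alpha))
  invisible(x)
}

#' Write a pairwise matrix as a long-format CSV
#'
#' Columns: `group_a, group_b, p, flag` (full precision; report rendering
#' rounds to 3 decimals).
#'
#' @param x a `pairwise_matrix`.
#' @param path file path.
#' @export
write_pairwise <- function(x, path) {
  stopifnot(inherits(x, "pairwise_matrix"))
  write.csv(x$long, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Render a pairwise matrix as Markdown
#'
#' @param x a `pairwise_matrix`.
#' @param digits p-value decimals (default 3, matching report tables).
#' @return Character vector of Markdown lines.
#' @export
format_pairwise_table <- function(x, digits = 3) {
  stopifnot(inherits(x, "pairwise_matrix"))
  cell <- function(i, j) {
    if (i == j) return("")
    sprintf("%s (%s)", x$flags[i, j],
            formatC(x$p[i, j], digits = digits, format = "g"))
  }
  rows <- vapply(seq_along(x$labels), function(i) {
    paste0("| ", x$labels[i], " | ",
           paste(vapply(seq_along(x$labels), cell, character(1), i = i),
                 collapse = " | "), " |")
  }, character(1))
  c(paste0("| Groups | ", paste(x$labels, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(x$labels) + 1), collapse = "|"), "|"),
    rows,
    "",
    sprintf("S = statistically significant; N = statistically non-significant; level of statistical significance is at p ≤ %g.",
            x$alpha))
}
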