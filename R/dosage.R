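# Dosage-sensitivity analysis: a LOESS fit of expression on dosage (CNV
# log2 ratio, or binary status for somatic-derived genes), the monotonicity
# statistic M of the fitted curve, the OLS slope K, the dosage-sensitivity
# score DS = M * |K|, and DSG/DRG classification.

#' Local polynomial (LOESS) fit of expression on dosage
#'
#' Tricube-weighted local polynomial regression via \code{stats::loess} with
#' exact (direct-surface) evaluation. When the dosage covariate has fewer
#' than four distinct values (e.g. binary somatic status) the local fit is
#' degenerate and the curve falls back to the least-squares line.
#'
#' @param x Dosage vector (>= 10 points).
#' @param y Expression vector of equal length.
#' @param span LOESS span in (0, 1] (default 0.75).
#' @param degree Local polynomial degree (default 2).
#' @return A function evaluating the fitted curve at new x values.
#' @export
loess_curve <- function(x, y, span = 0.75, degree = 2L) {
  assert_that(length(x) == length(y), "loess_curve: x and y lengths differ")
  assert_that(length(x) >= 10, "loess_curve: need at least 10 points")
  assert_that(span > 0 && span <= 1, "loess_curve: span must be in (0, 1]")
  if (length(unique(x)) < 4) {
    fit <- stats::lm(y ~ x)
    return(function(newx) unname(stats::predict(fit, data.frame(x = newx))))
  }
  fit <- stats::loess(y ~ x, span = span, degree = degree,
                      control = stats::loess.control(surface = "direct"))
  function(newx) unname(stats::predict(fit, data.frame(x = newx)))
}

#' Isometric points on a fitted curve
#'
#' Evaluates the fitted function at \code{n} equally spaced abscissae
#' spanning the dosage range.
#'
#' @param fit Function from \code{\link{loess_curve}}.
#' @param x_range Length-2 numeric range of the dosage values.
#' @param n Number of points (>= 2, default 50).
#' @return Numeric vector s_1..s_n of fitted values.
#' @export
isometric_points <- function(fit, x_range, n = 50L) {
  assert_that(n >= 2, "isometric_points: n must be >= 2")
  fit(seq(x_range[1], x_range[2], length.out = n))
}

#' Monotonicity statistic of a fitted curve
#'
#' \deqn{M = \frac{2}{n(n-1)} \sum_{i<j} S_{ij}, \quad
#'   S_{ij} = sign(s_j - s_i)} with differences within \code{tie_eps}
#' treated as ties (0). M is 1 for a strictly increasing sequence, -1 for
#' strictly decreasing, 0 for constant.
#'
#' @param s Fitted values s_1..s_n (n >= 2).
#' @param tie_eps Tie tolerance (default 1e-9).
#' @return M in [-1, 1].
#' @export
monotonicity <- function(s, tie_eps = 1e-9) {
  n <- length(s)
  assert_that(n >= 2, "monotonicity: need at least 2 points")
  D <- matrix(s, n, n, byrow = TRUE) - matrix(s, n, n)  # D[i, j] = s_j - s_i
  d <- D[upper.tri(D)]
  sgn <- sign(d)
  sgn[abs(d) <= tie_eps] <- 0
  2 / (n * (n - 1)) * sum(sgn)
}

#' Ordinary least-squares slope
#'
#' @param x Dosage vector (non-constant).
#' @param y Expression vector.
#' @return Slope K.
#' @export
linear_slope <- function(x, y) {
  assert_that(stats::var(x) > 0, "linear_slope: x is constant")
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Dosage-sensitivity score DS = M x |K|
#'
#' Larger DS indicates stronger dosage sensitivity.
#' @param M Monotonicity in [-1, 1].
#' @param K OLS slope.
#' @return DS.
#' @export
ds_score <- function(M, K) {
  assert_that(abs(M) <= 1 + 1e-12, "ds_score: M must lie in [-1, 1]")
  M * abs(K)
}

#' Classify a DS score as dosage-sensitive or dosage-resistant
#'
#' Scores at or outside the bounds are dosage-sensitive genes (DSG: the
#' expression tracks dosage, as when the regression slope magnitude exceeds
#' 1 and the local fit is monotone); scores strictly inside are
#' dosage-resistant genes (DRG: expression decoupled from dosage, flat
#' fits). \code{direction = "inside_dsg"} gives the sentence-literal inverse
#' reading.
#'
#' @param DS DS score (vectorized).
#' @param bounds Length-2 bounds (default c(-0.25, 0.25)).
#' @param direction "outside_dsg" (default) or "inside_dsg".
#' @return Character vector over \{"DSG", "DRG"\}.
#' @export
classify_ds <- function(DS, bounds = c(-0.25, 0.25),
                        direction = c("outside_dsg", "inside_dsg")) {
  direction <- match.arg(direction)
  outside <- DS <= bounds[1] | DS >= bounds[2]
  if (direction == "outside_dsg") ifelse(outside, "DSG", "DRG")
  else ifelse(outside, "DRG", "DSG")
}

#' Dosage-sensitivity analysis for a set of genes
#'
#' Runs the full per-gene pipeline: LOESS fit of expression on dosage,
#' \code{n_points} isometric points, monotonicity M, OLS slope K,
#' DS = M x |K| and DSG/DRG classification. Genes whose fit fails (e.g.
#' constant dosage) are skipped with a warning.
#'
#' @param expression Gene x sample expression matrix.
#' @param dosage Gene x sample dosage matrix (CNV log2 ratio, or 0/1 somatic
#'   status), rows covering \code{genes}.
#' @param genes Genes to analyze (default: rows of \code{dosage}).
#' @param span,degree LOESS controls (defaults 0.75, 2).
#' @param n_points Isometric evaluation points (default
#'   \code{min(50, sample count)}).
#' @param bounds DS classification bounds (default c(-0.25, 0.25)).
#' @param tie_eps Monotonicity tie tolerance.
#' @param direction Classification direction (see \code{\link{classify_ds}}).
#' @return data.frame of class \code{dosage_result} with columns gene, M, K,
#'   DS, class; fitted isometric points are kept in attribute \code{curves}.
#' @export
dosage_sensitivity <- function(expression, dosage, genes = rownames(dosage),
                               span = 0.75, degree = 2L, n_points = NULL,
                               bounds = c(-0.25, 0.25), tie_eps = 1e-9,
                               direction = "outside_dsg") {
  assert_that(length(genes) > 0, "dosage_sensitivity: no genes")
  samples <- intersect(colnames(expression), colnames(dosage))
  n_points <- n_points %||% min(50L, length(samples))
  rows <- list(); curves <- list()
  for (g in genes) {
    res <- tryCatch({
      x <- dosage[g, samples]
      y <- expression[g, samples]
      assert_that(length(x) >= 10, "fewer than 10 samples")
      assert_that(stats::var(x) > 0, "constant dosage")
      fit <- loess_curve(x, y, span = span, degree = degree)
      s <- isometric_points(fit, range(x), n_points)
      M <- monotonicity(s, tie_eps)
      K <- linear_slope(x, y)
      DS <- ds_score(M, K)
      list(row = data.frame(gene = g, M = M, K = K, DS = DS,
                            class = classify_ds(DS, bounds, direction),
                            stringsAsFactors = FALSE),
           curve = list(x = seq(min(x), max(x), length.out = n_points), s = s))
    }, error = function(e) {
      warning(sprintf("dosage_sensitivity: skipping %s (%s)", g,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(res)) { rows[[g]] <- res$row; curves[[g]] <- res$curve }
  }
  out <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    data.frame(gene = character(), M = numeric(), K = numeric(),
               DS = numeric(), class = character(), stringsAsFactors = FALSE)
  attr(out, "curves") <- curves
  attr(out, "bounds") <- bounds
  class(out) <- c("dosage_result", "data.frame")
  out
}

#' Plot a gene's dosage-expression relationship
#'
#' Scatter of expression against dosage with the OLS line (black) and the
#' LOESS curve (blue), the standard diagnostic for DSG/DRG calls.
#'
#' @param x A \code{dosage_result}.
#' @param gene Gene to plot.
#' @param expression,dosage The matrices used in the analysis.
#' @param ... Passed to \code{plot}.
#' @export
plot.dosage_result <- function(x, gene, expression, dosage, ...) {
  samples <- intersect(colnames(expression), colnames(dosage))
  xd <- dosage[gene, samples]; yd <- expression[gene, samples]
  row <- x[x$gene == gene, ]
  graphics::plot(xd, yd, col = "red", pch = 16,
                 xlab = "dosage (log2 CN ratio / mutation status)",
                 ylab = "expression",
                 main = sprintf("%s: M=%.2f K=%.2f DS=%.2f (%s)", gene,
                                row$M, row$K, row$DS, row$class), ...)
  graphics::abline(stats::lm(yd ~ xd), col = "black", lwd = 2)
  cv <- attr(x, "curves")[[gene]]
  if (!is.null(cv)) graphics::lines(cv$x, cv$s, col = "blue", lwd = 2)
  invisible(x)
}
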