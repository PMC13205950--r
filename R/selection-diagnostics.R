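#' Neutrality plot regression
#'
#' Regresses per-gene GC12 (mean of first- and second-position GC) on GC3.
#' A slope near 1 with a significant correlation indicates mutation
#' pressure as the dominant force; a shallow slope with weak correlation
#' indicates selection.
#'
#' @param profiles data.frame from [usage_indices()] (>= 3 genes).
#' @param slope_tolerance Half-width of the "slope close to 1" band used
#'   for the qualitative interpretation flag (default 0.25).
#' @return Object of class `neutrality_result`: list with `points`
#'   (gene, GC12, GC3), `slope`, `intercept`, `pearson_r`, `p_value`,
#'   `interpretation` (`"mutation-dominant"` or `"selection-dominant"`).
#' @export
neutrality_regression <- function(profiles, slope_tolerance = 0.25) {
  if (nrow(profiles) < 3) stop("need at least 3 genes")
  pts <- data.frame(gene = profiles$gene,
                    GC12 = (profiles$GC1 + profiles$GC2) / 2,
                    GC3 = profiles$GC3, stringsAsFactors = FALSE)
  if (sd(pts$GC3) == 0) stop("GC3 is constant: slope undefined")
  fit <- lm(GC12 ~ GC3, data = pts)
  ct <- if (sd(pts$GC12) == 0) list(estimate = 0, p.value = 1)
        else cor.test(pts$GC12, pts$GC3)
  slope <- unname(coef(fit)[2])
  interp <- if (abs(slope - 1) < slope_tolerance && ct$p.value < 0.05)
    "mutation-dominant" else "selection-dominant"
  structure(list(points = pts, slope = slope,
                 intercept = unname(coef(fit)[1]),
                 pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 interpretation = interp),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf("Neutrality plot: GC12 = %.4f + %.4f * GC3 (r = %.4f, p = %.4g)\n",
              x$intercept, x$slope, x$pearson_r, x$p_value))
  cat("  interpretation:", x$interpretation, "\n")
  invisible(x)
}

#' Expected ENC under mutation pressure alone
#'
#' The null ENC of a gene whose codon usage is governed only by its GC3s:
#' `2 + g + 29 / (g^2 + (1 - g)^2)`.
#'
#' @param gc3s GC3s fraction(s) in `[0, 1]`.
#' @return Expected ENC value(s).
#' @export
enc_expected <- function(gc3s) {
  if (any(gc3s < 0 | gc3s > 1)) stop("gc3s must be within [0, 1]")
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

# contiguous half-open ENC-ratio bins [0.205, 0.255), [0.255, 0.305), ...
# labelled with the conventional 2-decimal class names
enc_ratio_bin <- function(ratio) {
  j <- floor((ratio - 0.005) / 0.05)
  lo <- 0.05 * j + 0.01
  hi <- 0.05 * j + 0.05
  lab <- sprintf("%.2f–%.2f", lo, hi)
  lab[j == 4] <- "0.20–0.25"  # published label of the [0.205, 0.255) class
  lab
}

#' ENC plot with expected curve and ENC-ratio binning
#'
#' For each gene, pairs observed ENC with the GC3s-only expectation and the
#' ENC ratio `(ENC_exp - ENC_obs) / ENC_exp`, then bins the ratios into
#' contiguous 0.05-wide classes (0.20-0.25, 0.26-0.30, ..., extended as
#' needed to cover all values).
#'
#' @param profiles data.frame from [usage_indices()].
#' @return Object of class `enc_plot_result`: list with `points` (gene,
#'   GC3s, ENC_obs, ENC_exp, ENC_ratio) and `ratio_bins` (class, mid,
#'   count, frequency; frequencies sum to 1).
#' @export
enc_plot <- function(profiles) {
  pts <- data.frame(
    gene = profiles$gene, GC3s = profiles$GC3s, ENC_obs = profiles$ENC,
    stringsAsFactors = FALSE
  )
  pts$ENC_exp <- enc_expected(pts$GC3s)
  pts$ENC_ratio <- (pts$ENC_exp - pts$ENC_obs) / pts$ENC_exp
  lab <- enc_ratio_bin(pts$ENC_ratio)
  j <- floor((pts$ENC_ratio - 0.005) / 0.05)
  js <- seq(min(j, 4), max(j, 9))  # always span the conventional classes
  labs <- enc_ratio_bin(0.05 * js + 0.03)
  counts <- vapply(js, function(k) sum(j == k), integer(1))
  bins <- data.frame(class = labs, mid = 0.05 * js + 0.03, count = counts,
                     frequency = counts / nrow(pts), stringsAsFactors = FALSE)
  structure(list(points = pts, ratio_bins = bins), class = "enc_plot_result")
}

#' @export
print.enc_plot_result <- function(x, ...) {
  cat("ENC plot:", nrow(x$points), "genes;",
      sum(x$points$ENC_obs < x$points$ENC_exp), "below the expected curve\n")
  print(x$ratio_bins, row.names = FALSE)
  invisible(x)
}

#' PR2 (parity rule 2) plot coordinates
#'
#' Within-codon third-position parity diagnostic: per gene,
#' `x = G3 / (G3 + C3)` and `y = A3 / (A3 + T3)` over third-position base
#' tallies. (0.5, 0.5) is the strand-parity equilibrium. By default the
#' tallies cover synonymous codons only (families of size >= 2);
#' `all_codons = TRUE` uses every counted codon instead.
#'
#' @param genes A [gene_set()].
#' @param all_codons Use all codons' third positions instead of synonymous
#'   ones.
#' @return data.frame: gene, x, y, quadrant (1-4; NA on a boundary),
#'   deviation (Euclidean distance from (0.5, 0.5)). Undefined coordinates
#'   (zero denominator) are NA.
#' @export
pr2 <- function(genes, all_codons = FALSE) {
  stopifnot(inherits(genes, "gene_set"))
  code <- genes$code
  sel <- if (all_codons) code$sense_codons else synonymous_codons(code)
  rows <- lapply(names(genes$genes), function(id) {
    counts <- count_codons(genes$genes[[id]], code)[sel]
    third <- substr(sel, 3, 3)
    tot <- vapply(c("A", "T", "G", "C"),
                  function(b) sum(counts[third == b]), numeric(1))
    x <- if (tot[["G"]] + tot[["C"]] > 0) tot[["G"]] / (tot[["G"]] + tot[["C"]])
         else NA_real_
    y <- if (tot[["A"]] + tot[["T"]] > 0) tot[["A"]] / (tot[["A"]] + tot[["T"]])
         else NA_real_
    quad <- if (anyNA(c(x, y)) || x == 0.5 || y == 0.5) NA_integer_
            else if (x > 0.5 && y > 0.5) 1L
            else if (x < 0.5 && y > 0.5) 2L
            else if (x < 0.5) 3L else 4L
    data.frame(gene = id, x = x, y = y, quadrant = quad,
               deviation = sqrt((x - 0.5)^2 + (y - 0.5)^2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Diagnostic scatter plots
#'
#' Base-graphics renderings of the three diagnostics: the neutrality plot
#' with its fitted line and the diagonal, the ENC plot with the expected
#' curve, and the PR2 plot with its centre lines.
#'
#' @param x Result of [neutrality_regression()], [enc_plot()] or [pr2()].
#' @param ... Passed to [graphics::plot()].
#' @name diagnostic-plots
NULL

#' @rdname diagnostic-plots
#' @export
plot.neutrality_result <- function(x, ...) {
  graphics::plot(x$points$GC3, x$points$GC12, xlab = "GC3", ylab = "GC12",
                 pch = 19, ...)
  graphics::abline(x$intercept, x$slope, col = "red")
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' @rdname diagnostic-plots
#' @export
plot.enc_plot_result <- function(x, ...) {
  graphics::plot(x$points$GC3s, x$points$ENC_obs, xlab = "GC3s", ylab = "ENC",
                 ylim = c(0, 64), pch = 19, ...)
  g <- seq(0.01, 0.99, length.out = 200)
  graphics::lines(g, enc_expected(g))
  invisible(x)
}

#' Render a PR2 data.frame
#'
#' @param points data.frame from [pr2()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_pr2 <- function(points, ...) {
  graphics::plot(points$x, points$y, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "G3 / (G3 + C3)", ylab = "A3 / (A3 + T3)",
                 pch = 19, ...)
  graphics::abline(h = 0.5, v = 0.5, lty = 2, col = "grey")
  invisible(points)
}
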