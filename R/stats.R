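#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Orders the m raw p-values ascending and sets
#' `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`, then enforces monotonicity by
#' a running maximum and caps at 1; results are returned in the original
#' order. This is the step-down Sidak procedure used for the multiple
#' comparisons in the figure statistics this package reproduces.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
holm_sidak <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Group comparisons with Holm-Sidak adjustment
#'
#' Runs the between-group tests typically reported for islet coupling
#' summaries: two-sample or paired t-tests, and one- or two-way ANOVA
#' followed by pairwise group contrasts (pooled-variance t statistics on
#' the ANOVA residual error) with Holm-Sidak adjustment across contrasts.
#'
#' @param df data.frame in long format.
#' @param value name of the numeric response column.
#' @param group name of the grouping factor column.
#' @param design `"t"` (two-sample, pooled variance), `"paired_t"`
#'   (requires `subject`), `"anova1"`, or `"anova2"` (requires `factor2`;
#'   contrasts are group differences within each level of `factor2`).
#' @param factor2 second factor column for `anova2` (e.g. condition
#'   window).
#' @param subject subject column aligning paired observations.
#' @param adjust `"holm_sidak"` (default) or `"none"`.
#' @return A list of class `comparison_result`: `contrasts` (data.frame
#'   with contrast, estimate, p_raw, p_adj, n per group), `test`,
#'   `adjust`, and `anova` (the aov summary table, for ANOVA designs).
#' @export
compare_groups <- function(df, value, group,
                           design = c("t", "paired_t", "anova1", "anova2"),
                           factor2 = NULL, subject = NULL,
                           adjust = c("holm_sidak", "none")) {
  design <- match.arg(design)
  adjust <- match.arg(adjust)
  df <- as.data.frame(df)
  y <- df[[value]]
  g <- factor(df[[group]])
  if (nlevels(g) < 2) stop_isletconn("too_few_groups", "need >= 2 groups")
  anova_tab <- NULL

  if (design == "t" || design == "paired_t") {
    pairs <- utils::combn(levels(g), 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      ya <- y[g == pr[1]]; yb <- y[g == pr[2]]
      if (design == "paired_t") {
        if (is.null(subject)) {
          stop_isletconn("unbalanced_pairs",
                         "paired design needs a subject column")
        }
        sa <- df[[subject]][g == pr[1]]; sb <- df[[subject]][g == pr[2]]
        m <- match(sa, sb)
        if (anyNA(m) || length(ya) != length(yb)) {
          stop_isletconn("unbalanced_pairs",
                         "paired design requires aligned observations")
        }
        tt <- stats::t.test(ya, yb[m], paired = TRUE)
      } else {
        tt <- stats::t.test(ya, yb, var.equal = TRUE)
      }
      data.frame(contrast = paste(pr[1], "vs", pr[2]),
                 estimate = mean(ya) - mean(yb),
                 p_raw = tt$p.value, n_a = length(ya), n_b = length(yb))
    })
    contrasts <- do.call(rbind, rows)
  } else {
    if (design == "anova1") {
      fit <- stats::aov(y ~ g)
      anova_tab <- as.data.frame(summary(fit)[[1]])
      cells <- data.frame(g = levels(g), f2 = "")
    } else {
      if (is.null(factor2)) {
        stop_isletconn("missing_factor",
                       "anova2 needs a second factor column")
      }
      f2 <- factor(df[[factor2]])
      fit <- stats::aov(y ~ g * f2)
      anova_tab <- as.data.frame(summary(fit)[[1]])
      cells <- expand.grid(g = levels(g), f2 = levels(f2),
                           stringsAsFactors = FALSE)
    }
    mse <- stats::deviance(fit) / stats::df.residual(fit)
    dfree <- stats::df.residual(fit)
    f2v <- if (design == "anova2") factor(df[[factor2]]) else
      factor(rep("", length(y)))
    rows <- list()
    for (lev in unique(cells$f2)) {
      in_lev <- f2v == lev
      for (pr in utils::combn(levels(g), 2, simplify = FALSE)) {
        ya <- y[in_lev & g == pr[1]]; yb <- y[in_lev & g == pr[2]]
        if (length(ya) == 0 || length(yb) == 0) next
        est <- mean(ya) - mean(yb)
        se <- sqrt(mse * (1 / length(ya) + 1 / length(yb)))
        p <- 2 * stats::pt(-abs(est / se), dfree)
        lab <- paste(pr[1], "vs", pr[2])
        if (nzchar(lev)) lab <- paste0(lab, " @ ", lev)
        rows[[length(rows) + 1]] <-
          data.frame(contrast = lab, estimate = est, p_raw = p,
                     n_a = length(ya), n_b = length(yb))
      }
    }
    contrasts <- do.call(rbind, rows)
  }
  contrasts$p_adj <- if (adjust == "holm_sidak") {
    holm_sidak(contrasts$p_raw)
  } else contrasts$p_raw
  structure(list(contrasts = contrasts, test = design, adjust = adjust,
                 anova = anova_tab),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>", x$test, "with", x$adjust, "adjustment\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}
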