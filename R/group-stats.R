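#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak correction for a family of m p-values: order them
#' ascending and set adjusted_i = max over j <= i of 1 - (1 - p_j)^(m-j+1),
#' capped at 1. Controls the family-wise error rate at alpha under
#' independence (and is slightly more powerful than Holm's Bonferroni
#' step-down). `stats::p.adjust` offers Holm but not the Sidak variant,
#' hence this small implementation.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @examples
#' holm_sidak(c(0.01, 0.02, 0.04))   # 0.0297, 0.0396, 0.0400
#' @export
holm_sidak <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

sig_stars <- function(p) {
  cut(p, c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"))
}

#' Group comparison: one-way ANOVA plus Holm-Sidak-corrected pairwise t tests
#'
#' The statistical layer used throughout behavioural phenotyping figures:
#' an omnibus one-way ANOVA across all groups, then Student's two-sample
#' t tests for a specified set of pairs (by default each group against the
#' control, mirroring mutant-vs-wild-type designs), with Holm-Sidak
#' correction over the family. Both raw and adjusted p-values are reported;
#' significance stars (* p<0.05, ** p<0.01, *** p<0.001) are assigned from
#' the adjusted values.
#'
#' @param values Numeric response per fly.
#' @param group Factor or character of group labels, same length.
#' @param control Label of the reference group for the default comparison
#'   set (default: first level).
#' @param pairs Optional list of length-2 character vectors naming the
#'   pairs to test; overrides `control`. An empty list gives omnibus only.
#' @param var_equal Use the classical equal-variance Student's t (default
#'   TRUE); FALSE gives Welch.
#' @return An object of class `group_comparison`: list with `omnibus`
#'   (`F`, `df1`, `df2`, `p`), `pairwise` (data.frame `group1`, `group2`,
#'   `t`, `df`, `p_raw`, `p_adj`, `stars`), `groups` (per-group n, mean,
#'   sem).
#' @export
compare_groups <- function(values, group, control = NULL, pairs = NULL,
                           var_equal = TRUE) {
  group <- as.character(group)
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- group[ok]
  labs <- unique(group)
  if (length(labs) < 2) stop("need at least 2 groups")
  n_by <- table(group)
  if (any(n_by < 2)) stop("every group needs n >= 2")

  fit <- stats::aov(values ~ factor(group))
  an <- summary(fit)[[1]]
  omnibus <- list(F = an[["F value"]][1], df1 = an[["Df"]][1],
                  df2 = an[["Df"]][2], p = an[["Pr(>F)"]][1])

  if (is.null(pairs)) {
    if (is.null(control)) control <- labs[1]
    if (!control %in% labs) stop("control group '", control, "' not found")
    pairs <- lapply(setdiff(labs, control), function(g) c(control, g))
  }
  pw <- NULL
  if (length(pairs) > 0) {
    rows <- lapply(pairs, function(pr) {
      x <- values[group == pr[1]]; y <- values[group == pr[2]]
      if (stats::sd(c(x, y)) == 0) {
        # two flat identical groups: no evidence of difference
        return(data.frame(group1 = pr[1], group2 = pr[2], t = 0,
                          df = length(x) + length(y) - 2, p_raw = 1,
                          flat = TRUE))
      }
      tt <- stats::t.test(x, y, var.equal = var_equal)
      data.frame(group1 = pr[1], group2 = pr[2],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value, flat = FALSE)
    })
    pw <- do.call(rbind, rows)
    pw$p_adj <- holm_sidak(pw$p_raw)
    pw$stars <- as.character(sig_stars(pw$p_adj))
  }
  groups <- do.call(rbind, lapply(labs, function(g) {
    v <- values[group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  structure(list(omnibus = omnibus, pairwise = pw, groups = groups),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$omnibus$df1, x$omnibus$df2, x$omnibus$F, x$omnibus$p))
  if (!is.null(x$pairwise)) {
    cat("Pairwise t tests (Holm-Sidak adjusted):\n")
    print.data.frame(x$pairwise[, c("group1", "group2", "t", "p_raw",
                                    "p_adj", "stars")],
                     row.names = FALSE, digits = 4)
  }
  invisible(x)
}
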