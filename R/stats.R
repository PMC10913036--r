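#' Square-root transform
#'
#' Variance-stabilizing transform applied to PLV-type outcomes before group
#' statistics.
#'
#' @param values Non-negative numeric vector.
#' @return Element-wise square roots.
#' @export
sqrt_transform <- function(values) {
  if (any(values < 0, na.rm = TRUE)) {
    stop_invalid("negative values cannot be square-root transformed")
  }
  sqrt(values)
}

check_balance <- function(table, subject, factor) {
  tab <- table(table[[subject]], table[[factor]])
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    cells <- apply(bad, 1, function(ij) {
      sprintf("(%s, %s)", rownames(tab)[ij[1]], colnames(tab)[ij[2]])
    })
    stop_invalid("unbalanced design; cells not contributing exactly once: %s",
                 paste(cells, collapse = ", "))
  }
  invisible(tab)
}

# one-sample t on per-subject scores, with exact-separation handling
score_ttest <- function(scores) {
  n <- length(scores)
  m <- mean(scores)
  s <- sd(scores)
  # zap floating-point dust: a contrast of constant data is exactly null
  tol <- 1e-10 * max(1, max(abs(scores)))
  if (abs(m) < tol) m <- 0
  if (s < tol) s <- 0
  if (s == 0) {
    if (m == 0) {
      return(list(estimate = 0, t = 0, df = n - 1, p = 1, exact = FALSE))
    }
    # zero within-subject variability: certainty beyond the t machinery
    return(list(estimate = m, t = sign(m) * Inf, df = n - 1, p = 0,
                exact = TRUE))
  }
  tt <- t.test(scores)
  list(estimate = m, t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, exact = FALSE)
}

#' Within-subject linear trend across an ordered factor
#'
#' Computes the orthogonal-polynomial linear contrast of the outcome across
#' the ordered factor levels separately for each subject, then tests the
#' contrast scores against zero with a one-sample t-test (two-sided). This
#' is the within-subject analogue of a mixed-model linear trend contrast.
#'
#' @param table Data frame with one row per subject x level (balanced).
#' @param value Outcome column name (default `"peak_plv"`).
#' @param factor Ordered factor column name (default `"jitter"`).
#' @param subject Subject identifier column name.
#' @return List with `estimate` (mean contrast score), `slope_per_step`
#'   (equivalent change in the outcome per factor step), `t`, `df`, `p`,
#'   and `exact` (TRUE when within-subject variability is exactly zero and
#'   the p-value degenerates).
#' @export
linear_trend <- function(table, value = "peak_plv", factor = "jitter",
                         subject = "subject_id") {
  levs <- sort(unique(table[[factor]]))
  if (length(levs) < 3) stop_invalid("need >= 3 factor levels for a trend")
  subs <- unique(table[[subject]])
  if (length(subs) < 3) stop_invalid("need >= 3 subjects")
  check_balance(table, subject, factor)
  w <- stats::contr.poly(length(levs))[, 1]
  scores <- vapply(subs, function(s) {
    rows <- table[table[[subject]] == s, ]
    rows <- rows[order(rows[[factor]]), ]
    sum(w * rows[[value]])
  }, numeric(1))
  out <- score_ttest(scores)
  # linear-contrast score of a perfect unit-per-step ramp:
  out$slope_per_step <- out$estimate / sum(w * seq_along(levs))
  out
}

#' Paired contrast between two stimulus domains at one design cell
#'
#' Paired t-test on per-subject differences (second level minus first level
#' of `between`, alphabetical unless given as a factor), restricted to the
#' design cell in `at`.
#'
#' @param table Data frame of per-subject results.
#' @param between Column with exactly two levels to contrast (default
#'   `"stimulus"`).
#' @param at Named list selecting the design cell, e.g.
#'   `list(rate = 4.5, jitter = 0)`.
#' @param value Outcome column name.
#' @param subject Subject identifier column name.
#' @return List with `estimate` (mean difference), `t`, `df`, `p`, `exact`.
#' @export
paired_contrast <- function(table, between = "stimulus", at = list(),
                            value = "peak_plv", subject = "subject_id") {
  for (nm in names(at)) table <- table[table[[nm]] == at[[nm]], ]
  levs <- sort(unique(as.character(table[[between]])))
  if (length(levs) != 2) {
    stop_invalid("`between` must have exactly 2 levels in the cell, found %d",
                 length(levs))
  }
  a <- table[table[[between]] == levs[1], c(subject, value)]
  b <- table[table[[between]] == levs[2], c(subject, value)]
  if (!setequal(a[[subject]], b[[subject]]) ||
      anyDuplicated(a[[subject]]) || anyDuplicated(b[[subject]])) {
    stop_invalid("missing or duplicated subject pairs in the cell")
  }
  d <- b[[value]][match(a[[subject]], b[[subject]])] - a[[value]]
  out <- score_ttest(d)
  out$levels <- levs          # difference is levels[2] - levels[1]
  out
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Equal-length numeric vectors (n >= 3, finite, non-constant).
#' @return List with `r`, `t`, `df`, `p`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y differ in length")
  if (length(x) < 3) stop_invalid("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_invalid("non-finite values in input")
  }
  if (var(x) == 0 || var(y) == 0) {
    stop_invalid("zero-variance input; correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value)
}

#' Per-jitter stimulus-domain contrasts with Holm adjustment
#'
#' Runs [paired_contrast()] at each jitter level of the periodicity design
#' and applies Holm step-down multiple-comparison control across levels.
#'
#' @param table Per-subject results restricted to one rate.
#' @param value Outcome column name.
#' @return Data frame with one row per jitter level: estimate, t, df, p,
#'   p_adj.
#' @export
jitter_contrasts <- function(table, value = "peak_plv") {
  jits <- sort(unique(table$jitter))
  rows <- lapply(jits, function(j) {
    ct <- paired_contrast(table, at = list(jitter = j), value = value)
    data.frame(jitter = j, estimate = ct$estimate, t = ct$t, df = ct$df,
               p = ct$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "holm")
  out
}
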