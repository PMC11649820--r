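# Chance-corrected inter-rater agreement: weighted Gwet AC1 for two raters
# (local laboratory vs central re-computation) over ordinal AKI stages.

#' Agreement weight matrices for ordinal categories
#'
#' The default `"ordinal"` family is combinatorial:
#' `w_kl = 1 - choose(|k-l| + 1, 2) / choose(q, 2)`, giving, for q = 4
#' stages, off-diagonal weights 5/6, 1/2 and 0 at stage distances 1, 2 and
#' 3 — exact agreement gets full credit, adjacent stages most partial
#' credit, and opposite extremes none. `"linear"` (`1 - d/(q-1)`),
#' `"quadratic"` (`1 - (d/(q-1))^2`) and `"identity"` (unweighted) are
#' available for sensitivity checks.
#'
#' @param q number of categories (>= 2)
#' @param family one of `"ordinal"`, `"linear"`, `"quadratic"`, `"identity"`
#' @return symmetric `q x q` matrix with unit diagonal, entries in [0, 1]
#' @export
#' @examples
#' ordinal_weights(4)
ordinal_weights <- function(q, family = c("ordinal", "linear", "quadratic",
                                          "identity")) {
  if (q < 2) stop("need at least 2 categories")
  family <- match.arg(family)
  d <- abs(outer(seq_len(q) - 1L, seq_len(q) - 1L, "-"))
  w <- switch(family,
    ordinal = 1 - choose(d + 1, 2) / choose(q, 2),
    linear = 1 - d / (q - 1),
    quadratic = 1 - (d / (q - 1))^2,
    identity = (d == 0) * 1)
  dimnames(w) <- list(seq_len(q) - 1L, seq_len(q) - 1L)
  w
}

#' Cross-tabulate paired stages into a confusion matrix
#'
#' Rows are the local laboratory stage, columns the centrally recomputed
#' stage; all `q` categories are kept even when a marginal is empty (the
#' complete-case analysis relies on a retained, empty local-0 row).
#'
#' @param local,central integer vectors of stages in `0..(q-1)`
#' @param q number of categories (default 4: AKI stages 0--3)
#' @return object of class `aki_confusion`: integer counts matrix with an
#'   `n` attribute; `percents()` and `print()` render a report-style table
#'   with cell percents and marginals
#' @export
cross_tabulate <- function(local, central, q = 4) {
  stopifnot(length(local) == length(central))
  ok <- !is.na(local) & !is.na(central)
  local <- local[ok]
  central <- central[ok]
  if (length(local) && (any(local < 0 | local >= q) || any(central < 0 | central >= q))) {
    stop("stages must lie in 0..", q - 1)
  }
  lv <- seq_len(q) - 1L
  m <- table(factor(local, levels = lv), factor(central, levels = lv))
  m <- matrix(as.integer(m), q, q, dimnames = list(local = lv, central = lv))
  as_confusion(m)
}

#' Coerce a plain counts matrix to an `aki_confusion`
#' @param m square non-negative counts matrix
#' @return `aki_confusion`
#' @export
as_confusion <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  if (is.null(dimnames(m))) {
    dimnames(m) <- list(local = seq_len(nrow(m)) - 1L, central = seq_len(ncol(m)) - 1L)
  }
  structure(m, class = c("aki_confusion", "matrix"), n = sum(m))
}

#' Cell percents and marginals of a confusion matrix
#' @param m `aki_confusion` or counts matrix
#' @return list with `percent` (cells as percent of total), `row_total`,
#'   `col_total`, `n`
#' @export
percents <- function(m) {
  m <- unclass(as_confusion(m))
  attr(m, "n") <- NULL
  n <- sum(m)
  list(percent = 100 * m / n, row_total = rowSums(m), col_total = colSums(m),
       n = n)
}

#' @export
print.aki_confusion <- function(x, digits = 2, ...) {
  p <- percents(x)
  m <- unclass(x)
  q <- nrow(m)
  cat(sprintf("<aki_confusion> local (rows) vs central (cols), n = %s\n",
              format(p$n, big.mark = ",")))
  for (k in seq_len(q)) {
    cat(sprintf("  %s | %s | %9s  (%s%%)\n", rownames(m)[k],
                paste(sprintf("%9s", format(m[k, ], big.mark = ",")), collapse = " "),
                format(p$row_total[k], big.mark = ","),
                formatC(sum(p$percent[k, ]), digits = digits, format = "f")))
  }
  cat(sprintf("    | %s | %9s\n",
              paste(sprintf("%9s", format(p$col_total, big.mark = ",")), collapse = " "),
              format(p$n, big.mark = ",")))
  invisible(x)
}

#' Weighted Gwet agreement coefficient (AC1/AC2)
#'
#' Chance-corrected agreement between two raters over `q` ordinal
#' categories, robust to the extreme prevalence of stage 0 that defeats
#' kappa-type statistics. With weights `w` and cell proportions `p_kl`:
#' observed agreement `pa = sum(w * p)`; chance agreement
#' `pe = (sum(w) / (q (q - 1))) * sum(pi_k (1 - pi_k))` with
#' `pi_k = (row_k + col_k) / (2 n)`; coefficient `(pa - pe) / (1 - pe)`.
#' With identity weights this is Gwet's AC1; with ordinal weights the
#' weighted (AC2) generalisation.
#'
#' The standard error uses Gwet's closed-form two-rater variance with
#' subjects as independent units (computable from the cell counts alone);
#' `ci_method = "bootstrap"` instead resamples subjects multinomially over
#' the cells (seeded) — a cross-check, not the default.
#'
#' @param m `aki_confusion`, counts matrix, or the output of
#'   [cross_tabulate()]
#' @param weights a weight matrix or a family name accepted by
#'   [ordinal_weights()] (default `"ordinal"`)
#' @param conf_level confidence level (default 0.95; t quantile, n - 1 df)
#' @param ci_method `"analytic"` or `"bootstrap"`
#' @param n_boot bootstrap resamples (default 1000)
#' @param seed seed for the bootstrap resampler
#' @return object of class `agreement_result`: list with `coefficient`,
#'   `pa` (weighted observed agreement), `pa_unweighted`, `pe`, `se`,
#'   `ci` (length 2), `band`, `acceptable`, `n`, `q`, `weights_family`
#' @export
#' @examples
#' m <- diag(c(50, 30, 15, 5))
#' gwet_ac1(m)$coefficient  # 1
gwet_ac1 <- function(m, weights = "ordinal", conf_level = 0.95,
                     ci_method = c("analytic", "bootstrap"), n_boot = 1000,
                     seed = NULL) {
  ci_method <- match.arg(ci_method)
  m <- unclass(as_confusion(m))
  q <- nrow(m)
  n <- sum(m)
  if (n <= 0) stop("confusion matrix is empty")
  w <- if (is.character(weights)) ordinal_weights(q, weights) else as.matrix(weights)
  wf <- if (is.character(weights)) weights else "custom"
  stopifnot(all(dim(w) == q))

  p <- m / n
  pa <- sum(w * p)
  pa_unw <- sum(diag(p))
  pik <- (rowSums(m) + colSums(m)) / (2 * n)
  tw <- sum(w)
  pe <- tw / (q * (q - 1)) * sum(pik * (1 - pik))
  if (pe >= 1) stop("degenerate matrix: chance agreement is 1, coefficient undefined")
  gamma <- (pa - pe) / (1 - pe)

  se <- NA_real_
  if (n > 1) {
    if (ci_method == "analytic") {
      # Gwet's two-rater variance, aggregated over identical cells:
      # gamma_s = gamma*_s - 2 (1 - gamma) (pe_s - pe) / (1 - pe)
      pe_s <- tw / (q * (q - 1)) *
        outer((1 - pik), (1 - pik), function(a, b) (a + b) / 2)
      g_star <- (w - pe) / (1 - pe)
      g_s <- g_star - 2 * (1 - gamma) * (pe_s - pe) / (1 - pe)
      v <- sum(m * (g_s - gamma)^2) / (n * (n - 1))
      se <- sqrt(v)
    } else {
      if (!is.null(seed)) set.seed(seed)
      cells <- as.vector(m)
      reps <- vapply(seq_len(n_boot), function(i) {
        mb <- matrix(stats::rmultinom(1, n, cells / n), q, q)
        pb <- mb / n
        pab <- sum(w * pb)
        pikb <- (rowSums(mb) + colSums(mb)) / (2 * n)
        peb <- tw / (q * (q - 1)) * sum(pikb * (1 - pikb))
        (pab - peb) / (1 - peb)
      }, numeric(1))
      se <- sd(reps)
    }
  }
  alpha <- 1 - conf_level
  tq <- if (n > 1) qt(1 - alpha / 2, n - 1) else NA_real_
  ci <- pmin(1, pmax(-1, gamma + c(-1, 1) * tq * se))

  structure(list(coefficient = gamma, pa = pa, pa_unweighted = pa_unw,
                 pe = pe, se = se, ci = ci, conf_level = conf_level,
                 band = landis_koch_band(gamma),
                 acceptable = gamma >= 0.61,
                 n = n, q = q, weights_family = wf, ci_method = ci_method),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Gwet agreement coefficient (%s weights): %.4f\n",
              x$weights_family, x$coefficient))
  cat(sprintf("  observed agreement: %.4f weighted, %.4f unweighted\n",
              x$pa, x$pa_unweighted))
  cat(sprintf("  chance agreement:   %.4f\n", x$pe))
  cat(sprintf("  %d%% CI: %.4f, %.4f (se %.2g, %s)\n",
              round(100 * x$conf_level), x$ci[1], x$ci[2], x$se, x$ci_method))
  cat(sprintf("  n = %s; Landis-Koch: %s%s\n", format(x$n, big.mark = ","),
              x$band, if (x$acceptable) " (acceptable)" else ""))
  invisible(x)
}

#' Percent positive agreement
#'
#' The unweighted diagonal share of a confusion matrix (the proportion of
#' results where the two raters give the same stage), with the weighted
#' observed agreement reported alongside.
#'
#' @param m confusion matrix
#' @param weights weight family or matrix for the weighted variant
#' @return list with `unweighted` and `weighted` proportions
#' @export
percent_positive_agreement <- function(m, weights = "ordinal") {
  m <- unclass(as_confusion(m))
  n <- sum(m)
  if (n <= 0) stop("empty matrix")
  w <- if (is.character(weights)) ordinal_weights(nrow(m), weights) else as.matrix(weights)
  list(unweighted = sum(diag(m)) / n, weighted = sum(w * m) / n)
}

#' Landis-Koch interpretation band
#'
#' Conventional labels for agreement magnitude: below 0 `"poor"`, 0--0.20
#' `"slight"`, 0.21--0.40 `"fair"`, 0.41--0.60 `"moderate"`, 0.61--0.80
#' `"substantial"`, 0.81--1.00 `"almost perfect"`. Coefficients of 0.61 and
#' above are conventionally deemed acceptable; see the `acceptable` field of
#' [gwet_ac1()].
#'
#' @param coefficient numeric in [-1, 1]; vectorised
#' @return character vector of band labels
#' @export
landis_koch_band <- function(coefficient) {
  if (any(coefficient < -1 | coefficient > 1, na.rm = TRUE)) {
    stop("coefficient outside [-1, 1]")
  }
  x <- coefficient
  out <- rep(NA_character_, length(x))
  out[x < 0] <- "poor"
  out[x >= 0 & x <= 0.20] <- "slight"
  out[x > 0.20 & x <= 0.40] <- "fair"
  out[x > 0.40 & x <= 0.60] <- "moderate"
  out[x > 0.60 & x <= 0.80] <- "substantial"
  out[x > 0.80 & x <= 1] <- "almost perfect"
  out
}
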