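# Rank-correlation validation layer.
#
# Agreement between image-derived and clinical indices is summarised by
# Spearman's rho: the Pearson correlation of average ranks (ties receive the
# mean of the ranks they span). The two-sided p-value uses the t
# approximation t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of
# freedom; for n <= 8 an exact permutation p-value over all n! orderings is
# also reported.

# all permutations of 1..n as an n! x n matrix (n <= 8 -> at most 40320 rows)
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  smaller <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[smaller], nrow = nrow(smaller)))
  }))
}

spearman_exact_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  perms <- perm_matrix(n)
  ry_c <- ry - mean(ry)
  rx_c <- rx - mean(rx)
  denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
  # rho for every permutation of y against fixed x, via one matrix product
  rhos <- (matrix(ry_c[perms], nrow = nrow(perms)) %*% rx_c) / denom
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

#' Spearman rank correlation with p-value
#'
#' Computes Spearman's rho between two paired numeric vectors as the Pearson
#' correlation of average ranks, with a two-sided p-value from the
#' t-distribution approximation. For `n <= 8` the exact permutation p-value
#' (over all `n!` reorderings) is reported alongside.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, each with at least two
#'   distinct values.
#' @return One-row tibble: `rho`, `p_value` (t approximation), `p_exact`
#'   (permutation, `NA` for `n > 8`), `n`.
#' @examples
#' spearman_rank(1:4, c(10, 20, 30, 40))
#' @export
spearman_rank <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) {
    abort_input("`x` and `y` must be numeric vectors.")
  }
  if (length(x) != length(y)) {
    abort_input("`x` and `y` must have equal length.")
  }
  n <- length(x)
  if (n < 3L) abort_input("Spearman correlation requires n >= 3 pairs.")
  if (anyNA(x) || anyNA(y)) abort_input("Inputs must not contain NA.")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort(
      "Rank variance is zero (a constant input): rho is undefined.",
      class = c("selfieplaque_degenerate_ranks", "selfieplaque_input_error"))
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1 - 1e-12) {
    p_t <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_t <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  p_exact <- if (n <= 8L) spearman_exact_p(rx, ry, rho) else NA_real_
  tibble(rho = rho, p_value = p_t, p_exact = p_exact, n = n)
}

#' Pairwise Spearman correlation matrix of a cohort table
#'
#' All-pairs rank correlations among the numeric columns of a cohort table,
#' the shape of the standard selfie-vs-clinical validation table (VPI, DPI,
#' SVPI, SDPI, VPIant, DPIant, area fraction).
#'
#' @param data Data frame with at least two numeric columns; non-numeric
#'   columns (for example `subject_id`) are dropped.
#' @return A `correlation_matrix`: list with symmetric `rho` and `p_value`
#'   matrices (unit diagonal, `p` diagonal `NA`) and `n`, the number of rows.
#'   A column pair for which rho is undefined (constant column) yields `NA`
#'   entries.
#' @export
correlation_matrix <- function(data) {
  if (!is.data.frame(data)) abort_input("`data` must be a data frame.")
  num <- data[vapply(data, is.numeric, logical(1))]
  if (ncol(num) < 2L) {
    abort_input("Need at least two numeric columns to correlate.")
  }
  vars <- names(num)
  k <- length(vars)
  rho <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  pval <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      res <- tryCatch(spearman_rank(num[[i]], num[[j]]),
                      selfieplaque_degenerate_ranks = function(e) NULL)
      if (!is.null(res)) {
        rho[i, j] <- rho[j, i] <- res$rho
        pval[i, j] <- pval[j, i] <- res$p_value
      }
    }
  }
  structure(list(rho = rho, p_value = pval, n = nrow(num)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<correlation_matrix> Spearman rho over %d subjects\n", x$n))
  print(round(x$rho, digits))
  invisible(x)
}

#' Tidy a correlation matrix into long form
#'
#' @param x A `correlation_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per ordered variable pair: `var1`, `var2`,
#'   `rho`, `p_value`, `n`.
#' @method tidy correlation_matrix
#' @export
tidy.correlation_matrix <- function(x, ...) {
  vars <- rownames(x$rho)
  grid <- tidyr::expand_grid(var1 = vars, var2 = vars)
  dplyr::mutate(grid,
                rho = as.vector(t(x$rho)),
                p_value = as.vector(t(x$p_value)),
                n = x$n)
}

#' Heatmap of a Spearman correlation matrix
#'
#' @param object A `correlation_matrix`.
#' @param ... Unused.
#' @return A ggplot tile plot of rho with printed coefficients.
#' @method autoplot correlation_matrix
#' @export
autoplot.correlation_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)),
                       size = 3, na.rm = TRUE) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Spearman rho (n = %d)", object$n))
}

#' Write a correlation matrix to CSV and JSON
#'
#' Writes `<prefix>_rho.csv` and `<prefix>_p.csv` (wide matrices with a
#' leading `variable` column) and `<prefix>.json` (long form).
#'
#' @param x A `correlation_matrix`.
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_correlation <- function(x, prefix) {
  if (!inherits(x, "correlation_matrix")) {
    abort_input("`x` must be a `correlation_matrix`.")
  }
  wide <- function(m) {
    dplyr::bind_cols(tibble(variable = rownames(m)), as_tibble(m))
  }
  paths <- c(rho = paste0(prefix, "_rho.csv"),
             p = paste0(prefix, "_p.csv"),
             json = paste0(prefix, ".json"))
  readr::write_csv(wide(x$rho), paths["rho"])
  readr::write_csv(wide(x$p_value), paths["p"])
  jsonlite::write_json(tidy(x), paths["json"], auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(paths)
}
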