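#' One-at-a-time design matrix
#'
#' For each parameter `i` and level `j` the swept value is the uniform grid
#' point `x = A_i + (j - 1)(B_i - A_i)/(n_val - 1)`, with every other
#' parameter at baseline; `n_par * n_val` rows in total (100 for the
#' shipped ten-parameter table at ten levels).
#'
#' @param specs parameter table with columns `name`, `lower`, `upper`,
#'   `baseline` (default: the shipped table, [sensitivity_param_table()]).
#' @param n_val number of levels per parameter (>= 2; default 10).
#' @return tibble of class `design_matrix` with one column per parameter
#'   plus `.param` (the varied parameter) and `.level`; attribute
#'   `scheme = "oat"`.
#' @export
oat_design <- function(specs = sensitivity_param_table(), n_val = 10) {
  validate_param_specs(specs)
  if (n_val < 2) abort("n_val must be at least 2.")
  base <- setNames(as.list(specs$baseline), specs$name)
  rows <- purrr::pmap(specs, function(name, lower, upper, baseline, ...) {
    purrr::map(seq_len(n_val), function(j) {
      x <- base
      x[[name]] <- lower + (j - 1) * (upper - lower) / (n_val - 1)
      tibble::as_tibble(x) |>
        dplyr::mutate(.param = name, .level = j)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  structure(rows, class = c("design_matrix", class(rows)),
            scheme = "oat", seed = NA_integer_)
}

#' Latin hypercube design matrix
#'
#' Stratified uniform sampling over the parameter ranges: each column has
#' exactly one point in each of the `n_sam` equal-probability strata.
#' The default sample count is ten times the number of parameters.
#'
#' @inheritParams oat_design
#' @param n_sam number of samples (default `10 * nrow(specs)`).
#' @param seed integer seed (mandatory for reproducibility).
#' @return tibble of class `design_matrix`, one column per parameter;
#'   attributes `scheme = "lhs"` and `seed`.
#' @export
lhs_design <- function(specs = sensitivity_param_table(),
                       n_sam = 10 * nrow(specs), seed) {
  validate_param_specs(specs)
  if (missing(seed)) abort("lhs_design requires an explicit seed.")
  if (n_sam < nrow(specs)) abort("n_sam must be at least the number of parameters.")
  set.seed(seed)
  U <- lhs::randomLHS(n_sam, nrow(specs))
  X <- purrr::map2(seq_len(nrow(specs)), specs$name, function(i, nm) {
    specs$lower[i] + U[, i] * (specs$upper[i] - specs$lower[i])
  })
  out <- tibble::as_tibble(setNames(X, specs$name))
  structure(out, class = c("design_matrix", class(out)),
            scheme = "lhs", seed = as.integer(seed))
}

#' Product-moment correlation coefficient
#'
#' Direct evaluation of the sample correlation
#' `c(x, y) = sum (x_i - xbar)(y_i - ybar) / sqrt(sum (x_i - xbar)^2 sum (y_i - ybar)^2)`.
#' Authored explicitly (rather than delegating) because the downstream
#' partial and partial-rank coefficients are defined in terms of this
#' formula; the test suite checks it against a from-scratch double-loop
#' evaluation and `stats::cor`.
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return scalar in `[-1, 1]`.
#' @examples
#' correlation_coefficient(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
correlation_coefficient <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  if (length(x) < 3L) abort("need at least 3 observations.")
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) abort("undefined correlation: zero variance.")
  sum(dx * dy) / sqrt(sx * sy)
}

#' Partial correlation coefficient
#'
#' PCC between design column `j` and the response: both `x_j` and `y` are
#' regressed linearly on all remaining columns, and the correlation of the
#' two residual vectors is returned.
#'
#' @param X numeric matrix or data frame of predictors (design columns).
#' @param y numeric response vector.
#' @param j column index (or name) of the parameter of interest.
#' @return scalar partial correlation.
#' @export
partial_correlation <- function(X, y, j) {
  X <- as.matrix(X)
  if (is.character(j)) j <- match(j, colnames(X))
  if (is.na(j) || j < 1 || j > ncol(X)) abort("invalid column j.")
  n <- nrow(X)
  k <- ncol(X) - 1L
  if (n <= k + 2L) abort("too few samples for the partial regression.")
  Z <- cbind(1, X[, -j, drop = FALSE])
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    bad <- paste(colnames(X)[-j], collapse = ", ")
    abort(paste0("rank-deficient regression among columns: ", bad))
  }
  rx <- qr.resid(qz, X[, j])
  ry <- qr.resid(qz, y)
  correlation_coefficient(rx, ry)
}

# average ranks, as used by the rank transform (smallest value gets rank 1)
rank_transform <- function(v) rank(v, ties.method = "average")

#' Partial rank correlation coefficient
#'
#' Every design column and the response are replaced by their ranks
#' (average ranks on ties), then the partial correlation is computed. The
#' two-sided p-value uses the t statistic
#' `t = r sqrt((N - 2 - k)/(1 - r^2))` with `k` the number of adjusted-for
#' parameters.
#'
#' @inheritParams partial_correlation
#' @return list with `prcc` and `p_value`.
#' @export
prcc <- function(X, y, j) {
  X <- as.matrix(X)
  Xr <- apply(X, 2, rank_transform)
  colnames(Xr) <- colnames(X)
  yr <- rank_transform(y)
  r <- partial_correlation(Xr, yr, j)
  k <- ncol(X) - 1L
  df <- nrow(X) - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(prcc = r, p_value = 2 * pt(-abs(tstat), df))
}

#' PRCC sensitivity report
#'
#' Computes the full parameter-by-biomarker PRCC table with p-values and
#' significance marks (`+` / `-` at `p <= alpha`). Failed simulations
#' (rows with any non-finite biomarker) are excluded pairwise with a logged
#' mask, never imputed; if more than `max_failed_frac` of the rows failed,
#' the report refuses with diagnostics.
#'
#' @param design a [lhs_design()] (or any numeric design tibble; the
#'   `.param`/`.level` bookkeeping columns of an OAT design are dropped).
#' @param biomarkers data frame of responses, one row per design row.
#' @param alpha significance level (default 0.05).
#' @param max_failed_frac maximal tolerated fraction of failed rows.
#' @return object of class `prcc_report`: tibble with columns `parameter`,
#'   `biomarker`, `prcc`, `p_value`, `significant`, `sign`; attributes
#'   `n_used`, `n_failed`, `alpha`.
#' @export
sensitivity_report <- function(design, biomarkers, alpha = 0.05,
                               max_failed_frac = 0.2) {
  X <- dplyr::select(tibble::as_tibble(design), -dplyr::any_of(c(".param", ".level")))
  Y <- tibble::as_tibble(biomarkers)
  if (nrow(X) != nrow(Y)) abort("design and biomarker table must have equal rows.")
  ok <- complete.cases(X) & apply(as.matrix(Y), 1, function(r) all(is.finite(r)))
  n_failed <- sum(!ok)
  if (n_failed / nrow(X) > max_failed_frac) {
    abort(paste0(n_failed, " of ", nrow(X), " runs failed (more than ",
                 round(100 * max_failed_frac), "%); refusing to report."))
  }
  Xo <- as.matrix(X[ok, , drop = FALSE])
  grid <- tidyr::expand_grid(parameter = colnames(X), biomarker = names(Y))
  res <- purrr::pmap(grid, function(parameter, biomarker) {
    pr <- prcc(Xo, Y[[biomarker]][ok], parameter)
    tibble::tibble(parameter = parameter, biomarker = biomarker,
                   prcc = pr$prcc, p_value = pr$p_value)
  }) |> dplyr::bind_rows() |>
    dplyr::mutate(
      significant = .data$p_value <= alpha,
      sign = dplyr::if_else(.data$significant,
                            dplyr::if_else(.data$prcc > 0, "+", "-"), "")
    )
  structure(res, class = c("prcc_report", class(res)),
            n_used = sum(ok), n_failed = n_failed, alpha = alpha,
            failed_mask = which(!ok))
}

#' OAT monotonicity screening
#'
#' For each parameter of a one-at-a-time sweep, counts the sign changes of
#' successive response differences along the levels -- the screening use of
#' the OAT design (zero sign changes indicates a monotone, possibly
#' nonlinear, relationship).
#'
#' @param design an [oat_design()] (with `.param`, `.level`).
#' @param response numeric vector, one value per design row.
#' @return tibble with `parameter`, `sign_changes`, `monotone`.
#' @export
oat_monotonicity <- function(design, response) {
  if (!".param" %in% names(design)) abort("design must be an OAT design.")
  tibble::tibble(.param = design$.param, .level = design$.level, y = response) |>
    dplyr::group_by(.data$.param) |>
    dplyr::arrange(.data$.level, .by_group = TRUE) |>
    dplyr::summarise(
      sign_changes = {
        d <- diff(.data$y)
        d <- d[d != 0]
        if (length(d) < 2L) 0L else sum(diff(sign(d)) != 0)
      },
      .groups = "drop"
    ) |>
    dplyr::rename(parameter = ".param") |>
    dplyr::mutate(monotone = .data$sign_changes == 0L)
}
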