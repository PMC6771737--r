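#' Cubic regression spline basis over lag windows
#'
#' Builds the value-parameterized cubic regression ("cr") spline basis used
#' by the functional linear model terms: the coefficient function
#' `f_c(w) = sum_j B[w, j] gamma_j` is the natural cubic spline that
#' interpolates the points `(knot_j, gamma_j)`. Coefficients are therefore
#' directly interpretable as the value of the lag-coefficient function at
#' the knots, and rows of `B` at knot positions form the identity.
#'
#' The basis is computed column-by-column as the cardinal natural splines:
#' column j interpolates the j-th unit vector. Second derivatives at the
#' two boundary knots are zero (natural end conditions), obtained from the
#' standard tridiagonal system.
#'
#' @param n_windows Number of lag windows W (42 for fortnightly local
#'   weather, 19 for a monthly index).
#' @param n_knots Number of knots (default 8; at least 4).
#' @param knots Optional strictly increasing knot positions spanning
#'   `[1, n_windows]`; default evenly spaced.
#' @return An object of class `"flm_term"`: a list with `n_windows`,
#'   `knots`, `basis` (W x n_knots matrix), `gamma` (unset, `NULL`) and
#'   `variable_name`.
#' @examples
#' term <- build_cr_basis(42, 8)
#' dim(term$basis)  # 42 x 8
#' @export
build_cr_basis <- function(n_windows, n_knots = 8, knots = NULL) {
  if (n_knots < 4) stop("basis degeneracy: at least 4 knots are required")
  if (n_knots > n_windows) stop("n_knots must not exceed n_windows")
  if (is.null(knots)) knots <- seq(1, n_windows, length.out = n_knots)
  if (length(knots) != n_knots || is.unsorted(knots, strictly = TRUE))
    stop("knots must be strictly increasing and of length n_knots")
  if (abs(knots[1] - 1) > 1e-10 || abs(knots[n_knots] - n_windows) > 1e-10)
    stop("knots must span [1, n_windows]")
  w <- seq_len(n_windows)
  B <- vapply(seq_len(n_knots), function(j) {
    y <- numeric(n_knots)
    y[j] <- 1
    natural_spline_eval(knots, y, w)
  }, numeric(n_windows))
  dimnames(B) <- list(paste0("w", w), paste0("k", seq_len(n_knots)))
  structure(list(n_windows = n_windows, knots = knots, basis = B,
                 gamma = NULL, variable_name = NA_character_),
            class = "flm_term")
}

# Natural cubic spline interpolation: solve the tridiagonal system for the
# second derivatives at the knots (zero at both ends) and evaluate the
# piecewise cubic at `xout`. Evaluation outside [min(x), max(x)] is not
# needed by the basis and is disallowed.
natural_spline_eval <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  M <- numeric(n)  # second derivatives; M[1] = M[n] = 0
  if (n > 2) {
    A <- matrix(0, n - 2, n - 2)
    rhs <- numeric(n - 2)
    for (i in 2:(n - 1)) {
      k <- i - 1
      A[k, k] <- (h[i - 1] + h[i]) / 3
      if (k > 1) A[k, k - 1] <- h[i - 1] / 6
      if (k < n - 2) A[k, k + 1] <- h[i] / 6
      rhs[k] <- (y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]
    }
    M[2:(n - 1)] <- solve(A, rhs)
  }
  if (any(xout < x[1] - 1e-9 | xout > x[n] + 1e-9))
    stop("evaluation outside the knot span")
  idx <- findInterval(xout, x, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  idx[idx > n - 1] <- n - 1
  x0 <- x[idx]; x1 <- x[idx + 1]
  hi <- x1 - x0
  a <- (x1 - xout) / hi
  b <- (xout - x0) / hi
  a * y[idx] + b * y[idx + 1] +
    ((a^3 - a) * M[idx] + (b^3 - b) * M[idx + 1]) * hi^2 / 6
}

#' Evaluate the lag-coefficient function of an FLM term
#'
#' Returns `f_c(w) = B gamma` for every lag window, linear in the
#' coefficient vector.
#'
#' @param term An `"flm_term"` from [build_cr_basis()].
#' @param gamma Coefficient vector (defaults to `term$gamma`).
#' @return Numeric vector of length `term$n_windows`.
#' @export
eval_flm <- function(term, gamma = term$gamma) {
  if (is.null(gamma)) stop("gamma is unset")
  if (length(gamma) != ncol(term$basis))
    stop("gamma length (", length(gamma), ") does not match basis columns (",
         ncol(term$basis), ")")
  as.numeric(term$basis %*% gamma)
}

#' Evaluate the lag-coefficient function at arbitrary positions
#'
#' Evaluates the natural cubic spline defined by `(knots, gamma)` at any
#' positions inside the knot span (not just the integer windows), e.g. to
#' verify the interpolation property `f_c(knot_j) = gamma_j` or to plot a
#' dense curve.
#'
#' @param term An `"flm_term"`.
#' @param positions Numeric positions in `[1, n_windows]`.
#' @param gamma Coefficient vector (defaults to `term$gamma`).
#' @return Numeric vector of spline values.
#' @export
eval_flm_at <- function(term, positions, gamma = term$gamma) {
  if (is.null(gamma)) stop("gamma is unset")
  if (length(gamma) != length(term$knots))
    stop("gamma length does not match the number of knots")
  natural_spline_eval(term$knots, gamma, positions)
}

#' Climate contribution of an FLM term to the environmental axis
#'
#' Computes `sum_w f_c(w) C_tw` for every year, i.e. the per-year inner
#' product of the lag-coefficient function with the centered climate
#' anomaly matrix.
#'
#' @param term An `"flm_term"`.
#' @param C Year x window climate matrix (a `"climate_matrix"` or plain
#'   matrix with `n_windows` columns).
#' @param gamma Coefficient vector (defaults to `term$gamma`).
#' @return Numeric vector with one value per year (row of `C`).
#' @export
flm_contribution <- function(term, C, gamma = term$gamma) {
  Cm <- if (inherits(C, "climate_matrix")) C$values else C
  if (ncol(Cm) != term$n_windows)
    stop("climate matrix has ", ncol(Cm), " windows; term expects ",
         term$n_windows)
  as.numeric(Cm %*% eval_flm(term, gamma))
}
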