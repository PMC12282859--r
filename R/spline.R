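#' Restricted cubic spline basis on the log-time axis
#'
#' Specification and evaluation of the restricted cubic spline basis used
#' by the flexible parametric cure model. With knots k_1 < ... < k_m the
#' unrestricted-tail basis has m - 1 functions: the linear term u and, for
#' each interior knot j = 2..m-1, the truncated-power term
#'   v_j(u) = (u - k_j)_+^3 - l_j (u - k_1)_+^3 - (1 - l_j)(u - k_m)_+^3,
#'   l_j = (k_m - k_j) / (k_m - k_1),
#' which is zero below k_1 and linear above k_m (Durrleman-Simon
#' restriction). With the cure constraint the basis is reparametrized so
#' that every function has exactly zero slope at and beyond the last knot:
#' each v_j gains a compensating linear term b_j * u with slope b_j equal
#' to minus v_j's tail slope, making g_j(u) = v_j(u) + b_j * u constant for
#' u >= k_m (and linear below k_1). Any linear combination of the
#' constrained basis is therefore exactly flat beyond the last knot, which
#' is what turns the fitted survival tail into a genuine cure plateau.
#'
#' @param knots strictly increasing knot positions on the log-time axis
#'   (boundary knots included); at least 2, and at least 3 when
#'   `cure_constraint` is set (the constrained basis has m - 2 functions,
#'   the unconstrained one m - 1).
#' @param cure_constraint force zero slope at and beyond the last knot.
#' @return An object of class `spline_basis_spec`.
#' @export
spline_basis_spec <- function(knots, cure_constraint = FALSE) {
  knots <- as.numeric(knots)
  if (length(knots) < 2L) stop("at least 2 knots required")
  if (is.unsorted(knots, strictly = TRUE)) {
    stop("knots must be strictly increasing")
  }
  if (cure_constraint && length(knots) < 3L) {
    stop("the cure-constrained basis needs at least 3 knots")
  }
  structure(list(knots = knots, cure_constraint = cure_constraint,
                 n_basis = length(knots) - if (cure_constraint) 2L else 1L),
            class = "spline_basis_spec")
}

# Truncated-power nonlinear terms and derivatives, one column per interior
# knot. Shared by both basis variants.
.rcs_nonlinear <- function(u, knots) {
  m <- length(knots)
  k1 <- knots[1L]; km <- knots[m]
  cub <- function(x) pmax(x, 0)^3
  sq <- function(x) pmax(x, 0)^2
  inner <- knots[-c(1L, m)]
  val <- matrix(0, length(u), length(inner))
  der <- matrix(0, length(u), length(inner))
  for (j in seq_along(inner)) {
    kj <- inner[j]
    lj <- (km - kj) / (km - k1)
    val[, j] <- cub(u - kj) - lj * cub(u - k1) - (1 - lj) * cub(u - km)
    der[, j] <- 3 * (sq(u - kj) - lj * sq(u - k1) - (1 - lj) * sq(u - km))
  }
  list(value = val, deriv = der, inner = inner, k1 = k1, km = km)
}

#' Evaluate the unrestricted-tail restricted cubic spline basis
#'
#' @param u log-time values (vectorized).
#' @param spec a [spline_basis_spec()] (the `cure_constraint` flag is
#'   ignored here; see [cure_basis()] for the constrained variant).
#' @return List with `basis` and `deriv`, matrices with one column per free
#'   basis function (linear term first).
#' @export
rcs_basis <- function(u, spec) {
  stopifnot(inherits(spec, "spline_basis_spec"))
  nl <- .rcs_nonlinear(u, spec$knots)
  basis <- cbind(linear = u, nl$value)
  deriv <- cbind(linear = rep(1, length(u)), nl$deriv)
  if (ncol(basis) > 1L) {
    colnames(basis) <- colnames(deriv) <-
      c("linear", paste0("nl", seq_along(nl$inner)))
  }
  list(basis = basis, deriv = deriv)
}

#' Evaluate the cure-constrained spline basis
#'
#' Basis functions are constant (zero derivative) at and beyond the last
#' knot and linear below the first knot; see [spline_basis_spec()] for the
#' construction. Requires `cure_constraint = TRUE` in the spec.
#'
#' @inheritParams rcs_basis
#' @return List with `basis` and `deriv` (m - 2 columns each).
#' @export
cure_basis <- function(u, spec) {
  stopifnot(inherits(spec, "spline_basis_spec"))
  if (!isTRUE(spec$cure_constraint)) {
    stop("spec does not carry the cure constraint; use rcs_basis()")
  }
  knots <- spec$knots
  nl <- .rcs_nonlinear(u, knots)
  k1 <- nl$k1; km <- nl$km
  # tail slope of v_j is 3 * sum(c_i k_i^2); cancel it with a linear term
  b <- vapply(nl$inner, function(kj) {
    lj <- (km - kj) / (km - k1)
    -3 * (kj^2 - lj * k1^2 - (1 - lj) * km^2)
  }, numeric(1))
  basis <- nl$value + outer(u, b)
  deriv <- sweep(nl$deriv, 2, b, "+")
  # enforce the plateau exactly: beyond the last knot the analytic value is
  # constant and the derivative zero, but floating-point cancellation in
  # the truncated powers leaves ~1e-14 residue; clamp to the exact values
  at_tail <- u >= km
  if (any(at_tail)) {
    plateau <- .rcs_nonlinear(km, knots)$value[1L, ] + km * b
    basis[at_tail, ] <- rep(plateau, each = sum(at_tail))
    deriv[at_tail, ] <- 0
  }
  colnames(basis) <- colnames(deriv) <- paste0("cure", seq_along(nl$inner))
  list(basis = basis, deriv = deriv)
}

# Dispatch on the constraint flag; used by the flexible likelihood.
.spline_eval <- function(u, spec) {
  if (isTRUE(spec$cure_constraint)) cure_basis(u, spec) else
    rcs_basis(u, spec)
}

# Default knot placement: boundary knots at the extreme uncensored log
# event times, interior knots at upper event-time centiles (75th-95th).
# Late interior knots matter for cure splines: the log cumulative hazard
# of plateau data is near-linear in log time early on but bends sharply
# into the plateau, so the curvature budget belongs near the tail. The
# upper boundary is nudged just above the largest event: with the cure
# constraint the spline derivative is exactly zero at the last knot, so an
# event sitting exactly on it would have zero density and degenerate the
# likelihood.
.default_knots <- function(cohort, n_interior = 2L) {
  lt <- log(cohort$time_years[cohort$event == 1])
  if (length(unique(lt)) < n_interior + 2L) {
    stop("too few distinct event times for ", n_interior, " interior knots")
  }
  probs <- if (n_interior == 1L) 0.9 else
    seq(0.75, 0.95, length.out = n_interior)
  knots <- c(min(lt), stats::quantile(lt, probs, names = FALSE),
             max(lt) + 1e-3)
  if (is.unsorted(knots, strictly = TRUE)) knots <- unique(knots)
  knots
}
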