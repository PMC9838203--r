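#' Thin-plate regression spline basis with null-space decomposition
#'
#' Constructs a low-rank thin-plate regression spline (TPRS) basis by
#' eigen-truncation of the radial kernel matrix evaluated at the distinct
#' input points, together with the quadratic roughness penalty split into a
#' penalised ("wiggly") block and an unpenalised polynomial null-space block.
#' The radial kernel is \eqn{r^2 \log r} in two dimensions and \eqn{|r|^3} in
#' one dimension, with an order-2 polynomial null space (constant plus linear
#' terms).
#'
#' The returned basis underlies all smooth terms of the blending model: the
#' spatial intercept surface f(s), the spatial slope surface g(s) and the
#' station-specific non-linear covariate deviations h_j(x). For f the basis
#' is centered (sum-to-zero over the construction points, absorbed by
#' dropping the constant column and column-centering) so the overall
#' intercept stays identifiable; for h_j the polynomial null space is
#' excluded entirely so the smooth is purely non-linear.
#'
#' @param points numeric vector (1-D) or two-column matrix (2-D, lon/lat in
#'   decimal degrees) of construction points. Duplicates are removed before
#'   kernel construction.
#' @param n_basis number of columns of the returned model matrix (after
#'   constraint absorption / null-space removal).
#' @param center logical; absorb a sum-to-zero constraint over `points`.
#' @param include_null_space logical; keep the polynomial (constant + linear)
#'   columns. When `FALSE` the basis spans only the penalised non-linear
#'   space.
#' @return an object of class `tprs_basis` with elements `model_matrix`
#'   (`length(points)` x `n_basis`), `penalty_wiggly`, `penalty_null`,
#'   `null_space_dim`, `constraint_transform`, `eval_points` and the
#'   internals needed for evaluation at new points.
#' @seealso [evaluate_basis()]
#' @export
build_tprs <- function(points, n_basis, center = TRUE, include_null_space = TRUE) {
  pts <- as_point_matrix(points)
  d <- ncol(pts)
  if (!d %in% c(1L, 2L)) stop("points must be 1-D or 2-D")
  knots <- unique(pts)
  n_knots <- nrow(knots)
  if (n_knots < 2L) stop("degenerate geometry: need at least two distinct points")
  M <- d + 1L  # order-2 polynomial null space: {1, x} or {1, x, y}

  # internal truncation rank k so that ncol(model_matrix) == n_basis
  if (include_null_space) {
    k <- n_basis + as.integer(center)
  } else {
    k <- n_basis + M
  }
  if (k > n_knots) {
    stop(sprintf("capacity error: requested basis needs rank %d but only %d distinct points",
                 k, n_knots))
  }
  if (k < M || (!include_null_space && k == M))
    stop("n_basis too small for the polynomial null space")

  E <- tps_kernel(knots, knots, d)
  Tm <- poly_block(knots, d)
  eig <- eigen(E, symmetric = TRUE)
  ord <- order(abs(eig$values), decreasing = TRUE)[seq_len(k)]
  Uk <- eig$vectors[, ord, drop = FALSE]
  Dk <- eig$values[ord]

  # absorb the constraint T' U_k delta = 0 so the truncated smooth stays in
  # the space where the thin-plate energy is non-negative
  Z <- null_space(crossprod(Tm, Uk))            # k x (k - M)
  W_knots <- (Uk %*% (Dk * Z))                  # wiggly columns at knots
  Sw <- crossprod(Z, Dk * Z)
  Sw <- (Sw + t(Sw)) / 2

  # rescale wiggly columns to unit RMS at the knots; keeps the penalty and
  # the half-Cauchy prior on lambda on a comparable scale across bases
  scl <- sqrt(colMeans(W_knots^2))
  scl[scl < 1e-300] <- 1
  W_knots <- sweep(W_knots, 2, scl, "/")
  Sw <- Sw / tcrossprod(scl)

  n_wiggly <- ncol(W_knots)
  if (include_null_space) {
    X_knots <- cbind(Tm, W_knots)
    p <- M + n_wiggly
    S_wig <- matrix(0, p, p)
    if (n_wiggly > 0) S_wig[(M + 1):p, (M + 1):p] <- Sw
    S_null <- diag(c(rep(1, M), rep(0, n_wiggly)))
    keep <- seq_len(p)
    if (center) keep <- keep[-1L]           # drop the constant column
  } else {
    X_knots <- W_knots
    S_wig <- Sw
    S_null <- matrix(0, n_wiggly, n_wiggly)
    keep <- seq_len(n_wiggly)
  }

  idx <- match(point_key(pts), point_key(knots))
  X_full <- X_knots[idx, , drop = FALSE]
  X <- X_full[, keep, drop = FALSE]
  S_wig <- S_wig[keep, keep, drop = FALSE]
  S_null <- S_null[keep, keep, drop = FALSE]

  col_means <- rep(0, ncol(X))
  if (center) {
    col_means <- colMeans(X)
    X <- sweep(X, 2, col_means)
  }
  if (ncol(X) != n_basis)
    stop("internal error: basis column count mismatch")

  # selection/scaling map from the unconstrained (poly + raw wiggly) basis
  C <- diag(1, if (include_null_space) M + n_wiggly else n_wiggly)
  C <- C[, keep, drop = FALSE]

  structure(list(
    eval_points = pts,
    n_basis = ncol(X),
    model_matrix = X,
    penalty_wiggly = S_wig,
    penalty_null = S_null,
    constraint_transform = C,
    null_space_dim = if (include_null_space) M - as.integer(center) else 0L,
    d = d, M = M, knots = knots, Uk = Uk, Z = Z, scale = scl,
    keep = keep, col_means = col_means,
    center = center, include_null_space = include_null_space
  ), class = "tprs_basis")
}

#' Evaluate a TPRS basis at new points
#'
#' Returns the model matrix of the basis at arbitrary new points; its product
#' with a coefficient vector gives the smooth's value there. Evaluation at
#' the construction points reproduces `model_matrix` exactly (up to floating
#' point), and linear functions are reproduced exactly wherever the null
#' space is included.
#'
#' @param basis a [build_tprs()] object.
#' @param new_points numeric vector or matrix with the same dimension as the
#'   construction points.
#' @return a `nrow(new_points)` x `n_basis` matrix.
#' @export
evaluate_basis <- function(basis, new_points) {
  stopifnot(inherits(basis, "tprs_basis"))
  pts <- as_point_matrix(new_points)
  if (ncol(pts) != basis$d)
    stop(sprintf("shape error: basis is %d-D but new points are %d-D",
                 basis$d, ncol(pts)))
  E_new <- tps_kernel(pts, basis$knots, basis$d)
  W_new <- (E_new %*% basis$Uk) %*% basis$Z
  W_new <- sweep(W_new, 2, basis$scale, "/")
  X <- if (basis$include_null_space) cbind(poly_block(pts, basis$d), W_new) else W_new
  X <- X[, basis$keep, drop = FALSE]
  X <- sweep(X, 2, basis$col_means)
  if (!is.null(basis$ortho_B)) X <- X - poly_block(pts, basis$d) %*% basis$ortho_B
  X
}

#' @export
predict.tprs_basis <- function(object, newdata, ...) evaluate_basis(object, newdata)

#' Orthogonalise a basis against polynomial trends
#'
#' Residualises every basis column against the polynomial null-space
#' functions (constant and linear terms) evaluated at a reference point set,
#' typically the training covariate values. After this, any function built
#' from the basis has exactly zero least-squares linear trend over the
#' reference points — the construction used for the station-specific
#' non-linear deviations h_j, which must not compete with the spatially
#' varying linear slope term. The projection is baked into the basis and
#' applied consistently by [evaluate_basis()] at new points; the penalty is
#' unchanged (polynomial components carry no roughness energy).
#'
#' @param basis a [build_tprs()] object.
#' @param points reference points (default: the basis's evaluation points).
#' @return the modified `tprs_basis`.
#' @export
orthogonalize_basis <- function(basis, points = basis$eval_points) {
  stopifnot(inherits(basis, "tprs_basis"))
  pts <- as_point_matrix(points)
  basis$ortho_B <- NULL
  X <- evaluate_basis(basis, pts)
  P <- poly_block(pts, basis$d)
  basis$ortho_B <- qr.solve(crossprod(P), crossprod(P, X))
  basis$model_matrix <- evaluate_basis(basis, basis$eval_points)
  basis
}

#' @export
print.tprs_basis <- function(x, ...) {
  cat(sprintf("Thin-plate regression spline basis (%d-D, order 2)\n", x$d))
  cat(sprintf("  %d basis functions over %d distinct points; null-space dim %d%s%s\n",
              x$n_basis, nrow(x$knots), x$null_space_dim,
              if (x$center) "; centered" else "",
              if (!x$include_null_space) "; null space excluded" else ""))
  invisible(x)
}

# --- internals ---------------------------------------------------------------

as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(as.numeric(points), ncol = 1L)
  storage.mode(points) <- "double"
  points
}

point_key <- function(m) apply(m, 1L, function(r) paste(format(r, digits = 15), collapse = "|"))

# radial kernel: eta(r) = r^2 log r (2-D), |r|^3 (1-D); eta(0) = 0
tps_kernel <- function(a, b, d) {
  r2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  r2[r2 < 0] <- 0
  if (d == 2L) {
    K <- 0.5 * r2 * log(pmax(r2, 1e-300))
    K[r2 == 0] <- 0
  } else {
    K <- r2^1.5
  }
  K
}

poly_block <- function(pts, d) cbind(1, pts)

null_space <- function(A) {
  # orthonormal basis of the null space of A (rows >= 0), via complete QR of t(A)
  k <- ncol(A); m <- nrow(A)
  qr_t <- qr(t(A))
  r <- qr_t$rank
  Q <- qr.Q(qr_t, complete = TRUE)
  if (r >= k) return(matrix(0, k, 0))  # pure-polynomial basis: no wiggly part
  Q[, (r + 1):k, drop = FALSE]
}
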