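#' Molecular descriptor specification
#'
#' The NN input representation. `"inverse_distance"` maps a Cartesian
#' geometry to the vector of pairwise inverse distances 1/r_ab in fixed
#' lexicographic pair order (a < b), which is exactly invariant under
#' translation and rotation; its Jacobian with respect to the Cartesian
#' coordinates is analytic, which is what makes forces available as exact
#' derivatives of the network. `"coordinate"` is the identity map, used for
#' the one-dimensional models.
#'
#' @param type `"inverse_distance"` or `"coordinate"`.
#' @param n_dof Number of nuclear degrees of freedom (3N for Cartesian).
#' @param r_min Minimum allowed interatomic distance in Bohr
#'   (inverse-distance only); closer atoms raise an error.
#' @return Object of class `"descriptor_spec"` with field `n_in`, the
#'   descriptor length.
#' @export
descriptor_spec <- function(type = c("inverse_distance", "coordinate"),
                            n_dof, r_min = 1e-3) {
  type <- match.arg(type)
  if (type == "inverse_distance") {
    if (n_dof %% 3 != 0) stop("inverse-distance descriptor needs 3N dof")
    n_atoms <- n_dof / 3
    if (n_atoms < 2) stop("need at least two atoms")
    n_in <- n_atoms * (n_atoms - 1) / 2
  } else {
    n_in <- n_dof
  }
  structure(list(type = type, n_dof = as.integer(n_dof), n_in = as.integer(n_in),
                 r_min = r_min), class = "descriptor_spec")
}

#' Evaluate a descriptor and its Jacobian
#'
#' @param spec A [descriptor_spec()].
#' @param x Flat coordinate vector (Bohr) or a `geometry`.
#' @return List with `values` (length `n_in`) and `jacobian`
#'   (`n_in` x `n_dof` matrix of \eqn{\partial D_k / \partial x_m}).
#' @export
#' @examples
#' sp <- descriptor_spec("inverse_distance", 9)
#' g <- triatomic_geometry(2.6, 2.6, 2.8)
#' compute_descriptor(sp, flatten_coords(g))$values
compute_descriptor <- function(spec, x) {
  if (inherits(x, "geometry")) x <- flatten_coords(x)
  if (length(x) != spec$n_dof) stop("coordinate length does not match descriptor")
  if (spec$type == "coordinate") {
    return(list(values = as.numeric(x), jacobian = diag(1, spec$n_dof)))
  }
  n_atoms <- spec$n_dof / 3
  xm <- matrix(x, n_atoms, 3, byrow = TRUE)
  pr <- state_pairs(n_atoms)
  vals <- numeric(nrow(pr))
  J <- matrix(0, nrow(pr), spec$n_dof)
  for (p in seq_len(nrow(pr))) {
    a <- pr[p, 1]; b <- pr[p, 2]
    d <- xm[a, ] - xm[b, ]
    r <- sqrt(sum(d^2))
    if (r < spec$r_min)
      stop(sprintf("atoms %d and %d nearly coincident (r = %.2e Bohr)", a, b, r))
    vals[p] <- 1 / r
    g <- -d / r^3  # d(1/r)/d(x_a)
    J[p, (3 * a - 2):(3 * a)] <- g
    J[p, (3 * b - 2):(3 * b)] <- -g
  }
  list(values = vals, jacobian = J)
}
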