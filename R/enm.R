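#' Build a sharp-cutoff elastic network
#'
#' Connects every pair of beads whose reference distance is strictly below
#' the interaction cutoff by a harmonic spring of constant `k`.  An optional
#' `spring_fun` hook replaces the flat constant with a user-supplied function
#' of the reference distance (distance-dependent spring constants).
#'
#' @param structure A `"bead_structure"`.
#' @param cutoff Interaction cutoff R_c in Angstrom (springs for d < cutoff).
#' @param k Master spring constant (dimensionless; all downstream comparisons
#'   are scale-free).
#' @param spring_fun Optional function `k(d)` mapping reference distance to a
#'   spring constant; overrides `k`.
#' @return An object of class `"elastic_network"`: the structure, a spring
#'   table (`i`, `j`, `k`, `d` with `i < j`) and the cutoff.
#' @export
build_network <- function(structure, cutoff, k = 1, spring_fun = NULL) {
  if (nrow(structure) < 2) enm_stop("need at least 2 beads", "input")
  stopifnot(cutoff > 0, k > 0)
  X <- bead_coords(structure)
  D <- as.matrix(stats::dist(X))
  pairs <- which(upper.tri(D) & D < cutoff, arr.ind = TRUE)
  d <- D[pairs]
  kij <- if (is.null(spring_fun)) rep(k, length(d)) else vapply_num(d, spring_fun)
  springs <- data.frame(i = pairs[, 1], j = pairs[, 2], k = kij, d = d)
  springs <- springs[order(springs$i, springs$j), , drop = FALSE]
  rownames(springs) <- NULL
  structure(list(structure = structure, springs = springs, cutoff = cutoff),
            class = "elastic_network")
}

#' Fully connected random-spring null network
#'
#' The significance floor for ENM-ensemble agreement: all N(N-1)/2 bead pairs
#' interact harmonically, with each spring constant drawn independently from
#' the uniform distribution on \[0, 1\].  Such a network carries no structural
#' information beyond the reference geometry.
#'
#' @param structure A `"bead_structure"`.
#' @param seed Integer seed for the spring-constant draws.
#' @return An `"elastic_network"` with `cutoff = "none"`.
#' @export
build_random_network <- function(structure, seed) {
  if (nrow(structure) < 2) enm_stop("need at least 2 beads", "input")
  X <- bead_coords(structure)
  D <- as.matrix(stats::dist(X))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  o <- order(pairs[, 1], pairs[, 2])
  pairs <- pairs[o, , drop = FALSE]
  kij <- with_seed(seed, stats::runif(nrow(pairs)))
  springs <- data.frame(i = pairs[, 1], j = pairs[, 2], k = kij, d = D[pairs])
  rownames(springs) <- NULL
  structure(list(structure = structure, springs = springs, cutoff = "none"),
            class = "elastic_network")
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("Elastic network: %d beads, %d springs, cutoff %s\n",
              nrow(x$structure), nrow(x$springs),
              if (identical(x$cutoff, "none")) "none (random null model)"
              else paste0(x$cutoff, " A")))
  invisible(x)
}

#' Average number of interacting neighbours per bead
#'
#' The mean spring degree: for a sharp-cutoff network, the average number of
#' other beads within R_c of a bead.
#'
#' @param network An `"elastic_network"`.
#' @return A single number.
#' @export
neighbor_count <- function(network) {
  2 * nrow(network$springs) / nrow(network$structure)
}

#' Hessian of the elastic-network energy
#'
#' Second-order expansion of the pairwise harmonic energy
#' U = 1/2 sum k_ij (|r_i - r_j| - d_ij)^2 about the reference structure.
#' For a springed pair the off-diagonal 3x3 block is -k_ij (u u^T) with u the
#' unit reference separation; diagonal blocks are minus the sum of the bead's
#' off-diagonal blocks, which makes the matrix translation-invariant by
#' construction.
#'
#' @param network An `"elastic_network"`.
#' @return A 3N x 3N symmetric positive semi-definite matrix with bead labels
#'   attached as attribute `"labels"`.
#' @export
enm_hessian <- function(network) {
  X <- bead_coords(network$structure)
  N <- nrow(X)
  H <- matrix(0, 3 * N, 3 * N)
  sp <- network$springs
  if (any(sp$d <= 0))
    enm_stop("coincident beads share a spring (zero reference distance)",
             "degenerate_geometry")
  for (s in seq_len(nrow(sp))) {
    i <- sp$i[s]; j <- sp$j[s]
    u <- (X[i, ] - X[j, ]) / sp$d[s]
    blk <- sp$k[s] * tcrossprod(u)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  attr(H, "labels") <- bead_labels(network$structure)
  H
}

#' Zero (rigid-body) modes of a Hessian
#'
#' Eigenvalues below `rel_tol` times the largest eigenvalue count as zero
#' modes.  A connected, non-collinear network has exactly 6 (three
#' translations, three rotations); each additional disconnected rigid
#' component adds 6 more, and collinear geometries add spurious ones.
#'
#' @param H A Hessian matrix from [enm_hessian()].
#' @param rel_tol Relative eigenvalue tolerance (default 1e-10).
#' @return A list with `count`, the zero-mode eigenvectors (`modes`,
#'   orthonormal columns) and the full eigenvalue vector (`values`,
#'   increasing).
#' @export
zero_modes <- function(H, rel_tol = 1e-10) {
  e <- eigen(H, symmetric = TRUE)
  vals <- rev(e$values)                       # increasing
  vecs <- e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE]
  thr <- rel_tol * max(e$values)
  n0 <- sum(vals < thr)
  list(count = n0, modes = vecs[, seq_len(n0), drop = FALSE], values = vals)
}

#' Smallest physically viable interaction cutoff
#'
#' Scans a cutoff grid (default 3 to 30 Angstrom in 1 Angstrom steps) and
#' returns the smallest value whose network Hessian has exactly the six
#' roto-translational zero modes -- the left end of the physically meaningful
#' cutoff range.
#'
#' @param structure A `"bead_structure"`.
#' @param scan_min,scan_max,step Grid specification (Angstrom).
#' @param k Master spring constant (irrelevant to mode counts).
#' @return The smallest viable grid cutoff.
#' @export
min_viable_cutoff <- function(structure, scan_min = 3, scan_max = 30, step = 1,
                              k = 1) {
  stopifnot(scan_min < scan_max, step > 0)
  grid <- seq(scan_min, scan_max, by = step)
  counts <- integer(0)
  for (rc in grid) {
    net <- build_network(structure, cutoff = rc, k = k)
    if (nrow(net$springs) == 0) { counts <- c(counts, 3L * nrow(structure)); next }
    n0 <- zero_modes(enm_hessian(net))$count
    counts <- c(counts, n0)
    if (n0 == 6L) return(rc)
  }
  enm_stop(sprintf(
    "no cutoff in [%g, %g] yields exactly 6 zero modes (range seen: %d-%d)",
    scan_min, scan_max, min(counts), max(counts)), "not_found")
}

#' Gaussian fluctuation model from a covariance matrix
#'
#' Wraps a 3N x 3N covariance with its (clipped, descending) eigendecomposition
#' -- the essential dynamical space used by [rwsip()] and [msf()].
#'
#' @param covariance Symmetric positive semi-definite 3N x 3N matrix (A^2).
#' @param scale Multiplicative scale already applied (recorded only).
#' @param n_zero_modes_removed Number of spectrum modes removed upstream.
#' @param labels Optional per-bead labels (N rows).
#' @return An object of class `"gaussian_model"` with elements `covariance`,
#'   `values` (nonincreasing, >= 0), `vectors` (orthonormal columns),
#'   `n_zero_modes_removed`, `scale`, `labels`.
#' @export
gaussian_model <- function(covariance, scale = 1, n_zero_modes_removed = 0L,
                           labels = NULL) {
  covariance <- (covariance + t(covariance)) / 2
  e <- eigen(covariance, symmetric = TRUE)
  vmax <- max(e$values, 0)
  if (any(e$values < -1e-8 * max(vmax, 1)))
    enm_stop("covariance is not positive semi-definite", "input")
  vals <- pmax(e$values, 0)
  structure(list(covariance = covariance, values = vals, vectors = e$vectors,
                 n_zero_modes_removed = as.integer(n_zero_modes_removed),
                 scale = scale, labels = labels),
            class = "gaussian_model")
}

#' @export
print.gaussian_model <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("Gaussian model: %d dof (%d beads), rank %d, trace %.4g A^2\n",
              n, n %/% 3, sum(x$values > 1e-12 * max(x$values, 1e-300)),
              sum(x$values)))
  invisible(x)
}

#' Equilibrium covariance from the Hessian pseudoinverse
#'
#' The 3N x 3N covariance of thermal fluctuations is `scale` times the
#' Moore-Penrose pseudoinverse of the Hessian, obtained by inverting the
#' spectrum on the complement of the six rigid-body modes.  With the master
#' spring constant and k_B T both set to 1 the covariance is dimensionless up
#' to a global factor, which cancels in every comparison made here (MSF
#' correlations, RWSIP).
#'
#' @param H A Hessian from [enm_hessian()].
#' @param scale Multiplier (the k_B T / k factor; default 1).
#' @param rel_tol Zero-mode tolerance passed to [zero_modes()].
#' @return A `"gaussian_model"` with `n_zero_modes_removed = 6`.
#' @export
covariance_from_hessian <- function(H, scale = 1, rel_tol = 1e-10) {
  e <- eigen(H, symmetric = TRUE)           # values decreasing
  n <- length(e$values)
  if (max(e$values) <= 0)
    enm_stop("Hessian is identically zero (network has no springs); use a larger cutoff",
             "connectivity")
  n0 <- sum(e$values < rel_tol * max(e$values))
  # a connected, non-collinear network has exactly the 6 roto-translational
  # zero modes (a two-bead system only 5: rotation about its axis is trivial);
  # more signal disconnection or degenerate geometry
  if (n0 > 6L)
    enm_stop(sprintf(
      "Hessian has %d zero modes, not 6: the network is disconnected or geometrically degenerate; try a larger cutoff",
      n0), "connectivity")
  keep <- seq_len(n - n0)                   # nonzero modes
  inv_vals <- scale / e$values[keep]
  V <- e$vectors[, keep, drop = FALSE]
  C <- V %*% (inv_vals * t(V))
  C <- (C + t(C)) / 2
  # assemble in covariance-descending order: largest 1/lambda first,
  # then the zero-variance rigid modes
  ord <- order(inv_vals, decreasing = TRUE)
  vals <- c(inv_vals[ord], rep(0, n0))
  vecs <- cbind(V[, ord, drop = FALSE],
                e$vectors[, seq(n - n0 + 1, length.out = n0), drop = FALSE])
  structure(list(covariance = C, values = vals, vectors = vecs,
                 n_zero_modes_removed = n0, scale = scale,
                 labels = attr(H, "labels")),
            class = "gaussian_model")
}

#' Mean square fluctuation profile
#'
#' MSF of bead i is the trace of the i-th 3x3 diagonal covariance block: the
#' time-averaged squared displacement of the bead after global superposition.
#'
#' @param x A `"gaussian_model"` or `"enm"` fit.
#' @param ... Unused.
#' @return A `"fluct_profile"` data frame with bead labels and `value` (A^2).
#' @export
msf <- function(x, ...) UseMethod("msf")

#' @rdname msf
#' @export
msf.gaussian_model <- function(x, ...) {
  v <- rowSums(matrix(diag(x$covariance), ncol = 3, byrow = TRUE))
  fluct_profile(v, x$labels)
}

#' @rdname msf
#' @export
msf.enm <- function(x, ...) msf(x$model)

fluct_profile <- function(values, labels = NULL) {
  if (any(values < -1e-12 * max(abs(values), 1e-300)))
    enm_stop("negative fluctuation values", "input")
  values <- pmax(values, 0)
  df <- if (is.null(labels)) {
    data.frame(chain = "A", resid = as.character(seq_along(values)),
               role = "X", stringsAsFactors = FALSE)
  } else as.data.frame(labels)
  df$value <- values
  class(df) <- c("fluct_profile", "data.frame")
  df
}

#' Effective interaction matrix of a bead subset
#'
#' Integrates out the discarded beads by the (generalized) Schur complement
#' `M_a - W M_b^+ W^T` over the kept/discarded block partition of the
#' Hessian.  When the discarded block is invertible this is the plain
#' `M_b^{-1}` elimination; the pseudoinverse extends it to discarded beads
#' with locally soft directions (e.g. a two-spring bead free to move
#' perpendicular to both springs), where the positive semi-definiteness of
#' the full Hessian guarantees the generalized complement is the correct
#' energy minimization over the discarded coordinates.  The marginal
#' fluctuations of the kept beads under the reduced matrix equal the
#' rigid-projected sub-block of the full covariance.
#'
#' @param H A Hessian from [enm_hessian()] with at most 6 zero modes
#'   (a disconnected network makes the reduction ill-posed and is refused).
#' @param keep Bead indices (1-based) to retain.
#' @return The reduced 3\|keep\| x 3\|keep\| Hessian (labels subset attached).
#' @export
effective_hessian <- function(H, keep) {
  N <- nrow(H) / 3
  keep <- sort(unique(as.integer(keep)))
  if (length(keep) == 0 || any(keep < 1 | keep > N))
    enm_stop("keep must be a non-empty subset of bead indices", "input")
  labels <- attr(H, "labels")
  if (length(keep) == N) {
    Heff <- H
  } else {
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (sum(ev < 1e-10 * max(ev)) > 6L)
      enm_stop(paste0("network is disconnected: a discarded sub-component is ",
                      "decoupled from the kept beads and the reduction is ill-posed"),
               "reduction")
    a <- dof_index(keep)
    b <- setdiff(seq_len(3 * N), a)
    Mb <- H[b, b, drop = FALSE]
    W <- H[a, b, drop = FALSE]
    eb <- eigen(Mb, symmetric = TRUE)
    pos <- eb$values > 1e-12 * max(eb$values)
    Vb <- eb$vectors[, pos, drop = FALSE]
    WV <- W %*% Vb
    # PSD of the full matrix implies range(W^T) is inside range(M_b); verify
    resid <- W - WV %*% t(Vb)
    if (max(abs(resid)) > 1e-8 * max(abs(W), 1))
      enm_stop("coupling block escapes the range of the discarded block", "reduction")
    Heff <- H[a, a, drop = FALSE] - WV %*% (t(WV) / eb$values[pos])
    Heff <- (Heff + t(Heff)) / 2
  }
  if (!is.null(labels)) attr(Heff, "labels") <- labels[keep, , drop = FALSE]
  Heff
}

#' Fit an elastic network model to a bead structure
#'
#' The one-stop model constructor: builds the sharp-cutoff network, its
#' Hessian and the pseudoinverse covariance, and verifies the six-zero-mode
#' connectivity requirement.  When `cutoff` is omitted, the smallest
#' physically viable cutoff on the standard 3-30 Angstrom grid is used.
#'
#' @param structure A `"bead_structure"` (see [read_bead_structure()],
#'   [extract_beads()], [generate_duplex()]).
#' @param cutoff Interaction cutoff in Angstrom, or `NULL` to take the
#'   minimum viable value from [min_viable_cutoff()].
#' @param k Master spring constant (default 1).
#' @param scale Covariance scale factor (the k_B T / k multiplier; default 1).
#' @param spring_fun Optional distance-dependent spring-constant function.
#' @return An object of class `"enm"` with elements `structure`, `network`,
#'   `hessian`, `model` (the `"gaussian_model"`), `cutoff`, `k` and `call`.
#' @examples
#' dup <- generate_duplex(n_bp = 4)
#' fit <- enm(dup, cutoff = 10)
#' summary(fit)
#' head(msf(fit))
#' @export
enm <- function(structure, cutoff = NULL, k = 1, scale = 1, spring_fun = NULL) {
  if (!inherits(structure, "bead_structure"))
    enm_stop("structure must be a bead_structure", "input")
  if (coord_rank(bead_coords(structure)) < 3)
    enm_stop("bead coordinates are collinear or coplanar-degenerate; no valid ENM",
             "degenerate_geometry")
  if (is.null(cutoff)) cutoff <- min_viable_cutoff(structure, k = k)
  net <- build_network(structure, cutoff = cutoff, k = k, spring_fun = spring_fun)
  H <- enm_hessian(net)
  model <- covariance_from_hessian(H, scale = scale)
  structure(list(structure = structure, network = net, hessian = H,
                 model = model, cutoff = cutoff, k = k, scale = scale,
                 call = match.call()),
            class = "enm")
}

#' @export
print.enm <- function(x, ...) {
  cat("RNA elastic network model\n")
  sc <- attr(x$structure, "scheme")
  cat(sprintf("  scheme: %s | beads: %d | cutoff: %g A | springs: %d\n",
              if (is.null(sc)) "?" else sc$label, nrow(x$structure),
              x$cutoff, nrow(x$network$springs)))
  invisible(x)
}

#' @export
summary.enm <- function(object, ...) {
  m <- msf(object)
  out <- list(
    n_beads = nrow(object$structure),
    scheme = attr(object$structure, "scheme"),
    cutoff = object$cutoff,
    k = object$k,
    n_springs = nrow(object$network$springs),
    neighbor_count = neighbor_count(object$network),
    total_msf = sum(m$value),
    msf_range = range(m$value)
  )
  class(out) <- "summary.enm"
  out
}

#' @export
print.summary.enm <- function(x, ...) {
  cat("RNA elastic network model\n")
  cat(sprintf("  beads:           %d (scheme %s)\n", x$n_beads,
              if (is.null(x$scheme)) "?" else x$scheme$label))
  cat(sprintf("  cutoff R_c:      %g A\n", x$cutoff))
  cat(sprintf("  springs:         %d (mean neighbors %.2f)\n",
              x$n_springs, x$neighbor_count))
  cat(sprintf("  total MSF:       %.4g A^2 (per-bead range %.3g - %.3g)\n",
              x$total_msf, x$msf_range[1], x$msf_range[2]))
  invisible(x)
}

#' @export
plot.enm <- function(x, ...) {
  m <- msf(x)
  roles <- unique(m$role)
  idx <- seq_len(nrow(m))
  graphics::plot(idx, m$value, type = "n", xlab = "bead index",
                 ylab = expression(MSF ~ (ring(A)^2)), ...)
  for (r in seq_along(roles)) {
    sel <- m$role == roles[r]
    graphics::lines(idx[sel], m$value[sel], col = r)
    graphics::points(idx[sel], m$value[sel], col = r, pch = 20, cex = 0.6)
  }
  if (length(roles) > 1)
    graphics::legend("topright", legend = roles, col = seq_along(roles),
                     lty = 1, bty = "n")
  invisible(x)
}

#' Simulate conformers from a fitted elastic network model
#'
#' Draws frames from the model's zero-mean Gaussian about the reference
#' structure (see [sample_ensemble()]).
#'
#' @param object An `"enm"` fit.
#' @param nsim Number of frames.
#' @param seed Integer seed.
#' @param amplitude Global displacement scale multiplying the sampled
#'   deviations (Angstrom per unit model standard deviation).
#' @param ... Unused.
#' @return A `"conformer_ensemble"` (aligned: frames share the reference
#'   frame by construction).
#' @export
simulate.enm <- function(object, nsim = 1, seed = NULL, amplitude = 1, ...) {
  if (is.null(seed)) seed <- 1L
  sample_ensemble(object$model, object$structure, n_frames = nsim,
                  amplitude = amplitude, seed = seed)
}

#' Predicted flexibility profiles from a fitted model
#'
#' @param object An `"enm"` fit.
#' @param type `"msf"` (per-bead mean square fluctuation) or `"c2c2"`
#'   (per-nucleotide consecutive base-base distance variance, the SHAPE
#'   reactivity proxy; requires base beads).
#' @param ... Passed to [c2c2_profile()] for `type = "c2c2"`.
#' @return A `"fluct_profile"`.
#' @export
predict.enm <- function(object, type = c("msf", "c2c2"), ...) {
  type <- match.arg(type)
  switch(type, msf = msf(object), c2c2 = c2c2_profile(object, ...))
}
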