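#' Optimal rigid-body superposition of an ensemble (Kabsch)
#'
#' Superposes every frame onto a reference by the rotation and translation
#' minimising the RMSD over a bead subset (the classic Kabsch solution via
#' singular value decomposition, with the determinant correction that
#' excludes reflections).  The fitted transformation is applied to all beads
#' of the frame.
#'
#' @param ensemble A `"conformer_ensemble"`.
#' @param reference Reference coordinates: an N x 3 matrix or a
#'   `"bead_structure"` with matching bead count.
#' @param subset Bead indices used for the fit (default: all beads).
#' @return The aligned `"conformer_ensemble"` (`aligned = TRUE`).
#' @export
kabsch_align <- function(ensemble, reference, subset = NULL) {
  R0 <- if (inherits(reference, "bead_structure")) bead_coords(reference)
        else as.matrix(reference)
  N <- dim(ensemble$coords)[1]
  if (nrow(R0) != N) enm_stop("reference bead count does not match ensemble", "input")
  subset <- subset %||% seq_len(N)
  if (length(subset) < 3)
    enm_stop("alignment needs at least 3 fitting sites", "alignment")
  refc <- R0[subset, , drop = FALSE]
  if (coord_rank(refc) < 2)
    enm_stop("fitting sites are collinear; rotation is ill-determined", "alignment")
  ref_mean <- colMeans(refc)
  refc <- sweep(refc, 2, ref_mean)
  out <- ensemble$coords
  for (f in seq_len(dim(out)[3])) {
    P <- out[, , f]
    p_mean <- colMeans(P[subset, , drop = FALSE])
    Pc <- sweep(P[subset, , drop = FALSE], 2, p_mean)
    s <- svd(crossprod(Pc, refc))
    d <- sign(det(s$u %*% t(s$v)))
    rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    out[, , f] <- sweep(sweep(P, 2, p_mean) %*% rot, 2, ref_mean, "+")
  }
  conformer_ensemble(out, labels = ensemble$labels, aligned = TRUE)
}

#' Covariance of an aligned conformer ensemble
#'
#' The 3N x 3N covariance of bead deviations from the ensemble mean, with
#' divisor n (the plain time-average definition).  The ensemble must have
#' been superposed first: without alignment the covariance is inflated by
#' rigid-body motion.
#'
#' @param ensemble An aligned `"conformer_ensemble"` with >= 2 frames.
#' @return A `"gaussian_model"`.
#' @export
ensemble_covariance <- function(ensemble) {
  if (!ensemble$aligned)
    enm_stop("ensemble must be aligned (kabsch_align) before covariance", "contract")
  Fn <- n_frames(ensemble)
  if (Fn < 2) enm_stop("need at least 2 frames", "input")
  X <- ensemble_flat(ensemble)
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / Fn
  gaussian_model(C, labels = ensemble$labels)
}

#' Root weighted square inner product between essential spaces
#'
#' The eigenvalue-weighted overlap between the essential dynamical spaces of
#' two covariance models:
#' `RWSIP = sqrt( sum_ij la_i lb_j (va_i . vb_j)^2 / sum_i la_i lb_i )`,
#' with both spectra ranked nonincreasing and the shorter spectrum zero-padded.
#' Equals 1 when the ranked spaces coincide and 0 when they are orthogonal.
#'
#' @param A,B `"gaussian_model"` objects, or lists with elements `values`
#'   (nonincreasing, >= 0) and `vectors` (orthonormal columns).
#' @return A number in \[0, 1\].
#' @export
rwsip <- function(A, B) {
  ea <- as_essential_space(A)
  eb <- as_essential_space(B)
  if (nrow(ea$vectors) != nrow(eb$vectors))
    enm_stop("essential spaces live in different dimensions", "input")
  m <- max(length(ea$values), length(eb$values))
  la <- c(ea$values, rep(0, m - length(ea$values)))
  lb <- c(eb$values, rep(0, m - length(eb$values)))
  den <- sum(la * lb)
  if (den <= 0)
    enm_stop("RWSIP undefined: spectra share no weight (zero denominator)",
             "undefined_measure")
  ia <- which(ea$values > 0)
  ib <- which(eb$values > 0)
  G <- crossprod(ea$vectors[, ia, drop = FALSE], eb$vectors[, ib, drop = FALSE])
  num <- drop(t(ea$values[ia]) %*% (G^2) %*% eb$values[ib])
  sqrt(num / den)
}

#' Essential dynamical space of a covariance model
#'
#' @param x A `"gaussian_model"`, or a list with `values` and `vectors`.
#' @return A list with nonincreasing `values` and orthonormal `vectors`.
#' @export
as_essential_space <- function(x) {
  if (inherits(x, "gaussian_model")) return(list(values = x$values, vectors = x$vectors))
  if (is.list(x) && !is.null(x$values) && !is.null(x$vectors)) {
    if (is.unsorted(rev(x$values))) enm_stop("eigenvalues must be nonincreasing", "input")
    if (any(x$values < 0)) enm_stop("eigenvalues must be nonnegative", "input")
    return(list(values = x$values, vectors = as.matrix(x$vectors)))
  }
  enm_stop("cannot interpret object as an essential space", "input")
}

#' Correlation between two fluctuation profiles
#'
#' @param a,b `"fluct_profile"` data frames or plain numeric vectors of equal
#'   length >= 3.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return The correlation coefficient.
#' @export
msf_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  va <- if (is.data.frame(a)) a$value else as.numeric(a)
  vb <- if (is.data.frame(b)) b$value else as.numeric(b)
  if (length(va) != length(vb) || length(va) < 3)
    enm_stop("profiles must have equal length >= 3", "input")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    enm_stop("correlation undefined: a profile has zero variance",
             "undefined_correlation")
  stats::cor(va, vb, method = method)
}

# Sub-model of a gaussian_model restricted to a bead subset: the marginal
# covariance is the corresponding sub-block.
subset_model <- function(model, keep) {
  idx <- dof_index(keep)
  gaussian_model(model$covariance[idx, idx, drop = FALSE], scale = model$scale,
                 labels = if (!is.null(model$labels))
                   model$labels[keep, , drop = FALSE] else NULL)
}

scan_roles <- function(structure) {
  r <- intersect(c("P", "S", "B"), unique(structure$role))
  if (length(r) == 0) list(ALL = seq_len(nrow(structure)))
  else stats::setNames(lapply(r, function(x) which(structure$role == x)), r)
}

#' Cutoff scan of ENM-ensemble agreement
#'
#' For every cutoff on the grid whose network passes the six-zero-mode test,
#' fits the ENM, reduces it to each single-role bead subset (P, S, B) with
#' the effective interaction matrix, and scores RWSIP and the MSF Pearson
#' correlation against the ensemble covariance restricted to the same beads.
#' Grid points failing the connectivity test are flagged (`viable = FALSE`)
#' and not scored.
#'
#' @param structure A `"bead_structure"` (the ENM reference).
#' @param ensemble A `"conformer_ensemble"` over the same beads; aligned to
#'   `structure` on the fly if not already aligned.
#' @param grid Cutoff grid in Angstrom (default `3:30`).
#' @param k Master spring constant.
#' @return A data frame of class `"enm_scan"`: `cutoff`, `role`,
#'   `n_springs`, `n_zero_modes`, `viable`, `rwsip`, `msf_pearson`.
#' @export
cutoff_scan <- function(structure, ensemble, grid = 3:30, k = 1) {
  if (dim(ensemble$coords)[1] != nrow(structure))
    enm_stop("ensemble bead count does not match structure", "input")
  roles <- scan_roles(structure)
  # per-role ensemble covariance with the superposition performed on the same
  # beads that enter the comparison, so the subsystem's rigid-body content is
  # removed on both sides (the effective ENM removes it by construction)
  ens_sub <- lapply(roles, function(idx) {
    al <- kabsch_align(ensemble, structure, subset = idx)
    subset_model(ensemble_covariance(al), idx)
  })
  ens_msf <- lapply(ens_sub, msf)

  rows <- list()
  for (rc in sort(grid)) {
    net <- build_network(structure, cutoff = rc, k = k)
    n_spr <- nrow(net$springs)
    H <- if (n_spr > 0) enm_hessian(net) else NULL
    n0 <- if (is.null(H)) 3L * nrow(structure) else zero_modes(H)$count
    if (n0 != 6L) {
      rows[[length(rows) + 1L]] <- data.frame(
        cutoff = rc, role = names(roles), n_springs = n_spr,
        n_zero_modes = n0, viable = FALSE, rwsip = NA_real_,
        msf_pearson = NA_real_, stringsAsFactors = FALSE)
      next
    }
    for (rn in names(roles)) {
      idx <- roles[[rn]]
      Heff <- if (length(idx) == nrow(structure)) H else effective_hessian(H, idx)
      mod <- covariance_from_hessian(Heff)
      rw <- rwsip(mod, ens_sub[[rn]])
      mp <- msf_correlation(msf(mod), ens_msf[[rn]], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        cutoff = rc, role = rn, n_springs = n_spr, n_zero_modes = n0,
        viable = TRUE, rwsip = rw, msf_pearson = mp, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("enm_scan", "data.frame")
  out
}

#' @export
summary.enm_scan <- function(object, ...) {
  v <- object[object$viable, , drop = FALSE]
  if (nrow(v) == 0) enm_stop("no viable grid points in scan", "not_found")
  agg <- stats::aggregate(cbind(rwsip, msf_pearson) ~ cutoff, data = v, FUN = mean)
  agg[order(agg$cutoff), ]
}

#' @export
plot.enm_scan <- function(x, which = c("rwsip", "msf_pearson"), ...) {
  which <- match.arg(which)
  v <- x[x$viable, , drop = FALSE]
  roles <- unique(v$role)
  graphics::plot(range(v$cutoff), range(v[[which]]), type = "n",
                 xlab = expression(R[c] ~ (ring(A))), ylab = which, ...)
  for (r in seq_along(roles)) {
    sel <- v$role == roles[r]
    graphics::lines(v$cutoff[sel], v[[which]][sel], col = r, type = "b", pch = 20)
  }
  graphics::legend("bottomright", legend = roles, col = seq_along(roles),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Split-half self-agreement of an ensemble
#'
#' RWSIP between the covariances of the first and second halves of the frame
#' sequence: the practical upper reference for how well any model can agree
#' with the ensemble.
#'
#' @param ensemble An aligned `"conformer_ensemble"` with >= 4 frames.
#' @param keep Optional bead subset over which to compare.
#' @param reference Optional reference structure; when given together with
#'   `keep`, frames are re-superposed on the `keep` beads first (matching the
#'   per-role comparison protocol of [cutoff_scan()]).
#' @return The RWSIP between the two half-ensemble covariances.
#' @export
split_half_rwsip <- function(ensemble, keep = NULL, reference = NULL) {
  Fn <- n_frames(ensemble)
  if (Fn < 4) enm_stop("need at least 4 frames to split", "input")
  if (!is.null(keep) && !is.null(reference))
    ensemble <- kabsch_align(ensemble, reference, subset = keep)
  half <- Fn %/% 2
  e1 <- conformer_ensemble(ensemble$coords[, , seq_len(half), drop = FALSE],
                           labels = ensemble$labels, aligned = ensemble$aligned)
  e2 <- conformer_ensemble(ensemble$coords[, , (half + 1):Fn, drop = FALSE],
                           labels = ensemble$labels, aligned = ensemble$aligned)
  m1 <- ensemble_covariance(e1)
  m2 <- ensemble_covariance(e2)
  if (!is.null(keep)) { m1 <- subset_model(m1, keep); m2 <- subset_model(m2, keep) }
  rwsip(m1, m2)
}

#' Random-network (null model) agreement reference
#'
#' The significance floor: RWSIP between the ensemble covariance and the
#' fully connected uniform-random-spring network, averaged over several
#' seeds.
#'
#' @param structure The `"bead_structure"` reference.
#' @param ensemble An aligned `"conformer_ensemble"` over the same beads.
#' @param n_seeds Number of random networks to average (default 10).
#' @param seed Base seed; network s uses `seed + s - 1`.
#' @param keep Optional bead subset over which to compare.
#' @return A list with `mean`, `sd` and the per-seed `values`.
#' @export
null_reference_rwsip <- function(structure, ensemble, n_seeds = 10, seed = 1,
                                 keep = NULL) {
  if (!is.null(keep)) {
    ensemble <- kabsch_align(ensemble, structure, subset = keep)
    ens_model <- subset_model(ensemble_covariance(ensemble), keep)
  } else {
    if (!ensemble$aligned) ensemble <- kabsch_align(ensemble, structure)
    ens_model <- ensemble_covariance(ensemble)
  }
  vals <- vapply_num(seq_len(n_seeds), function(s) {
    net <- build_random_network(structure, seed = seed + s - 1)
    H <- enm_hessian(net)
    mod <- if (is.null(keep)) covariance_from_hessian(H)
           else covariance_from_hessian(effective_hessian(H, keep))
    rwsip(mod, ens_model)
  })
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}
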