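#' Ideal double-helix bead fixture
#'
#' Generates a deterministic two-strand bead structure on a regular helix
#' with sugar (C1'), base (C2) and phosphate (P) beads per nucleotide, for
#' validation without any structure download.  The second strand is the exact
#' two-fold (C2 symmetry) image of the first about an axis perpendicular to
#' the helix axis through its midpoint, so the structure is exactly
#' palindromic: bead (chain A, residue t, role) maps onto
#' (chain B, residue n_bp + 1 - t, role) under the end-to-end relabeling.
#' Default geometry is A-form-like (rise 2.81 A, twist 32.7 deg); these are
#' fixture parameters, not a reconstruction of any deposited structure.
#'
#' @param n_bp Number of base pairs (>= 2); the duplex has `2 * n_bp`
#'   nucleotides.
#' @param rise Axial rise per base step (Angstrom).
#' @param twist Helical twist per base step (degrees).
#' @param radius_sugar,radius_base,radius_phosphate Radial distances of the
#'   three bead types from the helix axis (Angstrom).
#' @param roles Which bead roles to generate (subset of `c("P", "S", "B")`).
#' @param noise Standard deviation of optional Gaussian coordinate jitter
#'   (Angstrom; default 0, exactly regular).
#' @param seed Seed for the jitter draws (only used when `noise > 0`).
#' @return A `"bead_structure"` with chains `"A"` and `"B"`, residues
#'   `1..n_bp` per chain, scheme attribute matching `roles`.
#' @examples
#' dup <- generate_duplex(n_bp = 8)
#' nrow(dup)  # 48 beads: 2 strands x 8 nt x 3 roles
#' @export
generate_duplex <- function(n_bp = 8, rise = 2.81, twist = 32.7,
                            radius_sugar = 9.4, radius_base = 5.0,
                            radius_phosphate = 9.9,
                            roles = c("P", "S", "B"),
                            noise = 0, seed = 1) {
  stopifnot(n_bp >= 2, rise > 0, radius_sugar > 0, radius_base > 0,
            radius_phosphate > 0)
  roles <- match.arg(roles, c("P", "S", "B"), several.ok = TRUE)
  tw <- twist * pi / 180
  # per-role (radius, angular offset, axial offset); the sugar's axial offset
  # keeps C2-partner sugars apart across the dyad
  beta <- 0.30
  geom <- list(P = c(radius_phosphate, -0.15, -1.0),
               S = c(radius_sugar,      0.00,  1.2),
               B = c(radius_base,       beta,  0.2))
  z_mid <- (n_bp - 1) * rise / 2
  # dyad azimuth: paired base beads (A,t) / (B, n+1-t) end up ~2 delta apart
  # in angle, i.e. about 3 A at the base radius -- strands genuinely pair
  delta <- 0.30
  psi <- ((n_bp - 1) * tw + 2 * beta) / 2 - delta

  one_bead <- function(t, role) {
    g <- geom[[role]]
    phi <- (t - 1) * tw + g[2]
    c(g[1] * cos(phi), g[1] * sin(phi), (t - 1) * rise + g[3])
  }
  # proper two-fold rotation about the in-plane axis at azimuth psi through
  # the helix midpoint: angle phi -> 2 psi - phi, z -> 2 z_mid - z
  dyad <- function(p) {
    c(cos(2 * psi) * p[1] + sin(2 * psi) * p[2],
      sin(2 * psi) * p[1] - cos(2 * psi) * p[2],
      2 * z_mid - p[3])
  }
  rows <- list()
  for (t in seq_len(n_bp)) {
    for (role in intersect(c("P", "S", "B"), roles)) {
      p <- one_bead(t, role)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = "A", resid = as.character(t), role = role,
        x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
    }
  }
  for (t in seq_len(n_bp)) {
    for (role in intersect(c("P", "S", "B"), roles)) {
      p <- dyad(one_bead(n_bp + 1 - t, role))
      rows[[length(rows) + 1L]] <- data.frame(
        chain = "B", resid = as.character(t), role = role,
        x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
    }
  }
  beads <- do.call(rbind, rows)
  rownames(beads) <- NULL
  if (noise > 0) {
    jit <- with_seed(seed, matrix(stats::rnorm(3 * nrow(beads), sd = noise),
                                  ncol = 3))
    beads$x <- beads$x + jit[, 1]
    beads$y <- beads$y + jit[, 2]
    beads$z <- beads$z + jit[, 3]
  }
  attr(beads, "scheme") <- bead_scheme(paste(
    intersect(c("S", "B", "P"), roles), collapse = ""))
  class(beads) <- c("bead_structure", "data.frame")
  beads
}

#' Sample conformers from a Gaussian fluctuation model
#'
#' Draws frames `reference + amplitude * z` with `z` from the zero-mean
#' Gaussian of the model covariance, using the eigendecomposition square root
#' so that rank-deficient covariances (six rigid modes removed) are sampled
#' exactly within the image of the covariance.
#'
#' @param model A `"gaussian_model"`.
#' @param reference The reference `"bead_structure"` (or N x 3 matrix).
#' @param n_frames Number of frames (>= 1).
#' @param amplitude Global displacement scale (> 0).
#' @param seed Integer seed; draws are reproducible.
#' @return An aligned `"conformer_ensemble"` (frames share the reference
#'   frame by construction).
#' @export
sample_ensemble <- function(model, reference, n_frames, amplitude = 1, seed = 1) {
  stopifnot(n_frames >= 1, amplitude > 0)
  R0 <- if (inherits(reference, "bead_structure")) bead_coords(reference)
        else as.matrix(reference)
  n_dof <- length(model$values)
  if (nrow(R0) * 3 != n_dof)
    enm_stop("reference bead count does not match model dimension", "input")
  pos <- which(model$values > 1e-14 * max(model$values))
  L <- model$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(model$values[pos]), nrow = length(pos))
  Z <- with_seed(seed, matrix(stats::rnorm(length(pos) * n_frames),
                              nrow = length(pos)))
  disp <- amplitude * (L %*% Z)               # 3N x F
  labels <- if (inherits(reference, "bead_structure")) bead_labels(reference)
            else model$labels
  frames <- lapply(seq_len(n_frames), function(f) {
    R0 + matrix(disp[, f], ncol = 3, byrow = TRUE)
  })
  conformer_ensemble(frames, labels = labels, aligned = TRUE)
}

#' Random bead cloud fixture
#'
#' Uniform points in a cube with a minimum-separation rejection rule;
#' deterministic under a fixed seed and non-collinear by construction check.
#'
#' @param n Number of beads (>= 2).
#' @param box Cube edge length (Angstrom).
#' @param min_separation Smallest allowed pairwise distance (Angstrom).
#' @param seed Integer seed.
#' @return A `"bead_structure"` (single chain, one `ATOM:X` bead per residue).
#' @export
random_cloud <- function(n, box = 20, min_separation = 2, seed = 1) {
  stopifnot(n >= 2, min_separation >= 0, box > 0)
  pts <- with_seed(seed, {
    out <- matrix(NA_real_, n, 3)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 10000L * n
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        enm_stop(sprintf(
          "could not place %d beads at separation >= %g in a %g A box", n,
          min_separation, box), "packing")
      cand <- stats::runif(3, 0, box)
      ok <- placed == 0L ||
        min(sqrt(colSums((t(out[seq_len(placed), , drop = FALSE]) - cand)^2))) >=
          min_separation
      if (ok) { placed <- placed + 1L; out[placed, ] <- cand }
    }
    out
  })
  beads <- data.frame(chain = "A", resid = as.character(seq_len(n)),
                      role = "ATOM:X", x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      stringsAsFactors = FALSE)
  if (n >= 4 && coord_rank(pts) < 3)
    enm_stop("sampled cloud is degenerate (collinear/coplanar)", "packing")
  attr(beads, "scheme") <- bead_scheme("AA")
  class(beads) <- c("bead_structure", "data.frame")
  beads
}
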