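#' Distance variance between two beads
#'
#' For a fitted Gaussian model the variance of the inter-bead distance
#' follows analytically from the covariance in the linear (small
#' fluctuation) regime:
#' `sigma^2_d = sum_{mu,nu} (d_mu d_nu / d^2) (C_ii + C_jj - C_ij - C_ji)_{mu,nu}`
#' with `d` the reference separation vector.  For a conformer ensemble it is
#' the plain variance (divisor n) of the per-frame Euclidean distance.
#'
#' @param x A `"gaussian_model"` (with `structure`), `"enm"` fit, or
#'   `"conformer_ensemble"`.
#' @param i,j Bead indices (1-based), `i != j`.
#' @param ... Method arguments (`structure` for the Gaussian-model method).
#' @return The distance variance in A^2.
#' @export
distance_variance <- function(x, i, j, ...) UseMethod("distance_variance")

#' @rdname distance_variance
#' @param structure The reference `"bead_structure"` supplying the separation
#'   vector.
#' @export
distance_variance.gaussian_model <- function(x, i, j, structure, ...) {
  if (i == j) enm_stop("i and j must differ", "input")
  X <- bead_coords(structure)
  d <- X[i, ] - X[j, ]
  d2 <- sum(d^2)
  if (d2 <= 0) enm_stop("coincident reference beads", "degenerate_geometry")
  C <- x$covariance
  ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
  D <- C[ii, ii] + C[jj, jj] - C[ii, jj] - C[jj, ii]
  v <- drop(t(d) %*% D %*% d) / d2
  if (v < -1e-12 * max(abs(diag(C)), 1))
    enm_stop("negative distance variance beyond tolerance", "input")
  max(v, 0)
}

#' @rdname distance_variance
#' @export
distance_variance.enm <- function(x, i, j, ...) {
  distance_variance(x$model, i, j, structure = x$structure)
}

#' @rdname distance_variance
#' @export
distance_variance.conformer_ensemble <- function(x, i, j, ...) {
  if (i == j) enm_stop("i and j must differ", "input")
  dif <- x$coords[i, , ] - x$coords[j, , ]
  d <- sqrt(colSums(dif^2))
  mean((d - mean(d))^2)
}

#' Angle variance over an ensemble
#'
#' Variance (divisor n) of the i-j-k angle at vertex j across frames, in
#' radians squared.  Angles are computed as the arccosine of the normalised
#' dot product of the two arm vectors.
#'
#' @param ensemble A `"conformer_ensemble"` with >= 2 frames.
#' @param i,j,k Bead indices; `j` is the vertex.
#' @return Angle variance (radians^2).
#' @export
angle_variance <- function(ensemble, i, j, k) {
  if (length(unique(c(i, j, k))) != 3) enm_stop("i, j, k must be distinct", "input")
  u <- ensemble$coords[i, , ] - ensemble$coords[j, , ]
  w <- ensemble$coords[k, , ] - ensemble$coords[j, , ]
  nu <- sqrt(colSums(u^2)); nw <- sqrt(colSums(w^2))
  if (any(nu <= 0) || any(nw <= 0))
    enm_stop("zero-length angle arm in a frame", "degenerate_geometry")
  cosang <- pmin(1, pmax(-1, colSums(u * w) / (nu * nw)))
  ang <- acos(cosang)
  mean((ang - mean(ang))^2)
}

# Ordered consecutive intra-chain base-bead pairs (residue t, t+1).
consecutive_base_pairs <- function(labels) {
  bidx <- which(labels$role == "B")
  if (length(bidx) < 2)
    enm_stop("scheme has no (or a single) base bead; C2-C2 profile needs base beads",
             "scheme")
  ch <- labels$chain[bidx]
  pairs <- NULL
  for (c1 in unique(ch)) {
    w <- bidx[ch == c1]
    if (length(w) >= 2)
      pairs <- rbind(pairs, cbind(w[-length(w)], w[-1]))
  }
  if (is.null(pairs))
    enm_stop("no chain has two consecutive base beads", "scheme")
  pairs
}

#' Consecutive base-base distance-fluctuation profile (SHAPE proxy)
#'
#' Computes the variance of the distance between consecutive base beads (C2
#' atoms of residues t and t+1 within each chain) and maps the pair values to
#' per-nucleotide values.  Base-base distance fluctuations track backbone
#' flexibility and correlate with SHAPE chemical-probing reactivity, making
#' this profile a structure-based reactivity proxy.
#'
#' @param x An `"enm"` fit, a `"gaussian_model"` (then give `structure`), or
#'   a `"conformer_ensemble"` with base-bead labels.
#' @param structure Reference `"bead_structure"` (required for a bare
#'   `"gaussian_model"`; taken from the fit or the ensemble labels otherwise).
#' @param assignment How a nucleotide inherits its flanking pair values:
#'   `"mean_flank"` (default: mean of the two flanking pairs; chain ends use
#'   their single flank), `"five_prime"` (pair (t, t+1) assigned to t) or
#'   `"three_prime"` (assigned to t+1).
#' @return A `"fluct_profile"` with one row per nucleotide carrying base
#'   beads; the raw pair values are attached as attribute `"pairs"`.
#' @export
c2c2_profile <- function(x, structure = NULL,
                         assignment = c("mean_flank", "five_prime", "three_prime")) {
  assignment <- match.arg(assignment)
  if (inherits(x, "enm")) {
    labels <- bead_labels(x$structure)
    pval_fun <- function(i, j) distance_variance(x$model, i, j, structure = x$structure)
  } else if (inherits(x, "gaussian_model")) {
    if (is.null(structure)) enm_stop("structure required with a gaussian_model", "input")
    labels <- bead_labels(structure)
    pval_fun <- function(i, j) distance_variance(x, i, j, structure = structure)
  } else if (inherits(x, "conformer_ensemble")) {
    if (is.null(x$labels)) enm_stop("ensemble lacks bead labels", "input")
    labels <- as.data.frame(x$labels)
    pval_fun <- function(i, j) distance_variance(x, i, j)
  } else enm_stop("unsupported object for c2c2_profile", "input")

  pairs <- consecutive_base_pairs(labels)
  pv <- vapply_num(seq_len(nrow(pairs)), function(r) pval_fun(pairs[r, 1], pairs[r, 2]))
  pair_df <- data.frame(chain = labels$chain[pairs[, 1]],
                        resid_5p = labels$resid[pairs[, 1]],
                        resid_3p = labels$resid[pairs[, 2]],
                        value = pv, stringsAsFactors = FALSE)

  bidx <- which(labels$role == "B")
  res <- data.frame(chain = labels$chain[bidx], resid = labels$resid[bidx],
                    stringsAsFactors = FALSE)
  val <- numeric(nrow(res))
  for (r in seq_len(nrow(res))) {
    left <- pair_df$value[pair_df$chain == res$chain[r] & pair_df$resid_3p == res$resid[r]]
    right <- pair_df$value[pair_df$chain == res$chain[r] & pair_df$resid_5p == res$resid[r]]
    val[r] <- switch(assignment,
      mean_flank = mean(c(left, right)),
      five_prime = if (length(right)) right else left,
      three_prime = if (length(left)) left else right)
  }
  out <- fluct_profile(val, data.frame(chain = res$chain, resid = res$resid,
                                       role = "B", stringsAsFactors = FALSE))
  attr(out, "pairs") <- pair_df
  out
}

#' Read a SHAPE reactivity profile
#'
#' Accepts whitespace- or comma-delimited text with two columns
#' (residue, reactivity) or three (residue, chain, reactivity); an optional
#' header line is detected and skipped.  Reactivities of `NA` stay missing.
#'
#' @param path File path.
#' @return A data frame of class `"shape_profile"` with columns `chain`
#'   (`NA` when absent from the file), `resid`, `reactivity`.
#' @export
read_shape <- function(path) {
  if (!file.exists(path)) enm_stop(paste0("no such file: ", path), "input")
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  if (length(lines) == 0) enm_stop("empty SHAPE file", "parse")
  split1 <- strsplit(lines[1], "[,[:space:]]+")[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(split1[1])))
  if (has_header) lines <- lines[-1]
  fields <- strsplit(lines, "[,[:space:]]+")
  ncol_ <- unique(lengths(fields))
  if (length(ncol_) != 1 || !ncol_ %in% 2:3)
    enm_stop("SHAPE file must have 2 or 3 columns", "parse")
  m <- do.call(rbind, fields)
  if (ncol_ == 2) {
    df <- data.frame(chain = NA_character_, resid = m[, 1],
                     reactivity = suppressWarnings(as.numeric(m[, 2])),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(chain = m[, 2], resid = m[, 1],
                     reactivity = suppressWarnings(as.numeric(m[, 3])),
                     stringsAsFactors = FALSE)
  }
  if (anyDuplicated(paste(df$chain, df$resid)))
    enm_stop("duplicate residue keys in SHAPE file", "parse")
  class(df) <- c("shape_profile", "data.frame")
  df
}

#' Correlate a flexibility profile with SHAPE reactivities
#'
#' Matches residues by (chain, residue) key -- by residue alone when the
#' SHAPE file carries no chain column -- and correlates the profile values
#' with the reactivities over the intersection.  Missing and negative
#' reactivities are treated as unmeasured and dropped; the dropped count is
#' reported.
#'
#' @param profile A `"fluct_profile"` (e.g. from [c2c2_profile()]).
#' @param shape A `"shape_profile"` from [read_shape()], or a data frame with
#'   `resid` and `reactivity` (and optionally `chain`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list of class `"shape_cor"`: `r`, `n_matched`, `n_dropped`,
#'   `method`.
#' @export
shape_correlation <- function(profile, shape, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  use_chain <- !is.null(shape$chain) && !all(is.na(shape$chain))
  pkey <- if (use_chain) paste(profile$chain, profile$resid) else as.character(profile$resid)
  skey <- if (use_chain) paste(shape$chain, shape$resid) else as.character(shape$resid)
  if (!use_chain && anyDuplicated(pkey))
    enm_stop("profile spans multiple chains but SHAPE file has no chain column",
             "input")
  hit <- match(pkey, skey)
  matched <- !is.na(hit)
  re <- shape$reactivity[hit[matched]]
  ok <- !is.na(re) & re >= 0
  n_dropped <- sum(!ok) + sum(!matched)
  v <- profile$value[matched][ok]
  r <- re[ok]
  if (length(v) < 3)
    enm_stop(sprintf("only %d residues matched between profile and SHAPE data",
                     length(v)), "insufficient_overlap")
  out <- list(r = stats::cor(v, r, method = method),
              n_matched = length(v), n_dropped = n_dropped, method = method)
  class(out) <- "shape_cor"
  out
}

#' @export
print.shape_cor <- function(x, ...) {
  cat(sprintf("%s correlation with SHAPE reactivity: r = %.3f (n = %d matched, %d dropped)\n",
              x$method, x$r, x$n_matched, x$n_dropped))
  invisible(x)
}

#' Write a fluctuation profile as delimited text
#' @param profile A `"fluct_profile"`.
#' @param path Output path (TSV: chain, resid, role, value).
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
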