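#' Bead schemes for RNA elastic networks
#'
#' An RNA nucleotide is coarse-grained into up to three interaction centers,
#' one per chemical group: the phosphate (bead atom P), the sugar (C1') and
#' the base (C2).  Any non-empty combination of the three defines a scheme;
#' the all-atom scheme instead keeps every heavy atom as a bead.
#'
#' @param scheme A string: any ordering of the letters `"S"`, `"B"`, `"P"`
#'   (e.g. `"SBP"`, `"P"`, `"SB"`), or `"AA"` for all heavy atoms.
#' @param include_ligand Include hetero residues (e.g. a bound ligand) as
#'   beads, one per heavy atom?  Default `FALSE`.
#' @return An object of class `"bead_scheme"`.
#' @examples
#' bead_scheme("SBP")
#' bead_scheme("P")
#' @export
bead_scheme <- function(scheme = "SBP", include_ligand = FALSE) {
  if (inherits(scheme, "bead_scheme")) return(scheme)
  stopifnot(is.character(scheme), length(scheme) == 1L)
  s <- toupper(scheme)
  all_atom <- identical(s, "AA")
  letters_ <- strsplit(s, "")[[1]]
  if (!all_atom && (length(letters_) == 0 || !all(letters_ %in% c("S", "B", "P"))))
    enm_stop(paste0("unknown bead scheme '", scheme, "'"), "input")
  out <- list(
    use_phosphate = all_atom || "P" %in% letters_,
    use_sugar     = all_atom || "S" %in% letters_,
    use_base      = all_atom || "B" %in% letters_,
    all_atom      = all_atom,
    include_ligand = isTRUE(include_ligand),
    label         = s
  )
  class(out) <- "bead_scheme"
  out
}

#' @export
print.bead_scheme <- function(x, ...) {
  cat("Bead scheme:", x$label,
      if (x$all_atom) "(all heavy atoms)" else "",
      if (x$include_ligand) "[+ligand]" else "", "\n")
  invisible(x)
}

# Read a PDB file (or in-memory PDB text) with bio3d and return the raw atom
# table for all models plus the per-model coordinate matrix.
read_pdb_raw <- function(pdb) {
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb[1]) || !file.exists(pdb[1])) {
    if (length(pdb) == 1L && !grepl("\n", pdb) && !file.exists(pdb))
      enm_stop(paste0("no such PDB file: ", pdb), "input")
    path <- tempfile(fileext = ".pdb")
    writeLines(if (length(pdb) > 1L) pdb else strsplit(pdb, "\n")[[1]], path)
    on.exit(unlink(path))
  }
  p <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) enm_stop(paste0("cannot parse PDB input: ",
                                        conditionMessage(e)), "parse")
  )
  if (is.null(p$atom) || nrow(p$atom) == 0)
    enm_stop("no ATOM/HETATM records found", "parse")
  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  list(atom = p$atom, xyz = xyz, n_models = nrow(xyz))
}

# Element symbol of an atom, falling back to the first alphabetic character
# of the atom name (after stripping digits and primes) when the element
# column is blank.
infer_element <- function(elesy, elety) {
  el <- trimws(ifelse(is.na(elesy), "", elesy))
  miss <- el == ""
  if (any(miss)) {
    nm <- gsub("[^A-Za-z]", "", elety[miss])
    el[miss] <- toupper(substr(nm, 1, 1))
  }
  toupper(el)
}

#' Parse a PDB structure into heavy-atom records
#'
#' Reads standard PDB text (ATOM/HETATM/MODEL records) and returns the heavy
#' atoms of one model.  Hydrogens (and deuteriums) are dropped; alternate
#' locations are resolved to the highest-occupancy conformer with ties broken
#' by file order; insertion codes are appended to the residue key so inserted
#' residues stay distinct.
#'
#' @param pdb Path to a PDB file, or PDB-format text (a single string with
#'   newlines, or a character vector of lines).
#' @param model Model number, 1-based.  Default 1 (the first model).
#' @return A data frame of class `"atom_records"` with columns `chain`,
#'   `resno`, `insert`, `resid` (residue key: number plus insertion code),
#'   `resname`, `atom`, `element`, `x`, `y`, `z`, `occupancy`, `is_hetero`.
#' @export
parse_structure <- function(pdb, model = 1L) {
  raw <- read_pdb_raw(pdb)
  if (model < 1L || model > raw$n_models)
    enm_stop(sprintf("model %d requested but file has %d model(s)",
                     model, raw$n_models), "range")
  a <- raw$atom
  n <- nrow(a)
  coords <- matrix(raw$xyz[model, ], ncol = 3, byrow = TRUE)
  insert <- ifelse(is.na(a$insert), "", a$insert)
  df <- data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    insert = insert,
    resid = paste0(a$resno, insert),
    resname = trimws(a$resid),
    atom = normalize_atom_name(a$elety),
    element = infer_element(a$elesy, a$elety),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = ifelse(is.na(a$o), 1, a$o),
    is_hetero = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  df <- df[!(df$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(df) == 0) enm_stop("no heavy atoms in requested model", "parse")
  # alternate locations: keep the highest-occupancy copy per atom slot,
  # ties resolved by file order
  df$.ord <- seq_len(nrow(df))
  key <- paste(df$chain, df$resid, df$resname, df$atom, sep = "\r")
  o <- order(key, -df$occupancy, df$.ord)
  df <- df[o, , drop = FALSE][!duplicated(key[o]), , drop = FALSE]
  df <- df[order(df$.ord), , drop = FALSE]
  df$.ord <- NULL
  rownames(df) <- NULL
  class(df) <- c("atom_records", "data.frame")
  df
}

# Old-style PDB files use * for the prime (C1* == C1').
normalize_atom_name <- function(x) gsub("\\*", "'", trimws(x))

role_atom_map <- c(P = "P", S = "C1'", B = "C2")

#' Map heavy atoms to elastic-network beads
#'
#' Selects one interaction center per chemical group per nucleotide under the
#' given scheme: the P atom for the phosphate, C1' for the sugar and C2 for
#' the base.  Under the all-atom scheme every heavy atom becomes a bead.
#' Hetero residues contribute beads (one per heavy atom, role
#' `LIGAND:<atom>`) only when the scheme includes ligands.  A residue missing
#' a selected representative atom (typically the 5'-terminal phosphate)
#' contributes no bead for that role; a warning reports the count.
#'
#' @param atoms An `"atom_records"` data frame from [parse_structure()].
#' @param scheme A [bead_scheme()] or scheme string.
#' @return A data frame of class `"bead_structure"` with columns `chain`,
#'   `resid`, `role`, `x`, `y`, `z`, ordered by chain, residue (file order)
#'   and fixed role order P, S, B.  The scheme is attached as attribute
#'   `"scheme"`.
#' @export
extract_beads <- function(atoms, scheme = "SBP") {
  scheme <- bead_scheme(scheme)
  if (nrow(atoms) == 0) enm_stop("no atoms to select beads from", "empty_selection")
  std <- atoms[!atoms$is_hetero, , drop = FALSE]
  het <- atoms[atoms$is_hetero, , drop = FALSE]

  rows <- list()
  n_missing <- 0L
  if (nrow(std) > 0) {
    # deterministic ordering independent of input atom order:
    # (chain, residue number, insertion code), atoms by name within a residue
    std <- std[order(std$chain, std$resno, std$insert, std$atom), , drop = FALSE]
    rkey <- paste(std$chain, std$resid, sep = "\r")
    residues <- split(std, factor(rkey, levels = unique(rkey)))
    for (res in residues) {
      if (scheme$all_atom) {
        rows[[length(rows) + 1L]] <- data.frame(
          chain = res$chain, resid = res$resid,
          role = paste0("ATOM:", res$atom),
          x = res$x, y = res$y, z = res$z, stringsAsFactors = FALSE)
      } else {
        for (role in c("P", "S", "B")) {
          use <- switch(role, P = scheme$use_phosphate,
                        S = scheme$use_sugar, B = scheme$use_base)
          if (!use) next
          hit <- which(res$atom == role_atom_map[[role]])
          if (length(hit) == 0) { n_missing <- n_missing + 1L; next }
          r1 <- res[hit[1], ]
          rows[[length(rows) + 1L]] <- data.frame(
            chain = r1$chain, resid = r1$resid, role = role,
            x = r1$x, y = r1$y, z = r1$z, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (scheme$include_ligand && nrow(het) > 0) {
    het <- het[order(het$chain, het$resno, het$insert, het$atom), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      chain = het$chain, resid = het$resid,
      role = paste0("LIGAND:", het$atom),
      x = het$x, y = het$y, z = het$z, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) enm_stop("scheme selects zero beads", "empty_selection")
  beads <- do.call(rbind, rows)
  rownames(beads) <- NULL
  if (n_missing > 0)
    enm_warn(sprintf("%d residue/role combination(s) lack the representative atom; beads omitted",
                     n_missing), "missing_atom")
  key <- paste(beads$chain, beads$resid, beads$role)
  if (anyDuplicated(key))
    enm_stop("duplicate (chain, residue, role) bead keys", "input")
  if (nrow(beads) < 2) enm_stop("fewer than 2 beads selected", "empty_selection")
  attr(beads, "scheme") <- scheme
  class(beads) <- c("bead_structure", "data.frame")
  beads
}

#' Read a bead structure directly from a PDB file
#'
#' Convenience wrapper: [parse_structure()] followed by [extract_beads()].
#'
#' @inheritParams parse_structure
#' @inheritParams extract_beads
#' @return A `"bead_structure"`.
#' @export
read_bead_structure <- function(pdb, scheme = "SBP", model = 1L) {
  extract_beads(parse_structure(pdb, model = model), scheme = scheme)
}

#' @export
print.bead_structure <- function(x, ...) {
  sc <- attr(x, "scheme")
  cat(sprintf("Bead structure: %d beads, %d chain(s), scheme %s\n",
              nrow(x), length(unique(x$chain)),
              if (is.null(sc)) "?" else sc$label))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more beads)\n", sep = "")
  invisible(x)
}

#' Bead coordinates as a numeric matrix
#' @param structure A `"bead_structure"`.
#' @return An N x 3 matrix of coordinates (Angstrom).
#' @export
bead_coords <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

bead_labels <- function(structure) structure[, c("chain", "resid", "role")]

# Expand bead indices to degree-of-freedom (x,y,z) indices in the 3N layout.
dof_index <- function(i) as.vector(rbind(3 * i - 2, 3 * i - 1, 3 * i))

#' Construct a conformer ensemble
#'
#' @param frames A list of N x 3 coordinate matrices, or an N x 3 x F array.
#' @param labels Optional bead labels (data frame with `chain`, `resid`,
#'   `role`) matching the N rows of each frame.
#' @param aligned Have the frames been superposed onto a common reference?
#' @return An object of class `"conformer_ensemble"`.
#' @export
conformer_ensemble <- function(frames, labels = NULL, aligned = FALSE) {
  if (is.list(frames)) {
    n <- unique(vapply(frames, nrow, integer(1)))
    if (length(n) != 1) enm_stop("frames differ in bead count", "input")
    arr <- array(unlist(frames), dim = c(n, 3, length(frames)))
  } else if (is.array(frames) && length(dim(frames)) == 3) {
    arr <- frames
  } else if (is.matrix(frames)) {
    arr <- array(frames, dim = c(nrow(frames), 3, 1))
  } else enm_stop("frames must be a list of matrices or an N x 3 x F array", "input")
  if (dim(arr)[1] < 2) enm_stop("ensembles need at least 2 beads", "input")
  if (!all(is.finite(arr))) enm_stop("non-finite coordinates in ensemble", "input")
  structure(list(coords = arr, labels = labels, aligned = isTRUE(aligned)),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Conformer ensemble: %d frames x %d beads%s\n",
              d[3], d[1], if (x$aligned) " (aligned)" else ""))
  invisible(x)
}

n_frames <- function(ensemble) dim(ensemble$coords)[3]
frame_matrix <- function(ensemble, f) ensemble$coords[, , f]

# Flatten to an F x 3N matrix (frame rows, dof columns in x1 y1 z1 x2 ... order).
ensemble_flat <- function(ensemble) {
  d <- dim(ensemble$coords)
  t(apply(ensemble$coords, 3, function(m) as.vector(t(m))))
}

#' Read a conformer ensemble from disk
#'
#' Two formats are supported: multi-model PDB (frames are MODEL blocks; beads
#' selected with `scheme`), and plain text frames of N lines of `x y z`
#' separated by blank lines.
#'
#' @param path File path.
#' @param format `"auto"` (default: decided by content), `"pdb"` or `"xyz"`.
#' @param scheme Bead scheme for PDB input.
#' @return A `"conformer_ensemble"` (unaligned).
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "xyz"), scheme = "SBP") {
  format <- match.arg(format)
  if (!file.exists(path)) enm_stop(paste0("no such file: ", path), "input")
  if (format == "auto") {
    head_lines <- readLines(path, n = 50)
    format <- if (any(grepl("^(ATOM|HETATM|MODEL|HEADER|REMARK)", head_lines)))
      "pdb" else "xyz"
  }
  if (format == "pdb") {
    raw <- read_pdb_raw(path)
    atoms1 <- parse_structure(path, model = 1L)
    beads1 <- extract_beads(atoms1, scheme = scheme)
    # locate the bead atoms in the raw (unfiltered) atom table so the same
    # columns can be pulled from every model
    a <- raw$atom
    raw_key <- paste(ifelse(is.na(a$chain), "A", a$chain),
                     paste0(a$resno, ifelse(is.na(a$insert), "", a$insert)),
                     normalize_atom_name(a$elety), sep = "\r")
    bead_atom <- ifelse(grepl(":", beads1$role),
                        sub("^[A-Z]+:", "", beads1$role),
                        role_atom_map[beads1$role])
    bead_key <- paste(beads1$chain, beads1$resid, bead_atom, sep = "\r")
    idx <- match(bead_key, raw_key)
    if (anyNA(idx)) enm_stop("bead atoms not found across models", "parse")
    frames <- lapply(seq_len(raw$n_models), function(m) {
      co <- matrix(raw$xyz[m, ], ncol = 3, byrow = TRUE)
      co[idx, , drop = FALSE]
    })
    conformer_ensemble(frames, labels = bead_labels(beads1), aligned = FALSE)
  } else {
    txt <- readLines(path)
    txt <- txt[!grepl("^\\s*#", txt)]
    blank <- grepl("^\\s*$", txt)
    grp <- cumsum(blank)
    blocks <- split(txt[!blank], grp[!blank])
    frames <- lapply(blocks, function(b) {
      m <- do.call(rbind, lapply(strsplit(trimws(b), "\\s+"), as.numeric))
      if (ncol(m) != 3 || anyNA(m))
        enm_stop("malformed xyz frame (expected 3 numeric columns)", "parse")
      m
    })
    if (length(frames) == 0) enm_stop("no frames found", "parse")
    conformer_ensemble(frames, aligned = FALSE)
  }
}

#' Write a conformer ensemble as plain-text frames
#'
#' @param ensemble A `"conformer_ensemble"`.
#' @param path Output path.  Frames are written as N lines of `x y z`
#'   separated by a blank line.
#' @export
write_ensemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    m <- frame_matrix(ensemble, f)
    writeLines(sprintf("%.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), con)
    if (f < n_frames(ensemble)) writeLines("", con)
  }
  invisible(path)
}

#' Centroid conformer of an aligned ensemble
#'
#' Returns the index of the frame with the lowest average mean-square
#' deviation from all frames (the natural reference structure of an
#' ensemble).  Ties go to the lowest index.
#'
#' @param ensemble An aligned `"conformer_ensemble"` (see [kabsch_align()]).
#' @return Frame index (1-based).
#' @export
centroid_of_ensemble <- function(ensemble) {
  if (!ensemble$aligned)
    enm_stop("ensemble must be aligned before centroid selection", "contract")
  X <- ensemble_flat(ensemble)              # F x 3N
  N <- dim(ensemble$coords)[1]
  sq <- rowSums(X^2)
  msd <- (outer(sq, sq, "+") - 2 * tcrossprod(X)) / N
  which.min(rowMeans(msd))
}

#' Write a bead structure as delimited text
#' @param structure A `"bead_structure"`.
#' @param path Output path (TSV: chain, resid, role, x, y, z).
#' @export
write_beads <- function(structure, path) {
  utils::write.table(as.data.frame(structure), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a bead structure as a pseudo-atom PDB file
#'
#' One ATOM record per bead (atom name = the bead's representative atom),
#' so that fixtures round-trip through [parse_structure()] and
#' [extract_beads()].
#'
#' @param structure A `"bead_structure"`.
#' @param path Output path.
#' @export
write_bead_pdb <- function(structure, path) {
  atom <- ifelse(grepl(":", structure$role),
                 sub("^[A-Z]+:", "", structure$role),
                 role_atom_map[structure$role])
  resno <- as.integer(sub("[A-Za-z]*$", "", structure$resid))
  xyz <- as.vector(t(bead_coords(structure)))
  n <- nrow(structure)
  suppressWarnings(bio3d::write.pdb(
    file = path, xyz = xyz, resno = resno, chain = structure$chain,
    resid = rep("G", n), elety = atom, o = rep(1, n), b = rep(0, n)
  ))
  invisible(path)
}
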