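# Internal helpers: classed conditions, seeded RNG scoping, small numerics.

# All package errors carry a reason class so callers (and the CLI) can map
# failure modes to distinct exit codes.
enm_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(paste0("rnaenm_", class), "rnaenm_error", "error", "condition"),
    list(message = paste0("[", toupper(class), "] ", msg), call = NULL)
  ))
}

enm_warn <- function(msg, class = "generic") {
  warning(structure(
    class = c(paste0("rnaenm_", class), "rnaenm_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Rank of a centered coordinate array; 3 means a genuinely 3D point set.
coord_rank <- function(xyz, tol = 1e-8) {
  xc <- sweep(xyz, 2, colMeans(xyz))
  s <- svd(xc, nu = 0, nv = 0)$d
  sum(s > tol * max(s, tol))
}

# Deterministic 32-bit string digest (djb2), for config fingerprints in
# output headers (no cryptographic intent).
config_digest <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "|")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

vapply_num <- function(X, FUN, ...) vapply(X, FUN, numeric(1), ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
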