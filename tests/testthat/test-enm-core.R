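test_that("build_network applies a strict sharp cutoff", {
  two <- make_beads(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(nrow(build_network(two, cutoff = 2)$springs), 1)
  expect_equal(nrow(build_network(two, cutoff = 0.5)$springs), 0)
  expect_equal(nrow(build_network(two, cutoff = 1)$springs), 0)  # strict <

  cloud <- random_cloud(20, box = 15, min_separation = 1.5, seed = 3)
  net <- build_network(cloud, cutoff = 8)
  X <- bead_coords(cloud)
  brute <- sum(as.matrix(dist(X))[upper.tri(diag(20))] < 8)
  expect_equal(nrow(net$springs), brute)
  expect_true(all(net$springs$i < net$springs$j))
  expect_false(anyDuplicated(paste(net$springs$i, net$springs$j)) > 0)
  expect_equal(neighbor_count(net), 2 * brute / 20)
})

test_that("spring and neighbor counts are nondecreasing in the cutoff", {
  cloud <- random_cloud(15, box = 12, min_separation = 1.5, seed = 8)
  counts <- vapply(3:20, function(rc) nrow(build_network(cloud, rc)$springs),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("random null network is fully connected, seeded and uniform", {
  cloud <- random_cloud(4, box = 10, min_separation = 1.5, seed = 5)
  net <- build_random_network(cloud, seed = 11)
  expect_equal(nrow(net$springs), 6)  # N(N-1)/2
  expect_identical(net$cutoff, "none")
  net2 <- build_random_network(cloud, seed = 11)
  expect_identical(net$springs, net2$springs)

  big <- random_cloud(142, box = 60, min_separation = 1.5, seed = 6)
  kk <- build_random_network(big, seed = 1)$springs$k  # 10011 draws
  expect_true(all(kk >= 0 & kk <= 1))
  se <- sqrt(1 / 12 / length(kk))
  expect_lt(abs(mean(kk) - 0.5), 3 * se)
})

test_that("two-bead Hessian has the analytic spectrum and covariance", {
  two <- make_beads(rbind(c(0, 0, 0), c(1, 0, 0)))
  H <- enm_hessian(build_network(two, cutoff = 2))
  ev <- sort(eigen(H, symmetric = TRUE)$values)
  expect_equal(ev[6], 2, tolerance = 1e-12)
  expect_equal(ev[1:5], rep(0, 5), tolerance = 1e-12)
  # rigid translation is annihilated
  tr <- rep(c(1, 0, 0), 2)
  expect_lt(max(abs(H %*% tr)), 1e-12)

  # pseudoinverse covariance: single mode with reciprocal eigenvalue
  mod <- covariance_from_hessian(H, rel_tol = 1e-10)
  expect_equal(sort(mod$values, decreasing = TRUE)[1], 0.5, tolerance = 1e-12)
  expect_equal(sum(mod$values > 1e-12), 1)
  m <- msf(mod)
  expect_equal(m$value, c(0.25, 0.25), tolerance = 1e-12)
  expect_equal(sum(m$value), sum(diag(mod$covariance)), tolerance = 1e-12)
})

test_that("Hessian matches finite differences of the explicit harmonic energy", {
  for (seed in 1:3) {
    net <- connected_network(n = 7, seed = seed)
    H <- enm_hessian(net)
    expect_lt(max(abs(H - fd_hessian(net))), 1e-4)
    # structural invariants
    expect_equal(H, t(H), tolerance = 1e-12)
    N <- nrow(net$structure)
    # translation invariance in all three directions
    for (ax in 1:3) {
      tvec <- rep(0, 3 * N); tvec[seq(ax, 3 * N, by = 3)] <- 1
      expect_lt(max(abs(H %*% tvec)), 1e-12)
    }
  }
})

test_that("zero-mode counts distinguish connected, disjoint and collinear networks", {
  cloud <- random_cloud(10, box = 10, min_separation = 1.5, seed = 2)
  H <- enm_hessian(build_network(cloud, cutoff = 30))
  expect_equal(zero_modes(H)$count, 6)

  # two rigid components: clouds far apart, cutoff below the gap
  c1 <- bead_coords(random_cloud(5, box = 5, min_separation = 1.5, seed = 1))
  c2 <- bead_coords(random_cloud(5, box = 5, min_separation = 1.5, seed = 9))
  both <- make_beads(rbind(c1, c2 + 100))
  H2 <- enm_hessian(build_network(both, cutoff = 20))
  expect_equal(zero_modes(H2)$count, 12)

  chain3 <- make_beads(cbind(0:2, 0, 0))
  H3 <- enm_hessian(build_network(chain3, cutoff = 10))
  expect_equal(zero_modes(H3)$count, 7)
})

test_that("min_viable_cutoff matches a direct zero-mode scan and rejects collinear input", {
  dup <- generate_duplex(n_bp = 4)
  got <- min_viable_cutoff(dup, scan_min = 3, scan_max = 30, step = 1)
  direct <- NULL
  for (rc in 3:30) {
    net <- build_network(dup, rc)
    if (nrow(net$springs) > 0 && zero_modes(enm_hessian(net))$count == 6) {
      direct <- rc; break
    }
  }
  expect_equal(got, direct)
  # a finer grid can only move the answer down within one coarse step
  fine <- min_viable_cutoff(dup, scan_min = 3, scan_max = 30, step = 0.25)
  expect_lte(fine, got)
  expect_gt(fine, got - 1)

  chain <- make_beads(cbind(seq(0, 8, by = 2), 0, 0))
  expect_error(min_viable_cutoff(chain), class = "rnaenm_not_found")
})

test_that("covariance_from_hessian refuses disconnected networks", {
  c1 <- bead_coords(random_cloud(5, box = 5, min_separation = 1.5, seed = 1))
  both <- make_beads(rbind(c1, c1 + 100))
  H <- enm_hessian(build_network(both, cutoff = 20))
  expect_error(covariance_from_hessian(H), class = "rnaenm_connectivity")
})

test_that("pseudoinverse identities and scaling hold on random connected networks", {
  for (seed in c(1, 4, 12)) {
    net <- connected_network(n = 9, seed = seed)
    H <- enm_hessian(net)
    C <- covariance_from_hessian(H)$covariance
    rel <- max(abs(C)) # covariance scale
    expect_lt(max(abs(C %*% H %*% C - C)) / rel, 1e-8)
    expect_lt(max(abs(H %*% C %*% H - H)) / max(abs(H)), 1e-8)
    # k -> c*k multiplies covariance by 1/c
    net2 <- build_network(net$structure, cutoff = net$cutoff, k = 2.5)
    C2 <- covariance_from_hessian(enm_hessian(net2))$covariance
    expect_equal(C2, C / 2.5, tolerance = 1e-10)
  }
})

test_that("rigid rotation conjugates the Hessian and preserves its spectrum", {
  net <- connected_network(n = 8, seed = 21)
  H <- enm_hessian(net)
  set.seed(77)
  R <- random_rotation()
  rot <- make_beads(bead_coords(net$structure) %*% t(R))
  Hr <- enm_hessian(build_network(rot, cutoff = net$cutoff))
  ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  evr <- sort(eigen(Hr, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(evr, ev, tolerance = 1e-10)
  # explicit conjugation by the block rotation
  Rblk <- kronecker(diag(nrow(net$structure)), R)
  expect_lt(max(abs(Rblk %*% H %*% t(Rblk) - Hr)), 1e-10)
})

test_that("effective_hessian reduces exactly: identity keep, marginalization, 3-bead oracle", {
  net <- connected_network(n = 10, seed = 31)
  H <- enm_hessian(net)
  expect_identical(effective_hessian(H, seq_len(10)), H)

  # marginalization: pinv(Schur) equals the rigid-projected covariance sub-block
  Cfull <- covariance_from_hessian(H)$covariance
  for (seed in 1:5) {
    set.seed(seed)
    keep <- sort(sample(10, sample(3:7, 1)))
    Heff <- effective_hessian(H, keep)
    Ceff <- covariance_from_hessian(Heff)$covariance
    idx <- dofi(keep)
    e <- eigen(Heff, symmetric = TRUE)
    Nn <- e$vectors[, e$values < 1e-10 * max(e$values), drop = FALSE]
    P <- diag(length(idx)) - tcrossprod(Nn)
    expect_lt(max(abs(P %*% Cfull[idx, idx] %*% P - Ceff)) / max(abs(Ceff)), 1e-8)
  }

  # 3-bead triangle, eliminate the middle bead: compare against a hand-built
  # block assembly and explicit generalized Schur elimination (the middle
  # bead's two springs leave one locally soft direction, so M_b needs a
  # generalized inverse)
  tri <- make_beads(rbind(c(0, 0, 0), c(1.5, 1, 0.2), c(3, 0, 0)))
  Ht <- enm_hessian(build_network(tri, cutoff = 10))
  X <- bead_coords(tri)
  blk <- function(i, j) {
    u <- (X[i, ] - X[j, ]) / sqrt(sum((X[i, ] - X[j, ])^2))
    tcrossprod(u)
  }
  Ma <- rbind(cbind(blk(1, 2) + blk(1, 3), -blk(1, 3)),
              cbind(-blk(1, 3), blk(2, 3) + blk(1, 3)))
  W <- rbind(-blk(1, 2), -blk(2, 3))
  Mb <- blk(1, 2) + blk(2, 3)
  oracle <- Ma - W %*% MASS::ginv(Mb) %*% t(W)
  got <- effective_hessian(Ht, keep = c(1, 3))
  expect_equal(got, oracle, tolerance = 1e-10, ignore_attr = TRUE)

  # decoupled discarded component is refused
  c1 <- bead_coords(random_cloud(5, box = 5, min_separation = 1.5, seed = 1))
  both <- make_beads(rbind(c1, c1 + 100))
  Hd <- enm_hessian(build_network(both, cutoff = 20))
  expect_error(effective_hessian(Hd, keep = 1:5), class = "rnaenm_reduction")
})

test_that("enm() fit validates geometry and exposes the model surface", {
  dup <- generate_duplex(n_bp = 4)
  fit <- enm(dup, cutoff = 9)
  expect_s3_class(fit, "enm")
  expect_equal(length(msf(fit)$value), nrow(dup))
  expect_output(print(fit), "elastic network")
  s <- summary(fit)
  expect_equal(s$n_springs, nrow(fit$network$springs))
  expect_error(enm(make_beads(cbind(0:4, 0, 0)), cutoff = 5),
               class = "rnaenm_degenerate_geometry")
  # default cutoff is the minimum viable one
  fit_auto <- enm(dup)
  expect_equal(fit_auto$cutoff, min_viable_cutoff(dup))
})

test_that("degenerate geometry in springs is an error", {
  two <- make_beads(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)))
  net <- build_network(two, cutoff = 5)
  expect_error(enm_hessian(net), class = "rnaenm_degenerate_geometry")
})
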