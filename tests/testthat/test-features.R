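make_coords <- function(frames, residues, atoms_per_res, positions) {
  # positions: function(frame, residue, atom) -> c(x, y, z)
  rows <- list()
  for (f in frames) for (r in seq_along(residues))
    for (a in seq_len(atoms_per_res[r])) {
      p <- positions(f, r, a)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, residue = residues[r], atom = paste0("A", a),
        x = p[1], y = p[2], z = p[3])
    }
  do.call(rbind, rows)
}

test_that("contact frequencies obey the strict 5 A rule", {
  # two single-atom residues at fixed separation
  at <- function(d) make_coords(1:5, c("R1", "R2"), c(1, 1),
                                function(f, r, a) c(if (r == 1) 0 else d, 0, 0))
  expect_equal(contact_frequencies(at(4.0))$frequency, 1.0)
  expect_equal(contact_frequencies(at(5.0))$frequency, 0.0) # strictly <
  expect_equal(contact_frequencies(at(4.999))$frequency, 1.0)
  expect_error(contact_frequencies(at(4), window = 99), "empty")
})

test_that("contact frequencies equal an exhaustive brute-force recount", {
  set.seed(42)
  coords <- make_coords(1:20, c("A", "B", "C"), c(2, 3, 1),
                        function(f, r, a) stats::rnorm(3, mean = r * 2, sd = 2))
  cm <- contact_frequencies(coords, cutoff = 5)
  # independent double-loop recount
  for (k in seq_len(nrow(cm))) {
    hits <- 0
    for (f in 1:20) {
      fa <- coords[coords$frame == f & coords$residue == cm$res_i[k], ]
      fb <- coords[coords$frame == f & coords$residue == cm$res_j[k], ]
      dmin <- Inf
      for (i in seq_len(nrow(fa))) for (j in seq_len(nrow(fb)))
        dmin <- min(dmin, sqrt(sum((fa[i, c("x", "y", "z")] -
                                      fb[j, c("x", "y", "z")])^2)))
      if (dmin < 5) hits <- hits + 1
    }
    expect_equal(cm$frequency[k], hits / 20)
  }
})

test_that("differential pair selection uses a strict 0.35 threshold and exclude list", {
  cmap <- function(freqs) structure(
    data.frame(res_i = c("A", "A", "B"), res_j = c("B", "C", "C"),
               frequency = freqs),
    cutoff = 5, window = c(1, 10), class = c("contact_map", "data.frame"))
  expect_equal(nrow(differential_contact_pairs(cmap(c(.9, .5, .1)),
                                               cmap(c(.9, .5, .1)))), 0L)
  d <- differential_contact_pairs(cmap(c(0.9, 0.5, 0.1)),
                                  cmap(c(0.4, 0.5, 0.1)))
  expect_equal(nrow(d), 1L)
  expect_equal(d$abs_diff, 0.5)
  # |diff| exactly at the threshold is rejected
  d2 <- differential_contact_pairs(cmap(c(0.50, 0, 0)), cmap(c(0.15, 0, 0)))
  expect_equal(nrow(d2), 0L)
  # exclude-list hook replaces manual pruning
  d3 <- differential_contact_pairs(cmap(c(0.9, 0.9, 0.1)),
                                   cmap(c(0.1, 0.1, 0.1)),
                                   exclude = cbind("A", "B"))
  expect_equal(nrow(d3), 1L)
  expect_equal(d3$res_j, "C")
  bad <- cmap(c(.1, .1, .1)); bad$res_j <- c("X", "Y", "Z")
  expect_error(differential_contact_pairs(cmap(c(.1, .1, .1)), bad),
               "different residue pairs")
})

test_that("atom-pair expansion yields 4/9/6 features and handles glycine", {
  info <- data.frame(
    residue = c("TRP428", "MET434", "GLY430", "G1", "A2", "C3"),
    kind = c("protein", "protein", "protein", "purine", "purine",
             "pyrimidine"),
    sidechain_atom = c("CH2", "CE", NA, NA, NA, NA))
  pp <- atom_pair_features(data.frame(res_i = "TRP428", res_j = "MET434"),
                           info)
  expect_equal(nrow(pp), 4L)
  rr <- atom_pair_features(data.frame(res_i = c("G1", "G1", "A2"),
                                      res_j = c("A2", "C3", "C3")), info)
  expect_equal(nrow(rr), 27L) # 3 pairs x 9
  expect_true(all(rr$kind == "intra-RNA"))
  pr <- atom_pair_features(data.frame(res_i = "TRP428", res_j = "G1"), info)
  expect_equal(nrow(pr), 6L)
  expect_true(all(pr$kind == "intermolecular"))
  expect_true(all(c("N9") %in% pr$atom_j))
  # glycine collapses to the alpha carbon: 1 x 2 = 2 features
  gly <- atom_pair_features(data.frame(res_i = "GLY430", res_j = "TRP428"),
                            info)
  expect_equal(nrow(gly), 2L)
  expect_error(atom_pair_features(data.frame(res_i = "XXX", res_j = "G1"),
                                  info), "not annotated")
  # total for p/r/m retained pairs is 4p + 9r + 6m
  allp <- rbind(data.frame(res_i = "TRP428", res_j = "MET434"),
                data.frame(res_i = c("G1", "G1", "A2"),
                           res_j = c("A2", "C3", "C3")),
                data.frame(res_i = c("TRP428", "MET434"),
                           res_j = c("G1", "C3")))
  expect_equal(nrow(atom_pair_features(allp, info)), 4 * 1 + 9 * 3 + 6 * 2)
})

test_that("sigmoid transform has the documented midpoint, asymptotes and monotonicity", {
  expect_equal(sigmoid_transform(15), 0.5)
  expect_equal(sigmoid_transform(1e6), 0, tolerance = 1e-12)
  expect_equal(sigmoid_transform(-1e6), 1)
  expect_equal(round(sigmoid_transform(5), 3), 0.982)
  expect_equal(round(sigmoid_transform(25), 3), 0.018)
  # strictly decreasing: reverses the order of any monotone distance trace
  x <- sort(stats::runif(50, 0, 40))
  expect_true(all(diff(sigmoid_transform(x)) < 0))
  expect_error(sigmoid_transform(10, tau_s = 0), "positive")
})

test_that("PCA reduction reports orthonormal loadings and correct spectra", {
  set.seed(7)
  X <- matrix(stats::rnorm(300), 100, 3)
  p <- pca_reduce(X, k = 3)
  expect_equal(sum(p$explained), 1.0, tolerance = 1e-12)
  expect_equal(crossprod(p$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(p$explained) <= 1e-12))
  # 2-D Gaussian with covariance [[2,1],[1,2]]: PC1 along (1,1)/sqrt(2),
  # eigenvalues 3 and 1
  set.seed(8)
  Z <- matrix(stats::rnorm(2e4), ncol = 2)
  A <- chol(matrix(c(2, 1, 1, 2), 2))
  Y <- Z %*% A
  p2 <- pca_reduce(Y, k = 2)
  v1 <- abs(p2$loadings[, 1])
  expect_equal(v1, rep(1 / sqrt(2), 2), tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(p2$explained[1] / p2$explained[2], 3, tolerance = 0.1)
  expect_error(pca_reduce(X, k = 5), "exceeds")
  # frame permutation leaves variance fractions unchanged
  perm <- sample(nrow(X))
  expect_equal(pca_reduce(X[perm, ], k = 2)$explained,
               pca_reduce(X, k = 2)$explained, tolerance = 1e-12)
})
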