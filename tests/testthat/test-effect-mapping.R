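test_that("joint histograms tally correctly and normalize to 1", {
  # x = y over 4 distinct values with 4 bins puts all mass on the diagonal
  v <- c(1, 2, 3, 4)
  h <- joint_histogram(v, v, n_bins = 4L)
  expect_equal(h$joint, diag(0.25, 4))
  expect_equal(sum(h$joint), 1)
  expect_equal(h$px, rowSums(h$joint))
  expect_equal(h$py, colSums(h$joint))
  # seeded samples against a brute-force counting oracle
  set.seed(10)
  x <- rnorm(100); y <- rnorm(100)
  h2 <- joint_histogram(x, y, n_bins = 8L)
  tally <- matrix(0, 8, 8)
  bx <- pmin(8, 1 + floor((x - min(x)) / diff(range(x)) * 8))
  by <- pmin(8, 1 + floor((y - min(y)) / diff(range(y)) * 8))
  for (i in 1:100) tally[bx[i], by[i]] <- tally[bx[i], by[i]] + 1
  expect_equal(h2$joint, tally / 100)
  # constant variable occupies a single bin
  hc <- joint_histogram(rep(2, 10), rnorm(10))
  expect_equal(sum(hc$px > 0), 1L)
})

test_that("entropy matches closed forms", {
  expect_equal(entropy(rep(0.25, 4)), 2)              # uniform over 4 bins
  expect_equal(entropy(c(1, 0, 0)), 0)                # degenerate
  expect_equal(entropy(c(0.5, 0.25, 0.25)),
               -(0.5 * log2(0.5) + 2 * 0.25 * log2(0.25)))  # = 1.5 bits
  expect_error(entropy(c(-0.1, 1.1)), "non-negative")
  expect_error(entropy(c(0.4, 0.4)), "sum to 1")
})

test_that("mutual information equals the relative-entropy double sum", {
  # independence by construction
  px <- c(0.2, 0.5, 0.3); py <- c(0.6, 0.4)
  h_ind <- structure(list(joint = px %o% py, px = px, py = py),
                     class = "joint_histogram")
  expect_equal(mutual_information(h_ind), 0, tolerance = 1e-12)
  # identity: x = y gives I = H(X)
  v <- c(1, 1, 2, 3, 3, 3)
  h_id <- joint_histogram(v, v, n_bins = 3L)
  expect_equal(mutual_information(h_id), entropy(h_id$px), tolerance = 1e-12)
  # random joint tables against the double-sum oracle
  set.seed(11)
  for (rep in 1:20) {
    j <- matrix(rexp(16), 4); j <- j / sum(j)
    h <- structure(list(joint = j, px = rowSums(j), py = colSums(j)),
                   class = "joint_histogram")
    expect_equal(mutual_information(h), oracle_mi_doublesum(j),
                 tolerance = 1e-12)
  }
})

test_that("normalized MI has its closed-form values and conventions", {
  xy <- rep(c(0, 1), 8)                      # fair binary, x = y
  h <- joint_histogram(xy, xy, n_bins = 2L)
  expect_equal(normalized_mi(h), 0.5)        # H / (2H)
  px <- c(0.3, 0.7); py <- c(0.5, 0.5)
  h_ind <- structure(list(joint = px %o% py, px = px, py = py),
                     class = "joint_histogram")
  expect_equal(normalized_mi(h_ind), 0, tolerance = 1e-12)
  hc <- joint_histogram(rep(1, 5), rep(2, 5))
  expect_equal(normalized_mi(hc), 0)         # both constant -> 0 by convention
})

test_that("effect values compose the weight with the NMI per voxel", {
  set.seed(12)
  x <- cbind(rnorm(30), rnorm(30), rnorm(30))
  y <- c(rep(1, 15), rep(-1, 15))
  x[, 1] <- x[, 1] + y          # informative voxel
  s <- intentmvpa:::new_labeled_samples(x, y)
  m <- train_linear_svm(s)
  em <- effect_values(m, s, n_bins = 8L)
  # composition of oracles: w_k * NMI(x_k; decision values)
  dv <- decision_values(m, x)
  for (k in 1:3) {
    j <- joint_histogram(x[, k], dv, n_bins = 8L)$joint
    nmi <- if (sum(j > 0) <= 1) 0 else
      oracle_mi_doublesum(j) /
        (entropy(rowSums(j)) + entropy(colSums(j)))
    expect_equal(em$E[k], m$w[k] * nmi, tolerance = 1e-12)
  }
  # sign(E) follows sign(w); zero weight gives zero effect
  expect_equal(sign(em$E), sign(m$w))
  m0 <- m; m0$w[2] <- 0
  expect_equal(unname(effect_values(m0, s, 8L)$E[2]), 0)
})

test_that("signed-log normalization preserves signs and handles zeros", {
  E <- c(1, -1, 2)
  s <- sqrt(mean((E - mean(E))^2))           # population sd, direct arithmetic
  expect_equal(normalize_effect_map(E),
               sign(E) * log(1 + abs(E) / s))
  expect_equal(normalize_effect_map(c(0, 0, 0)), c(0, 0, 0))
  set.seed(13)
  E2 <- rnorm(50)
  nE <- normalize_effect_map(E2)
  expect_equal(sign(nE), sign(E2))
  # monotone in |E|
  ord <- order(abs(E2))
  expect_true(all(diff(abs(nE)[ord]) >= 0))
})

test_that("group averaging consumes fold-by-participant maps", {
  set.seed(14)
  mk <- function(E) structure(list(E = E, nE = normalize_effect_map(E),
                                   n_voxels = length(E), contrast = "c"),
                              class = "effect_map")
  maps <- replicate(40, mk(rnorm(20)), simplify = FALSE)
  g <- group_average_emaps(maps, fwhm_mm = 0)
  expect_equal(g$n_maps, 40L)
  expect_equal(g$nE, rowMeans(sapply(maps, `[[`, "nE")))
  # identical inputs average to any input
  same <- replicate(4, maps[[1]], simplify = FALSE)
  expect_equal(group_average_emaps(same, fwhm_mm = 0)$nE, maps[[1]]$nE)
  bad <- c(maps[1:2], list(mk(rnorm(5))))
  expect_error(group_average_emaps(bad), "different voxel sets")
})

test_that("top-fraction selection is exact under ties", {
  nE <- c(rep(1, 10), rep(0.5, 490))
  sel <- top_fraction(nE, 0.20)
  expect_equal(sum(sel), 100L)               # ceiling(0.2 * 500)
  expect_true(all(sel[1:10]))                # highest magnitudes first
  expect_equal(which(sel)[11:100], 11:100)   # tie-break by voxel index
  expect_equal(sum(top_fraction(nE, 1.0)), 500L)
  expect_error(top_fraction(numeric(0), 0.2), "empty")
  expect_error(top_fraction(nE, 0), "fraction")
})

test_that("planted voxels receive larger effect magnitudes than null voxels", {
  cfg <- tiny_config(noise_sd = 0.3, n_runs_per_hand = 8L, seed = 21L)
  bold <- simulate_participant(cfg, 1)[[1]]
  masks <- config_roi_masks(cfg)
  both <- intentmvpa:::new_roi_mask("pair",
    masks$PPC$mask | masks$DLPFC$mask)
  z <- z_normalize(apply_mask(bold$data, both))
  lab <- schedule_to_labels(bold$schedule, cfg$delay_trs)
  s <- extract_condition_features(z, lab, "left-vs-right@imageryT1")
  em <- effect_values(train_linear_svm(s), s)
  idx <- attr(apply_mask(bold$data[1:2, ], both), "voxel_index")
  in_ppc <- idx %in% which(masks$PPC$mask)
  expect_gt(mean(abs(em$nE[in_ppc])), 2 * mean(abs(em$nE[!in_ppc])))
})
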