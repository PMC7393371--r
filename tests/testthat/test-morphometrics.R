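test_that("the landmark scheme fixes the tip and base of both curves", {
  sch <- stylet_landmark_scheme()
  expect_equal(sch$fixed, c(1L, 30L, 31L, 60L))
  expect_equal(sch$curves$far, 1:30)
  expect_equal(sch$curves$near, 31:60)
  sch12 <- stylet_landmark_scheme(12L)
  expect_equal(sch12$fixed, c(1L, 6L, 7L, 12L))
  expect_error(stylet_landmark_scheme(7L))
})

test_that("centroid size is exact, scales linearly, ignores translation", {
  sq <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  expect_equal(centroid_size(sq), 2 * sqrt(2))
  expect_equal(centroid_size(3 * sq), 3 * centroid_size(sq))
  expect_equal(centroid_size(sweep(sq, 2, c(10, -4), "+")),
               centroid_size(sq))
  expect_error(centroid_size(matrix(1, 4, 2)), "degenerate")
  # vectorised over an array
  arr <- fixture_shapes(n = 3)
  expect_equal(centroid_size(arr),
               apply(arr, 3, centroid_size))
})

test_that("mirroring negates x and toggles the flag; twice is the identity", {
  m <- fixture_shape()
  expect_equal(mirror_configuration(mirror_configuration(m)), m)
  tb <- tibble::tibble(specimen_id = "s1", landmark = 1:nrow(m),
                       x = m[, 1], y = m[, 2], mirrored = FALSE)
  mt <- mirror_configuration(tb)
  expect_equal(mt$x, -tb$x)
  expect_true(all(mt$mirrored))
  expect_equal(mirror_configuration(mt), tb)
})

test_that("landmark tibbles and arrays round-trip", {
  arr <- fixture_shapes(n = 4)
  attr(arr, "groups") <- setNames(rep(c("a", "b"), 2), dimnames(arr)[[3]])
  tb <- array_to_landmarks(arr)
  back <- landmarks_to_array(tb)
  expect_equal(unclass(back)[seq_along(arr)], as.numeric(arr))
  expect_equal(attr(back, "groups"), attr(arr, "groups"))
  # incomplete specimens are an error
  expect_error(landmarks_to_array(tb[-1, ]), "all 12 landmarks")
})

test_that("GPA recovers copies related by similarity transforms", {
  base <- fixture_shape()
  arr <- array(NA_real_, dim = c(nrow(base), 2, 4))
  arr[, , 1] <- base
  for (i in 2:4) arr[, , i] <- random_similarity(base, seed = i)
  fit <- gpa_align(arr)
  for (i in 2:4) {
    expect_lt(procrustes_distance(fit$aligned[, , 1], fit$aligned[, , i]),
              1e-8)
  }
  expect_equal(apply(fit$aligned, 3, centroid_size), rep(1, 4),
               tolerance = 1e-10)
  expect_equal(centroid_size(fit$consensus), 1, tolerance = 1e-10)
})

test_that("GPA is invariant to input order and to similarity transforms", {
  arr <- fixture_shapes(n = 6)
  fit <- gpa_align(arr)
  # permute specimens
  perm <- c(4, 1, 6, 2, 5, 3)
  fit_p <- gpa_align(arr[, , perm])
  expect_equal(fit_p$consensus, fit$consensus, tolerance = 1e-8)
  expect_equal(fit_p$aligned[, , match(1, perm)], fit$aligned[, , 1],
               tolerance = 1e-8)
  # transform one input arbitrarily (no reflection)
  arr2 <- arr
  arr2[, , 3] <- random_similarity(arr[, , 3], seed = 99)
  fit_t <- gpa_align(arr2)
  expect_equal(fit_t$consensus, fit$consensus, tolerance = 1e-8)
  expect_equal(fit_t$aligned, fit$aligned, tolerance = 1e-8)
})

test_that("GPA never reflects: a mirrored asymmetric shape stays distant", {
  base <- fixture_shape()
  mir <- mirror_configuration(base)
  expect_gt(procrustes_distance(base, mir), 0.1)
  arr <- array(c(base, base, mir), dim = c(nrow(base), 2, 3))
  fit <- gpa_align(arr)
  expect_gt(procrustes_distance(fit$aligned[, , 1], fit$aligned[, , 3]),
            0.1)
})

test_that("GPA residual trace is monotone nonincreasing", {
  arr <- fixture_shapes(n = 8, noise_sd = 0.05)
  fit <- gpa_align(arr)
  expect_true(all(diff(fit$rss_trace) <= 1e-12))
  expect_error(gpa_align(arr[, , 1, drop = FALSE]), "at least two")
})

test_that("Procrustes distance matches the singular-value closed form", {
  set.seed(21)
  a <- fixture_shape()
  b <- a + matrix(rnorm(2 * nrow(a), sd = 0.02), ncol = 2)
  A <- flatmate:::.center_scale(a)
  B <- flatmate:::.center_scale(b)
  s <- svd(crossprod(B, A))
  expect_gt(det(s$u %*% t(s$v)), 0)
  # min over rotations of |A - B R|^2 = 2 - 2 (sigma_1 + sigma_2)
  d_oracle <- sqrt(max(0, 2 - 2 * sum(s$d)))
  expect_equal(procrustes_distance(a, b), d_oracle, tolerance = 1e-10)

  skip_if_not_installed("vegan")
  # the symmetric solution additionally optimises a scaling, so it can
  # only be smaller; for near-identical shapes the two nearly coincide
  v <- vegan::procrustes(A, B, symmetric = TRUE)
  expect_lte(sqrt(v$ss), procrustes_distance(a, b) + 1e-10)
  expect_equal(sqrt(v$ss), procrustes_distance(a, b), tolerance = 0.05)
})

test_that("sliding leaves identical configurations untouched", {
  base <- fixture_shape()
  arr <- array(rep(base, 3), dim = c(nrow(base), 2, 3))
  fit <- gpa_align(arr)
  for (crit in c("bending", "chord")) {
    slid <- slide_semilandmarks(fit, criterion = crit)
    expect_equal(slid$aligned, fit$aligned, tolerance = 1e-6)
    expect_lt(max(slid$slide_trace), 1e-10)
  }
})

test_that("sliding reduces its objective monotonically", {
  arr <- fixture_shapes(n = 8, p = 20, noise_sd = 0.04, seed = 5)
  fit <- gpa_align(arr)
  for (crit in c("bending", "chord")) {
    slid <- slide_semilandmarks(fit, criterion = crit, max_iter = 6)
    expect_true(all(diff(slid$slide_trace) <= 1e-8))
    expect_equal(slid$slide_criterion, crit)
  }
})

test_that("chord sliding moves semilandmarks toward the consensus", {
  arr <- fixture_shapes(n = 8, p = 20, noise_sd = 0.04, seed = 6)
  fit <- gpa_align(arr)
  before <- sum(sweep(fit$aligned, c(1, 2), fit$consensus)^2)
  slid <- slide_semilandmarks(fit, criterion = "chord", max_iter = 10)
  after <- sum(sweep(slid$aligned, c(1, 2), slid$consensus)^2)
  expect_lt(after, before)
})

test_that("relative warps at alpha = 0 match the principal-component oracle", {
  arr <- fixture_shapes(n = 10, noise_sd = 0.03, seed = 8)
  fit <- gpa_align(arr)
  rw <- relative_warps(fit)
  X <- t(apply(fit$aligned, 3, as.vector))
  pc <- prcomp(X)
  k <- rw$n_warps
  scores <- as.matrix(rw$scores[, paste0("RWS", seq_len(k))])
  expect_equal(abs(scores), abs(pc$x[, seq_len(k)]),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(sum(rw$var_explained), 100)
  expect_error(relative_warps(gpa_align(arr[, , 1:2])), "at least 3")
})

test_that("72 configurations yield exactly 71 nonzero relative warps", {
  stylets <- sim_stylets(sim_params(seed = 2))
  fit <- gpa_align(stylets)
  rw <- relative_warps(fit)
  expect_equal(nrow(rw$scores), 72L)
  expect_equal(rw$n_warps, 71L)
})

test_that("nonzero alpha reweights but preserves total variation structure", {
  arr <- fixture_shapes(n = 9, p = 16, noise_sd = 0.03, seed = 12)
  fit <- gpa_align(arr)
  rw0 <- relative_warps(fit, alpha = 0)
  rw1 <- relative_warps(fit, alpha = 1)
  expect_equal(sum(rw1$var_explained), 100)
  expect_lte(rw1$n_warps, rw0$n_warps)
  expect_gt(rw1$n_warps, 0)
})

test_that("thin-plate splines interpolate exactly and vanish on affine maps", {
  ref <- fixture_shape(16L)
  # identity: undeformed grid
  tg <- tps_grid(ref, ref)
  expect_equal(tg$grid$x, tg$grid$x0, tolerance = 1e-9)
  expect_equal(tg$grid$y, tg$grid$y0, tolerance = 1e-9)
  expect_equal(tg$bending_energy, 0, tolerance = 1e-9)
  # pure affine target: zero bending energy
  A <- matrix(c(1.2, 0.3, -0.2, 0.9), 2, 2)
  aff <- ref %*% A + matrix(c(0.5, -0.25), nrow(ref), 2, byrow = TRUE)
  tga <- tps_grid(ref, aff)
  expect_equal(tga$bending_energy, 0, tolerance = 1e-8)
  # non-affine target: exact interpolation at the landmarks
  set.seed(4)
  tgt <- ref + matrix(rnorm(2 * nrow(ref), sd = 0.05), ncol = 2)
  tgn <- tps_grid(ref, tgt)
  expect_gt(tgn$bending_energy, 0)
  expect_equal(tgn$warp(ref), tgt, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("shape and size group comparisons run off relative warps", {
  stylets <- sim_stylets(sim_params(seed = 6))
  rw <- relative_warps(gpa_align(stylets))
  cmp <- compare_shape_groups(rw)
  expect_named(cmp, c("centroid_size", "RWS1"))
  expect_s3_class(cmp$RWS1, "group_comparison")
  # the three stylet classes separate clearly on RWS1
  expect_lt(glance(cmp$RWS1)$p_value, 1e-6)
})

test_that("TPS files round-trip and apply scale factors", {
  lines <- c("LM=3", "0 0", "1 0", "1 2", "ID=worm_1", "SCALE=0.5",
             "LM=3", "0 0", "2 0", "2 1", "ID=worm_2")
  path <- withr::local_tempfile(fileext = ".tps")
  writeLines(lines, path)
  lm <- read_tps(path)
  expect_equal(unique(lm$specimen_id), c("worm_1", "worm_2"))
  expect_equal(lm$x[lm$specimen_id == "worm_1"], c(0, 0.5, 0.5))
  expect_equal(lm$y[lm$specimen_id == "worm_1"], c(0, 0, 1))
  out <- withr::local_tempfile(fileext = ".tps")
  write_tps(lm, out)
  back <- read_tps(out)
  expect_equal(back$x, lm$x, tolerance = 1e-6)
  expect_equal(back$y, lm$y, tolerance = 1e-6)
  expect_equal(back$scale, lm$scale)
  # malformed files fail loudly
  writeLines(c("3", "0 0"), path)
  expect_error(read_tps(path), "LM=")
  writeLines(c("LM=2", "0 0"), path)
  expect_error(read_tps(path), "truncated")
})

test_that("morphometric S3 methods are wired", {
  stylets <- sim_stylets(sim_params(
    seed = 3, stylet = list(n = c(lignano = 4L, hybrid = 4L, janickei = 4L),
                            hybrid_weight = 0.5, hybrid_size = 1.15,
                            noise_sd = 0.01)))
  fit <- gpa_align(stylets)
  expect_output(print(fit), "Procrustes")
  rw <- relative_warps(fit)
  expect_output(print(rw), "Relative warps")
  expect_equal(tidy(rw), rw$scores)
  expect_equal(glance(rw)$n_specimens, 12L)
  tg <- tps_grid(rw$consensus, fit$aligned[, , 1])
  expect_output(print(tg), "bending energy")
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(rw), "ggplot")
  expect_s3_class(autoplot(tg), "ggplot")
})
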