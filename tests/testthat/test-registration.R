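test_that("identity, pure translation and exact rotation are recovered exactly", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1))
  fit <- estimate_rigid(pts, pts)
  expect_equal(fit$transform$theta, 0)
  expect_equal(unname(fit$transform$t), c(0, 0))
  expect_equal(fit$rms_residual, 0)

  fit <- estimate_rigid(pts, sweep(pts, 2, c(3, -2), "+"))
  expect_equal(fit$transform$theta, 0)
  expect_equal(unname(fit$transform$t), c(3, -2))
  expect_equal(fit$rms_residual, 0, tolerance = 1e-12)

  moving <- rbind(c(1, 0), c(0, 1))
  fixed <- rbind(c(0, 1), c(-1, 0))   # 90 degrees about the origin
  fit <- estimate_rigid(moving, fixed)
  expect_equal(fit$transform$theta, pi / 2)
  expect_equal(unname(fit$transform$t), c(0, 0), tolerance = 1e-12)
})

test_that("degenerate landmark input is rejected", {
  expect_error(estimate_rigid(rbind(c(1, 1)), rbind(c(2, 2))), "at least 2")
  expect_error(estimate_rigid(rbind(c(1, 1), c(1, 1)), rbind(c(0, 0), c(2, 2))),
               "coincide")
})

test_that("the closed-form fit never loses to a theta grid-search oracle", {
  set.seed(21)
  for (trial in 1:5) {
    theta <- runif(1, -pi / 2, pi / 2)
    t <- runif(2, -10, 10)
    moving <- matrix(runif(20, 0, 100), ncol = 2)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    fixed <- sweep(moving %*% t(R), 2, t, "+") +
      matrix(rnorm(20, 0, 0.5), ncol = 2)
    fit <- estimate_rigid(moving, fixed)
    expect_lte(fit$rms_residual, grid_search_rms(moving, fixed) + 1e-12)
  }
})

test_that("the fit is invariant to relabelling of point order", {
  set.seed(5)
  moving <- matrix(runif(16, 0, 50), ncol = 2)
  fixed <- matrix(runif(16, 0, 50), ncol = 2)
  f1 <- estimate_rigid(moving, fixed)
  perm <- sample(nrow(moving))
  f2 <- estimate_rigid(moving[perm, ], fixed[perm, ])
  expect_equal(f1$transform$theta, f2$transform$theta)
  expect_equal(f1$transform$t, f2$transform$t)
})

test_that("composing a transform with its inverse gives the identity", {
  set.seed(8)
  for (i in 1:20) {
    tf <- rigid_transform2d(runif(1, -pi, pi), runif(1, -50, 50), runif(1, -50, 50))
    id <- transform_compose(tf, transform_invert(tf))
    expect_lt(abs(id$theta), 1e-9)
    expect_lt(max(abs(id$t)), 1e-9)
    # rigid maps preserve pairwise distances
    pts <- matrix(runif(10, 0, 100), ncol = 2)
    d0 <- dist(pts); d1 <- dist(transform_apply(tf, pts))
    expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  }
})

test_that("noise-free parameter recovery is exact over many random slices", {
  set.seed(33)
  canon <- matrix(runif(24, 10, 90), ncol = 2)
  max_err_theta <- 0; max_err_t <- 0
  for (i in 1:50) {
    applied <- rigid_transform2d(runif(1, -5, 5) * pi / 180,
                                 runif(1, -10, 10), runif(1, -10, 10))
    moving <- transform_apply(applied, canon)
    fit <- estimate_rigid(moving, canon)   # recover the inverse
    inv <- transform_invert(applied)
    max_err_theta <- max(max_err_theta, abs(fit$transform$theta - inv$theta))
    max_err_t <- max(max_err_t, max(abs(fit$transform$t - inv$t)))
  }
  expect_lt(max_err_theta, 1e-6)
  expect_lt(max_err_t, 1e-6)
})

test_that("angular error shrinks as the landmark count grows (noisy landmarks)", {
  set.seed(12)
  mean_err <- vapply(c(4, 16, 64, 256), function(n_lm) {
    errs <- vapply(1:40, function(i) {
      canon <- matrix(runif(2 * n_lm, 0, 100), ncol = 2)
      applied <- rigid_transform2d(runif(1, -0.1, 0.1), runif(1, -5, 5),
                                   runif(1, -5, 5))
      moving <- transform_apply(applied, canon)
      noisy <- canon + matrix(rnorm(2 * n_lm, 0, 1), ncol = 2)
      fit <- estimate_rigid(moving, noisy)
      abs(fit$transform$theta - transform_invert(applied)$theta)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) < 0))
})

test_that("apply_rigid honours the p' = R p + t convention with nearest-neighbour sampling", {
  m <- matrix(0L, 8, 10)
  m[4, 6] <- 200L                       # (x=5, y=3) 0-based
  g <- gray_slice(m, 0)
  out <- apply_rigid(g, transform_identity())
  expect_identical(out$pixels, m)

  out <- apply_rigid(g, rigid_transform2d(0, 1, 0))
  expect_equal(out$pixels[4, 7], 200)   # moved to (x=6, y=3)
  expect_equal(sum(out$pixels), 200)
})

test_that("rotating a point-symmetric image by pi about its centre is a no-op", {
  n <- 15
  m <- matrix(0L, n, n)
  set.seed(2)
  for (i in 1:20) {
    r <- sample(n, 1); c <- sample(n, 1)
    v <- sample(50:250, 1)
    m[r, c] <- v
    m[n + 1 - r, n + 1 - c] <- v        # enforce symmetry about the centre
  }
  cen <- (n - 1) / 2                    # 0-based frame centre
  # rotation by pi about (cen, cen): R = -I, t = 2 * centre
  tf <- rigid_transform2d(pi, 2 * cen, 2 * cen)
  out <- apply_rigid(gray_slice(m, 0), tf)
  expect_identical(out$pixels, m)
})

test_that("align_stack recovers known misalignments from the generator truth", {
  for (mode in c("chain", "direct")) {
    g <- generate_stack(small_spec(misalignment = list(max_rot_deg = 5,
                                                       max_trans_px = 10)))
    slices <- lapply(g$sections, mark_and_grayscale)
    res <- align_stack(slices, g$truth$landmarks_moving, mode = mode)
    ref <- length(slices) %/% 2 + 1
    t_ref <- g$truth$applied_transforms[[ref]]
    for (k in seq_along(slices)) {
      # expected: map slice k's frame into the reference slice's frame
      expected <- transform_compose(t_ref,
                                    transform_invert(g$truth$applied_transforms[[k]]))
      expect_lt(abs(res$transforms[[k]]$theta - expected$theta), 1e-6)
      expect_lt(max(abs(res$transforms[[k]]$t - expected$t)), 1e-6)
    }
    expect_named(res$report, c("slice", "theta_deg", "tx", "ty", "rms"))
  }
})

test_that("single-slice stacks and bad reference indices follow the contract", {
  g <- generate_stack(stack_spec(n_slices = 1, width = 32, height = 32, seed = 2))
  slices <- lapply(g$sections, mark_and_grayscale)
  res <- align_stack(slices, g$truth$landmarks_moving)
  expect_equal(res$transforms[[1]]$theta, 0)
  expect_identical(res$slices[[1]]$pixels, slices[[1]]$pixels)

  expect_error(align_stack(slices, g$truth$landmarks_moving,
                           reference_index = 5), "out of range")
})

test_that("missing landmarks error unless the slice is flagged damaged", {
  g <- generate_stack(small_spec(damaged_slices = 1))
  slices <- lapply(g$sections, mark_and_grayscale)
  lms <- g$truth$landmarks_moving
  lms[[2]] <- NULL; lms <- append(lms, list(NULL), after = 1)  # damaged slice: ok
  res <- align_stack(slices, lms)
  expect_equal(res$transforms[[2]]$theta, 0)

  lms[[4]] <- NULL; lms <- append(lms, list(NULL), after = 3)  # healthy slice: error
  expect_error(align_stack(slices, lms), "not flagged damaged")
})
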