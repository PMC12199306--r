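test_that("centering removes column means and returns the centroid", {
  out <- center_hypershape(matrix(c(0, 2), 2, 1))
  expect_equal(out$centered, matrix(c(-1, 1), 2, 1))
  expect_equal(out$centroid, 1, ignore_attr = TRUE)

  single <- center_hypershape(matrix(c(1, 2, 3), 1, 3))
  expect_equal(unname(single$centered), matrix(0, 1, 3))

  m <- matrix(rnorm(60), 12, 5)
  expect_equal(unname(colMeans(center_hypershape(m)$centered)), rep(0, 5),
               tolerance = 1e-12)
})

test_that("principal axes match geometry and an SVD oracle", {
  # rank-1 cloud along x
  x <- cbind(c(-2, -1, 0, 1, 2), 0, 0)
  pa <- principal_axes(x)
  expect_equal(abs(pa$axes[, 1]), c(1, 0, 0))
  expect_equal(pa$eigenvalues[2:3], c(0, 0))
  expect_gt(pa$eigenvalues[1], 0)

  # SVD oracle on a random 50 x 4 matrix: eigenvalues are squared
  # singular values / A, eigenvectors match up to sign
  set.seed(42)
  m <- center_hypershape(matrix(rnorm(200), 50, 4))$centered
  pa <- principal_axes(m)
  sv <- svd(m)
  expect_equal(pa$eigenvalues, sv$d^2 / 50, tolerance = 1e-8)
  for (k in 1:4) {
    dot <- abs(sum(pa$axes[, k] * sv$v[, k]))
    expect_equal(dot, 1, tolerance = 1e-8)
  }

  # regular tetrahedron: isotropic, three equal eigenvalues
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  pa <- principal_axes(center_hypershape(tet)$centered)
  expect_equal(pa$eigenvalues, rep(pa$eigenvalues[1], 3), tolerance = 1e-10)

  # degenerate inputs: single atom / identical rows
  pa1 <- principal_axes(matrix(0, 1, 3))
  expect_true(pa1$degenerate)
  expect_equal(pa1$eigenvalues, rep(0, 3))
  expect_equal(pa1$axes, diag(3))
})

orient_1d <- function(scores, tol = 1e-4) {
  orient_axes(matrix(1), eigenvalues = 1, centered = matrix(scores),
              tolerance = tol)
}

test_that("the sign-orientation cascade follows the stated walk", {
  # largest |score| is negative -> flip
  fr <- orient_1d(c(-3, 1, 2))
  expect_equal(fr$n_c, 1L)
  expect_equal(as.vector(fr$scores), c(3, -1, -2))
  expect_length(fr$undetermined_axes, 0L)

  # symmetric pair at |2|; discriminant is the -1 at the second level
  fr <- orient_1d(c(-2, 2, -1))
  expect_equal(fr$n_c, 1L)
  expect_equal(as.vector(fr$scores), c(2, -2, 1))

  # positive discriminant after a pair -> no flip
  fr <- orient_1d(c(-2, 2, 1))
  expect_equal(fr$n_c, 0L)

  # fully paired scores: undetermined axis, no flip
  fr <- orient_1d(c(-2, -1, 1, 2))
  expect_equal(fr$n_c, 0L)
  expect_equal(fr$undetermined_axes, 1L)

  # near-symmetric pair within tolerance is still a pair
  fr <- orient_1d(c(-2.00001, 2, -1), tol = 1e-4)
  expect_equal(as.vector(fr$scores), c(2.00001, -2, 1))
})

test_that("determinant bookkeeping holds after every orientation", {
  for (seed in 1:25) {
    m <- generate_fixture("random_cloud", n_atoms = 3 + seed %% 8,
                          seed = seed)
    fr <- pc_frame(build_hypershape(m, "default6d"))
    expect_equal(fr$det_f, fr$det_i * (-1L)^fr$n_c)
    n <- ncol(fr$axes)
    expect_lt(max(abs(crossprod(fr$axes) - diag(n))), 1e-10)
  }
})

test_that("frames are equivariant under rigid motion and invariant under permutation", {
  m <- generate_fixture("random_cloud", n_atoms = 10, seed = 8)
  fr <- pc_frame(build_hypershape(m, "default6d"))
  set.seed(99)
  for (i in 1:10) {
    rot <- random_rotation()
    shift <- rnorm(3, sd = 5)
    fr2 <- pc_frame(build_hypershape(apply_rigid(m, rot, shift), "default6d"))
    expect_equal(fr2$eigenvalues, fr$eigenvalues, tolerance = 1e-8)
    expect_equal(fr2$scores, fr$scores, tolerance = 1e-8)
  }
  perm <- sample(n_atoms(m))
  frp <- pc_frame(build_hypershape(permute_atoms(m, perm), "default6d"))
  expect_equal(frp$axes, fr$axes, tolerance = 1e-10)
  expect_equal(frp$scores, fr$scores[perm, ], tolerance = 1e-10)
})

test_that("mirror images give identical score multisets when chirality is off", {
  for (seed in 1:5) {
    pair <- generate_fixture("mirror_pair", n_atoms = 7, seed = seed)
    f1 <- pc_frame(build_hypershape(pair$original, "3d"))
    f2 <- pc_frame(build_hypershape(pair$mirror, "3d"))
    expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-10)
    for (k in 1:3)
      expect_equal(sort(f1$scores[, k]), sort(f2$scores[, k]),
                   tolerance = 1e-8)
  }
})

test_that("chirality enforcement yields determinant +1 and separates mirror frames", {
  m <- generate_fixture("chiral_tetrahedron", seed = 2)
  mm <- reflect_x(m)
  f1 <- pc_frame(build_hypershape(m, "3d"), chirality = TRUE)
  f2 <- pc_frame(build_hypershape(mm, "3d"), chirality = TRUE)
  expect_equal(f1$det_f, 1L)
  expect_equal(f2$det_f, 1L)
  expect_true(f1$chirality_enforced && f2$chirality_enforced)
  # the two frames are no longer mirror images: their reference points
  # (hence distance distributions) differ
  r1 <- reference_points(f1)
  r2 <- reference_points(f2)
  expect_gt(max(abs(r1 - r2)), 1e-4)

  # enforcing on an already +1 frame is a no-op apart from the flag
  again <- enforce_chirality(f1)
  expect_equal(again$axes, f1$axes)
  expect_equal(again$n_c, f1$n_c)
})

test_that("chirality is refused for mirror-symmetric or flat hypershapes", {
  flat <- generate_fixture("planar", n_atoms = 6, seed = 4)
  expect_warning(fr <- pc_frame(build_hypershape(flat, "3d"),
                                chirality = TRUE),
                 "not applicable")
  expect_false(fr$chirality_enforced)
  rod <- generate_fixture("linear_symmetric")
  expect_warning(pc_frame(build_hypershape(rod, "3d"), chirality = TRUE),
                 "not applicable")
})
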