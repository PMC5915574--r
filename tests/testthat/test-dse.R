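test_that("single-voxel toy decomposition matches hand evaluation", {
  dse <- compute_dse_timeseries(matrix(c(1, 3), nrow = 1))
  expect_equal(dse$whole$A, c(1, 9))
  expect_equal(dse$whole$D, 1)     # ((3-1)/2)^2
  expect_equal(dse$whole$S, 4)     # ((1+3)/2)^2
  expect_equal(dse$whole$E, c(0.5, 4.5))
  av <- dse$averages$whole
  expect_equal(unlist(av), c(A = 5, D = 0.5, S = 2, E = 2.5))
  expect_equal(av$A, av$D + av$S + av$E)
  # single voxel: global equals whole, non-global identically 0
  expect_equal(dse$global, dse$whole)
  expect_equal(unlist(dse$nonglobal), rep(0, 6), ignore_attr = TRUE)
})

test_that("series agree with a brute-force oracle", {
  set.seed(5)
  for (rep in 1:5) {
    Y <- random_scaled(sample(2:40, 1), sample(3:30, 1))
    dse <- compute_dse_timeseries(Y)
    orc <- oracle_dse(Y)
    expect_equal(dse$whole$A, orc$A)
    expect_equal(dse$whole$D, orc$D)
    expect_equal(dse$whole$S, orc$S)
    expect_equal(dse$whole$E, orc$E)
    expect_equal(unlist(dse$averages$whole), orc$avg)
  }
})

test_that("identities and invariants hold for arbitrary random inputs", {
  set.seed(7)
  for (rep in 1:20) {
    Y <- random_scaled(sample(2:100, 1), sample(2:60, 1), sd = runif(1, 0.5, 5))
    dse <- compute_dse_timeseries(Y)
    v <- verify_identities(dse, tol = 1e-8)
    expect_true(v$ok)
    # nonnegativity across all scopes
    for (scope in c("whole", "global", "nonglobal"))
      expect_true(all(unlist(dse[[scope]]) >= 0))
    # scope-level A = D + S + E (global and non-global)
    for (scope in c("global", "nonglobal")) {
      a <- dse$averages[[scope]]
      expect_equal(a$A, a$D + a$S + a$E, tolerance = 1e-10)
    }
  }
})

test_that("symmetry properties: voxel permutation, time reversal, scaling", {
  set.seed(9)
  Y <- random_scaled(30, 15)
  dse <- compute_dse_timeseries(Y)
  perm <- compute_dse_timeseries(Y[sample(nrow(Y)), ])
  expect_equal(perm$whole, dse$whole)
  expect_equal(perm$global, dse$global)
  rev <- compute_dse_timeseries(Y[, ncol(Y):1])
  expect_equal(rev$averages, dse$averages)
  sc <- compute_dse_timeseries(3 * Y)
  expect_equal(sc$whole$A, 9 * dse$whole$A)
  expect_equal(sc$whole$D, 9 * dse$whole$D)
  expect_equal(unlist(sc$averages$whole), 9 * unlist(dse$averages$whole))
})

test_that("constant-in-time voxel gives D = 0, S_t = A_t = c^2", {
  dse <- compute_dse_timeseries(matrix(2.5, 1, 6))
  expect_equal(dse$whole$D, rep(0, 5))
  expect_equal(dse$whole$S, rep(6.25, 5))
  expect_equal(dse$whole$A, rep(6.25, 6))
})

test_that("verify_identities flags a perturbed series", {
  dse <- compute_dse_timeseries(random_scaled(10, 8))
  expect_true(verify_identities(dse)$ok)
  dse$whole$D[2] <- dse$whole$D[2] + 1
  expect_false(verify_identities(dse)$ok)
})

test_that("variance images match their definitions and spatial means", {
  img <- compute_dse_images(matrix(c(1, 3), nrow = 1))
  expect_equal(img$A_img, 5)     # (1 + 9)/2
  expect_equal(img$D_img, 0.5)   # (3-1)^2/(4*2)
  expect_equal(img$S_img, 2)     # (1+3)^2/(4*2)

  set.seed(13)
  Y <- random_scaled(50, 30)
  dse <- compute_dse_timeseries(Y)
  img <- compute_dse_images(Y)
  expect_true(all(img$A_img >= 0 & img$D_img >= 0 & img$S_img >= 0))
  expect_equal(mean(img$A_img), dse$averages$whole$A)
  expect_equal(mean(img$D_img), dse$averages$whole$D)
  expect_equal(mean(img$S_img), dse$averages$whole$S)
  # a single large jump dominates the D image at that voxel
  Y[17, 15] <- Y[17, 15] + 50
  expect_equal(which.max(compute_dse_images(Y)$D_img), 17)
})

test_that("IID D-to-A image ratio matches its nominal value", {
  set.seed(17)
  Y <- matrix(rnorm(4000 * 200), 4000, 200)
  img <- compute_dse_images(Y)
  expect_equal(mean(img$D_img) / mean(img$A_img), 0.5 * 199 / 200,
               tolerance = 0.02)
})

test_that("dvars_series is 2*sqrt(D) and round-trips", {
  expect_equal(dvars_series(c(1, 0, 4.07)), c(2, 0, 2 * sqrt(4.07)))
  expect_equal(dvars_series(4.07), 4.035, tolerance = 1e-3)
  set.seed(19)
  dse <- compute_dse_timeseries(random_scaled(20, 12))
  dv <- dvars_series(dse)
  expect_equal(dv^2 / 4, dse$whole$D, tolerance = 1e-14)
})

test_that("tidy layout is schema-stable", {
  dse <- compute_dse_timeseries(random_scaled(5, 6))
  df <- as.data.frame(dse)
  expect_named(df, c("index", "abscissa", "component", "scope", "value"))
  expect_setequal(unique(df$scope), c("whole", "global", "nonglobal"))
  # D and S live on the half-integer abscissa
  expect_true(all(df$abscissa[df$component %in% c("D", "S")] %% 1 == 0.5))
})
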