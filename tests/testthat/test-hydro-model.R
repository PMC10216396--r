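test_that("built-in scales cover all 20 residues and are nonnegative", {
  for (nm in c("black_mould", "kyte_doolittle")) {
    sc <- hydro_scale(nm)
    expect_length(sc, 20)
    expect_true(all(as.numeric(sc) >= 0))
    expect_equal(max(as.numeric(sc)), 1)
  }
  bm <- hydro_scale("black_mould")
  expect_equal(bm[["F"]], 1)     # phenylalanine most hydrophobic
  expect_equal(bm[["R"]], 0)     # arginine least
})

test_that("scale files round-trip and incomplete scales are rejected", {
  path <- withr::local_tempfile(fileext = ".txt")
  bm <- hydro_scale("black_mould")
  writeLines(c("# test scale", paste(names(bm), as.numeric(bm))), path)
  sc <- hydro_scale(path)
  expect_equal(as.numeric(sc), as.numeric(bm))
  writeLines(c("A 1.0", "G 0.5"), path)
  expect_error(hydro_scale(path), "does not cover")
})

test_that("envelope center, axes and sigma follow the stated rules", {
  # cube corners: full symmetry, equal sigmas, center at origin
  cube <- as.matrix(expand.grid(c(-4, 4), c(-4, 4), c(-4, 4)))
  u <- make_unit(cube, rep("A", 8))
  env <- fit_envelope(u)
  expect_equal(unname(env$center), c(0, 0, 0))
  expect_equal(env$sigma[1], env$sigma[2], tolerance = 1e-9)
  expect_equal(env$sigma[2], env$sigma[3], tolerance = 1e-9)
  expect_equal(crossprod(env$axes), diag(3), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_gt(det(env$axes), 0)
})

test_that("two collinear points give sigma = half-extent/3 with the floor", {
  u <- make_unit(rbind(c(-6, 0, 0), c(6, 0, 0)), c("A", "A"))
  env <- suppressWarnings(fit_envelope(u))
  expect_equal(env$sigma, c(2, 1, 1))          # 6/3 = 2; floor 1 elsewhere
  env2 <- suppressWarnings(fit_envelope(u, sigma_rule = "std_dev"))
  expect_equal(env2$sigma[2:3], c(1, 1))
})

test_that("sigma triple is invariant under rigid motion", {
  u <- generate_unit(synthetic_spec("micelle", n_residues = 40, seed = 11))
  s0 <- fit_envelope(u)$sigma
  for (seed in 1:5) {
    s1 <- fit_envelope(rigid_motion(u, seed))$sigma
    expect_equal(s1, s0, tolerance = 1e-6)
  }
})

test_that("theoretical profile normalizes, stays positive, obeys symmetry", {
  u <- make_unit(rbind(c(-5, 0, 0), c(5, 0, 0)), c("A", "G"))
  expect_equal(theoretical_profile(u, suppressWarnings(fit_envelope(u))),
               c(0.5, 0.5))
  # three collinear points at {-sigma, 0, +sigma}: e^-1/2, 1, e^-1/2
  u3 <- make_unit(rbind(c(-3, 0, 0), c(0, 0, 0), c(3, 0, 0)), rep("A", 3))
  env <- list(center = c(0, 0, 0), axes = diag(3), sigma = c(3, 1, 1))
  raw <- c(exp(-0.5), 1, exp(-0.5))
  expect_equal(theoretical_profile(u3, env), raw / sum(raw))
})

test_that("moving a residue outward from the center lowers its T share", {
  env <- list(center = c(0, 0, 0), axes = diag(3), sigma = c(4, 4, 4))
  base <- rbind(c(2, 0, 0), c(0, 3, 0), c(0, 0, 1), c(-2, -2, 0))
  prev <- Inf
  for (r in seq(2, 12, by = 2)) {
    xyz <- base
    xyz[1, ] <- c(r, 0, 0)
    ti <- theoretical_profile(make_unit(xyz, rep("A", 4)), env)[1]
    expect_lt(ti, prev)
    prev <- ti
  }
})

test_that("observed profile matches the spec's two-residue arithmetic", {
  # custom scale H(A) = 1, H(G) = 2, others irrelevant
  vals <- as.numeric(default_scale)
  names(vals) <- names(default_scale)
  vals["A"] <- 1
  vals["G"] <- 2
  sc <- fodm:::new_hydro_scale(vals, "test")
  c0 <- 9
  # at r = c the bracket vanishes: only self terms (2H) survive
  u <- make_unit(rbind(c(0, 0, 0), c(c0, 0, 0)), c("A", "G"))
  expect_equal(observed_profile(u, sc, cutoff_c = c0),
               c(2, 4) / 6)
  # at r = c/2 the bracket is 189/512 (independent polynomial evaluation)
  u2 <- make_unit(rbind(c(0, 0, 0), c(c0 / 2, 0, 0)), c("A", "G"))
  b <- 189 / 512
  raw <- c(2 * 1 + 3 * b, 2 * 2 + 3 * b)
  expect_equal(observed_profile(u2, sc, cutoff_c = c0), raw / sum(raw))
  # identical residues at any separation split evenly
  u3 <- make_unit(rbind(c(0, 0, 0), c(4, 0, 0)), c("L", "L"))
  expect_equal(observed_profile(u3, sc), c(0.5, 0.5))
})

test_that("self-term flag changes only the self contribution", {
  u <- make_unit(rbind(c(0, 0, 0), c(20, 0, 0), c(40, 0, 0)),
                 c("L", "V", "F"))
  # residues beyond the cutoff interact only with themselves: without the
  # self term the observed sum degenerates
  expect_error(observed_profile(u, include_self = FALSE), "degenerate")
  o <- observed_profile(u, include_self = TRUE)
  h <- as.numeric(default_scale)[match(c("L", "V", "F"),
                                       names(default_scale))]
  expect_equal(o, h / sum(h))
})

test_that("observed profile is invariant to positive scale rescaling", {
  u <- rand_unit(25, seed = 3)
  vals <- as.numeric(default_scale) * 7.3
  names(vals) <- names(default_scale)
  sc2 <- fodm:::new_hydro_scale(vals, "rescaled")
  expect_equal(observed_profile(u, sc2), observed_profile(u, default_scale),
               tolerance = 1e-12)
})

test_that("all-zero hydrophobicity raises the degenerate-distribution error", {
  vals <- stats::setNames(rep(0, 20), names(default_scale))
  sc0 <- fodm:::new_hydro_scale(vals, "zero")
  u <- rand_unit(10, seed = 4)
  expect_error(observed_profile(u, sc0), "degenerate")
})

test_that("T and O are rigid-motion invariant", {
  u <- generate_unit(synthetic_spec("inverted", n_residues = 50, seed = 21))
  t0 <- theoretical_profile(u, fit_envelope(u))
  o0 <- observed_profile(u)
  for (seed in 1:3) {
    v <- rigid_motion(u, seed)
    expect_equal(theoretical_profile(v, fit_envelope(v)), t0,
                 tolerance = 1e-6)
    expect_equal(observed_profile(v), o0, tolerance = 1e-6)
  }
})
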