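test_that("force-curve TSV round trip and metadata validation", {
  cv <- synthForceCurve(10e3, n = 50L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeForceCurve(cv, path)
  back <- loadForceCurve(path)
  expect_equal(back@z, cv@z)
  expect_equal(back@d, cv@d, tolerance = 1e-12)
  expect_equal(back@kSpring, 0.25)
  expect_equal(back@RTip, 2.5e-6)

  lines <- readLines(path)
  writeLines(lines[!grepl("k_spring", lines)], path)
  expect_error(loadForceCurve(path), "k_spring")

  nonmono <- c("# k_spring: 0.25", "# sensitivity: 5e-8",
               "# R_tip: 2.5e-6", "# nu: 0.5",
               "0\t0", "1e-6\t0", "0.5e-6\t0")
  writeLines(nonmono, path)
  expect_error(loadForceCurve(path), "monotone")
})

test_that("force and indentation arithmetic", {
  cv <- methods::new("ForceCurve", z = seq(0, 1e-6, length.out = 5),
                     d = rep(40e-9, 5), kSpring = 0.25,
                     sensitivity = 5e-8, RTip = 2.5e-6, nu = 0.5,
                     direction = "approach")
  fi <- forceIndentation(cv, z0 = 0)
  expect_equal(fi$F, rep(10e-9, 5))  # k d = 0.25 * 40 nm = 10 nN
  expect_equal(fi$delta, cv@z - 40e-9)
  expect_true(fi$preContact[1])

  # at z = z0 with d = 0: delta = 0 and F = 0
  cvg <- methods::new("ForceCurve", z = c(0, 1e-6, 2e-6, 3e-6),
                      d = c(0, 0, 0, 0.5e-6), kSpring = 0.25,
                      sensitivity = 5e-8, RTip = 2.5e-6, nu = 0.5,
                      direction = "approach")
  fig <- forceIndentation(cvg, 2e-6)
  expect_identical(fig$F[3], 0)
  expect_identical(fig$delta[3], 0)
  expect_false(fig$preContact[3])

  # all points pre-contact: empty fit set, flagged by hertzFit
  cv0 <- synthForceCurve(10e3, z0 = 2e-6, n = 100L)
  fiAll <- forceIndentation(cv0, max(cv0@z))
  fit <- hertzFit(fiAll$F, fiAll$delta, 2.5e-6)
  expect_identical(qcFlags(fit), "too_few_points")
  expect_error(forceIndentation(cv0, -1), "range")
})

test_that("contact point is recovered and flat curves flagged", {
  cv <- synthForceCurve(10e3, z0 = 2e-6, n = 400L)
  spacing <- diff(cv@z[1:2])
  cp <- estimateContactPoint(cv)
  expect_false(cp$noContact)
  expect_lt(abs(cp$z0 - 2e-6), spacing)

  flat <- methods::new("ForceCurve", z = seq(0, 1e-6, length.out = 100),
                       d = rep(0, 100), kSpring = 0.25, sensitivity = 5e-8,
                       RTip = 2.5e-6, nu = 0.5, direction = "approach")
  expect_true(estimateContactPoint(flat)$noContact)
  expect_error(estimateContactPoint(
    methods::new("ForceCurve", z = 1:5 * 1e-7, d = rep(0, 5), kSpring = 0.25,
                 sensitivity = 5e-8, RTip = 2.5e-6, nu = 0.5,
                 direction = "approach")), "20 samples")

  # graceful degradation under noise (SNR 20 on a 10 nN curve)
  errs <- vapply(1:20, function(s) {
    noisy <- synthForceCurve(10e3, z0 = 2e-6, noiseSd = 0.5e-9,
                             seed = s, n = 400L)
    abs(estimateContactPoint(noisy)$z0 - 2e-6) / spacing
  }, numeric(1))
  expect_lte(median(errs), 3)
})

test_that("Hertz fit inverts the generator and respects the force window", {
  for (E in c(1e3, 5e3, 20e3, 100e3)) {
    for (R in c(1e-6, 2.5e-6, 5e-6)) {
      cv <- synthForceCurve(E, RTip = R, n = 300L)
      fit <- fitForceCurve(cv)
      expect_lte(abs(youngsModulus(fit) - E) / E, 1e-6)
      expect_gt(fit@rSquared, 1 - 1e-9)
    }
  }
  # prefactor algebra: E = 3 m (1 - nu^2) / (4 sqrt(R))
  delta <- seq(1e-8, 1e-6, length.out = 50)
  m <- 4 * 12e3 * sqrt(2.5e-6) / (3 * 0.75)
  fit <- hertzFit(m * delta^1.5, delta, 2.5e-6, nu = 0.5, window = c(0.2, 0.8))
  expect_equal(youngsModulus(fit), 12e3, tolerance = 1e-12)

  # window retains exactly the points with 0.2 Fmax <= F <= 0.8 Fmax
  F <- seq_len(100) / 100 * 10e-9
  fit2 <- hertzFit(F, (F / m)^(2 / 3), 2.5e-6, window = c(0.2, 0.8))
  expect_equal(fit2@nPoints, sum(F >= 0.2 * max(F) & F <= 0.8 * max(F)))
})

test_that("fitted modulus is linear in force and resampling-invariant", {
  cv <- synthForceCurve(8e3, n = 300L)
  fi <- forceIndentation(cv, estimateContactPoint(cv)$z0)
  fit1 <- hertzFit(fi$F, fi$delta, cv@RTip)
  fit2 <- hertzFit(2 * fi$F, fi$delta, cv@RTip)
  expect_equal(youngsModulus(fit2), 2 * youngsModulus(fit1),
               tolerance = 1e-12)
  dense <- synthForceCurve(8e3, n = 1200L)
  expect_equal(youngsModulus(fitForceCurve(dense)),
               youngsModulus(fitForceCurve(cv)), tolerance = 0.01)
})

test_that("QC filter logs rejection reasons", {
  mk <- function(E, r2, flags = character()) {
    methods::new("HertzFit", E = E, z0 = 0, window = c(0.2, 0.8),
                 rSquared = r2, nPoints = 50L, qcFlags = flags)
  }
  fits <- list(mk(5e3, 0.99), mk(6e3, 0.5), mk(5e9, 0.99),
               mk(NA_real_, NA_real_, "no_contact"))
  qc <- qcFilter(fits, r2Min = 0.9, EMax = 1e6)
  expect_length(qc$accepted, 1L)
  expect_identical(qc$rejected$reason,
                   c("low_r_squared", "unphysically_stiff", "no_contact"))
  all3 <- list(mk(5e3, 0.99), mk(6e3, 0.95))
  expect_length(qcFilter(all3)$accepted, 2L)
})

test_that("stiffness maps respect shape, masks and summaries", {
  mk <- function(E) methods::new("HertzFit", E = E, z0 = 0,
                                 window = c(0.2, 0.8), rSquared = 0.99,
                                 nPoints = 50L, qcFlags = character())
  set.seed(8)
  Es <- runif(24 * 24, 2e3, 30e3)
  fits <- lapply(Es, mk)
  coords <- cbind(rep(1:24, each = 24), rep(1:24, 24))
  map <- buildStiffnessMap(fits, coords)
  expect_identical(dim(youngsModulus(map)), c(24L, 24L))
  expect_equal(attr(map, "summary")$median, median(Es))

  mask <- matrix(FALSE, 24, 24); mask[1:4, ] <- TRUE  # hair shaft rows
  map2 <- buildStiffnessMap(fits, coords, mask = mask)
  expect_true(all(is.na(youngsModulus(map2)[1:4, ])))
  expect_equal(attr(map2, "summary")$n, 24 * 24 - 4 * 24)
  expect_error(buildStiffnessMap(fits[c(1, 1)], coords[c(1, 1), ],
                                 shape = c(24, 24)), "duplicate")
})

test_that("region comparison is exact for small samples and powered at scale", {
  res <- compareRegions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.1)
  self <- compareRegions(c(2, 5, 9, 11), c(2, 5, 9, 11))
  expect_equal(self$p, 1)
  expect_error(compareRegions(1:2, 1:5), ">= 3")

  # location shift of one pooled SD, ~150 measurements per region
  set.seed(9)
  hits <- mean(replicate(100, {
    a <- rnorm(150, 10, 2)
    b <- rnorm(150, 12, 2)
    compareRegions(a, b)$p < 0.01
  }))
  expect_gte(hits, 0.95)
})
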