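test_that("attend-OUT pooling draws equal numbers from each condition", {
  p <- pool_attend_out(1:50, 101:150, seed = 3)
  expect_length(p, 100)
  expect_equal(sum(p <= 50), 50)
  p2 <- pool_attend_out(1:30, 101:150, seed = 3)
  expect_length(p2, 60) # equal-number rule: min(30, 50) from each
  expect_equal(sum(p2 <= 30), 30)
  expect_identical(pool_attend_out(1:30, 101:150, seed = 3), p2)
  expect_false(identical(pool_attend_out(1:50, 101:150, seed = 4), p))
  expect_error(pool_attend_out(integer(0), 1:5), "non-empty")
})

test_that("the modulation index follows its formula and is antisymmetric", {
  expect_equal(modulation_index(2, 1), 1 / 3)
  expect_equal(modulation_index(1, 1), 0)
  expect_equal(modulation_index(3, 0), 1)
  a <- runif(20); b <- runif(20)
  expect_equal(modulation_index(a, b), -modulation_index(b, a))
  expect_true(all(abs(modulation_index(a, b)) <= 1))
  expect_true(is.na(modulation_index(0, 0)))
})

test_that("wilcoxon_fdr corrects within families and flags unusable tests", {
  set.seed(31)
  n <- 12
  strong <- matrix(rep(abs(rnorm(n)) + 0.5, 3), 3, n, byrow = TRUE)
  null_d <- matrix(rnorm(5 * n), 5, n)
  diffs <- rbind(strong, null_d)
  fam <- factor(c(rep("a", 3), rep("b", 5)))
  res <- wilcoxon_fdr(diffs, family = fam, q = 0.05)
  expect_true(all(res$significant[1:3]))
  expect_true(all(res$q_value[res$family == "a"] <= 0.05))
  # mirrored samples: zero differences leave nothing to test
  res0 <- wilcoxon_fdr(matrix(0, 1, n))
  expect_true(res0$skipped)
  expect_false(res0$significant)
  # fewer than 5 non-tied pairs is skipped
  res1 <- wilcoxon_fdr(c(0.1, -0.2, 0.3, 0, 0, 0, 0))
  expect_true(res1$skipped)
})

test_that("family-wise correction is independent across bands", {
  set.seed(32)
  n <- 20
  one_strong <- abs(rnorm(n)) + 1
  many_null <- matrix(rnorm(30 * n, sd = 5), 30, n)
  # same strong test, alone in its family vs drowned among nulls
  res <- wilcoxon_fdr(rbind(one_strong, many_null),
                      family = factor(c("solo", rep("crowd", 30))))
  expect_true(res$significant[1])
})

test_that("dominance matrices are antisymmetric and empty under symmetry", {
  set.seed(33)
  n_ses <- 12
  sym <- array(rep(1, n_ses * 3 * 3), c(n_ses, 3, 3)) +
    array(rnorm(n_ses * 9, sd = 1e-3), c(n_ses, 3, 3))
  # make it exactly direction-symmetric per session
  for (s in seq_len(n_ses)) sym[s, , ] <- (sym[s, , ] + t(sym[s, , ])) / 2
  dm <- dominance_matrix(sym)
  expect_true(all(dm$matrix == 0))
  # a genuinely dominant 1 -> 2 direction
  dom <- sym
  dom[, 1, 2] <- dom[, 1, 2] + 0.5
  dm2 <- dominance_matrix(dom)
  expect_gt(dm2$matrix[1, 2], 0)
  expect_equal(dm2$matrix[2, 1], -dm2$matrix[1, 2])
  # swapping direction labels flips every sign
  flipped <- array(0, dim(dom))
  for (s in seq_len(n_ses)) flipped[s, , ] <- t(dom[s, , ])
  dm3 <- dominance_matrix(flipped)
  expect_equal(dm3$matrix, t(dm2$matrix))
  expect_error(dominance_matrix(dom[1:3, , ]), "at least 5 sessions")
})

test_that("cGC band normalization scales each group to its own maximum", {
  v <- c(theta = 1, alpha = 2, beta = 4, low_gamma = 0.5, high_gamma = 1)
  expect_equal(unname(normalize_cgc(v)), c(0.25, 0.5, 1, 0.125, 0.25))
  expect_equal(unname(normalize_cgc(c(a = 3))), 1)
  m <- rbind(g1 = c(1, 2), g2 = c(10, 5))
  nm <- normalize_cgc(m)
  expect_equal(unname(apply(nm, 1, max)), c(1, 1))
  expect_error(normalize_cgc(c(0, 0)), "zero maximum")
})

test_that("compartment pooling averages directed pairs and excludes unassigned", {
  comp <- c("supragranular", "supragranular", "granular", "infragranular", "unassigned")
  vals <- matrix(2, 5, 5)
  pooled <- compartment_pool(vals, comp)
  expect_true(all(pooled == 2, na.rm = TRUE))
  expect_equal(attr(pooled, "n")["granular", "granular"], 0L) # single contact, no self-pairs
  # effect confined to granular -> supragranular
  vals2 <- matrix(0.1, 5, 5)
  vals2[3, 1:2] <- 5
  pooled2 <- compartment_pool(vals2, comp)
  expect_equal(unname(pooled2["granular", "supragranular"]), 5)
  expect_true(all(pooled2[pooled2 != 5] <= 0.1, na.rm = TRUE))
})

test_that("SMI preserves the time-frequency grid and vanishes for identical maps", {
  set.seed(34)
  ep <- array(abs(rnorm(6 * 1 * 768)), c(6, 1, 768))
  tf <- sliding_spectrogram(ep, 1017.375, taper_spec(3, 2, 256), step_ms = 40)
  s0 <- smi(tf, tf)
  expect_equal(dim(s0$values), dim(tf$values))
  expect_true(all(s0$values == 0 | is.na(s0$values)))
  tf2 <- tf; tf2$values <- tf$values * 3
  s1 <- smi(tf2, tf)
  expect_equal(s1$values[is.finite(s1$values)],
               rep(0.5, sum(is.finite(s1$values))))
  tf3 <- sliding_spectrogram(ep[, , 1:700, drop = FALSE], 1017.375,
                             taper_spec(3, 2, 256), step_ms = 40)
  expect_error(smi(tf, tf3), "grids do not match")
  tfneg <- tf; tfneg$values[1] <- -1
  expect_error(smi(tfneg, tf), "nonnegative")
})

test_that("repeated-measures ANOVA flags a genuine condition effect", {
  set.seed(35)
  base <- rnorm(12)
  vals <- cbind(RF = base + 1.5, OUT1 = base + rnorm(12, sd = 0.2),
                OUT2 = base + rnorm(12, sd = 0.2))
  res <- attention_anova(vals)
  expect_lt(res$p, 0.01)
  null_vals <- cbind(RF = rnorm(12), OUT1 = rnorm(12), OUT2 = rnorm(12))
  res0 <- attention_anova(null_vals)
  expect_true(res0$p >= 0 && res0$p <= 1)
})
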