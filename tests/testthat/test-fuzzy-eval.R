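test_that("min-max membership maps column extremes to 0 and 1", {
  t1 <- table1_fixture()
  r <- build_membership_matrix(t1$scores)
  expect_equal(r["Pazufloxacin", "3IP9"], 1.0)     # column max
  expect_equal(r["Balofloxacin", "2L0W"], 0.0)     # column min
  # interior value by direct hand arithmetic on the score column
  expect_equal(r["Difloxacin", "3N8V"],
               (97.120 - 63.247) / (99.890 - 63.247), tolerance = 5e-4)
  expect_true(all(r >= 0 & r <= 1))
  expect_true(all(apply(r, 2, max) == 1) && all(apply(r, 2, min) == 0))
})

test_that("smaller_is_better mirrors the membership", {
  s <- cbind(a = c(1, 2, 4))
  expect_equal(drop(build_membership_matrix(s, "smaller_is_better")),
               c(1, 2/3, 0), ignore_attr = TRUE)
})

test_that("degenerate endpoints error, naming the endpoint", {
  s <- cbind(ok = c(1, 2), flat = c(3, 3))
  expect_error(build_membership_matrix(s), "flat")
})

test_that("weighted aggregation reproduces the published CEIs", {
  t1 <- table1_fixture()
  cei <- composite_index(build_membership_matrix(t1$scores), t1$weights)
  expect_equal(cei$cei_display[cei$compound == "Pazufloxacin"], 0.925)
  expect_equal(cei$cei_display[cei$compound == "Difloxacin"], 0.687)
})

test_that("identical membership rows make the weights marginalize out", {
  r <- matrix(rep(c(0.2, 0.7, 0.4), each = 3), nrow = 3,
              dimnames = list(paste0("c", 1:3), paste0("e", 1:3)))
  out <- composite_index(r, c(0.5, 0.3, 0.2))
  expect_equal(out$cei, unname(rowSums(r * rep(c(0.5, 0.3, 0.2), each = 3))))
  # a compound with constant memberships gets exactly that value
  r2 <- matrix(0.6, 2, 3, dimnames = list(c("a", "b"), paste0("e", 1:3)))
  expect_equal(composite_index(r2, c(0.5, 0.4, 0.1))$cei, c(0.6, 0.6))
})

test_that("weight validation rejects bad vectors", {
  r <- matrix(runif(6), 2, 3, dimnames = list(c("a", "b"), paste0("e", 1:3)))
  expect_error(composite_index(r, c(0.5, 0.5)), "mismatch")
  expect_error(composite_index(r, c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(composite_index(r, c(-0.1, 1.0, 0.1)), "non-negative")
})

test_that("relative change is the signed percent difference", {
  expect_equal(relative_change(0.619, 0.925), -33.081, tolerance = 1e-4)
  expect_equal(relative_change(5, 5), 0)
  expect_equal(round_half_up(relative_change(0.140, 1.140), 2), -87.72)
  expect_error(relative_change(1, 0), "nonzero")
})

test_that("evaluate_table reproduces the whole published CEI column", {
  t1 <- table1_fixture()
  out <- evaluate_table(t1$scores, t1$weights)
  expect_equal(nrow(out), 29L)
  expect_true(all(abs(out$cei - t1$cei_printed) <= 5e-4))
  expect_identical(out$cei_display, unname(t1$cei_printed))
})

test_that("single-endpoint table returns the memberships as CEI", {
  s <- cbind(only = c(2, 8, 5))
  rownames(s) <- paste0("c", 1:3)
  out <- evaluate_table(s, 1.0)
  expect_equal(out$cei, out$r_only)
})

test_that("symmetric 2x2 score pattern gives equal CEIs", {
  s <- cbind(e1 = c(0, 1), e2 = c(1, 0))
  rownames(s) <- c("a", "b")
  out <- evaluate_table(s, c(0.5, 0.5))
  expect_equal(out$cei, c(0.5, 0.5))
})

test_that("membership and CEI are invariant to affine endpoint rescaling", {
  t1 <- table1_fixture()
  r0 <- build_membership_matrix(t1$scores)
  s2 <- t1$scores
  s2[, "3N8V"] <- 3.7 * s2[, "3N8V"] + 11.2
  r2 <- build_membership_matrix(s2)
  expect_equal(r2, r0, tolerance = 1e-12)
  expect_equal(composite_index(r2, t1$weights)$cei,
               composite_index(r0, t1$weights)$cei, tolerance = 1e-12)
})

test_that("CEI is bounded in [0,1] and 1 for an all-max compound", {
  set.seed(42)
  for (rep in 1:20) {
    s <- matrix(rnorm(8 * 4), 8, 4,
                dimnames = list(paste0("c", 1:8), paste0("e", 1:4)))
    s[1, ] <- apply(s, 2, max) + 1  # compound 1 dominates every endpoint
    w <- abs(rnorm(4)); w <- w / sum(w)
    cei <- composite_index(build_membership_matrix(s), w)$cei
    expect_true(all(cei >= -1e-12 & cei <= 1 + 1e-12))
    expect_equal(cei[1], 1.0)
  }
})

test_that("raising a score on a larger-is-better endpoint never lowers CEI", {
  set.seed(7)
  for (rep in 1:20) {
    s <- matrix(rnorm(6 * 3), 6, 3,
                dimnames = list(paste0("c", 1:6), paste0("e", 1:3)))
    w <- abs(rnorm(3)); w <- w / sum(w)
    before <- composite_index(build_membership_matrix(s), w)$cei
    i <- sample(6, 1); j <- sample(3, 1)
    s[i, j] <- s[i, j] + runif(1, 0, 2)
    after <- composite_index(build_membership_matrix(s), w)$cei
    expect_gte(after[i], before[i] - 1e-12)
  }
})
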