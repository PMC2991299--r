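test_that("label_components uses 8-connectivity with deterministic labels", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE       # diagonal touch: one component
  m[5, 5] <- TRUE                        # isolated pixel: another
  lab <- label_components(m)
  expect_equal(lab[1, 1], 1L)
  expect_equal(lab[2, 2], 1L)
  expect_equal(lab[5, 5], 2L)
  expect_equal(sum(lab > 0), 3)

  # 4-connectivity would split this diagonal staircase
  st <- matrix(FALSE, 4, 4)
  st[cbind(1:4, 1:4)] <- TRUE
  expect_equal(max(label_components(st)), 1L)

  expect_equal(label_components(matrix(FALSE, 3, 3)), matrix(0L, 3, 3))
})

test_that("label partitions match the flood-fill oracle on random images", {
  set.seed(11)
  for (i in 1:25) {
    m <- matrix(runif(100) < 0.45, 10, 10)
    a <- label_components(m)
    b <- oracle_label(m)
    # same partition: every label of one maps to exactly one of the other
    expect_equal(max(a), max(b))
    for (l in seq_len(max(a)))
      expect_equal(length(unique(b[a == l])), 1L)
  }
})

test_that("largest_signed_component honours sign, region, point and min_area", {
  v <- matrix(0, 6, 6)
  v[2:3, 2:3] <- 5          # positive blob, 4 px
  v[5:6, 5:6] <- -7         # negative blob, 4 px
  v[1, 6] <- 2              # positive speck, 1 px
  all6 <- matrix(TRUE, 6, 6)

  pos <- largest_signed_component(v, 1, all6)
  expect_equal(sum(pos), 4)
  expect_true(all(pos[2:3, 2:3]))

  neg <- largest_signed_component(v, -1, all6)
  expect_true(all(neg[5:6, 5:6]))

  # min_area filters the speck even when the blob is excluded by the region
  reg <- matrix(TRUE, 6, 6); reg[2:3, 2:3] <- FALSE
  expect_equal(sum(largest_signed_component(v, 1, reg, min_area = 2L)), 0)

  # required_point selects the containing component (0-based coords)
  m <- largest_signed_component(v, 1, all6, required_point = c(0, 5))
  expect_equal(sum(m), 1)
  expect_true(m[1, 6])
  # point in background: empty mask is a valid result
  expect_equal(sum(largest_signed_component(v, 1, all6,
                                            required_point = c(0, 0))), 0)

  expect_error(largest_signed_component(v, 1, matrix(FALSE, 6, 6)),
               "empty search region")
})
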