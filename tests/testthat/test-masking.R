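test_that("median filter matches a brute-force disc median on a fixed patch", {
  set.seed(3)
  patch <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
  got <- median_filter(patch, 1)

  # brute-force oracle: reflect-pad, sort each disc neighborhood
  r <- 1
  pad <- patch[c(r:1, 1:5, 5:(5 - r + 1)), c(r:1, 1:5, 5:(5 - r + 1))]
  offs <- subset(expand.grid(dy = -1:1, dx = -1:1), dy^2 + dx^2 <= 1)
  want <- matrix(0L, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    vals <- mapply(function(dy, dx) pad[i + r + dy, j + r + dx],
                   offs$dy, offs$dx)
    want[i, j] <- as.integer(median(vals))
  }
  expect_identical(got, want)
})

test_that("median filter identity, impulse removal and idempotence", {
  const <- matrix(37L, 8, 8)
  expect_identical(median_filter(const, 2), const)

  expect_identical(median_filter(const, 0), const)

  imp <- matrix(0L, 9, 9); imp[5, 5] <- 255L
  expect_true(all(median_filter(imp, 1) == 0L))

  # idempotent on a piecewise-constant image away from the boundary
  pc <- matrix(10L, 16, 16); pc[, 9:16] <- 200L
  once <- median_filter(pc, 2)
  expect_identical(median_filter(once, 2), once)
})

test_that("Otsu threshold matches the exhaustive maximizer", {
  # two equal spikes: flat objective over [50, 199], tie broken at 50
  h <- integer(256); h[50 + 1] <- 100L; h[200 + 1] <- 100L
  expect_identical(otsu_threshold(h), 50L)

  # degenerate single-level histogram
  h <- integer(256); h[128 + 1] <- 42L
  expect_identical(otsu_threshold(h), 128L)

  h <- integer(256); h[40 + 1] <- 100L; h[220 + 1] <- 300L
  expect_identical(otsu_threshold(h), otsu_brute(h))

  set.seed(101)
  for (i in 1:200) {
    h <- random_histogram()
    expect_identical(otsu_threshold(h), otsu_brute(h))
  }
})

test_that("moments threshold matches the direct Tsai solution", {
  # degenerate single-level histogram
  h <- integer(256); h[70 + 1] <- 9L
  expect_identical(moments_threshold(h), 70L)

  # two equal spikes: darker class fraction 0.5, threshold separates them
  h <- integer(256); h[50 + 1] <- 100L; h[200 + 1] <- 100L
  t <- moments_threshold(h)
  expect_gte(t, 50L); expect_lt(t, 200L)
  expect_identical(t, moments_oracle(h))

  # trimodal fixed histogram against the reference oracle
  h <- integer(256)
  h[30 + 1] <- 150L; h[120 + 1] <- 60L; h[210 + 1] <- 90L
  expect_identical(moments_threshold(h), moments_oracle(h))

  set.seed(202)
  for (i in 1:200) {
    h <- random_histogram()
    expect_identical(moments_threshold(h), moments_oracle(h))
  }
})

test_that("thresholding marks dark (stain-positive) pixels", {
  ch <- matrix(c(0L, 100L, 200L), 1, 3)
  expect_equal(apply_threshold(ch, 100), matrix(c(TRUE, TRUE, FALSE), 1, 3))
  expect_true(all(apply_threshold(ch, 255)))
  expect_equal(sum(apply_threshold(ch, 0)), 1)
})

test_that("overlap exclusion: pixel subtracts, component removes regions", {
  tumor <- matrix(FALSE, 8, 8); tumor[1:4, 1:2] <- TRUE
  stroma <- matrix(FALSE, 8, 8)
  stroma[1:4, 2:4] <- TRUE    # component 1, half-covered by tumor
  stroma[7:8, 6:8] <- TRUE    # component 2, disjoint

  px <- exclude_overlap(stroma, tumor, "pixel")
  cm <- exclude_overlap(stroma, tumor, "component")

  expect_false(any(px & tumor))
  expect_false(any(cm & tumor))
  # pixel mode keeps the uncovered part of component 1
  expect_equal(sum(px), sum(stroma) - sum(stroma & tumor))
  # component mode drops component 1 entirely, keeps component 2
  expect_equal(sum(cm), 6)
  expect_true(all(cm[7:8, 6:8]))
  expect_lte(sum(cm), sum(px))

  # disjoint masks pass through; identical masks vanish
  expect_identical(exclude_overlap(stroma, matrix(FALSE, 8, 8), "pixel"), stroma)
  expect_identical(exclude_overlap(stroma, matrix(FALSE, 8, 8), "component"), stroma)
  expect_false(any(exclude_overlap(tumor, tumor, "pixel")))
  expect_false(any(exclude_overlap(tumor, tumor, "component")))
  expect_error(exclude_overlap(stroma, matrix(FALSE, 4, 4)), "shape")
})

test_that("component labelling is 8-connected", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE  # diagonal touch = one component
  m[4, 4] <- TRUE
  tumor <- matrix(FALSE, 4, 4); tumor[1, 1] <- TRUE
  out <- exclude_overlap(m, tumor, "component")
  expect_false(out[2, 2])  # removed with its diagonal neighbor
  expect_true(out[4, 4])
})

test_that("four-sides criterion requires tumor in all four edge bands", {
  all_t <- matrix(TRUE, 40, 40)
  expect_true(four_sides_qc(all_t))

  center <- matrix(FALSE, 40, 40); center[15:25, 15:25] <- TRUE
  expect_false(four_sides_qc(center))

  three <- matrix(FALSE, 40, 40)
  three[1, 20] <- TRUE; three[40, 20] <- TRUE; three[20, 1] <- TRUE
  expect_false(four_sides_qc(three))  # east missing
  three[20, 40] <- TRUE
  expect_true(four_sides_qc(three))

  # monotone: adding tumor pixels never turns pass into fail
  set.seed(5)
  m <- matrix(FALSE, 40, 40)
  pass_seen <- FALSE
  for (i in 1:60) {
    m[sample(40, 1), sample(40, 1)] <- TRUE
    p <- four_sides_qc(m)
    if (pass_seen) expect_true(p)
    pass_seen <- pass_seen || p
  }
})

test_that("EpCAM-negativity flag uses a strict area-fraction cutoff", {
  empty <- matrix(FALSE, 10, 10)
  expect_true(epcam_negativity_flag(empty, 0.01))
  expect_false(epcam_negativity_flag(matrix(TRUE, 10, 10), 0.01))
  at_cut <- matrix(FALSE, 10, 10); at_cut[1, 1] <- TRUE  # exactly 1%
  expect_false(epcam_negativity_flag(at_cut, 0.01))
})
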