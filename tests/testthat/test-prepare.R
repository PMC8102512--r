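# Manifest rows without backing files, for protocol-only tests.
fake_manifest <- function(counts) {
  rows <- do.call(rbind, lapply(seq_along(counts), function(k) {
    g <- k - 1L
    n <- counts[k]
    data.frame(image_id = sprintf("g%d_%06d", g, seq_len(n)),
               path = sprintf("g%d_%06d.png", g, seq_len(n)),
               grade = g, split = "unassigned",
               stringsAsFactors = FALSE)
  }))
  for (col in drsaliency:::manifest_mask_cols()) rows[[col]] <- "m.png"
  rows
}

test_that("rebalancing the published EyePACS distribution gives the cap", {
  man <- fake_manifest(unname(eyepacs_class_counts()))
  out <- rebalance(man, cap = 500, seed = 4)
  expect_identical(as.integer(table(out$grade)), rep(500L, 5))
  # undersampling never repeats a row; oversampling must
  for (g in 0:4) {
    ids <- out$image_id[out$grade == g]
    if (eyepacs_class_counts()[g + 1] >= 500)
      expect_identical(anyDuplicated(ids), 0L)
    else expect_gt(sum(duplicated(ids)), 0L)
  }
  expect_identical(out, rebalance(man, cap = 500, seed = 4))
})

test_that("rebalance degenerate cases behave as contracted", {
  man <- fake_manifest(c(4, 4, 4, 4, 4))
  out <- rebalance(man, cap = 4, seed = 1)
  expect_setequal(out$image_id, man$image_id)   # a permutation
  one <- fake_manifest(c(1, 1, 1, 1, 1))
  out1 <- rebalance(one, cap = 4, seed = 1)
  expect_identical(as.integer(table(out1$image_id)), rep(4L, 5))
  empty_grade <- fake_manifest(c(2, 2, 2, 2, 2))
  empty_grade <- empty_grade[empty_grade$grade != 3, ]
  expect_identical(as.integer(table(rebalance(empty_grade, 2,
                                              seed = 1)$grade)),
                   rep(2L, 4))
})

test_that("stratified split matches fractions and is deterministic", {
  man <- fake_manifest(rep(20L, 5))
  out <- split_manifest(man, c(0.8, 0.1, 0.1), seed = 6)
  expect_identical(sum(out$split == "train"), 80L)
  expect_identical(sum(out$split == "val"), 10L)
  expect_identical(sum(out$split == "test"), 10L)
  expect_identical(out, split_manifest(man, c(0.8, 0.1, 0.1), seed = 6))
  # per-grade proportions within one row of the overall proportions
  for (g in 0:4) {
    sub <- out[out$grade == g, ]
    expect_lte(abs(sum(sub$split == "train") - 16), 1)
    expect_lte(abs(sum(sub$split == "val") - 2), 1)
    expect_lte(abs(sum(sub$split == "test") - 2), 1)
  }
  expect_error(split_manifest(fake_manifest(c(2, 5, 5, 5, 5))),
               "grade 0")
})

test_that("oversampled duplicates never straddle splits", {
  man <- fake_manifest(c(3, 40, 40, 40, 40))
  man <- rebalance(man, cap = 40, seed = 2)   # grade 0 heavily duplicated
  out <- split_manifest(man, seed = 3)
  per_id <- split(out$split, out$image_id)
  for (sp in per_id) expect_identical(length(unique(sp)), 1L)
})

test_that("augmentation identity and involution cases are exact", {
  af <- fixture_fundus()
  ident <- augment(af, rotation = 0, shift = 0, zoom = 0,
                   flip_horizontal = FALSE, flip_vertical = FALSE,
                   seed = 1)
  expect_identical(ident$image, af$image)
  expect_identical(ident$masks, af$masks)
  once <- augment(af, rotation = 0, shift = 0, zoom = 0,
                  flip_horizontal = TRUE, flip_vertical = FALSE,
                  force_flips = TRUE, seed = 1)
  expect_false(identical(once$image, af$image))
  twice <- augment(once, rotation = 0, shift = 0, zoom = 0,
                   flip_horizontal = TRUE, flip_vertical = FALSE,
                   force_flips = TRUE, seed = 2)
  expect_identical(twice$image, af$image)
  expect_identical(twice$masks, af$masks)
})

test_that("90-degree rotation equals the index-permutation oracle", {
  af <- fixture_fundus()
  rot <- transform_annotated(af, theta = pi / 2)
  # oracle: counter-clockwise quarter turn is the index permutation
  # out[n+1-j, i] = m[i, j], i.e. reverse the rows of the transpose
  rot90_oracle <- function(m) t(m)[nrow(m):1, , drop = FALSE]
  for (comp in dr_components()) {
    oracle <- rot90_oracle(af$masks[[comp]])
    expect_identical(sum(rot$masks[[comp]]), sum(af$masks[[comp]]))
    expect_identical(unname(rot$masks[[comp]]), unname(oracle))
  }
})

test_that("augmented masks stay binary and inside the frame", {
  af <- fixture_fundus()
  aug <- augment(af, seed = 31)   # default full-strength ranges
  for (comp in dr_components())
    expect_true(all(aug$masks[[comp]] %in% c(0L, 1L)))
  expect_true(all(aug$image >= 0 & aug$image <= 1))
})
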