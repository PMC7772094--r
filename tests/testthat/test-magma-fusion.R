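stack16 <- function(...) simulate_atlas_stack(grid_shape = c(16, 16, 16), ...)

test_that("jacobian similarity is 1 for the target's own map and -1 for its negation", {
  st <- stack16(n_candidates = 3, seed = 2)
  r <- jacobian_similarity(st$target_jacobian, list(st$target_jacobian), st$mask)
  expect_equal(r, 1, tolerance = 1e-12)
  neg <- 2 - st$target_jacobian  # affine negation; raw scale keeps it exact
  r2 <- jacobian_similarity(st$target_jacobian, list(neg), st$mask,
                            log_scale = FALSE)
  expect_equal(r2, -1, tolerance = 1e-12)
})

test_that("similarity matches the hand-evaluated Pearson formula on 5 voxels", {
  tj <- array(1, c(5, 1, 1)); cj <- array(1, c(5, 1, 1))
  tj[, 1, 1] <- c(1.0, 1.1, 0.9, 1.2, 0.8)
  cj[, 1, 1] <- c(1.0, 1.2, 0.8, 1.3, 0.7)
  mask <- array(TRUE, c(5, 1, 1))
  # oracle: direct formula on the 5 pairs (raw scale)
  x <- c(1.0, 1.1, 0.9, 1.2, 0.8); y <- c(1.0, 1.2, 0.8, 1.3, 0.7)
  xm <- x - mean(x); ym <- y - mean(y)
  r_hand <- sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  expect_equal(
    jacobian_similarity(tj, list(cj), mask, log_scale = FALSE), r_hand,
    tolerance = 1e-12)
})

test_that("zero-variance candidate scores NA with a warning and ranks last", {
  st <- stack16(n_candidates = 2, seed = 3)
  flat <- array(1, dim(st$target_jacobian))
  expect_warning(
    r <- jacobian_similarity(st$target_jacobian,
                             list(st$candidate_jacobians[[1]], flat), st$mask),
    "zero-variance")
  expect_true(is.na(r[2]))
  sel <- select_exemplars(r, 2)
  expect_equal(sel$chosen, c(1L, 2L))
})

test_that("exemplar selection takes the top-k with deterministic tie-breaks", {
  sel <- select_exemplars(c(0.9, 0.5, 0.1), 2)
  expect_equal(sel$chosen, c(1L, 2L))
  sel_tie <- select_exemplars(c(0.5, 0.5, 0.5), 2)
  expect_equal(sel_tie$chosen, c(1L, 2L))
  expect_warning(sel_all <- select_exemplars(c(0.2, 0.8), 5), "exceeds")
  expect_equal(sel_all$chosen, c(2L, 1L))
})

test_that("exemplar ranking reproduces the generated correlation ladder", {
  ladder <- c(0.5, 0.9, 0.1)
  st <- stack16(n_candidates = 3, jacobian_correlations = ladder, seed = 4)
  r <- jacobian_similarity(st$target_jacobian, st$candidate_jacobians, st$mask)
  # by construction the in-mask log-scale correlations equal the ladder
  expect_equal(r, ladder, tolerance = 1e-10)
  sel <- select_exemplars(r, 3)
  expect_equal(sel$chosen, order(ladder, decreasing = TRUE))
})

test_that("unanimous votes win regardless of weights; zero disagreement gives the truth back", {
  st <- stack16(n_candidates = 4, n_label_sets = 2, disagreement = 0, seed = 5)
  sel <- select_exemplars(
    jacobian_similarity(st$target_jacobian, st$candidate_jacobians, st$mask), 4)
  fused <- fuse_labels(st, sel)
  expect_identical(fused$labels, st$true_labels)
})

test_that("weighted majority: the similar atlas's label wins at every voxel", {
  # two candidates; candidate 1's intensity matches the target exactly,
  # candidate 2 is far off, so candidate 1's weight dominates everywhere
  dims <- c(8, 8, 8)
  target <- array(100 + seq_len(prod(dims)) %% 7, dims)
  labA <- array(1L, dims); labB <- array(2L, dims)
  st <- list(target_intensity = target,
             candidate_intensities = list(target, target + 50),
             candidate_labels = list(list(labA), list(labB)),
             mask = array(TRUE, dims), voxel_dims = c(1, 1, 1))
  class(st) <- "atlas_stack"
  sel <- list(chosen = 1:2, scores = c(1, 0), k = 2)
  class(sel) <- "exemplar_selection"
  fused <- fuse_labels(st, sel)
  expect_true(all(fused$labels == 1L))
  # and ties go to the lowest code: identical intensities, different labels
  st$candidate_intensities <- list(target, target)
  fused_tie <- fuse_labels(st, sel)
  expect_true(all(fused_tie$labels == 1L))
})

test_that("fusion is invariant to atlas order and its labels come from the inputs", {
  st <- stack16(n_candidates = 5, n_label_sets = 3, disagreement = 0.2, seed = 6)
  scores <- jacobian_similarity(st$target_jacobian, st$candidate_jacobians, st$mask)
  fused <- fuse_labels(st, select_exemplars(scores, 5))
  perm <- c(4, 1, 5, 3, 2)
  st2 <- st
  st2$candidate_intensities <- st$candidate_intensities[perm]
  st2$candidate_labels <- st$candidate_labels[perm]
  st2$candidate_jacobians <- st$candidate_jacobians[perm]
  scores2 <- jacobian_similarity(st2$target_jacobian, st2$candidate_jacobians, st2$mask)
  fused2 <- fuse_labels(st2, select_exemplars(scores2, 5))
  expect_identical(fused$labels, fused2$labels)
  input_codes <- unique(unlist(lapply(st$candidate_labels, lapply, unique)))
  expect_true(all(unique(as.vector(fused$labels)) %in% input_codes))
})

test_that("single exemplar with a single label set reproduces that label map", {
  st <- stack16(n_candidates = 2, n_label_sets = 1, disagreement = 0.3, seed = 7)
  sel <- list(chosen = 2L, scores = c(0, 1), k = 1)
  class(sel) <- "exemplar_selection"
  fused <- fuse_labels(st, sel)
  expect_identical(fused$labels, st$candidate_labels[[2]][[1]])
})

test_that("volumes are voxel counts times voxel volume and sum exactly to ICV", {
  lab <- array(0L, c(10, 10, 10))
  lab[1:10, 1, 1] <- 7L
  v <- extract_volumes(lab, voxel_dims = c(1, 1, 1),
                       region_dictionary = c("7" = "pons"))
  expect_equal(unname(v$volumes["pons"]), 10)
  expect_equal(v$icv, 10)
  # anisotropic voxels
  v2 <- extract_volumes(lab, voxel_dims = c(0.5, 2, 1.5),
                        region_dictionary = c("7" = "pons"))
  expect_equal(unname(v2$volumes["pons"]), 10 * 1.5)
  # empty map
  v3 <- extract_volumes(array(0L, c(4, 4, 4)))
  expect_equal(length(v3$volumes), 0)
  expect_equal(v3$icv, 0)
})

test_that("volumes match brute-force per-code counting on a random map", {
  set.seed(8)
  lab <- array(sample(0:4, 4096, replace = TRUE), c(16, 16, 16))
  vd <- c(1.2, 0.9, 1.1)
  v <- extract_volumes(lab, voxel_dims = vd)
  for (code in 1:4) {
    cnt <- 0L  # naive loop oracle
    for (i in seq_along(lab)) if (lab[i] == code) cnt <- cnt + 1L
    expect_equal(unname(v$volumes[paste0("region_", code)]), cnt * prod(vd))
  }
  expect_equal(sum(v$volumes), v$icv)
})

test_that("a label code absent from the dictionary is an error", {
  lab <- array(c(0L, 3L), c(2, 1, 1))
  expect_error(extract_volumes(lab, c(1, 1, 1), region_dictionary = c("1" = "a")),
               "missing from region dictionary")
})

test_that("mismatched grids are rejected", {
  st <- stack16(n_candidates = 2, seed = 9)
  st$candidate_intensities[[2]] <- array(0, c(8, 8, 8))
  sel <- list(chosen = 1:2, scores = c(1, 1), k = 2)
  class(sel) <- "exemplar_selection"
  expect_error(fuse_labels(st, sel), "grid")
  expect_error(fuse_labels(st, structure(list(chosen = integer(0)),
                                         class = "exemplar_selection")))
})

test_that("atlas stacks round-trip through NIfTI files", {
  st <- stack16(n_candidates = 2, n_label_sets = 2, seed = 10)
  dir <- tempfile("stack")
  write_atlas_stack(st, dir)
  st2 <- read_atlas_stack(dir)
  expect_equal(st2$target_intensity, unclass(st$target_intensity),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(st2$mask, st$mask, ignore_attr = TRUE)
  expect_equal(st2$candidate_labels[[1]][[2]], st$candidate_labels[[1]][[2]],
               ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
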