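test_that("cosine similarity matches its definition", {
  expect_equal(cosine_similarity(c(2, 1, 0), c(2, 1, 0)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero vector")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "length")
  set.seed(1)
  for (i in 1:10) {
    a <- rnorm(300); b <- rnorm(300)
    ref <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))  # independent arithmetic
    expect_equal(cosine_similarity(a, b), ref, tolerance = 1e-12)
    expect_gte(cosine_similarity(a, b), -1); expect_lte(cosine_similarity(a, b), 1)
  }
})

test_that("decoys partition into positives, excluded band and negative candidates", {
  known <- pocket_at(c(0, 0, 0), id = "known")
  mk <- function(d_nm, id) pocket_at(c(d_nm * 10, 0, 0), id = id)
  decoys <- list(mk(0.25, "a"), mk(0.5, "b"), mk(1.2, "c"))
  part <- label_decoys(known, decoys)
  expect_equal(vapply(part$positives, `[[`, character(1), "id"), "a")
  expect_equal(vapply(part$excluded_band, `[[`, character(1), "id"), "b")
  expect_equal(vapply(part$negative_candidates, `[[`, character(1), "id"), "c")
  # boundary values fall in the excluded band, and the partition is exhaustive
  set.seed(3)
  for (rep in 1:5) {
    ds <- runif(10, 0, 3)
    decoys <- lapply(seq_along(ds), function(i) mk(ds[i], as.character(i)))
    part <- label_decoys(known, decoys)
    expect_equal(length(part$positives) + length(part$excluded_band) +
                   length(part$negative_candidates), 10)
  }
  part <- label_decoys(known, list(mk(0.3, "edge1"), mk(1.0, "edge2")))
  expect_length(part$excluded_band, 2)
})

test_that("negative sampling takes all when short, k distinct otherwise, reproducibly", {
  expect_equal(select_negatives(list("a", "b"), k = 3), list("a", "b"))
  ten <- as.list(letters[1:10])
  got <- select_negatives(ten, k = 3, seed = 5)
  expect_length(got, 3)
  expect_length(unique(unlist(got)), 3)
  expect_identical(got, select_negatives(ten, k = 3, seed = 5))
  expect_length(select_negatives(list(), k = 3), 0)
})

test_that("similarity filter removes near-collinear vectors at the cutoff", {
  known <- c(1, 2, 3, 4)
  vecs <- rbind(known, c(-2, 1, 0, 0), -known)  # sim = 1, 0, -1
  keep <- similarity_filter(vecs, known, cutoff = 0.995)
  expect_equal(unname(as.logical(keep)), c(FALSE, TRUE, TRUE))
  expect_equal(attr(keep, "similarity"), c(1, 0, -1), tolerance = 1e-12)
  # removal at S >= cutoff: an exact duplicate survives only below cutoff 1 boundary
  expect_false(similarity_filter(matrix(known, 1), known, cutoff = 1.0)[1])
  # raising the cutoff never removes more
  set.seed(2)
  vs <- matrix(rnorm(40), nrow = 10)
  k1 <- sum(similarity_filter(vs, known, cutoff = 0.8))
  k2 <- sum(similarity_filter(vs, known, cutoff = 0.95))
  expect_gte(k2, k1)
  # zero-norm candidate is retained with a warning
  expect_warning(kz <- similarity_filter(rbind(c(0, 0, 0, 0)), known), "zero vector")
  expect_true(kz[1])
})

test_that("fixed normalization applies the reference affine map exactly", {
  params <- reference_norm_params("near_native")
  expect_equal(params$mean, -0.5696)
  expect_equal(params$std, 30.8744)
  out <- normalize_features(matrix(c(-0.5696, 30.3048), 1), params)
  expect_identical(out[1, 1], 0)
  expect_equal(out[1, 2], 1.0)
  native <- reference_norm_params("native")
  expect_equal(c(native$mean, native$std), c(-0.9610, 63.6607))
  expect_error(norm_params("fixed", mean = 0, std = 0), "positive")
})

test_that("self normalization yields global mean 0 and sd 1, and inverts exactly", {
  set.seed(8)
  X <- matrix(rnorm(50 * 60, mean = 3, sd = 7), nrow = 50)
  Xn <- normalize_features(X, norm_params("self"))
  expect_equal(mean(Xn), 0, tolerance = 1e-9)
  expect_equal(sd(as.vector(Xn)), 1, tolerance = 1e-9)
  params <- attr(Xn, "norm_params")
  expect_equal(denormalize_features(Xn, params), X, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(normalize_features(matrix(1, 3, 3), norm_params("self")),
               "zero standard deviation")
})

test_that("dataset build follows the labeling protocol for both strategies", {
  tab <- tiny_table(dim = 16)
  tc <- make_toy_complex(c(0.1, 0.2, 0.5, 1.5, 2.0, 2.5), seed = 7)
  cx <- list(id = "toy", structure = tc$structure, ligand = tc$ligand,
             decoys = tc$pockets)
  ds <- build_dataset(list(cx), tab, "near_native", seed = 11)
  expect_equal(sum(ds$y == 1), 2)
  expect_equal(sum(ds$y == 0), 3)
  expect_equal(ncol(ds$X), 32)
  expect_true(all(ds$meta$center_distance_nm[ds$meta$label == 1] < 0.3))
  expect_true(all(ds$meta$center_distance_nm[ds$meta$label == 0] > 1.0))

  dsn <- build_dataset(list(cx), tab, "native", seed = 11)
  expect_equal(sum(dsn$y == 1), 1)
  expect_equal(sum(dsn$y == 0), 3)
  # native positive pairs the known pocket with the ligand
  expect_equal(dsn$meta$center_distance_nm[dsn$meta$label == 1], 0)

  # a duplicate-composition decoy at 2 nm is removed by the similarity
  # filter and negatives are unchanged
  tcd <- make_toy_complex(c(0.1, 0.2, 0.5, 1.5, 2.0, 2.5), seed = 7,
                          duplicate_decoy = TRUE)
  cxd <- list(id = "toy", structure = tcd$structure, ligand = tcd$ligand,
              decoys = tcd$pockets)
  dsd <- build_dataset(list(cxd), tab, "near_native", seed = 11)
  expect_equal(sum(dsd$y == 0), 3)
  expect_false("7" %in% dsd$meta$pocket_id)

  # bit-for-bit reproducible under a fixed seed
  ds2 <- build_dataset(list(cx), tab, "near_native", seed = 11)
  expect_identical(ds$X, ds2$X)
  expect_identical(ds$meta, ds2$meta)

  # positive replication knob
  ds3 <- build_dataset(list(cx), tab, "near_native", seed = 11,
                       replicate_positives = 3)
  expect_equal(sum(ds3$y == 1), 6)
})

test_that("datasets round-trip through the plain-text writer", {
  tab <- tiny_table(dim = 16)
  tc <- make_toy_complex(c(0.1, 1.5, 2.0), seed = 2)
  cx <- list(id = "toy", structure = tc$structure, ligand = tc$ligand,
             decoys = tc$pockets)
  ds <- build_dataset(list(cx), tab, "near_native", seed = 4)
  dir <- tempfile()
  write_dataset(ds, dir, params = reference_norm_params("near_native"))
  back <- read_dataset(dir)
  expect_equal(back$X, ds$X, tolerance = 1e-9)
  expect_equal(back$y, ds$y)
  expect_equal(back$meta$pocket_id, as.character(ds$meta$pocket_id))
  np <- attr(back, "norm_params")
  expect_equal(np$mean, -0.5696)
  expect_equal(np$std, 30.8744)
})
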