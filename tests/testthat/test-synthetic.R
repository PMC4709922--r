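# Synthetic data generation with planted ground truth.

test_that("null configuration produces plain decoy matrices with empty truth", {
  spec <- synthetic_spec(n_genes = 10, n_samples_a = 5, n_samples_b = 5,
                         n_differential = 0, shift = 0, seed = 1)
  ds <- generate_expression_dataset(spec)
  expect_equal(dim(ds$matrix_a), c(10, 5))
  expect_equal(dim(ds$matrix_b), c(10, 5))
  expect_length(ds$truth$differential_gene_ids, 0)
  expect_equal(nrow(ds$truth$triplet_records), 0)
  expect_true(all(ds$matrix_a >= 0) && all(ds$matrix_b >= 0))
})

test_that("identical specs give bit-identical data; differential bookkeeping holds", {
  spec <- synthetic_spec(n_genes = 15, n_samples_a = 12, n_samples_b = 9,
                         n_differential = 3, shift = 5,
                         planted_triplets = list(planted_triplet(1, 2, 3, "3", 0.2)),
                         seed = 2)
  d1 <- generate_expression_dataset(spec)
  d2 <- generate_expression_dataset(spec)
  expect_identical(d1$matrix_a, d2$matrix_a)
  expect_identical(d1$matrix_b, d2$matrix_b)
  expect_length(d1$truth$differential_gene_ids, 3)
  # differential genes never overlap planted triplet genes
  expect_length(intersect(d1$truth$differential_gene_ids,
                          c("g001", "g002", "g003")), 0)
})

test_that("invalid spec fields raise errors naming the field", {
  expect_error(synthetic_spec(n_genes = 0), "n_genes")
  expect_error(synthetic_spec(n_genes = 5, n_differential = 6), "n_differential")
  expect_error(synthetic_spec(n_genes = 5, n_samples_a = -1), "n_samples_a")
  expect_error(planted_triplet(1, 1, 2, "1", 0), "distinct")
  expect_error(planted_triplet(1, 2, 3, "9", 0))
  expect_error(planted_triplet(1, 2, 3, "1", 1.5), "noise_prob")
  expect_error(synthetic_spec(n_genes = 3,
                              planted_triplets = list(planted_triplet(1, 2, 4, "1", 0))),
               "beyond n_genes")
})

test_that("planting gives perfect dependence at noise 0 and independence at noise 1", {
  spec0 <- synthetic_spec(n_genes = 8, n_samples_a = 50, n_samples_b = 5,
                          planted_triplets = list(planted_triplet(1, 2, 3, "1", 0)),
                          seed = 7)
  ds0 <- generate_expression_dataset(spec0)
  norm <- t(apply(ds0$matrix_a, 1, minmax_normalize))
  dl <- discretize_matrix(norm, k = 1)
  f <- apply_proper_function("1", dl[["g001"]], dl[["g002"]])
  expect_equal(uncertainty(f, dl[["g003"]])$value, 1)

  spec1 <- synthetic_spec(n_genes = 8, n_samples_a = 2000, n_samples_b = 5,
                          planted_triplets = list(planted_triplet(1, 2, 3, "1", 1)),
                          seed = 8)
  ds1 <- generate_expression_dataset(spec1)
  norm1 <- t(apply(ds1$matrix_a, 1, minmax_normalize))
  dl1 <- discretize_matrix(norm1, k = 1)
  f1 <- apply_proper_function("1", dl1[["g001"]], dl1[["g002"]])
  expect_lt(uncertainty(f1, dl1[["g003"]])$value, 0.01)

  expect_error(plant_logic_triplet(ds0$matrix_a, 1, 1, 3, "1", 0), "distinct")
  expect_error(plant_logic_triplet(ds0$matrix_a, 1, 2, 99, "1", 0), "out of range")
})

test_that("the planted function outscores every non-equivalent function under noise", {
  spec <- synthetic_spec(n_genes = 8, n_samples_a = 50, n_samples_b = 5,
                         planted_triplets = list(planted_triplet(1, 2, 3, "1", 0.2)),
                         seed = 7)
  ds <- generate_expression_dataset(spec)
  norm <- t(apply(ds$matrix_a, 1, minmax_normalize))
  dl <- discretize_matrix(norm, k = 1)
  A <- dl[["g001"]]; B <- dl[["g002"]]; C <- dl[["g003"]]
  us <- vapply(logic_types(), function(ty) {
    uncertainty(apply_proper_function(ty, A, B), C)$value
  }, numeric(1))
  equiv <- equivalent_logic_types("1")
  expect_true(all(us[equiv] > us[setdiff(logic_types(), equiv)]))
  expect_equal(best_second_order(A, B, C)$logic_type, "1")
})

test_that("recovered-triplet precision does not increase with noise", {
  precision_at <- function(noise, seeds) {
    mean(vapply(seeds, function(s) {
      spec <- synthetic_spec(
        n_genes = 12, n_samples_a = 40, n_samples_b = 5,
        planted_triplets = list(planted_triplet(1, 2, 3, "3", noise),
                                planted_triplet(4, 5, 6, "1", noise)),
        seed = s)
      ds <- generate_expression_dataset(spec)
      rel <- scan_condition(ds, t = 0.3)
      if (!nrow(rel)) return(NA_real_)
      planted_keys <- paste(
        pmin(ds$truth$triplet_records$source_a, ds$truth$triplet_records$source_b),
        pmax(ds$truth$triplet_records$source_a, ds$truth$triplet_records$source_b),
        ds$truth$triplet_records$target)
      got_keys <- paste(pmin(rel$source_a, rel$source_b),
                        pmax(rel$source_a, rel$source_b), rel$target)
      mean(got_keys %in% planted_keys)
    }, numeric(1)), na.rm = TRUE)
  }
  seeds <- 1:20
  p0 <- precision_at(0, seeds)
  p2 <- precision_at(0.2, seeds)
  p5 <- precision_at(0.5, seeds)
  expect_gte(p0, p2 - 0.02)
  expect_gte(p2, p5 - 0.02)
})
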