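identity_matching <- function(n) {
  tibble::tibble(element_id = seq_len(n), ref_id = seq_len(n), distance = 0)
}

test_that("identical stress fields give ratio 1, counted as shielded", {
  vm <- matrix(runif(50, 0.5, 5), ncol = 1, dimnames = list(NULL, "standing"))
  rep <- stress_ratio_report(vm, vm, identity_matching(50))
  expect_true(all(abs(rep$ratios$ratio - 1) < 1e-15))
  expect_equal(rep$fractions$fraction_shielded, 1)  # bin edge -> lower bin
  expect_equal(rep$fractions$fraction_above, 0)
})

test_that("zero implanted stress puts everything in the first bin", {
  vm_i <- matrix(runif(40, 1, 2), ncol = 1, dimnames = list(NULL, "standing"))
  vm_p <- matrix(0, 40, 1, dimnames = list(NULL, "standing"))
  rep <- stress_ratio_report(vm_i, vm_p, identity_matching(40))
  expect_true(all(rep$ratios$ratio == 0))
  h <- rep$histogram
  expect_equal(h$n[h$bin == 1], 40L)
  expect_equal(sum(h$n[h$bin > 1]), 0L)
})

test_that("histogram fractions are permutation invariant and sum to one", {
  set.seed(3)
  n <- 200
  vm_i <- matrix(runif(2 * n, 0.5, 3), ncol = 2,
                 dimnames = list(NULL, c("a", "b")))
  vm_p <- vm_i * matrix(runif(2 * n, 0, 2.5), ncol = 2)
  r1 <- stress_ratio_report(vm_i, vm_p, identity_matching(n))
  perm <- sample(n)
  mt <- tibble::tibble(element_id = perm, ref_id = perm, distance = 0)
  r2 <- stress_ratio_report(vm_i, vm_p, mt)
  expect_equal(r1$histogram, r2$histogram)
  sums <- tapply(r1$histogram$fraction, r1$histogram$case, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  expect_equal(r1$fractions$fraction_shielded + r1$fractions$fraction_above,
               c(1, 1))
  # shielded fraction equals the first ten bins by construction
  for (cs in c("a", "b")) {
    h <- subset(r1$histogram, case == cs)
    expect_equal(sum(h$fraction[h$bin <= 10]),
                 r1$fractions$fraction_shielded[r1$fractions$case == cs])
  }
})

test_that("near-zero intact stress is excluded by the denominator floor", {
  vm_i <- matrix(c(1e-9, 1e-9, 1, 2), ncol = 1,
                 dimnames = list(NULL, "standing"))
  vm_p <- matrix(c(5, 5, 0.5, 1), ncol = 1, dimnames = list(NULL, "standing"))
  rep <- stress_ratio_report(vm_i, vm_p, identity_matching(4))
  expect_equal(nrow(rep$ratios), 2L)
  expect_equal(rep$n_excluded, 2L)
  expect_error(stress_ratio_report(vm_i, vm_p,
                                   tibble::tibble(element_id = 1:4,
                                                  ref_id = NA_integer_,
                                                  distance = NA_real_)),
               "zero matched")
})

test_that("ratio bins are right-closed with bin edges in the lower bin", {
  idx <- osteosim:::ratio_bin_index(c(0, 0.05, 0.1, 0.1000000001, 1, 1.95,
                                      2, 2.5, 10))
  expect_equal(idx, c(1L, 1L, 1L, 2L, 10L, 20L, 20L, 21L, 21L))
})

test_that("the femur fixture shows neck-dominant shielding", {
  sl <- small_pair_solves()
  rep <- stress_ratio_report(sl$vm_i, sl$vm_p, sl$matching,
                             mesh = sl$pair$implanted)
  rm <- rep$region_means
  stand_neck <- rm$mean_ratio[rm$case == "standing" & rm$zone == "neck"]
  stand_shaft <- rm$mean_ratio[rm$case == "standing" & rm$zone == "shaft"]
  expect_lt(stand_neck, stand_shaft)
  neck_ratios <- subset(rep$ratios, case == "standing" & zone == "neck")$ratio
  expect_gt(mean(neck_ratios <= 1), 0.5)
})

test_that("element matching caps the distance and flags unmatched queries", {
  pair <- small_femur_pair()
  mt <- match_elements(pair$implanted, pair$implanted)
  expect_true(all(mt$distance == 0))
  expect_equal(mt$element_id, mt$ref_id)
  shifted <- pair$implanted
  shifted$nodes <- shifted$nodes + 1000
  mt2 <- match_elements(shifted, pair$implanted, cap = 1)
  expect_true(all(is.na(mt2$ref_id)))
})

test_that("density difference of a run with itself is zero, max is consistent", {
  pair <- small_femur_pair()
  prm <- remodeling_params(fe_update_interval = 10)
  sim <- simulate_remodeling(pair$implanted, pair$intact, params = prm,
                             days = 20, snapshot_days = c(10, 20))
  dd <- density_difference(sim, sim, 20)
  expect_true(all(dd$delta[!is.na(dd$delta)] == 0))
  expect_equal(dd$summary$max_abs_delta, 0)
  # against the unstimulated start: summary max equals the field max
  sim0 <- simulate_remodeling(pair$implanted, pair$intact, params = prm,
                              days = 10, snapshot_days = 10)
  base <- list(state = sim$state,
               snapshots = list("10" = sim$inputs$material$rho))
  dd2 <- density_difference(base, sim0, 10)
  bone <- which(pair$implanted$region == "bone")
  expect_equal(dd2$summary$max_abs_delta, max(abs(dd2$delta[bone])))
  expect_equal(dd2$summary$max_loss, max(pmax(dd2$delta[bone], 0)))
  expect_equal(nrow(dd2$sections), 3L)
  expect_error(density_difference(sim, sim, 99), "snapshot")
})

test_that("tidiers and autoplot produce well-formed output", {
  pair <- small_femur_pair()
  sim <- simulate_remodeling(pair$implanted, pair$intact,
                             params = remodeling_params(fe_update_interval = 10),
                             days = 10)
  td <- tidy(sim)
  expect_true(all(c("day", "group", "mean_density", "rate") %in% names(td)))
  expect_setequal(unique(td$group), c("cortical", "cancellous", "neck"))
  gl <- glance(sim)
  expect_equal(gl$days, 10L)
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(autoplot(sim, what = "rate"), "ggplot")
  sl <- small_pair_solves()
  rep <- stress_ratio_report(sl$vm_i, sl$vm_p, sl$matching,
                             mesh = sl$pair$implanted)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_equal(sum(tidy(rep)$fraction), 3)   # one per load case
  expect_equal(ncol(glance(rep)), 6L)
})
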