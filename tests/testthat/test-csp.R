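# Reverse minimal-shift mapping: weighting, distances, gates, height
# floor, greedy matching and the per-residue profile.

test_that("weighting from the assigned shift ranges", {
  w <- compute_weight(4.504, 30.616)
  expect_equal(round(w$weight, 3), 0.147)
  expect_equal(compute_weight(1, 1)$weight, 1)
  expect_equal(compute_weight(2.5, 12.5)$weight, 0.2)
  expect_error(compute_weight(0, 30), "positive")
  expect_error(compute_weight(4.5, -1), "positive")
})

test_that("weighted distance is the weighted Euclidean combined shift", {
  pa <- list(shift_h = 8.0, shift_n = 120.0)
  expect_equal(weighted_distance(pa, pa, 0.147), 0)
  pb <- list(shift_h = 8.03, shift_n = 120.0)
  expect_equal(weighted_distance(pa, pb, 0.9), 0.03)  # single-axis
  pc <- list(shift_h = 8.06, shift_n = 120.5)
  # independent hand arithmetic: sqrt(0.06^2 + (0.147*0.5)^2)
  expect_equal(weighted_distance(pa, pc, 0.147),
               sqrt(0.06^2 + 0.0735^2), tolerance = 1e-12)
  expect_equal(weighted_distance(pa, pc, 0.147),
               weighted_distance(pc, pa, 0.147))
})

test_that("height floor keeps peaks strictly above the fraction", {
  pl <- peak_list(shift_h = c(8, 8.5, 9), shift_n = c(110, 115, 120),
                  height = c(100, 6, 4))
  kept <- filter_by_height(pl, 0.05)
  expect_equal(sort(kept$height), c(6, 100))  # 4 < 5 dropped; 6 > 5 kept
  expect_equal(attr(kept, "reference_id"), pl$id[1])
  expect_equal(nrow(filter_by_height(pl, 0)), 3L)
  zero <- peak_list(shift_h = 1:3, shift_n = 1:3, height = 0)
  expect_error(filter_by_height(zero), "zero")
  set.seed(61)
  h <- stats::runif(500, 0, 50)
  pl2 <- peak_list(shift_h = runif(500), shift_n = runif(500), height = h)
  kept2 <- filter_by_height(pl2, 0.05)
  expect_setequal(kept2$id, pl2$id[h > 0.05 * max(h)])
})

test_that("obvious nearest neighbours are matched and gates take precedence", {
  bound <- peak_list(shift_h = c(8.0, 9.0), shift_n = c(120, 125),
                     assignment = c("A10", "L11"), id = c("b1", "b2"))
  free <- peak_list(shift_h = c(8.02, 9.05), shift_n = c(120.3, 124.8),
                    id = c("f1", "f2"))
  mp <- reverse_assign(free, bound, 0.147, gate_spec())
  expect_equal(nrow(mp$pairs), 2L)
  expect_equal(mp$pairs$free_id[match(c("b1", "b2"), mp$pairs$bound_id)],
               c("f1", "f2"))

  # dH = 0.12 exceeds the 0.1 ppm gate even though the weighted distance
  # is small
  free2 <- peak_list(shift_h = 8.12, shift_n = 120.0, id = "f1")
  bound2 <- peak_list(shift_h = 8.0, shift_n = 120.0, assignment = "A10",
                      id = "b1")
  mp2 <- reverse_assign(free2, bound2, 0.147, gate_spec())
  expect_equal(nrow(mp2$pairs), 0L)
  expect_equal(mp2$unmatched_free, "f1")
  expect_error(reverse_assign(free2, bound2[0, ], 0.147), "empty")
})

test_that("global greedy equals the brute-force oracle on random instances", {
  set.seed(71)
  w <- 0.147
  for (rep in 1:8) {
    nb <- sample(10:50, 1); nf <- sample(10:50, 1)
    bound <- peak_list(shift_h = runif(nb, 7, 10), shift_n = runif(nb, 108, 132),
                       assignment = paste0("A", seq_len(nb)),
                       id = sprintf("b%02d", seq_len(nb)))
    free <- peak_list(shift_h = runif(nf, 7, 10), shift_n = runif(nf, 108, 132),
                      id = sprintf("f%02d", seq_len(nf)))
    mp <- reverse_assign(free, bound, w, gate_spec(0.1, 0.68))
    oracle <- brute_force_greedy(free, bound, w, 0.1, 0.68)
    got <- mp$pairs[order(mp$pairs$distance, mp$pairs$bound_id,
                          mp$pairs$free_id), c("bound_id", "free_id")]
    expect_equal(got$bound_id, oracle$bound_id)
    expect_equal(got$free_id, oracle$free_id)
    # one-to-one and gate soundness invariants
    expect_false(anyDuplicated(mp$pairs$bound_id) > 0)
    expect_false(anyDuplicated(mp$pairs$free_id) > 0)
    expect_true(all(abs(mp$pairs$dh) <= 0.1))
    expect_true(all(abs(mp$pairs$dn) <= 0.68))
    # greedy optimal-first: first accepted pair is the global minimum
    if (nrow(mp$pairs) > 0) {
      expect_equal(min(mp$pairs$distance), oracle$distance[1])
    }
  }
})

test_that("ground truth is fully recovered on within-gate synthetic lists", {
  spec <- simulation_spec(seed = 42, n_residues = 60, pocket_fraction = 0,
                          dropout_fraction = 0.3)
  sim <- simulate_peaklists(spec)
  mp <- reverse_assign(sim$free, sim$bound, 0.147, gate_spec())
  sc <- score_mapping(mp, sim$truth)
  expect_equal(sc$recovery_percent, 100)
  expect_equal(sc$n_spurious, 0L)
  expect_equal(sc$n_matchable, sum(!is.na(sim$truth$free_id)))
})

test_that("matched fraction decreases as perturbations grow past the gates", {
  fracs <- vapply(c(0.02, 0.08, 0.2, 0.5), function(s) {
    spec <- simulation_spec(seed = 9, n_residues = 60, pocket_fraction = 0,
                            core_sd_h = s, core_sd_n = s * 5,
                            dropout_fraction = 0)
    sim <- simulate_peaklists(spec)
    mp <- reverse_assign(sim$free, sim$bound, 0.147, gate_spec())
    nrow(mp$pairs) / nrow(sim$bound)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
  expect_equal(fracs[1], 1)
})

test_that("sequential variant also recovers well-separated truth", {
  spec <- simulation_spec(seed = 13, n_residues = 40, pocket_fraction = 0,
                          dropout_fraction = 0.2)
  sim <- simulate_peaklists(spec)
  mp <- reverse_assign(sim$free, sim$bound, 0.147, gate_spec(),
                       method = "sequential")
  expect_equal(score_mapping(mp, sim$truth)$recovery_percent, 100)
})

test_that("minimal-shift profile reports matched, bound-only and unobserved", {
  bound <- peak_list(shift_h = c(8, 8.5, 9), shift_n = c(110, 120, 130),
                     assignment = c("A2", "F3", "K5"),
                     id = c("b1", "b2", "b3"))
  # perfectly overlaid free list: all delta_min zero
  free0 <- peak_list(shift_h = bound$shift_h, shift_n = bound$shift_n,
                     id = paste0("f", 1:3))
  mp0 <- reverse_assign(free0, bound, 0.147, gate_spec())
  prof0 <- minimal_shift_profile(mp0, bound, residues = 1:5)
  expect_equal(prof0$delta_min[prof0$status == "matched"], rep(0, 3))
  # residue 5's peak vanishes from the free list -> bound-only; residues
  # 1 and 4 have no bound peak -> unobserved
  mp1 <- reverse_assign(free0[1:2, ], bound, 0.147, gate_spec())
  prof1 <- minimal_shift_profile(mp1, bound, residues = 1:5)
  expect_equal(prof1$status, c("unobserved", "matched", "matched",
                               "unobserved", "bound-only"))
})

test_that("profile ranks constructed perturbed residues highest", {
  spec <- simulation_spec(seed = 77, n_residues = 40, pocket_fraction = 0,
                          core_sd_h = 0.002, core_sd_n = 0.01,
                          dropout_fraction = 0)
  sim <- simulate_peaklists(spec)
  # push five residues by a known within-gate vector
  shifted <- c(4, 11, 19, 27, 33)
  free <- sim$free
  j <- match(sprintf("F%03d", shifted), free$id)
  free$shift_h[j] <- free$shift_h[j] + 0.07
  free$shift_n[j] <- free$shift_n[j] + 0.4
  mp <- reverse_assign(free, sim$bound, 0.147, gate_spec())
  prof <- minimal_shift_profile(mp, sim$bound, residues = 1:40)
  top5 <- prof$residue[order(-prof$delta_min)][1:5]
  expect_setequal(top5, shifted)
})
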