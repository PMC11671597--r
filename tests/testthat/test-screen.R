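# Candidate-selection cascade.

triplet_cov <- function(triplets) {
  do.call(rbind, lapply(names(triplets), function(id) {
    data.frame(protein_id = id,
               condition = c("control", "pronase", "pronase_drug"),
               coverage = triplets[[id]])
  }))
}

test_that("screen statistics are the documented coverage arithmetic", {
  st <- compute_screen_stats(triplet_cov(list(A = c(90, 40, 60))))
  expect_equal(st$degradation, 50)
  expect_equal(st$stabilization, 20)
  expect_equal(st$fold_change, 1.5)
  st2 <- compute_screen_stats(triplet_cov(list(B = c(90, 90, 90))))
  expect_equal(c(st2$degradation, st2$stabilization, st2$fold_change),
               c(0, 0, 1))
  st3 <- compute_screen_stats(triplet_cov(list(C = c(80, 0, 10))))
  expect_false(st3$fc_defined)
  expect_true(is.na(st3$fold_change))
  expect_equal(st3$stabilization, 10)
})

test_that("missing conditions are reported by protein", {
  cov <- triplet_cov(list(A = c(90, 40, 60)))[-2, ]
  expect_error(compute_screen_stats(cov), "A")
})

test_that("default 5/5-point strict filters reproduce hand-applied results", {
  st <- compute_screen_stats(triplet_cov(list(A = c(90, 40, 60),
                                              B = c(90, 88, 89),
                                              C = c(85, 30, 33))))
  sc <- screen_candidates(st)
  expect_setequal(sc$degraded, c("A", "C"))
  expect_equal(sc$candidates$protein_id, "A")
  expect_equal(unname(sc$cascade), c(3, 2, 1))
})

test_that("identical conditions yield an empty candidate list", {
  st <- compute_screen_stats(triplet_cov(list(A = c(50, 50, 50),
                                              B = c(10, 10, 10))))
  sc <- screen_candidates(st)
  expect_equal(nrow(sc$candidates), 0)
  expect_warning(export_heatmap_matrix(sc), "empty")
})

test_that("non-strict zero thresholds admit all nonnegative deltas", {
  st <- compute_screen_stats(triplet_cov(list(A = c(50, 50, 50),
                                              B = c(60, 40, 45))))
  sc <- screen_candidates(st, screen_thresholds(0, 0, strict = FALSE))
  expect_setequal(sc$candidates$protein_id, c("A", "B"))
})

test_that("relative-mode thresholds rescale by the reference coverage", {
  # degradation 10/80 = 12.5% relative; stabilization 5/70 = 7.1% relative
  st <- compute_screen_stats(triplet_cov(list(A = c(80, 70, 75))))
  expect_equal(nrow(screen_candidates(st)$candidates), 0) # points mode
  sc <- screen_candidates(st, screen_thresholds(5, 5, mode = "relative"))
  expect_equal(sc$candidates$protein_id, "A")
})

test_that("cascade counts are monotone and candidates nest in degraded", {
  for (s in 1:5) {
    sc0 <- demo_triplet(s, n_proteins = 10)
    st <- compute_screen_stats(coverage_table(sc0$proteome, sc0$evidence))
    sc <- screen_candidates(st)
    expect_true(all(sc$candidates$protein_id %in% sc$degraded))
    expect_true(all(sc$degraded %in% st$protein_id))
    expect_true(all(diff(unname(sc$cascade)) <= 0))
  }
})

test_that("screen output is invariant under protein permutation", {
  st <- compute_screen_stats(triplet_cov(list(A = c(90, 40, 60),
                                              B = c(80, 20, 70),
                                              C = c(85, 30, 60))))
  sc1 <- screen_candidates(st)
  sc2 <- screen_candidates(st[c(3, 1, 2), ])
  expect_identical(sc1$candidates, sc2$candidates)
  expect_setequal(sc1$degraded, sc2$degraded)
})

test_that("ranking orders by stabilization then fold change", {
  # A and B tie on stabilization (30 points); B wins on fold change 2.0
  # vs 1.75; C trails on stabilization
  st <- compute_screen_stats(triplet_cov(list(A = c(90, 40, 70),
                                              B = c(95, 30, 60),
                                              C = c(60, 20, 45))))
  sc <- screen_candidates(st)
  expect_equal(sc$candidates$protein_id, c("B", "A", "C"))
  expect_equal(sc$candidates$rank, 1:3)
})

test_that("heatmap matrix holds raw coverages ordered by rank", {
  st <- compute_screen_stats(triplet_cov(list(A = c(90, 40, 60))))
  sc <- screen_candidates(st)
  m <- export_heatmap_matrix(sc)
  expect_equal(dim(m), c(1, 3))
  expect_equal(unname(m["A", ]), c(90, 40, 60))
  path <- withr::local_tempfile(fileext = ".csv")
  export_heatmap_matrix(sc, path)
  back <- utils::read.csv(path)
  expect_equal(back$control, 90)
})
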