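# unconstrained helper: peaks with no standards, wide-open window
open_world <- function(n_tgt, n_sample, spacing = 20) {
  roster <- compound_roster(rep("target", n_tgt))
  base <- spacing * seq_len(n_tgt)
  library <- tiny_library(base, roster)
  peaks <- peak_list(base[seq_len(max(n_sample, 1))][seq_len(n_sample)] + 1)
  list(roster = roster, library = library, peaks = peaks)
}

test_that("candidate count is the binomial coefficient", {
  expect_equal(count_candidates(20, 10), 184756)
  expect_equal(count_candidates(7, 7), 1)
  expect_equal(count_candidates(5, 0), 1)
  # matches explicit enumeration on a small case
  expect_equal(count_candidates(4, 2), nrow(oracle_assignments(1:4, 2)))
  expect_error(count_candidates(3, 4), "n_sample <= n_tgt")
})

test_that("unconstrained enumeration equals the combinatorial count", {
  w <- open_world(20, 10)
  cfg <- exhaustive_config()
  n <- enumerate_candidates(w$peaks, w$library, cfg, collect = FALSE)
  expect_equal(n, 184756)
  for (case in list(c(6, 3), c(5, 5), c(8, 1), c(4, 0))) {
    w <- open_world(case[1], case[2])
    got <- enumerate_candidates(w$peaks, w$library, cfg)
    expect_equal(attr(got, "count"), count_candidates(case[1], case[2]))
    expect_equal(got, oracle_assignments(seq_len(case[1]), case[2]),
                 ignore_attr = TRUE)
  }
})

test_that("the cutoff window filters pairs against any retained trajectory", {
  roster <- compound_roster(rep("target", 4))
  library <- tiny_library(c(10, 20, 30, 40), roster)
  peaks <- peak_list(c(11, 29))
  got <- enumerate_candidates(peaks, library, match_config(delta_t = 2))
  expect_equal(got, matrix(c(1L, 3L), 1), ignore_attr = TRUE)
  # brute force over all 6 pairs with the same window
  cand <- oracle_assignments(1:4, 2)
  keep <- apply(cand, 1, function(a)
    all(abs(c(10, 20, 30, 40)[a] - peaks$rt) <= 2))
  expect_equal(sum(keep), 1L)
  expect_equal(cand[keep, ], c(1L, 3L))
})

test_that("a sample covering the full roster has exactly one candidate", {
  w <- open_world(6, 6)
  got <- enumerate_candidates(w$peaks, w$library, exhaustive_config())
  expect_equal(got, matrix(1:6, 1), ignore_attr = TRUE)
})

test_that("standard partitioning restricts peaks to bracketed compound intervals", {
  # std A between targets 5 and 6
  roster <- tiny_roster(10, std_after = 5)
  sid <- roster$id[roster$role == "standard"]
  base <- 10 * seq_len(11)
  library <- tiny_library(base, roster)
  # peak before the standard peak, one after
  peaks <- peak_list(c(31, 95), std_id = c(NA, NA))
  peaks <- peak_list(c(31, 60, 95), std_id = c(NA, sid, NA), roster = roster)
  part <- partition_by_standards(peaks, library)
  expect_equal(part[1, ], c(lo = 1L, hi = 5L))
  expect_equal(part[2, ], c(lo = 6L, hi = 10L))

  # no labeled standards: full range
  part0 <- partition_by_standards(peak_list(c(31, 95)), library)
  expect_equal(unname(part0), matrix(c(1L, 1L, 10L, 10L), 2))

  # two standards: the interval between them, checked by brute force with
  # the anchors fixed
  roster2 <- tiny_roster(8, std_after = c(2, 6))
  sids <- roster2$id[roster2$role == "standard"]
  base2 <- 10 * seq_len(10)
  library2 <- tiny_library(base2, roster2)
  rank_s <- match(sids, roster2$id)
  peaks2 <- peak_list(c(base2[rank_s[1]], 55, base2[rank_s[2]]),
                      std_id = c(sids[1], NA, sids[2]), roster = roster2)
  part2 <- partition_by_standards(peaks2, library2)
  lib_rt <- library2$trajectories[[1]]$rts
  ok_ids <- Filter(function(id) {
    rt <- lib_rt[as.character(id)]
    rt > lib_rt[as.character(sids[1])] && rt < lib_rt[as.character(sids[2])]
  }, roster2$id[roster2$role == "target"])
  expect_equal(unname(part2[1, "lo"]), min(unlist(ok_ids)))
  expect_equal(unname(part2[1, "hi"]), max(unlist(ok_ids)))
})

test_that("filtering is anti-monotone in delta_t and standard labels", {
  roster <- tiny_roster(8, std_after = 4)
  sid <- roster$id[roster$role == "standard"]
  base <- c(15, 30, 45, 60, 72, 85, 100, 115, 130)
  library <- tiny_library(base, roster, shifts = list(0, 3))
  rts <- c(31, 59, 101)
  key <- function(m) apply(m, 1, paste, collapse = ",")

  wide <- enumerate_candidates(peak_list(rts), library,
                               match_config(delta_t = 50, allow_interferents = FALSE))
  narrow <- enumerate_candidates(peak_list(rts), library,
                                 match_config(delta_t = 6, allow_interferents = FALSE))
  expect_true(all(key(narrow) %in% key(wide)))
  expect_gt(nrow(wide), nrow(narrow))

  anchored <- enumerate_candidates(
    peak_list(c(rts, 72), std_id = c(NA, NA, NA, sid), roster = roster),
    library, match_config(delta_t = 50, allow_interferents = FALSE))
  expect_true(all(key(anchored) %in% key(wide)))
  expect_lte(nrow(anchored), nrow(wide))
  # streams contain no duplicates and every row passes the validator
  for (m in list(wide, narrow, anchored)) {
    expect_false(anyDuplicated(key(m)) > 0)
    apply(m, 1, validate_assignment, roster = roster)
  }
})

test_that("empty streams carry a distinguishing diagnostic", {
  roster <- compound_roster(rep("target", 3))
  library <- tiny_library(c(100, 200, 300), roster)
  got <- enumerate_candidates(peak_list(c(500)), library,
                              match_config(delta_t = 5, allow_interferents = FALSE))
  expect_equal(nrow(got), 0L)
  expect_match(attr(got, "diagnostic"), "delta_t too small")

  # window fine per peak, but order makes assignment impossible:
  # three peaks all near compound 3 only
  got2 <- enumerate_candidates(peak_list(c(298, 299.5, 301)), library,
                               match_config(delta_t = 5, allow_interferents = FALSE))
  expect_equal(nrow(got2), 0L)
  expect_match(attr(got2, "diagnostic"), "order conflict")
})

test_that("peaks beyond every window must carry the interferent label", {
  roster <- compound_roster(rep("target", 3))
  library <- tiny_library(c(100, 200, 300), roster)
  got <- enumerate_candidates(peak_list(c(101, 500)), library,
                              match_config(delta_t = 5, allow_interferents = TRUE))
  expect_true(all(got[, 2] == INTERFERENT))
  expect_true(nrow(got) >= 1)
})
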