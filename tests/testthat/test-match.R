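test_that("internal-standard SSR follows the sum-of-squares formula", {
  roster <- tiny_roster(2, std_after = c(0, 2))
  sids <- roster$id[roster$role == "standard"]
  tr <- rtt_trajectory("a", c(100, 150, 180, 200), roster)

  same <- peak_list(c(100, 200), std_id = sids, roster = roster)
  expect_equal(ssr_std(tr, same), 0)

  off <- peak_list(c(101, 198), std_id = sids, roster = roster)
  expect_equal(ssr_std(tr, off), 1 + 4)

  # term-by-term accumulation oracle on random standard RTs
  withr::with_seed(11, {
    for (rep in 1:20) {
      srt <- sort(100 + runif(2, -8, 8) * c(1, 10) + c(0, 100))
      pl <- peak_list(srt, std_id = sids, roster = roster)
      acc <- 0
      for (k in seq_along(sids))
        acc <- acc + (tr$rts[as.character(sids[k])] - srt[k])^2
      expect_equal(ssr_std(tr, pl), unname(acc))
    }
  })
})

test_that("screening sorts by standard residuals and truncates per rule", {
  roster <- tiny_roster(1, std_after = c(0, 1))
  sids <- roster$id[roster$role == "standard"]
  shifts <- list(5, 0.5, 3, 0.1, 8, 1)  # lib_1..lib_6
  library <- tiny_library(c(100, 150, 200), roster, shifts = shifts)
  peaks <- peak_list(c(100, 200), std_id = sids, roster = roster)

  half <- screen_libraries(library, peaks,
                           match_config(screen_rule = "keep_fraction",
                                        screen_value = 0.5, screen_floor = 1))
  expect_equal(lib_labels <- vapply(half$trajectories, `[[`, "", "label"),
               c("lib_4", "lib_2", "lib_6"))

  all6 <- screen_libraries(library, peaks, match_config(screen_rule = "keep_all"))
  expect_equal(vapply(all6$trajectories, `[[`, "", "label"),
               paste0("lib_", order(unlist(shifts))))
  expect_equal(attr(all6, "ssr_std"), sort(2 * unlist(shifts)^2))

  # ties broken by library order, per a stable-sort oracle
  library2 <- tiny_library(c(100, 150, 200), roster, shifts = list(2, 1, 2, 1))
  top2 <- screen_libraries(library2, peaks,
                           match_config(screen_rule = "keep_top_k",
                                        screen_value = 2, screen_floor = 1))
  s <- vapply(library2$trajectories, ssr_std, numeric(1), peaks = peaks)
  expect_equal(vapply(top2$trajectories, `[[`, "", "label"),
               paste0("lib_", order(s)[1:2]))
  expect_equal(vapply(top2$trajectories, `[[`, "", "label"),
               c("lib_2", "lib_4"))

  # default floor keeps small libraries whole
  expect_equal(n_trajectories <- length(screen_libraries(
    library, peaks, match_config())$trajectories), 6L)

  # no labeled standards: all retained in input order
  expect_equal(vapply(screen_libraries(library, peak_list(c(100, 200)),
                                       match_config(screen_floor = 1))$trajectories,
                      `[[`, "", "label"),
               paste0("lib_", 1:6))
})

test_that("MSR arithmetic matches the displayed formula", {
  roster <- tiny_roster(3, std_after = c(0, 3))
  sids <- roster$id[roster$role == "standard"]
  tr <- rtt_trajectory("a", c(50, 100, 150, 200, 250), roster)

  # perfect match
  pl0 <- peak_list(c(50, 100, 150, 200, 250),
                   std_id = c(sids[1], NA, NA, NA, sids[2]), roster = roster)
  expect_equal(msr(tr, c(1L, 2L, 3L), pl0), 0)

  # standards off by (1, 2); peaks off by (0.5, 0.5, 1)
  pl <- peak_list(c(51, 100.5, 150.5, 201, 248),
                  std_id = c(sids[1], NA, NA, NA, sids[2]), roster = roster)
  expect_equal(msr(tr, c(1L, 2L, 3L), pl), (1 + 4 + 0.25 + 0.25 + 1) / 5)
  # interferent-labeled peak contributes neither residual nor count
  expect_equal(msr(tr, c(1L, 2L, INTERFERENT), pl), (1 + 4 + 0.25 + 0.25) / 4)

  # vacuous: no standards, all interferents
  pl2 <- peak_list(c(60, 70))
  expect_error(msr(tr, c(INTERFERENT, INTERFERENT), pl2), "vacuous")
})

test_that("a sample equal to a trajectory restriction self-matches with MSR 0", {
  roster <- tiny_roster(20, std_after = c(7, 14))
  sids <- roster$id[roster$role == "standard"]
  base <- 25 * seq_len(22) + 3 * sin(seq_len(22))
  library <- tiny_library(base, roster, shifts = list(0, 4, -4))
  tr <- library$trajectories[[1]]
  pl <- peak_list(unname(tr$rts),
                  std_id = ifelse(roster$role == "standard", roster$id, NA),
                  roster = roster)
  res <- match_sample(pl, library, match_config())
  expect_equal(res[[1]]$msr, 0)
  expect_equal(res[[1]]$assignment, roster$id[roster$role == "target"])
  expect_equal(res[[1]]$lib_label, "lib_1")
  expect_equal(res[[1]]$rank, 1L)
})

test_that("match_sample equals exhaustive brute force on random small instances", {
  n_checked <- 0
  seed <- 0
  while (n_checked < 60) {
    seed <- seed + 1
    inst <- random_instance(seed)
    if (is.null(inst)) next
    n_checked <- n_checked + 1
    res <- match_sample(inst$peaks, inst$library, exhaustive_config())
    best <- oracle_match(inst$peaks, inst$library)
    expect_equal(res[[1]]$msr, best$msr, tolerance = 1e-9)
    expect_equal(res[[1]]$assignment, as.integer(best$a))
    expect_equal(res[[1]]$lib_label, best$label)
    expect_equal(res[[1]]$ssr, best$ssr, tolerance = 1e-9)
  }
})

test_that("stored SSR, counts and MSR are mutually consistent", {
  for (seed in c(3, 14, 27)) {
    inst <- random_instance(seed)
    if (is.null(inst)) next
    res <- match_sample(inst$peaks, inst$library, exhaustive_config())
    n_std <- sum(!is.na(inst$peaks$std_id))
    for (r in res) {
      denom <- n_std + length(r$assignment) - r$n_interf
      expect_equal(r$msr, r$ssr / denom, tolerance = 1e-12)
      expect_gte(r$msr, 0)
    }
  }
})

test_that("library order does not change scores and screening only removes", {
  inst <- random_instance(101)
  cfg <- exhaustive_config()
  res <- match_sample(inst$peaks, inst$library, cfg)
  perm <- rev(seq_along(inst$library$trajectories))
  lib2 <- rtt_library(inst$library$roster, inst$library$trajectories[perm])
  res2 <- match_sample(inst$peaks, lib2, cfg)
  expect_equal(res[[1]]$msr, res2[[1]]$msr)
  expect_equal(res[[1]]$assignment, res2[[1]]$assignment)
  expect_equal(res[[1]]$lib_label, res2[[1]]$lib_label)

  # screened run: every reported MSR also appears in (or exceeds) the
  # exhaustive run's ordering, and retained trajectories score identically
  scr <- match_sample(inst$peaks, inst$library,
                      match_config(delta_t = Inf, screen_rule = "keep_fraction",
                                   screen_value = 0.5, screen_floor = 1,
                                   allow_interferents = FALSE))
  if (length(scr)) expect_gte(scr[[1]]$msr, res[[1]]$msr - 1e-12)
})

test_that("match reports round-trip to delimited text", {
  inst <- random_instance(55)
  res <- match_sample(inst$peaks, inst$library, exhaustive_config(max_results = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_match_report(res, f)
  df <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(nrow(df), length(res))
  expect_equal(df$rank, seq_along(res))
  expect_equal(df$msr, vapply(res, `[[`, numeric(1), "msr"), tolerance = 1e-6)
})
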