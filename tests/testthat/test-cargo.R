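test_that("the positivity threshold is the type-7 99th percentile", {
  thr <- background_threshold(1:100, 99)
  expect_equal(unname(thr["cargo"]), 99.01, tolerance = 1e-12)
  expect_equal(unname(background_threshold(rep(7, 200))["cargo"]), 7)
  expect_error(background_threshold(numeric(0)), "empty")
  expect_error(background_threshold(rnorm(50)), "at least 100")
  expect_error(background_threshold(1:200, 0), "percentile")
  # multiple channels in one call
  thr2 <- background_threshold(list(EGF = 1:1000, TF = 1:200), 99)
  expect_equal(unname(thr2["EGF"]), quantile(1:1000, 0.99, names = FALSE))
  expect_named(thr2, c("EGF", "TF"))
})

test_that("about 1% of held-out background exceeds the threshold", {
  set.seed(0)
  ctrl <- rlnorm(1e4, log(15), 0.45)
  thr <- background_threshold(ctrl, 99)
  set.seed(1)
  held <- rlnorm(1e5, log(15), 0.45)
  frac <- mean(held > thr[1])
  # 3-sigma error budget: control-quantile estimation error
  # (sqrt(p(1-p)/n_ctrl)) dominates the held-out binomial term
  sigma <- sqrt(0.01 * 0.99 / 1e4 + 0.01 * 0.99 / 1e5)
  expect_lt(abs(frac - 0.01), 3 * sigma)
})

test_that("cargo filtering applies the zero-marker and threshold rules", {
  tab <- particle_table(data.frame(
    replicate = 1L, condition = "u", timepoint = 0,
    RAB5  = c(0, 5, 5, 5, 5),
    RAB7  = c(4, 4, 4, 4, 0),
    RAB11 = c(3, 3, 3, 3, 3),
    LAMP1 = c(1, 1, 1, 1, 1),
    EGF   = c(900, 900, 10, 10, 900),
    TF    = c(10, 10, 10, 600, 900),
    area  = 1L),
    markers = c("RAB5", "RAB7", "RAB11", "LAMP1", "EGF", "TF"))
  thr <- structure(c(EGF = 500, TF = 500), percentile = 99,
                   class = "cargo_thresholds")
  out <- filter_cargo_particles(tab, thr, mode = "sum")
  # row 1: RAB5 = 0 removed despite bright EGF; row 3: below both cargo
  # thresholds; row 5: RAB7 = 0 removed
  expect_identical(out$EGF, c(900, 10))   # survivors are rows 2 and 4
  expect_identical(nrow(out), 2L)
  expect_identical(out$EGF_positive, c(TRUE, FALSE))
  expect_identical(out$TF_positive, c(FALSE, TRUE))
  # idempotence
  out2 <- filter_cargo_particles(out, thr, mode = "sum")
  expect_identical(as.data.frame(out2), as.data.frame(out))
  expect_error(filter_cargo_particles(tab, structure(c(XX = 1),
    class = "cargo_thresholds")), "missing column")
})

test_that("filtering matches a brute-force row predicate on random tables", {
  set.seed(12)
  for (rep in 1:3) {
    n <- 200
    df <- data.frame(replicate = 1L, condition = "u", timepoint = 0,
                     RAB5 = rpois(n, 2), RAB7 = rpois(n, 2),
                     RAB11 = rpois(n, 2), LAMP1 = rpois(n, 5),
                     EGF = rlnorm(n, 3, 1.5), TF = rlnorm(n, 3, 1.5),
                     area = sample(1:20, n, TRUE))
    tab <- particle_table(df, markers = c("RAB5", "RAB7", "RAB11",
                                          "LAMP1", "EGF", "TF"))
    thr <- structure(c(EGF = 40, TF = 30), class = "cargo_thresholds")
    out <- filter_cargo_particles(tab, thr, mode = "sum")
    keep_oracle <- vapply(seq_len(n), function(i)
      df$RAB5[i] > 0 && df$RAB7[i] > 0 && df$RAB11[i] > 0 &&
        (df$EGF[i] >= 40 || df$TF[i] >= 30), logical(1))
    expect_identical(out$EGF, df$EGF[keep_oracle])
    # mean mode divides by area first
    outm <- filter_cargo_particles(tab, thr, mode = "mean")
    keep_m <- vapply(seq_len(n), function(i)
      df$RAB5[i] > 0 && df$RAB7[i] > 0 && df$RAB11[i] > 0 &&
        (df$EGF[i] / df$area[i] >= 40 ||
           df$TF[i] / df$area[i] >= 30), logical(1))
    expect_identical(outm$EGF, df$EGF[keep_m])
  }
})

test_that("cluster proportions normalize within each group", {
  df <- data.frame(replicate = 1L,
                   condition = rep("u", 20), timepoint = rep(c(0, 10), 10),
                   RAB5 = 1, RAB7 = 1, RAB11 = 1, LAMP1 = 1,
                   EGF = 1, TF = 1, area = 1L,
                   EGF_positive = rep(c(TRUE, FALSE), each = 10),
                   TF_positive = rep(c(FALSE, TRUE), each = 10),
                   cluster = rep(c(1, 1, 2, 3, 3), 4))
  tab <- particle_table(df, markers = c("RAB5", "RAB7", "RAB11", "LAMP1",
                                        "EGF", "TF"))
  tc <- cluster_proportions(tab)
  # hand tally: EGF positives at t = 0 are rows 1,3,5,7,9 with clusters
  # 1,2,3,1,3 -> counts (2,1,2)
  got <- tc[tc$cargo == "EGF" & tc$timepoint == 0, ]
  expect_identical(got$count, c(2L, 1L, 2L))
  expect_equal(got$proportion, c(2, 1, 2) / 5)
  # every group with positives sums to 1; all-positives-in-one-cluster
  # gives proportion 1
  sums <- tapply(tc$proportion, interaction(tc$condition, tc$timepoint,
                                            tc$cargo), sum)
  expect_true(all(abs(na.omit(sums) - 1) < 1e-12))
  one <- cluster_proportions(particle_table(
    within(df, cluster <- 2), markers = markers(tab)))
  expect_true(all(one$proportion[one$cluster == 2] == 1))
  # zero-positive groups are flagged, unlabeled particles refused
  df2 <- df; df2$EGF_positive <- FALSE
  tc2 <- cluster_proportions(particle_table(df2, markers = markers(tab)))
  expect_true(all(is.na(tc2$proportion[tc2$cargo == "EGF"])))
  expect_true(all(tc2$count[tc2$cargo == "EGF"] == 0L))
  df3 <- df; df3$cluster[1] <- NA
  expect_error(cluster_proportions(particle_table(df3,
    markers = markers(tab))), "cluster label")
})

test_that("sqrt-percent-max scaling follows its closed form", {
  v <- c(0, 25, 50, 100)
  expect_equal(sqrt_percent_max(v), sqrt(100 * v / 100))
  expect_equal(sqrt_percent_max(c(2, 8))[2], 10)        # max maps to 10
  expect_equal(sqrt_percent_max(c(1, 4))[1], 5)         # max/4 maps to 5
  set.seed(3)
  r <- rlnorm(50, 2, 1)
  expect_equal(sqrt_percent_max(r), sqrt(100 * r / max(r)))
  expect_identical(sqrt_percent_max(c(0, 0, 0)), c(0, 0, 0))
  expect_error(sqrt_percent_max(c(-1, 2)), "non-negative")
})

test_that("simulated cargo routes follow the programmed transitions", {
  tab <- sample_cargo_timecourse(n_per_timepoint = 700, seed = 2)
  thr <- background_threshold(
    list(EGF = exp(rnorm(5000, log(15), 0.45)),
         TF = exp(rnorm(5000, log(15), 0.45))), 99)
  out <- filter_cargo_particles(tab, thr, mode = "sum")
  # use the generative states as cluster labels; the modal state of each
  # cargo should move along its programmed route
  tc <- cluster_proportions(out, labels = out$true_state)
  modal <- function(cargo, t) {
    g <- tc[tc$cargo == cargo & tc$timepoint == t, ]
    as.character(g$cluster[which.max(g$count)])
  }
  expect_identical(modal("EGF", 0), "early")
  expect_true(modal("EGF", 40) %in% c("late_lysosome", "lysosome"))
  expect_identical(modal("TF", 0), "early")
  expect_true(modal("TF", 40) %in% c("recycling_a", "recycling_b"))
  # contamination by unloaded bystanders stays near the ~1%-per-channel
  # false-positive rate the threshold is built to admit
  expect_lt(mean(out$true_cargo == "none"), 0.03)
})
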