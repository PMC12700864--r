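test_that("filter_surveys applies behaviour and resight rules", {
  s1 <- make_surveys(list(c("A", "B")), "2000-05-01 09:00:00", "forage")
  expect_identical(nrow(filter_surveys(s1)), 0L)
  expect_identical(nrow(filter_surveys(
    s1, filter_rules(exclude_forage = FALSE))), 1L)

  # identical membership 90 min apart: first retained only
  s2 <- make_surveys(list(c("A", "B"), c("A", "B")),
                     c("2000-05-01 09:00:00", "2000-05-01 10:30:00"))
  expect_identical(filter_surveys(s2)$survey_id, "T001")
  # 150 min apart: both retained
  s3 <- make_surveys(list(c("A", "B"), c("A", "B")),
                     c("2000-05-01 09:00:00", "2000-05-01 11:30:00"))
  expect_identical(nrow(filter_surveys(s3)), 2L)

  # 5 surveys: 2 forage, 1 resight of a retained non-forage survey -> 2 kept
  s4 <- make_surveys(
    list(c("A", "B"), c("C"), c("A", "B"), c("B", "C"), c("A", "C")),
    c("2000-05-01 09:00:00", "2000-05-01 09:30:00",
      "2000-05-01 10:00:00", "2000-05-01 10:15:00",
      "2000-05-01 11:00:00"),
    c("social", "forage", "travel", "forage", "rest"))
  kept <- filter_surveys(s4)
  expect_identical(kept$survey_id, c("T001", "T005"))

  # a resight of a *dropped* (forage) survey is itself retained
  s5 <- make_surveys(list(c("A", "B"), c("A", "B")),
                     c("2000-05-01 09:00:00", "2000-05-01 09:40:00"),
                     c("forage", "social"))
  expect_identical(filter_surveys(s5)$survey_id, "T002")

  # overlap-fraction criterion
  s6 <- make_surveys(list(c("A", "B", "C", "D"), c("A", "B", "C")),
                     c("2000-05-01 09:00:00", "2000-05-01 09:30:00"))
  r <- filter_rules(resight_criterion = "overlap_fraction",
                    overlap_theta = 0.7)
  expect_identical(filter_surveys(s6, r)$survey_id, "T001")
  r2 <- filter_rules(resight_criterion = "overlap_fraction",
                     overlap_theta = 0.8)
  expect_identical(nrow(filter_surveys(s6, r2)), 2L)

  bad <- s2; bad$timestamp <- c("2000-05-01 09:00:00", "not-a-time")
  expect_error(filter_surveys(bad), "T002")
})

test_that("window_surveys spans first sighting through Dec 31 of sampling year", {
  s <- make_surveys(list("A", "A", c("A", "B"), "A", "A"),
                    c("1998-06-01 09:00:00", "2001-03-01 09:00:00",
                      "2005-02-01 09:00:00", "2005-12-30 09:00:00",
                      "2006-01-02 09:00:00"))
  w <- window_surveys(s, "A", as.Date("2005-03-01"))
  expect_identical(w$survey_id, c("T001", "T002", "T003", "T004"))
  # focal first seen 2001: earlier surveys excluded
  s2 <- make_surveys(list("B", c("A", "B"), "A"),
                     c("1998-01-01 09:00:00", "2001-05-01 09:00:00",
                       "2002-01-01 09:00:00"))
  w2 <- window_surveys(s2, "A", as.Date("2002-06-01"))
  expect_identical(w2$survey_id, c("T002", "T003"))
  expect_error(window_surveys(s2, "Z", as.Date("2002-06-01")),
               "empty window")
})

test_that("dyad counts and SRI match their definitions", {
  s <- make_surveys(list(c("A", "B"), "A", "B", "C"),
                    sprintf("2000-05-0%d 09:00:00", 1:4))
  cnt <- dyad_counts("A", "B", s)
  expect_identical(c(cnt$x, cnt$y_a, cnt$y_b), c(1L, 1L, 1L))
  s2 <- make_surveys(rep(list(c("A", "B")), 5),
                     sprintf("2000-05-0%d 09:00:00", 1:5))
  cnt2 <- dyad_counts("A", "B", s2)
  expect_identical(c(cnt2$x, cnt2$y_a, cnt2$y_b), c(5L, 0L, 0L))
  expect_error(dyad_counts("A", "A", s), "differ")

  expect_identical(sri(list(x = 0, y_a = 3, y_b = 2)), 0)
  expect_identical(sri(list(x = 7, y_a = 0, y_b = 0)), 1)
  expect_identical(sri(list(x = 3, y_a = 2, y_b = 5)), 0.3)
  expect_identical(sri(list(x = 0, y_a = 0, y_b = 0)), 0) # never observed
  expect_error(sri(list(x = -1, y_a = 0, y_b = 0)), "non-negative")
})

test_that("dyad counts equal the brute-force oracle on random surveys", {
  set.seed(31)
  ids <- LETTERS[1:6]
  sets <- replicate(20, sample(ids, sample(1:4, 1)), simplify = FALSE)
  s <- make_surveys(sets, format(
    as.POSIXct("2000-01-01 08:00:00", tz = "UTC") +
      cumsum(runif(20, 3600, 7200))))
  for (pair in list(c("A", "B"), c("C", "F"), c("E", "D"))) {
    got <- dyad_counts(pair[1], pair[2], s)
    want <- oracle_dyad(pair[1], pair[2], s)
    expect_identical(c(got$x, got$y_a, got$y_b), unname(want),
                     label = paste(pair, collapse = "-"))
  }
})

test_that("node strength sums SRIs; normalization and CV behave", {
  s <- make_surveys(
    list(c("A", "B"), c("A", "B"), c("A", "C"), c("B", "C"), "A"),
    sprintf("2000-05-%02d 09:00:00", 1:5))
  expect_identical(node_strength("A", character(0), s), 0)
  # sri(A,B) = 2/5; sri(A,C): x=1, A-alone=3, C-alone=1 -> 1/5
  expect_equal(node_strength("A", c("B", "C"), s), 2 / 5 + 1 / 5)
  expect_error(node_strength("A", c("A", "B"), s), "focal")

  expect_identical(cv_bond_strength("A", make_surveys(
    rep(list(c("A", "B"), c("A", "C"), c("A", "D")), 2),
    sprintf("2000-05-%02d 09:00:00", 1:6))), 0) # all SRIs equal
  cv <- cv_bond_strength("A", s, partner_ids = c("B", "C"))
  vals <- c(2 / 5, 1 / 5)
  expect_equal(cv, sd(vals) / mean(vals))
  # the hand formula: SRIs {0.1, 0.3} -> sd 0.1414 / mean 0.2 = 0.7071
  expect_equal(sd(c(0.1, 0.3)) / mean(c(0.1, 0.3)), 0.7071, tolerance = 1e-4)
  # fewer than two nonzero SRIs -> NA sentinel
  lone <- make_surveys(list(c("A", "B"), "C"),
                       sprintf("2000-05-0%d 09:00:00", 1:2))
  expect_true(is.na(cv_bond_strength("A", lone)))
})

test_that("normalized node strength and group size on a constructed cohort", {
  inds <- data.frame(id = c("A", "B", "C", "D", "F1"),
                     sex = c("M", "M", "M", "M", "F"))
  # A-B tight pair, C loosely attached, D solitary; female F1 tags along.
  # D appears first so every focal's window covers all surveys.
  sets <- c(list("D"), rep(list(c("A", "B", "F1")), 10),
            rep(list(c("A", "C")), 4), rep(list("D"), 9),
            rep(list(c("B", "C")), 2), rep(list("C"), 2))
  s <- make_surveys(sets, format(
    seq(as.POSIXct("2003-01-01 09:00:00", tz = "UTC"),
        by = "3 days", length.out = length(sets))))
  rules <- filter_rules(min_sightings = 8)
  date <- as.Date("2003-12-01")
  # strengths: A = sri(AB)+sri(AC), etc.; max over eligible {A, B, D}
  sAB <- 10 / 16; sAC <- 4 / 18; sBC <- 2 / 18
  sA <- sAB + sAC; sB <- sAB + sBC; sD <- 0
  expect_equal(normalized_node_strength("A", date, s, inds, rules), 1.0)
  expect_equal(normalized_node_strength("B", date, s, inds, rules),
               sB / sA)
  expect_equal(normalized_node_strength("D", date, s, inds, rules), 0)

  # group size: A seen with B (x10) and C (x4): mean = 14/14 = 1
  expect_equal(mean_male_group_size("A", date, s, inds, rules), 1.0)
  expect_equal(mean_male_group_size("D", date, s, inds, rules), 0) # alone
  # counts of 2 and 4 other males average to 3
  s2 <- make_surveys(list(c("A", "B", "C"), c("A", "B", "C", "D", "E")),
                     sprintf("2003-05-0%d 09:00:00", 1:2))
  inds2 <- data.frame(id = c("A", "B", "C", "D", "E"), sex = "M")
  expect_equal(mean_male_group_size("A", as.Date("2003-12-01"), s2, inds2,
                                    filter_rules(min_sightings = 1)), 3.0)
  # males with < min_sightings still count toward group size (C, E here)
  expect_equal(mean_male_group_size("A", date, s, inds,
                                    filter_rules(min_sightings = 8)), 1.0)
})

test_that("SRI invariants hold on generated cohorts", {
  co <- random_cohort(101)
  f <- filter_surveys(co$surveys)
  males <- co$individuals$id[co$individuals$sex == "M"]
  pairs <- combn(males[1:5], 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    sab <- sri(dyad_counts(a, b, f))
    expect_gte(sab, 0); expect_lte(sab, 1)
    expect_identical(sab, sri(dyad_counts(b, a, f))) # symmetry
  }
  # removing a survey containing neither a nor b leaves sri unchanged
  a <- males[1]; b <- males[2]
  neither <- which(!sapply(f$members, function(m) a %in% m | b %in% m))
  if (length(neither)) {
    expect_identical(sri(dyad_counts(a, b, f)),
                     sri(dyad_counts(a, b, f[-neither[1], ])))
  }
})

test_that("group size is invariant to relabelling non-member individuals", {
  inds <- data.frame(id = c("A", "B", "F1", "F2"),
                     sex = c("M", "M", "F", "F"))
  s <- make_surveys(rep(list(c("A", "B", "F1")), 3),
                    sprintf("2003-05-0%d 09:00:00", 1:3))
  rules <- filter_rules(min_sightings = 1)
  g1 <- mean_male_group_size("A", as.Date("2003-12-01"), s, inds, rules)
  # relabel the tag-along female and an unseen female: no male counts change
  inds2 <- inds; inds2$id <- c("A", "B", "F9", "F8")
  s2 <- s; s2$members <- rep(list(c("A", "B", "F9")), 3)
  g2 <- mean_male_group_size("A", as.Date("2003-12-01"), s2, inds2, rules)
  expect_identical(g1, g2)
})

test_that("compute_social_metrics: per-sample windows, bounds, and oracle", {
  co <- random_cohort(7)
  rules <- filter_rules(min_sightings = 5)
  sm <- compute_social_metrics(co$samples, co$surveys, co$individuals,
                               rules)
  males <- co$individuals$id[co$individuals$sex == "M"]
  expect_true(all(sm$individual_id %in% males))
  # repeatedly sampled individual -> one record per sample
  expect_identical(nrow(sm),
                   sum(co$samples$individual_id %in% males))
  ok <- !is.na(sm$bond_strength_norm)
  expect_true(all(sm$bond_strength_norm[ok] >= 0 &
                    sm$bond_strength_norm[ok] <= 1))
  expect_true(all(sm$mean_male_group_size[ok] >= 0))
  # spot-check three records against the independent oracle
  for (i in seq_len(min(3, nrow(sm)))) {
    want <- oracle_metrics(sm$individual_id[i],
                           co$samples$sampling_date[
                             match(sm$sample_id[i], co$samples$sample_id)],
                           co$surveys, co$individuals, rules$min_sightings)
    expect_identical(sm$n_sightings[i], as.integer(want$n_sightings))
    expect_equal(sm$bond_strength_norm[i], want$bond)
    expect_equal(sm$cv_bond[i], want$cv)
    expect_equal(sm$mean_male_group_size[i], want$group_size)
  }
})
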