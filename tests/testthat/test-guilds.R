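# Helper: build a results/traits pair with prescribed support patterns.
mk_cohort <- function(n, support, guild, axis = "habitat") {
  ids <- sprintf("G%03d", seq_len(n))
  results <- data.frame(species_id = ids, support = support,
                        rel_mean = ifelse(support == "no_linear", NA,
                                          ifelse(support ==
                                                   "positive_supported",
                                                 0.5, -0.5)),
                        stringsAsFactors = FALSE)
  traits <- data.frame(species_id = ids,
                       habitat_guild = "forest", nesting_guild = "ground",
                       migration_guild = "long", food_guild = "insectivore",
                       stringsAsFactors = FALSE)
  traits[[paste0(axis, "_guild")]] <- guild
  list(results = results, traits = traits)
}

test_that("guild percentages are integer shares of all guild species", {
  expect_equal(guild_percentage(12, 51), 24)
  expect_equal(guild_percentage(15, 37), 41)  # 40.54 rounds up
  expect_equal(guild_percentage(8, 37), 22)
  expect_equal(guild_percentage(2, 37), 5)
  expect_equal(guild_percentage(0, 9), 0)

  co <- mk_cohort(51, c(rep("no_linear", 12), rep("unsupported", 20),
                        rep("negative_supported", 15),
                        rep("positive_supported", 4)), "forest")
  s <- summarize_guilds(co$results, co$traits, "habitat")
  expect_equal(s$n_species, 51)
  expect_equal(s$n_linear + s$n_no_linear, s$n_species)
  expect_equal(s$pct_no_linear, 24)
  expect_equal(s$pct_neg_supported, guild_percentage(15, 51))
  expect_equal(s$pct_pos_supported, guild_percentage(4, 51))

  # zero supported species in a guild -> both percentages 0
  co0 <- mk_cohort(9, rep("unsupported", 9), "alpine")
  s0 <- summarize_guilds(co0$results, co0$traits, "habitat")
  expect_equal(s0$pct_neg_supported, 0)
  expect_equal(s0$pct_pos_supported, 0)
})

test_that("nesting axis excludes species outside the nesting guilds", {
  co <- mk_cohort(10, rep("unsupported", 10),
                  c(rep("ground", 5), rep("higher", 4), "none"),
                  axis = "nesting")
  s <- summarize_guilds(co$results, co$traits, "nesting")
  expect_equal(sum(s$n_species), 9)
  expect_false("none" %in% s$guild_level)
  # the same cohort keeps all 10 species on other axes (partition check)
  sh <- summarize_guilds(co$results, co$traits, "habitat")
  expect_equal(sum(sh$n_species), 10)
})

test_that("unknown guild levels and orphan species are rejected", {
  co <- mk_cohort(4, rep("unsupported", 4), c("forest", "forest",
                                              "moon", "forest"))
  expect_error(summarize_guilds(co$results, co$traits, "habitat"),
               "unknown habitat")
  co2 <- mk_cohort(4, rep("unsupported", 4), "forest")
  expect_error(summarize_guilds(co2$results, co2$traits[-1, ], "habitat"),
               "trait")
})

test_that("the overall tally splits linear species by slope sign", {
  results <- data.frame(
    species_id = sprintf("S%02d", 1:10),
    support = c("negative_supported", "negative_supported", "unsupported",
                "unsupported", "positive_supported", "unsupported",
                "no_linear", "no_linear", "unsupported", "unsupported"),
    rel_mean = c(-1, -0.5, -0.1, -0.2, 0.8, 0.3, NA, NA, 0.1, 0),
    stringsAsFactors = FALSE
  )
  t1 <- overall_tally(results)
  expect_equal(t1$n_linear, 8)
  expect_equal(t1$n_no_linear, 2)
  # rel_mean of exactly 0 counts as negative (documented tie-break)
  expect_equal(t1$n_negative, 5)
  expect_equal(t1$n_positive, 3)
  expect_equal(t1$n_neg_supported, 2)
  expect_equal(t1$n_pos_supported, 1)
  expect_equal(t1$n_negative + t1$n_positive, t1$n_linear)

  # permutation invariance
  t2 <- overall_tally(results[sample(10), ])
  expect_identical(t1, t2)

  # degenerate cohort: everything non-monotone
  allnl <- data.frame(species_id = c("a", "b"), support = "no_linear",
                      rel_mean = NA, stringsAsFactors = FALSE)
  t3 <- overall_tally(allnl)
  expect_equal(unlist(t3[c("n_linear", "n_negative", "n_positive",
                           "n_neg_supported", "n_pos_supported")]),
               c(n_linear = 0, n_negative = 0, n_positive = 0,
                 n_neg_supported = 0, n_pos_supported = 0))
  expect_equal(t3$n_no_linear, 2)
})

test_that("guild reports phrase counts as 'X out of N (P%)' style lines", {
  co <- mk_cohort(8, c(rep("no_linear", 2), rep("unsupported", 6)),
                  "settlement")
  s <- summarize_guilds(co$results, co$traits, "habitat")
  line <- format_guild_report(s)
  expect_match(line, "no linear 2 out of 8 \\(25%\\)")
})
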