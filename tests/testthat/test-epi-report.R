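# Exclusions, ACR classification, stratified tables, prevalence.

make_records <- function(n, age = 60, sex = "male", vbmd = 100,
                         missing = FALSE, fracture = FALSE) {
  data.frame(id = sprintf("r%04d", seq_len(n)),
             age = rep_len(age, n), sex = rep_len(sex, n),
             vbmd = rep_len(vbmd, n),
             flag_missing_L1 = rep_len(missing, n),
             flag_fracture_implant = rep_len(fracture, n),
             stringsAsFactors = FALSE)
}

test_that("the exclusion tally conserves the cohort", {
  r0 <- apply_exclusions(make_records(0))
  expect_equal(unname(r0$tally["included"]), 0)
  expect_equal(unname(r0$tally["total_excluded"]), 0)

  rec <- make_records(10)
  rec$flag_missing_L1[1:3] <- TRUE
  rec$flag_fracture_implant[3:5] <- TRUE  # record 3 carries both flags
  res <- apply_exclusions(rec)
  expect_equal(unname(res$tally["missing_L1"]), 3)
  expect_equal(unname(res$tally["fracture_implant"]), 2)
  expect_equal(nrow(res$included), 5)
  expect_equal(unname(res$tally["included"] + res$tally["total_excluded"]),
               unname(res$tally["input"]))

  # property: conservation under random flag configurations
  withr::with_seed(99, {
    for (i in 1:20) {
      n <- sample(1:50, 1)
      rec <- make_records(n,
                          missing = sample(c(TRUE, FALSE), n, replace = TRUE),
                          fracture = sample(c(TRUE, FALSE), n, replace = TRUE))
      res <- apply_exclusions(rec)
      expect_equal(unname(res$tally["included"] + res$tally["missing_L1"] +
                            res$tally["fracture_implant"]), n)
    }
  })
})

test_that("ACR classification matches the printed cut-offs with boundaries as osteopenia", {
  expect_equal(as.character(classify_acr(c(79.99, 121))),
               c("osteoporosis", "normal"))
  expect_equal(as.character(classify_acr(c(80, 120))),
               c("osteopenia", "osteopenia"))
  expect_equal(as.character(classify_acr(c(60, 80, 100, 120, 121))),
               c("osteoporosis", "osteopenia", "osteopenia", "osteopenia",
                 "normal"))
  # monotone: lower vBMD never maps to a less severe category
  v <- sort(runif(100, 10, 250))
  sev <- as.integer(classify_acr(v))  # 1 = osteoporosis ... 3 = normal
  expect_true(all(diff(sev) >= 0))
  expect_error(classify_acr(c(100, -3)), class = "qct_bad_argument")
  expect_error(classify_acr(NaN), class = "qct_bad_argument")
})

test_that("stratified table reports type-7 median and IQR per bin and sex", {
  rec <- make_records(5, age = c(61, 62, 63, 64, 64.9), vbmd = c(1, 2, 3, 4, 5))
  tab <- stratify_bmd(rec)
  row <- tab[tab$bin == "60-64", ]
  expect_equal(row$n_all, 5)
  expect_equal(row$median_all, 3)
  expect_equal(c(row$q1_all, row$q3_all), c(2, 4))
  expect_equal(row$n_male, 5)
  expect_equal(row$n_female, 0)
  expect_true(is.na(row$median_female))  # empty bin: no fabricated zeros
  one <- stratify_bmd(make_records(1, age = 30, vbmd = 7))
  r1 <- one[one$bin == "30-34", ]
  expect_equal(c(r1$median_all, r1$q1_all, r1$q3_all), c(7, 7, 7))
})

test_that("cohort medians decline monotonically from the 50-54 bin onward", {
  rec <- fixture_classified_cohort(2500, seed = 3)
  tab <- stratify_bmd(rec)
  med <- tab$median_all[match(c("50-54", "55-59", "60-64", "65-69", "70-74",
                                "75-79", "80-84", "85+"), tab$bin)]
  expect_true(all(diff(med) <= 0))
})

test_that("crude prevalence divides counts by the over-min-age denominator", {
  rec <- make_records(12, age = c(rep(60, 10), 30, 40))
  rec$vbmd <- c(rep(60, 3), rep(150, 7), 60, 60)  # under-50s never counted
  rec$category <- classify_acr(rec$vbmd)
  cp <- crude_prevalence(rec)
  row <- cp[cp$group == "combined" & cp$category == "osteoporosis", ]
  expect_equal(row$denominator, 10)
  expect_equal(row$count, 3)
  expect_equal(row$pct, 30)
  expect_equal(row$pct_display, 30.0)

  young <- make_records(5, age = 35)
  young$category <- classify_acr(young$vbmd)
  cp2 <- crude_prevalence(young)
  expect_true(all(cp2$undefined))
  expect_true(all(is.na(cp2$pct)))
})

test_that("direct standardization is a convex combination with the stated identities", {
  # uniform prevalence is a fixed point under any weights
  pb <- data.frame(bin = c("50-54", "55-59", "60-64"), prevalence = 20)
  w <- c("50-54" = 0.5, "55-59" = 0.3, "60-64" = 0.2)
  expect_equal(as.numeric(age_standardize(pb, w)), 20)
  # worked example: 0.25 * 10 + 0.75 * 30
  pb2 <- data.frame(bin = c("50-54", "55-59"), prevalence = c(10, 30))
  expect_equal(as.numeric(age_standardize(
    pb2, c("50-54" = 0.25, "55-59" = 0.75))), 25)
  expect_error(age_standardize(pb2, c("50-54" = -0.1, "55-59" = 1.1)),
               class = "qct_bad_argument")
  # renormalization warning when the cohort lacks weighted bins
  pb3 <- data.frame(bin = c("50-54", "55-59"), prevalence = c(10, NA))
  expect_warning(v <- age_standardize(pb3, w), "renormaliz")
  expect_equal(as.numeric(v), 10)
  # convexity: bounded by min and max per-bin prevalence
  withr::with_seed(42, {
    for (i in 1:20) {
      p <- runif(5, 0, 100)
      wts <- runif(5); wts <- wts / sum(wts)
      names(wts) <- paste0("b", 1:5)
      pbx <- data.frame(bin = names(wts), prevalence = p)
      v <- as.numeric(age_standardize(pbx, wts))
      expect_gte(v, min(p)); expect_lte(v, max(p))
    }
  })
})

test_that("weights equal to the cohort's own bin shares reproduce the crude rate", {
  rec <- fixture_classified_cohort(1500, seed = 5)
  pb <- prevalence_by_bin(rec, "osteoporosis")
  w <- pb$n / sum(pb$n)
  names(w) <- pb$bin
  std <- as.numeric(age_standardize(pb, w))
  crude <- crude_prevalence(rec)
  crude_pct <- crude$pct[crude$group == "combined" &
                           crude$category == "osteoporosis"]
  expect_equal(std, crude_pct, tolerance = 1e-12)
})

test_that("category counts partition the classified cohort", {
  rec <- fixture_classified_cohort(1500, seed = 5)
  expect_equal(sum(table(rec$category)), nrow(rec))
  cp <- crude_prevalence(rec)
  comb <- cp[cp$group == "combined", ]
  expect_equal(sum(comb$count), comb$denominator[1])
  expect_equal(sum(comb$pct), 100)
})

test_that("the bundled synthetic standard population loads and is normalized", {
  sp <- read_standard_population()
  expect_s3_class(sp, "standard_population")
  expect_equal(sum(sp$weights), 1)
  expect_true(all(c("50-54", "85+") %in% names(sp$weights)))
  expect_match(sp$provenance, "synthetic")
})

test_that("the prevalence report combines crude and standardized views", {
  rec <- fixture_classified_cohort(1500, seed = 5)
  rep <- prevalence_report(rec)
  expect_equal(nrow(rep$standardized), 6)
  std <- rep$standardized
  for (i in seq_len(nrow(std))) {
    pb <- rep$per_bin[[paste(std$group[i], std$category[i], sep = ".")]]
    expect_gte(std$standardized_pct[i], min(pb$prevalence, na.rm = TRUE))
    expect_lte(std$standardized_pct[i], max(pb$prevalence, na.rm = TRUE))
  }
  path <- withr::local_tempfile(fileext = ".csv")
  txt <- withr::local_tempfile(fileext = ".txt")
  write_prevalence_report(rep, path, txt)
  back <- utils::read.csv(path)
  expect_true(all(c("group", "category", "count", "pct",
                    "standardized_pct") %in% names(back)))
  expect_match(paste(readLines(txt), collapse = " "), "standard population")
})
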