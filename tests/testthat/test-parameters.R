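test_that("the bundled trial model loads with the expected inputs", {
  m <- trial_model()
  s <- strategies(m)
  cs <- s[s$strategy == "collaborative_surveillance", ]
  expect_equal(cs$p_aki, 0.079)
  expect_equal(cs$p_aki_low, 0.064)
  expect_equal(cs$p_aki_high, 0.095)
  expect_equal(cs$upfront, 12.74)
  e <- economics(m)
  expect_equal(unname(e$utilities), c(0.85, 0.80, 0.70, 0))
  expect_equal(e$aki_episode_cost, 14000)
  expect_equal(unname(e$annual_state_costs[c("ckd", "esrd")]), c(25322, 78537))
  expect_equal(e$discount_rate, 0.03)
  expect_equal(e$horizon_years, 3)
  expect_equal(e$wtp, 1e5)
})

test_that("the no-AKI 30-day row is renormalized with a warning at load", {
  path <- system.file("extdata", "improve_aki.yaml", package = "akicea")
  expect_warning(load_model(path), "renormalizing")
  m <- trial_model()
  d30 <- thirty_day_matrix(m)
  expect_equal(unname(rowSums(d30)), c(1, 1))
  # the printed row sums to 0.999; proportional renormalization
  expect_equal(d30["no_aki", "death"], 0.014 / 0.999)
  expect_equal(d30["no_aki", "esrd"], 0)
})

test_that("conservation violations and bad intervals fail at load with names", {
  m <- trial_model()
  bad <- m
  ix <- match(paste0("p30.aki.", health_states()), bad$params$id)
  bad$params$value[ix] <- 0.5
  bad$params$low[ix] <- 0.5
  bad$params$high[ix] <- 0.5
  expect_error(validate_aki_model(bad), "sums to 2")

  bad2 <- m
  i <- match("p_aki.assistance", bad2$params$id)
  bad2$params$low[i] <- 0.2   # lower bound above the mean
  expect_error(validate_aki_model(bad2), "p_aki.assistance")

  bad3 <- m
  i <- match("annual.ckd.post_aki.death", bad3$params$id)
  bad3$params$value[i] <- 0.98
  bad3$params$high[i] <- 0.99
  expect_error(validate_aki_model(bad3), "negative stay residual|exceed")

  incomplete <- m
  incomplete$params <- m$params[m$params$id != "utility.ckd", ]
  expect_error(validate_aki_model(incomplete), "utility.ckd")
})

test_that("annual stay probabilities are the residual of the printed exits", {
  m <- trial_model()
  P <- annual_matrix(m, "post_aki")
  expect_equal(P["ckd", "ckd"], 1 - 0.047 - 0.297)  # residual 0.656
  expect_equal(P["esrd", "death"], 0.345)
  expect_equal(P["esrd", "esrd"], 0.655)
  expect_equal(unname(rowSums(P)), rep(1, 4))
  # no backward transitions
  expect_equal(P["ckd", "normal"], 0)
  expect_equal(P["esrd", "ckd"], 0)
})

test_that("write_model/load_model round-trips numeric fields to full precision", {
  for (seed in c(11, 23)) {
    m <- random_model(seed)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_model(m, path)
    m2 <- suppressWarnings(load_model(path))
    expect_equal(m2$params$value, m$params$value, tolerance = 1e-12)
    expect_equal(m2$params$low, m$params$low, tolerance = 1e-12)
    expect_equal(m2$params$high, m$params$high, tolerance = 1e-12)
    expect_equal(m2$settings$discount_rate, m$settings$discount_rate)
  }
})

test_that("percent-unit model files are converted to fractions", {
  m <- trial_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(m, path)
  doc <- yaml::read_yaml(path)
  doc$units <- "percent"
  scale_pct <- function(x) lapply(x, function(v) {
    if (is.list(v)) scale_pct(v) else v * 100
  })
  doc$strategies <- lapply(doc$strategies, function(s) {
    s$p_aki <- scale_pct(s$p_aki); s
  })
  doc$thirty_day <- scale_pct(doc$thirty_day)
  doc$annual <- scale_pct(doc$annual)
  doc$utilities <- scale_pct(doc$utilities)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(doc, precision = 15), path2)
  m2 <- suppressWarnings(load_model(path2))
  expect_equal(m2$params$value, m$params$value, tolerance = 1e-12)
})

test_that("probability estimates enforce interval ordering", {
  expect_error(prob_estimate(0.5, 0.6, 0.7, "pX"), "pX")
  expect_error(prob_estimate(1.2, 1.1, 1.3), "<= 1")
  pe <- prob_estimate(0.106, 0.104, 0.108)
  expect_equal(pe$mean, 0.106)
})

test_that("thirty-day rows of random valid models stay row-stochastic", {
  for (seed in 1:5) {
    m <- random_model(seed)
    d30 <- thirty_day_matrix(m)
    expect_equal(unname(rowSums(d30)), c(1, 1), tolerance = 1e-12)
    for (h in c("post_aki", "no_aki")) {
      expect_equal(unname(rowSums(annual_matrix(m, h))), rep(1, 4),
                   tolerance = 1e-12)
    }
  }
})
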