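# small deterministic climate index table: one variable per window kind.
# "trace" values encode (year, window) for alignment checks; "noise"
# values are independent deterministic series for recovery checks.
toy_indices <- function(years = 1990:2019, mode = c("trace", "noise")) {
  mode <- match.arg(mode)
  tab <- tidyr::expand_grid(
    year = years,
    variable = "ppt",
    window = c(toupper(month.abb), "VP", "PW")
  )
  wn <- match(tab$window, c(toupper(month.abb), "VP", "PW"))
  if (mode == "trace") {
    tab$value <- tab$year + wn / 100 +
      ifelse(tab$window == "FEB", sin(tab$year), 0)
  } else {
    set.seed(990)
    tab <- dplyr::arrange(tab, wn, year)
    tab$value <- rnorm(nrow(tab))
    tab <- dplyr::arrange(tab, year, window)
  }
  tab
}

toy_gic <- function(years = 1990:2019, values = NULL) {
  structure(
    tibble::tibble(
      year = years,
      index = if (is.null(values)) 1 + 0.1 * sin(years) else values,
      depth = 5L
    ),
    species = "toy", class = c("gic", "tbl_df", "tbl", "data.frame")
  )
}

test_that("design matrix aligns previous-year months with a one-year lag", {
  dm <- build_design_matrix(toy_gic(), toy_indices())
  # the first chronology year has no previous-year climate and is trimmed
  expect_equal(dm$year, 1991:2019)
  # previous September of row-year 2003 is September 2002
  expect_equal(
    dm$ppt.sep[dm$year == 2003],
    2002 + 9 / 100
  )
  # current February of 2003 is February 2003
  expect_equal(
    dm$ppt.FEB[dm$year == 2003],
    2003 + 2 / 100 + sin(2003)
  )
  # current months beyond September are not screened
  expect_false("ppt.OCT" %in% names(dm))
  expect_true(all(c("ppt.VP", "ppt.PW") %in% names(dm)))
})

test_that("design matrix drops degenerate columns and short overlaps error", {
  idx <- toy_indices()
  idx$value[idx$window == "MAR"] <- 7 # zero variance
  expect_warning(dm <- build_design_matrix(toy_gic(), idx), "Dropping")
  expect_false("ppt.MAR" %in% names(dm))

  expect_error(
    build_design_matrix(toy_gic(2010:2019), toy_indices(2010:2019)),
    "overlapping years"
  )
})

test_that("bootstrap pearson reports the full-sample r and honours the seed", {
  set.seed(2)
  x <- rnorm(26)
  y <- 0.8 * x + 0.6 * rnorm(26)
  b1 <- bootstrap_pearson(x, y, seed = 42)
  expect_equal(b1$r, cor(x, y))
  expect_true(b1$ci_low > 0 || b1$ci_high < 0) # strong signal
  b2 <- bootstrap_pearson(x, y, seed = 42)
  expect_identical(b1, b2)
  b3 <- bootstrap_pearson(x, y, seed = 43)
  expect_false(identical(b1$ci_low, b3$ci_low))

  # perfect correlation
  bp <- bootstrap_pearson(x, x, seed = 1)
  expect_equal(bp$r, 1)
  expect_true(bp$significant)
})

test_that("bootstrap pearson is symmetric in (x, y) and leaves the RNG alone", {
  set.seed(3)
  x <- rnorm(30)
  y <- rnorm(30)
  bxy <- bootstrap_pearson(x, y, seed = 7)
  byx <- bootstrap_pearson(y, x, seed = 7)
  expect_equal(bxy$r, byx$r)
  expect_equal(bxy$ci_low, byx$ci_low)
  expect_equal(bxy$ci_high, byx$ci_high)

  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(bootstrap_pearson(x, y, seed = 9))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("bootstrap pearson input validation", {
  expect_error(bootstrap_pearson(1:5, 1:5), "10")
  expect_error(bootstrap_pearson(rep(1, 20), rnorm(20)), "zero variance")
  expect_error(bootstrap_pearson(rnorm(10), rnorm(11)), "equal length")
})

test_that("bootstrap CI shrinks with the sample size", {
  width <- function(n, seed) {
    set.seed(seed)
    x <- rnorm(n)
    y <- 0.5 * x + sqrt(0.75) * rnorm(n)
    b <- bootstrap_pearson(x, y, seed = seed)
    b$ci_high - b$ci_low
  }
  w26 <- mean(vapply(1:10, function(s) width(26, s), numeric(1)))
  w200 <- mean(vapply(1:10, function(s) width(200, s), numeric(1)))
  expect_lt(w200, w26)
})

test_that("correlation function recovers a programmed positive driver", {
  idx <- toy_indices(mode = "noise")
  feb <- idx$value[idx$window == "FEB"]
  set.seed(11)
  z <- as.numeric(scale(feb))
  gic <- toy_gic(values = 1 + 0.12 * z + 0.08 * rnorm(30))
  cf <- correlation_function(gic, idx, seed = 1)
  cell <- cf[cf$window == "FEB", ]
  expect_true(cell$significant)
  expect_gt(cell$r, 0)
  # and it is the strongest cell
  expect_equal(which.max(abs(cf$r)), which(cf$window == "FEB"))
})

test_that("correlation function recovers a negative driver with correct sign", {
  idx <- toy_indices(mode = "noise")
  feb <- idx$value[idx$window == "FEB"]
  set.seed(12)
  z <- as.numeric(scale(feb))
  gic <- toy_gic(values = 1 - 0.1 * z + 0.1 * rnorm(30))
  cf <- correlation_function(gic, idx, seed = 2)
  cell <- cf[cf$window == "FEB", ]
  expect_true(cell$significant)
  expect_lt(cell$r, 0)
})

test_that("correlation function output is reproducible and filterable", {
  idx <- toy_indices()
  gic <- toy_gic()
  a <- correlation_function(gic, idx, seed = 4)
  b <- correlation_function(gic, idx, seed = 4)
  expect_equal(as.data.frame(a), as.data.frame(b))
  s <- correlation_function(gic, idx, seed = 4, significant_only = TRUE)
  expect_true(all(s$significant))
  expect_equal(glance(a)$n_significant, nrow(s))
})
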